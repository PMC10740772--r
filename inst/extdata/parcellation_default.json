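{
  "name": "ppole-default",
  "regions": {
    "FOVEAL": [
      [4, 4],
      [5, 4],
      [4, 5],
      [5, 5]
    ],
    "PARAFOVEAL": [
      [3, 3],
      [4, 3],
      [5, 3],
      [6, 3],
      [3, 4],
      [6, 4],
      [3, 5],
      [6, 5],
      [3, 6],
      [4, 6],
      [5, 6],
      [6, 6]
    ],
    "PERIFOVEAL": [
      [2, 2],
      [3, 2],
      [4, 2],
      [5, 2],
      [6, 2],
      [7, 2],
      [2, 3],
      [7, 3],
      [2, 4],
      [7, 4],
      [2, 5],
      [7, 5],
      [2, 6],
      [7, 6],
      [2, 7],
      [3, 7],
      [4, 7],
      [5, 7],
      [6, 7],
      [7, 7]
    ],
    "PMB": [
      [4, 6],
      [5, 6],
      [4, 7],
      [5, 7],
      [4, 8],
      [5, 8]
    ],
    "PARAMACULAR": [
      [3, 3],
      [4, 3],
      [5, 3],
      [6, 3],
      [3, 4],
      [6, 4],
      [3, 5],
      [6, 5],
      [3, 6],
      [6, 6]
    ],
    "SN": [
      [5, 5],
      [7, 5],
      [8, 5],
      [7, 6],
      [8, 6],
      [6, 7],
      [7, 7],
      [8, 7],
      [6, 8],
      [7, 8],
      [8, 8]
    ],
    "IN": [
      [1, 5],
      [2, 5],
      [4, 5],
      [1, 6],
      [2, 6],
      [1, 7],
      [2, 7],
      [3, 7],
      [1, 8],
      [2, 8],
      [3, 8]
    ],
    "IT": [
      [1, 1],
      [2, 1],
      [3, 1],
      [4, 1],
      [1, 2],
      [2, 2],
      [3, 2],
      [4, 2],
      [1, 3],
      [2, 3],
      [1, 4],
      [2, 4],
      [4, 4]
    ],
    "ST": [
      [5, 1],
      [6, 1],
      [7, 1],
      [8, 1],
      [5, 2],
      [6, 2],
      [7, 2],
      [8, 2],
      [7, 3],
      [8, 3],
      [5, 4],
      [7, 4],
      [8, 4]
    ]
  }
}
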