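# Shared fixtures and independent oracles.

make_cells <- function(value = 100) matrix(value, 8, 8)

make_grid <- function(subject_id = "S1", eye = "OD", layer = "GCL",
                      cells = make_cells(), quality = 30,
                      orientation = "native") {
  thickness_grid(subject_id, eye, layer, cells, quality, orientation)
}

make_subject <- function(subject_id = "S1", cohort = "HC", age = 70,
                         sex = "F", grids = list(make_grid(subject_id))) {
  ppole_subject(subject_id, cohort, age, sex, grids)
}

# Independent AUROC oracle: explicit pairwise loop with 1 / 0.5 / 0 credit.
brute_force_auroc <- function(x, y) {
  total <- 0
  for (xi in x) for (yj in y) {
    total <- total + if (xi > yj) 1 else if (xi == yj) 0.5 else 0
  }
  total / (length(x) * length(y))
}

# Independent sample-size oracle: smallest n per group whose two-sided
# z-test power reaches the target, found by scanning n upward.
brute_force_sample_size <- function(delta, sigma, alpha, power) {
  zc <- qnorm(1 - alpha / 2)
  for (n in 2:10000) {
    ncp <- delta / (sigma * sqrt(2 / n))
    pw <- pnorm(ncp - zc) + pnorm(-ncp - zc)
    if (pw >= power) return(n)
  }
  stop("no n found")
}

# A subject whose grids hold anatomically anchored values: cell (r,c) of
# every layer carries 100 + r + c/10 in right-normalized orientation.
make_anatomical_subject <- function(subject_id, cohort, eye,
                                    layers = PPOLE_LAYERS) {
  anat <- outer(1:8, 1:8, function(r, c) 100 + r + c / 10)
  grids <- lapply(layers, function(L) {
    cells <- if (eye == "OS") anat[, 8:1] else anat
    thickness_grid(subject_id, eye, L, cells, quality = 30,
                   orientation = "native")
  })
  ppole_subject(subject_id, cohort, 70, "F", grids)
}

# Small three-cohort set with a constant per-cohort offset on every cell,
# handy for pipeline-level checks with known orderings.
make_offset_cohorts <- function(n_per = 4, offsets = c(HC = 0, MS = -10,
                                                       AD = -5),
                                layer_set = PPOLE_LAYERS, jitter_seed = 42) {
  withr::with_seed(jitter_seed, {
    subjects <- list()
    for (g in names(offsets)) {
      for (i in seq_len(n_per)) {
        base <- make_cells(100 + offsets[[g]]) +
          matrix(rnorm(64, 0, 0.5), 8, 8) + rnorm(1, 0, 1)
        grids <- lapply(layer_set, function(L)
          thickness_grid(sprintf("%s%02d", g, i), "OD", L, base,
                         quality = 30, orientation = "right-normalized"))
        subjects[[length(subjects) + 1L]] <-
          ppole_subject(sprintf("%s%02d", g, i), g, 70, "F", grids)
      }
    }
    subjects
  })
}

# Default scenario rescaled to a given per-cohort size.
scenario_with_n <- function(n, seed = 20231L, parc = default_parcellation()) {
  sc <- default_scenario(parc, seed = seed)
  synthetic_scenario(sc$name, c(HC = n, MS = n, AD = n), sc$baseline,
                     sc$effect, sc$sigma_subject, sc$sigma_cell,
                     sc$age_mean, sc$age_sd, seed)
}
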