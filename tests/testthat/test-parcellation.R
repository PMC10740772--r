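test_that("default parcellation satisfies every structural invariant", {
  parc <- default_parcellation()
  expect_setequal(names(parc$regions), PPOLE_REGIONS)
  # exhaustive re-check, independent of the constructor's validation
  key <- function(m) paste(m[, 1], m[, 2])
  for (rn in PPOLE_REGIONS) {
    cells <- parc$regions[[rn]]
    expect_gt(nrow(cells), 0)
    expect_true(all(cells >= 1 & cells <= 8))
    expect_false(anyDuplicated(key(cells)) > 0)
  }
  for (fam in list(RING_REGIONS, ZONE_REGIONS)) {
    all_keys <- unlist(lapply(parc$regions[fam], key))
    expect_false(anyDuplicated(all_keys) > 0)
  }
  # zones tile the full grid; rings cover the central 6x6
  expect_setequal(unlist(lapply(parc$regions[ZONE_REGIONS], key)),
                  key(as.matrix(expand.grid(1:8, 1:8))))
  expect_setequal(unlist(lapply(parc$regions[RING_REGIONS], key)),
                  key(as.matrix(expand.grid(2:7, 2:7))))
  # concentricity: each ring's cells are 8-adjacent to the enclosed ring
  cheb_adj <- function(a, b) {
    any(apply(a, 1, function(cell)
      any(pmax(abs(b[, 1] - cell[1]), abs(b[, 2] - cell[2])) <= 1)))
  }
  expect_true(cheb_adj(parc$regions$PARAFOVEAL, parc$regions$FOVEAL))
  expect_true(cheb_adj(parc$regions$PERIFOVEAL, parc$regions$PARAFOVEAL))
  # the PMB sits on the nasal half, straddling the horizontal midline
  expect_true(all(parc$regions$PMB[, 2] >= 5))
  expect_setequal(unique(parc$regions$PMB[, 1]), 4:5)
})

test_that("parcellation constructor reports invariant violations", {
  parc <- default_parcellation()
  regions <- parc$regions
  bad <- regions
  bad$PARAFOVEAL <- rbind(bad$PARAFOVEAL, c(4L, 4L)) # cell already in FOVEAL
  expect_error(parcellation("bad", bad), "overlap at cell \\(4,4\\)")
  bad <- regions
  bad$SN <- rbind(bad$SN, c(0L, 5L))
  expect_error(parcellation("bad", bad), "outside the 8x8 grid")
  bad <- regions
  names(bad)[names(bad) == "PMB"] <- "MACULAR"
  expect_error(parcellation("bad", bad), "unknown region")
  bad <- regions
  bad$FOVEAL <- bad$FOVEAL[0, , drop = FALSE]
  expect_error(parcellation("bad", bad), "empty")
  bad <- regions
  # the grid corner is two steps from the parafoveal ring: not concentric
  bad$PARAFOVEAL <- rbind(bad$PARAFOVEAL, c(1L, 1L))
  expect_error(parcellation("bad", bad), "detached|8-connected")
})

test_that("region means follow the skip-missing unweighted-mean rule", {
  parc <- default_parcellation()
  g <- make_grid(cells = make_cells(100), orientation = "right-normalized")
  for (rn in PPOLE_REGIONS)
    expect_equal(region_mean(g, parc, rn)$mean_thickness, 100)
  # FOVEAL = {(4,4),(4,5),(5,4),(5,5)}: plant known values there
  cells <- make_cells(0)
  cells[4, 4] <- 80; cells[4, 5] <- 90; cells[5, 4] <- 100; cells[5, 5] <- 110
  g <- make_grid(cells = cells, orientation = "right-normalized")
  obs <- region_mean(g, parc, "FOVEAL")
  expect_equal(obs$mean_thickness, 95)
  expect_equal(obs$n_cells_used, 4L)
  cells[5, 5] <- NA
  g <- make_grid(cells = cells, orientation = "right-normalized")
  obs <- region_mean(g, parc, "FOVEAL")
  expect_equal(obs$mean_thickness, 90)
  expect_equal(obs$n_cells_used, 3L)
  cells[4, 4] <- cells[4, 5] <- cells[5, 4] <- NA
  g <- make_grid(cells = cells, orientation = "right-normalized")
  obs <- region_mean(g, parc, "FOVEAL")
  expect_true(is.na(obs$mean_thickness))
  expect_equal(obs$n_cells_used, 0L)
  expect_error(region_mean(make_grid(), parc, "FOVEAL"), "right-normalized")
})

test_that("region mean is permutation-invariant in member-cell values", {
  parc <- default_parcellation()
  withr::with_seed(3, {
    for (i in 1:10) {
      rn <- sample(PPOLE_REGIONS, 1)
      cells <- matrix(runif(64, 50, 150), 8, 8)
      g1 <- make_grid(cells = cells, orientation = "right-normalized")
      m <- parc$regions[[rn]]
      perm <- cells
      perm[m] <- cells[m][sample(nrow(m))]
      g2 <- make_grid(cells = perm, orientation = "right-normalized")
      expect_equal(region_mean(g2, parc, rn)$mean_thickness,
                   region_mean(g1, parc, rn)$mean_thickness)
    }
  })
})

test_that("adding a cell equal to the current mean leaves the mean fixed", {
  parc <- default_parcellation()
  cells <- make_cells(NA_real_)
  m <- parc$regions$PERIFOVEAL
  vals <- seq(80, 120, length.out = 10)
  cells[m[1:10, ]] <- vals
  g <- make_grid(cells = cells, orientation = "right-normalized")
  before <- region_mean(g, parc, "PERIFOVEAL")
  cells[m[11, , drop = FALSE]] <- mean(vals)
  g2 <- make_grid(cells = cells, orientation = "right-normalized")
  after <- region_mean(g2, parc, "PERIFOVEAL")
  expect_equal(after$mean_thickness, before$mean_thickness)
  expect_equal(after$n_cells_used, before$n_cells_used + 1L)
})

test_that("mirrored grid with mirrored parcellation gives identical means", {
  parc <- default_parcellation()
  mirrored <- lapply(parc$regions, function(m)
    cbind(m[, 1], 9L - m[, 2]))
  parc_m <- parcellation("mirrored", mirrored)
  withr::with_seed(5, {
    cells <- matrix(runif(64, 50, 150), 8, 8)
    g <- make_grid(cells = cells, orientation = "right-normalized")
    g_m <- make_grid(cells = cells[, 8:1],
                     orientation = "right-normalized")
    for (rn in PPOLE_REGIONS)
      expect_equal(region_mean(g_m, parc_m, rn)$mean_thickness,
                   region_mean(g, parc, rn)$mean_thickness)
  })
})

test_that("regionize_cohort yields one ordered row per eye-layer-region", {
  parc <- default_parcellation()
  subs <- list(make_anatomical_subject("S1", "HC", "OD"),
               make_anatomical_subject("S2", "MS", "OD"))
  subs <- normalize_subjects(subs)
  obs <- regionize_cohort(subs, parc)
  expect_equal(nrow(obs), 2 * 1 * 4 * 9)
  expect_equal(obs$subject_id, rep(c("S1", "S2"), each = 36))
  expect_equal(obs$layer[1:36], rep(PPOLE_LAYERS, each = 9))
  expect_equal(obs$region[1:9], PPOLE_REGIONS)
  expect_equal(nrow(regionize_cohort(list(), parc)), 0)
  # both eyes double the observations per layer x region
  both <- ppole_subject("S3", "AD", 70, "F", list(
    make_grid("S3", "OD", "GCL", orientation = "right-normalized"),
    make_grid("S3", "OS", "GCL", orientation = "right-normalized")))
  obs2 <- regionize_cohort(list(both), parc)
  expect_equal(nrow(obs2), 2 * 9)
})

test_that("an OS eye analyzed after normalization matches its OD twin", {
  parc <- default_parcellation()
  od <- make_anatomical_subject("R1", "HC", "OD")
  os <- make_anatomical_subject("R1", "HC", "OS")
  obs_od <- regionize_cohort(normalize_subjects(list(od)), parc)
  obs_os <- regionize_cohort(normalize_subjects(list(os)), parc)
  expect_equal(obs_os$mean_thickness, obs_od$mean_thickness)
})

test_that("user parcellation JSON round-trips through load_parcellation", {
  parc <- default_parcellation()
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(name = "custom",
         regions = lapply(parc$regions, function(m) unname(m))),
    path, auto_unbox = TRUE)
  parc2 <- load_parcellation(path)
  expect_equal(parc2$source, "user-config")
  expect_equal(parc2$regions, parc$regions, ignore_attr = TRUE)
})
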