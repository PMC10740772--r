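# Parcellation of the 8x8 posterior-pole grid into the nine analysis
# regions: three concentric rings (foveal, parafoveal, perifoveal) and six
# zones (papillomacular bundle PMB, paramacular, and the four quadrants
# SN, IN, IT, ST). Region membership is a first-class configurable input:
# the built-in default is a documented approximation anchored to the
# right-normalized coordinate frame ((1,1) infero-temporal, (8,8)
# supero-nasal), and every analysis records which parcellation it used.

#' Analysis region identifiers
#'
#' Nine regions in two families: the RING family of concentric rings
#' (FOVEAL, PARAFOVEAL, PERIFOVEAL) and the ZONE family (PMB, PARAMACULAR,
#' SN, IN, IT, ST). Regions are disjoint within a family; a cell may belong
#' to one ring and one zone simultaneously.
#' @export
PPOLE_REGIONS <- c("FOVEAL", "PARAFOVEAL", "PERIFOVEAL",
                   "PMB", "PARAMACULAR", "SN", "IN", "IT", "ST")

#' @rdname PPOLE_REGIONS
#' @export
RING_REGIONS <- c("FOVEAL", "PARAFOVEAL", "PERIFOVEAL")

#' @rdname PPOLE_REGIONS
#' @export
ZONE_REGIONS <- c("PMB", "PARAMACULAR", "SN", "IN", "IT", "ST")

#' Construct and validate a parcellation
#'
#' @param name Label recorded in analysis provenance.
#' @param regions Named list mapping each region in [PPOLE_REGIONS] to an
#'   n x 2 matrix (or list of `c(row, col)` pairs) of 1-based cell indices
#'   in right-normalized orientation.
#' @param source `"default"` for the packaged map, `"user-config"` for a
#'   user-supplied one.
#' @return An object of class `parcellation`. Errors name the offending
#'   region or cell when an invariant is violated.
#' @details Validated invariants: all cells within the 8x8 grid; every
#'   region non-empty; rings pairwise disjoint and zones pairwise disjoint;
#'   rings structurally concentric (the foveal block is 8-connected, and
#'   each outer ring is chained by 8-adjacency to the ring it encloses).
#' @export
parcellation <- function(name, regions,
                         source = c("user-config", "default")) {
  source <- match.arg(source)
  unknown <- setdiff(names(regions), PPOLE_REGIONS)
  if (length(unknown))
    stop("unknown region name: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(PPOLE_REGIONS, names(regions))
  if (length(missing))
    stop("parcellation lacks region(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  regions <- lapply(regions, function(cells) {
    if (is.list(cells)) cells <- do.call(rbind, cells)
    cells <- matrix(as.integer(cells), ncol = 2,
                    dimnames = list(NULL, c("row", "col")))
    cells
  })
  for (rn in PPOLE_REGIONS) {
    cells <- regions[[rn]]
    if (nrow(cells) == 0) stop("region ", rn, " is empty", call. = FALSE)
    bad <- which(is.na(cells) | cells < 1 | cells > GRID_DIM,
                 arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("region %s: cell (%s,%s) outside the 8x8 grid", rn,
                   cells[bad[1, 1], 1], cells[bad[1, 1], 2]), call. = FALSE)
    if (anyDuplicated(cell_keys(cells)))
      stop("region ", rn, " lists a cell twice", call. = FALSE)
  }
  check_family_disjoint(regions, RING_REGIONS)
  check_family_disjoint(regions, ZONE_REGIONS)
  check_concentric(regions)
  structure(list(name = as.character(name), source = source,
                 regions = regions[PPOLE_REGIONS]),
            class = "parcellation")
}

cell_keys <- function(cells) (cells[, 1] - 1L) * GRID_DIM + cells[, 2]

check_family_disjoint <- function(regions, family) {
  keys <- lapply(regions[family], cell_keys)
  for (i in seq_along(family)[-1]) for (j in seq_len(i - 1)) {
    shared <- intersect(keys[[i]], keys[[j]])
    if (length(shared)) {
      r <- (shared[1] - 1L) %/% GRID_DIM + 1L
      c <- (shared[1] - 1L) %% GRID_DIM + 1L
      stop(sprintf("regions %s and %s overlap at cell (%d,%d)",
                   family[i], family[j], r, c), call. = FALSE)
    }
  }
}

# 8-neighbourhood adjacency between two cell sets (Chebyshev distance <= 1)
adjacent_any <- function(cell, cells) {
  any(abs(cells[, 1] - cell[1]) <= 1 & abs(cells[, 2] - cell[2]) <= 1)
}

check_connected <- function(cells, label) {
  n <- nrow(cells)
  if (n == 1) return(invisible())
  visited <- rep(FALSE, n)
  visited[1] <- TRUE
  repeat {
    grew <- FALSE
    for (i in which(!visited)) {
      if (adjacent_any(cells[i, ], cells[visited, , drop = FALSE])) {
        visited[i] <- TRUE
        grew <- TRUE
      }
    }
    if (all(visited)) return(invisible())
    if (!grew) stop(label, " is not 8-connected", call. = FALSE)
  }
}

check_concentric <- function(regions) {
  check_connected(regions$FOVEAL, "FOVEAL block")
  for (pair in list(c("PARAFOVEAL", "FOVEAL"),
                    c("PERIFOVEAL", "PARAFOVEAL"))) {
    outer <- regions[[pair[1]]]
    inner <- regions[[pair[2]]]
    ok <- vapply(seq_len(nrow(outer)), function(i) {
      adjacent_any(outer[i, ], inner) ||
        adjacent_any(outer[i, ], outer[-i, , drop = FALSE])
    }, logical(1))
    if (!all(ok)) {
      det <- outer[!ok, , drop = FALSE]
      stop(sprintf("region %s: cell (%d,%d) is detached from the %s ring",
                   pair[1], det[1, 1], det[1, 2], pair[2]), call. = FALSE)
    }
    touches <- any(vapply(seq_len(nrow(outer)), function(i)
      adjacent_any(outer[i, ], inner), logical(1)))
    if (!touches)
      stop("region ", pair[1], " does not touch ", pair[2], call. = FALSE)
  }
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> '%s' (%s)\n", x$name, x$source))
  for (rn in PPOLE_REGIONS)
    cat(sprintf("  %-11s %2d cells\n", rn, nrow(x$regions[[rn]])))
  invisible(x)
}

#' Load a parcellation from JSON or use the packaged default
#'
#' JSON schema: `{"name": str, "regions": {"FOVEAL": [[row, col], ...],
#' ...}}` with 1-based indices in right-normalized orientation.
#'
#' @param path Path to a parcellation JSON file, or `NULL` for the packaged
#'   default map.
#' @return A validated [parcellation()].
#' @export
load_parcellation <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "parcellation_default.json",
                        package = "ppoleauc", mustWork = TRUE)
    src <- "default"
  } else src <- "user-config"
  cfg <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  regions <- lapply(cfg$regions, function(m) matrix(m, ncol = 2))
  parcellation(cfg$name, regions, source = src)
}

#' @rdname load_parcellation
#' @export
default_parcellation <- function() load_parcellation(NULL)

# ---------------------------------------------------------------------------
# Region means

#' Mean thickness of one region of one grid
#'
#' Unweighted arithmetic mean over the region's present cells (all cells
#' cover equal 3x3-degree areas, so no area weighting is needed). Missing
#' cells are skipped; a region whose member cells are all missing yields a
#' missing mean with `n_cells_used = 0`.
#'
#' @param grid A right-normalized [thickness_grid()].
#' @param parc A [parcellation()].
#' @param region One of [PPOLE_REGIONS].
#' @return One-row data frame: `subject_id`, `eye`, `layer`, `region`,
#'   `mean_thickness`, `n_cells_used`.
#' @export
region_mean <- function(grid, parc, region) {
  stopifnot(inherits(grid, "thickness_grid"), inherits(parc, "parcellation"))
  if (grid$orientation != "right-normalized")
    stop("grid must be right-normalized before region averaging",
         call. = FALSE)
  region <- match.arg(region, PPOLE_REGIONS)
  vals <- grid$cells[parc$regions[[region]]]
  n_used <- sum(!is.na(vals))
  data.frame(subject_id = grid$subject_id, eye = grid$eye,
             layer = grid$layer, region = region,
             mean_thickness = if (n_used) mean(vals, na.rm = TRUE)
                              else NA_real_,
             n_cells_used = n_used, stringsAsFactors = FALSE)
}

#' Region observations for a whole cohort
#'
#' One observation per (eye, layer, region) across all subjects, in the
#' deterministic order (subject_id, eye, layer, region).
#'
#' @param subjects List of [ppole_subject()] with normalized,
#'   quality-filtered grids.
#' @param parc A [parcellation()].
#' @return Data frame with columns `subject_id`, `cohort`, `eye`, `layer`,
#'   `region`, `mean_thickness`, `n_cells_used`.
#' @export
regionize_cohort <- function(subjects, parc) {
  rows <- list()
  for (s in subjects) {
    for (g in s$grids) {
      for (region in PPOLE_REGIONS) {
        obs <- region_mean(g, parc, region)
        obs$cohort <- s$cohort
        rows[[length(rows) + 1L]] <- obs
      }
    }
  }
  if (!length(rows))
    return(data.frame(subject_id = character(), cohort = character(),
                      eye = character(), layer = character(),
                      region = character(), mean_thickness = numeric(),
                      n_cells_used = integer(), stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df <- df[, c("subject_id", "cohort", "eye", "layer", "region",
               "mean_thickness", "n_cells_used")]
  df <- df[order(df$subject_id, df$eye, match(df$layer, PPOLE_LAYERS),
                 match(df$region, PPOLE_REGIONS)), ]
  rownames(df) <- NULL
  df
}
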