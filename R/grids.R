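# Core data structures for posterior-pole thickness grids.
#
# Coordinate convention: rows and columns are 1-based. After laterality
# normalization every grid is in right-eye orientation, with cell (1,1) at
# the infero-temporal corner and (8,8) at the supero-nasal corner. Rows run
# inferior -> superior, columns temporal -> nasal (the optic disc lies off
# the nasal edge, beyond column 8).

#' Retinal layers analysed by the package
#'
#' The four neural-retina layers reported by the Posterior Pole protocol
#' that carry diagnostic signal in neurodegeneration: retinal nerve fibre
#' layer (RNFL), ganglion cell layer (GCL), inner plexiform layer (IPL) and
#' outer nuclear layer (ONL).
#' @export
PPOLE_LAYERS <- c("RNFL", "GCL", "IPL", "ONL")

#' Cohort labels
#'
#' Healthy controls (HC), relapsing-remitting multiple sclerosis (MS) and
#' Alzheimer's disease (AD).
#' @export
PPOLE_COHORTS <- c("HC", "MS", "AD")

#' Eye laterality codes
#'
#' OD = right eye, OS = left eye.
#' @export
PPOLE_EYES <- c("OD", "OS")

GRID_DIM <- 8L
THICKNESS_MAX <- 1000 # sanity bound in micrometres

#' Construct a single-eye, single-layer thickness grid
#'
#' An 8x8 map of mean retinal thickness (micrometres) for one layer of one
#' eye, as produced by the Spectralis Posterior Pole protocol (64 cells of
#' 3x3 degrees each). Missing cells are `NA`.
#'
#' @param subject_id Opaque subject identifier.
#' @param eye `"OD"` (right) or `"OS"` (left).
#' @param layer One of [PPOLE_LAYERS].
#' @param cells 8x8 numeric matrix of thicknesses in micrometres; `NA`
#'   marks a missing cell. Values must be in `[0, 1000)`.
#' @param quality Scan quality score in `[0, 40]` (device convention:
#'   0 poor, 40 excellent).
#' @param orientation `"native"` (as scanned) or `"right-normalized"`
#'   (already mirrored to the right-eye convention).
#' @return An object of class `thickness_grid`.
#' @seealso [normalize_laterality()], [quality_filter()]
#' @export
thickness_grid <- function(subject_id, eye, layer, cells, quality,
                           orientation = c("native", "right-normalized")) {
  orientation <- match.arg(orientation)
  eye <- match.arg(eye, PPOLE_EYES)
  layer <- match.arg(layer, PPOLE_LAYERS)
  cells <- as.matrix(cells)
  if (!is.numeric(cells) || !identical(dim(cells), c(GRID_DIM, GRID_DIM)))
    stop("`cells` must be a numeric 8x8 matrix", call. = FALSE)
  bad <- !is.na(cells) & (cells < 0 | cells >= THICKNESS_MAX)
  if (any(bad))
    stop(sprintf("thickness out of [0, %d) at cell (%d,%d)", THICKNESS_MAX,
                 which(bad, arr.ind = TRUE)[1, 1],
                 which(bad, arr.ind = TRUE)[1, 2]), call. = FALSE)
  if (!is.numeric(quality) || length(quality) != 1L || is.na(quality) ||
      quality < 0 || quality > 40)
    stop("`quality` must be a single value in [0, 40]", call. = FALSE)
  dimnames(cells) <- NULL
  structure(
    list(subject_id = as.character(subject_id), eye = eye, layer = layer,
         cells = cells, quality = as.numeric(quality),
         orientation = orientation),
    class = "thickness_grid")
}

#' @export
print.thickness_grid <- function(x, ...) {
  cat(sprintf("<thickness_grid> subject %s, eye %s, layer %s (%s)\n",
              x$subject_id, x$eye, x$layer, x$orientation))
  cat(sprintf("  quality %.1f, %d/64 cells present, mean %.1f um\n",
              x$quality, sum(!is.na(x$cells)),
              mean(x$cells, na.rm = TRUE)))
  invisible(x)
}

#' Construct a subject record
#'
#' Bundles a subject's metadata with their per-eye, per-layer thickness
#' grids. A subject contributes at most two lateralities per layer.
#'
#' @param subject_id Opaque identifier.
#' @param cohort One of [PPOLE_COHORTS].
#' @param age Age in years.
#' @param sex `"M"` or `"F"`.
#' @param grids List of [thickness_grid()] objects belonging to the subject.
#' @return An object of class `ppole_subject`.
#' @export
ppole_subject <- function(subject_id, cohort, age, sex, grids = list()) {
  cohort <- match.arg(cohort, PPOLE_COHORTS)
  sex <- match.arg(sex, c("M", "F"))
  stopifnot(all(vapply(grids, inherits, logical(1), "thickness_grid")))
  key <- vapply(grids, function(g) paste(g$eye, g$layer), character(1))
  if (anyDuplicated(key))
    stop("duplicate (eye, layer) grid for subject ", subject_id,
         call. = FALSE)
  structure(
    list(subject_id = as.character(subject_id), cohort = cohort,
         age = as.numeric(age), sex = sex, grids = grids),
    class = "ppole_subject")
}

#' @export
print.ppole_subject <- function(x, ...) {
  cat(sprintf("<ppole_subject> %s: cohort %s, age %.0f, sex %s, %d grids\n",
              x$subject_id, x$cohort, x$age, x$sex, length(x$grids)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# CSV input / output
#
# Long format, one row per grid cell:
#   subject_id, cohort, age, sex, eye, layer, quality, row, col, thickness_um
# Missing cells are simply absent rows; a fully absent (row, col) on read
# becomes an NA cell.

GRID_TABLE_COLUMNS <- c("subject_id", "cohort", "age", "sex", "eye", "layer",
                        "quality", "row", "col", "thickness_um")

#' Read subjects from a long-format grid table
#'
#' Parses a UTF-8 CSV with one row per grid cell into a list of subjects.
#' Expected columns (renameable via `schema`): `subject_id`, `cohort`
#' (HC/MS/AD), `age`, `sex` (M/F), `eye` (OD/OS), `layer`
#' (RNFL/GCL/IPL/ONL), `quality` (0-40), `row` and `col` (1-8) and
#' `thickness_um`. Cells absent from the file become missing (`NA`) cells;
#' a duplicated (subject, eye, layer, row, col) is an integrity error.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector mapping the canonical
#'   column names to the names used in the file, e.g.
#'   `c(thickness_um = "value")`.
#' @return List of [ppole_subject()] objects, ordered by subject id. Grids
#'   are tagged with `orientation = "native"`.
#' @export
read_grid_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # read everything as character ("F" would otherwise parse as logical),
  # then convert the numeric columns explicitly
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      idx <- match(schema[[canon]], names(df))
      if (is.na(idx))
        stop("schema maps ", canon, " to missing column ", schema[[canon]],
             call. = FALSE)
      names(df)[idx] <- canon
    }
  }
  missing_cols <- setdiff(GRID_TABLE_COLUMNS, names(df))
  if (length(missing_cols))
    stop("grid table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0) return(list())
  for (col in c("age", "quality", "thickness_um"))
    df[[col]] <- as.numeric(df[[col]])
  for (col in c("row", "col")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    df[[col]] <- ifelse(is.na(v) | v != floor(v), NA_integer_,
                        as.integer(v))
  }

  check_enum <- function(col, allowed) {
    bad <- which(!(df[[col]] %in% allowed))
    if (length(bad))
      stop(sprintf("unknown %s '%s' at data line %d", col,
                   df[[col]][bad[1]], bad[1]), call. = FALSE)
  }
  check_enum("cohort", PPOLE_COHORTS)
  check_enum("eye", PPOLE_EYES)
  check_enum("layer", PPOLE_LAYERS)
  check_enum("sex", c("M", "F"))
  for (col in c("row", "col")) {
    v <- df[[col]]
    bad <- which(is.na(v) | v != as.integer(v) | v < 1 | v > GRID_DIM)
    if (length(bad))
      stop(sprintf("%s=%s outside 1-%d at data line %d", col, v[bad[1]],
                   GRID_DIM, bad[1]), call. = FALSE)
  }
  key <- paste(df$subject_id, df$eye, df$layer, df$row, df$col, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate cell at data line ", which(duplicated(key))[1],
         call. = FALSE)

  subjects <- list()
  for (sid in sort(unique(df$subject_id))) {
    sdf <- df[df$subject_id == sid, , drop = FALSE]
    meta <- sdf[1, c("cohort", "age", "sex")]
    grids <- list()
    gkey <- unique(sdf[, c("eye", "layer")])
    gkey <- gkey[order(gkey$eye, match(gkey$layer, PPOLE_LAYERS)), ,
                 drop = FALSE]
    for (i in seq_len(nrow(gkey))) {
      gdf <- sdf[sdf$eye == gkey$eye[i] & sdf$layer == gkey$layer[i], ,
                 drop = FALSE]
      cells <- matrix(NA_real_, GRID_DIM, GRID_DIM)
      cells[cbind(gdf$row, gdf$col)] <- gdf$thickness_um
      grids[[length(grids) + 1L]] <- thickness_grid(
        sid, gkey$eye[i], gkey$layer[i], cells,
        quality = gdf$quality[1], orientation = "native")
    }
    subjects[[length(subjects) + 1L]] <- ppole_subject(
      sid, meta$cohort, meta$age, meta$sex, grids)
  }
  subjects
}

#' Write subjects to a long-format grid table
#'
#' Inverse of [read_grid_table()]: serializes every present cell of every
#' grid to one CSV row, full precision, missing cells omitted. Reading the
#' file back reproduces the subjects up to floating-point representation.
#'
#' @param subjects List of [ppole_subject()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_table <- function(subjects, path) {
  rows <- list()
  for (s in subjects) {
    for (g in s$grids) {
      idx <- which(!is.na(g$cells), arr.ind = TRUE)
      if (nrow(idx) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s$subject_id, cohort = s$cohort, age = s$age,
        sex = s$sex, eye = g$eye, layer = g$layer, quality = g$quality,
        row = idx[, 1], col = idx[, 2],
        thickness_um = g$cells[idx], stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 10)),
                    GRID_TABLE_COLUMNS)
  # full precision: format numerics explicitly so write.csv does not round
  df$thickness_um <- format(df$thickness_um, digits = 17, trim = TRUE,
                            scientific = FALSE)
  df$age <- format(df$age, digits = 17, trim = TRUE, scientific = FALSE)
  df$quality <- format(df$quality, digits = 17, trim = TRUE,
                       scientific = FALSE)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Laterality and quality

mirror_cells <- function(cells) cells[, GRID_DIM:1, drop = FALSE]

#' Normalize a grid to right-eye orientation
#'
#' Left-eye (OS) grids are mirrored about the vertical axis (column `c`
#' maps to column `9 - c`; rows unchanged) so that the nasal/temporal axis
#' matches the right-eye convention used by the parcellation: after
#' normalization, cell (1,1) is infero-temporal and (8,8) supero-nasal for
#' every eye. Right-eye (OD) grids keep their cell values. Idempotent on
#' already-normalized grids.
#'
#' @param grid A [thickness_grid()].
#' @return The grid with `orientation = "right-normalized"`.
#' @export
normalize_laterality <- function(grid) {
  stopifnot(inherits(grid, "thickness_grid"))
  if (grid$orientation == "right-normalized") return(grid)
  if (grid$eye == "OS") grid$cells <- mirror_cells(grid$cells)
  grid$orientation <- "right-normalized"
  grid
}

#' Normalize every grid of every subject
#'
#' @param subjects List of [ppole_subject()] objects.
#' @return The subjects with all grids right-normalized.
#' @export
normalize_subjects <- function(subjects) {
  lapply(subjects, function(s) {
    s$grids <- lapply(s$grids, normalize_laterality)
    s
  })
}

#' Filter grids on scan quality
#'
#' Keeps grids whose quality score is strictly greater than `min_score`
#' (device scale 0-40); the conventional cut-off retains only scans scoring
#' above 25. Input order is preserved.
#'
#' @param grids List of [thickness_grid()] objects.
#' @param min_score Strict lower bound on the quality score (default 25).
#' @return The retained grids; a message reports how many were removed.
#' @export
quality_filter <- function(grids, min_score = 25) {
  keep <- vapply(grids, function(g) g$quality > min_score, logical(1))
  n_removed <- sum(!keep)
  if (n_removed > 0)
    message(n_removed, " grid(s) removed by quality filter (score <= ",
            min_score, ")")
  if (all(!keep) && length(grids) > 0)
    warning("quality filter removed every grid", call. = FALSE)
  grids[keep]
}

#' Apply the quality filter within each subject
#'
#' @inheritParams quality_filter
#' @param subjects List of [ppole_subject()] objects.
#' @return Subjects with sub-threshold grids dropped (subjects left with no
#'   grids are retained with an empty grid list).
#' @export
quality_filter_subjects <- function(subjects, min_score = 25) {
  lapply(subjects, function(s) {
    s$grids <- suppressMessages(quality_filter(s$grids, min_score))
    s
  })
}

#' Reduce each subject to a single eye
#'
#' The default analysis uses eyes as units (each eye contributes one
#' observation per layer and region). To address within-subject correlation
#' between fellow eyes, this helper keeps one laterality per subject,
#' preferring `prefer` when both are present.
#'
#' @param subjects List of [ppole_subject()] objects.
#' @param prefer Laterality kept when a subject has both eyes (default OD).
#' @return Subjects with at most one laterality each.
#' @export
one_eye_per_subject <- function(subjects, prefer = c("OD", "OS")) {
  prefer <- match.arg(prefer)
  lapply(subjects, function(s) {
    eyes <- unique(vapply(s$grids, `[[`, character(1), "eye"))
    if (length(eyes) > 1) {
      keep_eye <- if (prefer %in% eyes) prefer else eyes[1]
      s$grids <- Filter(function(g) g$eye == keep_eye, s$grids)
    }
    s
  })
}
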