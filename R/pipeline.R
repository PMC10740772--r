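# Cohort comparisons: assemble per-region two-sample sets, compute folded
# AUROCs with confidence intervals across the layer x region design, and
# serialize the resulting tables. No multiplicity adjustment is applied
# across the 36 layer x region cells: significance is the fixed folded
# AUROC > 0.75 rule, cell by cell.

#' Specify a cohort comparison
#'
#' @param label Short label used in output file names (e.g. `"HC_vs_MS"`).
#' @param group_x,group_y Cohort selectors: one of `"HC"`, `"MS"`, `"AD"`
#'   or the pooled patient group `"MS+AD"`. `group_x` is the first-named
#'   group (conventionally the one expected thicker); folded reporting
#'   makes results orientation-invariant.
#' @param layers,regions Subsets of [PPOLE_LAYERS] / [PPOLE_REGIONS]
#'   (default: all, the full 4 x 9 design).
#' @param n_boot,ci_seed,level Bootstrap settings for [auroc_ci()].
#' @param ci_method CI method (see [auroc_ci()]).
#' @param threshold Significance threshold on the folded AUROC.
#' @return An object of class `comparison_spec`.
#' @export
comparison_spec <- function(label, group_x, group_y,
                            layers = PPOLE_LAYERS, regions = PPOLE_REGIONS,
                            n_boot = 2000, ci_seed = 1L, level = 0.95,
                            ci_method = "bootstrap", threshold = 0.75) {
  selectors <- c(PPOLE_COHORTS, "MS+AD")
  group_x <- match.arg(group_x, selectors)
  group_y <- match.arg(group_y, selectors)
  if (identical(group_x, group_y))
    stop("group_x and group_y must differ", call. = FALSE)
  layers <- match.arg(layers, PPOLE_LAYERS, several.ok = TRUE)
  regions <- match.arg(regions, PPOLE_REGIONS, several.ok = TRUE)
  structure(list(label = label, group_x = group_x, group_y = group_y,
                 layers = layers, regions = regions,
                 n_boot = as.integer(n_boot), ci_seed = as.integer(ci_seed),
                 level = level, ci_method = ci_method,
                 threshold = threshold),
            class = "comparison_spec")
}

#' The four preset cohort comparisons
#'
#' Controls vs pooled patients, controls vs MS, controls vs AD, and MS vs
#' AD — the full comparison design over the three cohorts.
#'
#' @param ... Arguments forwarded to every [comparison_spec()] (e.g.
#'   `n_boot`, `ci_seed`, `ci_method`).
#' @return Named list of four `comparison_spec`s.
#' @export
preset_comparisons <- function(...) {
  list(HC_vs_MSAD = comparison_spec("HC_vs_MSAD", "HC", "MS+AD", ...),
       HC_vs_MS = comparison_spec("HC_vs_MS", "HC", "MS", ...),
       HC_vs_AD = comparison_spec("HC_vs_AD", "HC", "AD", ...),
       MS_vs_AD = comparison_spec("MS_vs_AD", "MS", "AD", ...))
}

select_cohort <- function(obs, selector) {
  groups <- if (selector == "MS+AD") c("MS", "AD") else selector
  obs[obs$cohort %in% groups, , drop = FALSE]
}

# Deterministic per-cell CI seed, independent of group order so swapped
# comparisons reproduce identical intervals.
cell_seed <- function(base, layer, region) {
  as.integer((as.numeric(base) + 997 * match(layer, PPOLE_LAYERS) +
                7919 * match(region, PPOLE_REGIONS)) %% 2147483647)
}

#' Run one cohort comparison over the layer x region design
#'
#' For every requested layer and region, collects the per-eye region-mean
#' thicknesses of the two groups (missing observations excluded pairwise),
#' computes the folded Mann-Whitney AUROC, its confidence interval and the
#' threshold significance flag.
#'
#' @param subjects List of [ppole_subject()] objects, already normalized
#'   and quality-filtered.
#' @param spec A [comparison_spec()].
#' @param parc A [parcellation()].
#' @return An object of class `comparison_table`: `spec`, `results` (data
#'   frame with one row per layer x region) and `provenance`. Cells where
#'   either group has no observations are flagged with NA results and a
#'   warning, and the run continues.
#' @export
run_comparison <- function(subjects, spec, parc) {
  stopifnot(inherits(spec, "comparison_spec"),
            inherits(parc, "parcellation"))
  obs <- regionize_cohort(subjects, parc)
  rows <- list()
  for (L in spec$layers) for (rg in spec$regions) {
    sel <- obs[obs$layer == L & obs$region == rg, , drop = FALSE]
    xs <- select_cohort(sel, spec$group_x)$mean_thickness
    ys <- select_cohort(sel, spec$group_y)$mean_thickness
    xs <- xs[!is.na(xs)]; ys <- ys[!is.na(ys)]
    if (length(xs) == 0 || length(ys) == 0) {
      warning(sprintf("%s: no observations for %s/%s in some group; cell skipped",
                      spec$label, L, rg), call. = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        layer = L, region = rg, auroc = NA_real_, auroc_folded = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, n_x = length(xs),
        n_y = length(ys), significant = NA, stringsAsFactors = FALSE)
      next
    }
    ts <- two_sample(xs, ys)
    a <- auroc(ts)
    af <- fold_auroc(a)
    ci <- auroc_ci(ts, n_boot = spec$n_boot,
                   seed = cell_seed(spec$ci_seed, L, rg),
                   level = spec$level, method = spec$ci_method)
    rows[[length(rows) + 1L]] <- data.frame(
      layer = L, region = rg, auroc = a, auroc_folded = af,
      ci_low = ci$ci_low, ci_high = ci$ci_high,
      n_x = ts$n_x, n_y = ts$n_y,
      significant = classify_significant(af, spec$threshold),
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(spec = spec, results = results,
                 provenance = list(
                   parcellation = parc$name,
                   parcellation_source = parc$source,
                   ci_method = spec$ci_method, n_boot = spec$n_boot,
                   ci_seed = spec$ci_seed, level = spec$level,
                   threshold = spec$threshold,
                   package_version =
                     as.character(utils::packageVersion("ppoleauc")))),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf("<comparison_table> %s (%s vs %s), parcellation '%s'\n",
              x$spec$label, x$spec$group_x, x$spec$group_y,
              x$provenance$parcellation))
  wide <- stats::reshape(
    x$results[, c("layer", "region", "auroc_folded")],
    idvar = "layer", timevar = "region", direction = "wide")
  names(wide) <- sub("^auroc_folded\\.", "", names(wide))
  print(format(wide, digits = 2), row.names = FALSE)
  invisible(x)
}

#' Per-cohort, per-region distribution summaries for one layer
#'
#' Five-number-style summaries of the per-eye region means, mirroring
#' box-plot reporting: median, quartiles by the median-of-halves (Tukey
#' hinge) rule as implemented by [stats::fivenum()], interquartile range,
#' range and n.
#'
#' @param subjects Normalized, quality-filtered [ppole_subject()] list.
#' @param layer One of [PPOLE_LAYERS].
#' @param parc A [parcellation()].
#' @return Data frame with one row per (cohort, region): `median`, `q1`,
#'   `q3`, `iqr`, `min`, `max`, `n`.
#' @export
summarize_regions <- function(subjects, layer, parc) {
  layer <- match.arg(layer, PPOLE_LAYERS)
  obs <- regionize_cohort(subjects, parc)
  obs <- obs[obs$layer == layer & !is.na(obs$mean_thickness), ,
             drop = FALSE]
  rows <- list()
  for (g in PPOLE_COHORTS) for (rg in PPOLE_REGIONS) {
    v <- obs$mean_thickness[obs$cohort == g & obs$region == rg]
    if (length(v) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        cohort = g, region = rg, median = NA_real_, q1 = NA_real_,
        q3 = NA_real_, iqr = NA_real_, min = NA_real_, max = NA_real_,
        n = 0L, stringsAsFactors = FALSE)
      next
    }
    fn <- stats::fivenum(v)
    rows[[length(rows) + 1L]] <- data.frame(
      cohort = g, region = rg, median = fn[3], q1 = fn[2], q3 = fn[4],
      iqr = fn[4] - fn[2], min = fn[1], max = fn[5], n = length(v),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize a comparison table
#'
#' Writes the table under `outdir` as `<label>_auroc.csv` (full-precision
#' values plus display columns rounded to 2 decimals, round-half-even) and
#' `<label>_auroc.json` (values plus provenance), and optionally one
#' folded-AUROC heatmap PNG per layer (`<label>_<layer>_heatmap.png`),
#' painting each grid cell with its zone's folded AUROC. Outputs embed the
#' run's provenance and are byte-identical across reruns with the same
#' inputs and seeds (no timestamps are written).
#'
#' @param table A [comparison_table][run_comparison()].
#' @param outdir Output directory (created if needed).
#' @param formats Subset of `c("csv", "json", "heatmap")`.
#' @return Character vector of the files written.
#' @export
render_outputs <- function(table, outdir, formats = c("csv", "json")) {
  stopifnot(inherits(table, "comparison_table"))
  formats <- match.arg(formats, c("csv", "json", "heatmap"),
                       several.ok = TRUE)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- character()
  label <- table$spec$label
  if ("csv" %in% formats) {
    p <- file.path(outdir, paste0(label, "_auroc.csv"))
    df <- table$results
    df$auroc_folded_2dp <- round(df$auroc_folded, 2)
    df$ci_low_2dp <- round(df$ci_low, 2)
    df$ci_high_2dp <- round(df$ci_high, 2)
    num <- vapply(df, is.numeric, logical(1)) &
      !names(df) %in% c("n_x", "n_y")
    df[num] <- lapply(df[num], function(v)
      ifelse(is.na(v), "", format(v, digits = 17, trim = TRUE,
                                  scientific = FALSE)))
    con <- file(p, open = "w", encoding = "UTF-8")
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
    close(con)
    paths <- c(paths, p)
  }
  if ("json" %in% formats) {
    p <- file.path(outdir, paste0(label, "_auroc.json"))
    jsonlite::write_json(
      list(spec = unclass(table$spec), provenance = table$provenance,
           results = table$results),
      p, auto_unbox = TRUE, digits = NA, na = "null", dataframe = "rows")
    paths <- c(paths, p)
  }
  if ("heatmap" %in% formats) {
    parc <- default_parcellation() # zone geometry for display only
    for (L in unique(table$results$layer)) {
      p <- file.path(outdir, paste0(label, "_", L, "_heatmap.png"))
      sub <- table$results[table$results$layer == L, ]
      cells <- do.call(rbind, lapply(ZONE_REGIONS, function(rg) {
        if (!rg %in% sub$region) return(NULL)
        m <- parc$regions[[rg]]
        data.frame(row = m[, 1], col = m[, 2], region = rg,
                   auroc_folded = sub$auroc_folded[sub$region == rg])
      }))
      gg <- ggplot2::ggplot(cells,
              ggplot2::aes(x = .data$col, y = .data$row,
                           fill = .data$auroc_folded)) +
        ggplot2::geom_tile(colour = "grey30") +
        ggplot2::scale_fill_gradient(limits = c(0.5, 1), low = "white",
                                     high = "firebrick",
                                     name = "folded AUROC") +
        ggplot2::coord_fixed() +
        ggplot2::labs(title = paste(label, L),
                      x = "column (temporal → nasal)",
                      y = "row (inferior → superior)") +
        ggplot2::theme_minimal()
      ggplot2::ggsave(p, gg, width = 5, height = 4, dpi = 120)
      paths <- c(paths, p)
    }
  }
  paths
}

#' Re-read a serialized comparison table
#'
#' Inverse of the JSON output of [render_outputs()].
#'
#' @param path Path to a `*_auroc.json` file.
#' @return A `comparison_table` equal to the one serialized (spec, results
#'   and provenance).
#' @export
read_comparison_table <- function(path) {
  j <- jsonlite::fromJSON(path)
  spec <- do.call(comparison_spec, j$spec[c("label", "group_x", "group_y",
                                            "layers", "regions", "n_boot",
                                            "ci_seed", "level", "ci_method",
                                            "threshold")])
  results <- j$results
  structure(list(spec = spec, results = results, provenance = j$provenance),
            class = "comparison_table")
}
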