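# Tie-aware Mann-Whitney AUROC, confidence intervals and the fixed 0.75
# significance rule.
#
# For two measurement sets X and Y, AUROC = Prob(X > Y) equals the
# Mann-Whitney U statistic divided by n_x * n_y, counting each (x, y) pair
# as 1 when x > y, 1/2 when x == y and 0 otherwise. Reporting is
# direction-agnostic: results are "folded" to max(A, 1 - A) in [0.5, 1].

#' Two-sample container for AUROC computation
#'
#' @param x,y Numeric vectors of measurements for the two groups; `NA`s are
#'   dropped. By convention `x` is the group expected thicker (e.g.
#'   controls), but folded reporting makes the orientation immaterial.
#' @return An object of class `two_sample` with fields `x`, `y`, `n_x`,
#'   `n_y`.
#' @export
two_sample <- function(x, y) {
  x <- as.numeric(x[!is.na(x)])
  y <- as.numeric(y[!is.na(y)])
  if (length(x) < 1 || length(y) < 1)
    stop("both samples must contain at least one non-missing value",
         call. = FALSE)
  structure(list(x = x, y = y, n_x = length(x), n_y = length(y)),
            class = "two_sample")
}

as_two_sample <- function(sample) {
  if (inherits(sample, "two_sample")) sample
  else stop("expected a two_sample object", call. = FALSE)
}

#' Mann-Whitney U statistic with half-credit ties
#'
#' `U = sum over pairs (x_i, y_j) of [x_i > y_j] + 0.5 [x_i == y_j]`,
#' computed via midranks in O(n log n).
#'
#' @param sample A [two_sample()].
#' @return U, a value in `[0, n_x * n_y]`.
#' @export
mann_whitney_u <- function(sample) {
  s <- as_two_sample(sample)
  r <- rank(c(s$x, s$y)) # midranks give ties half credit
  sum(r[seq_len(s$n_x)]) - s$n_x * (s$n_x + 1) / 2
}

#' Empirical AUROC of two samples
#'
#' `auroc = U / (n_x * n_y)`: the probability that a random X measurement
#' exceeds a random Y measurement, ties counted half.
#'
#' @param sample A [two_sample()].
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(sample) {
  s <- as_two_sample(sample)
  mann_whitney_u(s) / (s$n_x * s$n_y)
}

#' Fold an AUROC onto the direction-agnostic scale
#'
#' @param a AUROC in `[0, 1]`.
#' @return `max(a, 1 - a)`, in `[0.5, 1]`.
#' @export
fold_auroc <- function(a) {
  stopifnot(all(a >= 0 & a <= 1))
  pmax(a, 1 - a)
}

#' Significance by the fixed AUROC threshold
#'
#' A folded AUROC strictly greater than the threshold (default 0.75) is
#' taken as evidence of a difference between the two samples; exactly 0.75
#' is not significant.
#'
#' @param a_folded Folded AUROC in `[0.5, 1]`.
#' @param threshold Decision threshold (default 0.75).
#' @return Logical.
#' @export
classify_significant <- function(a_folded, threshold = 0.75) {
  stopifnot(all(a_folded >= 0.5 - 1e-12 & a_folded <= 1 + 1e-12))
  a_folded > threshold
}

#' Closed-form AUROC under the binormal model
#'
#' If `X ~ N(mu + delta, sigma^2)` and `Y ~ N(mu, sigma^2)` then
#' `AUROC = pnorm(delta / (sigma * sqrt(2)))`. Used both to calibrate the
#' synthetic-cohort generator and as an independent oracle in tests.
#'
#' @param delta Mean difference (same units as the measurements).
#' @param sigma Common standard deviation, > 0.
#' @return AUROC in `(0, 1)`.
#' @export
binormal_auroc <- function(delta, sigma) {
  stopifnot(all(sigma > 0))
  stats::pnorm(delta / (sigma * sqrt(2)))
}

#' Mean difference achieving a target binormal AUROC
#'
#' Inverse of [binormal_auroc()]: `delta = sigma * sqrt(2) * qnorm(target)`.
#'
#' @param target Desired AUROC in `(0, 1)`.
#' @param sigma Common standard deviation, > 0.
#' @return The required mean difference.
#' @export
binormal_delta <- function(target, sigma) {
  stopifnot(all(target > 0 & target < 1), all(sigma > 0))
  sigma * sqrt(2) * stats::qnorm(target)
}

# ---------------------------------------------------------------------------
# Confidence intervals

# Orientation-canonical form: CIs on the folded AUROC must not depend on
# which group was passed first, so resampling is tied to a deterministic
# canonical ordering of the two samples, not to the argument order.
canonical_order <- function(s) {
  a <- c(s$n_x, sum(s$x), sum(s$x^2))
  b <- c(s$n_y, sum(s$y), sum(s$y^2))
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  TRUE
}

#' Confidence interval for the folded AUROC
#'
#' Default method: percentile bootstrap resampling the two groups
#' independently with replacement, applied to the folded AUROC;
#' deterministic given `seed`, and invariant to swapping the two groups.
#' Closed-form alternatives for sensitivity analysis: `"hanley"`
#' (Hanley-McNeil variance) and `"delong"` (DeLong placement-value
#' variance), both as normal intervals around the folded estimate. To match
#' the folded reporting scale the interval is clipped to `[0.5, 1]`; the
#' unclipped bounds are returned alongside.
#'
#' @param sample A [two_sample()] with at least 2 values per group.
#' @param n_boot Bootstrap replicates (>= 100; default 2000). Ignored by
#'   the closed-form methods.
#' @param seed Integer seed making the bootstrap deterministic.
#' @param level Confidence level (default 0.95).
#' @param method `"bootstrap"` (default), `"hanley"` or `"delong"`.
#' @return List: `ci_low`, `ci_high` (clipped to `[0.5, 1]`),
#'   `ci_low_raw`, `ci_high_raw` (unclipped), `method`, `n_boot`, `seed`,
#'   `level`.
#' @export
auroc_ci <- function(sample, n_boot = 2000, seed = 1L, level = 0.95,
                     method = c("bootstrap", "hanley", "delong")) {
  method <- match.arg(method)
  s <- as_two_sample(sample)
  if (s$n_x < 2 || s$n_y < 2)
    stop("confidence interval needs at least 2 values per group",
         call. = FALSE)
  raw <- switch(method,
    bootstrap = ci_bootstrap(s, n_boot, seed, level),
    hanley = ci_hanley(s, level),
    delong = ci_delong(s, level))
  list(ci_low = min(max(raw[1], 0.5), 1), ci_high = min(max(raw[2], 0.5), 1),
       ci_low_raw = raw[1], ci_high_raw = raw[2], method = method,
       n_boot = if (method == "bootstrap") as.integer(n_boot) else NA_integer_,
       seed = if (method == "bootstrap") as.integer(seed) else NA_integer_,
       level = level)
}

ci_bootstrap <- function(s, n_boot, seed, level) {
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  if (canonical_order(s)) {
    first <- s$x; second <- s$y
  } else {
    first <- s$y; second <- s$x
  }
  n1 <- length(first); n2 <- length(second)
  stat <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      f <- first[sample.int(n1, replace = TRUE)]
      g <- second[sample.int(n2, replace = TRUE)]
      r <- rank(c(f, g))
      u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
      fold_auroc(u / (n1 * n2))
    }, numeric(1))
  })
  alpha <- 1 - level
  unname(stats::quantile(stat, c(alpha / 2, 1 - alpha / 2), type = 7))
}

ci_hanley <- function(s, level) {
  a <- fold_auroc(auroc(s))
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  v <- (a * (1 - a) + (s$n_x - 1) * (q1 - a^2) +
          (s$n_y - 1) * (q2 - a^2)) / (s$n_x * s$n_y)
  z <- stats::qnorm(1 - (1 - level) / 2)
  a + c(-1, 1) * z * sqrt(max(v, 0))
}

ci_delong <- function(s, level) {
  a <- auroc(s)
  # placement values: fraction of the other group each observation beats
  psi <- function(u, v) (outer(u, v, ">") + 0.5 * outer(u, v, "==") )
  m <- psi(s$x, s$y)
  v10 <- rowMeans(m)
  v01 <- colMeans(m)
  v <- stats::var(v10) / s$n_x + stats::var(v01) / s$n_y
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- a + c(-1, 1) * z * sqrt(max(v, 0))
  if (a < 0.5) ci <- rev(1 - ci) # fold the interval with the estimate
  ci
}

# ---------------------------------------------------------------------------
# Sample size

#' Per-group sample size for detecting a mean difference
#'
#' Normal-approximation formula for a two-sided two-sample comparison of
#' means with common standard deviation `sigma`:
#' `n_per_group = ceiling((1 + 1/r) * sigma^2 * (z_{1-alpha/2} + z_{power})^2
#' / delta^2)` with allocation ratio `r` (equal groups, `r = 1`, give the
#' familiar `2 sigma^2 (z_{1-alpha/2} + z_{1-beta})^2 / delta^2`). Units are
#' eyes per group when eyes are the analysis units.
#'
#' @param delta Minimum detectable difference in micrometres, > 0.
#' @param sigma Assumed common standard deviation in micrometres, > 0 (a
#'   required input: take it from pilot data for the instrument and layer).
#' @param alpha Two-sided type-I risk (default 0.05).
#' @param power Target power `1 - beta` (default 0.90).
#' @param allocation_ratio `n_x / n_y` (default 1).
#' @return Integer sample size for the (second) group; with
#'   `allocation_ratio = 1`, the common per-group size.
#' @export
sample_size_two_means <- function(delta, sigma, alpha = 0.05, power = 0.90,
                                  allocation_ratio = 1) {
  if (delta <= 0 || sigma <= 0)
    stop("delta and sigma must be positive", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1,
            allocation_ratio > 0)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n <- (1 + 1 / allocation_ratio) * sigma^2 * z^2 / delta^2
  as.integer(ceiling(n - 1e-9))
}
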