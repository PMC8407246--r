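# Label-incorporation kinetics and first-order turnover-rate estimation.
#
# Model: with first-order turnover at rate k (per hour) and constant total
# protein amount, the heavy fraction is I(t) = 1 - exp(-k t), so the H/L
# ratio follows r(t) = I/(1-I) = exp(k t) - 1 and ln(r + 1) = k t. The rate
# is the through-origin least-squares slope of y = ln(r+1) on t,
#     k = sum(y_i * t_i) / sum(t_i^2),
# and the half-life is T1/2 = ln(2) / k. The estimator does not involve the
# growth rate, which is what makes it usable in growth-arrested cells.

#' Heavy-label incorporation fraction from an H/L ratio
#'
#' `incorporation_fraction(r)` returns `r / (1 + r)`, the heavy intensity
#' divided by total (heavy plus light) intensity. `ratio_from_incorporation()`
#' is its inverse on `[0, 1)`.
#'
#' @param ratio_hl nonnegative finite H/L ratio(s); `NA` passes through.
#' @return incorporation fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' incorporation_fraction(1)       # 0.5
#' incorporation_fraction(17.52)   # ~0.946, a saturated resuscitation ratio
incorporation_fraction <- function(ratio_hl) {
  bad <- !is.na(ratio_hl) & (!is.finite(ratio_hl) | ratio_hl < 0)
  if (any(bad)) .err("domain error: H/L ratios must be finite and >= 0")
  ratio_hl / (1 + ratio_hl)
}

#' @rdname incorporation_fraction
#' @param fraction incorporation fraction(s) in `[0, 1)`.
#' @export
ratio_from_incorporation <- function(fraction) {
  bad <- !is.na(fraction) & (!is.finite(fraction) | fraction < 0 | fraction >= 1)
  if (any(bad)) .err("domain error: fractions must lie in [0, 1)")
  fraction / (1 - fraction)
}

#' Fit a first-order turnover rate to one H/L ratio time course
#'
#' Closed-form through-origin least squares of `y = ln(ratio + 1)` on time:
#' `k = sum(y * t) / sum(t^2)`. The goodness of fit is the uncentered
#' coefficient of determination `R^2 = 1 - sum((y - k t)^2) / sum(y^2)`
#' (the centered version is misleading for a no-intercept model). The t = 0
#' control must be excluded by the caller; missing pairs are dropped.
#'
#' @param times sampling times in hours, strictly positive.
#' @param ratios nonnegative H/L ratios, same length. Ratios of exactly 0
#'   are kept (`ln 1 = 0`): they are informative of slow turnover.
#' @param protein_id optional identifier carried into the result.
#' @return one-row data frame (class `turnover_fits`): `protein_id`, `k`
#'   (per hour), `half_life_h` (`Inf` when k = 0), `r_squared` (`NA` when
#'   all ratios are 0), `n_points`, `reliable` (`NA` until
#'   [select_reliable_fits()] is applied; `FALSE` for zero-signal fits).
#' @export
#' @examples
#' fit_turnover_rate(1:5, expm1(0.1 * (1:5)))  # recovers k = 0.1, R^2 = 1
fit_turnover_rate <- function(times, ratios, protein_id = NA_character_) {
  if (length(times) != length(ratios)) .err("times and ratios must have equal length")
  keep <- !is.na(times) & !is.na(ratios)
  times <- as.numeric(times[keep]); ratios <- as.numeric(ratios[keep])
  m <- length(times)
  if (m == 0) .err("no (time, ratio) pairs to fit")
  if (any(!is.finite(times)) || any(times <= 0))
    .err("domain error: times must be finite and > 0 (exclude the t = 0 control)")
  if (any(!is.finite(ratios)) || any(ratios < 0))
    .err("domain error: ratios must be finite and >= 0")

  y <- log1p(ratios)
  k <- sum(y * times) / sum(times^2)
  sy2 <- sum(y^2)
  r2 <- if (sy2 == 0) NA_real_ else 1 - sum((y - k * times)^2) / sy2
  data.frame(protein_id = protein_id, k = k,
             half_life_h = half_life_from_rate(k),
             r_squared = r2, n_points = m,
             reliable = if (sy2 == 0) FALSE else NA,
             stringsAsFactors = FALSE)
}

#' Fit turnover rates for every protein in a merged time course
#'
#' Applies [fit_turnover_rate()] per protein to the post-pulse (t > 0)
#' merged H/L ratios. Proteins with no usable pair are skipped.
#'
#' @param merged a `merged_timecourse` from [merge_replicates()].
#' @return data frame of class `turnover_fits`, one row per fitted protein.
#' @export
fit_turnover_rates <- function(merged) {
  stopifnot(inherits(merged, "merged_timecourse"))
  d <- merged[merged$time_h > 0 & !is.na(merged$ratio_hl), , drop = FALSE]
  fits <- lapply(split(d, d$protein_id, drop = TRUE), function(g)
    fit_turnover_rate(g$time_h, g$ratio_hl, protein_id = g$protein_id[1]))
  out <- do.call(rbind, c(fits, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(protein_id = character(), k = numeric(),
                      half_life_h = numeric(), r_squared = numeric(),
                      n_points = integer(), reliable = logical())
  structure(out, class = c("turnover_fits", "data.frame"))
}

#' Half-life from a turnover rate
#'
#' `T1/2 = ln(2) / k`; a rate of exactly zero yields the `Inf` sentinel
#' (serialized as an empty cell by the pipeline) rather than a fake large
#' number.
#'
#' @param k turnover rate(s), per hour, `>= 0`.
#' @return half-life in hours.
#' @export
#' @examples
#' half_life_from_rate(log(2) / 250)  # 250 h, the persistence-median regime
half_life_from_rate <- function(k) {
  if (any(!is.na(k) & k < 0)) .err("domain error: k must be >= 0")
  ifelse(is.na(k), NA_real_, ifelse(k == 0, Inf, log(2) / k))
}

#' Keep only reliable turnover fits
#'
#' A fit is reliable iff it used at least `min_points` time points and its
#' uncentered R-squared exceeds `min_r2`. The defaults encode the usual
#' "more than 4 time points" (read strictly, i.e. >= 5) and R^2 > 0.70
#' curve-fit quality rules.
#'
#' @param fits a `turnover_fits` data frame.
#' @param min_points minimum number of contributing time points (default 5).
#' @param min_r2 exclusive lower bound on uncentered R-squared (default 0.70).
#' @return the reliable subset, with `reliable = TRUE` filled in.
#' @export
select_reliable_fits <- function(fits, min_points = 5L, min_r2 = 0.70) {
  stopifnot(is.data.frame(fits))
  rel <- fits$n_points >= min_points & !is.na(fits$r_squared) & fits$r_squared > min_r2
  fits$reliable <- rel
  out <- fits[rel, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("turnover_fits", "data.frame"))
}

#' Flag reliability without subsetting
#'
#' Convenience wrapper setting the `reliable` column on all fits (used when
#' writing full result tables).
#' @inheritParams select_reliable_fits
#' @return `fits` with `reliable` filled in for every row.
#' @export
flag_reliable_fits <- function(fits, min_points = 5L, min_r2 = 0.70) {
  fits$reliable <- fits$n_points >= min_points &
    !is.na(fits$r_squared) & fits$r_squared > min_r2
  fits
}

#' Estimate heavy-pool purity from missed-cleavage peptide label states
#'
#' Amino-acid recycling releases light lysine from degraded proteins and
#' dilutes the heavy pool. For newly synthesized peptides carrying two
#' lysines (one missed cleavage), the two residues draw independently from
#' the pool: heavy-heavy peptides appear with probability `p^2` and mixed
#' heavy-light peptides with `2 p (1 - p)`. Fully light new peptides are
#' indistinguishable from pre-existing protein, so conditioning on "at least
#' one heavy residue" gives the maximum-likelihood pool purity
#' `p = 2 HH / (2 HH + HL)`. A turnover rate estimated from apparent
#' incorporation can then be corrected as `k / p` (see
#' [recycling_corrected_rate()]). This estimator is a documented
#' reconstruction and is off by default in the pipeline.
#'
#' @param n_heavy_heavy count of doubly heavy two-lysine peptides (HH).
#' @param n_heavy_light count of mixed-label two-lysine peptides (HL).
#' @return object of class `recycling_estimate` with fields `pool_purity`,
#'   `n_peptides_used`, `method`.
#' @export
#' @examples
#' estimate_recycling_factor(64, 32)  # pool purity 0.8
estimate_recycling_factor <- function(n_heavy_heavy, n_heavy_light) {
  for (v in list(n_heavy_heavy, n_heavy_light))
    if (length(v) != 1 || is.na(v) || v < 0 || v != round(v))
      .err("counts must be single nonnegative integers")
  if (n_heavy_heavy + n_heavy_light == 0)
    .err("at least one labeled missed-cleavage peptide is required")
  p <- 2 * n_heavy_heavy / (2 * n_heavy_heavy + n_heavy_light)
  structure(list(pool_purity = p,
                 n_peptides_used = as.integer(n_heavy_heavy + n_heavy_light),
                 method = "binomial label-state MLE (conditional on >=1 heavy residue)"),
            class = "recycling_estimate")
}

#' @export
print.recycling_estimate <- function(x, ...) {
  cat(sprintf("<recycling_estimate> pool purity %.4f from %d peptides (%s)\n",
              x$pool_purity, x$n_peptides_used, x$method))
  invisible(x)
}

#' Correct a turnover rate for heavy-pool impurity
#'
#' @param k apparent turnover rate(s), per hour.
#' @param estimate a `recycling_estimate` (or a purity value in (0, 1]).
#' @return corrected rate(s) `k / p`.
#' @export
recycling_corrected_rate <- function(k, estimate) {
  p <- if (inherits(estimate, "recycling_estimate")) estimate$pool_purity else estimate
  if (length(p) != 1 || is.na(p) || p <= 0 || p > 1)
    .err("pool purity must lie in (0, 1]")
  k / p
}
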