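# Clustering of complete label-incorporation profiles and cluster-level
# time to 50% incorporation.

#' Build a complete-case incorporation profile matrix
#'
#' Converts per-replicate H/L ratios into incorporation fractions
#' (`r / (1 + r)`), takes the median across replicates at every post-pulse
#' time point, and keeps only proteins quantified at *every* time point
#' (complete cases). The t = 0 control column carries no heavy signal and is
#' excluded.
#'
#' @param records a filtered `protein_quant` data frame.
#' @param design optional design; defaults to the one attached to `records`.
#' @return numeric matrix (proteins x time points) of fractions in `[0, 1]`,
#'   with protein ids as row names, times as column names and a numeric
#'   `times` attribute.
#' @export
build_profile_matrix <- function(records, design = attr(records, "design")) {
  stopifnot(inherits(records, "protein_quant"))
  d <- records[records$time_h > 0 & !is.na(records$ratio_hl), , drop = FALSE]
  times <- sort(unique(if (!is.null(design)) design$time_points_h[design$time_points_h > 0]
                       else d$time_h))
  prot <- unique(records$protein_id)
  mat <- matrix(NA_real_, nrow = length(prot), ncol = length(times),
                dimnames = list(prot, as.character(times)))
  if (nrow(d)) {
    d$fraction <- incorporation_fraction(d$ratio_hl)
    med <- aggregate(fraction ~ protein_id + time_h, data = d, FUN = median)
    mat[cbind(match(med$protein_id, prot), match(med$time_h, times))] <- med$fraction
  }
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  attr(mat, "times") <- times
  mat
}

# Pooled tricube local-polynomial conditional mean of fraction on time.
# Degree 2 rather than 1: local-linear smoothing of a saturating
# incorporation curve carries a curvature bias large enough to shift the
# 50%-crossing by the better part of an hour at span 0.5 (see vignette).
.smoothed_conditional_mean <- function(profiles, times, span) {
  # conditional mean given time = average over members; the local-polynomial
  # smoother then operates on the (time, mean) points, which for a shared
  # time grid is equivalent to smoothing the pooled member points
  x <- times
  y <- colMeans(profiles)
  grid <- sort(unique(c(times, seq(min(times), max(times), length.out = 200))))
  n <- length(x)
  if (n < 5) {
    s <- stats::approx(x, y, xout = grid, rule = 2)$y
  } else {
    span_eff <- max(span, min(1, 4.5 / n))  # local quadratic needs >= 4 points
    fit <- loess(y ~ x, span = span_eff, degree = 2, family = "gaussian",
                 surface = "direct",
                 control = loess.control(statistics = "none"))
    s <- predict(fit, newdata = data.frame(x = grid))
  }
  data.frame(time_h = grid, smoothed_mean = as.numeric(s))
}

.first_crossing <- function(time, value, threshold = 0.5) {
  if (value[1] >= threshold) return(time[1])
  below <- value[-length(value)] < threshold
  above <- value[-1] >= threshold
  i <- which(below & above)[1]
  if (is.na(i)) return(NA_real_)
  time[i] + (threshold - value[i]) / (value[i + 1] - value[i]) * (time[i + 1] - time[i])
}

#' Time to 50% label incorporation of a profile group
#'
#' Computes the group's smoothed conditional mean curve (tricube-weighted
#' local polynomial regression of fraction on time, evaluated on the union
#' of the sample times and 200 equispaced points) and returns the earliest
#' time at which it crosses the 50% level from below, located by linear
#' interpolation between adjacent evaluation points. `NA` sentinel when the
#' curve never reaches 50%.
#'
#' @param profiles matrix of member profiles (rows) over `times`, or a
#'   single numeric profile.
#' @param times sampling times in hours.
#' @param span smoother span in `(0, 1]` (fraction of points in each local
#'   fit; default 0.5).
#' @param threshold crossing level (default 0.5).
#' @return crossing time in hours, or `NA` if never crossed.
#' @export
time_to_half_incorporation <- function(profiles, times, span = 0.5,
                                       threshold = 0.5) {
  if (!is.numeric(span) || length(span) != 1 || span <= 0 || span > 1)
    .err("config error: span must lie in (0, 1]")
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1)
  if (ncol(profiles) != length(times))
    .err("profiles and times are inconsistent")
  if (nrow(profiles) == 0) .err("empty cluster")
  curve <- .smoothed_conditional_mean(profiles, times, span)
  .first_crossing(curve$time_h, curve$smoothed_mean, threshold)
}

#' Cluster incorporation profiles hierarchically
#'
#' Agglomerative hierarchical clustering of complete incorporation profiles
#' using Euclidean distance and Ward's minimum-variance linkage
#' (`hclust(method = "ward.D2")`, i.e. squared-distance Ward on raw
#' Euclidean distances), cut into `K` groups. Deterministic given the input.
#' For every cluster the smoothed conditional mean curve and its time to
#' 50% incorporation are computed.
#'
#' @param mat profile matrix from [build_profile_matrix()].
#' @param K number of clusters (default 8).
#' @param span smoother span passed to [time_to_half_incorporation()].
#' @return object of class `cluster_result`: `assignment` (named integer
#'   vector, labels 1..K), `K`, `sizes`, `hclust`, `curves` (list of
#'   per-cluster data frames `time_h`/`smoothed_mean`), `t50_h` (numeric,
#'   `NA` sentinel when a cluster never reaches 50%).
#' @export
cluster_profiles <- function(mat, K = 8L, span = 0.5) {
  if (!is.matrix(mat) || nrow(mat) == 0) .err("profile matrix is empty")
  K <- as.integer(K)
  if (K < 1) .err("K must be >= 1")
  if (K > nrow(mat))
    .err("K = %d exceeds the %d complete profiles available", K, nrow(mat))
  times <- attr(mat, "times") %||% as.numeric(colnames(mat))

  hc <- hclust(dist(mat), method = "ward.D2")
  assignment <- cutree(hc, k = K)
  curves <- vector("list", K)
  t50 <- rep(NA_real_, K)
  for (g in seq_len(K)) {
    members <- mat[assignment == g, , drop = FALSE]
    curves[[g]] <- .smoothed_conditional_mean(members, times, span)
    t50[g] <- .first_crossing(curves[[g]]$time_h, curves[[g]]$smoothed_mean)
  }
  structure(list(assignment = assignment, K = K,
                 sizes = as.integer(table(factor(assignment, levels = seq_len(K)))),
                 hclust = hc, curves = curves, t50_h = t50),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d profiles in %d clusters\n",
              length(x$assignment), x$K))
  cat("sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat("t50_h:", paste(ifelse(is.na(x$t50_h), "-", sprintf("%.2f", x$t50_h)),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions (up to label renaming), ~0 for independent
#' ones. Used to compare recovered clusters against generator truth.
#'
#' @param a,b label vectors of equal length.
#' @return adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) .err("partitions must have equal length")
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}
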