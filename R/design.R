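#' Describe a pulse-labeling experiment
#'
#' An experiment design attaches biological meaning to the columns of a
#' protein-groups table: which condition was run, which replicates exist and
#' at which times (in hours) samples were taken. Time zero is the pre-pulse
#' control and must be present. Times are never parsed from column names;
#' the design supplies the sample label for every (replicate, time) pair.
#'
#' @param condition `"persistence"` (near-arrested cells, partial labeling)
#'   or `"resuscitation"` (regrowing cells, label saturating high).
#' @param replicates character vector of replicate identifiers.
#' @param time_points_h numeric vector of sampling times in hours, strictly
#'   increasing, containing 0 (the unlabeled control).
#' @param labels optional character matrix/vector of sample labels, one per
#'   (replicate, time) pair in replicate-major order. Defaults to
#'   `"<rep>_T<index>"` with a zero-padded time index.
#' @param bin_scheme optional [bin_scheme()] used by binning stages.
#' @return An object of class `experiment_design` with a `samples` data frame
#'   (`label`, `replicate`, `time_h`).
#' @seealso [default_time_points()], [default_bin_scheme()]
#' @export
#' @examples
#' d <- experiment_design("persistence", paste0("R", 1:3), c(0, 1, 2, 4, 8))
#' head(d$samples)
experiment_design <- function(condition = c("persistence", "resuscitation"),
                              replicates = paste0("R", 1:3),
                              time_points_h = default_time_points(condition),
                              labels = NULL,
                              bin_scheme = NULL) {
  condition <- match.arg(condition)
  replicates <- as.character(replicates)
  if (anyDuplicated(replicates)) .err("duplicate replicate identifiers")
  time_points_h <- as.numeric(time_points_h)
  if (any(!is.finite(time_points_h)) || any(time_points_h < 0))
    .err("time_points_h must be finite and >= 0")
  if (is.unsorted(time_points_h, strictly = TRUE))
    .err("time_points_h must be strictly increasing")
  if (!0 %in% time_points_h)
    .err("time_points_h must include 0 (the pre-pulse control)")

  grid <- expand.grid(time_h = time_points_h, replicate = replicates,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$replicate, replicates), grid$time_h), ]
  if (is.null(labels)) {
    idx <- match(grid$time_h, time_points_h)
    labels <- sprintf("%s_T%02d", grid$replicate, idx)
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(grid)) .err("labels must have one entry per (replicate, time) pair")
  if (anyDuplicated(labels)) .err("duplicate sample labels")

  structure(list(condition = condition,
                 replicates = replicates,
                 time_points_h = time_points_h,
                 samples = data.frame(label = labels,
                                      replicate = grid$replicate,
                                      time_h = grid$time_h,
                                      stringsAsFactors = FALSE),
                 bin_scheme = bin_scheme),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("<experiment_design> %s: %d replicates x %d time points (%g-%g h)\n",
              x$condition, length(x$replicates), length(x$time_points_h),
              min(x$time_points_h), max(x$time_points_h)))
  invisible(x)
}

#' Default sampling grids for the two labeling regimes
#'
#' Persistence: 17 time points from 0 to 24 h (pulse window far shorter than
#' typical half-lives under growth arrest). Resuscitation: 21 time points
#' from 0 to 30 h covering regrowth through early stationary phase.
#'
#' @param condition `"persistence"` or `"resuscitation"`.
#' @return numeric vector of times in hours.
#' @export
default_time_points <- function(condition = c("persistence", "resuscitation")) {
  condition <- match.arg(condition)
  if (condition == "persistence")
    c(0, 1/6, 1/3, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 10, 12, 16, 20, 24)
  else
    c(0, 1/6, 1/3, 0.5, 0.75, 1, 1.5, 2, 2.5, 3, 4, 5, 6, 7, 8, 10, 12, 15, 20, 25, 30)
}

#' Construct a time-bin scheme
#'
#' Bins pool neighbouring time points so that per-bin medians are robust to
#' missing values. Bins must be disjoint; they need not cover every time
#' point (e.g. the resuscitation analysis bins only the first 8 h).
#'
#' @param bins named list; each element is the numeric vector of member time
#'   points (hours) of one bin, in experiment time order.
#' @param condition condition the scheme applies to.
#' @return object of class `bin_scheme`.
#' @export
bin_scheme <- function(bins, condition = c("persistence", "resuscitation")) {
  condition <- match.arg(condition)
  if (!is.list(bins) || is.null(names(bins)) || any(names(bins) == ""))
    .err("bins must be a named list of numeric time-point vectors")
  bins <- lapply(bins, as.numeric)
  if (any(lengths(bins) == 0)) .err("every bin must contain at least one time point")
  all_members <- unlist(bins, use.names = FALSE)
  if (anyDuplicated(all_members)) .err("bins must be disjoint")
  structure(list(bins = bins, condition = condition), class = "bin_scheme")
}

#' Default bin scheme for a time grid
#'
#' The persistence scheme splits all post-pulse time points into six
#' contiguous bins with sizes as equal as possible (earlier bins take the
#' extra point) -- a documented reconstruction, as the original six-bin
#' boundaries were not published. The resuscitation scheme uses the five
#' published bins (10-30 min, 45-90 min, 2-3 h, 4-5 h, 6-8 h) whenever the
#' time grid contains them, and otherwise falls back to five contiguous
#' near-equal bins over the first 8 h.
#'
#' @param condition condition to build the scheme for.
#' @param time_points_h the design's time grid (hours, including 0).
#' @return a [bin_scheme()].
#' @export
default_bin_scheme <- function(condition = c("persistence", "resuscitation"),
                               time_points_h = default_time_points(condition)) {
  condition <- match.arg(condition)
  post <- sort(time_points_h[time_points_h > 0])
  contiguous <- function(times, n_bins, prefix) {
    np <- length(times)
    if (np < n_bins) .err("need at least %d post-pulse time points for %d bins", n_bins, n_bins)
    base <- np %/% n_bins
    sizes <- base + c(rep(1, np %% n_bins), rep(0, n_bins - np %% n_bins))
    ends <- cumsum(sizes)
    starts <- c(1, head(ends, -1) + 1)
    b <- lapply(seq_len(n_bins), function(i) times[starts[i]:ends[i]])
    names(b) <- sprintf("%s%d", prefix, seq_len(n_bins))
    b
  }
  if (condition == "persistence")
    return(bin_scheme(contiguous(post, 6L, "bin"), condition))

  published <- list(bin1 = c(1/6, 1/3, 0.5), bin2 = c(0.75, 1, 1.5),
                    bin3 = c(2, 2.5, 3), bin4 = c(4, 5), bin5 = c(6, 7, 8))
  if (all(unlist(published) %in% post))
    bin_scheme(published, condition)
  else
    bin_scheme(contiguous(post[post <= 8], 5L, "bin"), condition)
}

#' MaxQuant proteinGroups column-name templates
#'
#' Column dialects drift between quantification software versions, so the
#' mapping from logical fields to column names is configurable. Templates
#' may contain the placeholder `{label}`, replaced by each sample label from
#' the [experiment_design()].
#'
#' @param protein_id,gene_name identifier columns (`gene_name` may be absent
#'   from the table; it is then filled with empty strings).
#' @param ratio,ratio_count,intensity_h,intensity_l per-sample templates.
#' @param contaminant,reverse,only_by_site quality-flag columns; cells equal
#'   to `"+"` mean flagged.
#' @return named list of class `mq_column_map`.
#' @export
mq_column_map <- function(protein_id = "Protein IDs",
                          gene_name = "Gene names",
                          ratio = "Ratio H/L {label}",
                          ratio_count = "Ratio H/L count {label}",
                          intensity_h = "Intensity H {label}",
                          intensity_l = "Intensity L {label}",
                          contaminant = "Potential contaminant",
                          reverse = "Reverse",
                          only_by_site = "Only identified by site") {
  structure(list(protein_id = protein_id, gene_name = gene_name,
                 ratio = ratio, ratio_count = ratio_count,
                 intensity_h = intensity_h, intensity_l = intensity_l,
                 contaminant = contaminant, reverse = reverse,
                 only_by_site = only_by_site),
            class = "mq_column_map")
}

.fill_label <- function(template, label) {
  vapply(label, function(l) gsub("{label}", l, template, fixed = TRUE), character(1),
         USE.NAMES = FALSE)
}
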