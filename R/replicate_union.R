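# Union of biological replicates, time binning and within-bin ranking.

#' Merge biological replicates into one time course per protein
#'
#' Per protein and time point the H/L ratio is kept if measured in only one
#' replicate (confidence class I), averaged if measured in two (class II) or
#' three (class III). Time points with no value in any replicate are
#' omitted; the union never invents values.
#'
#' @param records a filtered `protein_quant` data frame
#'   (see [apply_quality_filters()]).
#' @return data frame of class `merged_timecourse` with columns
#'   `protein_id`, `time_h`, `ratio_hl`, `n_replicates`, `confidence_class`.
#' @export
merge_replicates <- function(records) {
  stopifnot(inherits(records, "protein_quant"))
  d <- records[!is.na(records$ratio_hl),
               c("protein_id", "time_h", "ratio_hl"), drop = FALSE]
  if (nrow(d) == 0) {
    out <- data.frame(protein_id = character(), time_h = numeric(),
                      ratio_hl = numeric(), n_replicates = integer(),
                      confidence_class = factor(character(),
                                                levels = c("I", "II", "III")))
  } else {
    means <- aggregate(ratio_hl ~ protein_id + time_h, data = d, FUN = mean)
    counts <- aggregate(ratio_hl ~ protein_id + time_h, data = d, FUN = length)
    out <- means
    out$n_replicates <- as.integer(counts$ratio_hl)
    out$confidence_class <- factor(c("I", "II", "III")[pmin(out$n_replicates, 3L)],
                                   levels = c("I", "II", "III"))
    out <- out[order(out$protein_id, out$time_h), ]
    rownames(out) <- NULL
  }
  structure(out, design = attr(records, "design"),
            class = c("merged_timecourse", "data.frame"))
}

#' Pool merged time points into bins
#'
#' For every protein and bin, the median of the protein's non-missing merged
#' H/L ratios among the bin's member time points; missing if all members are
#' missing. Medians over an even count use the midpoint of the two central
#' values.
#'
#' @param merged a `merged_timecourse` from [merge_replicates()].
#' @param scheme a [bin_scheme()].
#' @param design optional [experiment_design()]; when given, every bin
#'   member must be one of the design's time points (config error otherwise).
#' @return data frame of class `binned_ratios`: `protein_id`, `bin`
#'   (ordered factor), `median_ratio` (NA when the bin is empty).
#' @export
assign_time_bins <- function(merged, scheme, design = attr(merged, "design")) {
  stopifnot(inherits(merged, "merged_timecourse"), inherits(scheme, "bin_scheme"))
  if (!is.null(design)) {
    unknown <- setdiff(unlist(scheme$bins), design$time_points_h)
    if (length(unknown))
      .err("config error: bin scheme references unknown time point(s): %s",
           paste(unknown, collapse = ", "))
  }
  prot <- unique(merged$protein_id)
  bins <- names(scheme$bins)
  res <- vector("list", length(bins))
  for (b in seq_along(bins)) {
    sel <- merged$time_h %in% scheme$bins[[b]]
    med <- rep(NA_real_, length(prot))
    if (any(sel)) {
      agg <- tapply(merged$ratio_hl[sel], factor(merged$protein_id[sel], levels = prot),
                    median)
      med <- as.numeric(agg)
    }
    res[[b]] <- data.frame(protein_id = prot, bin = bins[b], median_ratio = med,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$bin <- factor(out$bin, levels = bins, ordered = TRUE)
  rownames(out) <- NULL
  structure(out, class = c("binned_ratios", "data.frame"))
}

#' Rank proteins into quartiles within each time bin
#'
#' Within each bin, non-missing proteins are sorted by median ratio in
#' descending order (ties broken by `protein_id` lexicographic order) and cut
#' into quartile categories at ranks `ceiling(n/4)`, `ceiling(n/2)` and
#' `ceiling(3n/4)`. Bins with fewer than 4 non-missing proteins are assigned
#' `missing` throughout, with a warning. Because only ranks are used, the
#' categorisation is invariant to any strictly monotone transform of the
#' ratios.
#'
#' @param binned a `binned_ratios` data frame from [assign_time_bins()].
#' @return data frame of class `binned_rank_matrix`: input columns plus
#'   `quartile` (factor: `top25`, `p25_50`, `p50_75`, `bottom25`, `missing`).
#' @export
rank_within_bins <- function(binned) {
  stopifnot(inherits(binned, "binned_ratios"))
  lv <- c("top25", "p25_50", "p50_75", "bottom25", "missing")
  out <- binned
  out$quartile <- "missing"
  for (b in levels(binned$bin)) {
    rows <- which(out$bin == b & !is.na(out$median_ratio))
    n <- length(rows)
    if (n < 4) {
      if (n > 0)
        warning(sprintf("bin '%s': fewer than 4 quantified proteins; all set missing", b),
                call. = FALSE)
      next
    }
    ord <- rows[order(-out$median_ratio[rows], out$protein_id[rows])]
    rank <- seq_len(n)
    cat <- ifelse(rank <= ceiling(n / 4), "top25",
           ifelse(rank <= ceiling(n / 2), "p25_50",
           ifelse(rank <= ceiling(3 * n / 4), "p50_75", "bottom25")))
    out$quartile[ord] <- cat
  }
  out$quartile <- factor(out$quartile, levels = lv)
  structure(out, class = c("binned_rank_matrix", "data.frame"))
}
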