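# In-silico Lys-C digestion and heavy-channel iBAQ.

#' In-silico Lys-C digest of a protein sequence
#'
#' Lys-C cleaves C-terminal to every lysine, including Lys-Pro bonds
#' (unlike trypsin). The digest enumerates every contiguous join of at most
#' `max_missed + 1` fragments; a peptide's missed-cleavage count is the
#' number of internal lysines it spans. The observable count -- the iBAQ
#' denominator -- is the number of *unique* peptide sequences whose length
#' falls within `[min_len, max_len]`. The protein N-terminal methionine is
#' not removed.
#'
#' @param sequence amino-acid string (upper- or lowercase).
#' @param max_missed maximum missed cleavage sites (default 2, the usual
#'   database-search setting for Lys-C).
#' @param min_len minimum observable peptide length (default 7, matching
#'   the search engine's minimum).
#' @param max_len maximum observable peptide length (default 30, the usual
#'   iBAQ convention; set large to disable).
#' @param protein_id optional id carried into the result.
#' @return object of class `digest_result`: `protein_id`, `peptides` (data
#'   frame `sequence`, `start`, `end` (1-based inclusive),
#'   `missed_cleavages`), `observable_count`.
#' @export
#' @examples
#' digest_lysc("MKAAAAAAKLLLLLLLKR", max_missed = 0)$observable_count  # 2
#' digest_lysc("MKAAAAAAKLLLLLLLKR", max_missed = 2)$observable_count  # 7
digest_lysc <- function(sequence, max_missed = 2L, min_len = 7L, max_len = 30L,
                        protein_id = NA_character_) {
  if (length(sequence) != 1 || is.na(sequence) || !nzchar(sequence))
    .err("sequence must be a single nonempty string")
  if (max_missed < 0 || min_len < 1 || max_len < min_len)
    .err("invalid digest parameters")
  s <- toupper(sequence)
  n <- nchar(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  ends <- unique(c(which(chars == "K"), n))
  starts <- c(1L, head(ends, -1L) + 1L)
  nf <- length(starts)

  pep_start <- integer(0); pep_end <- integer(0); pep_missed <- integer(0)
  for (i in seq_len(nf)) {
    jmax <- min(nf, i + max_missed)
    js <- i:jmax
    pep_start <- c(pep_start, rep(starts[i], length(js)))
    pep_end <- c(pep_end, ends[js])
    pep_missed <- c(pep_missed, js - i)
  }
  peptides <- data.frame(sequence = substring(s, pep_start, pep_end),
                         start = pep_start, end = pep_end,
                         missed_cleavages = pep_missed,
                         stringsAsFactors = FALSE)
  len <- peptides$end - peptides$start + 1L
  observable <- unique(peptides$sequence[len >= min_len & len <= max_len])
  structure(list(protein_id = protein_id, peptides = peptides,
                 observable_count = length(observable)),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("<digest_result> %s: %d peptides, %d observable\n",
              if (is.na(x$protein_id)) "?" else x$protein_id,
              nrow(x$peptides), x$observable_count))
  invisible(x)
}

#' Digest every sequence of a proteome
#'
#' @param sequences named character vector of sequences (see [read_fasta()]).
#' @param ... passed to [digest_lysc()].
#' @return named list of `digest_result` objects.
#' @export
digest_proteome <- function(sequences, ...) {
  if (is.null(names(sequences))) .err("sequences must be named by protein id")
  out <- lapply(seq_along(sequences), function(i)
    digest_lysc(sequences[[i]], ..., protein_id = names(sequences)[i]))
  names(out) <- names(sequences)
  out
}

#' Heavy-channel iBAQ estimates
#'
#' iBAQ (intensity-based absolute quantification) in the heavy SILAC
#' channel estimates the molar amount of *newly synthesized* protein:
#' per protein and time point, the median heavy intensity across replicates
#' divided by the count of theoretically observable Lys-C peptides.
#' Proteins without a digest, or with zero observable peptides, are skipped
#' and listed in the `skipped` attribute.
#'
#' @param records a filtered `protein_quant` data frame.
#' @param digests named list of `digest_result` objects
#'   (see [digest_proteome()]).
#' @return data frame `protein_id`, `time_h`, `ibaq_heavy`, with a
#'   `skipped` attribute (data frame `protein_id`, `reason`).
#' @export
compute_ibaq_heavy <- function(records, digests) {
  stopifnot(inherits(records, "protein_quant"))
  prot <- unique(records$protein_id)
  counts <- vapply(prot, function(p) {
    dg <- digests[[p]]
    if (is.null(dg)) NA_integer_ else as.integer(dg$observable_count)
  }, integer(1))
  skipped <- data.frame(protein_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  no_digest <- prot[is.na(counts)]
  zero_obs <- prot[!is.na(counts) & counts == 0]
  if (length(no_digest)) {
    message(length(no_digest), " protein(s) without a digest skipped")
    skipped <- rbind(skipped, data.frame(protein_id = no_digest,
                                         reason = "no_digest"))
  }
  if (length(zero_obs)) {
    message(length(zero_obs), " protein(s) with zero observable peptides skipped")
    skipped <- rbind(skipped, data.frame(protein_id = zero_obs,
                                         reason = "zero_observable"))
  }
  usable <- prot[!is.na(counts) & counts > 0]
  d <- records[records$protein_id %in% usable & !is.na(records$intensity_h),
               c("protein_id", "time_h", "intensity_h"), drop = FALSE]
  if (nrow(d)) {
    med <- aggregate(intensity_h ~ protein_id + time_h, data = d, FUN = median)
    med$ibaq_heavy <- med$intensity_h / counts[med$protein_id]
    out <- med[order(med$protein_id, med$time_h),
               c("protein_id", "time_h", "ibaq_heavy")]
  } else {
    out <- data.frame(protein_id = character(), time_h = numeric(),
                      ibaq_heavy = numeric())
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
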