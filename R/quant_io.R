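# Reading/writing protein-groups tables and FASTA, plus quality filters.
# The long "protein_quant" data frame is the package's working container:
# one row per (protein, replicate, time point).

.parse_num <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  v[is.nan(v)] <- NA_real_   # "NaN" cells are missing, never zero
  v
}

.parse_flag <- function(x) !is.na(x) & trimws(x) == "+"

#' Read a protein-groups quantification table
#'
#' Parses a tab-separated protein-groups table (MaxQuant `proteinGroups.txt`
#' dialect) into a long data frame with one row per protein, replicate and
#' time point, carrying heavy/light intensities, the non-normalized H/L
#' ratio, the peptide ratio count and the three quality flags. Flag cells
#' equal to `"+"` parse as `TRUE`; unparseable numeric cells (including the
#' literal `"NaN"`) become missing, never zero. Intensities of exactly zero
#' are stored as missing ("not detected" convention).
#'
#' @param path path to the tab-separated table (header row required).
#' @param design an [experiment_design()] supplying the (replicate, time)
#'   meaning of every sample label.
#' @param column_map an [mq_column_map()] naming the columns.
#' @return data frame of class `protein_quant` with columns `protein_id`,
#'   `gene_name`, `label`, `replicate`, `time_h`, `intensity_h`,
#'   `intensity_l`, `ratio_hl`, `ratio_count`, `contaminant`, `reverse`,
#'   `only_by_site`; the design and column map are attached as attributes.
#' @export
read_protein_groups <- function(path, design, column_map = mq_column_map()) {
  stopifnot(inherits(design, "experiment_design"))
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    quote = "", colClasses = "character")

  samples <- design$samples
  need <- c(column_map$protein_id,
            column_map$contaminant, column_map$reverse, column_map$only_by_site,
            .fill_label(column_map$ratio, samples$label),
            .fill_label(column_map$ratio_count, samples$label),
            .fill_label(column_map$intensity_h, samples$label),
            .fill_label(column_map$intensity_l, samples$label))
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    .err("schema error: missing required column(s): %s",
         paste(missing_cols, collapse = ", "))

  ids <- raw[[column_map$protein_id]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    .err("duplicate protein_id(s): %s", paste(dup, collapse = ", "))

  genes <- if (column_map$gene_name %in% names(raw)) raw[[column_map$gene_name]]
           else rep("", nrow(raw))
  genes[is.na(genes)] <- ""
  flags <- data.frame(contaminant = .parse_flag(raw[[column_map$contaminant]]),
                      reverse = .parse_flag(raw[[column_map$reverse]]),
                      only_by_site = .parse_flag(raw[[column_map$only_by_site]]))

  n <- nrow(raw)
  blocks <- lapply(seq_len(nrow(samples)), function(i) {
    lab <- samples$label[i]
    data.frame(protein_id = ids, gene_name = genes, label = lab,
               replicate = samples$replicate[i], time_h = samples$time_h[i],
               intensity_h = .parse_num(raw[[.fill_label(column_map$intensity_h, lab)]]),
               intensity_l = .parse_num(raw[[.fill_label(column_map$intensity_l, lab)]]),
               ratio_hl = .parse_num(raw[[.fill_label(column_map$ratio, lab)]]),
               ratio_count = .parse_num(raw[[.fill_label(column_map$ratio_count, lab)]]),
               contaminant = flags$contaminant, reverse = flags$reverse,
               only_by_site = flags$only_by_site,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  out$intensity_h[!is.na(out$intensity_h) & out$intensity_h == 0] <- NA_real_
  out$intensity_l[!is.na(out$intensity_l) & out$intensity_l == 0] <- NA_real_
  bad_ratio <- !is.na(out$ratio_hl) & (out$ratio_hl < 0 | !is.finite(out$ratio_hl))
  if (any(bad_ratio)) .err("negative or non-finite H/L ratios in input")
  rownames(out) <- NULL
  structure(out, design = design, column_map = column_map,
            class = c("protein_quant", "data.frame"))
}

#' Apply row- and cell-level quality filters
#'
#' Removes protein groups flagged as contaminant, reverse (decoy) or
#' identified only by a modification site, and masks (sets missing) every
#' H/L ratio whose paired peptide ratio count is below `min_ratio_count`.
#' Masking is cell-level: a protein is only dropped if no ratio cell
#' survives. Intensities are never modified. The operation is idempotent.
#'
#' @param records a `protein_quant` data frame from [read_protein_groups()].
#' @param min_ratio_count minimum peptide ratio count for a quantification
#'   event to be trusted (default 2). Cells with a missing count are masked.
#' @return filtered `protein_quant` data frame (possibly zero rows).
#' @export
apply_quality_filters <- function(records, min_ratio_count = 2) {
  stopifnot(inherits(records, "protein_quant"))
  flagged <- records$contaminant | records$reverse | records$only_by_site
  out <- records[!flagged, , drop = FALSE]

  mask <- !is.na(out$ratio_hl) &
    (is.na(out$ratio_count) | out$ratio_count < min_ratio_count)
  out$ratio_hl[mask] <- NA_real_

  has_cell <- tapply(!is.na(out$ratio_hl), out$protein_id, any)
  keep <- names(has_cell)[has_cell]
  out <- out[out$protein_id %in% keep, , drop = FALSE]
  if (nrow(out) == 0)
    warning("all records removed by quality filters", call. = FALSE)
  rownames(out) <- NULL
  structure(out, design = attr(records, "design"),
            column_map = attr(records, "column_map"),
            class = c("protein_quant", "data.frame"))
}

#' Read a protein FASTA file
#'
#' @param path FASTA file (uncompressed or gzip).
#' @param id `"accession"` extracts the accession from UniProt-style
#'   `db|ACC|NAME` headers (first whitespace token otherwise);
#'   `"token"` always keeps the full first token.
#' @return named character vector of uppercase sequences. Sequences with
#'   characters outside the 20 canonical residues plus `X` are retained and
#'   flagged in the logical `nonstandard` attribute.
#' @export
read_fasta <- function(path, id = c("accession", "token")) {
  id <- match.arg(id)
  if (!file.exists(path) || file.size(path) == 0) .err("empty or missing FASTA: %s", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) .err("FASTA contains no sequences: %s", path)
  tokens <- sub("\\s.*$", "", names(aa))
  ids <- if (id == "accession") {
    vapply(tokens, function(tk) {
      parts <- strsplit(tk, "|", fixed = TRUE)[[1]]
      if (length(parts) >= 3 && parts[1] %in% c("sp", "tr")) parts[2] else tk
    }, character(1), USE.NAMES = FALSE)
  } else tokens
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) .err("duplicate FASTA ids: %s", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(aa))
  names(seqs) <- ids
  nonstd <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)
  names(nonstd) <- ids
  if (any(nonstd))
    message(sum(nonstd), " sequence(s) contain non-standard residues (flagged)")
  attr(seqs, "nonstandard") <- nonstd
  seqs
}

#' Write a result table as TSV
#'
#' Tab-separated, header row, missing values as empty strings, UTF-8,
#' newline-terminated. Numeric values are formatted at full double
#' precision (15 significant digits) so write/read round trips are exact to
#' formatting precision.
#'
#' @param rows a data frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  write.table(rows, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "", eol = "\n")
  invisible(path)
}

#' Serialize records back into the wide protein-groups dialect
#'
#' Inverse of [read_protein_groups()]: produces a wide data frame in the
#' same column dialect the parser reads, with missing ratios/counts written
#' as `"NaN"`, missing intensities as `0` and flags as `"+"`/empty, so that
#' write/read round trips preserve every value.
#'
#' @param records a `protein_quant` data frame.
#' @return wide data frame ready for [write_table()].
#' @export
as_protein_groups_table <- function(records) {
  stopifnot(inherits(records, "protein_quant"))
  design <- attr(records, "design")
  map <- attr(records, "column_map") %||% mq_column_map()
  prot <- unique(records$protein_id)
  first <- match(prot, records$protein_id)

  fmt <- function(v, na) {
    s <- vapply(v, function(x) if (is.na(x)) na else
      format(x, digits = 15, scientific = FALSE, trim = TRUE), character(1))
    s
  }
  out <- data.frame(prot, records$gene_name[first],
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c(map$protein_id, map$gene_name)

  key_rec <- paste(records$protein_id, records$label, sep = "\r")
  for (i in seq_len(nrow(design$samples))) {
    lab <- design$samples$label[i]
    idx <- match(paste(prot, lab, sep = "\r"), key_rec)
    out[[.fill_label(map$ratio, lab)]] <- fmt(records$ratio_hl[idx], "NaN")
    out[[.fill_label(map$ratio_count, lab)]] <- fmt(records$ratio_count[idx], "NaN")
    out[[.fill_label(map$intensity_h, lab)]] <- fmt(records$intensity_h[idx], "0")
    out[[.fill_label(map$intensity_l, lab)]] <- fmt(records$intensity_l[idx], "0")
  }
  out[[map$contaminant]] <- ifelse(records$contaminant[first], "+", "")
  out[[map$reverse]] <- ifelse(records$reverse[first], "+", "")
  out[[map$only_by_site]] <- ifelse(records$only_by_site[first], "+", "")
  out
}
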