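# Fisher exact over/underrepresentation testing with BH FDR control.

#' Read a GMT-like annotation file
#'
#' Each line: category id, category name, then tab-separated member protein
#' ids. Duplicate members within a category are dropped.
#'
#' @param path path to the GMT file.
#' @return object of class `annotation_sets`: a named list of member-id
#'   vectors with a `descriptions` attribute. An optional `source` attribute
#'   (named character) may be set by the caller to group categories for
#'   per-source FDR adjustment.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) .err("empty annotation file: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    .err("malformed GMT line(s) (need id, name, >=1 member): %s",
         paste(bad, collapse = ", "))
  ids <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(ids)) .err("duplicate category ids in %s", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  attr(sets, "descriptions") <- setNames(vapply(parts, `[[`, character(1), 2), ids)
  class(sets) <- "annotation_sets"
  sets
}

#' Two-sided Fisher exact test for one 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed that
#' of the observed table (the usual "probability mass" rule). The odds
#' ratio is `(a d) / (b c)`, with a 0.5 continuity correction added to every
#' cell iff any cell is zero.
#'
#' @param a,b,c,d nonnegative integer cell counts: `a` in-set annotated,
#'   `b` in-set not annotated, `c` background-only annotated, `d`
#'   background-only not annotated.
#' @return list with `p_value`, `odds_ratio`, `direction` (`"over"` iff the
#'   in-set annotation fraction strictly exceeds the background fraction).
#' @export
fisher_test_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    .err("cell counts must be nonnegative integers")
  m <- a + c; n <- b + d; k <- a + b
  if (m + n == 0) .err("empty table")
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))

  cc <- if (any(cells == 0)) 0.5 else 0
  odds <- ((a + cc) * (d + cc)) / ((b + cc) * (c + cc))
  prop_set <- if (a + b > 0) a / (a + b) else 0
  prop_bg <- if (c + d > 0) c / (c + d) else 0
  list(p_value = p, odds_ratio = odds,
       direction = if (prop_set > prop_bg) "over" else "under")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up procedure: after sorting ascending, `q(i) = min_{j >= i}
#' p(j) * m / j`, capped at 1, returned in the original input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]` (no `NA`).
#' @return q-values in input order.
#' @export
#' @examples
#' adjust_fdr_bh(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
adjust_fdr_bh <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    .err("domain error: p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

#' Test functional categories for over/underrepresentation
#'
#' For every annotation category (intersected with the universe and skipped
#' when smaller than `min_category_size`), a 2x2 table of membership in
#' `protein_set` versus the rest of the universe is tested with the
#' two-sided Fisher exact test, and p-values are BH-adjusted. If the
#' annotation object carries a named `source` attribute, adjustment is done
#' within each source; otherwise across all categories jointly.
#'
#' @param protein_set character vector of protein ids (must be a subset of
#'   `universe`).
#' @param universe character vector of all quantified protein ids (the
#'   enrichment background).
#' @param annotations an `annotation_sets` object (see [read_gmt()]).
#' @param min_category_size categories with fewer members inside the
#'   universe are skipped (default 3).
#' @return data frame of class `enrichment_result`, ordered by p-value:
#'   `category_id`, `category_name`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `p_value`, `q_value`, `direction`.
#' @export
fisher_overrepresentation <- function(protein_set, universe, annotations,
                                      min_category_size = 3L) {
  protein_set <- unique(as.character(protein_set))
  universe <- unique(as.character(universe))
  if (length(protein_set) == 0) .err("protein_set is empty")
  offenders <- setdiff(protein_set, universe)
  if (length(offenders))
    .err("protein_set contains ids not in the universe: %s",
         paste(offenders, collapse = ", "))
  if (!inherits(annotations, "annotation_sets"))
    .err("annotations must be an annotation_sets object")

  desc <- attr(annotations, "descriptions")
  src <- attr(annotations, "source")
  rows <- list()
  for (id in names(annotations)) {
    members <- intersect(annotations[[id]], universe)
    if (length(members) < min_category_size) {
      message(sprintf("skipping category '%s': %d member(s) in universe",
                      id, length(members)))
      next
    }
    a <- length(intersect(protein_set, members))
    b <- length(protein_set) - a
    cc <- length(members) - a
    dd <- length(universe) - a - b - cc
    ft <- fisher_test_2x2(a, b, cc, dd)
    rows[[id]] <- data.frame(
      category_id = id,
      category_name = if (!is.null(desc)) unname(desc[id]) else "",
      a = a, b = b, c = cc, d = dd,
      odds_ratio = ft$odds_ratio, p_value = ft$p_value,
      q_value = NA_real_, direction = ft$direction,
      source = if (!is.null(src)) unname(src[id]) else "all",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    return(structure(data.frame(category_id = character()),
                     class = c("enrichment_result", "data.frame")))
  for (s in unique(out$source))
    out$q_value[out$source == s] <- adjust_fdr_bh(out$p_value[out$source == s])
  if (is.null(src)) out$source <- NULL
  out <- out[order(out$p_value, out$category_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"))
}
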