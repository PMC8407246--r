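# Shared fixture builders. All fixtures are constructed in code at test time.

toy_design <- function(times = c(0, 1, 2, 4, 8),
                       reps = paste0("R", 1:3),
                       condition = "persistence") {
  experiment_design(condition, reps, times)
}

# Build a protein_quant long data frame from sparse (protein, replicate,
# time) tuples; unspecified cells are missing. `values` needs protein_id,
# replicate, time_h, ratio_hl and may carry ratio_count (default 2),
# intensity_h, intensity_l. `flags` is a named list protein_id -> flag
# column names to set TRUE.
make_pq <- function(design, values, flags = NULL) {
  prot <- unique(values$protein_id)
  s <- design$samples
  out <- do.call(rbind, lapply(seq_len(nrow(s)), function(i)
    data.frame(protein_id = prot, gene_name = "", label = s$label[i],
               replicate = s$replicate[i], time_h = s$time_h[i],
               intensity_h = NA_real_, intensity_l = NA_real_,
               ratio_hl = NA_real_, ratio_count = NA_real_,
               contaminant = FALSE, reverse = FALSE, only_by_site = FALSE,
               stringsAsFactors = FALSE)))
  key <- function(p, r, t) paste(p, r, t, sep = "\r")
  idx <- match(key(values$protein_id, values$replicate, values$time_h),
               key(out$protein_id, out$replicate, out$time_h))
  stopifnot(!anyNA(idx))
  out$ratio_hl[idx] <- values$ratio_hl
  out$ratio_count[idx] <-
    if ("ratio_count" %in% names(values)) values$ratio_count else 2
  if ("intensity_h" %in% names(values)) out$intensity_h[idx] <- values$intensity_h
  if ("intensity_l" %in% names(values)) out$intensity_l[idx] <- values$intensity_l
  if (!is.null(flags))
    for (p in names(flags))
      for (f in flags[[p]]) out[[f]][out$protein_id == p] <- TRUE
  structure(out, design = design, column_map = mq_column_map(),
            class = c("protein_quant", "data.frame"))
}

# Write a protein_quant fixture as a wide TSV and return the path.
write_pq_table <- function(records, path = tempfile(fileext = ".tsv")) {
  write_table(as_protein_groups_table(records), path)
  path
}

write_toy_fasta <- function(entries, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(entries), function(h)
    c(paste0(">", h), entries[[h]]))), path)
  path
}

write_toy_gmt <- function(categories, path = tempfile(fileext = ".gmt")) {
  writeLines(vapply(names(categories), function(id)
    paste(c(id, paste0(id, " description"), categories[[id]]), collapse = "\t"),
    character(1)), path)
  path
}

write_pipeline_config <- function(table_path, design,
                                  out_dir = tempfile("out"),
                                  fasta = NULL, annotations = NULL,
                                  params = NULL, seed = 1) {
  cfg <- list(paths = c(list(protein_groups = table_path, out_dir = out_dir),
                        if (!is.null(fasta)) list(fasta = fasta),
                        if (!is.null(annotations)) list(annotations = annotations)),
              design = list(condition = design$condition,
                            replicates = design$replicates,
                            time_points_h = design$time_points_h),
              seed = seed)
  if (!is.null(params)) cfg$params <- params
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  path
}
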