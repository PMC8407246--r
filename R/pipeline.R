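# Pipeline orchestration: JSON config validation and staged execution.

.param_defaults <- function() {
  list(min_ratio_count = 2, min_points = 5, min_r2 = 0.70,
       k_clusters = 8, span = 0.5, fdr = 0.1,
       min_pep_len = 7, max_pep_len = 30, max_missed = 2)
}

.stage_deps <- list(filter = character(), merge = "filter", bin = "merge",
                    turnover = "merge", cluster = "filter",
                    enrich = "cluster", ibaq = "filter")

#' Validate a pipeline configuration file
#'
#' Reads a JSON config, rejects unknown keys, fills documented defaults
#' (`min_ratio_count = 2`, `min_points = 5`, `min_r2 = 0.70`,
#' `k_clusters = 8`, `span = 0.5`, `fdr = 0.1`, digest window 7-30 aa with
#' at most 2 missed cleavages, `seed = 1`), checks parameter ranges and that
#' every referenced input path exists.
#'
#' Expected structure:
#' \preformatted{
#' {
#'   "paths":  {"protein_groups": "...", "fasta": null,
#'              "annotations": null, "out_dir": "output"},
#'   "design": {"condition": "persistence",
#'              "replicates": ["R1","R2","R3"],
#'              "time_points_h": [0, 0.5, 1, ...]},
#'   "bins":   {"bin1": [0.5, 1], ...},   // optional, defaults per condition
#'   "params": { ... },                    // optional overrides
#'   "seed":   1
#' }
#' }
#'
#' @param path path to the JSON config file.
#' @return object of class `pipeline_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) .err("config file not found: %s", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)

  allowed_top <- c("paths", "design", "bins", "params", "seed")
  unknown <- setdiff(names(cfg), allowed_top)
  if (length(unknown)) .err("config error: unknown key(s): %s",
                            paste(unknown, collapse = ", "))
  if (is.null(cfg$paths) || is.null(cfg$paths$protein_groups))
    .err("config error: paths$protein_groups is required")
  allowed_paths <- c("protein_groups", "fasta", "annotations", "out_dir")
  unknown <- setdiff(names(cfg$paths), allowed_paths)
  if (length(unknown)) .err("config error: unknown path key(s): %s",
                            paste(unknown, collapse = ", "))
  for (key in c("protein_groups", "fasta", "annotations")) {
    p <- cfg$paths[[key]]
    if (!is.null(p) && !file.exists(p))
      .err("config error: paths$%s does not exist: %s", key, p)
  }
  cfg$paths$out_dir <- cfg$paths$out_dir %||% "output"

  if (is.null(cfg$design) || is.null(cfg$design$condition) ||
      is.null(cfg$design$time_points_h))
    .err("config error: design$condition and design$time_points_h are required")
  design <- experiment_design(cfg$design$condition,
                              cfg$design$replicates %||% paste0("R", 1:3),
                              cfg$design$time_points_h)

  params <- .param_defaults()
  unknown <- setdiff(names(cfg$params), names(params))
  if (length(unknown)) .err("config error: unknown parameter(s): %s",
                            paste(unknown, collapse = ", "))
  params[names(cfg$params)] <- cfg$params
  rng <- function(ok, field, range)
    if (!ok) .err("config error: %s out of range (allowed: %s)", field, range)
  rng(params$span > 0 && params$span <= 1, "span", "(0, 1]")
  rng(params$min_r2 >= 0 && params$min_r2 < 1, "min_r2", "[0, 1)")
  rng(params$fdr > 0 && params$fdr <= 1, "fdr", "(0, 1]")
  rng(params$k_clusters >= 1, "k_clusters", ">= 1")
  rng(params$min_points >= 1, "min_points", ">= 1")
  rng(params$min_ratio_count >= 0, "min_ratio_count", ">= 0")
  rng(params$min_pep_len >= 1 && params$max_pep_len >= params$min_pep_len,
      "min_pep_len/max_pep_len", "1 <= min <= max")
  rng(params$max_missed >= 0, "max_missed", ">= 0")

  bins <- if (!is.null(cfg$bins)) bin_scheme(as.list(cfg$bins), design$condition)
          else default_bin_scheme(design$condition, design$time_points_h)
  unknown_t <- setdiff(unlist(bins$bins), design$time_points_h)
  if (length(unknown_t))
    .err("config error: bin scheme references unknown time point(s): %s",
         paste(unknown_t, collapse = ", "))

  structure(list(paths = cfg$paths, design = design, bins = bins,
                 params = params, seed = as.integer(cfg$seed %||% 1L)),
            class = "pipeline_config")
}

.log_stage <- function(level, stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", level, stage, sprintf(fmt, ...)))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order on the configured
#' inputs, writing every output TSV into `paths$out_dir` together with a
#' config echo (`run_config.json`) and a machine-readable run manifest
#' (`manifest.json`: artifact list with md5 checksums and row counts,
#' config hash, seed, stage timings). Outputs are a pure function of
#' (input files, config, seed): reruns are diff-clean on all TSVs.
#'
#' Stage dependencies: `merge` needs `filter`; `bin` and `turnover` need
#' `merge`; `cluster` needs `filter`; `enrich` needs `cluster` plus an
#' annotations path; `ibaq` needs `filter` plus a FASTA path. Requesting a
#' stage without its upstream stage is an error naming the missing
#' artifact.
#'
#' @param config a `pipeline_config` from [validate_config()].
#' @param stages character vector of stages, or `"all"` (default): every
#'   core stage, plus `enrich`/`ibaq` when their inputs are configured.
#' @return invisibly, the manifest list (with `artifacts`, `counts`,
#'   `config_hash`, `seed`, `timings_s`).
#' @export
run_pipeline <- function(config, stages = "all") {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- names(.stage_deps)
  if (identical(stages, "all")) {
    stages <- c("filter", "merge", "bin", "turnover", "cluster")
    if (!is.null(config$paths$annotations)) stages <- c(stages, "enrich")
    if (!is.null(config$paths$fasta)) stages <- c(stages, "ibaq")
  }
  bad <- setdiff(stages, all_stages)
  if (length(bad)) .err("unknown stage(s): %s", paste(bad, collapse = ", "))
  for (s in stages) {
    need <- setdiff(.stage_deps[[s]], stages)
    if (length(need))
      .err("stage '%s' requires the upstream artifact of stage '%s' which is not scheduled",
           s, paste(need, collapse = ", "))
  }
  if ("enrich" %in% stages && is.null(config$paths$annotations))
    .err("stage 'enrich' requires paths$annotations")
  if ("ibaq" %in% stages && is.null(config$paths$fasta))
    .err("stage 'ibaq' requires paths$fasta")
  stages <- all_stages[all_stages %in% stages]   # dependency order

  out_dir <- config$paths$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  p <- config$params

  artifacts <- list(); counts <- list(); timings <- list()
  add_artifact <- function(name, obj, file) {
    path <- file.path(out_dir, file)
    write_table(obj, path)
    artifacts[[name]] <<- list(file = file, md5 = unname(md5sum(path)),
                               rows = nrow(obj))
  }
  env <- new.env()
  for (s in stages) {
    t0 <- proc.time()[["elapsed"]]
    switch(s,
      filter = {
        raw <- read_protein_groups(config$paths$protein_groups, config$design)
        env$filtered <- apply_quality_filters(raw, p$min_ratio_count)
        .log_stage("INFO", "filter", "%d -> %d protein groups",
                   length(unique(raw$protein_id)),
                   length(unique(env$filtered$protein_id)))
        add_artifact("filtered", as_protein_groups_table(env$filtered),
                     "filtered_protein_groups.tsv")
        counts$proteins_in <- length(unique(raw$protein_id))
        counts$proteins_filtered <- length(unique(env$filtered$protein_id))
      },
      merge = {
        env$merged <- merge_replicates(env$filtered)
        .log_stage("INFO", "merge", "%d merged (protein, time) values",
                   nrow(env$merged))
        out <- env$merged
        out$confidence_class <- as.character(out$confidence_class)
        add_artifact("merged", out, "merged_timecourse.tsv")
      },
      bin = {
        binned <- assign_time_bins(env$merged, config$bins, config$design)
        ranked <- rank_within_bins(binned)
        ranked$bin <- as.character(ranked$bin)
        ranked$quartile <- as.character(ranked$quartile)
        .log_stage("INFO", "bin", "%d bins x %d proteins",
                   length(config$bins$bins), length(unique(ranked$protein_id)))
        add_artifact("binned_ranks", ranked, "binned_ranks.tsv")
      },
      turnover = {
        fits <- flag_reliable_fits(fit_turnover_rates(env$merged),
                                   p$min_points, p$min_r2)
        .log_stage("INFO", "turnover", "%d fits, %d reliable",
                   nrow(fits), sum(fits$reliable))
        out <- fits
        out$half_life_h[is.infinite(out$half_life_h)] <- NA_real_
        add_artifact("turnover_fits", out, "turnover_fits.tsv")
        counts$fits <- nrow(fits); counts$reliable_fits <- sum(fits$reliable)
      },
      cluster = {
        env$profile_matrix <- build_profile_matrix(env$filtered, config$design)
        env$clusters <- cluster_profiles(env$profile_matrix,
                                         p$k_clusters, p$span)
        .log_stage("INFO", "cluster", "%d complete profiles -> %d clusters",
                   nrow(env$profile_matrix), env$clusters$K)
        add_artifact("cluster_assignments",
                     data.frame(protein_id = names(env$clusters$assignment),
                                cluster = unname(env$clusters$assignment)),
                     "cluster_assignments.tsv")
        curves <- do.call(rbind, lapply(seq_len(env$clusters$K), function(g)
          cbind(cluster = g, env$clusters$curves[[g]])))
        add_artifact("cluster_curves", curves, "cluster_curves.tsv")
        add_artifact("cluster_summary",
                     data.frame(cluster = seq_len(env$clusters$K),
                                size = env$clusters$sizes,
                                t50_h = env$clusters$t50_h),
                     "cluster_summary.tsv")
        counts$complete_profiles <- nrow(env$profile_matrix)
      },
      enrich = {
        annotations <- read_gmt(config$paths$annotations)
        universe <- names(env$clusters$assignment)
        res <- lapply(seq_len(env$clusters$K), function(g) {
          set <- universe[env$clusters$assignment == g]
          er <- fisher_overrepresentation(set, universe, annotations)
          if (nrow(er)) cbind(cluster = g, er) else NULL
        })
        out <- do.call(rbind, res)
        if (is.null(out)) out <- data.frame(cluster = integer())
        if (nrow(out)) out$significant <- out$q_value <= p$fdr
        .log_stage("INFO", "enrich", "%d cluster x category tests", nrow(out))
        add_artifact("cluster_enrichment", out, "cluster_enrichment.tsv")
      },
      ibaq = {
        seqs <- read_fasta(config$paths$fasta)
        digests <- digest_proteome(seqs, max_missed = p$max_missed,
                                   min_len = p$min_pep_len,
                                   max_len = p$max_pep_len)
        ib <- compute_ibaq_heavy(env$filtered, digests)
        .log_stage("INFO", "ibaq", "%d (protein, time) estimates, %d skipped",
                   nrow(ib), nrow(attr(ib, "skipped")))
        add_artifact("ibaq_heavy", ib, "ibaq_heavy.tsv")
      })
    timings[[s]] <- round(proc.time()[["elapsed"]] - t0, 3)
  }

  cfg_echo <- file.path(out_dir, "run_config.json")
  jsonlite::write_json(list(paths = config$paths,
                            design = list(condition = config$design$condition,
                                          replicates = config$design$replicates,
                                          time_points_h = config$design$time_points_h),
                            bins = config$bins$bins,
                            params = config$params, seed = config$seed),
                       cfg_echo, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(package = "silacdyn",
                   version = as.character(utils::packageVersion("silacdyn")),
                   seed = config$seed,
                   config_hash = unname(md5sum(cfg_echo)),
                   stages = stages, artifacts = artifacts,
                   counts = counts, timings_s = timings,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
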