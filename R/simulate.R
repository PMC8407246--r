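# Ground-truthed synthetic pulse-SILAC experiments.
#
# World model: each protein has a true first-order turnover rate k drawn
# log-uniformly. Its true incorporation trajectory is
#     I(t) = plateau * pool_purity * (1 - exp(-k t)),
# the exact inverse of the through-origin estimator's model when
# plateau * pool_purity = 1 (then r(t) = exp(k t) - 1). The persistent
# light channel implicitly models the unlabeled dead-cell background; pool
# impurity from amino-acid recycling enters as a plateau multiplier.
# Intensities carry independent multiplicative lognormal noise per channel
# and replicate; missingness is logistic in log10 total intensity
# (low-abundance dropout); a configurable fraction of cells receives a
# ratio count of 1 to exercise the count filter.

#' Configuration of a synthetic pulse-SILAC experiment
#'
#' Defaults state the emulated world: persistence uses 17 time points over
#' 0-24 h with rates log-uniform in 1e-4 to 1e-1 per hour (partial
#' incorporation, median half-life of hundreds of hours); resuscitation
#' uses 21 time points over 0-30 h, rates log-uniform in 0.05 to 1 per hour
#' and a 0.95 incorporation plateau (saturation near 95%).
#'
#' @param condition `"persistence"` or `"resuscitation"`.
#' @param n_proteins number of simulated protein groups (default 500).
#' @param replicates number of biological replicates (default 3).
#' @param time_points_h sampling times (hours, including 0); defaults per
#'   condition via [default_time_points()].
#' @param rate_bounds length-2 bounds of the log-uniform true-rate
#'   distribution, per hour.
#' @param plateau maximum incorporation in `(0, 1]`.
#' @param pool_purity heavy-pool purity in `(0, 1]`; multiplies the plateau.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   intensity noise (per channel and replicate); 0 disables noise.
#' @param dropout `NULL` to disable, or
#'   `list(midpoint_log10 =, steepness =)`: cells are dropped with
#'   probability `plogis(steepness * (midpoint_log10 - log10(total)))`.
#'   The t = 0 control cells are never dropped.
#' @param abundance_meanlog,abundance_sdlog lognormal parameters of total
#'   protein intensity (arbitrary MS units).
#' @param frac_low_count fraction of cells assigned ratio count 1 (default
#'   0.1), exercising the cell-level count filter.
#' @param seed mandatory integer seed.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(condition = c("persistence", "resuscitation"),
                              n_proteins = 500L,
                              replicates = 3L,
                              time_points_h = NULL,
                              rate_bounds = NULL,
                              plateau = NULL,
                              pool_purity = 1,
                              noise_cv = 0.1,
                              dropout = list(midpoint_log10 = 7, steepness = 1.5),
                              abundance_meanlog = log(1e9),
                              abundance_sdlog = 1.5,
                              frac_low_count = 0.1,
                              seed) {
  condition <- match.arg(condition)
  if (missing(seed)) .err("config error: field 'seed' is mandatory")
  if (is.null(time_points_h)) time_points_h <- default_time_points(condition)
  if (is.null(rate_bounds))
    rate_bounds <- if (condition == "persistence") c(1e-4, 1e-1) else c(0.05, 1)
  if (is.null(plateau)) plateau <- if (condition == "persistence") 1 else 0.95

  chk <- function(ok, field) if (!ok) .err("config error: invalid field '%s'", field)
  chk(length(n_proteins) == 1 && n_proteins >= 1, "n_proteins")
  chk(length(replicates) == 1 && replicates >= 1, "replicates")
  chk(length(rate_bounds) == 2 && all(rate_bounds > 0) &&
        rate_bounds[1] <= rate_bounds[2], "rate_bounds")
  chk(length(plateau) == 1 && plateau > 0 && plateau <= 1, "plateau")
  chk(length(pool_purity) == 1 && pool_purity > 0 && pool_purity <= 1, "pool_purity")
  chk(length(noise_cv) == 1 && noise_cv >= 0, "noise_cv")
  if (!is.null(dropout)) {
    chk(is.list(dropout) &&
          setequal(names(dropout), c("midpoint_log10", "steepness")) &&
          dropout$steepness > 0, "dropout")
  }
  chk(abundance_sdlog >= 0, "abundance_sdlog")
  chk(frac_low_count >= 0 && frac_low_count < 1, "frac_low_count")
  chk(length(seed) == 1 && is.finite(seed) && seed == round(seed), "seed")

  structure(list(condition = condition, n_proteins = as.integer(n_proteins),
                 replicates = as.integer(replicates),
                 time_points_h = as.numeric(time_points_h),
                 rate_bounds = as.numeric(rate_bounds), plateau = plateau,
                 pool_purity = pool_purity, noise_cv = noise_cv,
                 dropout = dropout, abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 frac_low_count = frac_low_count, seed = as.integer(seed)),
            class = "simulation_config")
}

# Core generator given per-protein true rates (RNG state is the caller's).
.generate_experiment <- function(config, true_k, true_cluster) {
  n <- config$n_proteins
  design <- experiment_design(config$condition,
                              paste0("R", seq_len(config$replicates)),
                              config$time_points_h)
  ids <- sprintf("P%04d", seq_len(n))
  genes <- sprintf("gene%04d", seq_len(n))
  abundance <- rlnorm(n, config$abundance_meanlog, config$abundance_sdlog)

  samples <- design$samples
  ns <- nrow(samples)
  idx_p <- rep(seq_len(n), times = ns)
  idx_s <- rep(seq_len(ns), each = n)
  t_h <- samples$time_h[idx_s]

  I <- config$plateau * config$pool_purity * (1 - exp(-true_k[idx_p] * t_h))
  sigma <- sqrt(log(1 + config$noise_cv^2))
  noise_h <- rlnorm(n * ns, -sigma^2 / 2, sigma)
  noise_l <- rlnorm(n * ns, -sigma^2 / 2, sigma)
  heavy <- abundance[idx_p] * I * noise_h
  light <- abundance[idx_p] * (1 - I) * noise_l
  ratio <- heavy / light

  count <- 2L + rpois(n * ns, 6)
  low <- runif(n * ns) < config$frac_low_count
  count[low] <- 1L

  drop <- rep(FALSE, n * ns)
  if (!is.null(config$dropout)) {
    total <- heavy + light
    p_drop <- plogis(config$dropout$steepness *
                       (config$dropout$midpoint_log10 - log10(total)))
    drop <- runif(n * ns) < p_drop
    drop[t_h == 0] <- FALSE   # control structure is never removed
  }
  heavy[drop] <- NA_real_
  light[drop] <- NA_real_
  ratio[drop] <- NA_real_
  count[drop] <- NA_integer_
  heavy[!is.na(heavy) & heavy == 0] <- NA_real_   # parser convention: 0 = missing

  records <- data.frame(protein_id = ids[idx_p], gene_name = genes[idx_p],
                        label = samples$label[idx_s],
                        replicate = samples$replicate[idx_s], time_h = t_h,
                        intensity_h = heavy, intensity_l = light,
                        ratio_hl = ratio, ratio_count = as.numeric(count),
                        contaminant = FALSE, reverse = FALSE,
                        only_by_site = FALSE, stringsAsFactors = FALSE)
  records <- structure(records, design = design, column_map = mq_column_map(),
                       class = c("protein_quant", "data.frame"))

  truth <- data.frame(protein_id = ids, true_k = true_k,
                      true_half_life_h = log(2) / true_k,
                      true_cluster = true_cluster,
                      true_abundance = abundance, stringsAsFactors = FALSE)
  list(table = as_protein_groups_table(records), records = records,
       truth = truth, design = design)
}

#' Simulate a pulse-SILAC protein-groups experiment
#'
#' Draws per-protein true turnover rates from the configured log-uniform
#' distribution and generates a protein-groups table in the wide dialect
#' read by [read_protein_groups()], together with the ground truth. With
#' `noise_cv = 0`, `dropout = NULL`, `plateau = 1` and `pool_purity = 1`
#' every generated ratio equals `exp(k t) - 1` exactly, so
#' [fit_turnover_rate()] recovers the true rates to machine precision.
#' The same config and seed always produce an identical table.
#'
#' @param config a [simulation_config()].
#' @return list with `table` (wide data frame), `records` (the equivalent
#'   parsed `protein_quant` long form, for convenience), `truth`
#'   (`protein_id`, `true_k`, `true_half_life_h`, `true_cluster`,
#'   `true_abundance`) and `design`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  true_k <- exp(runif(config$n_proteins,
                      log(config$rate_bounds[1]), log(config$rate_bounds[2])))
  .generate_experiment(config, true_k, NA_integer_)
}

#' Simulate a known-cluster scenario
#'
#' All proteins in cluster `j` share the true rate `rates[j]`, so the
#' generator truth induces a reference partition for evaluating
#' [cluster_profiles()].
#'
#' @param K number of clusters.
#' @param proteins_per_cluster cluster size.
#' @param rates length-`K` vector of distinct true rates (per hour).
#' @param config a [simulation_config()]; its `n_proteins` is overridden.
#' @return as [simulate_experiment()], with `true_cluster` filled in.
#' @export
make_cluster_scenario <- function(K, proteins_per_cluster, rates, config) {
  stopifnot(inherits(config, "simulation_config"))
  K <- as.integer(K)
  if (length(rates) != K) .err("rates must have length K")
  if (anyDuplicated(rates)) .err("duplicate rates")
  config$n_proteins <- K * as.integer(proteins_per_cluster)
  set.seed(config$seed)
  true_k <- rep(as.numeric(rates), each = proteins_per_cluster)
  true_cluster <- rep(seq_len(K), each = proteins_per_cluster)
  .generate_experiment(config, true_k, true_cluster)
}
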