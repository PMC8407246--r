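# turnover_kinetics: incorporation fractions, rate estimator, half-lives,
# reliability filter, recycling estimator.

test_that("incorporation fraction matches the labeling regimes and inverts", {
  expect_equal(incorporation_fraction(1), 0.5)
  expect_equal(incorporation_fraction(0), 0)
  # persistence endpoint (~8.64% of total ion intensity) and resuscitation
  # saturation (~94.6%) regimes
  expect_equal(incorporation_fraction(0.09457), 0.0864, tolerance = 1e-3)
  expect_equal(incorporation_fraction(17.52), 0.946, tolerance = 1e-3)

  f <- seq(0, 0.99, by = 0.01)
  expect_equal(incorporation_fraction(ratio_from_incorporation(f)), f)
  r <- c(0, 0.3, 1, 20)
  expect_equal(ratio_from_incorporation(incorporation_fraction(r)), r)

  expect_error(incorporation_fraction(-0.1), "domain")
  expect_error(incorporation_fraction(Inf), "domain")
  expect_error(ratio_from_incorporation(1), "domain")
  expect_true(is.na(incorporation_fraction(NA)))
})

test_that("rate estimator is exact on model data and single points", {
  t <- 1:5
  fit <- fit_turnover_rate(t, expm1(0.1 * t))
  expect_equal(fit$k, 0.1, tolerance = 1e-14)
  expect_equal(fit$r_squared, 1, tolerance = 1e-14)
  expect_equal(fit$n_points, 5L)

  # one point: k = ln(2) * 10 / 100
  f1 <- fit_turnover_rate(10, 1.0)
  expect_equal(f1$k, log(2) * 10 / 100, tolerance = 1e-14)

  # zero signal: k = 0, R^2 undefined, never reliable
  f0 <- fit_turnover_rate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(f0$k, 0)
  expect_true(is.na(f0$r_squared))
  expect_false(f0$reliable)
  expect_true(is.infinite(f0$half_life_h))

  expect_error(fit_turnover_rate(numeric(0), numeric(0)), "no .time, ratio.")
  expect_error(fit_turnover_rate(c(0, 1), c(1, 1)), "t = 0")
  expect_error(fit_turnover_rate(1, -0.5), "domain")
  expect_error(fit_turnover_rate(1:2, 1), "equal length")
})

test_that("estimator agrees with the brute-force grid minimizer", {
  set.seed(101)
  for (rep in 1:20) {
    m <- sample(3:12, 1)
    t <- sort(runif(m, 0.1, 24))
    r <- expm1(runif(1, 1e-3, 0.3) * t) * exp(rnorm(m, 0, 0.2))
    fit <- fit_turnover_rate(t, r)
    k_star <- oracle_k_grid(t, r)
    expect_equal(fit$k, k_star, tolerance = 1e-10)
  }
})

test_that("doubling all times halves the estimate exactly", {
  set.seed(7)
  t <- sort(runif(8, 0.5, 20))
  r <- expm1(0.05 * t) * exp(rnorm(8, 0, 0.1))
  k1 <- fit_turnover_rate(t, r)$k
  k2 <- fit_turnover_rate(2 * t, r)$k
  expect_equal(k2, k1 / 2, tolerance = 1e-14)
})

test_that("half-life obeys T1/2 * k = ln 2 with an Inf sentinel at k = 0", {
  ks <- 10^seq(-4, 1, length.out = 30)
  expect_equal(half_life_from_rate(ks) * ks, rep(log(2), 30), tolerance = 1e-14)
  expect_equal(half_life_from_rate(log(2)), 1.0)
  # persistence-median regime
  expect_equal(half_life_from_rate(0.0027726), 250.0, tolerance = 1e-4)
  expect_identical(half_life_from_rate(0), Inf)
  expect_error(half_life_from_rate(-1), "domain")
})

test_that("reliability filter applies the >=5 points and R^2 > 0.70 rules", {
  fits <- data.frame(protein_id = c("a", "b", "c", "d"),
                     k = 0.1, half_life_h = log(2) / 0.1,
                     r_squared = c(0.99, 0.69, 0.95, NA),
                     n_points = c(4L, 6L, 5L, 9L),
                     reliable = NA)
  out <- select_reliable_fits(fits)
  expect_equal(out$protein_id, "c")   # a: 4 points; b: R^2 at 0.69; d: NA R^2
  expect_true(all(out$reliable))
  flagged <- flag_reliable_fits(fits)
  expect_equal(flagged$reliable, c(FALSE, FALSE, TRUE, FALSE))
  # boundary: R^2 exactly at the threshold is excluded (strict >)
  expect_equal(nrow(select_reliable_fits(
    transform(fits, r_squared = 0.70, n_points = 5L))), 0)
})

test_that("per-protein fits use post-pulse merged values only", {
  design <- toy_design(times = c(0, 1, 2, 4, 8))
  k_true <- c(A = 0.05, B = 0.3)
  vals <- expand.grid(protein_id = c("A", "B"), replicate = "R1",
                      time_h = c(0, 1, 2, 4, 8), stringsAsFactors = FALSE)
  vals$ratio_hl <- expm1(k_true[vals$protein_id] * vals$time_h)
  m <- merge_replicates(make_pq(design, vals))
  fits <- fit_turnover_rates(m)
  expect_equal(fits$k[match(c("A", "B"), fits$protein_id)], unname(k_true),
               tolerance = 1e-12)
  expect_true(all(fits$n_points == 4))   # t = 0 excluded
})

test_that("recycling estimator matches the conditional-likelihood maximum", {
  est <- estimate_recycling_factor(64, 32)
  expect_equal(est$pool_purity, 0.8)
  expect_equal(est$n_peptides_used, 96L)
  expect_equal(est$pool_purity, oracle_pool_purity(64, 32), tolerance = 1e-4)

  set.seed(3)
  for (i in 1:5) {
    hh <- sample(1:200, 1); hl <- sample(1:200, 1)
    expect_equal(estimate_recycling_factor(hh, hl)$pool_purity,
                 oracle_pool_purity(hh, hl), tolerance = 1e-4)
  }

  expect_equal(estimate_recycling_factor(10, 0)$pool_purity, 1.0)
  expect_equal(estimate_recycling_factor(0, 10)$pool_purity, 0.0)
  expect_error(estimate_recycling_factor(0, 0), "at least one")
  expect_error(estimate_recycling_factor(-1, 5), "nonnegative")

  expect_equal(recycling_corrected_rate(0.04, est), 0.05)
  expect_error(recycling_corrected_rate(0.04, 0), "purity")
})
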