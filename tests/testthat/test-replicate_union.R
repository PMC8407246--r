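# replicate_union: merge classes, time-bin medians, quartile ranking.

merged_fixture <- function() {
  design <- toy_design(times = c(0, 1, 2, 3))
  rec <- make_pq(design, data.frame(
    protein_id = c("A", "A",       "B",      "C", "C", "C"),
    replicate =  c("R1", "R2",     "R1",     "R1", "R2", "R3"),
    time_h = 1,
    ratio_hl =   c(0.2, 0.4,       0.5,      0.1, 0.2, 0.3)))
  merge_replicates(rec)
}

test_that("merge assigns means and confidence classes by replicate count", {
  m <- merged_fixture()
  a <- m[m$protein_id == "A" & m$time_h == 1, ]
  expect_equal(a$ratio_hl, 0.3)
  expect_equal(as.character(a$confidence_class), "II")
  b <- m[m$protein_id == "B" & m$time_h == 1, ]
  expect_equal(b$ratio_hl, 0.5)
  expect_equal(as.character(b$confidence_class), "I")
  cc <- m[m$protein_id == "C" & m$time_h == 1, ]
  expect_equal(cc$ratio_hl, 0.2)
  expect_equal(as.character(cc$confidence_class), "III")
  # time points with no replicate value are omitted entirely
  expect_true(all(m$time_h == 1))
})

test_that("union never invents values and accounts for every cell", {
  design <- toy_design(times = c(0, 1, 2))
  set.seed(21)
  grid <- expand.grid(protein_id = sprintf("P%d", 1:12),
                      replicate = paste0("R", 1:3),
                      time_h = c(1, 2), stringsAsFactors = FALSE)
  grid <- grid[runif(nrow(grid)) < 0.6, ]
  grid$ratio_hl <- runif(nrow(grid))
  rec <- make_pq(design, grid)
  m <- merge_replicates(rec)

  for (i in seq_len(nrow(m))) {
    contrib <- grid$ratio_hl[grid$protein_id == m$protein_id[i] &
                               grid$time_h == m$time_h[i]]
    expect_equal(m$ratio_hl[i], mean(contrib))
    expect_equal(m$n_replicates[i], length(contrib))
  }
  # class histogram + omitted = proteins x time points (post-pulse grid here)
  omitted <- length(unique(grid$protein_id)) * 3 - nrow(m)
  expect_equal(sum(table(m$confidence_class)) + omitted,
               length(unique(grid$protein_id)) * 3)
})

test_that("time bins take medians and flag empty bins missing", {
  design <- toy_design(times = c(0, 1/6, 1/3, 0.5, 1, 2))
  rec <- make_pq(design, data.frame(
    protein_id = c("A", "A", "A", "B", "C"),
    replicate = "R1",
    time_h =   c(1/6, 1/3, 0.5, 1, 2),
    ratio_hl = c(0.1, 0.2, 0.4, 0.7, 0.9)))
  m <- merge_replicates(rec)
  scheme <- bin_scheme(list(early = c(1/6, 1/3, 0.5), late = c(1, 2)),
                       "persistence")
  binned <- assign_time_bins(m, scheme, design)

  expect_equal(binned$median_ratio[binned$protein_id == "A" & binned$bin == "early"], 0.2)
  expect_equal(binned$median_ratio[binned$protein_id == "B" & binned$bin == "late"], 0.7)
  expect_true(is.na(binned$median_ratio[binned$protein_id == "B" & binned$bin == "early"]))

  bad <- bin_scheme(list(x = c(42)), "persistence")
  expect_error(assign_time_bins(m, bad, design), "unknown time point")
  expect_error(bin_scheme(list(a = 1, a2 = 1), "persistence"), "disjoint")
})

test_that("quartile ranking matches the ceiling-rank convention", {
  design <- toy_design(times = c(0, 1))
  rec8 <- make_pq(design, data.frame(protein_id = sprintf("P%d", 1:8),
                                     replicate = "R1", time_h = 1,
                                     ratio_hl = 1:8))
  b8 <- rank_within_bins(assign_time_bins(
    merge_replicates(rec8), bin_scheme(list(b1 = 1), "persistence")))
  expect_setequal(b8$protein_id[b8$quartile == "top25"], c("P8", "P7"))
  expect_setequal(b8$protein_id[b8$quartile == "bottom25"], c("P1", "P2"))

  rec4 <- make_pq(design, data.frame(protein_id = c("P1", "P2", "P3", "P4"),
                                     replicate = "R1", time_h = 1,
                                     ratio_hl = c(4, 3, 2, 1)))
  b4 <- rank_within_bins(assign_time_bins(
    merge_replicates(rec4), bin_scheme(list(b1 = 1), "persistence")))
  expect_equal(as.character(b4$quartile[match(paste0("P", 1:4), b4$protein_id)]),
               c("top25", "p25_50", "p50_75", "bottom25"))

  # tie at the top25 boundary broken by protein_id lexicographic order
  rect <- make_pq(design, data.frame(protein_id = c("PA", "PB", "PC", "PD"),
                                     replicate = "R1", time_h = 1,
                                     ratio_hl = c(5, 5, 2, 1)))
  bt <- rank_within_bins(assign_time_bins(
    merge_replicates(rect), bin_scheme(list(b1 = 1), "persistence")))
  expect_equal(as.character(bt$quartile[bt$protein_id == "PA"]), "top25")
  expect_equal(as.character(bt$quartile[bt$protein_id == "PB"]), "p25_50")

  # fewer than 4 proteins: everything missing, with a warning
  rec2 <- make_pq(design, data.frame(protein_id = c("P1", "P2"),
                                     replicate = "R1", time_h = 1,
                                     ratio_hl = c(1, 2)))
  expect_warning(
    bs <- rank_within_bins(assign_time_bins(
      merge_replicates(rec2), bin_scheme(list(b1 = 1), "persistence"))),
    "fewer than 4")
  expect_true(all(bs$quartile == "missing"))
})

test_that("ranking is invariant under strictly monotone ratio transforms", {
  design <- toy_design(times = c(0, 1, 2))
  set.seed(5)
  vals <- expand.grid(protein_id = sprintf("P%02d", 1:15), replicate = "R1",
                      time_h = c(1, 2), stringsAsFactors = FALSE)
  vals$ratio_hl <- runif(nrow(vals), 0.01, 5)
  scheme <- bin_scheme(list(b1 = 1, b2 = 2), "persistence")

  rank_of <- function(v) {
    vv <- vals; vv$ratio_hl <- v
    r <- rank_within_bins(assign_time_bins(
      merge_replicates(make_pq(design, vv)), scheme))
    as.character(r$quartile[order(r$protein_id, r$bin)])
  }
  base <- rank_of(vals$ratio_hl)
  expect_equal(rank_of(exp(vals$ratio_hl)), base)
  expect_equal(rank_of(vals$ratio_hl^3 + 2), base)
})
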