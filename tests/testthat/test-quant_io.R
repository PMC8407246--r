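# quant_io: table parsing, quality filters, FASTA, TSV round trips.

test_that("read_protein_groups parses values, flags and missing conventions", {
  design <- toy_design(times = c(0, 1, 2))
  rec <- make_pq(design, data.frame(
    protein_id = rep(c("A", "B", "C"), each = 2),
    replicate = "R1", time_h = rep(c(1, 2), 3),
    ratio_hl = c(0.5, 1.25, 0.3, NA, 2, 4),
    intensity_h = c(1e7, 2e7, 3e6, NA, 5e8, 6e8),
    intensity_l = c(2e7, 2e7, 1e7, 1e7, 1e8, 1e8)),
    flags = list(B = "contaminant"))
  path <- write_pq_table(rec)
  got <- read_protein_groups(path, design)

  expect_s3_class(got, "protein_quant")
  expect_setequal(unique(got$protein_id), c("A", "B", "C"))
  expect_true(all(got$contaminant[got$protein_id == "B"]))
  expect_false(any(got$contaminant[got$protein_id != "B"]))

  a1 <- got[got$protein_id == "A" & got$replicate == "R1" & got$time_h == 1, ]
  expect_equal(a1$ratio_hl, 0.5)
  expect_equal(a1$intensity_h, 1e7)
  # "NaN" ratio cell and zero intensity both parse as missing
  b2 <- got[got$protein_id == "B" & got$replicate == "R1" & got$time_h == 2, ]
  expect_true(is.na(b2$ratio_hl))
  expect_true(is.na(b2$intensity_h))
  # unquantified (replicate R2) cells are missing, not zero
  expect_true(all(is.na(got$ratio_hl[got$replicate == "R2"])))
})

test_that("schema violations and duplicate ids are reported by name", {
  design <- toy_design(times = c(0, 1))
  rec <- make_pq(design, data.frame(protein_id = "A", replicate = "R1",
                                    time_h = 1, ratio_hl = 0.5))
  wide <- as_protein_groups_table(rec)

  broken <- wide[, !grepl("^Ratio H/L count", names(wide))]
  p1 <- tempfile(fileext = ".tsv"); write_table(broken, p1)
  expect_error(read_protein_groups(p1, design), "Ratio H/L count R1_T01")

  dup <- rbind(wide, wide)
  p2 <- tempfile(fileext = ".tsv"); write_table(dup, p2)
  expect_error(read_protein_groups(p2, design), "duplicate protein_id.*A")
})

test_that("quality filters drop flagged rows and mask low-count cells", {
  design <- toy_design(times = c(0, 1, 2))
  rec <- make_pq(design, data.frame(
    protein_id = c("A", "B", "C", "D", "E"),
    replicate = "R1", time_h = 1,
    ratio_hl = c(0.3, 0.4, 0.5, 0.6, 0.7),
    ratio_count = c(1, 3, 3, 3, 3),
    intensity_h = 1e6, intensity_l = 1e6),
    flags = list(D = "reverse", E = "reverse"))
  # protein A also has a trusted cell at t = 2 so masking keeps the row
  rec$ratio_hl[rec$protein_id == "A" & rec$time_h == 2 & rec$replicate == "R1"] <- 0.9
  rec$ratio_count[rec$protein_id == "A" & rec$time_h == 2 & rec$replicate == "R1"] <- 5

  out <- apply_quality_filters(rec, min_ratio_count = 2)
  expect_setequal(unique(out$protein_id), c("A", "B", "C"))   # 5 -> 3
  a <- out[out$protein_id == "A" & out$replicate == "R1", ]
  expect_true(is.na(a$ratio_hl[a$time_h == 1]))    # count 1 cell masked
  expect_equal(a$ratio_hl[a$time_h == 2], 0.9)     # trusted cell kept
  expect_equal(a$intensity_h[a$time_h == 1], 1e6)  # intensities untouched

  # idempotence
  expect_identical(as.data.frame(apply_quality_filters(out, 2)),
                   as.data.frame(out))

  all_flagged <- make_pq(design, data.frame(protein_id = "X", replicate = "R1",
                                            time_h = 1, ratio_hl = 1),
                         flags = list(X = "only_by_site"))
  expect_warning(empty <- apply_quality_filters(all_flagged), "all records removed")
  expect_equal(nrow(empty), 0)
})

test_that("read_fasta parses accessions and flags nonstandard residues", {
  path <- write_toy_fasta(list(
    "sp|P0A7D1|RAIA_ECOLI Ribosome-associated inhibitor A" = "MKAAAAAAKLLLLLLLKR",
    "plain_id some description" = "mkbaaaaak"))
  seqs <- read_fasta(path)
  expect_length(seqs, 2)
  expect_named(seqs, c("P0A7D1", "plain_id"))
  expect_equal(unname(seqs["plain_id"]), "MKBAAAAAK")   # uppercased, retained
  expect_equal(unname(attr(seqs, "nonstandard")), c(FALSE, TRUE))

  full <- read_fasta(path, id = "token")
  expect_named(full, c("sp|P0A7D1|RAIA_ECOLI", "plain_id"))

  dup <- write_toy_fasta(list("X a" = "MKAAAK", "X b" = "MKCCCK"))
  expect_error(read_fasta(dup), "duplicate")
  empty <- tempfile(); file.create(empty)
  expect_error(read_fasta(empty), "empty")
})

test_that("write_table emits TSV with empty-string missing values", {
  df <- data.frame(x = c(1.5, NA), y = c("a", "b"), z = c(10L, 20L))
  path <- tempfile(fileext = ".tsv")
  write_table(df, path)
  lines <- readLines(path)
  expect_length(lines, 3)
  expect_equal(lines[1], "x\ty\tz")
  expect_equal(lines[3], "\tb\t20")

  write_table(df[0, ], path)
  expect_length(readLines(path), 1)
})

test_that("write/read round trip preserves all numeric values", {
  design <- toy_design(times = c(0, 0.5, 1, 2))
  set.seed(11)
  vals <- expand.grid(protein_id = sprintf("P%02d", 1:6),
                      replicate = paste0("R", 1:3),
                      time_h = c(0.5, 1, 2), stringsAsFactors = FALSE)
  vals$ratio_hl <- exp(rnorm(nrow(vals), -4, 2))       # spans tiny magnitudes
  vals$ratio_count <- sample(2:9, nrow(vals), TRUE)
  vals$intensity_h <- exp(rnorm(nrow(vals), 18, 2))
  vals$intensity_l <- exp(rnorm(nrow(vals), 20, 2))
  rec <- make_pq(design, vals)

  path <- write_pq_table(rec)
  back <- read_protein_groups(path, design)
  for (col in c("ratio_hl", "ratio_count", "intensity_h", "intensity_l"))
    expect_equal(back[[col]], rec[[col]], tolerance = 1e-12, info = col)

  # a second write/read cycle is byte-stable
  path2 <- write_pq_table(back)
  expect_identical(readLines(path), readLines(path2))
})
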