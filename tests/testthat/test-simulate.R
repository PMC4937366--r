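test_that("undamaged, uncontaminated fragments reproduce the source genome exactly", {
  p <- generate_panel(seed = 2, genome_length = 400, n_sites_per_branch = 2)
  frags <- simulate_fragments(p, "neanderthal", n = 60,
                              damage = damage_model(p_max = 0, p_base = 0),
                              contamination_fraction = 0, seed = 9)
  src <- p$genomes$seq[p$genomes$lineage == "neanderthal"][[1]]
  src2 <- paste0(src, src)
  for (k in seq_len(nrow(frags))) {
    slice <- substr(src2, frags$start[k], frags$start[k] + frags$length[k] - 1L)
    expected <- if (frags$strand[k] == "-") revcomp(slice) else slice
    expect_identical(frags$seq[k], expected)
  }
  expect_true(all(frags$source == "endogenous"))
  expect_true(all(frags$n_damage == 0L))
})

test_that("fragment simulation is deterministic and respects length bounds", {
  p <- generate_panel(seed = 2, genome_length = 300, n_sites_per_branch = 0)
  a <- simulate_fragments(p, "modern_human", 200, seed = 5)
  b <- simulate_fragments(p, "modern_human", 200, seed = 5)
  expect_identical(dplyr::select(a, -damage_pos), dplyr::select(b, -damage_pos))
  expect_true(all(a$length >= 30 & a$length <= 80))
  expect_true(all(a$start >= 1 & a$start <= 300))
})

test_that("terminal damage rate and contaminant fraction match their parameters", {
  p <- generate_panel(seed = 4, genome_length = 1000, n_sites_per_branch = 0)
  pm <- 0.3
  frags <- simulate_fragments(p, "modern_human", 4000,
                              damage = damage_model(p_max = pm, p_base = 0.01),
                              seed = 21)
  prof <- damage_profile(frags, K = 5)
  for (side in c("five_prime", "three_prime")) {
    row <- prof %>% dplyr::filter(end == side, i == 0L)
    se <- sqrt(pm * (1 - pm) / row$observed)
    expect_lt(abs(row$freq - pm), 3 * se)
  }

  cf <- 0.4
  mix <- simulate_fragments(p, "modern_human", 4000,
                            damage = damage_model(0.3, 0.01),
                            contamination_fraction = cf, seed = 22)
  se <- sqrt(cf * (1 - cf) / nrow(mix))
  expect_lt(abs(mean(mix$source == "contaminant") - cf), 3 * se)

  all_contam <- simulate_fragments(p, "modern_human", 50, contamination_fraction = 1,
                                   seed = 23)
  expect_true(all(all_contam$source == "contaminant"))
})

test_that("double-stranded damage mode puts C->T at 5' and G->A at 3'", {
  p <- generate_panel(seed = 6, genome_length = 800, n_sites_per_branch = 0)
  frags <- simulate_fragments(p, "modern_human", 3000,
                              damage = damage_model(0.4, 0.005, both_ends = FALSE),
                              seed = 31)
  prof <- damage_profile(frags, K = 3, include_ga = TRUE)
  ct5 <- prof %>% dplyr::filter(end == "five_prime", i == 0, substitution == "C>T")
  ct3 <- prof %>% dplyr::filter(end == "three_prime", i == 0, substitution == "C>T")
  ga3 <- prof %>% dplyr::filter(end == "three_prime", i == 0, substitution == "G>A")
  expect_gt(ct5$freq, 0.3)
  expect_lt(ct3$freq, 0.05)
  expect_gt(ga3$freq, 0.3)
})

test_that("FASTQ pairs and truth SAM round-trip the simulated molecules", {
  p <- generate_panel(seed = 8, genome_length = 400, n_sites_per_branch = 0)
  frags <- simulate_fragments(p, "modern_human", 40,
                              damage = damage_model(0.3, 0.01), seed = 12)
  r1 <- tempfile(fileext = "_1.fastq")
  r2 <- tempfile(fileext = "_2.fastq")
  suppressWarnings(write_fragment_fastq(frags, r1, r2))
  pairs <- read_fastq_pairs(r1, r2)
  expect_equal(pairs$seq1, frags$seq)
  expect_equal(pairs$seq2, revcomp(frags$seq))

  sam <- tempfile(fileext = ".sam")
  write_truth_sam(frags, sam)
  back <- read_sam(sam)
  expect_equal(back$seq, frags$seq)
  expect_equal(back$start, frags$start)
  expect_equal(back$end, frags$end)
  expect_equal(back$strand, frags$strand)
})

test_that("collagen record profiles pass or fail QC for the constructed reason", {
  good <- simulate_collagen_record("good", seed = 1)
  cn <- simulate_collagen_record("failed_cn", seed = 2)
  yield <- simulate_collagen_record("failed_yield", seed = 3)
  qc <- collagen_qc(dplyr::bind_rows(good, cn, yield))
  expect_equal(qc$pass, c(TRUE, FALSE, FALSE))
  expect_equal(qc$qc_reasons[2], "C:N out of range")
  expect_equal(qc$qc_reasons[3], "yield below cutoff")
})

test_that("simulated peak lists carry the marker masses and honour dropout", {
  clean <- simulate_peaklist("Homininae", mass_jitter_sd = 0, noise_peaks = 0, seed = 1)
  expect_setequal(clean$mz, c(1235.6, 1477.8, 2115.1, 2832.4, 2957.5))
  dropped <- simulate_peaklist("Homininae", dropout_markers = c("A", "G"),
                               mass_jitter_sd = 0, seed = 1)
  expect_setequal(dropped$mz, c(1477.8, 2115.1, 2832.4))
  noisy <- simulate_peaklist("Suidae", noise_peaks = 7, mass_jitter_sd = 0.05, seed = 2)
  expect_equal(nrow(noisy), 12)
  expect_true(all(noisy$mz >= 900 & noisy$mz <= 4000))
  expect_error(simulate_peaklist("Dinosauria"), "unknown taxon")
})
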