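# a 60 bp reference whose composition is easy to reason about
damage_ref <- function() {
  set.seed(123)
  paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
}

test_that("terminal substitution counting handles the degenerate cases", {
  ref <- "CATGCATGCATGCATGCATGCATGCATGCATG"  # C at position 1
  L <- nchar(ref)
  frag_t <- toy_fragment("x", paste0("T", substr(ref, 2, 25)), 1, "+", L)
  prof <- damage_profile(frag_t, reference = ref, K = 3)
  t5 <- prof %>% dplyr::filter(end == "five_prime", i == 0)
  expect_equal(t5$observed, 1L)
  expect_equal(t5$freq, 1.0)

  # no reference C at the 5' terminal -> undefined, not zero
  frag_a <- toy_fragment("y", substr(ref, 2, 25), 2, "+", L)  # starts at A
  prof_a <- damage_profile(frag_a, reference = ref, K = 2)
  expect_true(is.na(prof_a$freq[prof_a$end == "five_prime" & prof_a$i == 0]))

  expect_error(damage_profile(frag_t[0, ], reference = ref), "empty")
})

test_that("profile frequencies are invariant under fragment order permutation", {
  p <- generate_panel(seed = 31, genome_length = 500, n_sites_per_branch = 0)
  frags <- simulate_fragments(p, "modern_human", 300,
                              damage = damage_model(0.3, 0.01), seed = 32)
  prof1 <- damage_profile(frags, K = 8)
  set.seed(1)
  prof2 <- damage_profile(frags[sample(nrow(frags)), ], reference = attr(frags, "reference"),
                          K = 8)
  expect_equal(as.data.frame(prof1), as.data.frame(prof2))
})

test_that("profile recovers the simulator's damage parameters within 3 SE", {
  p <- generate_panel(seed = 41, genome_length = 1000, n_sites_per_branch = 0)
  for (seed in c(51, 52)) {
    frags <- simulate_fragments(p, "modern_human", 4000,
                                damage = damage_model(0.25, 0.02), seed = seed)
    prof <- damage_profile(frags, K = 15)
    t0 <- prof %>% dplyr::filter(end == "five_prime", i == 0)
    expect_lt(abs(t0$freq - 0.25), 3 * sqrt(0.25 * 0.75 / t0$observed))
    int <- prof %>% dplyr::filter(end == "interior")
    expect_lt(abs(int$freq - 0.02), 3 * sqrt(0.02 * 0.98 / int$observed))
  }
})

test_that("the conditional filter keeps a subset, is idempotent, and reads the opposite end", {
  ref <- "CATGCATGCATGCATGCATGCATGCATGCATG"
  L <- nchar(ref)
  # fragment whose 3'-terminal reference base is C, read as T
  mol <- substr(ref, 1, 25)
  mol3 <- paste0(substr(mol, 1, 24), "T")  # position 25 of ref is C
  stopifnot(substr(ref, 25, 25) == "C")
  f3 <- toy_fragment("ct3", mol3, 1, "+", L)
  none <- toy_fragment("clean", mol, 1, "+", L)
  both <- dplyr::bind_rows(f3, none)
  kept <- conditional_filter(both, end = "five_prime", reference = ref)
  expect_equal(kept$id, "ct3")
  expect_equal(nrow(conditional_filter(both, end = "three_prime", reference = ref)), 0L)

  p <- generate_panel(seed = 61, genome_length = 600, n_sites_per_branch = 0)
  frags <- simulate_fragments(p, "modern_human", 500,
                              damage = damage_model(0.3, 0.01), seed = 62)
  f1 <- conditional_filter(frags, "five_prime")
  expect_true(all(f1$id %in% frags$id))
  f2 <- conditional_filter(f1, "five_prime")
  expect_equal(f2$id, f1$id)
})

test_that("conditional filtering enriches damage in a mixture but not in a pure sample", {
  p <- generate_panel(seed = 71, genome_length = 1000, n_sites_per_branch = 0)
  mix <- simulate_fragments(p, "modern_human", 6000,
                            damage = damage_model(0.3, 0.01),
                            contamination_fraction = 0.5, seed = 72)
  enr <- conditional_enrichment(mix)
  # the filtered estimate must exceed the unconditional one beyond the
  # latter's sampling noise (the conditional subset is small by nature)
  expect_gt(enr$cond_freq, enr$uncond_freq)
  expect_gt(enr$cond_freq - enr$uncond_freq, 3 * enr$uncond_se)

  # pure damaged sample: conditional and unconditional agree within 3 SE of
  # the difference
  pure <- simulate_fragments(p, "modern_human", 6000,
                             damage = damage_model(0.3, 0.01), seed = 73)
  enr2 <- conditional_enrichment(pure)
  se_diff <- sqrt(enr2$uncond_se^2 + enr2$cond_se^2)
  expect_lt(abs(enr2$cond_freq - enr2$uncond_freq), 3 * se_diff)
})

test_that("authentication flags damaged specimens and clears undamaged ones", {
  p <- generate_panel(seed = 81, genome_length = 800, n_sites_per_branch = 0)
  damaged <- simulate_fragments(p, "modern_human", 3000,
                                damage = damage_model(0.3, 0.01), seed = 82)
  res <- authenticate_fragments(damaged, specimen_id = "damaged")
  expect_true(res$verdict$evidence_for_ancient_dna)
  expect_gt(res$verdict$conditional_freq_5, 0)

  contam <- simulate_fragments(p, "modern_human", 3000,
                               damage = damage_model(0.01, 0.01), seed = 83)
  res2 <- authenticate_fragments(contam, specimen_id = "contaminant")
  expect_false(res2$verdict$evidence_for_ancient_dna)

  td <- tidy(res$verdict)
  expect_equal(nrow(td), 1L)
  expect_true(td$evidence_for_ancient_dna)

  # insufficient data: no reference C at either terminal of the only fragment
  ref <- "ATGGATGGATGGATGGATGGATGGATGGATGG"
  lone <- toy_fragment("z", substr(ref, 1, 24), 1, "+", nchar(ref))
  v <- authenticate(damage_profile(lone, reference = ref, K = 2))
  expect_false(v$evidence_for_ancient_dna)
  expect_match(v$reason, "insufficient")
})
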