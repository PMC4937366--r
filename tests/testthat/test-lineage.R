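test_that("diagnostic-site definitions apply on hand-built columns", {
  # 30 identical columns except: pos 5 modern-human-derived, pos 10 gapped
  base <- strrep("G", 30)
  mh <- paste0(substr(base, 1, 4), "A", substr(base, 6, 30))
  den_gap <- paste0(substr(base, 1, 9), "-", substr(base, 11, 30))
  panel <- make_panel(list(modern_human = c(mh, mh),
                           neanderthal = base,
                           denisova_sh = den_gap,
                           outgroup = base))
  sites <- find_diagnostic_sites(panel, "branch_specific")
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$pos, 5L)
  expect_equal(sites$branch, "modern_human")
  expect_equal(sites$derived, "A")
  expect_equal(sites$ancestral, "G")
  # the gapped column (which would otherwise be denisova-diagnostic via the
  # gap) is excluded
  expect_false(10L %in% sites$pos)

  # split within a lineage disqualifies a column
  mh_split <- make_panel(list(modern_human = c(mh, base), neanderthal = base,
                              denisova_sh = base, outgroup = base))
  expect_equal(nrow(find_diagnostic_sites(mh_split, "branch_specific")), 0L)

  expect_error(find_diagnostic_sites(make_panel(list(modern_human = mh,
                                                     neanderthal = base)),
                                     "branch_specific"), "outgroup")
})

test_that("site caller equals the brute-force column oracle on random panels", {
  for (seed in 1:20) {
    p <- generate_panel(seed = seed, genome_length = 300,
                        n_sites_per_branch = sample(0:3, 1),
                        n_pairwise_sites = sample(0:2, 1))
    for (mode in c("branch_specific", "pairwise")) {
      got <- find_diagnostic_sites(p, mode)
      want <- bf_diagnostic_sites(p, mode)
      expect_equal(got %>% dplyr::select(pos, branch, derived, ancestral),
                   want, info = paste("seed", seed, mode))
    }
  }
})

test_that("support counting follows the derived/ancestral bookkeeping", {
  # reference all G; one modern-human site at pos 10, derived A
  ref <- strrep("G", 60)
  sites <- tibble::tibble(pos = 10L, branch = "modern_human", derived = "A",
                          ancestral = "G", transition = FALSE, polarized = TRUE)
  L <- 60L
  mk <- function(id, base_at_10, start = 1L) {
    s <- strrep("G", 30)
    off <- 10L - start + 1L
    toy_fragment(id, paste0(substr(s, 1, off - 1), base_at_10,
                            substr(s, off + 1, 30)), start, "+", L)
  }
  frags <- dplyr::bind_rows(mk("d1", "A"), mk("d2", "A"), mk("d3", "A", start = 5L),
                            mk("a1", "G"), mk("x1", "T"))  # T matches neither
  bs <- branch_support(frags, sites, reference = ref)
  expect_equal(bs$n_derived, 3L)
  expect_equal(bs$n_total, 4L)        # the T observation is excluded
  expect_equal(bs$percent_derived, 75)

  # order and duplication of non-overlapping fragments leave percentages alone
  far <- toy_fragment("far", strrep("G", 20), 35L, "+", L)
  bs2 <- branch_support(dplyr::bind_rows(far, frags[sample(nrow(frags)), ], far),
                        sites, reference = ref)
  expect_equal(bs2$percent_derived, bs$percent_derived)
  expect_equal(bs2$n_total, bs$n_total)
})

test_that("fragments from each lineage support their own branch fully and others not at all", {
  p <- generate_panel(seed = 17, genome_length = 1000, n_sites_per_branch = 8)
  sites <- find_diagnostic_sites(p, "branch_specific")
  for (lin in c("modern_human", "neanderthal")) {
    frags <- simulate_fragments(p, lin, 2000, damage = damage_model(0, 0), seed = 18)
    bs <- branch_support(frags, sites)
    own <- bs %>% dplyr::filter(branch == lin)
    other <- bs %>% dplyr::filter(branch != lin, n_total > 0)
    expect_equal(own$percent_derived, 100)
    expect_true(all(other$percent_derived == 0))
    expect_gt(own$n_total, 100)
  }
})

test_that("mtDNA classification combines damage evidence with filtered support", {
  p <- generate_panel(seed = 19, genome_length = 1000, n_sites_per_branch = 10,
                      n_pairwise_sites = 10)
  sites <- find_diagnostic_sites(p, "both")
  damaged <- simulate_fragments(p, "modern_human", 2500,
                                damage = damage_model(0.3, 0.01),
                                contamination_fraction = 0.2, seed = 20)
  verdict <- authenticate_fragments(damaged, specimen_id = "anc")$verdict
  support <- branch_support(damaged, sites, exclude_damage_prone_sites = TRUE)
  expect_equal(classify_mtdna(support, verdict), "Modern Human")

  nea <- simulate_fragments(p, "neanderthal", 2500,
                            damage = damage_model(0.3, 0.01), seed = 21)
  v_nea <- authenticate_fragments(nea, specimen_id = "nea")$verdict
  s_nea <- branch_support(nea, sites, exclude_damage_prone_sites = TRUE)
  expect_equal(classify_mtdna(s_nea, v_nea), "Neanderthal")

  contam <- simulate_fragments(p, "modern_human", 2500,
                               damage = damage_model(0.01, 0.01), seed = 22)
  v_c <- authenticate_fragments(contam, specimen_id = "con")$verdict
  s_c <- branch_support(contam, sites)
  expect_equal(classify_mtdna(s_c, v_c), "No evidence for ancient human DNA")

  # damage evidence but no informative coverage -> ambiguous
  empty_support <- branch_support(damaged, sites[0, ], reference = attr(damaged, "reference"))
  expect_equal(classify_mtdna(empty_support, verdict), "ambiguous")
})

test_that("the support tree rendering carries the percentages and counts", {
  support <- tibble::tibble(
    branch = c("modern_human", "neanderthal", "denisova_sh"),
    n_derived = c(120L, 0L, 0L), n_total = c(120L, 40L, 30L),
    percent_derived = c(100, 0, 0),
    n_derived_filtered = c(12L, 0L, 0L), n_total_filtered = c(12L, 4L, 3L),
    percent_derived_filtered = c(100, 0, 0))
  lines <- format_support_tree(support)
  expect_true(any(grepl("100% \\[120/120\\]", lines)))
  expect_true(any(grepl("0% \\[0/40\\]", lines)))
})
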