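test_that("proxy merging renders gaps, resolves aliases and flags conflicts", {
  mtdna <- tibble::tibble(specimen_id = c("IGVR 20334", "S2", "S3"),
                          mtdna_label = c("Modern Human",
                                          "No evidence for ancient human DNA",
                                          "Modern Human"))
  zooms <- tibble::tibble(specimen_id = c("S2", "S3"),
                          zooms_label = c("Suidae", "Suidae"))
  rep <- merge_reports(mtdna = mtdna, zooms = zooms)
  # alias resolved to the canonical museum number
  expect_true("IGVR 203334" %in% rep$specimen_id)
  expect_false("IGVR 20334" %in% rep$specimen_id)
  # analyses not performed are rendered, not dropped
  expect_equal(rep$zooms[rep$specimen_id == "IGVR 203334"], "Not analysed")
  # non-hominin collagen with no ancient DNA is consistent
  expect_equal(rep$consistency_note[rep$specimen_id == "S2"], "")
  # hominin mtDNA against Suidae collagen must be flagged
  expect_match(rep$consistency_note[rep$specimen_id == "S3"], "CONFLICT")

  dup <- tibble::tibble(specimen_id = c("S1", "S1"),
                        mtdna_label = c("Modern Human", "Neanderthal"))
  expect_error(merge_reports(mtdna = dup), "conflicting duplicate")
  expect_error(merge_reports(), "no proxy outputs")
})

test_that("the pipeline runs the stages the config requests, deterministically", {
  expect_error(run_pipeline(list()), "empty config")

  # collagen-only configuration -> QC columns only
  res <- run_pipeline(list(collagen = mezzena_collagen()))
  expect_equal(nrow(res$report), 5L)
  expect_true("collagen_qc" %in% names(res$report))
  expect_false("mtdna" %in% names(res$report))
  expect_equal(res$thresholds$qc_preset, "paper")

  # full synthetic cohort: every stage populated, re-run byte-identical
  cfg <- list(simulation = list(seed = 33, n_specimens = 4L, n_ancient = 2L,
                                n_fragments = 400L),
              collagen = dplyr::bind_rows(
                simulate_collagen_record("good", seed = 1, specimen_id = "SPEC-01"),
                simulate_collagen_record("failed_cn", seed = 2, specimen_id = "SPEC-03")),
              peaks = list(`SPEC-01` = simulate_peaklist("Homininae", seed = 5),
                           `SPEC-03` = simulate_peaklist("Suidae", seed = 6)))
  r1 <- run_pipeline(cfg)
  r2 <- run_pipeline(cfg)
  expect_identical(r1$report, r2$report)
  expect_equal(nrow(r1$report), 4L)
  expect_true(all(c("mtdna", "zooms", "collagen_qc") %in% names(r1$report)))
  expect_equal(r1$report$mtdna[r1$report$specimen_id == "SPEC-01"], "Modern Human")
  expect_equal(r1$report$zooms[r1$report$specimen_id == "SPEC-03"], "Suidae")
  # an ancient-human specimen with Suidae collagen would conflict; SPEC-03 is
  # contaminant-only here so the row stays clean
  expect_equal(r1$report$consistency_note[r1$report$specimen_id == "SPEC-03"], "")

  dir <- tempfile()
  write_report(r1$report, dir, r1$thresholds)
  write_report(r1$report, file.path(dir, "again"), r1$thresholds)
  expect_identical(readLines(file.path(dir, "specimen_report.csv")),
                   readLines(file.path(dir, "again", "specimen_report.csv")))
  expect_true(file.exists(file.path(dir, "specimen_report.json")))
  expect_true(file.exists(file.path(dir, "specimen_report.md")))
})

test_that("every report field traces back to its owning module", {
  cfg <- list(simulation = list(seed = 44, n_specimens = 2L, n_ancient = 1L,
                                n_fragments = 500L))
  res <- run_pipeline(cfg)
  # recompute one specimen's verdict with the owning modules alone
  sim <- simulate_cohort(seed = 44, n_specimens = 2L, n_ancient = 1L,
                         n_fragments = 500L)
  fr <- sim$specimens[["SPEC-01"]]
  sites <- find_diagnostic_sites(sim$panel, "both")
  verdict <- authenticate_fragments(fr, specimen_id = "SPEC-01")$verdict
  label <- classify_mtdna(branch_support(fr, sites, exclude_damage_prone_sites = TRUE),
                          verdict)
  expect_equal(res$report$mtdna[res$report$specimen_id == "SPEC-01"], label)
  expect_equal(res$report$evidence_for_ancient_dna[res$report$specimen_id == "SPEC-01"],
               verdict$evidence_for_ancient_dna)
})
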