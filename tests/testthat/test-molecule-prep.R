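test_that("pair merging handles identity, partial overlap and failure", {
  # full-overlap identity: mate 2 is the exact reverse complement
  m <- merge_read_pair("ACGTACGTACGTAACC", revcomp("ACGTACGTACGTAACC"), min_overlap = 5)
  expect_equal(m$seq, "ACGTACGTACGTAACC")
  expect_equal(m$overlap, 16)

  # staggered overlap, expected molecule verified by exhaustive enumeration
  s1 <- "ACGTACGTACGTAAA"
  s2 <- revcomp("CGTACGTAAACCC")
  oracle <- bf_merge(s1, s2, min_overlap = 10)
  expect_equal(oracle$seq, "ACGTACGTACGTAAACCC")  # frozen from the oracle
  m2 <- merge_read_pair(s1, s2, min_overlap = 10)
  expect_equal(m2$seq, oracle$seq)
  expect_equal(m2$overlap, oracle$o)

  # disjoint sequences: no qualifying overlap
  expect_null(merge_read_pair("AAAAAAAAAAAA", "CCCCCCCCCCCC", min_overlap = 6))
  expect_error(merge_read_pair("", "ACGT"), "non-empty")
})

test_that("overlap consensus takes the higher-quality base", {
  # disagreement in the overlap: read1 says C (q40), read2 says T (q20) and
  # vice versa at another position
  s1 <- "AACCGGTTCACGTACGT"
  mol_t <- sub("CACGT", "TACGT", s1)  # read2 believes T at the C position
  s2 <- revcomp(mol_t)
  q1 <- strrep("I", nchar(s1))  # Phred 40
  q2 <- strrep("5", nchar(s2))  # Phred 20
  m <- merge_read_pair(s1, s2, q1, q2, min_overlap = 5, max_mismatch_frac = 0.2)
  expect_equal(m$seq, s1)  # high-quality read 1 wins
  m_flip <- merge_read_pair(s1, s2, q2, q1, min_overlap = 5, max_mismatch_frac = 0.2)
  expect_equal(m_flip$seq, mol_t)  # now read 2 wins
})

test_that("circular placement matches the exhaustive rotation scan", {
  set.seed(99)
  ref <- paste(sample(c("A", "C", "G", "T"), 240, replace = TRUE), collapse = "")
  L <- nchar(ref)
  ref2 <- paste0(ref, ref)

  # exact interior substring
  mol <- substr(ref, 101, 140)
  pl <- align_to_circular_reference(mol, ref)
  expect_equal(pl[c("start", "end", "strand", "n_mismatch")],
               list(start = 101L, end = 140L, strand = "+", n_mismatch = 0L))

  # origin-spanning molecule: last 10 + first 15 bases
  wrap <- paste0(substr(ref, L - 9, L), substr(ref, 1, 15))
  pw <- align_to_circular_reference(wrap, ref)
  expect_equal(pw$start, L - 9L)
  expect_equal(pw$end, 15L)
  expect_lt(pw$end, pw$start)
  expect_equal(pw$n_mismatch, 0L)

  # reverse complement of a substring: same span, minus strand
  pm <- align_to_circular_reference(revcomp(substr(ref, 31, 75)), ref)
  expect_equal(pm[c("start", "end", "strand")], list(start = 31L, end = 75L, strand = "-"))

  # molecules with substitutions agree with the brute-force oracle
  set.seed(7)
  for (k in 1:10) {
    s <- sample(L, 1)
    len <- sample(30:60, 1)
    mol <- substr(ref2, s, s + len - 1)
    ch <- strsplit(mol, "")[[1]]
    flip <- sample(len, 2)
    ch[flip] <- vapply(ch[flip], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    mol <- paste(ch, collapse = "")
    if (sample(c(TRUE, FALSE), 1)) mol <- revcomp(mol)
    got <- align_to_circular_reference(mol, ref, max_edit_frac = 0.15)
    want <- bf_align(mol, ref)
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$n_mismatch, want$mm)
  }
})

test_that("deduplication collapses by placement, keeps the best copy, and is idempotent", {
  L <- 200L
  frags <- dplyr::bind_rows(
    toy_fragment("a", "ACGTACGTACGTACGTACGTA", 10, "+", L, qual = strrep("I", 21)),
    toy_fragment("b", "ACGTACGTACGTACGTACGTA", 10, "+", L, qual = strrep("5", 21)),
    toy_fragment("c", "ACGTACGTACGTACGTACGTA", 10, "-", L),
    toy_fragment("d", "TTTTACGTACGTACGTACGTA", 50, "+", L))
  dd <- deduplicate(frags)
  expect_equal(nrow(dd), 3L)                       # a/b collapse, c and d stay
  expect_true("a" %in% dd$id && !"b" %in% dd$id)   # higher summed quality survives
  expect_true("c" %in% dd$id)                      # strand is part of the key
  dd2 <- deduplicate(dd)
  expect_equal(as.data.frame(dd2), as.data.frame(dd))
  expect_equal(glance(dd)$n_unique, 3L)

  # n distinct placements -> n survivors
  distinct <- dplyr::bind_rows(lapply(1:5, function(k) {
    toy_fragment(paste0("f", k), strrep("ACGT", 6), 10 + 3 * k, "+", L)
  }))
  expect_equal(nrow(deduplicate(distinct)), 5L)
})

test_that("merge + align recovers the true placement of simulated molecules", {
  p <- generate_panel(seed = 13, genome_length = 1000, n_sites_per_branch = 0)
  frags <- simulate_fragments(p, "modern_human", 150,
                              damage = damage_model(0, 0), seed = 14)
  r1 <- tempfile(fileext = ".fastq")
  r2 <- tempfile(fileext = ".fastq")
  suppressWarnings(write_fragment_fastq(frags, r1, r2))
  fc <- prep_fragments(r1, r2, panel_reference(p))
  joined <- dplyr::inner_join(as_tibble(fc), as_tibble(frags), by = "id",
                              suffix = c("", ".true"))
  expect_equal(joined$seq, joined$seq.true)
  recovered <- mean(joined$start == joined$start.true &
                      joined$end == joined$end.true &
                      joined$strand == joined$strand.true)
  expect_gte(recovered, 0.99)
  counts <- glance(fc)
  expect_true(counts$n_unique <= counts$n_aligned &&
                counts$n_aligned <= counts$n_merged &&
                counts$n_merged <= counts$n_raw)
})
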