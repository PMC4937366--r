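# Independent brute-force oracles and fixture builders. These deliberately
# use naive loop implementations, not the package's vectorised code paths.

# build a lineage_panel by hand from named character vectors of sequences
make_panel <- function(seqs) {
  genomes <- dplyr::bind_rows(purrr::imap(seqs, function(ss, lin) {
    tibble::tibble(lineage = lin,
                   genome_id = paste0(lin, "_", seq_along(ss)),
                   seq = ss)
  }))
  structure(list(genomes = genomes,
                 truth_sites = tibble::tibble(pos = integer(0), branch = character(0),
                                              derived = character(0), ancestral = character(0),
                                              transition = logical(0), polarized = logical(0)),
                 length = nchar(genomes$seq[[1]]), seed = NA_integer_),
            class = "lineage_panel")
}

# naive per-column diagnostic-site scan
bf_diagnostic_sites <- function(panel, mode) {
  g <- panel$genomes
  L <- nchar(g$seq[[1]])
  lineages <- unique(g$lineage)
  hominins <- intersect(c("modern_human", "neanderthal", "denisova_sh"), lineages)
  base_at <- function(lin, pos) {
    unique(vapply(g$seq[g$lineage == lin], substr, "", pos, pos, USE.NAMES = FALSE))
  }
  rows <- list()
  for (pos in seq_len(L)) {
    al <- lapply(lineages, base_at, pos = pos)
    names(al) <- lineages
    clean <- vapply(al, function(a) length(a) == 1 && a %in% c("A", "C", "G", "T"), TRUE)
    if (mode == "branch_specific") {
      for (br in hominins) {
        others <- setdiff(lineages, br)
        if (!clean[[br]] || !all(clean[others])) next
        oa <- unique(unlist(al[others]))
        if (length(oa) == 1 && oa != al[[br]]) {
          rows[[length(rows) + 1]] <- tibble::tibble(pos = pos, branch = br,
                                                     derived = al[[br]], ancestral = oa)
        }
      }
    } else {
      if (clean[["modern_human"]] && clean[["neanderthal"]] &&
          al[["modern_human"]] != al[["neanderthal"]]) {
        og <- if ("outgroup" %in% lineages && clean[["outgroup"]]) al[["outgroup"]] else NA
        pol <- !is.na(og) && og %in% c(al[["modern_human"]], al[["neanderthal"]])
        der <- if (pol && og == al[["modern_human"]]) al[["neanderthal"]] else al[["modern_human"]]
        anc <- if (pol && og == al[["modern_human"]]) al[["modern_human"]] else al[["neanderthal"]]
        rows[[length(rows) + 1]] <- tibble::tibble(pos = pos, branch = "pairwise_nea_vs_mh",
                                                   derived = der, ancestral = anc)
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(pos = integer(0), branch = character(0),
                          derived = character(0), ancestral = character(0)))
  }
  dplyr::arrange(dplyr::bind_rows(rows), pos, branch)
}

# exhaustive placement scan over every rotation and both strands
bf_align <- function(molecule, reference) {
  L <- nchar(reference)
  l <- nchar(molecule)
  ref2 <- paste0(reference, reference)
  best <- NULL
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") molecule else paleoproof::revcomp(molecule)
    pc <- strsplit(pat, "")[[1]]
    for (s in seq_len(L)) {
      rc <- strsplit(substr(ref2, s, s + l - 1), "")[[1]]
      mm <- sum(pc != rc)
      better <- is.null(best) || mm < best$mm ||
        (mm == best$mm && (s < best$start ||
                             (s == best$start && strand == "+" && best$strand == "-")))
      if (better) best <- list(start = s, strand = strand, mm = mm)
    }
  }
  best
}

# enumerate every suffix/prefix overlap; fewest mismatches wins, ties to the
# longest overlap
bf_merge <- function(seq1, seq2, min_overlap, max_mismatch_frac = 0.1) {
  rc2 <- paleoproof::revcomp(seq2)
  l1 <- nchar(seq1)
  l2 <- nchar(rc2)
  best <- NULL
  for (o in seq(min_overlap, min(l1, l2))) {
    a <- strsplit(substr(seq1, l1 - o + 1, l1), "")[[1]]
    b <- strsplit(substr(rc2, 1, o), "")[[1]]
    mm <- sum(a != b)
    if (mm / o <= max_mismatch_frac &&
        (is.null(best) || mm < best$mm || (mm == best$mm && o > best$o))) {
      best <- list(o = o, mm = mm,
                   seq = paste0(substr(seq1, 1, l1 - o), substr(rc2, 1, l2)))
    }
  }
  best
}

# toy aligned fragment row on a given reference
toy_fragment <- function(id, seq, start, strand = "+", L, qual = NULL) {
  tibble::tibble(id = id, seq = seq, qual = qual %||% strrep("F", nchar(seq)),
                 start = as.integer(start),
                 end = ((start + nchar(seq) - 2L) %% L) + 1L,
                 strand = strand, length = nchar(seq))
}

`%||%` <- rlang::`%||%`

# write a small IntCal-dialect curve file and return its path
write_curve_file <- function(lines, path = tempfile(fileext = ".14c")) {
  writeLines(lines, path)
  path
}

# pooled (both ends) unconditional vs opposite-end-conditional terminal C->T
# frequencies, with binomial SEs from the observed counts
conditional_enrichment <- function(frags) {
  ref <- attr(frags, "reference")
  term <- function(prof, side) {
    dplyr::filter(prof, end == side, i == 0L)
  }
  u <- paleoproof::damage_profile(frags, reference = ref, K = 2)
  u5 <- term(u, "five_prime")
  u3 <- term(u, "three_prime")
  c5 <- term(paleoproof::damage_profile(
    paleoproof::conditional_filter(frags, "five_prime", reference = ref),
    reference = ref, K = 2), "five_prime")
  c3 <- term(paleoproof::damage_profile(
    paleoproof::conditional_filter(frags, "three_prime", reference = ref),
    reference = ref, K = 2), "three_prime")
  pool <- function(a, b) {
    n <- a$observed + b$observed
    p <- (a$converted + b$converted) / n
    list(freq = p, n = n, se = sqrt(p * (1 - p) / n))
  }
  pu <- pool(u5, u3)
  pc <- pool(c5, c3)
  list(uncond_freq = pu$freq, uncond_se = pu$se, uncond_n = pu$n,
       cond_freq = pc$freq, cond_se = pc$se, cond_n = pc$n)
}
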