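#' Merge an overlapping read pair into a full-length molecule
#'
#' Finds the best overlap between the suffix of read 1 and the prefix of
#' the reverse complement of read 2 (the standard geometry for a short
#' insert sequenced from both ends). Among overlap lengths
#' `>= min_overlap` whose mismatch fraction is `<= max_mismatch_frac`, the
#' overlap with the fewest mismatches wins, ties going to the longer
#' overlap. In the overlapped region the consensus takes the
#' higher-quality base (read 1 on quality ties) and the higher of the two
#' qualities. Pairs with no qualifying overlap fail (return `NULL`):
#' non-overlapping pairs cannot yield a full-length molecule and are
#' discarded upstream.
#'
#' @param seq1,seq2 Read sequences (read 2 in sequencing orientation).
#' @param qual1,qual2 Phred+33 quality strings; default constant Phred 37.
#' @param min_overlap Minimum acceptable overlap length (>= 1).
#' @param max_mismatch_frac Maximum mismatch fraction within the overlap.
#' @return `list(seq, qual, overlap, mismatches)` or `NULL` on failure.
#' @examples
#' merge_read_pair("ACGTACGTACGT", revcomp("ACGTACGTACGT"), min_overlap = 5)
#' @export
merge_read_pair <- function(seq1, seq2, qual1 = NULL, qual2 = NULL,
                            min_overlap = 11L, max_mismatch_frac = 0.1) {
  if (nchar(seq1) == 0L || nchar(seq2) == 0L) abort("reads must be non-empty")
  if (min_overlap < 1L) abort("min_overlap must be >= 1")
  qual1 <- qual1 %||% strrep("F", nchar(seq1))
  qual2 <- qual2 %||% strrep("F", nchar(seq2))
  rc2 <- revcomp(seq2)
  q2 <- stringi::stri_reverse(qual2)
  l1 <- nchar(seq1)
  l2 <- nchar(rc2)
  r1 <- charToRaw(seq1)
  r2 <- charToRaw(rc2)

  best <- NULL
  for (o in seq(from = min(l1, l2), to = min_overlap, by = -1L)) {
    mm <- sum(r1[(l1 - o + 1L):l1] != r2[1L:o])
    if (mm / o <= max_mismatch_frac &&
        (is.null(best) || mm < best$mm)) {
      best <- list(o = o, mm = mm)
      if (mm == 0L) break
    }
  }
  if (is.null(best)) return(NULL)

  o <- best$o
  p1 <- phred_scores(qual1)
  p2 <- phred_scores(q2)
  ov1 <- (l1 - o + 1L):l1
  ov2 <- 1L:o
  take2 <- p2[ov2] > p1[ov1]
  cons <- r1[ov1]
  cons[take2] <- r2[ov2][take2]
  seq <- paste0(substr(seq1, 1L, l1 - o), rawToChar(cons),
                substr(rc2, o + 1L, l2))
  qual <- phred_string(c(p1[seq_len(l1 - o)], pmax(p1[ov1], p2[ov2]),
                         p2[seq(o + 1L, length.out = l2 - o)]))
  list(seq = seq, qual = qual, overlap = o, mismatches = best$mm)
}

#' Merge a table of read pairs
#'
#' Vectorised driver for [merge_read_pair()] over a pair table such as the
#' one produced by [read_fastq_pairs()]. Pairs that fail to merge are
#' dropped; the number of raw pairs is recorded in the `n_raw` attribute.
#'
#' @param pairs Tibble with `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @inheritParams merge_read_pair
#' @return Tibble `id`, `seq`, `qual`, `length` of merged molecules.
#' @export
merge_pairs <- function(pairs, min_overlap = 11L, max_mismatch_frac = 0.1) {
  merged <- purrr::pmap(list(pairs$seq1, pairs$seq2, pairs$qual1, pairs$qual2),
                        function(s1, s2, q1, q2) {
                          merge_read_pair(s1, s2, q1, q2,
                                          min_overlap = min_overlap,
                                          max_mismatch_frac = max_mismatch_frac)
                        })
  ok <- !purrr::map_lgl(merged, is.null)
  out <- tibble(id = pairs$id[ok],
                seq = purrr::map_chr(merged[ok], "seq"),
                qual = purrr::map_chr(merged[ok], "qual"))
  out$length <- nchar(out$seq)
  attr(out, "n_raw") <- nrow(pairs)
  out
}

#' Place a molecule on a circular reference
#'
#' Gap-free semi-global placement: the molecule and its reverse complement
#' are scanned against the doubled reference (so origin-spanning placements
#' are found), and the placement with the fewest substitutions is reported
#' in the coordinates of the original circle. Ties are broken by smallest
#' start position, then by the forward strand. Placements whose mismatch
#' fraction exceeds `max_edit_frac` are rejected.
#'
#' @param molecule Molecule sequence (>= 20 bp).
#' @param reference Circular reference sequence (character or
#'   `Biostrings::DNAString`), at least as long as the molecule.
#' @param max_edit_frac Maximum tolerated mismatch fraction.
#' @return `list(start, end, strand, n_mismatch)` with `end < start`
#'   indicating an origin-spanning placement, or `NULL` when unaligned.
#' @examples
#' ref <- strrep("ACGTTGCAAC", 10)
#' align_to_circular_reference(substr(ref, 11, 40), ref)
#' @export
align_to_circular_reference <- function(molecule, reference, max_edit_frac = 0.1) {
  reference <- as_reference_string(reference)
  l <- nchar(molecule)
  L <- nchar(reference)
  if (l < 20L) abort("molecule must be at least 20 bp")
  if (L < l) abort("reference must be at least as long as the molecule")
  ref2 <- Biostrings::DNAString(paste0(reference, reference))
  fwd <- Biostrings::DNAString(molecule)
  rev <- Biostrings::reverseComplement(fwd)
  max_mm <- floor(max_edit_frac * l)

  for (mm in 0:max_mm) {
    hits <- list()
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") fwd else rev
      m <- Biostrings::matchPattern(pat, ref2, max.mismatch = mm, with.indels = FALSE)
      starts <- Biostrings::start(m)
      starts <- starts[starts <= L]  # each circular placement once
      if (length(starts) > 0L) {
        hits[[strand]] <- tibble(start = starts, strand = strand)
      }
    }
    if (length(hits) > 0L) {
      cand <- bind_rows(hits) %>%
        arrange(.data$start, .data$strand) %>%
        slice(1L)
      return(list(start = cand$start,
                  end = circular_end(cand$start, l, L),
                  strand = cand$strand,
                  n_mismatch = mm))
    }
  }
  NULL
}

#' Align a table of molecules to the circular reference
#'
#' Driver for [align_to_circular_reference()]; unaligned molecules are
#' dropped and counted. The result is a fragment table in the shape shared
#' with the simulator (`seq` kept in molecule orientation).
#'
#' @param molecules Tibble with `id`, `seq`, `qual` (e.g. from
#'   [merge_pairs()]).
#' @inheritParams align_to_circular_reference
#' @return Fragment tibble with `id`, `seq`, `qual`, `start`, `end`,
#'   `strand`, `length`, `n_mismatch`; attributes `reference`, `n_merged`,
#'   `n_raw` (when present on the input).
#' @export
align_fragments <- function(molecules, reference, max_edit_frac = 0.1) {
  reference <- as_reference_string(reference)
  placements <- purrr::map(molecules$seq, align_to_circular_reference,
                           reference = reference, max_edit_frac = max_edit_frac)
  ok <- !purrr::map_lgl(placements, is.null)
  out <- tibble(id = molecules$id[ok],
                seq = molecules$seq[ok],
                qual = molecules$qual[ok],
                start = purrr::map_int(placements[ok], ~ as.integer(.x$start)),
                end = purrr::map_int(placements[ok], ~ as.integer(.x$end)),
                strand = purrr::map_chr(placements[ok], "strand"),
                length = nchar(molecules$seq[ok]),
                n_mismatch = purrr::map_int(placements[ok], ~ as.integer(.x$n_mismatch)))
  attr(out, "reference") <- reference
  attr(out, "ref_length") <- nchar(reference)
  attr(out, "n_raw") <- attr(molecules, "n_raw") %||% nrow(molecules)
  attr(out, "n_merged") <- nrow(molecules)
  out
}

#' Collapse amplification duplicates
#'
#' Fragments sharing the same placement — identical `(start, end, strand)`
#' — are taken to be PCR copies of one template molecule and collapsed to
#' the representative with the highest summed base quality (first by id on
#' ties). The uniqueness key is the placement, not the sequence, so copies
#' differing only by deamination collapse together. Raw/merged/aligned/
#' unique molecule counts are carried in attributes and reported by
#' [glance()].
#'
#' @param fragments Aligned fragment tibble.
#' @return A `fragment_collection` tibble of unique molecules.
#' @examples
#' frags <- tibble::tibble(id = c("a", "b"), seq = c("ACGT", "ACGT"),
#'                         qual = c("FFFF", "::::"), start = 1L, end = 4L,
#'                         strand = "+", length = 4L)
#' deduplicate(frags)
#' @export
deduplicate <- function(fragments) {
  check_fragments(fragments)
  qsum <- purrr::map_int(fragments$qual, ~ sum(phred_scores(.x)))
  out <- fragments %>%
    mutate(.qsum = qsum) %>%
    arrange(.data$start, .data$end, .data$strand, dplyr::desc(.data$.qsum), .data$id) %>%
    distinct(.data$start, .data$end, .data$strand, .keep_all = TRUE) %>%
    select(-".qsum")
  for (a in c("reference", "ref_length", "n_raw", "n_merged")) {
    attr(out, a) <- attr(fragments, a)
  }
  attr(out, "n_aligned") <- attr(fragments, "n_aligned") %||% nrow(fragments)
  attr(out, "n_unique") <- nrow(out)
  class(out) <- unique(c("fragment_collection", class(out)))
  out
}

#' @export
#' @method glance fragment_collection
glance.fragment_collection <- function(x, ...) {
  tibble(n_raw = attr(x, "n_raw") %||% NA_integer_,
         n_merged = attr(x, "n_merged") %||% NA_integer_,
         n_aligned = attr(x, "n_aligned") %||% nrow(x),
         n_unique = attr(x, "n_unique") %||% nrow(x))
}

#' Reconstruct, align and deduplicate molecules from FASTQ pairs
#'
#' End-to-end preparation: merge fully-overlapping read pairs into
#' molecules, place each on the circular reference, and collapse
#' amplification duplicates. This is the fragment set every genetic
#' analysis downstream consumes.
#'
#' @param r1_path,r2_path Paired FASTQ files.
#' @param reference Circular reference sequence.
#' @inheritParams merge_read_pair
#' @inheritParams align_to_circular_reference
#' @return A [fragment_collection][deduplicate] tibble.
#' @export
prep_fragments <- function(r1_path, r2_path, reference,
                           min_overlap = 11L, max_mismatch_frac = 0.1,
                           max_edit_frac = 0.1) {
  read_fastq_pairs(r1_path, r2_path) %>%
    merge_pairs(min_overlap = min_overlap, max_mismatch_frac = max_mismatch_frac) %>%
    align_fragments(reference = reference, max_edit_frac = max_edit_frac) %>%
    deduplicate()
}

#' Per-base mismatch records of aligned fragments
#'
#' Lists every position where a fragment differs from the reference, with
#' reference position (1-based on the circle), reference base, read base
#' (reference-forward orientation) and Phred quality. Bases below
#' `min_base_quality` are reported as `N`.
#'
#' @param fragments Aligned fragment tibble.
#' @param reference Circular reference; defaults to the table's `reference`
#'   attribute.
#' @param min_base_quality Quality floor below which bases are masked.
#' @return Tibble `id`, `ref_pos`, `ref_base`, `read_base`, `qual`.
#' @export
fragment_mismatches <- function(fragments, reference = attr(fragments, "reference"),
                                min_base_quality = 20L) {
  check_fragments(fragments)
  reference <- as_reference_string(reference)
  L <- nchar(reference)
  fwd <- forward_seq(fragments)
  fq <- forward_qual(fragments)
  ref2 <- paste0(reference, reference)
  rows <- purrr::pmap(list(fragments$id, fwd, fq, fragments$start, fragments$length),
                      function(id, s, q, st, len) {
                        rb <- strsplit(substr(ref2, st, st + len - 1L), "")[[1L]]
                        sb <- strsplit(s, "")[[1L]]
                        qs <- phred_scores(q)
                        sb[qs < min_base_quality] <- "N"
                        hit <- which(sb != rb)
                        if (length(hit) == 0L) return(NULL)
                        tibble(id = id,
                               ref_pos = ((st - 1L + hit - 1L) %% L) + 1L,
                               ref_base = rb[hit], read_base = sb[hit],
                               qual = qs[hit])
                      })
  rows <- rows[!purrr::map_lgl(rows, is.null)]
  if (length(rows) == 0L) {
    return(tibble(id = character(0), ref_pos = integer(0), ref_base = character(0),
                  read_base = character(0), qual = integer(0)))
  }
  bind_rows(rows)
}
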