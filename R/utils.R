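#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character strings. Gaps (`-`) and
#' `N` are preserved.
#'
#' @param x Character vector of DNA sequences over `{A,C,G,T,N,-}`.
#' @return Character vector of the same length.
#' @examples
#' revcomp(c("ACGT", "TTAA"))
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgt", "TGCAtgca", x))
}

# phred scores (integer vector) from a Phred+33 quality string
phred_scores <- function(qual) {
  as.integer(charToRaw(qual)) - 33L
}

phred_string <- function(scores) {
  rawToChar(as.raw(scores + 33L))
}

# positions covered by a (possibly origin-spanning) fragment, 1-based on a
# circle of length L
circular_positions <- function(start, len, L) {
  ((start - 1L + seq_len(len) - 1L) %% L) + 1L
}

# 1-based offset of reference position pos within a fragment starting at
# start on a circle of length L; may exceed the fragment length (not covered)
circular_offset <- function(pos, start, L) {
  ((pos - start) %% L) + 1L
}

# end coordinate of a fragment on the circle
circular_end <- function(start, len, L) {
  ((start + len - 2L) %% L) + 1L
}

# coerce a reference given as character scalar, DNAString or length-1
# DNAStringSet to an upper-case character scalar
as_reference_string <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    if (length(reference) != 1L) {
      abort("reference must be a single sequence")
    }
    reference <- reference[[1L]]
  }
  if (inherits(reference, "DNAString")) {
    reference <- as.character(reference)
  }
  if (!is.character(reference) || length(reference) != 1L || nchar(reference) < 1L) {
    abort("reference must be a single non-empty DNA sequence")
  }
  toupper(reference)
}

# exact binomial confidence interval; NA bounds when n == 0
binom_ci <- function(x, n, conf_level = 0.95) {
  if (n == 0L) {
    return(c(NA_real_, NA_real_))
  }
  as.numeric(binom.test(x, n, conf.level = conf_level)$conf.int)
}

# molecule-oriented reference slice for each fragment: the reference bases
# under the placement, reverse-complemented for minus-strand fragments so
# that they line up with `seq` in read orientation
molecule_ref_seq <- function(fragments, reference) {
  reference <- as_reference_string(reference)
  L <- nchar(reference)
  ref2 <- paste0(reference, reference)
  slice <- substring(ref2, fragments$start, fragments$start + fragments$length - 1L)
  ifelse(fragments$strand == "-", revcomp(slice), slice)
}

# reference-forward-oriented fragment sequence (and quality) so that
# substr(seq_fwd, off, off) is the base the fragment places at reference
# offset `off` from its start
forward_seq <- function(fragments) {
  ifelse(fragments$strand == "-", revcomp(fragments$seq), fragments$seq)
}

forward_qual <- function(fragments) {
  ifelse(fragments$strand == "-", stringi::stri_reverse(fragments$qual), fragments$qual)
}

check_fragments <- function(fragments) {
  needed <- c("id", "seq", "qual", "start", "end", "strand", "length")
  missing <- setdiff(needed, names(fragments))
  if (length(missing) > 0L) {
    abort(paste0("fragment table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  invisible(fragments)
}
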