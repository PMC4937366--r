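#' Position-from-end substitution (deamination) profile
#'
#' For each distance `i` from the 5' and 3' fragment ends (`i = 0` at the
#' terminal base, molecule orientation), computes the frequency with which
#' a reference C is read as T, the signature of post-mortem cytosine
#' deamination. The denominator at a position counts fragments whose
#' reference base there is C and whose read base is confidently called
#' (quality at or above the floor); positions with zero such observations
#' are reported as `NA`, never as zero. An `interior` row gives the
#' baseline frequency over positions more than `K` bases from both ends.
#' G-to-A frequencies (the complementary-strand signature relevant to
#' double-stranded libraries) can be profiled alongside.
#'
#' @param fragments Aligned fragment tibble (simulator output or
#'   [prep_fragments()] result).
#' @param reference Circular reference; defaults to the `reference`
#'   attribute of `fragments`.
#' @param K Profile depth: positions `0 .. K-1` from each end.
#' @param min_base_quality Phred floor for a base to count as confidently
#'   called.
#' @param include_ga Also profile G->A substitutions.
#' @return A `damage_profile` tibble: `end` (`"five_prime"`,
#'   `"three_prime"`, `"interior"`), `i` (`NA` for interior),
#'   `substitution`, `observed`, `converted`, `freq`, `ci_low`, `ci_high`
#'   (exact binomial 95% CI).
#' @examples
#' panel <- generate_panel(seed = 1, genome_length = 500, n_sites_per_branch = 0)
#' frags <- simulate_fragments(panel, "modern_human", 200,
#'                             damage = damage_model(0.4, 0.01), seed = 2)
#' damage_profile(frags, K = 5)
#' @export
damage_profile <- function(fragments, reference = attr(fragments, "reference"),
                           K = 15L, min_base_quality = 20L, include_ga = FALSE) {
  check_fragments(fragments)
  if (nrow(fragments) == 0L) abort("cannot profile an empty fragment collection")
  if (K < 1L) abort("K must be >= 1")
  reference <- as_reference_string(reference)
  refm <- molecule_ref_seq(fragments, reference)
  seqs <- fragments$seq
  quals <- fragments$qual
  lens <- fragments$length
  ok_chars <- c("A", "C", "G", "T")
  good_qual_chars <- strsplit(intToUtf8(seq(33L + min_base_quality, 126L)), "")[[1L]]

  subs <- if (include_ga) c("C>T", "G>A") else "C>T"
  count_at <- function(j, from_ref, to_read) {
    use <- lens >= j & j >= 1L
    s <- substring(seqs[use], j[use], j[use])
    r <- substring(refm[use], j[use], j[use])
    q_ok <- substring(quals[use], j[use], j[use]) %in% good_qual_chars
    obs <- sum(r == from_ref & s %in% ok_chars & q_ok)
    conv <- sum(r == from_ref & s == to_read & q_ok)
    c(obs, conv)
  }

  rows <- list()
  for (sub in subs) {
    from_ref <- substr(sub, 1L, 1L)
    to_read <- substr(sub, 3L, 3L)
    for (i in 0:(K - 1L)) {
      oc5 <- count_at(rep(i + 1L, length(lens)), from_ref, to_read)
      oc3 <- count_at(lens - i, from_ref, to_read)
      rows[[length(rows) + 1L]] <- tibble(
        end = c("five_prime", "three_prime"), i = i, substitution = sub,
        observed = c(oc5[1L], oc3[1L]), converted = c(oc5[2L], oc3[2L]))
    }
    # interior baseline: positions > K from both ends
    use <- lens > 2L * K
    if (any(use)) {
      int_s <- paste(substr(seqs[use], K + 1L, lens[use] - K), collapse = "")
      int_r <- paste(substr(refm[use], K + 1L, lens[use] - K), collapse = "")
      int_q <- paste(substr(quals[use], K + 1L, lens[use] - K), collapse = "")
      rs <- strsplit(int_r, "")[[1L]]
      ss <- strsplit(int_s, "")[[1L]]
      q_ok <- strsplit(int_q, "")[[1L]] %in% good_qual_chars
      obs <- sum(rs == from_ref & ss %in% ok_chars & q_ok)
      conv <- sum(rs == from_ref & ss == to_read & q_ok)
    } else {
      obs <- 0L
      conv <- 0L
    }
    rows[[length(rows) + 1L]] <- tibble(end = "interior", i = NA_integer_,
                                        substitution = sub,
                                        observed = obs, converted = conv)
  }

  out <- bind_rows(rows) %>%
    mutate(freq = ifelse(.data$observed > 0L, .data$converted / .data$observed, NA_real_))
  cis <- purrr::map2(out$converted, out$observed, binom_ci)
  out$ci_low <- purrr::map_dbl(cis, 1L)
  out$ci_high <- purrr::map_dbl(cis, 2L)
  attr(out, "K") <- K
  attr(out, "n_fragments") <- nrow(fragments)
  class(out) <- unique(c("damage_profile", class(out)))
  out
}

# terminal C->T flags within `window` positions of each molecule end
terminal_ct_flags <- function(fragments, reference = attr(fragments, "reference"),
                              window = 1L, min_base_quality = 20L) {
  check_fragments(fragments)
  reference <- as_reference_string(reference)
  refm <- molecule_ref_seq(fragments, reference)
  seqs <- fragments$seq
  lens <- fragments$length
  good_qual_chars <- strsplit(intToUtf8(seq(33L + min_base_quality, 126L)), "")[[1L]]
  ct_at <- function(j) {
    valid <- j >= 1L & j <= lens
    res <- logical(length(lens))
    res[valid] <- substring(refm[valid], j[valid], j[valid]) == "C" &
      substring(seqs[valid], j[valid], j[valid]) == "T" &
      substring(fragments$qual[valid], j[valid], j[valid]) %in% good_qual_chars
    res
  }
  ct5 <- rep(FALSE, length(lens))
  ct3 <- rep(FALSE, length(lens))
  for (w in seq_len(window)) {
    ct5 <- ct5 | ct_at(rep(w, length(lens)))
    ct3 <- ct3 | ct_at(lens - w + 1L)
  }
  tibble(ct5 = ct5, ct3 = ct3)
}

#' Conditional (opposite-end) deamination filter
#'
#' Retains only fragments showing a C->T substitution at the terminal
#' position of the end *opposite* to the one under study. Because
#' present-day contaminant molecules essentially never carry terminal
#' C->T, the filtered set is enriched for endogenous ancient molecules;
#' recomputing the damage profile at the measured end on this subset, or
#' counting diagnostic alleles on it, conditions the analysis on molecules
#' that are plausibly ancient without using the measured end itself.
#'
#' @param fragments Aligned fragment tibble.
#' @param end The end being measured: the filter inspects the other end.
#' @param reference Circular reference (defaults to the attribute).
#' @param window Number of terminal positions inspected (default 1: the
#'   terminal base only).
#' @param min_base_quality Phred floor for the terminal call.
#' @return The filtered fragment tibble (a subset of the input, attributes
#'   preserved).
#' @export
conditional_filter <- function(fragments, end = c("five_prime", "three_prime"),
                               reference = attr(fragments, "reference"),
                               window = 1L, min_base_quality = 20L) {
  end <- match.arg(end)
  flags <- terminal_ct_flags(fragments, reference, window, min_base_quality)
  keep <- if (end == "five_prime") flags$ct3 else flags$ct5
  out <- fragments[keep, , drop = FALSE]
  for (a in c("reference", "ref_length")) attr(out, a) <- attr(fragments, a)
  out
}

#' Decide whether a specimen shows evidence of authentic ancient DNA
#'
#' A specimen is called ancient when the terminal C->T frequency at either
#' end reaches `min_terminal_freq` *and* a one-sided exact binomial test of
#' the terminal counts against the interior baseline frequency rejects at
#' `alpha`. The verdict records both terminal frequencies, the conditional
#' (opposite-end-filtered) frequencies when supplied, and the decision
#' trail. Undefined terminal frequencies (no reference-C observations at
#' either terminal) yield an "insufficient data" verdict with the flag
#' down.
#'
#' @param profile [damage_profile()] of the full fragment set.
#' @param conditional_profile_5,conditional_profile_3 Optional profiles of
#'   the [conditional_filter()]ed sets (measuring the 5' and 3' end
#'   respectively); only their terminal frequencies are reported.
#' @param min_terminal_freq Minimum terminal frequency (default 0.10, a
#'   conventional screening threshold for single-stranded libraries).
#' @param alpha Test level for terminal-vs-interior elevation.
#' @param specimen_id Optional id carried into the verdict.
#' @return An `adna_verdict` object; see [tidy.adna_verdict()].
#' @export
authenticate <- function(profile, conditional_profile_5 = NULL,
                         conditional_profile_3 = NULL,
                         min_terminal_freq = 0.10, alpha = 0.01,
                         specimen_id = NA_character_) {
  term <- profile %>%
    filter(.data$substitution == "C>T", .data$end != "interior", .data$i == 0L)
  t5 <- term %>% filter(.data$end == "five_prime")
  t3 <- term %>% filter(.data$end == "three_prime")
  interior <- profile %>%
    filter(.data$substitution == "C>T", .data$end == "interior")
  baseline <- if (nrow(interior) == 1L && interior$observed > 0L) interior$freq else 0

  cond_freq <- function(cp, which_end) {
    if (is.null(cp)) return(NA_real_)
    cp %>%
      filter(.data$substitution == "C>T", .data$end == which_end, .data$i == 0L) %>%
      pull("freq") %>%
      first() %||% NA_real_
  }

  end_test <- function(row) {
    if (nrow(row) == 0L || row$observed == 0L) {
      return(list(freq = NA_real_, p = NA_real_))
    }
    p0 <- min(max(baseline, 1e-9), 1 - 1e-9)
    list(freq = row$freq,
         p = binom.test(row$converted, row$observed, p = p0,
                        alternative = "greater")$p.value)
  }
  e5 <- end_test(t5)
  e3 <- end_test(t3)

  if (is.na(e5$freq) && is.na(e3$freq)) {
    flag <- FALSE
    reason <- "insufficient data: no reference-C observations at either terminal position"
  } else {
    hit5 <- !is.na(e5$freq) && e5$freq >= min_terminal_freq && e5$p <= alpha
    hit3 <- !is.na(e3$freq) && e3$freq >= min_terminal_freq && e3$p <= alpha
    flag <- hit5 || hit3
    reason <- if (flag) {
      sprintf("terminal C->T %s >= %.2f and elevated over interior baseline %.4f (alpha %.3g)",
              paste(sprintf("%.3f", c(e5$freq, e3$freq)[c(hit5, hit3)]), collapse = "/"),
              min_terminal_freq, baseline, alpha)
    } else {
      sprintf("terminal C->T (5' %.3f, 3' %.3f) not substantially elevated over interior %.4f",
              e5$freq %||% NA_real_, e3$freq %||% NA_real_, baseline)
    }
  }

  structure(list(specimen_id = specimen_id,
                 terminal_freq_5 = e5$freq, terminal_freq_3 = e3$freq,
                 p_value_5 = e5$p, p_value_3 = e3$p,
                 conditional_freq_5 = cond_freq(conditional_profile_5, "five_prime"),
                 conditional_freq_3 = cond_freq(conditional_profile_3, "three_prime"),
                 interior_freq = baseline,
                 evidence_for_ancient_dna = flag,
                 reason = reason,
                 params = list(min_terminal_freq = min_terminal_freq, alpha = alpha)),
            class = "adna_verdict")
}

#' @export
print.adna_verdict <- function(x, ...) {
  cat("<adna_verdict>", if (!is.na(x$specimen_id)) x$specimen_id else "", "\n")
  cat("  evidence for ancient DNA:", x$evidence_for_ancient_dna, "\n")
  cat(sprintf("  terminal C->T: 5' %.3f, 3' %.3f (interior %.4f)\n",
              x$terminal_freq_5, x$terminal_freq_3, x$interior_freq))
  if (!is.na(x$conditional_freq_5) || !is.na(x$conditional_freq_3)) {
    cat(sprintf("  conditional:   5' %.3f, 3' %.3f\n",
                x$conditional_freq_5, x$conditional_freq_3))
  }
  cat("  ", x$reason, "\n", sep = "")
  invisible(x)
}

#' One-call damage authentication of a fragment set
#'
#' Computes the damage profile, the two conditional (opposite-end-filtered)
#' profiles, and the [authenticate()] verdict.
#'
#' @inheritParams damage_profile
#' @inheritParams authenticate
#' @return List with `profile`, `conditional_5`, `conditional_3`,
#'   `verdict`.
#' @export
authenticate_fragments <- function(fragments, reference = attr(fragments, "reference"),
                                   K = 15L, min_base_quality = 20L,
                                   min_terminal_freq = 0.10, alpha = 0.01,
                                   specimen_id = NA_character_) {
  profile <- damage_profile(fragments, reference, K, min_base_quality)
  f5 <- conditional_filter(fragments, "five_prime", reference,
                           min_base_quality = min_base_quality)
  f3 <- conditional_filter(fragments, "three_prime", reference,
                           min_base_quality = min_base_quality)
  cp5 <- if (nrow(f5) > 0L) damage_profile(f5, reference, K, min_base_quality) else NULL
  cp3 <- if (nrow(f3) > 0L) damage_profile(f3, reference, K, min_base_quality) else NULL
  verdict <- authenticate(profile, cp5, cp3,
                          min_terminal_freq = min_terminal_freq, alpha = alpha,
                          specimen_id = specimen_id)
  list(profile = profile, conditional_5 = cp5, conditional_3 = cp3, verdict = verdict)
}
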