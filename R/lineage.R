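#' Derived-state support per branch
#'
#' For each branch, counts the observations of fragments overlapping that
#' branch's diagnostic positions: a confident base equal to the derived
#' allele counts as derived support, one equal to the ancestral allele as
#' ancestral support; bases matching neither allele are excluded from the
#' total. The same triple is computed a second time restricted to
#' fragments passing the [conditional_filter()] at either end (putatively
#' deaminated, i.e. endogenous-enriched, molecules). Percentages are
#' `NA` where a branch has no informative observations.
#'
#' By default every (fragment, site) observation counts once; with
#' `per_fragment = TRUE` a fragment overlapping several sites of one
#' branch contributes a single majority-vote observation instead (counting
#' sequences rather than observations).
#'
#' @param fragments Aligned fragment tibble.
#' @param sites Diagnostic-site tibble from [find_diagnostic_sites()] (or
#'   a panel's `truth_sites`).
#' @param reference Circular reference (defaults to the attribute).
#' @param min_base_quality Phred floor for an allele call.
#' @param exclude_damage_prone_sites Drop C<->T / G<->A sites from the
#'   deamination-filtered counts, where residual damage could masquerade
#'   as the derived or ancestral allele.
#' @param per_fragment Collapse multiple same-branch observations of one
#'   fragment to a majority vote.
#' @return Tibble with one row per branch: `branch`, `n_derived`,
#'   `n_total`, `percent_derived`, and the `_filtered` triple computed on
#'   putatively deaminated fragments only.
#' @examples
#' panel <- generate_panel(seed = 3, genome_length = 600, n_sites_per_branch = 4)
#' frags <- simulate_fragments(panel, "neanderthal", 300,
#'                             damage = damage_model(0.3, 0.01), seed = 4)
#' branch_support(frags, panel$truth_sites)
#' @export
branch_support <- function(fragments, sites,
                           reference = attr(fragments, "reference"),
                           min_base_quality = 20L,
                           exclude_damage_prone_sites = FALSE,
                           per_fragment = FALSE) {
  check_fragments(fragments)
  reference <- as_reference_string(reference)
  L <- nchar(reference)
  fwd <- forward_seq(fragments)
  fq <- forward_qual(fragments)
  good_qual_chars <- strsplit(intToUtf8(seq(33L + min_base_quality, 126L)), "")[[1L]]
  damaged <- terminal_ct_flags(fragments, reference,
                               min_base_quality = min_base_quality)
  is_damaged <- damaged$ct5 | damaged$ct3

  obs <- purrr::pmap(list(sites$pos, sites$branch, sites$derived, sites$ancestral,
                          sites$transition),
                     function(pos, branch, der, anc, transition) {
                       off <- circular_offset(pos, fragments$start, L)
                       cover <- off <= fragments$length
                       if (!any(cover)) return(NULL)
                       base <- substring(fwd[cover], off[cover], off[cover])
                       q_ok <- substring(fq[cover], off[cover], off[cover]) %in% good_qual_chars
                       state <- dplyr::case_when(!q_ok ~ NA_character_,
                                                 base == der ~ "derived",
                                                 base == anc ~ "ancestral",
                                                 TRUE ~ NA_character_)
                       keep <- !is.na(state)
                       if (!any(keep)) return(NULL)
                       tibble(frag = which(cover)[keep], branch = branch,
                              state = state[keep], transition = transition)
                     })
  obs <- bind_rows(obs[!purrr::map_lgl(obs, is.null)])
  branches <- unique(sites$branch)
  if (nrow(obs) == 0L) {
    return(tibble(branch = branches, n_derived = 0L, n_total = 0L,
                  percent_derived = NA_real_, n_derived_filtered = 0L,
                  n_total_filtered = 0L, percent_derived_filtered = NA_real_))
  }
  if (per_fragment) {
    obs <- obs %>%
      group_by(.data$frag, .data$branch) %>%
      summarise(state = ifelse(mean(.data$state == "derived") >= 0.5,
                               "derived", "ancestral"),
                transition = any(.data$transition), .groups = "drop")
  }

  tally <- function(o) {
    o %>%
      group_by(.data$branch) %>%
      summarise(n_derived = sum(.data$state == "derived"), n_total = n(),
                .groups = "drop") %>%
      mutate(percent_derived = 100 * .data$n_derived / .data$n_total)
  }
  full <- tally(obs)
  obs_f <- obs %>% filter(is_damaged[.data$frag])
  if (exclude_damage_prone_sites) obs_f <- obs_f %>% filter(!.data$transition)
  filt <- if (nrow(obs_f) > 0L) tally(obs_f) else
    tibble(branch = character(0), n_derived = integer(0), n_total = integer(0),
           percent_derived = double(0))

  tibble(branch = branches) %>%
    left_join(full, by = "branch") %>%
    left_join(filt %>%
                rename(n_derived_filtered = "n_derived",
                       n_total_filtered = "n_total",
                       percent_derived_filtered = "percent_derived"),
              by = "branch") %>%
    mutate(across(c("n_derived", "n_total", "n_derived_filtered", "n_total_filtered"),
                  ~ ifelse(is.na(.x), 0L, .x)))
}

#' Classify a specimen's mtDNA type
#'
#' Combines the ancient-DNA authentication verdict with the
#' deamination-filtered branch support: a specimen is called
#' `"Modern Human"` when it shows evidence of ancient DNA, its filtered
#' modern-human derived-state support is at least `min_support` percent
#' over at least `min_informative` informative observations, and filtered
#' Neanderthal-branch support is at most `max_other` percent (an undefined
#' Neanderthal percentage — no informative observations — does not block
#' the call). The rule is symmetric for `"Neanderthal"`. When the
#' branch-specific filtered counts are too sparse, the expanded
#' Neanderthal-vs-modern-human pairwise site set (branch
#' `pairwise_nea_vs_mh`, whose `derived` slot holds the modern-human
#' allele when unpolarized) is consulted instead. Specimens without
#' damage evidence are `"No evidence for ancient human DNA"`; anything
#' else is `"ambiguous"`.
#'
#' @param support [branch_support()] table.
#' @param verdict [authenticate()] verdict.
#' @param min_informative Minimum informative filtered observations.
#' @param min_support,max_other Percent thresholds (defaults 95 / 5).
#' @return Character label.
#' @export
classify_mtdna <- function(support, verdict, min_informative = 3L,
                           min_support = 95, max_other = 5) {
  if (!isTRUE(verdict$evidence_for_ancient_dna)) {
    return("No evidence for ancient human DNA")
  }
  row_of <- function(branch) support %>% filter(.data$branch == !!branch)
  pick <- function(branch) {
    r <- row_of(branch)
    if (nrow(r) == 1L && r$n_total_filtered >= min_informative) {
      return(list(pct = r$percent_derived_filtered, n = r$n_total_filtered))
    }
    NULL
  }
  mh <- pick("modern_human")
  ne <- pick("neanderthal")
  pw <- pick("pairwise_nea_vs_mh")
  # pairwise percent is % modern-human allele; fall back to it when a
  # branch-specific count is too sparse
  mh_pct <- if (!is.null(mh)) mh$pct else if (!is.null(pw)) pw$pct else NA_real_
  ne_pct <- if (!is.null(ne)) ne$pct else if (!is.null(pw)) 100 - pw$pct else NA_real_

  other_ok <- function(p) is.na(p) || p <= max_other
  if (!is.na(mh_pct) && mh_pct >= min_support && other_ok(ne_pct)) {
    return("Modern Human")
  }
  if (!is.na(ne_pct) && ne_pct >= min_support && other_ok(mh_pct)) {
    return("Neanderthal")
  }
  "ambiguous"
}

#' Render a branch-support table as a text tree
#'
#' A compact fixed-width rendering of the hominin tree with, on each
#' branch, the percentage of sequences supporting the derived state and
#' the bracketed derived/total counts; the second line of each branch
#' gives the same numbers restricted to putatively deaminated sequences.
#'
#' @param support [branch_support()] table.
#' @return Character vector of lines (printed invisibly-friendly).
#' @export
format_support_tree <- function(support) {
  fmt <- function(branch) {
    r <- support %>% filter(.data$branch == !!branch)
    if (nrow(r) == 0L) return(c("  n/a", "  n/a"))
    line <- function(pct, d, t) {
      if (t == 0L) "  -- [0/0]" else sprintf("  %.0f%% [%d/%d]", pct, d, t)
    }
    c(line(r$percent_derived, r$n_derived, r$n_total),
      line(r$percent_derived_filtered, r$n_derived_filtered, r$n_total_filtered))
  }
  mh <- fmt("modern_human")
  ne <- fmt("neanderthal")
  de <- fmt("denisova_sh")
  c("                 +-- modern_human",
    paste0("                 |  ", mh[1L], "   (all sequences)"),
    paste0("                 |  ", mh[2L], "   (deaminated only)"),
    "         +-------+",
    "         |       +-- neanderthal",
    paste0("         |          ", ne[1L]),
    paste0("         |          ", ne[2L]),
    "  root --+",
    "         +---------- denisova_sh",
    paste0("         |          ", de[1L]),
    paste0("         |          ", de[2L]),
    "         +---------- outgroup")
}
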