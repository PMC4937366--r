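#' Simulate a collagen measurement record
#'
#' Generates one row in the layout of a standard collagen QC table
#' (`coll_percent`, `d13C`, `d15N`, `pC`, `pN`): a `"good"` profile
#' satisfies the preservation criteria (yield > 1%, atomic C:N within
#' 2.9–3.6); `"failed_cn"` has acceptable yield but a C:N ratio above the
#' window; `"failed_yield"` has good C:N but yield below the cutoff.
#' Isotope values are drawn around typical Holocene human bone collagen
#' (d13C ~ -20.7, d15N ~ 9).
#'
#' @param profile One of `"good"`, `"failed_cn"`, `"failed_yield"`.
#' @param seed Integer seed.
#' @param specimen_id Optional id for the row.
#' @return One-row tibble with columns `specimen_id`, `coll_percent`,
#'   `d13C`, `d15N`, `pC`, `pN`.
#' @examples
#' simulate_collagen_record("good", seed = 1)
#' @export
simulate_collagen_record <- function(profile = c("good", "failed_cn", "failed_yield"),
                                     seed = 1L, specimen_id = NULL) {
  profile <- match.arg(profile)
  set.seed(seed)
  cn_target <- switch(profile,
                      good = runif(1, 3.0, 3.5),
                      failed_cn = runif(1, 3.8, 4.4),
                      failed_yield = runif(1, 3.0, 3.5))
  coll <- switch(profile,
                 good = runif(1, 1.5, 5),
                 failed_cn = runif(1, 1.2, 3),
                 failed_yield = runif(1, 0.2, 0.9))
  pN <- runif(1, 5, 13)
  pC <- cn_target * pN * 12.011 / 14.007
  tibble(specimen_id = specimen_id %||% paste0("SIM-", profile),
         coll_percent = round(coll, 1),
         d13C = round(rnorm(1, -20.7, 0.5), 1),
         d15N = round(rnorm(1, 9, 1), 1),
         pC = round(pC, 1),
         pN = round(pN, 1))
}

#' Simulate a MALDI-TOF peak list for a taxon
#'
#' Emits the taxon's collagen peptide marker masses from a
#' [marker panel][default_marker_panel] (minus any dropped markers),
#' each perturbed by Gaussian mass jitter, plus uniform random noise peaks
#' in the 900–4000 m/z acquisition window.
#'
#' @param taxon Taxon label present in `panel`.
#' @param panel Marker panel tibble (`taxon`, `marker`, `mz`).
#' @param dropout_markers Marker letters to omit (e.g. `"A"`).
#' @param noise_peaks Number of random noise peaks.
#' @param mass_jitter_sd Gaussian jitter SD in m/z units (>= 0).
#' @param seed Integer seed.
#' @param specimen_id Optional id attached as attribute.
#' @return Tibble `(mz, intensity)` sorted by ascending m/z.
#' @examples
#' simulate_peaklist("Homininae", seed = 1)
#' @export
simulate_peaklist <- function(taxon, panel = default_marker_panel(),
                              dropout_markers = character(0),
                              noise_peaks = 0L, mass_jitter_sd = 0,
                              seed = 1L, specimen_id = NULL) {
  if (mass_jitter_sd < 0) abort("mass_jitter_sd must be >= 0")
  rows <- panel %>% filter(.data$taxon == !!taxon, !.data$marker %in% dropout_markers)
  if (!taxon %in% panel$taxon) abort(paste0("unknown taxon: ", taxon))
  set.seed(seed)
  mz <- rows$mz + rnorm(nrow(rows), 0, mass_jitter_sd)
  intensity <- runif(nrow(rows), 2000, 10000)
  if (noise_peaks > 0L) {
    mz <- c(mz, runif(noise_peaks, 900, 4000))
    intensity <- c(intensity, runif(noise_peaks, 100, 1500))
  }
  out <- tibble(mz = mz, intensity = intensity) %>% arrange(.data$mz)
  attr(out, "specimen_id") <- specimen_id %||% paste0("SIM-", taxon)
  out
}

#' Simulate a multi-specimen cohort with known ground truth
#'
#' Builds one lineage panel and, for each specimen, a fragment set: the
#' first `n_ancient` specimens carry damaged endogenous molecules of
#' `ancient_lineage` mixed with present-day contamination; the remainder are
#' contaminant-only (no terminal damage). This reproduces the study design
#' in which only a subset of a museum collection retains authentic ancient
#' DNA.
#'
#' @param seed Integer seed; specimen seeds are derived from it.
#' @param n_specimens Cohort size.
#' @param n_ancient Number of specimens with authentic ancient DNA.
#' @param ancient_lineage Source lineage of the ancient specimens.
#' @param n_fragments Fragments per specimen.
#' @param damage [damage_model()] for the ancient specimens.
#' @param contamination_fraction Contaminant fraction within ancient
#'   specimens.
#' @param panel Optional pre-built [lineage_panel][generate_panel]; by
#'   default one is generated from `seed` with 10 branch sites per branch
#'   and 10 pairwise sites.
#' @return List with `panel`, `specimens` (named list of fragment tibbles)
#'   and `truth` (tibble `specimen_id`, `ancient`, `source_lineage`).
#' @export
simulate_cohort <- function(seed, n_specimens = 9L, n_ancient = 4L,
                            ancient_lineage = "modern_human",
                            n_fragments = 1000L,
                            damage = damage_model(p_max = 0.3, p_base = 0.01),
                            contamination_fraction = 0.3,
                            panel = NULL) {
  if (n_ancient > n_specimens) abort("n_ancient cannot exceed n_specimens")
  panel <- panel %||% generate_panel(seed = seed, genome_length = 1000L,
                                     n_sites_per_branch = 10L, n_pairwise_sites = 10L)
  undamaged <- damage_model(p_max = damage$p_base, p_base = damage$p_base,
                            decay = damage$decay, both_ends = damage$both_ends)
  ids <- sprintf("SPEC-%02d", seq_len(n_specimens))
  specimens <- vector("list", n_specimens)
  for (k in seq_len(n_specimens)) {
    ancient <- k <= n_ancient
    specimens[[k]] <- simulate_fragments(
      panel,
      source_lineage = if (ancient) ancient_lineage else "modern_human",
      n = n_fragments,
      damage = if (ancient) damage else undamaged,
      contamination_fraction = if (ancient) contamination_fraction else 1,
      seed = (seed * 131L + k) %% .Machine$integer.max)
  }
  names(specimens) <- ids
  list(panel = panel,
       specimens = specimens,
       truth = tibble(specimen_id = ids,
                      ancient = seq_len(n_specimens) <= n_ancient,
                      source_lineage = ifelse(seq_len(n_specimens) <= n_ancient,
                                              ancient_lineage, "modern_human")))
}
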