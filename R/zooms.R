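#' Default collagen peptide-marker panel
#'
#' The shipped panel contains the five published hominin marker masses
#' (markers A, B, D, E, G) plus synthetic demonstration taxa whose masses
#' are invented for testing and examples — they are *not* published marker
#' values and are labelled synthetic here so nobody mistakes them for the
#' real compendium, which users should supply as their own panel TSV. The
#' demonstration taxa are constructed so that the shipped
#' [ambiguity groups][default_marker_groups] arise naturally: Cervidae and
#' Saiga share every marker (never separable), and the three carnivore
#' families share all markers except A (separable only when A is
#' observed).
#'
#' @return Tibble `taxon`, `marker`, `mz`.
#' @export
default_marker_panel <- function() {
  tribble(
    ~taxon, ~marker, ~mz,
    # hominin masses as published
    "Homininae", "A", 1235.6,
    "Homininae", "B", 1477.8,
    "Homininae", "D", 2115.1,
    "Homininae", "E", 2832.4,
    "Homininae", "G", 2957.5,
    # synthetic demonstration taxa (invented masses)
    "Suidae", "A", 1240.7,
    "Suidae", "B", 1453.8,
    "Suidae", "D", 2145.2,
    "Suidae", "E", 2843.3,
    "Suidae", "G", 2964.6,
    "Cervidae", "A", 1180.6,
    "Cervidae", "B", 1427.8,
    "Cervidae", "D", 2131.1,
    "Cervidae", "E", 2792.4,
    "Cervidae", "G", 2883.5,
    "Saiga", "A", 1180.6,
    "Saiga", "B", 1427.8,
    "Saiga", "D", 2131.1,
    "Saiga", "E", 2792.4,
    "Saiga", "G", 2883.5,
    "Mustelidae", "A", 1196.6,
    "Mustelidae", "B", 1505.9,
    "Mustelidae", "D", 2129.3,
    "Mustelidae", "E", 2808.4,
    "Mustelidae", "G", 2915.5,
    "Pantherinae", "A", 1201.7,
    "Pantherinae", "B", 1505.9,
    "Pantherinae", "D", 2129.3,
    "Pantherinae", "E", 2808.4,
    "Pantherinae", "G", 2915.5,
    "Hyaenidae", "A", 1211.8,
    "Hyaenidae", "B", 1505.9,
    "Hyaenidae", "D", 2129.3,
    "Hyaenidae", "E", 2808.4,
    "Hyaenidae", "G", 2915.5
  )
}

#' Default taxon ambiguity groups
#'
#' Maps sets of taxa that cannot be separated on a given spectrum to the
#' group label reported in their place.
#'
#' @return Tibble `group_label`, `taxa` (list column of taxon sets).
#' @export
default_marker_groups <- function() {
  tibble(group_label = c("Cervid/Saiga", "Mustelidae/Pantherinae/Hyaenidae"),
         taxa = list(c("Cervidae", "Saiga"),
                     c("Hyaenidae", "Mustelidae", "Pantherinae")))
}

#' Match a MALDI-TOF peak list against a marker panel
#'
#' A marker matches when any peak lies within `+/- tolerance` of its m/z;
#' one peak may satisfy several markers. Intensities are ignored for
#' matching (presence/absence only) beyond an optional minimum-intensity
#' floor.
#'
#' @param peaks Tibble `(mz, intensity)`; an attached `specimen_id`
#'   attribute is carried through.
#' @param panel Marker panel tibble (`taxon`, `marker`, `mz`).
#' @param tolerance Mass tolerance in m/z units (> 0), default 0.2.
#' @param min_intensity Peaks below this intensity are ignored.
#' @return A `zooms_matches` tibble: one row per (taxon, marker) with
#'   `matched` (logical) and `peak_idx` (list column of matching peak
#'   indices); attributes `n_peaks`, `tolerance`, `specimen_id`.
#' @examples
#' peaks <- simulate_peaklist("Homininae", seed = 1)
#' match_markers(peaks)
#' @export
match_markers <- function(peaks, panel = default_marker_panel(),
                          tolerance = 0.2, min_intensity = 0) {
  if (tolerance <= 0) abort("tolerance must be > 0")
  use <- peaks$intensity >= min_intensity
  peak_mz <- peaks$mz[use]
  peak_pos <- which(use)
  out <- panel %>%
    mutate(peak_idx = purrr::map(.data$mz, function(m) {
      peak_pos[abs(peak_mz - m) <= tolerance]
    }),
    matched = purrr::map_int(.data$peak_idx, length) > 0L)
  attr(out, "n_peaks") <- sum(use)
  attr(out, "tolerance") <- tolerance
  attr(out, "specimen_id") <- attr(peaks, "specimen_id") %||% NA_character_
  class(out) <- unique(c("zooms_matches", class(out)))
  out
}

#' Taxonomic call from a marker match table
#'
#' Candidate taxa are those with at least `min_markers` matched markers
#' and (when `require_discriminating`) no conflicting marker — a marker
#' letter for which the spectrum contains another taxon's mass but not
#' this taxon's. Among candidates with the maximal number of matches, a
#' single survivor is reported as the taxon; several survivors whose
#' matched peaks are identical are reported as their ambiguity-group
#' label. An empty spectrum (below `min_peaks`) is `"No Collagen"`; no
#' candidate at all is `"unidentified"`. The marker series is annotated
#' `"complete"` when every panel marker of the reported taxon/group
#' matched, `"partial"` otherwise.
#'
#' @param matches A [match_markers()] table.
#' @param grouping Ambiguity-group table as [default_marker_groups()].
#' @param min_markers Minimum matched markers for a candidate call.
#' @param require_discriminating Drop candidates contradicted by a
#'   wrong-mass discriminating marker present in the spectrum.
#' @param min_peaks Peak-count floor below which the spectrum counts as
#'   empty.
#' @return A `zooms_call`: one-row tibble with `specimen_id`, `label`,
#'   `series`, `n_matched`, `candidates` and `missing_markers` (list
#'   columns).
#' @export
classify_zooms <- function(matches, grouping = default_marker_groups(),
                           min_markers = 2L, require_discriminating = TRUE,
                           min_peaks = 1L) {
  sid <- attr(matches, "specimen_id") %||% NA_character_
  n_peaks <- attr(matches, "n_peaks") %||% NA_integer_
  call_row <- function(label, series, n_matched, candidates, missing) {
    tibble(specimen_id = sid, label = label, series = series,
           n_matched = n_matched, candidates = list(candidates),
           missing_markers = list(missing))
  }
  if (!is.na(n_peaks) && n_peaks < min_peaks) {
    return(call_row("No Collagen", "none", 0L, character(0), character(0)))
  }

  per_taxon <- matches %>%
    group_by(.data$taxon) %>%
    summarise(n_matched = sum(.data$matched), n_markers = n(), .groups = "drop")
  cand <- per_taxon %>% filter(.data$n_matched >= min_markers)

  if (require_discriminating && nrow(cand) > 0L) {
    conflicted <- purrr::map_lgl(cand$taxon, function(tx) {
      mine <- matches %>% filter(.data$taxon == tx)
      other <- matches %>% filter(.data$taxon != tx, .data$matched)
      any(other$marker %in% mine$marker[!mine$matched])
    })
    cand <- cand[!conflicted, , drop = FALSE]
  }
  if (nrow(cand) == 0L) {
    return(call_row("unidentified", "none", 0L, character(0), character(0)))
  }

  cand <- cand %>% filter(.data$n_matched == max(.data$n_matched))
  taxa <- sort(cand$taxon)
  missing_of <- function(taxa_set) {
    matches %>%
      filter(.data$taxon %in% taxa_set, !.data$matched) %>%
      pull("marker") %>%
      unique() %>%
      sort()
  }
  if (length(taxa) == 1L) {
    miss <- missing_of(taxa)
    return(call_row(taxa, if (length(miss) == 0L) "complete" else "partial",
                    cand$n_matched[[1L]], taxa, miss))
  }

  # several equally-supported candidates: indistinguishable when their
  # matched peaks coincide -> report the ambiguity group
  peak_sets <- purrr::map(taxa, function(tx) {
    matches %>%
      filter(.data$taxon == tx, .data$matched) %>%
      pull("peak_idx") %>%
      unlist() %>%
      sort() %>%
      unique()
  })
  indistinct <- all(purrr::map_lgl(peak_sets, identical, peak_sets[[1L]]))
  label <- if (indistinct) {
    hit <- purrr::map_lgl(grouping$taxa, ~ setequal(.x, taxa))
    if (any(hit)) grouping$group_label[which(hit)[1L]] else paste(taxa, collapse = "/")
  } else {
    paste(taxa, collapse = "/")
  }
  miss <- missing_of(taxa)
  call_row(label, if (length(miss) == 0L) "complete" else "partial",
           cand$n_matched[[1L]], taxa, miss)
}

#' Read a two-column peak-list CSV
#'
#' @param path CSV with columns `mz` and `intensity` (header required).
#' @param specimen_id Optional id attached as attribute.
#' @return Tibble sorted by ascending m/z.
#' @export
read_peaklist <- function(path, specimen_id = NULL) {
  out <- readr::read_csv(path, show_col_types = FALSE) %>% arrange(.data$mz)
  if (any(out$intensity < 0)) abort("peak intensities must be non-negative")
  attr(out, "specimen_id") <- specimen_id
  out
}
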