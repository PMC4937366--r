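#' Atomic C:N ratio of collagen
#'
#' Molar (atomic) carbon-to-nitrogen ratio from the elemental mass
#' percentages: `(pC / 12.011) / (pN / 14.007)`. Well-preserved bone
#' collagen falls near 3.2; ratios outside roughly 2.9-3.6 indicate
#' degradation or contamination. No rounding is applied here — round only
#' at the presentation layer.
#'
#' @param pC,pN Percent carbon and nitrogen by mass (`pN > 0`). Vectorised.
#' @return Numeric atomic ratio.
#' @examples
#' atomic_cn_ratio(30.2, 10.0)  # ~3.52
#' @export
atomic_cn_ratio <- function(pC, pN) {
  if (any(is.na(pN)) || any(pN <= 0)) {
    abort("pN must be positive: atomic C:N is undefined at pN = 0")
  }
  (pC / 12.011) / (pN / 14.007)
}

#' Collagen quality-control thresholds
#'
#' Two presets: `"paper"` — collagen yield above 1% and atomic C:N between
#' 2.9 and 3.6 (the DeNiro window); `"vanKlinken"` — the stricter C:N
#' window 3.1-3.5. Yield is compared strictly (`> min_coll_percent`).
#'
#' @param preset `"paper"` or `"vanKlinken"`, or pass the fields directly.
#' @param min_coll_percent,cn_low,cn_high Override individual thresholds.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(preset = c("paper", "vanKlinken"),
                          min_coll_percent = NULL, cn_low = NULL, cn_high = NULL) {
  preset <- match.arg(preset)
  def <- switch(preset,
                paper = list(min_coll_percent = 1.0, cn_low = 2.9, cn_high = 3.6),
                vanKlinken = list(min_coll_percent = 1.0, cn_low = 3.1, cn_high = 3.5))
  out <- list(min_coll_percent = min_coll_percent %||% def$min_coll_percent,
              cn_low = cn_low %||% def$cn_low,
              cn_high = cn_high %||% def$cn_high,
              preset = preset)
  if (out$cn_low >= out$cn_high) abort("cn_low must be below cn_high")
  structure(out, class = "qc_thresholds")
}

#' Collagen preservation quality control
#'
#' Applies the yield and atomic C:N criteria to a table of collagen
#' records. A record passes when `coll_percent` strictly exceeds the
#' cutoff *and* its atomic C:N lies within the window; every violated
#' criterion is listed as a reason. The C:N ratio is taken from a
#' `cn_ratio` column when present, otherwise computed from `pC`/`pN` with
#' [atomic_cn_ratio()]. An optional logical `dated_despite_failure`
#' column is carried through to record specimens submitted for dating in
#' spite of a failed screen.
#'
#' @param records Tibble with `coll_percent` and either `cn_ratio` or
#'   both `pC` and `pN` (a `specimen_id` column is carried through).
#' @param thresholds A [qc_thresholds()] object.
#' @return The input with `cn_ratio` (computed if absent), `pass`
#'   (logical) and `qc_reasons` (character; `""` when passing, otherwise
#'   reasons separated by `"; "`).
#' @examples
#' collagen_qc(tibble::tibble(specimen_id = "x", coll_percent = 4.5,
#'                            pC = 38.2, pN = 13.3))
#' @export
collagen_qc <- function(records, thresholds = qc_thresholds("paper")) {
  if (!"coll_percent" %in% names(records)) {
    abort("records are missing required field: coll_percent")
  }
  has_cn <- "cn_ratio" %in% names(records)
  if (!has_cn && !all(c("pC", "pN") %in% names(records))) {
    missing <- setdiff(c("pC", "pN"), names(records))
    abort(paste0("records are missing required field(s): ",
                 paste(missing, collapse = ", "),
                 " (or supply cn_ratio directly)"))
  }
  cn <- if (has_cn) records$cn_ratio else atomic_cn_ratio(records$pC, records$pN)
  yield_ok <- records$coll_percent > thresholds$min_coll_percent
  cn_ok <- cn >= thresholds$cn_low & cn <= thresholds$cn_high
  reasons <- purrr::map2_chr(yield_ok, cn_ok, function(y, c) {
    r <- c(if (!y) "yield below cutoff", if (!c) "C:N out of range")
    paste(r, collapse = "; ")
  })
  records %>%
    mutate(cn_ratio = cn, pass = yield_ok & cn_ok, qc_reasons = reasons)
}

#' Default isotope reference ranges
#'
#' Editable placeholder d15N ranges (permil vs AIR) for broad dietary
#' populations of the late Pleistocene / Holocene; values are literature-
#' style placeholders meant to be replaced with study-appropriate
#' comparative data, not hard-coded science.
#'
#' @return Tibble `label`, `d15N_low`, `d15N_high`, `human` (logical).
#' @export
default_isotope_ranges <- function() {
  tibble(label = c("human (terrestrial diet)", "herbivore/omnivore"),
         d15N_low = c(8, 3),
         d15N_high = c(12, 7),
         human = c(TRUE, FALSE))
}

#' Isotope plausibility screen
#'
#' Flags, for each record, every reference population whose d15N range
#' contains the measured value; raises `low_for_human_diet` when the value
#' falls below every configured human range (suggesting a herbivorous or
#' omnivorous animal rather than a human of that period); and flags pairs
#' of records with identical d13C *and* d15N as possibly deriving from the
#' same individual.
#'
#' @param records Tibble with `d15N` (and `d13C` for the same-individual
#'   check; `specimen_id` carried through).
#' @param reference_ranges Tibble as [default_isotope_ranges()].
#' @return The input plus `populations` (list column of matching labels),
#'   `low_for_human_diet` (logical) and `possible_same_individual_as`
#'   (list column of specimen ids sharing both isotope values).
#' @export
isotope_plausibility <- function(records, reference_ranges = default_isotope_ranges()) {
  if (nrow(reference_ranges) == 0L) abort("reference_ranges must be non-empty")
  if (!"d15N" %in% names(records)) abort("records are missing required field: d15N")
  pops <- purrr::map(records$d15N, function(v) {
    reference_ranges$label[v >= reference_ranges$d15N_low &
                             v <= reference_ranges$d15N_high]
  })
  human_lo <- reference_ranges$d15N_low[reference_ranges$human]
  low_flag <- if (length(human_lo) > 0L) records$d15N < min(human_lo) else
    rep(FALSE, nrow(records))
  same <- vector("list", nrow(records))
  if (all(c("d13C", "specimen_id") %in% names(records))) {
    key <- paste(records$d13C, records$d15N)
    for (k in seq_len(nrow(records))) {
      same[[k]] <- records$specimen_id[key == key[k] &
                                         records$specimen_id != records$specimen_id[k]]
    }
  } else {
    same <- purrr::map(seq_len(nrow(records)), ~ character(0))
  }
  records %>%
    mutate(populations = pops, low_for_human_diet = low_flag,
           possible_same_individual_as = same)
}

#' Bundled collagen measurements of the Riparo Mezzena specimens
#'
#' The five directly-dated specimens' collagen yield, stable isotope
#' values and elemental concentrations, as published, in the standard QC
#' table layout. Useful as a worked example for [collagen_qc()] and
#' [atomic_cn_ratio()].
#'
#' @return Tibble with columns `specimen_id`, `element`, `coll_percent`,
#'   `d13C`, `d15N`, `pC`, `pN`, `cn_printed`, `age_bp`, `sigma`.
#' @export
mezzena_collagen <- function() {
  path <- system.file("extdata", "mezzena_collagen.csv", package = "paleoproof")
  readr::read_csv(path, show_col_types = FALSE)
}
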