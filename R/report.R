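#' Default specimen-id alias map
#'
#' Museum numbers are the canonical ids; known alternate spellings map
#' onto them (the mandible appears in the literature both as
#' "IGVR 20334" and "IGVR 203334").
#'
#' @return Named character vector `alias -> canonical`.
#' @export
default_alias_map <- function() {
  c("IGVR 20334" = "IGVR 203334")
}

canonical_id <- function(id, aliases = default_alias_map()) {
  hit <- match(id, names(aliases))
  ifelse(is.na(hit), id, unname(aliases[hit]))
}

#' Merge per-proxy outputs into a per-specimen report
#'
#' Joins the outputs of the independent proxies — collagen QC,
#' radiocarbon calibration, ancient-DNA authentication / mtDNA typing,
#' and ZooMS — into one row per specimen. Ids are resolved through the
#' alias map; analyses a specimen never underwent are rendered
#' `"Not analysed"`; cross-proxy conflicts (hominin mtDNA against a
#' non-hominin ZooMS identification) are flagged in `consistency_note`,
#' never silently reconciled.
#'
#' @param mtdna Tibble `specimen_id`, `mtdna_label` (and optionally
#'   `evidence_for_ancient_dna`).
#' @param zooms Tibble `specimen_id`, `zooms_label`.
#' @param collagen Output of [collagen_qc()] (with `specimen_id`).
#' @param calibration Output of [calibrate_table()] (with `specimen_id`);
#'   the widest-level interval is rendered.
#' @param layers Optional tibble `specimen_id`, `layer`.
#' @param aliases Alias map as [default_alias_map()].
#' @return A `specimen_report` tibble, one row per specimen.
#' @export
merge_reports <- function(mtdna = NULL, zooms = NULL, collagen = NULL,
                          calibration = NULL, layers = NULL,
                          aliases = default_alias_map()) {
  inputs <- list(mtdna = mtdna, zooms = zooms, collagen = collagen,
                 calibration = calibration, layers = layers)
  inputs <- inputs[!purrr::map_lgl(inputs, is.null)]
  if (length(inputs) == 0L) abort("no proxy outputs supplied")

  std <- purrr::imap(inputs, function(x, nm) {
    if (!"specimen_id" %in% names(x)) {
      abort(paste0(nm, " table is missing specimen_id"))
    }
    x %>% mutate(specimen_id = canonical_id(.data$specimen_id, aliases))
  })

  check_unique <- function(x, nm, cols) {
    cols <- intersect(cols, names(x))
    dup <- x %>%
      distinct(dplyr::pick(dplyr::all_of(c("specimen_id", cols)))) %>%
      count(.data$specimen_id) %>%
      filter(.data$n > 1L)
    if (nrow(dup) > 0L) {
      abort(paste0("conflicting duplicate ", nm, " rows for specimen(s): ",
                   paste(dup$specimen_id, collapse = ", ")))
    }
  }

  pieces <- list()
  if (!is.null(std$mtdna)) {
    check_unique(std$mtdna, "mtDNA", "mtdna_label")
    pieces$mtdna <- std$mtdna %>%
      distinct(.data$specimen_id, .keep_all = TRUE) %>%
      select("specimen_id", mtdna = "mtdna_label",
              dplyr::any_of("evidence_for_ancient_dna"))
  }
  if (!is.null(std$zooms)) {
    check_unique(std$zooms, "ZooMS", "zooms_label")
    pieces$zooms <- std$zooms %>%
      distinct(.data$specimen_id, .keep_all = TRUE) %>%
      select("specimen_id", zooms = "zooms_label")
  }
  if (!is.null(std$collagen)) {
    check_unique(std$collagen, "collagen", c("pass", "qc_reasons"))
    pieces$collagen <- std$collagen %>%
      distinct(.data$specimen_id, .keep_all = TRUE) %>%
      mutate(collagen_qc = ifelse(.data$pass, "pass",
                                  paste0("fail (", .data$qc_reasons, ")"))) %>%
      select("specimen_id", "collagen_qc",
              dplyr::any_of(c("coll_percent", "cn_ratio", "d13C", "d15N")))
  }
  if (!is.null(std$calibration)) {
    pieces$calibration <- std$calibration %>%
      group_by(.data$specimen_id) %>%
      filter(.data$level == max(.data$level)) %>%
      summarise(
        age_bp = first(.data$age_bp),
        cal_range = paste(sprintf("%s-%s cal BP",
                                  format(.data$from_cal_bp, big.mark = ",", trim = TRUE),
                                  format(.data$to_cal_bp, big.mark = ",", trim = TRUE)),
                          collapse = "; "),
        cal_level = max(.data$level), .groups = "drop")
  }
  if (!is.null(std$layers)) {
    check_unique(std$layers, "layer", "layer")
    pieces$layers <- std$layers %>%
      distinct(.data$specimen_id, .keep_all = TRUE) %>%
      select("specimen_id", "layer")
  }

  out <- purrr::reduce(pieces, full_join, by = "specimen_id")
  for (col in intersect(c("mtdna", "zooms", "collagen_qc", "cal_range", "layer"),
                        names(out))) {
    out[[col]][is.na(out[[col]])] <- "Not analysed"
  }
  hominin_dna <- if ("mtdna" %in% names(out)) {
    out$mtdna %in% c("Modern Human", "Neanderthal")
  } else {
    rep(FALSE, nrow(out))
  }
  hominin_zooms <- if ("zooms" %in% names(out)) {
    out$zooms %in% c("Homininae", "Not analysed", "No Collagen")
  } else {
    rep(TRUE, nrow(out))
  }
  out$consistency_note <- ifelse(
    hominin_dna & !hominin_zooms,
    paste0("CONFLICT: hominin mtDNA vs ZooMS '",
           if ("zooms" %in% names(out)) out$zooms else "", "'"),
    "")
  out <- out %>% arrange(.data$specimen_id)
  class(out) <- unique(c("specimen_report", class(out)))
  out
}

#' Run the multi-proxy pipeline on a declarative configuration
#'
#' Executes whichever analysis stages the configuration requests and
#' merges their outputs into a [specimen report][merge_reports]. The
#' configuration is a plain list:
#'
#' * `simulation`: arguments to [simulate_cohort()] (at minimum `seed`) —
#'   generates fragment sets and runs the genetic stages on them; or
#' * `fragments` + `reference` (+ `sites` or `panel`): named list of
#'   aligned fragment tibbles per specimen;
#' * `collagen`: collagen record tibble or CSV path, with optional
#'   `qc_preset`;
#' * `dates`: radiocarbon tibble (`specimen_id`, `age_bp`, `sigma`) with
#'   `curve` a path or `cal_curve`;
#' * `peaks`: named list of peak tibbles (or CSV paths) per specimen,
#'   with optional `marker_panel`;
#' * `layers`: tibble `specimen_id`, `layer`.
#'
#' Every threshold used is echoed in the returned `thresholds` element so
#' reports are auditable.
#'
#' @param config Configuration list (see Details).
#' @param out_dir Optional directory; when given, the report is written
#'   as CSV, JSON and Markdown via [write_report()].
#' @return List with `report`, `details` (per-stage raw outputs) and
#'   `thresholds`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.null(config) || length(config) == 0L) {
    abort("empty config: request at least one analysis stage")
  }
  details <- list()
  thresholds <- list(
    min_terminal_freq = config$min_terminal_freq %||% 0.10,
    alpha = config$alpha %||% 0.01,
    K = config$K %||% 15L,
    min_base_quality = config$min_base_quality %||% 20L,
    min_informative = config$min_informative %||% 3L,
    exclude_damage_prone_sites = config$exclude_damage_prone_sites %||% TRUE,
    qc_preset = config$qc_preset %||% "paper",
    zooms_tolerance = config$zooms_tolerance %||% 0.2,
    zooms_min_markers = config$zooms_min_markers %||% 2L)

  mtdna_tbl <- NULL
  fragments <- NULL
  sites <- NULL
  reference <- NULL
  if (!is.null(config$simulation)) {
    sim <- do.call(simulate_cohort, config$simulation)
    fragments <- sim$specimens
    reference <- panel_reference(sim$panel)
    sites <- find_diagnostic_sites(sim$panel, mode = "both")
    details$simulation_truth <- sim$truth
  } else if (!is.null(config$fragments)) {
    fragments <- config$fragments
    reference <- config$reference
    sites <- config$sites %||%
      (if (!is.null(config$panel)) find_diagnostic_sites(config$panel, "both") else NULL)
  }
  if (!is.null(fragments)) {
    if (is.null(reference)) abort("genetic stage requested without a reference")
    rows <- purrr::imap(fragments, function(fr, sid) {
      auth <- authenticate_fragments(
        fr, reference, K = thresholds$K,
        min_base_quality = thresholds$min_base_quality,
        min_terminal_freq = thresholds$min_terminal_freq,
        alpha = thresholds$alpha, specimen_id = sid)
      label <- if (is.null(sites)) NA_character_ else {
        classify_mtdna(
          branch_support(fr, sites, reference,
                         min_base_quality = thresholds$min_base_quality,
                         exclude_damage_prone_sites = thresholds$exclude_damage_prone_sites),
          auth$verdict, min_informative = thresholds$min_informative)
      }
      tibble(specimen_id = sid, mtdna_label = label,
             evidence_for_ancient_dna = auth$verdict$evidence_for_ancient_dna)
    })
    mtdna_tbl <- bind_rows(rows)
    details$mtdna <- mtdna_tbl
  }

  collagen_tbl <- NULL
  if (!is.null(config$collagen)) {
    rec <- config$collagen
    if (is.character(rec)) rec <- readr::read_csv(rec, show_col_types = FALSE)
    collagen_tbl <- collagen_qc(rec, qc_thresholds(thresholds$qc_preset))
    details$collagen <- collagen_tbl
  }

  cal_tbl <- NULL
  if (!is.null(config$dates)) {
    curve <- config$curve
    if (is.null(curve)) abort("dates supplied without a calibration curve")
    if (is.character(curve)) curve <- read_curve(curve)
    cal_tbl <- calibrate_table(config$dates, curve)
    details$calibration <- cal_tbl
  }

  zooms_tbl <- NULL
  if (!is.null(config$peaks)) {
    panel <- config$marker_panel %||% default_marker_panel()
    zooms_tbl <- purrr::imap(config$peaks, function(pk, sid) {
      if (is.character(pk)) pk <- read_peaklist(pk, specimen_id = sid)
      attr(pk, "specimen_id") <- sid
      classify_zooms(match_markers(pk, panel, tolerance = thresholds$zooms_tolerance),
                     min_markers = thresholds$zooms_min_markers) %>%
        select("specimen_id", zooms_label = "label")
    }) %>% bind_rows()
    details$zooms <- zooms_tbl
  }

  if (is.null(mtdna_tbl) && is.null(collagen_tbl) && is.null(cal_tbl) &&
      is.null(zooms_tbl)) {
    abort("config did not request any recognised stage")
  }
  report <- merge_reports(mtdna = mtdna_tbl, zooms = zooms_tbl,
                          collagen = collagen_tbl, calibration = cal_tbl,
                          layers = config$layers)
  if (!is.null(out_dir)) write_report(report, out_dir, thresholds)
  list(report = report, details = details, thresholds = thresholds)
}

#' Write a specimen report as CSV, JSON and Markdown
#'
#' @param report A [specimen_report][merge_reports] tibble.
#' @param dir Output directory (created if needed).
#' @param thresholds Optional threshold list echoed into the outputs.
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir, thresholds = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  flat <- as_tibble(report)
  readr::write_csv(flat, file.path(dir, "specimen_report.csv"))
  jsonlite::write_json(list(thresholds = thresholds, report = flat),
                       file.path(dir, "specimen_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  md <- c("# Specimen report", "",
          if (!is.null(thresholds)) {
            c("Thresholds: ",
              paste0("- ", names(thresholds), ": ",
                     purrr::map_chr(thresholds, ~ paste(format(.x), collapse = " "))),
              "")
          },
          paste(names(flat), collapse = " | "),
          paste(rep("---", ncol(flat)), collapse = " | "),
          purrr::map_chr(seq_len(nrow(flat)), function(i) {
            paste(purrr::map_chr(flat[i, ], ~ paste(format(.x), collapse = " ")),
                  collapse = " | ")
          }))
  writeLines(md, file.path(dir, "specimen_report.md"))
  invisible(dir)
}
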