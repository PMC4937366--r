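#' Tidy an ancient-DNA authentication verdict
#'
#' @param x An [authenticate()] verdict.
#' @param ... Unused.
#' @return One-row tibble with the terminal, conditional and interior
#'   frequencies, the test p-values and the evidence flag.
#' @export
#' @method tidy adna_verdict
tidy.adna_verdict <- function(x, ...) {
  tibble(specimen_id = x$specimen_id,
         terminal_freq_5 = x$terminal_freq_5,
         terminal_freq_3 = x$terminal_freq_3,
         conditional_freq_5 = x$conditional_freq_5,
         conditional_freq_3 = x$conditional_freq_3,
         interior_freq = x$interior_freq,
         p_value_5 = x$p_value_5,
         p_value_3 = x$p_value_3,
         evidence_for_ancient_dna = x$evidence_for_ancient_dna,
         reason = x$reason)
}

#' Tidy a calibration result
#'
#' @param x A [calibrate_date()] result.
#' @param ... Unused.
#' @return Tibble of HPD intervals (`level`, `from_cal_bp`, `to_cal_bp`),
#'   the older bound first.
#' @export
#' @method tidy cal_result
tidy.cal_result <- function(x, ...) {
  x$intervals %>%
    mutate(lab_code = x$lab_code, age_bp = x$age_bp, sigma = x$sigma,
           .before = 1L)
}

#' @rdname tidy.cal_result
#' @return `glance()` returns a one-row posterior summary: mode, median
#'   and mean calendar age, and the grid size.
#' @export
#' @method glance cal_result
glance.cal_result <- function(x, ...) {
  post <- x$posterior
  cum <- cumsum(post$prob)
  tibble(lab_code = x$lab_code, age_bp = x$age_bp, sigma = x$sigma,
         mode_cal_bp = post$cal_bp[which.max(post$prob)],
         median_cal_bp = post$cal_bp[which(cum >= 0.5)[1L]],
         mean_cal_bp = sum(post$cal_bp * post$prob),
         curve = x$curve_name, n_grid = nrow(post))
}
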