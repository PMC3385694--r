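#' Radiobiology parameters
#'
#' Linear-quadratic parameters and sensitivity modifiers used in the
#' per-cell kill calculation. Defaults are alpha = 0.3 / Gy and
#' beta = 0.03 / Gy^2 (alpha/beta = 10 Gy, typical of squamous cell
#' carcinoma), with non-cycling cells (late differentiating, fully
#' differentiated, G0-phase and hypoxia-quiescent) at half the
#' radiosensitivity of oxic cycling cells.
#'
#' @param alpha LQ alpha (Gy^-1).
#' @param beta LQ beta (Gy^-2).
#' @param oer an [oer_params()] describing the OER lethality curve.
#' @param noncycling_factor multiplicative kill-probability factor for
#'   non-cycling cells, in (0, 1].
#' @return an object of class `radiobiology_params`.
#' @export
radiobiology_params <- function(alpha = 0.3, beta = 0.03, oer = oer_params(),
                                noncycling_factor = 0.5) {
  stopifnot(alpha > 0, beta > 0, inherits(oer, "oer_params"),
            noncycling_factor > 0, noncycling_factor <= 1)
  structure(list(alpha = alpha, beta = beta, oer = oer,
                 noncycling_factor = noncycling_factor),
            class = "radiobiology_params")
}

#' Linear-quadratic surviving fraction
#'
#' SF(d) = exp(-alpha d - beta d^2). With the default alpha = 0.3 and
#' beta = 0.03, SF(2 Gy) = 0.487.
#'
#' @param d dose in Gy (>= 0), vectorised.
#' @param params a [radiobiology_params()].
#' @return surviving fractions in (0, 1].
#' @export
survival_fraction <- function(d, params = radiobiology_params()) {
  if (any(d < 0)) stop("dose must be non-negative")
  exp(-params$alpha * d - params$beta * d^2)
}

#' Per-cell kill probability for one dose fraction
#'
#' The probability that a cell dies in a fraction of dose `d`:
#' `(1 - SF(d))` scaled by the normalised OER lethality factor at the
#' cell's pO2, and additionally by the non-cycling sensitivity factor if
#' the cell is not actively cycling.
#'
#' @param d dose in Gy.
#' @param po2 cellular pO2 in mmHg (vectorised).
#' @param cycling logical; is the cell actively cycling (S/T/D1/D2 in
#'   cycle)? Non-cycling covers D3 cells, cells in the G0 phase and
#'   hypoxia-induced quiescent cells.
#' @param params a [radiobiology_params()].
#' @return kill probabilities in \[0, 1\].
#' @export
kill_probability <- function(d, po2, cycling = TRUE,
                             params = radiobiology_params()) {
  p <- (1 - survival_fraction(d, params)) *
    oer_lethality_factor(po2, params$oer)
  ifelse(cycling, p, p * params$noncycling_factor)
}
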