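#' Relative pentose phosphate pathway flux
#'
#' From [1,2-13C]-glucose tracing: M1-labeled lactate arises from
#' glucose routed through the oxidative PPP (one labeled carbon lost as
#' CO2), M2-labeled lactate from direct glycolysis. Relative PPP flux,
#' normalized by glycolysis, is
#' `rate * lac_m1 / (lac_m1 + lac_m2)`, optionally divided by a control
#' flux. M1/M2 may be fractional abundances or raw intensities — the
#' ratio is scale-invariant — but must be natural-abundance corrected
#' upstream.
#'
#' @param rate Glucose consumption rate (amount per time; units carried
#'   through).
#' @param lac_m1,lac_m2 M1 / M2 lactate isotopologue fractions or
#'   intensities (non-negative; their sum must be positive).
#' @param control_flux Optional control-group flux for normalization.
#' @return Flux value(s); vectorized.
#' @export
#' @examples
#' relative_ppp_flux(10, 0.2, 0.2)  # 5
relative_ppp_flux <- function(rate, lac_m1, lac_m2, control_flux = NULL) {
  stopifnot(all(rate > 0), all(lac_m1 >= 0), all(lac_m2 >= 0))
  if (any(lac_m1 + lac_m2 <= 0))
    stop("undefined flux: lac_m1 + lac_m2 must be positive", call. = FALSE)
  flux <- rate * lac_m1 / (lac_m1 + lac_m2)
  if (!is.null(control_flux)) {
    stopifnot(all(control_flux > 0))
    flux <- flux / control_flux
  }
  flux
}

#' PPP flux for a sample table
#'
#' Computes each sample's flux and, where a `control_group` column marks
#' control samples, divides every flux by the mean flux of its group's
#' controls ("normalized to the corresponding control group").
#'
#' @param table Tibble: `sample`, `rate`, `lac_m1`, `lac_m2`, optional
#'   `group` and logical `control_group`.
#' @return `table` with `flux` and (when controls are given)
#'   `relative_flux`.
#' @export
ppp_flux_table <- function(table) {
  out <- dplyr::mutate(table,
                       flux = relative_ppp_flux(.data$rate, .data$lac_m1,
                                                .data$lac_m2))
  if ("control_group" %in% names(table)) {
    grp <- if ("group" %in% names(table)) table$group else rep("all", nrow(table))
    ctrl <- tapply(out$flux[table$control_group], grp[table$control_group], mean)
    out$relative_flux <- as.numeric(out$flux / ctrl[grp])
  }
  out
}

#' Glucose consumption rate from media aliquots
#'
#' `(conc_start - conc_end) * volume / (time * cell_count)`: amount of
#' glucose consumed per cell per unit time, with units following the
#' inputs (e.g. mM * mL / (h * cell) = mmol/h/cell when volume is in
#' litres x 1000).
#'
#' @param conc_start,conc_end Media glucose concentrations at the start
#'   and end of labeling.
#' @param volume Media volume.
#' @param time Labeling duration.
#' @param cell_count Number of cells.
#' @return Consumption rate; vectorized.
#' @export
glucose_consumption_rate <- function(conc_start, conc_end, volume, time,
                                     cell_count) {
  stopifnot(all(time > 0), all(cell_count > 0))
  (conc_start - conc_end) * volume / (time * cell_count)
}
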