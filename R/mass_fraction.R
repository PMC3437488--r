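#' Bacterial mass concentration from genome counts
#'
#' Converts an airborne bacterial genome concentration to a mass
#' concentration assuming one genome per cell and a fixed per-cell mass
#' (default 655 fg, a representative wet mass for airborne bacteria);
#' 1 fg = 1e-9 ug.
#'
#' @param genome_conc Genome concentration(s), copies/m3.
#' @param cell_mass_fg Mass per bacterium, femtograms.
#' @return Mass concentration(s), ug/m3.
#' @examples
#' bacterial_mass_concentration(1.527e6)  # ~1 ug/m3
#' @export
bacterial_mass_concentration <- function(genome_conc, cell_mass_fg = 655) {
  if (cell_mass_fg <= 0) stop("cell mass must be positive", call. = FALSE)
  if (any(genome_conc < 0, na.rm = TRUE)) {
    stop("genome concentration must be non-negative", call. = FALSE)
  }
  genome_conc * cell_mass_fg * 1e-9
}

#' Bacterial fraction of particulate mass, in ppm
#'
#' Per-bin ratio of bacterial mass to total particulate mass, times 1e6
#' (parts per million). The overall fraction is mass-pooled:
#' `1e6 * sum(bacterial) / sum(pm)` over reportable bins, so it always lies
#' between the per-bin extremes. Bins with zero or missing particulate mass
#' are flagged and excluded from the overall pooling.
#'
#' @param bacterial_mass Per-bin bacterial mass, ug/m3.
#' @param pm_mass Per-bin total particulate mass, ug/m3.
#' @return List with `per_bin_ppm` (NA where PM is zero/missing, with `flag`
#'   attribute) and `overall_ppm`.
#' @export
ppm_fraction <- function(bacterial_mass, pm_mass) {
  if (length(bacterial_mass) != length(pm_mass)) {
    stop("bacterial and PM mass vectors differ in length", call. = FALSE)
  }
  bad <- is.na(pm_mass) | pm_mass <= 0 | is.na(bacterial_mass)
  ppm <- ifelse(bad, NA_real_, 1e6 * bacterial_mass / pm_mass)
  attr(ppm, "flag") <- ifelse(bad, "no_pm_mass", "ok")
  overall <- if (all(bad)) NA_real_ else {
    1e6 * sum(bacterial_mass[!bad]) / sum(pm_mass[!bad])
  }
  list(per_bin_ppm = ppm, overall_ppm = overall)
}
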