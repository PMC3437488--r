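#' rRNA operon copy-number configuration
#'
#' qPCR of the 16S/18S rRNA-encoding gene counts gene copies, not organisms.
#' Converting to genomes requires the operon copy number of the calibrant
#' organism used for the standard curve and the copy number assumed for the
#' sampled community.
#'
#' Defaults per target:
#' * bacteria — calibrated against *Bacillus atrophaeus* genomic DNA
#'   (10 rRNA operon copies per genome); the airborne community is assigned
#'   an average of 4 operon copies per genome.
#' * fungi — calibrated against *Aspergillus fumigatus* (55 operon copies).
#'   Fungal operon counts are highly variable and poorly cataloged, so
#'   results are expressed as *A. fumigatus* equivalent genomes: the assumed
#'   sample copy number equals the calibrant's and no community correction is
#'   applied.
#'
#' @param target `"bacteria"` or `"fungi"`.
#' @param calibrant_operons Operon copies per genome of the standard-curve
#'   organism.
#' @param sample_operons Operon copies per genome assumed for the sampled
#'   community.
#' @return An object of class `operon_config`.
#' @export
operon_config <- function(target = c("bacteria", "fungi"),
                          calibrant_operons = NULL, sample_operons = NULL) {
  target <- match.arg(target)
  calibrant_operons <- calibrant_operons %||%
    switch(target, bacteria = 10L, fungi = 55L)
  sample_operons <- sample_operons %||%
    switch(target, bacteria = 4L, fungi = calibrant_operons)
  if (calibrant_operons < 1 || sample_operons < 1 ||
      calibrant_operons != round(calibrant_operons) ||
      sample_operons != round(sample_operons)) {
    stop("operon copy numbers must be integers >= 1", call. = FALSE)
  }
  structure(list(target = target,
                 calibrant = switch(target, bacteria = "B_atrophaeus",
                                    fungi = "A_fumigatus"),
                 calibrant_operons = as.integer(calibrant_operons),
                 sample_operons = as.integer(sample_operons)),
            class = "operon_config")
}

#' Fit a qPCR standard curve
#'
#' Least-squares line `Ct = slope * log10(copies) + intercept` through a
#' dilution series of known calibrant genome quantities. The amplification
#' efficiency is derived as `10^(-1/slope) - 1` (1.0 means perfect doubling,
#' slope -3.32). At least three dilution points spanning at least two decades
#' are required; a non-negative slope is a calibration error.
#'
#' @param log10_copies log10 calibrant genome copies of each dilution point.
#' @param ct Measured cycle-threshold values.
#' @param operons An [operon_config()] identifying the calibrant.
#' @return Object of class `standard_curve`: `slope`, `intercept`,
#'   `efficiency`, `ct_range`, `log10_range`, `operons`.
#' @export
fit_standard_curve <- function(log10_copies, ct,
                               operons = operon_config("bacteria")) {
  if (length(log10_copies) != length(ct)) {
    stop("log10_copies and ct lengths differ", call. = FALSE)
  }
  if (length(unique(log10_copies)) < 3) {
    stop("standard curve needs >= 3 distinct dilution levels", call. = FALSE)
  }
  if (diff(range(log10_copies)) < 2) {
    stop("dilution series must span >= 2 decades", call. = FALSE)
  }
  fit <- stats::lm(ct ~ log10_copies)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) {
    stop("standard-curve slope must be negative (Ct falls as copies rise)",
         call. = FALSE)
  }
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 efficiency = 10^(-1 / slope) - 1,
                 ct_range = range(ct),
                 log10_range = range(log10_copies),
                 operons = operons),
            class = "standard_curve")
}

#' Expected Ct for a calibrant genome quantity
#'
#' Inverse use of a [fit_standard_curve()] line; used by the synthetic-data
#' generator and in roundtrip checks.
#'
#' @param copies Calibrant genome copies (> 0).
#' @param curve A `standard_curve`.
#' @return Expected cycle-threshold value(s).
#' @export
ct_from_copies <- function(copies, curve) {
  if (any(copies <= 0)) stop("copies must be positive", call. = FALSE)
  curve$slope * log10(copies) + curve$intercept
}

#' Convert qPCR Ct values to genome copies
#'
#' Replicate Ct values (conventionally a triplicate) are averaged
#' arithmetically; the standard curve converts the mean Ct to
#' calibrant-genome equivalents, which are scaled to rRNA gene copies by the
#' calibrant's operon count and then to sample genomes by the assumed
#' community operon count:
#' `genomes = equivalents * calibrant_operons / sample_operons`.
#'
#' For fungi the sample operon count equals the calibrant's, so the result
#' stays in *A. fumigatus* equivalent genomes and is labelled as such — the
#' package never converts fungal gene copies to true genomes.
#'
#' Failed replicates are passed as NA. If fewer than two replicates
#' amplified, the sample is reported below detection (`genomes = NA`,
#' `flag = "below_detection"`), never as zero. A mean Ct outside the
#' calibrated range is extrapolation and is flagged.
#'
#' @param ct Numeric vector of replicate Ct values (NA = no amplification).
#' @param curve A [fit_standard_curve()] result.
#' @param operons An [operon_config()]; defaults to the curve's.
#' @return List with `genomes`, `gene_copies`, `calibrant_equivalents`,
#'   `mean_ct`, `flag` (`"ok"`, `"extrapolated"` or `"below_detection"`),
#'   and `units`.
#' @export
quantify_genomes <- function(ct, curve, operons = NULL) {
  stopifnot(inherits(curve, "standard_curve"))
  operons <- operons %||% curve$operons
  n_ok <- sum(!is.na(ct))
  if (n_ok < 2 && length(ct) >= 3) {
    return(list(genomes = NA_real_, gene_copies = NA_real_,
                calibrant_equivalents = NA_real_, mean_ct = NA_real_,
                flag = "below_detection", units = quant_units(operons)))
  }
  if (n_ok == 0) {
    return(list(genomes = NA_real_, gene_copies = NA_real_,
                calibrant_equivalents = NA_real_, mean_ct = NA_real_,
                flag = "below_detection", units = quant_units(operons)))
  }
  mean_ct <- mean(ct, na.rm = TRUE)
  equivalents <- 10^((mean_ct - curve$intercept) / curve$slope)
  gene_copies <- equivalents * operons$calibrant_operons
  genomes <- gene_copies / operons$sample_operons
  flag <- if (mean_ct < curve$ct_range[1] || mean_ct > curve$ct_range[2]) {
    "extrapolated"
  } else "ok"
  list(genomes = genomes, gene_copies = gene_copies,
       calibrant_equivalents = equivalents, mean_ct = mean_ct,
       flag = flag, units = quant_units(operons))
}

quant_units <- function(operons) {
  if (operons$target == "fungi") "equivalent genomes" else "genomes"
}

#' Airborne concentration from filter genome counts
#'
#' Scales genomes measured in a DNA-extraction aliquot up to the whole filter
#' (`/ aliquot_fraction`) and divides by the air volume drawn through the
#' sampler (`flow_lpm * duration_h * 60 / 1000` m3).
#'
#' @param genomes_in_aliquot Genome (or equivalent-genome) copies measured in
#'   the extracted aliquot.
#' @param duration_h Cumulative pump-on sampling time, h.
#' @param aliquot_fraction Fraction of the filter extracted (default 1/4).
#' @param flow_lpm Sampler flow rate, L/min (default 28.3, a standard
#'   cascade-impactor flow).
#' @return Concentration, copies/m3.
#' @examples
#' air_concentration(1e6, duration_h = 22.2)  # ~1.06e5 copies/m3
#' @export
air_concentration <- function(genomes_in_aliquot, duration_h,
                              aliquot_fraction = 0.25, flow_lpm = 28.3) {
  if (aliquot_fraction <= 0 || aliquot_fraction > 1) {
    stop("aliquot_fraction must be in (0, 1]", call. = FALSE)
  }
  if (flow_lpm <= 0) stop("flow must be positive", call. = FALSE)
  if (duration_h <= 0) stop("sampling duration must be positive", call. = FALSE)
  volume_m3 <- flow_lpm * duration_h * 60 / 1000
  (genomes_in_aliquot / aliquot_fraction) / volume_m3
}
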