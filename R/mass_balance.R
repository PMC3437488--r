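#' Room and occupancy parameters
#'
#' Parameters of the steady-state well-mixed room model: volume `V` (m3),
#' air-exchange rate (1/h, so the ventilation flow is `Q = aer * V` m3/h),
#' and the mean number of occupants `N` during the occupied sampling period.
#'
#' @param volume_m3 Room volume, m3.
#' @param aer_per_h Air-exchange rate, 1/h.
#' @param occupancy Mean number of persons present.
#' @return An object of class `room_params` with derived `Q_m3_h`.
#' @examples
#' room_params(volume_m3 = 90, aer_per_h = 5.5, occupancy = 4.7)
#' @export
room_params <- function(volume_m3, aer_per_h, occupancy) {
  if (volume_m3 <= 0) stop("room volume must be positive", call. = FALSE)
  if (aer_per_h < 0) stop("air-exchange rate must be non-negative", call. = FALSE)
  if (occupancy < 0) stop("occupancy must be non-negative", call. = FALSE)
  structure(list(volume_m3 = volume_m3, aer_per_h = aer_per_h,
                 occupancy = occupancy, Q_m3_h = aer_per_h * volume_m3),
            class = "room_params")
}

.analytes <- c("mass", "bacterial_genomes", "fungal_equiv_genomes")

default_units <- function(analyte) {
  switch(analyte,
         mass = "ug/m3",
         bacterial_genomes = "copies/m3",
         fungal_equiv_genomes = "equivalent copies/m3")
}

#' Size-binned concentration profile
#'
#' A per-bin, time-averaged concentration for one analyte at one location in
#' one occupancy state. Analytes are total particle mass (ug/m3), bacterial
#' genomes (copies/m3) or equivalent fungal genomes (equivalent copies/m3 —
#' fungal quantities are expressed relative to the calibrant's operon count
#' and are never converted to true genomes, see [quantify_genomes()]).
#'
#' @param bins A [size_bins()] grid.
#' @param conc Per-bin concentration; non-negative (NA marks below-detection).
#' @param analyte One of `"mass"`, `"bacterial_genomes"`,
#'   `"fungal_equiv_genomes"`.
#' @param location `"indoor"` or `"outdoor"`.
#' @param state `"occupied"` or `"vacant"`.
#' @param units Unit string; defaults by analyte.
#' @return Data frame of class `concentration_profile` with columns
#'   `d_lo_um`, `d_hi_um`, `conc` and attributes `analyte`, `location`,
#'   `state`, `units`.
#' @export
concentration_profile <- function(bins, conc,
                                  analyte = .analytes,
                                  location = c("indoor", "outdoor"),
                                  state = c("occupied", "vacant"),
                                  units = NULL) {
  bins <- as_size_bins(bins)
  analyte <- match.arg(analyte)
  location <- match.arg(location)
  state <- match.arg(state)
  if (length(conc) != nrow(bins)) stop("one concentration per bin required",
                                       call. = FALSE)
  if (any(conc < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative (use NA for below-detection)",
         call. = FALSE)
  }
  out <- data.frame(bins, conc = as.numeric(conc))
  structure(out, analyte = analyte, location = location, state = state,
            units = units %||% default_units(analyte),
            class = c("concentration_profile", "size_bins", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

profile_meta <- function(p) {
  c(analyte = attr(p, "analyte"), location = attr(p, "location"),
    state = attr(p, "state"))
}

check_profile <- function(p, location = NULL, state = NULL, what = "profile") {
  if (!inherits(p, "concentration_profile")) {
    stop(what, " must be a concentration_profile", call. = FALSE)
  }
  if (!is.null(location) && attr(p, "location") != location) {
    stop(what, " must be a ", location, " profile (got ",
         attr(p, "location"), ")", call. = FALSE)
  }
  if (!is.null(state) && attr(p, "state") != state) {
    stop(what, " must be a ", state, "-state profile (got ",
         attr(p, "state"), ")", call. = FALSE)
  }
  invisible(p)
}

#' Size-resolved infiltration factors
#'
#' The infiltration factor `f` is the indoor/outdoor concentration ratio in
#' the absence of indoor sources; it folds together envelope penetration,
#' filtration in the ventilation system and deposition losses of
#' outdoor-origin particles. It is estimated per size bin from the vacant
#' sampling period, `f_i = C_in,i / C_out,i`, and assumed to carry over to the
#' occupied period at the same size.
#'
#' Bins with zero or missing outdoor concentration have undefined `f`; they
#' are flagged `"undefined"` (with a warning) and excluded from downstream
#' emission inversion. Factors above 1.5 are physically surprising for
#' particles and draw a warning but are retained.
#'
#' @param indoor_vacant,outdoor_vacant Vacant-state [concentration_profile()]s
#'   for the same analyte on the same bin grid.
#' @return Data frame of class `infiltration_factors` with columns `d_lo_um`,
#'   `d_hi_um`, `f`, `flag`.
#' @export
infiltration_factors <- function(indoor_vacant, outdoor_vacant) {
  check_profile(indoor_vacant, "indoor", "vacant", "indoor_vacant")
  check_profile(outdoor_vacant, "outdoor", "vacant", "outdoor_vacant")
  stop_if_bins_differ(indoor_vacant, outdoor_vacant, "vacant profiles")
  if (attr(indoor_vacant, "analyte") != attr(outdoor_vacant, "analyte")) {
    stop("vacant profiles are for different analytes", call. = FALSE)
  }
  bad <- is.na(outdoor_vacant$conc) | outdoor_vacant$conc == 0 |
    is.na(indoor_vacant$conc)
  f <- ifelse(bad, NA_real_, indoor_vacant$conc / outdoor_vacant$conc)
  if (any(bad)) {
    warning("infiltration factor undefined for bin(s) ",
            paste(bin_labels(indoor_vacant)[bad], collapse = ", "),
            " (zero or missing concentration); excluded downstream",
            call. = FALSE)
  }
  if (any(f > 1.5, na.rm = TRUE)) {
    warning("infiltration factor(s) above 1.5; check vacant data",
            call. = FALSE)
  }
  structure(data.frame(d_lo_um = indoor_vacant$d_lo_um,
                       d_hi_um = indoor_vacant$d_hi_um,
                       f = f,
                       flag = ifelse(bad, "undefined", "ok")),
            analyte = attr(indoor_vacant, "analyte"),
            class = c("infiltration_factors", "size_bins", "data.frame"))
}

#' Per-bin, per-person emission profile
#'
#' Holds the per-person emission rate `E` per bin (ug/h/person for mass,
#' copies/h/person for genomes) together with the size-distribution density
#' `E_dlogdp = E / dlog10(dp)` and a per-bin provenance flag:
#' `"ok"`, `"negative_clamped"` (inferred indoor excess was negative and was
#' clamped to zero; the raw value is kept in the `raw` attribute) or
#' `"excluded"` (no usable infiltration factor or below-detection input).
#'
#' @param bins A [size_bins()] grid.
#' @param E Per-bin emission rate (NA for excluded bins).
#' @param flag Per-bin character flag; defaults to `"ok"`.
#' @param analyte Analyte label carried through from the concentrations.
#' @param units Unit string for `E`.
#' @return Data frame of class `emission_profile` with columns `d_lo_um`,
#'   `d_hi_um`, `E`, `E_dlogdp`, `flag`.
#' @export
emission_profile <- function(bins, E, flag = NULL, analyte = NULL,
                             units = NULL) {
  bins <- as_size_bins(bins)
  if (length(E) != nrow(bins)) stop("one E per bin required", call. = FALSE)
  flag <- flag %||% rep("ok", nrow(bins))
  ok <- flag %in% c("ok", "negative_clamped", "excluded", "below_detection")
  if (!all(ok)) stop("unknown emission flag: ", flag[!ok][1], call. = FALSE)
  structure(data.frame(bins, E = as.numeric(E),
                       E_dlogdp = as.numeric(E) / dlog_width(bins),
                       flag = flag),
            analyte = analyte, units = units,
            class = c("emission_profile", "size_bins", "data.frame"))
}

removal_rate <- function(room, k) {
  # total removal flow Q + k*V (m3/h), per bin
  if (!inherits(k, "bin_loss_rates")) stop("k must be bin_loss_rates",
                                           call. = FALSE)
  room$Q_m3_h + k$k_per_h * room$volume_m3
}

#' Forward steady-state indoor concentration
#'
#' The well-mixed material balance: the time-averaged indoor concentration is
#' a fraction `f` of the outdoor concentration plus the occupant source term
#' divided by the total removal rate,
#' `C = f * C_out + N * E / (Q + k * V)` per size bin. Linear in both `E` and
#' `C_out`; [invert_emission()] is its exact algebraic inverse.
#'
#' @param f [infiltration_factors()].
#' @param outdoor Outdoor [concentration_profile()].
#' @param E [emission_profile()] of per-person emission rates.
#' @param room [room_params()].
#' @param k [bin_loss_rates()].
#' @return Indoor occupied [concentration_profile()].
#' @export
steady_state_concentration <- function(f, outdoor, E, room, k) {
  check_profile(outdoor, "outdoor", NULL, "outdoor")
  stop_if_bins_differ(f, outdoor, "f and outdoor")
  stop_if_bins_differ(outdoor, E, "outdoor and E")
  stop_if_bins_differ(outdoor, k, "outdoor and k")
  denom <- removal_rate(room, k)
  if (any(denom == 0 & E$E > 0, na.rm = TRUE)) {
    stop("zero total removal rate with a positive source: singular model",
         call. = FALSE)
  }
  conc <- f$f * outdoor$conc + room$occupancy * E$E / denom
  concentration_profile(as_size_bins(outdoor), conc,
                        analyte = attr(outdoor, "analyte"),
                        location = "indoor", state = "occupied",
                        units = attr(outdoor, "units"))
}

#' Invert the material balance for per-person emission rates
#'
#' Solves the steady-state balance for the per-person, size-resolved emission
#' rate: `E = (C - f * C_out) * (Q + k * V) / N` per bin. This is the exact
#' inverse of [steady_state_concentration()].
#'
#' A negative indoor excess `C - f * C_out` would imply a negative source,
#' which has no physical meaning; such bins are reported as `E = 0` with flag
#' `"negative_clamped"` and the raw value retained in the `raw` attribute.
#' Bins whose infiltration factor is flagged undefined, or with missing
#' concentrations, are returned as NA with flag `"excluded"`.
#'
#' @param indoor_occupied,outdoor_occupied Occupied-state
#'   [concentration_profile()]s.
#' @param f [infiltration_factors()] (from the vacant period).
#' @param room [room_params()]; `occupancy` must be positive.
#' @param k [bin_loss_rates()].
#' @return An [emission_profile()]; attribute `raw` holds the unclamped rates.
#' @export
invert_emission <- function(indoor_occupied, outdoor_occupied, f, room, k) {
  check_profile(indoor_occupied, "indoor", "occupied", "indoor_occupied")
  check_profile(outdoor_occupied, "outdoor", "occupied", "outdoor_occupied")
  stop_if_bins_differ(indoor_occupied, outdoor_occupied, "occupied profiles")
  stop_if_bins_differ(indoor_occupied, f, "concentrations and f")
  stop_if_bins_differ(indoor_occupied, k, "concentrations and k")
  if (room$occupancy <= 0) {
    stop("occupancy must be positive: emission rates are per person",
         call. = FALSE)
  }
  excess <- indoor_occupied$conc - f$f * outdoor_occupied$conc
  E_raw <- excess * removal_rate(room, k) / room$occupancy
  excluded <- f$flag != "ok" | is.na(indoor_occupied$conc) |
    is.na(outdoor_occupied$conc)
  clamped <- !excluded & E_raw < 0
  E <- E_raw
  E[clamped] <- 0
  E[excluded] <- NA_real_
  flag <- rep("ok", length(E))
  flag[clamped] <- "negative_clamped"
  flag[excluded] <- "excluded"
  out <- emission_profile(as_size_bins(indoor_occupied), E, flag,
                          analyte = attr(indoor_occupied, "analyte"),
                          units = emission_units(attr(indoor_occupied, "analyte")))
  attr(out, "raw") <- E_raw
  out
}

emission_units <- function(analyte) {
  if (is.null(analyte)) return(NULL)
  switch(analyte,
         mass = "ug/h/person",
         bacterial_genomes = "copies/h/person",
         fungal_equiv_genomes = "equivalent copies/h/person",
         NULL)
}

#' Decadal-log size-distribution normalization
#'
#' Converts per-bin totals to densities per unit log10 diameter
#' (`value / dlog10(dp)`), the conventional way to draw size distributions so
#' that areas are comparable across unequal bins. [denormalize_dlogdp()] is
#' the exact inverse.
#'
#' @param values Per-bin values.
#' @param bins A [size_bins()] grid.
#' @return Per-bin densities (same length as `values`).
#' @export
normalize_dlogdp <- function(values, bins) {
  bins <- as_size_bins(bins)
  if (length(values) != nrow(bins)) stop("one value per bin required",
                                         call. = FALSE)
  w <- dlog_width(bins)
  if (any(w == 0)) stop("zero-width bin", call. = FALSE)
  values / w
}

#' @rdname normalize_dlogdp
#' @export
denormalize_dlogdp <- function(values, bins) {
  bins <- as_size_bins(bins)
  if (length(values) != nrow(bins)) stop("one value per bin required",
                                         call. = FALSE)
  values * dlog_width(bins)
}

#' Occupied-to-vacant concentration ratios
#'
#' Per-bin ratios of occupied to vacant indoor concentrations, a direct
#' measure of occupancy-associated enhancement, plus two across-bin summaries
#' computed side by side because they answer different questions and can
#' differ substantially on skewed size distributions: the unweighted mean of
#' per-bin ratios, and the ratio of summed concentrations (total-burden
#' ratio).
#'
#' @param occupied,vacant [concentration_profile()]s for the same analyte and
#'   location on the same grid.
#' @return List with `per_bin` (ratios, NA where vacant is zero/missing, with
#'   a `flag` attribute), `mean_of_ratios` and `ratio_of_means`.
#' @export
occupied_vacant_ratio <- function(occupied, vacant) {
  check_profile(occupied, NULL, "occupied", "occupied")
  check_profile(vacant, NULL, "vacant", "vacant")
  stop_if_bins_differ(occupied, vacant, "occupied and vacant profiles")
  bad <- is.na(vacant$conc) | vacant$conc == 0 | is.na(occupied$conc)
  ratios <- ifelse(bad, NA_real_, occupied$conc / vacant$conc)
  attr(ratios, "flag") <- ifelse(bad, "undefined", "ok")
  list(per_bin = ratios,
       mean_of_ratios = mean(ratios, na.rm = TRUE),
       ratio_of_means = sum(occupied$conc[!bad]) / sum(vacant$conc[!bad]))
}
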