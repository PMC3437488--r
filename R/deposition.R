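#' Cubic log-log deposition model
#'
#' Empirical size-specific deposition loss-rate model of the form
#' `Y = c0 + c1*X + c2*X^2 + c3*X^3` with `X = log10(dp / um)` and
#' `Y = log10(k * h)`, where `k` is the first-order rate at which airborne
#' particles of aerodynamic diameter `dp` are lost to indoor surfaces.
#'
#' The default coefficients reproduce a cubic fitted to chamber deposition
#' measurements for a furnished room at high airspeed, covering 0.5-9 um
#' particles. Evaluation beyond the fitted range (notably up to the 20 um cap
#' of the largest impactor stage) is an extrapolation; [bin_averaged_loss_rate()]
#' emits a message when a bin requires it.
#'
#' @param c0,c1,c2,c3 Polynomial coefficients (dimensionless).
#' @param fitted_range_um Diameter range over which the cubic was fitted, um.
#' @return An object of class `cubic_deposition_model`.
#' @examples
#' m <- cubic_deposition_model()
#' cubic_loss_rate(1.0, m)  # X = 0, so k = 10^c0
#' @export
cubic_deposition_model <- function(c0 = -0.407, c1 = 1.232, c2 = 1.818,
                                   c3 = -1.594, fitted_range_um = c(0.5, 9)) {
  coef <- c(c0 = c0, c1 = c1, c2 = c2, c3 = c3)
  if (any(!is.finite(coef))) stop("coefficients must be finite", call. = FALSE)
  structure(list(coef = coef, fitted_range_um = fitted_range_um),
            class = "cubic_deposition_model")
}

#' Pointwise deposition loss rate from the cubic model
#'
#' @param dp_um Aerodynamic diameter(s), um; must be positive.
#' @param model A [cubic_deposition_model()].
#' @return Loss-rate coefficient(s) k, 1/h (strictly positive).
#' @export
cubic_loss_rate <- function(dp_um, model = cubic_deposition_model()) {
  if (!is.numeric(dp_um) || any(!is.finite(dp_um)) || any(dp_um <= 0)) {
    stop("dp_um must be positive and finite", call. = FALSE)
  }
  x <- log10(dp_um)
  co <- model$coef
  10^(co[["c0"]] + co[["c1"]] * x + co[["c2"]] * x^2 + co[["c3"]] * x^3)
}

#' Bin-averaged loss-rate coefficient
#'
#' Averages a pointwise loss-rate model over each size bin assuming particle
#' mass is uniformly distributed with respect to log10 of diameter within the
#' bin: `k_bar = (1/dX) * integral of k(10^X) dX` over
#' `X in [log10(d_lo), log10(d_hi)]`, by adaptive quadrature
#' ([stats::integrate()], relative tolerance `rel_tol`). The integrand is
#' smooth, so the average always lies between the pointwise extremes on the
#' bin.
#'
#' @param bins A [size_bins()] grid.
#' @param model A `cubic_deposition_model`, a `settling_model`, or a function
#'   `k(dp_um)` returning 1/h.
#' @param rel_tol Relative quadrature tolerance.
#' @return Numeric vector of bin-averaged k, 1/h, one per bin.
#' @examples
#' bin_averaged_loss_rate(impactor_bins())  # the six-stage k table
#' @export
bin_averaged_loss_rate <- function(bins, model = cubic_deposition_model(),
                                   rel_tol = 1e-8) {
  bins <- as_size_bins(bins)
  fn <- pointwise_loss_fn(model)
  if (inherits(model, "cubic_deposition_model")) {
    rng <- model$fitted_range_um
    extrap <- bins$d_lo_um < rng[1] | bins$d_hi_um > rng[2]
    if (any(extrap)) {
      message("cubic deposition model extrapolated beyond its fitted range (",
              rng[1], "-", rng[2], " um) for bin(s): ",
              paste(bin_labels(bins)[extrap], collapse = ", "))
    }
  }
  vapply(seq_len(nrow(bins)), function(i) {
    x1 <- log10(bins$d_lo_um[i]); x2 <- log10(bins$d_hi_um[i])
    q <- tryCatch(
      stats::integrate(function(x) fn(10^x), x1, x2, rel.tol = rel_tol),
      error = function(e) {
        stop("quadrature failed on bin ", bin_labels(bins)[i], ": ",
             conditionMessage(e), call. = FALSE)
      })
    q$value / (x2 - x1)
  }, numeric(1))
}

pointwise_loss_fn <- function(model) {
  if (is.function(model)) return(model)
  if (inherits(model, "cubic_deposition_model")) {
    return(function(dp) cubic_loss_rate(dp, model))
  }
  if (inherits(model, "settling_model")) {
    return(function(dp) settling_loss_rate(dp, model))
  }
  stop("unsupported loss-rate model", call. = FALSE)
}

#' Per-bin loss-rate table
#'
#' Convenience wrapper returning the bin grid together with bin-averaged
#' loss-rate coefficients as a `bin_loss_rates` data frame, the form consumed
#' by the material-balance operations.
#'
#' @inheritParams bin_averaged_loss_rate
#' @return Data frame of class `bin_loss_rates` with columns `d_lo_um`,
#'   `d_hi_um`, `k_per_h`.
#' @export
deposition_loss_rates <- function(bins = impactor_bins(),
                                  model = cubic_deposition_model(),
                                  rel_tol = 1e-8) {
  bins <- as_size_bins(bins)
  k <- bin_averaged_loss_rate(bins, model, rel_tol)
  bin_loss_rates(bins, k)
}

#' @rdname deposition_loss_rates
#' @param k Per-bin loss-rate coefficients, 1/h (non-negative).
#' @export
bin_loss_rates <- function(bins, k) {
  bins <- as_size_bins(bins)
  if (length(k) != nrow(bins)) stop("one k per bin required", call. = FALSE)
  if (any(!is.finite(k)) || any(k < 0)) {
    stop("loss-rate coefficients must be finite and non-negative",
         call. = FALSE)
  }
  structure(data.frame(bins, k_per_h = k),
            class = c("bin_loss_rates", "size_bins", "data.frame"))
}

#' Gravitational-settling loss-rate model
#'
#' First-order loss by gravitational settling in a well-mixed room of height
#' `H`: `k = v_s / H`, with the Stokes settling velocity
#' `v_s = rho * g * dp^2 / (18 * mu)`. Diameters are aerodynamic, so the
#' unit-density convention (`rho` = 1000 kg/m3) applies by default and the
#' particle's true density is already folded into `dp`. No slip correction is
#' applied: it is negligible for the supermicron sizes this model is used for,
#' and every sensitivity ratio built on this model cancels the prefactor
#' entirely, leaving pure `dp^2` scaling.
#'
#' @param room_height_m Room height, m.
#' @param particle_density_kg_m3 Particle density, kg/m3 (unit density for
#'   aerodynamic diameters).
#' @param air_viscosity_pa_s Dynamic viscosity of air, Pa s (default 20 C).
#' @param g_m_s2 Gravitational acceleration, m/s2.
#' @return An object of class `settling_model`.
#' @export
settling_model <- function(room_height_m = 3,
                           particle_density_kg_m3 = 1000,
                           air_viscosity_pa_s = 1.81e-5,
                           g_m_s2 = 9.80665) {
  if (room_height_m <= 0) stop("room height must be positive", call. = FALSE)
  if (particle_density_kg_m3 <= 0) stop("density must be positive", call. = FALSE)
  structure(list(room_height_m = room_height_m,
                 particle_density_kg_m3 = particle_density_kg_m3,
                 air_viscosity_pa_s = air_viscosity_pa_s,
                 g_m_s2 = g_m_s2),
            class = "settling_model")
}

#' Pointwise settling loss rate
#'
#' @param dp_um Aerodynamic diameter(s), um; positive.
#' @param model A [settling_model()].
#' @return Loss rate k = v_s/H, 1/h; strictly increasing in `dp_um`.
#' @export
settling_loss_rate <- function(dp_um, model = settling_model()) {
  if (!is.numeric(dp_um) || any(!is.finite(dp_um)) || any(dp_um <= 0)) {
    stop("dp_um must be positive and finite", call. = FALSE)
  }
  v_s <- model$particle_density_kg_m3 * model$g_m_s2 * (dp_um * 1e-6)^2 /
    (18 * model$air_viscosity_pa_s)          # m/s
  v_s / model$room_height_m * 3600           # 1/h
}

#' Bin-averaged settling loss rate (closed form)
#'
#' For the Stokes settling model `k` is proportional to `dp^2`, so the
#' log-uniform bin average has the closed form
#' `mean(dp^2) = (d_hi^2 - d_lo^2) / (2 * ln(d_hi/d_lo))`
#' over `X = log10(dp)` uniform on the bin. Returns both the dimensionless
#' `dp^2` mean (um2), which every sensitivity ratio reduces to, and the
#' corresponding loss rate for the given model.
#'
#' @param bins A [size_bins()] grid.
#' @param model A [settling_model()].
#' @return List with `dp2_mean_um2` and `k_per_h`, each one value per bin.
#' @examples
#' settling_bin_average(size_bins(9, 20))$dp2_mean_um2  # approx. 199.7
#' @export
settling_bin_average <- function(bins, model = settling_model()) {
  bins <- as_size_bins(bins)
  dp2 <- (bins$d_hi_um^2 - bins$d_lo_um^2) /
    (2 * log(bins$d_hi_um / bins$d_lo_um))
  k_unit <- settling_loss_rate(1, model)     # k at dp = 1 um; k = k_unit*dp^2
  list(dp2_mean_um2 = dp2, k_per_h = k_unit * dp2)
}

#' Sensitivity of the top-stage loss rate and emission rate to the upper
#' size cap
#'
#' The largest impactor stage has no sharp upper cut-point; an upper limit
#' must be assumed. This operation quantifies how moving that cap from
#' `base_bin$d_hi_um` to `alt_upper_um` changes (i) the bin-averaged
#' loss-rate coefficient under gravitational settling (a pure `dp^2` ratio,
#' independent of density, viscosity and room height) and (ii) the emission
#' rate inferred through the total removal rate `AER + k`:
#' `pct_change_E = 100 * ((aer + k_alt) / (aer + k_base) - 1)` with
#' `k_alt = base_k * (1 + pct_change_k/100)`.
#'
#' @param base_bin Single-bin [size_bins()] for the top stage (e.g. 9-20 um).
#' @param alt_upper_um Alternative upper cap, um; must exceed the bin's lower
#'   edge.
#' @param aer_per_h Air-exchange rate, 1/h.
#' @param base_k_per_h Loss-rate coefficient in use for the base bin, 1/h.
#' @return List with `pct_change_k` and `pct_change_E` (percent).
#' @examples
#' upper_limit_sensitivity(size_bins(9, 20), 15, aer_per_h = 5.5,
#'                         base_k_per_h = 9.6)
#' @export
upper_limit_sensitivity <- function(base_bin, alt_upper_um,
                                    aer_per_h, base_k_per_h) {
  base_bin <- as_size_bins(base_bin)
  if (nrow(base_bin) != 1L) stop("base_bin must be a single bin", call. = FALSE)
  if (alt_upper_um <= base_bin$d_lo_um) {
    stop("alternative upper limit must exceed the bin's lower edge",
         call. = FALSE)
  }
  alt_bin <- size_bins(base_bin$d_lo_um, alt_upper_um)
  ratio <- settling_bin_average(alt_bin)$dp2_mean_um2 /
    settling_bin_average(base_bin)$dp2_mean_um2
  pct_k <- 100 * (ratio - 1)
  k_alt <- base_k_per_h * ratio
  pct_e <- 100 * ((aer_per_h + k_alt) / (aer_per_h + base_k_per_h) - 1)
  list(pct_change_k = pct_k, pct_change_E = pct_e)
}
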