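#' Tracer-gas concentration series
#'
#' A time series of tracer concentration (e.g. CO2, ppm) recorded after a
#' release or after occupants leave, used to estimate the air-exchange rate
#' from the first-order decay of the above-background excess. The background
#' is the concentration the room relaxes to (for CO2, the outdoor/baseline
#' level); it is subtracted before the log-linear fit and must be supplied
#' from the measurement context — estimating it from the tail of a still-
#' decaying series biases the rate, so no automatic default is attempted.
#'
#' @param t_h Sampling times, h; strictly increasing.
#' @param conc Tracer concentration at each time.
#' @param background Baseline concentration subtracted before fitting.
#' @return An object of class `tracer_series`.
#' @export
tracer_series <- function(t_h, conc, background = 0) {
  if (length(t_h) != length(conc)) stop("t_h and conc lengths differ",
                                        call. = FALSE)
  if (any(diff(t_h) <= 0)) stop("t_h must be strictly increasing",
                                call. = FALSE)
  if (sum(conc - background > 0, na.rm = TRUE) < 3) {
    stop("need at least 3 samples above background", call. = FALSE)
  }
  structure(list(t_h = t_h, conc = conc, background = background),
            class = "tracer_series")
}

#' Air-exchange rate from tracer decay
#'
#' In a well-mixed room the above-background tracer excess decays as
#' `C(t) - C_bg = C0 * exp(-aer * t)`, so ordinary least squares of
#' `ln(conc - background)` against time recovers the air-exchange rate as the
#' negative slope. A noiseless exponential is recovered exactly, for any rate
#' and background; the fit is invariant to multiplying the excess by any
#' positive constant.
#'
#' @param series A [tracer_series()].
#' @param window Optional `c(t_min, t_max)` in h restricting the fit; default
#'   the full series.
#' @return Object of class `aer_estimate`: list with `aer_per_h`,
#'   `stderr_per_h`, `r_squared`, `window_h`, `n`.
#' @examples
#' s <- tracer_series(seq(0, 0.5, length.out = 20),
#'                    400 + 1600 * exp(-5.5 * seq(0, 0.5, length.out = 20)),
#'                    background = 400)
#' fit_tracer_decay(s)$aer_per_h  # 5.5
#' @export
fit_tracer_decay <- function(series, window = NULL) {
  stopifnot(inherits(series, "tracer_series"))
  keep <- rep(TRUE, length(series$t_h))
  if (!is.null(window)) {
    keep <- series$t_h >= window[1] & series$t_h <= window[2]
  }
  t <- series$t_h[keep]
  excess <- series$conc[keep] - series$background
  if (length(t) < 3) stop("fewer than 3 samples in the fit window",
                          call. = FALSE)
  if (any(excess <= 0 | is.na(excess))) {
    bad <- which(excess <= 0 | is.na(excess))[1]
    stop("non-positive tracer excess at t = ", t[bad],
         " h; shrink the fit window or lower the background", call. = FALSE)
  }
  fit <- stats::lm(log(excess) ~ t)
  sm <- summary(fit)
  structure(list(aer_per_h = -unname(stats::coef(fit)[2]),
                 stderr_per_h = unname(sm$coefficients[2, "Std. Error"]),
                 r_squared = sm$r.squared,
                 window_h = range(t), n = length(t)),
            class = "aer_estimate")
}

#' Aggregate replicate air-exchange-rate estimates
#'
#' Arithmetic mean and sample standard deviation over replicate tracer
#' releases. A single estimate reports sd 0 with `n = 1` so the caller can
#' see the spread is not estimable.
#'
#' @param estimates List of [fit_tracer_decay()] results (or bare numerics).
#' @return List with `mean_per_h`, `sd_per_h`, `n`.
#' @export
aggregate_aer <- function(estimates) {
  if (length(estimates) == 0) stop("no estimates to aggregate", call. = FALSE)
  vals <- vapply(estimates, function(e) {
    if (inherits(e, "aer_estimate")) e$aer_per_h else as.numeric(e)
  }, numeric(1))
  list(mean_per_h = mean(vals),
       sd_per_h = if (length(vals) > 1) stats::sd(vals) else 0,
       n = length(vals))
}
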