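#' Measurement-noise model for synthetic observations
#'
#' Concentration and tracer noise are multiplicative lognormal with the given
#' coefficient of variation, parameterised to have mean exactly 1 (so noisy
#' observations are unbiased around the truth); concentrations are strictly
#' positive and span decades, which an additive model cannot respect. Ct
#' noise is additive Gaussian on the cycle scale. Taxa reads are multinomial
#' draws per bin at `read_depth` (no overdispersion by default).
#'
#' @param concentration_cv CV of concentration noise (0 = noiseless).
#' @param ct_sd Standard deviation of replicate Ct values, cycles.
#' @param read_depth Sequencing reads per size bin.
#' @param tracer_cv CV of tracer concentration noise.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(concentration_cv = 0.1, ct_sd = 0.15,
                        read_depth = 60, tracer_cv = 0.02) {
  vals <- c(concentration_cv, ct_sd, read_depth, tracer_cv)
  if (any(vals < 0)) stop("noise parameters must be non-negative",
                          call. = FALSE)
  structure(list(concentration_cv = concentration_cv, ct_sd = ct_sd,
                 read_depth = as.integer(read_depth), tracer_cv = tracer_cv),
            class = "noise_model")
}

# mean-1 multiplicative lognormal factors
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

default_taxa_composition <- function() {
  taxa <- c("Propionibacterineae", "Staphylococcus", "Enterobacteriaceae",
            "Corynebacterineae", "Pasteurellaceae", "Fusobacterium",
            "Veillonella", "Sphingomonas", "Rhodobacteria", "Streptophyta",
            "Other")
  # per-bin skin/oral mass, remainder split across environmental taxa
  skin_bin <- c(0.13, 0.073, 0.15, 0.18, 0.15, 0.31)   # pooled ~0.17
  oral_bin <- c(0.004, 0.018, 0.004, 0.004, 0.04, 0.004)
  indoor <- t(vapply(seq_along(skin_bin), function(i) {
    skin <- skin_bin[i] * c(0.45, 0.25, 0.1, 0.2)
    oral <- oral_bin[i] * c(0.5, 0.25, 0.25)
    env <- (1 - skin_bin[i] - oral_bin[i]) * c(0.2, 0.15, 0.25, 0.4)
    c(skin, oral, env)
  }, numeric(length(taxa))))
  outdoor_skin <- 0.049 * c(0.8, 0.05, 0.05, 0.1)      # mostly Propionibacterineae
  outdoor_oral <- 0.004 * c(0.3, 0.2, 0.5)
  outdoor_env <- (1 - sum(outdoor_skin) - sum(outdoor_oral)) *
    c(0.3, 0.2, 0.3, 0.2)
  outdoor <- matrix(rep(c(outdoor_skin, outdoor_oral, outdoor_env),
                        each = length(skin_bin)),
                    nrow = length(skin_bin))
  colnames(indoor) <- taxa
  colnames(outdoor) <- taxa
  list(taxa = taxa, indoor = indoor, outdoor = outdoor)
}

#' Generate a ground-truth room scenario
#'
#' Builds a fully specified synthetic study scenario: a classroom-like room
#' (90 m3, air-exchange rate 5.5/h, mean occupancy 4.7 persons), the
#' six-stage impactor bin grid with a 20 um top cap, bin-averaged deposition
#' coefficients from the cubic log-log model, per-bin infiltration factors,
#' true per-person emission profiles and outdoor concentrations for all three
#' analytes, per-bin indoor/outdoor taxa compositions whose pooled
#' skin-group fraction is ~17% indoors and ~4.9% outdoors, and tracer-release
#' parameters. Every default can be overridden through `config`; the result
#' is deterministic (the seed only matters for [simulate_observations()]).
#'
#' @param config Named list overriding any scenario field.
#' @param seed Integer seed stored in the scenario and used as the default
#'   for simulation.
#' @return Object of class `room_scenario`.
#' @export
generate_scenario <- function(config = list(), seed = 1L) {
  defaults <- list(
    room = room_params(volume_m3 = 90, aer_per_h = 5.5, occupancy = 4.7),
    bins = impactor_bins(),
    # f falls with size (poorer penetration/survival of coarse particles);
    # outdoor levels and per-person emissions are set so the across-bin
    # occupied/vacant indoor ratios come out near the observed study
    # conditions: ~15 for mass, ~170 for bacterial genomes, ~2.3 for fungi.
    f_true = c(0.50, 0.40, 0.30, 0.20, 0.10, 0.05),
    E_true = list(
      mass = c(40, 80, 200, 550, 1700, 9000),                    # ug/h/person
      bacterial_genomes = c(0.46, 1.9, 2.5, 15, 13.3, 1.7) * 1e6,
      fungal_equiv_genomes = c(3.5, 7, 17.5, 28, 14, 52.5) * 1e5),
    outdoor_true = list(
      mass = c(3, 2, 1.5, 1, 0.8, 0.5),                          # ug/m3
      bacterial_genomes = c(870, 720, 580, 430, 290, 140),
      fungal_equiv_genomes = c(2, 3, 5, 3, 2, 1) * 1e4),
    taxa_composition = default_taxa_composition(),
    aer_true = 5.5,
    tracer = list(background = 400, initial_excess = 1600,
                  duration_h = 0.5, n_samples = 20, n_releases = 6),
    qpcr = list(slope = -1 / log10(2),   # perfect-efficiency slope, -3.3219
                intercept = 37,
                aliquot_fraction = 0.25, flow_lpm = 28.3,
                duration_h = 22.2))
  unknown <- setdiff(names(config), c(names(defaults), "k"))
  if (length(unknown)) {
    stop("unknown scenario field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sc <- utils::modifyList(defaults, config)
  sc$bins <- as_size_bins(sc$bins)
  nb <- nrow(sc$bins)
  if (is.null(config$k)) {
    sc$k <- suppressMessages(deposition_loss_rates(sc$bins))
  } else if (!inherits(sc$k, "bin_loss_rates") ||
             !same_bins(sc$k, sc$bins)) {
    stop("k must be bin_loss_rates on the scenario's bin grid", call. = FALSE)
  }
  for (fld in c("f_true")) {
    if (length(sc[[fld]]) != nb) stop(fld, " must have one value per bin",
                                      call. = FALSE)
  }
  for (an in names(sc$E_true)) {
    if (length(sc$E_true[[an]]) != nb ||
        length(sc$outdoor_true[[an]]) != nb) {
      stop("E_true and outdoor_true must have one value per bin for ", an,
           call. = FALSE)
    }
    if (any(sc$E_true[[an]] < 0) || any(sc$outdoor_true[[an]] < 0)) {
      stop("true emissions and concentrations must be non-negative",
           call. = FALSE)
    }
  }
  comp <- sc$taxa_composition
  rs <- c(rowSums(comp$indoor), rowSums(comp$outdoor))
  if (any(abs(rs - 1) > 1e-9)) {
    stop("taxa composition rows must sum to 1", call. = FALSE)
  }
  sc$seed <- as.integer(seed)
  class(sc) <- "room_scenario"
  sc
}

true_indoor_occupied <- function(scenario, analyte) {
  f <- structure(data.frame(scenario$bins, f = scenario$f_true,
                            flag = "ok"),
                 class = c("infiltration_factors", "size_bins", "data.frame"))
  outdoor <- concentration_profile(scenario$bins,
                                   scenario$outdoor_true[[analyte]],
                                   analyte = analyte, location = "outdoor",
                                   state = "occupied")
  E <- emission_profile(scenario$bins, scenario$E_true[[analyte]],
                        analyte = analyte)
  steady_state_concentration(f, outdoor, E, scenario$room, scenario$k)
}

#' Simulate observed study tables from a scenario
#'
#' Draws one complete synthetic data set in the structure of the field
#' campaign: for each analyte the four concentration profiles
#' (indoor/outdoor x occupied/vacant, where occupied indoor truth is the
#' steady-state balance and vacant indoor truth is `f * outdoor`) under
#' multiplicative lognormal noise; per-bin multinomial taxa read counts for
#' indoor-occupied and outdoor-occupied air; a qPCR standard-curve dilution
#' series plus sample Ct triplicates consistent with the occupied indoor
#' bacterial concentrations; and replicate tracer-decay series. All draws are
#' reproducible from `seed`.
#'
#' @param scenario A [generate_scenario()] result.
#' @param noise A [noise_model()].
#' @param seed Integer; defaults to the scenario's seed.
#' @return List with elements `concentrations` (per analyte, the four
#'   profiles), `taxa` (indoor/outdoor [abundance_table()]s), `qpcr`
#'   (`standards` data frame, `samples` per-bin Ct triplicates), `tracer`
#'   (list of [tracer_series()]), and `scenario`.
#' @export
simulate_observations <- function(scenario, noise = noise_model(),
                                  seed = scenario$seed) {
  stopifnot(inherits(scenario, "room_scenario"),
            inherits(noise, "noise_model"))
  set.seed(seed)
  nb <- nrow(scenario$bins)
  cv <- noise$concentration_cv

  mk <- function(conc, analyte, location, state) {
    concentration_profile(scenario$bins, conc * rlnorm_cv(nb, cv),
                          analyte = analyte, location = location,
                          state = state)
  }
  concentrations <- lapply(stats::setNames(nm = names(scenario$E_true)),
                           function(an) {
    out_true <- scenario$outdoor_true[[an]]
    in_occ_true <- true_indoor_occupied(scenario, an)$conc
    list(indoor_occupied = mk(in_occ_true, an, "indoor", "occupied"),
         outdoor_occupied = mk(out_true, an, "outdoor", "occupied"),
         indoor_vacant = mk(scenario$f_true * out_true, an, "indoor",
                            "vacant"),
         outdoor_vacant = mk(out_true, an, "outdoor", "vacant"))
  })

  comp <- scenario$taxa_composition
  draw_counts <- function(p) {
    counts <- t(apply(p, 1, function(pr) {
      stats::rmultinom(1, size = noise$read_depth, prob = pr)[, 1]
    }))
    colnames(counts) <- comp$taxa
    abundance_table(scenario$bins, counts)
  }
  taxa <- list(indoor = draw_counts(comp$indoor),
               outdoor = draw_counts(comp$outdoor))

  qp <- scenario$qpcr
  curve_truth <- list(slope = qp$slope, intercept = qp$intercept)
  std_log10 <- rep(1:6, each = 3)
  standards <- data.frame(
    log10_copies = std_log10,
    ct = qp$slope * std_log10 + qp$intercept +
      stats::rnorm(length(std_log10), 0, noise$ct_sd))
  op <- operon_config("bacteria")
  volume_m3 <- qp$flow_lpm * qp$duration_h * 60 / 1000
  genomes_aliquot <- concentrations$bacterial_genomes$indoor_occupied$conc *
    volume_m3 * qp$aliquot_fraction
  equivalents <- genomes_aliquot * op$sample_operons / op$calibrant_operons
  ct_true <- qp$slope * log10(equivalents) + qp$intercept
  samples <- data.frame(
    bin = bin_labels(scenario$bins),
    ct1 = ct_true + stats::rnorm(nb, 0, noise$ct_sd),
    ct2 = ct_true + stats::rnorm(nb, 0, noise$ct_sd),
    ct3 = ct_true + stats::rnorm(nb, 0, noise$ct_sd))

  tr <- scenario$tracer
  t_h <- seq(0, tr$duration_h, length.out = tr$n_samples)
  tracer <- lapply(seq_len(tr$n_releases), function(i) {
    excess <- tr$initial_excess * exp(-scenario$aer_true * t_h) *
      rlnorm_cv(tr$n_samples, noise$tracer_cv)
    tracer_series(t_h, tr$background + excess, background = tr$background)
  })

  list(concentrations = concentrations, taxa = taxa,
       qpcr = list(standards = standards, samples = samples,
                   curve_truth = curve_truth),
       tracer = tracer, scenario = scenario)
}
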