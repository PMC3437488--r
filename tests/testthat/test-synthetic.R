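test_that("scenario generation is deterministic and uses study defaults", {
  a <- generate_scenario(seed = 5)
  b <- generate_scenario(seed = 5)
  expect_identical(a, b)
  expect_equal(a$room$volume_m3, 90)
  expect_equal(a$room$aer_per_h, 5.5)
  expect_equal(a$room$occupancy, 4.7)
  expect_equal(a$bins$d_lo_um, c(0.4, 1.1, 2.1, 3.3, 4.7, 9))
  expect_equal(a$bins$d_hi_um[6], 20)
  expect_equal(signif(a$k$k_per_h, 2), c(0.31, 0.79, 2.1, 4.4, 8.6, 9.6))
  # composition rows are probability vectors
  expect_equal(rowSums(a$taxa_composition$indoor), rep(1, 6))
  expect_equal(rowSums(a$taxa_composition$outdoor), rep(1, 6))
  expect_error(generate_scenario(list(bogus_field = 1)), "unknown")
})

test_that("default scenario embodies the observed occupied/vacant ratios", {
  # across-bin (total-burden) occupied/vacant indoor ratios of ~15 for
  # particulate mass, ~170 for bacterial genomes and ~2.3 for fungi
  sc <- generate_scenario(seed = 1)
  obs <- simulate_observations(sc, noise_model(0, 0, 60, 0))
  target <- c(mass = 15, bacterial_genomes = 170, fungal_equiv_genomes = 2.3)
  for (an in names(target)) {
    r <- occupied_vacant_ratio(obs$concentrations[[an]]$indoor_occupied,
                               obs$concentrations[[an]]$indoor_vacant)
    expect_equal(r$ratio_of_means, unname(target[an]), tolerance = 0.06)
  }
})

test_that("simulated draws are reproducible by seed", {
  sc <- generate_scenario(seed = 12)
  o1 <- simulate_observations(sc, noise_model(), seed = 12)
  o2 <- simulate_observations(sc, noise_model(), seed = 12)
  expect_identical(o1$concentrations, o2$concentrations)
  expect_identical(o1$taxa$indoor$counts, o2$taxa$indoor$counts)
  expect_identical(o1$qpcr, o2$qpcr)
  o3 <- simulate_observations(sc, noise_model(), seed = 13)
  expect_false(identical(o1$concentrations, o3$concentrations))
})

test_that("zero-emission scenario makes occupied indoor equal f x outdoor", {
  sc <- generate_scenario(list(E_true = list(
    mass = rep(0, 6), bacterial_genomes = rep(0, 6),
    fungal_equiv_genomes = rep(0, 6))), seed = 4)
  obs <- simulate_observations(sc, noise_model(0, 0, 60, 0))
  for (an in names(obs$concentrations)) {
    set <- obs$concentrations[[an]]
    expect_equal(set$indoor_occupied$conc,
                 sc$f_true * set$outdoor_occupied$conc, tolerance = 1e-12)
  }
})

test_that("noiseless simulation lets the pipeline recover truth exactly", {
  sc <- generate_scenario(seed = 31)
  obs <- simulate_observations(sc, noise_model(0, 0, 60, 0))
  res <- run_pipeline(obs$concentrations, sc$room, k = sc$k)
  for (an in names(res$emissions)) {
    expect_equal(res$emissions[[an]]$E, sc$E_true[[an]], tolerance = 1e-10)
    expect_equal(res$infiltration[[an]]$f, sc$f_true, tolerance = 1e-12)
  }
})

test_that("vacant-period infiltration estimates converge to f_true as CV -> 0", {
  sc <- generate_scenario(seed = 17)
  for (cv in c(0.05, 0.005)) {
    set.seed(17)
    errs <- replicate(50, {
      obs <- simulate_observations(sc, noise_model(cv, 0, 60, 0),
                                   seed = sample.int(1e6, 1))
      f <- infiltration_factors(
        obs$concentrations$mass$indoor_vacant,
        obs$concentrations$mass$outdoor_vacant)
      max(abs(f$f / sc$f_true - 1))
    })
    if (cv == 0.05) err_hi <- median(errs) else err_lo <- median(errs)
  }
  expect_lt(err_lo, err_hi / 5)
})

test_that("read depth 60 per bin recovers the pooled skin fraction", {
  sc <- generate_scenario(seed = 23)
  obs <- simulate_observations(sc, noise_model(read_depth = 60), seed = 23)
  ga <- group_abundance(obs$taxa$indoor, skin_taxa_group())
  p_true <- sum(sc$taxa_composition$indoor[, skin_taxa_group()$members]) / 6
  n <- 6 * 60
  sd3 <- 3 * sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(ga$overall_pooled - p_true), sd3)
})

test_that("simulated qPCR tables chain back to the simulated concentrations", {
  sc <- generate_scenario(seed = 41)
  obs <- simulate_observations(sc, noise_model(0.0, 0, 60, 0), seed = 41)
  curve <- fit_standard_curve(obs$qpcr$standards$log10_copies,
                              obs$qpcr$standards$ct)
  conc <- vapply(seq_len(6), function(i) {
    q <- quantify_genomes(as.numeric(obs$qpcr$samples[i, c("ct1", "ct2",
                                                           "ct3")]), curve)
    air_concentration(q$genomes, duration_h = sc$qpcr$duration_h,
                      aliquot_fraction = sc$qpcr$aliquot_fraction,
                      flow_lpm = sc$qpcr$flow_lpm)
  }, numeric(1))
  expect_equal(conc, obs$concentrations$bacterial_genomes$indoor_occupied$conc,
               tolerance = 1e-8)
})
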