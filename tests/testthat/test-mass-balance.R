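test_that("infiltration factors are per-bin vacant indoor/outdoor ratios", {
  f <- infiltration_factors(profile(c(0.5, 1.5, 3, 0.9, 0.2, 0.1),
                                    "indoor", "vacant"),
                            profile(c(1, 2, 4, 2, 1, 1),
                                    "outdoor", "vacant"))
  expect_equal(f$f, c(0.5, 0.75, 0.75, 0.45, 0.2, 0.1))
  # identical profiles give f = 1 everywhere
  p <- profile(1:6, "indoor", "vacant")
  q <- profile(1:6, "outdoor", "vacant")
  expect_equal(infiltration_factors(p, q)$f, rep(1, 6))
})

test_that("zero outdoor concentration flags the bin and keeps the rest", {
  expect_warning(
    f <- infiltration_factors(profile(c(1, 2, 3, 4, 5, 6), "indoor", "vacant"),
                              profile(c(2, 0, 3, 4, 5, 6), "outdoor",
                                      "vacant")),
    "undefined")
  expect_equal(f$flag, c("ok", "undefined", rep("ok", 4)))
  expect_true(is.na(f$f[2]))
  expect_equal(f$f[1], 0.5)
})

test_that("state and analyte contracts are enforced", {
  expect_error(infiltration_factors(profile(1:6), profile(1:6, "outdoor",
                                                          "vacant")),
               "vacant")
  expect_error(
    infiltration_factors(profile(1:6, "indoor", "vacant", "mass"),
                         profile(1:6, "outdoor", "vacant")),
    "analyte")
})

test_that("forward model reproduces the hand-computed classroom case", {
  # V = 90 m3, aer 5.5/h (Q = 495), N = 4.7, k = 4.4/h, f = 0.8,
  # C_out = 1000, E = 1e6: C = 800 + 4.7e6/891
  bins <- size_bins(3.3, 4.7)
  f <- make_f(0.8, bins)
  outdoor <- profile(1000, "outdoor", "occupied", bins = bins)
  E <- emission_profile(bins, 1e6)
  C <- steady_state_concentration(f, outdoor, E, classroom_room(),
                                  bin_loss_rates(bins, 4.4))
  expect_equal(C$conc, 800 + 4.7e6 / 891)
  # no-source limit
  C0 <- steady_state_concentration(f, outdoor, emission_profile(bins, 0),
                                   classroom_room(), bin_loss_rates(bins, 4.4))
  expect_equal(C0$conc, 800)
  # doubling occupancy doubles only the source term
  room2 <- room_params(90, 5.5, 9.4)
  C2 <- steady_state_concentration(f, outdoor, E, room2,
                                   bin_loss_rates(bins, 4.4))
  expect_equal(C2$conc - 800, 2 * (C$conc - 800))
})

test_that("inversion is the exact inverse of the forward model", {
  set.seed(42)
  room <- classroom_room()
  for (i in 1:50) {
    bins <- six_bins()
    f <- make_f(runif(6, 0.1, 1.2))
    outdoor <- profile(runif(6, 10, 1e5), "outdoor", "occupied")
    k <- bin_loss_rates(bins, runif(6, 0.1, 12))
    E_true <- runif(6, 0, 1e7)
    C <- steady_state_concentration(f, outdoor,
                                    emission_profile(bins, E_true), room, k)
    E_hat <- invert_emission(C, outdoor, f, room, k)
    expect_equal(E_hat$E, E_true, tolerance = 1e-12)
    expect_true(all(E_hat$flag == "ok"))
  }
})

test_that("inversion recovers the hand-computed emission rate", {
  bins <- size_bins(3.3, 4.7)
  f <- make_f(0.8, bins)
  outdoor <- profile(1000, "outdoor", "occupied", bins = bins)
  k <- bin_loss_rates(bins, 4.4)
  indoor <- profile(800 + 4.7e6 / 891, "indoor", "occupied", bins = bins)
  E <- invert_emission(indoor, outdoor, f, classroom_room(), k)
  expect_equal(E$E, 1e6)
  # C = f*C_out exactly gives E = 0
  E0 <- invert_emission(profile(800, "indoor", "occupied", bins = bins),
                        outdoor, f, classroom_room(), k)
  expect_equal(E0$E, 0)
})

test_that("negative indoor excess is clamped with the raw value retained", {
  bins <- size_bins(1, 10)
  f <- make_f(1, bins)
  E <- invert_emission(profile(1, "indoor", "occupied", bins = bins),
                       profile(10, "outdoor", "occupied", bins = bins),
                       f, classroom_room(), bin_loss_rates(bins, 1))
  expect_equal(E$E, 0)
  expect_equal(E$flag, "negative_clamped")
  expect_lt(attr(E, "raw"), 0)
})

test_that("zero occupancy is rejected as emissions are per person", {
  bins <- size_bins(1, 10)
  expect_error(
    invert_emission(profile(5, "indoor", "occupied", bins = bins),
                    profile(1, "outdoor", "occupied", bins = bins),
                    make_f(0.5, bins), room_params(90, 5.5, 0),
                    bin_loss_rates(bins, 1)),
    "per person")
})

test_that("E scales as 1/N and the source term as N", {
  bins <- six_bins()
  f <- make_f(rep(0.5, 6))
  outdoor <- profile(rep(100, 6), "outdoor", "occupied")
  indoor <- profile(rep(500, 6), "indoor", "occupied")
  k <- flat_loss_rates(2)
  E1 <- invert_emission(indoor, outdoor, f, room_params(90, 5.5, 2), k)
  E2 <- invert_emission(indoor, outdoor, f, room_params(90, 5.5, 4), k)
  expect_equal(E1$E, 2 * E2$E)
  # monotonicity in k and aer for a fixed excess
  E_hi_k <- invert_emission(indoor, outdoor, f, room_params(90, 5.5, 2),
                            flat_loss_rates(8))
  E_hi_a <- invert_emission(indoor, outdoor, f, room_params(90, 9, 2), k)
  expect_true(all(E_hi_k$E > E1$E))
  expect_true(all(E_hi_a$E > E1$E))
})

test_that("occupied/vacant ratios expose both averaging conventions", {
  b2 <- size_bins(c(1, 2), c(2, 4))
  occ <- concentration_profile(b2, c(10, 2), analyte = "mass",
                               location = "indoor", state = "occupied")
  vac <- concentration_profile(b2, c(1, 1), analyte = "mass",
                               location = "indoor", state = "vacant")
  r <- occupied_vacant_ratio(occ, vac)
  expect_equal(r$per_bin, c(10, 2), ignore_attr = TRUE)
  expect_equal(r$mean_of_ratios, 6)
  expect_equal(r$ratio_of_means, 6)
  # uniform scaling gives the same summary under either convention
  occ3 <- profile(3 * (1:6))
  vac3 <- profile(1:6, state = "vacant")
  r3 <- occupied_vacant_ratio(occ3, vac3)
  expect_equal(r3$mean_of_ratios, 3)
  expect_equal(r3$ratio_of_means, 3)
})
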