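two_bin_table <- function(counts, status = NULL) {
  abundance_table(size_bins(c(1, 2), c(2, 4)), counts, status)
}

test_that("relative abundances normalise per bin and respect status", {
  tab <- two_bin_table(cbind(A = c(3, 1), B = c(1, 9)))
  p <- relative_abundances(tab)
  expect_equal(p[1, ], c(A = 0.75, B = 0.25))
  expect_equal(rowSums(p), c(1, 1))
  # failed bin propagates NA, not proportions
  tabf <- two_bin_table(cbind(A = c(3, 0), B = c(1, 0)),
                        status = c("ok", "failed_pcr"))
  pf <- relative_abundances(tabf)
  expect_true(all(is.na(pf[2, ])))
  expect_equal(attr(pf, "status")[2], "failed_pcr")
})

test_that("table invariants reject bad counts", {
  expect_error(two_bin_table(cbind(A = c(-1, 2), B = c(1, 1))),
               "non-negative")
  expect_error(two_bin_table(cbind(A = c(0, 1), B = c(0, 1))), "zero total")
  expect_error(abundance_table(size_bins(1, 2), matrix(1, 1, 1)), "named")
})

test_that("multinomial sampling recovers composition within 3 binomial sd", {
  set.seed(8)
  p_true <- c(A = 0.17, B = 0.53, C = 0.30)
  depth <- 1e4
  counts <- t(stats::rmultinom(1, depth, p_true))
  tab <- abundance_table(size_bins(1, 2), counts)
  p_hat <- relative_abundances(tab)[1, ]
  sd3 <- 3 * sqrt(p_true * (1 - p_true) / depth)
  expect_true(all(abs(p_hat - p_true) < sd3))
})

test_that("group abundance pools reads across bins by default", {
  # member reads 3/10 and 1/10: pooled 4/20 = 0.2, mean of (0.3, 0.1) = 0.2
  # with uneven depth the conventions differ; exercise both
  tab <- two_bin_table(cbind(A = c(3, 1), B = c(7, 9)))
  g <- taxa_group("g", "A")
  ga <- group_abundance(tab, g)
  expect_equal(ga$per_bin, c(0.3, 0.1))
  expect_equal(ga$overall_pooled, 4 / 20)
  tab2 <- two_bin_table(cbind(A = c(30, 1), B = c(70, 9)))
  ga2 <- group_abundance(tab2, g)
  expect_equal(ga2$overall_pooled, 31 / 110)
  expect_equal(ga2$overall_mean, 0.2)
  expect_equal(group_abundance(tab2, g, pooled = FALSE)$overall, 0.2)
})

test_that("group covering all taxa has fraction 1; unmatched members warn", {
  tab <- two_bin_table(cbind(A = c(3, 1), B = c(7, 9)))
  all_g <- taxa_group("all", c("A", "B"))
  expect_equal(group_abundance(tab, all_g)$per_bin, c(1, 1))
  expect_warning(ga <- group_abundance(tab, taxa_group("x", "Zzz")),
                 "not in table")
  expect_equal(ga$per_bin, c(0, 0))
})

test_that("default human-microbiome groups follow the staph convention", {
  expect_true("Staphylococcus" %in% skin_taxa_group()$members)
  expect_false("Staphylococcus" %in% oral_taxa_group()$members)
  expect_true("Staphylococcus" %in% oral_taxa_group(staph = TRUE)$members)
  expect_false("Staphylococcus" %in% skin_taxa_group(staph = FALSE)$members)
})

test_that("apportionment multiplies totals by fractions and sums over data", {
  bins <- six_bins()
  E_tot <- emission_profile(bins, c(0.46, 1.9, 2.5, 15, 13.3, 1.7) * 1e6)
  frac <- c(0.13, 0.073, NA, 0.18, 0.15, 0.31)
  gp <- apportion_emissions(E_tot, frac)
  expect_equal(gp$E_group[4], 15e6 * 0.18)
  expect_true(is.na(gp$E_group[3]))
  expect_equal(gp$pct_of_total[6], 31)
  expect_equal(total_emission(gp), sum(gp$E_group, na.rm = TRUE))
  # implied total from a published-style row: E_group 2.7e6 at 18%
  expect_equal(2.7e6 / 0.18, 1.5e7)
  # zero fraction gives zero; out-of-range fractions are rejected
  expect_equal(apportion_emissions(E_tot, rep(0, 6))$E_group, rep(0, 6))
  expect_error(apportion_emissions(E_tot, rep(1.2, 6)), "\\[0, 1\\]")
})

test_that("apportionment commutes with scaling and respects partitions", {
  bins <- six_bins()
  set.seed(3)
  E_tot <- emission_profile(bins, runif(6, 1e5, 1e7))
  f1 <- runif(6, 0, 0.5); f2 <- runif(6, 0, 0.4)
  g1 <- apportion_emissions(E_tot, f1)
  E_scaled <- emission_profile(bins, 10 * E_tot$E)
  expect_equal(apportion_emissions(E_scaled, f1)$E_group, 10 * g1$E_group)
  # disjoint groups sum below the total; a full partition reaches it
  g2 <- apportion_emissions(E_tot, f2)
  expect_true(all(g1$E_group + g2$E_group <= E_tot$E + 1e-9))
  rest <- apportion_emissions(E_tot, 1 - f1 - f2)
  expect_equal(g1$E_group + g2$E_group + rest$E_group, E_tot$E)
})

test_that("enrichment factor is the indoor/outdoor fraction ratio", {
  expect_equal(signif(enrichment_factor(17, 4.9), 2), 3.5)
  expect_equal(enrichment_factor(0.25, 0.25), 1)
  expect_equal(enrichment_factor(0, 0.05), 0)
  und <- enrichment_factor(0.1, 0)
  expect_true(is.na(und))
  expect_equal(attr(und, "indoor_fraction"), 0.1)
})
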