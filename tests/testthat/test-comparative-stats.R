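test_that("dispersion is population variance over mean", {
  expect_identical(dispersion(c(0.2, 0.2, 0.2)), 0)
  expect_equal(dispersion(c(1, 2, 3)), (2 / 3) / 2)
  # scaling: dispersion(c x) = c dispersion(x)
  set.seed(8)
  for (i in 1:20) {
    x <- rlnorm(sample(3:20, 1))
    c0 <- runif(1, 0.1, 10)
    expect_equal(dispersion(c0 * x), c0 * dispersion(x), tolerance = 1e-12)
    # brute-force two-pass oracle
    m <- sum(x) / length(x)
    v <- sum((x - m)^2) / length(x)
    expect_equal(dispersion(x), v / m, tolerance = 1e-12)
  }
  expect_warning(d <- dispersion(c(-2, 1)), "non-positive")
  expect_true(is.na(d))
  expect_error(dispersion(0.5), "at least 2")
})

test_that("intracomplex dispersion applies the five-subunit rule", {
  membership <- data.frame(
    complex_id = rep(c("big", "tight", "small"), c(5, 5, 4)),
    protein_id = c(paste0("b", 1:5), paste0("t", 1:5), paste0("s", 1:4)))
  rates <- data.frame(
    protein_id = c(paste0("b", 1:5), paste0("t", 1:5), paste0("s", 1:4)),
    tissue = "liver",
    k = c(0.1, 0.1, 0.1, 0.1, 0.6, 0.19, 0.2, 0.2, 0.2, 0.21,
          0.3, 0.3, 0.3, 0.3))
  d <- intracomplex_dispersion(membership, rates)
  expect_setequal(d$complex_id, c("big", "tight")) # 4 subunits skipped
  expect_gt(d$d[d$complex_id == "big"], 10 * d$d[d$complex_id == "tight"])
  # identical rates give zero dispersion
  rates$k[1:5] <- 0.25
  d2 <- intracomplex_dispersion(membership, rates)
  expect_identical(d2$d[d2$complex_id == "big"], 0)
})

test_that("random null is seeded, reproducible, and variance-ordered", {
  proteome <- rlnorm(300, -1.5, 0.7)
  n1 <- random_complex_null(6, proteome, n_draws = 200, seed = 99)
  n2 <- random_complex_null(6, proteome, n_draws = 200, seed = 99)
  expect_identical(n1, n2)
  n3 <- random_complex_null(6, proteome, n_draws = 200, seed = 100)
  expect_false(identical(n1, n3))
  # higher-variance proteome yields a larger null median
  lo <- random_complex_null(5, rlnorm(300, -1.5, 0.2), 300, seed = 1)
  hi <- random_complex_null(5, rlnorm(300, -1.5, 1.2), 300, seed = 1)
  expect_gt(median(hi), median(lo))
  expect_error(random_complex_null(10, 1:5), "smaller")
})

test_that("coherence test separates tight complexes from chance", {
  null <- rlnorm(500, -2, 0.5)
  expect_lt(coherence_test(rep(0, 10), null), 0.001)
  # single observed complex: empirical percentile
  p_one <- coherence_test(min(null) / 2, null)
  expect_equal(p_one, 1 / 501, tolerance = 1e-9)
  expect_warning(p_tied <- coherence_test(rep(1, 5), rep(1, 5)), "tied")
  expect_identical(p_tied, 1)
})

test_that("the Welch rate comparison is symmetric and well-behaved", {
  same <- rate_difference_test(0.3, 0.05, 18, 0.3, 0.05, 18)
  expect_gt(same$p_value, 0.99)
  # 5-sigma separation
  k2 <- 0.3 + 5 * sqrt(0.05^2 + 0.05^2)
  far <- rate_difference_test(0.3, 0.05, 100, k2, 0.05, 100)
  expect_lt(far$p_value, 1e-4)
  ab <- rate_difference_test(0.21, 0.03, 18, 0.35, 0.05, 12)
  ba <- rate_difference_test(0.35, 0.05, 12, 0.21, 0.03, 18)
  expect_identical(ab$p_value, ba$p_value)
  expect_error(rate_difference_test(0.3, 0, 18, 0.2, 0.05, 18), "positive")
})

test_that("division-dominated fraction counts k_t at or below k_div", {
  expect_identical(division_dominated_fraction(rep(1, 50), 0.1), 0)
  expect_identical(division_dominated_fraction(c(0.5, 2, 3), 0), 0)
  # constructed 15% below threshold
  set.seed(12)
  k_div <- 0.231
  k_t <- c(runif(150, 0.01, k_div), runif(850, k_div * 1.001, 2))
  expect_equal(division_dominated_fraction(k_t, k_div), 0.15)
  # SE-aware tolerance widens the band
  k_t2 <- rep(k_div * 1.05, 100)
  se <- rep(k_div * 0.05, 100)
  expect_identical(division_dominated_fraction(k_t2, k_div), 0)
  expect_identical(
    division_dominated_fraction(k_t2, k_div, se = se, se_tolerance = 2), 1)
  expect_error(division_dominated_fraction(numeric(0), 0.1), "empty")
})

test_that("subset-versus-proteome comparison reports shift and direction", {
  set.seed(33)
  proteome <- rlnorm(400, -1.3, 0.6)
  shifted <- proteome[1:40] * 8
  res <- subset_vs_proteome_test(shifted, c(shifted, proteome[-(1:40)]))
  expect_lt(res$p_value, 1e-4)
  expect_identical(res$direction, "higher")
  expect_warning(skip <- subset_vs_proteome_test(proteome[1:4], proteome),
                 "smaller than 5")
  expect_true(is.na(skip$p_value))
  expect_error(subset_vs_proteome_test(proteome, proteome), "strictly")
})

test_that("complex median decile is tested against the proteome middle", {
  mid <- complex_median_decile(rep(c(5, 6), 5))
  expect_identical(mid$median_decile, 5.5)
  expect_gt(mid$p_value, 0.9)
  slow <- complex_median_decile(rep(1, 10))
  expect_identical(slow$median_decile, 1)
  expect_lt(slow$p_value, 1e-4)
  expect_identical(complex_median_decile(c(1, 2, 9, 10, 5))$median_decile, 5)
  expect_warning(sk <- complex_median_decile(c(1, 2, 3)), "skipped")
  expect_true(is.na(sk$median_decile))
})

test_that("cross-tissue dispersion table handles shared proteins", {
  rates <- data.frame(
    protein_id = rep(c("a", "b", "c"), each = 3),
    tissue = rep(c("liver", "fat", "heart"), 3),
    k = c(0.2, 0.2, 0.2, 0.1, 0.2, 0.3, 0.5, NA, 0.7))
  D <- cross_tissue_dispersion(rates)
  expect_identical(D$D[D$protein_id == "a"], 0)
  expect_equal(D$D[D$protein_id == "b"], dispersion(c(0.1, 0.2, 0.3)))
  expect_identical(D$n_tissues[D$protein_id == "c"], 2L)
})
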