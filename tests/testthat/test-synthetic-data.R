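test_that("generators are byte-reproducible for a fixed seed", {
  cfg <- sim_config(n_proteins = 30, seed = 5)
  s1 <- simulate_proteome_timecourse(cfg)
  s2 <- simulate_proteome_timecourse(cfg)
  expect_identical(s1, s2)

  dcfg <- dna_sim_config(k_div = 0.1, seed = 5)
  expect_identical(simulate_dna_labeling(dcfg), simulate_dna_labeling(dcfg))

  m1 <- simulate_multi_tissue(tissue_profiles(), n_proteins = 100, seed = 4)
  m2 <- simulate_multi_tissue(tissue_profiles(), n_proteins = 100, seed = 4)
  expect_identical(m1, m2)
  expect_error(sim_config(n_proteins = 10), "seed")
})

test_that("truth manifests score every downstream estimate", {
  cfg <- sim_config(n_proteins = 25, seed = 6, k_div = 0.05)
  sim <- simulate_proteome_timecourse(cfg)
  expect_setequal(names(sim$truth),
                  c("protein_id", "k_deg", "k_div", "k_t", "baseline",
                    "division_dominated"))
  expect_identical(nrow(sim$truth), 25L)
  expect_equal(sim$truth$k_t, sim$truth$k_deg + sim$truth$k_div)

  dcfg <- dna_sim_config(k_div = 0.2, seed = 6)
  dsim <- simulate_dna_labeling(dcfg)
  expect_equal(dsim$truth$f_new, 1 - exp(-0.2 * dsim$truth$timepoint_days))
})

test_that("DNA spectra limits behave as the forward model dictates", {
  dcfg <- dna_sim_config(k_div = 0.3, noise_sigma = 0, n_replicates = 1,
                         seed = 9)
  sim <- simulate_dna_labeling(dcfg)
  # t = 0: natural-abundance-convolved delta at m = 0
  t0 <- sim$spectra[sim$spectra$timepoint_days == 0 &
                      sim$spectra$base == "dA", ]
  mono0 <- t0$intensity[t0$unit == "mono"][order(t0$m_shift[t0$unit ==
                                                              "mono"])]
  expect_equal(natural_abundance_correct(mono0, dcfg$a15N),
               c(1, 0, 0, 0, 0, 0), tolerance = 1e-9)

  # t -> infinity with r = 0: mono spectrum equals p_lab
  dcfg2 <- dna_sim_config(k_div = 5, r = 0, noise_sigma = 0,
                          n_replicates = 1, timepoints = c(0, 2, 4, 1000),
                          seed = 9)
  sim2 <- simulate_dna_labeling(dcfg2)
  late <- sim2$spectra[sim2$spectra$timepoint_days == 1000 &
                         sim2$spectra$base == "dT" &
                         sim2$spectra$unit == "mono", ]
  mono_inf <- natural_abundance_correct(
    late$intensity[order(late$m_shift)], dcfg2$a15N)
  ria <- dcfg2$ria_asym * (1 - exp(-1000 / dcfg2$ria_tau))
  p_lab <- dbinom(1:2, 2, ria)
  p_lab <- p_lab / sum(p_lab)
  expect_equal(mono_inf, c(0, p_lab), tolerance = 1e-6)
})

test_that("tissue profiles hit the targeted median observed half-life", {
  prof <- tissue_profiles()
  expect_identical(prof$tissue, c("intestine", "liver", "fat", "heart"))
  expect_equal(log(2) / prof$k_div, prof$doubling_days)
  # large-sample median of simulated k_t matches the profile target
  for (i in seq_len(nrow(prof))) {
    cfg <- sim_config(n_proteins = 20000,
                      k_deg_meanlog = prof$k_deg_meanlog[i],
                      k_deg_sdlog = prof$k_deg_sdlog[i],
                      k_div = prof$k_div[i],
                      dilution_fraction = prof$dilution_fraction[i],
                      seed = 100 + i)
    sim <- simulate_proteome_timecourse(cfg)
    med_t_half <- median(log(2) / sim$truth$k_t)
    expect_equal(med_t_half, prof$median_t_half[i], tolerance = 0.05)
  }
})

test_that("multi-tissue simulation controls dispersion structure", {
  prof <- tissue_profiles()
  # identical tissue distributions and zero spread: D = 0 everywhere
  flat <- prof
  flat$k_deg_meanlog <- flat$k_deg_meanlog[2]
  flat$k_deg_sdlog <- 0.8
  sim0 <- simulate_multi_tissue(flat, n_proteins = 80,
                                cross_tissue_spread = 0, n_complexes = 0,
                                subunits_per_complex = 0, seed = 21)
  D <- cross_tissue_dispersion(
    data.frame(protein_id = sim0$rates$protein_id,
               tissue = sim0$rates$tissue, k = sim0$rates$k_deg))
  expect_true(all(D$D < 1e-12))
  expect_true(all(sim0$truth$D < 1e-12))

  # coherent complexes sit well below the random null
  sim <- simulate_multi_tissue(prof, n_proteins = 400,
                               cross_tissue_spread = 0.25, n_complexes = 12,
                               subunits_per_complex = 6,
                               within_complex_spread = 0.05, seed = 22)
  rates_l <- sim$rates[sim$rates$tissue == "liver", ]
  d <- intracomplex_dispersion(
    sim$complexes, data.frame(protein_id = rates_l$protein_id,
                              tissue = rates_l$tissue, k = rates_l$k_deg))
  null <- random_complex_null(6, rates_l$k_deg, n_draws = 500, seed = 23)
  expect_lt(coherence_test(d$d, null), 0.05)
})
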