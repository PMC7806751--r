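test_that("simulator configuration is validated", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(sex_ratio = 1.5))
  expect_error(sim_config(plates_range = c(5, 2)))
  expect_error(sim_config(bin_edges = c(0, 21, 100)), "starting at 1")
  expect_error(sim_config(availability = list(nope = c(0, 1))))
})

test_that("host simulation is seed-reproducible and hits its configured means", {
  cfg <- sim_config(n_hosts = 0)
  expect_equal(nrow(simulate_hosts(cfg, 1)), 0)

  cfg1 <- sim_config(n_hosts = 12)
  h1 <- simulate_hosts(cfg1, 99)
  h2 <- simulate_hosts(cfg1, 99)
  expect_identical(h1, h2)
  expect_true(all(h1$curvilinear_length_cm > 0 & h1$umbilicus_girth_cm > 0))

  # zero-variance cohort collapses to the configured female means
  cfg0 <- sim_config(n_hosts = 5, sex_ratio = 1, length_sd = 0, girth_sd = 0,
                     length_girth_cor = 0)
  h0 <- simulate_hosts(cfg0, 3)
  expect_equal(h0$curvilinear_length_cm, rep(262, 5))
  expect_equal(h0$umbilicus_girth_cm, rep(217, 5))
  expect_equal(h0$tail_length_cm, rep(64, 5))

  # law of large numbers: n = 1000 females, sample mean within 3 SE
  cfgN <- sim_config(n_hosts = 1000, sex_ratio = 1)
  hN <- simulate_hosts(cfgN, 7)
  se <- cfgN$length_sd / sqrt(1000)
  expect_lt(abs(mean(hN$curvilinear_length_cm) - 262), 3 * se)
})

test_that("sample simulation is deterministic, conserves binning, and respects availability", {
  cfg <- sim_config(n_hosts = 4, n_passes = 3,
                    availability = depth_profile("C_manati"))
  sv1 <- simulate_survey(cfg, 42)
  sv2 <- simulate_survey(cfg, 42)
  expect_identical(sv1$samples, sv2$samples)
  s <- sv1$samples
  expect_s3_class(s, "scrape_survey")
  expect_true(all(s$level %in% 0:3))
  expect_true(all(s$area_cm2 == 25))
  # forced absence: availability 0 at pass 1 -> level 0 on every pass-1 plate
  expect_true(all(s$level[s$species == "C_manati" & s$pass_index == 1] == 0))
  # deeper passes can carry the species
  expect_true(any(s$level[s$species == "C_manati" & s$pass_index > 1] > 0))
})

test_that("saturating latent means produce the top category", {
  cfg <- sim_config(n_hosts = 3, density_meanlog = log(c(200, 200, 200)),
                    density_sdlog = 0, dispersion = Inf)
  s <- simulate_survey(cfg, 8)$samples
  # Poisson(5000) mass below 100 is negligible
  expect_true(all(s$level == 3))
})

test_that("counts of zero always map to level 0 and bins partition the counts", {
  expect_equal(count_to_category(0L), 0L)
  counts <- c(0:25, 95:105, 1000)
  lev <- count_to_category(counts)
  expect_true(all(lev %in% 0:3))
  expect_equal(lev[counts == 0], 0L)
  expect_true(all(lev[counts >= 1 & counts <= 20] == 1L))
  expect_true(all(lev[counts >= 21 & counts <= 99] == 2L))
  expect_true(all(lev[counts >= 100] == 3L))
})

test_that("juvenile attenuation lowers estimated density under the same seed stream", {
  cfg_ad <- sim_config(n_hosts = 6, juvenile_fraction = 0)
  cfg_juv <- sim_config(n_hosts = 6, juvenile_fraction = 1,
                        juvenile_attenuation = 0.05)
  d_ad <- population_mean_density(simulate_survey(cfg_ad, 12)$samples,
                                  rule = "all")$densities
  d_juv <- population_mean_density(simulate_survey(cfg_juv, 12)$samples,
                                   rule = "all")$densities
  expect_true(all(d_juv <= d_ad))
  expect_lt(sum(d_juv), sum(d_ad))
})

test_that("depth-stratified simulation hides the biofilm-avoider from first-pass data", {
  cfg <- sim_config(n_hosts = 7, n_passes = 4,
                    availability = depth_profile("C_manati"))
  s <- simulate_survey(cfg, 21)$samples
  first <- prevalence_summary(s[s$pass_index == 1, ])
  all_p <- prevalence_summary(s)
  expect_equal(sum(first$presence[, "C_manati"]), 0)
  expect_gt(sum(all_p$presence[, "C_manati"]), 0)
})

test_that("the estimator's numerical expectation is exact in closed-form corners", {
  # every plate saturated at the top level: expectation is c3 / area
  cfg <- sim_config(density_meanlog = log(c(500, 500, 500)),
                    density_sdlog = 0, dispersion = Inf)
  e <- expected_mapped_density(cfg)
  expect_equal(unname(e), rep(100 / 25, 3), tolerance = 1e-10)
  # availability 0 collapses the expectation to the zero count
  cfg0 <- sim_config(availability = list(C_manati = c(0)),
                     density_sdlog = 0)
  expect_equal(expected_mapped_density(cfg0)[["C_manati"]], 0)
})

test_that("recovery experiment reports bias against the numerical expectation", {
  cfg <- sim_config(n_hosts = 5, plates_range = c(3, 5))
  rec <- recovery_experiment(cfg, seed = 31, n_reps = 20)
  expect_s3_class(rec, "recovery_experiment")
  expect_equal(dim(rec$estimates), c(20, 3))
  per <- rec$per_species
  expect_equal(per$bias, per$mean_estimate - per$expected)
  expect_true(all(per$expected > 0))
  # deterministic saturated config recovers exactly c3/area with zero spread
  cfg_sat <- sim_config(n_hosts = 3, density_meanlog = log(c(500, 500, 500)),
                        density_sdlog = 0, dispersion = Inf)
  rec_sat <- recovery_experiment(cfg_sat, seed = 5, n_reps = 3)
  expect_equal(rec_sat$per_species$mean_estimate, rep(4, 3))
  expect_equal(rec_sat$per_species$sd_estimate, rep(0, 3))
})
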