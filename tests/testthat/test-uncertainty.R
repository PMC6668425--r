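test_that("parameter draws are reproducible and respect their bounds", {
  cfg <- mc_config(n_ensemble = 5000, seed = 42)
  d1 <- sample_parameters(cfg)
  d2 <- sample_parameters(cfg)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 5000)
  for (col in c("f_de_concentrates", "f_de_grass", "f_de_so")) {
    expect_true(all(d1[[col]] > 0.3 & d1[[col]] < 0.9))
  }
  expect_true(all(d1$y_m > 0))
})

test_that("draw dispersion matches the configured uncertainties", {
  cfg <- mc_config(n_ensemble = 10000, seed = 7,
                   regression = fit_diet_ch4_regression(
                     ruminant_diet_observations(), seed = 1))
  d <- sample_parameters(cfg)
  en <- energy_params()
  # ~95% of grass digestibility draws inside the 95% CI used to set the sd
  inside <- mean(abs(d$f_de_grass - en$f_de_grass) <=
                   1.96 * en$sd_f_de_grass)
  expect_gt(inside, 0.93)
  expect_lt(inside, 0.97)
  expect_equal(mean(d$y_m), 0.065, tolerance = 1e-3)
  # regression coefficients carry the fit covariance
  expect_equal(stats::sd(d$slope), cfg$regression$cov["slope", "slope"]^0.5,
               tolerance = 0.05)
})

test_that("an all-zero-uncertainty config collapses to the central pipeline", {
  cfg0 <- mc_config(
    n_ensemble = 10, seed = 3,
    energy = energy_params(sd_f_de_concentrates = 0, sd_f_de_grass = 0,
                           sd_f_de_so = 0),
    emission = emission_params(sd_y_m = 0),
    isotope = isotope_params(sd_c3_concentrates = 0, sd_c3_grass_other = 0,
                             sd_c4_concentrates = 0, sd_c4_grass_other = 0))
  draws <- sample_parameters(cfg0)
  expect_true(all(vapply(draws, function(x) all(x == x[1]), logical(1))))
  expect_equal(draws$slope[1], 0.91)

  world <- generate_livestock_world(
    synthetic_world_config(n_countries = 3, years = 1970:1974, seed = 21))
  ens <- run_ensemble(world$ground_truth, draws, world$co2_series)
  s <- ens$summary
  expect_equal(s$sd, rep(0, nrow(s)), tolerance = 1e-12)
  expect_equal(s$lo, s$mean, tolerance = 1e-12)
  expect_equal(s$hi, s$mean, tolerance = 1e-12)
  # the collapsed ensemble equals the deterministic ground truth
  gt <- world$ground_truth
  f_true <- as.numeric(rowsum(gt$f_ch4, gt$year))
  expect_equal(s$mean[s$variable == "f_ch4"], f_true, tolerance = 1e-12)
  q_so_true <- as.numeric(rowsum(gt$q_so, gt$year))
  expect_equal(s$mean[s$variable == "q_so"], q_so_true, tolerance = 1e-9)
  # flux-weighted signature equals the manual computation
  want <- as.numeric(rowsum((0.91 * gt$d13c_diet - 43.49) * gt$f_ch4,
                            gt$year)) / f_true
  expect_equal(s$mean[s$variable == "d13c_ch4"], want, tolerance = 1e-12)
})

test_that("ensemble summaries are ordered and seed-reproducible", {
  world <- generate_livestock_world(
    synthetic_world_config(n_countries = 2, years = 1980:1983, seed = 5))
  cfg <- mc_config(n_ensemble = 300, seed = 14)
  e1 <- run_ensemble(world$ground_truth, sample_parameters(cfg),
                     world$co2_series)
  e2 <- run_ensemble(world$ground_truth, sample_parameters(cfg),
                     world$co2_series)
  expect_identical(e1$summary, e2$summary)
  expect_true(all(e1$summary$lo <= e1$summary$mean + 1e-12))
  expect_true(all(e1$summary$mean <= e1$summary$hi + 1e-12))
  expect_equal(e1$n_failed, 0)
})

test_that("inflating a parameter uncertainty widens the intervals", {
  world <- generate_livestock_world(
    synthetic_world_config(n_countries = 2, years = 1980:1983, seed = 5))
  base <- mc_config(n_ensemble = 800, seed = 9)
  wide <- mc_config(n_ensemble = 800, seed = 9,
                    emission = emission_params(sd_y_m = 2 * 0.01 / 1.96))
  e_base <- run_ensemble(world$ground_truth, sample_parameters(base),
                         world$co2_series)
  e_wide <- run_ensemble(world$ground_truth, sample_parameters(wide),
                         world$co2_series)
  w_base <- with(subset(e_base$summary, variable == "f_ch4"), hi - lo)
  w_wide <- with(subset(e_wide$summary, variable == "f_ch4"), hi - lo)
  expect_true(all(w_wide > w_base))
})

test_that("run_ensemble validates its world table", {
  world <- generate_livestock_world(
    synthetic_world_config(n_countries = 2, years = 1980:1981, seed = 5))
  bad <- world$ground_truth[, setdiff(names(world$ground_truth), "me")]
  expect_error(run_ensemble(bad, sample_parameters(mc_config(10)),
                            world$co2_series))
  expect_error(mc_config(n_ensemble = 1), ">= 2")
  expect_error(mc_config(regression = list(mean = c(slope = 1))),
               "regression")
})
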