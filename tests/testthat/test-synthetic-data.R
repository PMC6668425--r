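test_that("the synthetic world is deterministic under its seed", {
  cfg <- synthetic_world_config(n_countries = 3, years = 1990:1995, seed = 11)
  w1 <- generate_livestock_world(cfg)
  w2 <- generate_livestock_world(cfg)
  expect_identical(w1$ground_truth, w2$ground_truth)
  expect_identical(w1$supply, w2$supply)
  w3 <- generate_livestock_world(
    synthetic_world_config(n_countries = 3, years = 1990:1995, seed = 12))
  expect_false(identical(w1$ground_truth$f_ch4, w3$ground_truth$f_ch4))
})

test_that("the synthetic world has the advertised shape and positivity", {
  cfg <- synthetic_world_config(n_countries = 4, years = 1975:1980, seed = 2)
  w <- generate_livestock_world(cfg)
  n_cy <- 4 * 6
  expect_equal(nrow(w$ground_truth), n_cy)
  expect_equal(nrow(w$supply), n_cy * 7)          # seven commodity groups
  expect_equal(nrow(w$production), n_cy * 4)      # four species
  gt <- w$ground_truth
  expect_true(all(w$supply$supply > 0))
  expect_true(all(gt$me > 0 & gt$f_ch4 > 0 & gt$q_so > 0))
  expect_true(all(gt$c4_grass_fraction >= 0 & gt$c4_grass_fraction <= 1))
  # the ground-truth diet signature lies in the physical range
  expect_true(all(gt$d13c_diet > -30 & gt$d13c_diet < -12))
})

test_that("the ground truth closes the energy balance by construction", {
  w <- generate_livestock_world(
    synthetic_world_config(n_countries = 3, years = 2000:2004, seed = 8))
  gt <- w$ground_truth
  ep <- w$config$energy
  me <- gt$q_concentrates * ep$e_ge_feed * ep$f_de_concentrates *
    rem(ep$f_de_concentrates) +
    gt$q_grass * ep$e_ge_feed * ep$f_de_grass * rem(ep$f_de_grass) +
    gt$q_so * ep$e_ge_feed * ep$f_de_so * rem(ep$f_de_so)
  expect_equal(me, gt$me, tolerance = 1e-12)
})

test_that("the delta13C-CO2 series hits its anchors and declines", {
  s <- generate_co2_isotope_series()
  expect_equal(s$d13c_co2[s$year == 1960], -6.9)
  expect_equal(s$d13c_co2[s$year == 2012], -6.9 - 1.3)
  expect_true(all(diff(s$d13c_co2) < 0))
  flat <- generate_co2_isotope_series(decline = 0)
  expect_true(all(flat$d13c_co2 == -6.9))
  expect_error(generate_co2_isotope_series(years = 1990:2012), "1960-2012")
})

test_that("regression observations sit on the requested line", {
  obs <- generate_regression_observations(n_obs = 30, slope = 0.8,
                                          intercept = -40, sd_noise = 0,
                                          seed = 6)
  expect_equal(obs$d13c_ch4, 0.8 * obs$d13c_diet - 40, tolerance = 1e-12)
  expect_true(all(obs$d13c_diet >= -30 & obs$d13c_diet <= -12))
  # reproducible under the seed
  obs2 <- generate_regression_observations(n_obs = 30, slope = 0.8,
                                           intercept = -40, sd_noise = 0,
                                           seed = 6)
  expect_identical(obs, obs2)
  expect_error(generate_regression_observations(n_obs = 2), "n_obs")
  expect_error(generate_regression_observations(sd_noise = -1), "sd_noise")
})

test_that("source signatures cover fourteen components, all 13C-depleted", {
  sig <- default_source_signatures()
  expect_equal(nrow(sig), 14)
  expect_equal(sum(sig$natural), 5)
  expect_true(all(sig$d13c < 0))
  expect_true("enteric" %in% sig$component)
})

test_that("steady atmosphere inputs give a flat record at S / lambda", {
  atm <- generate_atmosphere_inputs(seed = 4, steady = TRUE)
  totals <- inventory_totals(atm$inventory)
  expect_true(all(totals$s_total == totals$s_total[1]))
  want_ppb <- totals$s_total[1] / atm$lambda_true / 2.767
  expect_equal(atm$record$ppb, rep(want_ppb, nrow(atm$record)),
               tolerance = 1e-9)
})

test_that("growing anthropogenic sources give a rising record", {
  atm <- generate_atmosphere_inputs(seed = 4)
  # sources start growing in 1851, so the burden rises from 1851 onwards
  post <- atm$record$ppb[atm$record$year >= 1851]
  expect_true(all(diff(post) > 0))
  # natural components are constant through time
  wet <- atm$inventory$flux[atm$inventory$component == "wetlands"]
  expect_true(all(wet == wet[1]))
})

test_that("the source inventory interpolates, splits and validates", {
  anchors <- tibble::tribble(~component, ~flux,
                             "wetlands", 100,
                             "fossil_fuel", 2,
                             "grass_burning", 10)
  decadal <- tibble::tribble(~year, ~component, ~flux,
                             1850, "fossil_fuel", 2,
                             1860, "fossil_fuel", 4,
                             1850, "agriculture", 30,
                             1850, "grass_burning", 10,
                             1960, "grass_burning", 20)
  annual <- tibble::tibble(
    year = rep(1970:1972, times = 4),
    component = rep(c("fossil_fuel", "rice", "enteric", "manure"), each = 3),
    flux = c(10, 11, 12, 3, 3, 3, 6, 6, 6, 1, 1, 1))
  signatures <- tibble::tribble(~component, ~d13c,
                                "wetlands", -59, "fossil_fuel", -44,
                                "rice", -62, "enteric", -62, "manure", -55,
                                "c3_grass_burning", -27,
                                "c4_savanna_burning", -12)
  inv <- build_source_inventory(anchors, decadal, annual, signatures,
                                natural = "wetlands",
                                c4_burn_fraction = 0.4)
  at <- function(comp, yr) inv$flux[inv$component == comp & inv$year == yr]
  # natural component constant at the 1700 anchor
  expect_equal(at("wetlands", 1775), 100)
  expect_equal(at("wetlands", 1972), 100)
  # linear interpolation between knots
  expect_equal(at("fossil_fuel", 1775), 2)
  expect_equal(at("fossil_fuel", 1855), 3)
  expect_equal(at("fossil_fuel", 1915), 7)     # midway between 4 and 10
  # agriculture split by the 1970 shares 0.3 / 0.6 / 0.1
  expect_equal(at("enteric", 1850), 18)
  expect_equal(at("rice", 1850), 9)
  expect_equal(at("manure", 1850), 3)
  # grass burning split into C3 (0.6) and C4 (0.4)
  expect_equal(at("c3_grass_burning", 1700), 6)
  expect_equal(at("c4_savanna_burning", 1850), 4)
  expect_equal(at("c4_savanna_burning", 1905), 6) # between 4 and 8
  # every year x component combination is present
  expect_equal(nrow(inv), 7 * length(1700:1972))
  # missing signatures are rejected
  expect_error(
    build_source_inventory(anchors, decadal, annual, signatures[-4, ],
                           natural = "wetlands"),
    "missing delta13C signature")
})
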