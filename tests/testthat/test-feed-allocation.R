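test_that("fcr_at reproduces the schedule anchors", {
  expect_equal(fcr_at("poultry", 2005, "developed"), 1.95)
  expect_equal(fcr_at("egg", 2005, "developed"), 1.95)
  expect_equal(fcr_at("pig", 1995, "developed"), 3.28)
})

test_that("fcr_at applies the time trend and developing multiplier", {
  # poultry improves at 0.01 / yr from the 2005 anchor
  expect_equal(fcr_at("poultry", 2012, "developed"), 1.95 - 0.01 * 7)
  expect_equal(fcr_at("poultry", 1961, "developed"), 1.95 + 0.01 * 44)
  # developing countries carry a 1.2x multiplier
  expect_equal(fcr_at("poultry", 2005, "developing"), 1.95 * 1.2)
  expect_equal(fcr_at("pig", 1995, "developing"), 3.28 * 1.2)
  # vectorised over year and status
  out <- fcr_at("pig", c(1990, 1995, 2000), "developed")
  expect_equal(out, 3.28 + 0.015 * c(5, 0, -5))
})

test_that("fcr_at floors extrapolation and validates inputs", {
  steep <- fcr_schedule(poultry = list(base = 1.95, anchor = 1961,
                                       rate = -0.1))
  # 1.95 - 0.1 * 51 would be negative; floored at half the anchor value
  expect_equal(fcr_at("poultry", 2012, "developed", steep), 0.5 * 1.95)
  expect_error(fcr_at("poultry", 1950, "developed"), "1961-2012")
  expect_error(fcr_at("horse", 2000, "developed"), "unknown species")
  expect_error(fcr_at("pig", 2000, "rich"), "status")
})

test_that("farming intensity is the anchor for developed countries", {
  expect_equal(farming_intensity_at(c(1961, 1980, 2012), 0.85, "developed"),
               rep(0.85, 3))
})

test_that("developing-country intensity follows a calibrated logistic", {
  yrs <- 1961:2012
  f <- farming_intensity_at(yrs, 0.6, "developing")
  # passes through the year-2000 anchor
  expect_equal(f[yrs == 2000], 0.6, tolerance = 1e-8)
  # calibrated so f(1961) = 0.4 x anchor
  expect_equal(f[yrs == 1961], 0.4 * 0.6, tolerance = 1e-6)
  # monotone non-decreasing and capped
  expect_true(all(diff(f) >= 0))
  expect_true(all(f <= 0.95))
  # a zero anchor yields zero intensity everywhere
  expect_equal(farming_intensity_at(yrs, 0, "developing"), rep(0, length(yrs)))
  expect_error(farming_intensity_at(2000, 1.2, "developing"), "anchor")
})

test_that("live weights apply the dressing percentages", {
  prod <- tibble::tibble(
    country = "A", year = 2000,
    species = c("chickens", "pig", "laying_hens"),
    n = c(1000, 100, 10),
    yield = c(1.4, 60, 12)
  )
  w <- live_weight_totals(prod)
  expect_equal(w$weight_poultry_meat, 1000 * 1.4 / 0.70)
  expect_equal(w$weight_pig, 100 * 60 / 0.60)
  # eggs need no dressing conversion
  expect_equal(w$weight_egg, 10 * 12)
})

test_that("live weights sum poultry species and tolerate absences", {
  prod <- tibble::tibble(
    country = "A", year = 2000,
    species = c("chickens", "ducks", "turkeys"),
    n = c(100, 50, 10), yield = 2
  )
  w <- live_weight_totals(prod)
  expect_equal(w$weight_poultry_meat, 160 * 2 / 0.70)
  expect_equal(w$weight_egg, 0)
  expect_equal(w$weight_pig, 0)
  prod$n[1] <- -1
  expect_error(live_weight_totals(prod), "non-negative")
})

test_that("feed requirement is weight x FCR x intensity", {
  expect_equal(feed_requirement(100, 2, 0.5), 100)
  expect_equal(feed_requirement(100, 2, 0), 0)
  # linear in each argument
  expect_equal(feed_requirement(200, 2, 0.5), 2 * feed_requirement(100, 2, 0.5))
  expect_error(feed_requirement(-1, 2, 0.5), "non-negative")
})

test_that("allocation conserves supply and serves priorities in order", {
  supply <- flat_supply(1000)
  req <- simple_requirements(q_poultry = 500, q_eggs = 250, q_pig = 400)
  out <- allocate_concentrates(supply, req)
  # exact conservation in every commodity group
  total <- out$alloc_poultry_meat + out$alloc_eggs + out$alloc_pig +
    out$residual_ruminant
  expect_equal(total, out$supply, tolerance = 1e-12)
  expect_false(any(out$shortfall))
  # no demand is cut when supply is ample: allocations equal demands
  maize <- out[out$group == "maize", ]
  expect_equal(maize$alloc_poultry_meat, 500 * 0.40)
  expect_equal(maize$alloc_eggs, 250 * 0.40)
  expect_equal(maize$alloc_pig, 400 * 0.30)
  # groups no monogastric draws on go entirely to ruminants
  oil <- out[out$group == "oilseeds", ]
  expect_equal(oil$residual_ruminant, 1000)
})

test_that("zero monogastric demand leaves the whole supply to ruminants", {
  out <- allocate_concentrates(flat_supply(700), simple_requirements())
  expect_equal(out$residual_ruminant, rep(700, 7))
  expect_false(any(out$shortfall))
})

test_that("shortfall is served pro-rata within a stage and flagged", {
  supply <- flat_supply(10)
  # maize demand: poultry 30 * .4 = 12, eggs 15 * .4 = 6; 18 > 10
  req <- simple_requirements(q_poultry = 30, q_eggs = 15, q_pig = 50)
  out <- allocate_concentrates(supply, req)
  maize <- out[out$group == "maize", ]
  expect_equal(maize$alloc_poultry_meat, 10 * 12 / 18)
  expect_equal(maize$alloc_eggs, 10 * 6 / 18)
  # nothing left for pigs or ruminants
  expect_equal(maize$alloc_pig, 0)
  expect_equal(maize$residual_ruminant, 0)
  expect_true(maize$shortfall)
  # conservation holds under shortfall too
  total <- out$alloc_poultry_meat + out$alloc_eggs + out$alloc_pig +
    out$residual_ruminant
  expect_equal(total, out$supply, tolerance = 1e-12)
})

test_that("higher monogastric demand never increases the ruminant residual", {
  supply <- flat_supply(1000)
  base <- allocate_concentrates(
    supply, simple_requirements(q_poultry = 300, q_eggs = 100, q_pig = 400))
  more <- allocate_concentrates(
    supply, simple_requirements(q_poultry = 600, q_eggs = 200, q_pig = 800))
  expect_true(all(more$residual_ruminant <=
                    base$residual_ruminant + 1e-9))
  expect_true(all(more$residual_ruminant >= 0))
})

test_that("C3/C4 split of the ruminant residual follows the sub-shares", {
  alloc <- tibble::tibble(
    country = "A", year = 2000,
    group = commodity_groups(),
    residual_ruminant = c(50, 100, 0, 0, 0, 0, 40)  # maize, other_cereals,
  )                                                  # ..., others
  out <- split_ruminant_concentrates_c3c4(alloc,
                                          millet_sorghum_share = 0.3,
                                          sugarcane_share = 0.25)
  expect_equal(out$q_concentrates, 190)
  expect_equal(out$q_c4_concentrates, 50 + 0.3 * 100 + 0.25 * 40)
  expect_equal(out$q_c3_concentrates,
               out$q_concentrates - out$q_c4_concentrates)
  # zero sub-shares: only maize is C4
  out0 <- split_ruminant_concentrates_c3c4(alloc)
  expect_equal(out0$q_c4_concentrates, 50)
  expect_error(
    split_ruminant_concentrates_c3c4(alloc, millet_sorghum_share = 1.5),
    "sub-shares")
})
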