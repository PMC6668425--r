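test_that("isotopologue split conserves mass and inverts cleanly", {
  k <- box_constants()
  sp <- isotopologue_split(c(100, 550), c(-62, -48), k)
  expect_equal(sp$s12 + sp$s13, c(100, 550), tolerance = 1e-12)
  expect_equal(delta_from_ratio(sp$s12, sp$s13, k), c(-62, -48),
               tolerance = 1e-9)
  # a delta of zero means the standard ratio exactly
  sp0 <- isotopologue_split(1, 0, k)
  expect_equal(sp0$s13 / sp0$s12, k$r_std, tolerance = 1e-12)
  # heavier sources carry more 13C at the same total flux
  heavier <- isotopologue_split(100, -40, k)
  lighter <- isotopologue_split(100, -70, k)
  expect_gt(heavier$s13, lighter$s13)
})

test_that("box_step has the right fixed point and limits", {
  # at steady state the burden does not move
  expect_equal(box_step(c_beg = 500 / 0.1, s = 500, lambda = 0.1), 5000)
  # pure decay without sources
  expect_equal(box_step(1000, 0, 0.2), 1000 * exp(-0.2))
  # vanishing sink: the source simply accumulates
  expect_equal(box_step(1500, 500, 1e-12), 2000, tolerance = 1e-3)
  expect_error(box_step(1000, 500, 0), "lambda")
})

test_that("deduce_sink recovers a known constant sink", {
  k <- box_constants()
  lambda_true <- 0.11
  s <- rep(520, 10)
  cc <- numeric(11)
  cc[1] <- 4000
  for (i in 1:10) cc[i + 1] <- box_step(cc[i], s[i], lambda_true)
  record <- tibble::tibble(year = 2000:2010, ppb = cc / k$conversion)
  sinks <- deduce_sink(record, s)
  expect_equal(sinks$lambda, rep(lambda_true, 10), tolerance = 1e-10)
  expect_equal(sinks$year, 2000:2009)
})

test_that("deduce_sink refuses budgets no positive sink can close", {
  record <- tibble::tibble(year = c(2000, 2001), ppb = c(1000, 2000))
  expect_error(deduce_sink(record, 10), "2000")
})

test_that("the 1700 steady state balances both isotopologues", {
  k <- box_constants()
  sp <- isotopologue_split(200, -53, k)
  st <- steady_state_1700(sp$s12, sp$s13, c_total = 1800, constants = k)
  expect_equal(st$c12 + st$c13, 1800, tolerance = 1e-9)
  expect_equal(st$lambda13, k$alpha * st$lambda12)
  # each isotopologue is at its own steady state
  expect_equal(box_step(st$c12, sp$s12, st$lambda12), st$c12,
               tolerance = 1e-9)
  expect_equal(box_step(st$c13, sp$s13, st$lambda13), st$c13,
               tolerance = 1e-9)
  # sink fractionation leaves the atmosphere enriched relative to the source
  d_atm <- delta_from_ratio(st$c12, st$c13, k)
  expect_gt(d_atm, -53)
  expect_lt(d_atm, -53 + 8)
})

test_that("isotopologue sink deduction reproduces the record", {
  atm <- generate_atmosphere_inputs(seed = 9)
  totals <- inventory_totals(atm$inventory)
  n_step <- nrow(atm$record) - 1
  ded <- deduce_sink_isotopologues(atm$record, totals$s12[seq_len(n_step)],
                                   totals$s13[seq_len(n_step)])
  expect_equal(ded$trajectory$ppb, atm$record$ppb, tolerance = 1e-9)
  expect_equal(ded$sinks$lambda13, box_constants()$alpha * ded$sinks$lambda12)
  # the synthetic record was built with a constant sink; it is recovered
  expect_equal(ded$sinks$lambda12 + 0,
               rep(ded$sinks$lambda12[1], n_step), tolerance = 1e-6)
})

test_that("run_forward holds a steady state flat", {
  k <- box_constants()
  sp <- isotopologue_split(550, -53, k)
  st <- steady_state_1700(sp$s12, sp$s13, 550 * 9.1, k)
  n <- 50
  traj <- run_forward(2000 + 0:n, rep(sp$s12, n), rep(sp$s13, n),
                      rep(st$lambda12, n), rep(st$lambda13, n),
                      st$c12, st$c13, k)
  expect_equal(traj$ppb, rep(traj$ppb[1], n + 1), tolerance = 1e-12)
  expect_equal(traj$d13c_atm, rep(traj$d13c_atm[1], n + 1), tolerance = 1e-9)
  expect_error(run_forward(2000:2002, 1, 1, 0.1, 0.1, 10, 1), "length")
})

test_that("a null enteric revision leaves every scenario at the baseline", {
  atm <- generate_atmosphere_inputs(seed = 2)
  ent <- atm$inventory[atm$inventory$component == "enteric" &
                         atm$inventory$year >= 1961, ]
  exps <- run_experiments(atm$inventory, atm$record,
                          revised_flux = ent[, c("year", "flux")],
                          revised_delta = tibble::tibble(year = ent$year,
                                                         d13c = ent$d13c))
  expect_true(all(abs(exps$deltas$d_ppb) < 1e-8))
  expect_true(all(abs(exps$deltas$d_d13c_atm) < 1e-8))
  expect_true(all(abs(exps$deltas$d_d13c_source) < 1e-10))
})

test_that("scenario semantics: only R1 leaves the concentration record", {
  atm <- generate_atmosphere_inputs(seed = 2)
  ent <- atm$inventory[atm$inventory$component == "enteric" &
                         atm$inventory$year >= 1961, ]
  revised_flux <- tibble::tibble(year = ent$year, flux = ent$flux * 1.15)
  revised_delta <- tibble::tibble(year = ent$year, d13c = ent$d13c + 4)
  exps <- run_experiments(atm$inventory, atm$record, revised_flux,
                          revised_delta)
  d <- exps$deltas
  # R1 keeps the baseline sinks, so a larger source raises the concentration
  r1_2012 <- d[d$scenario == "R1" & d$year == 2012, ]
  expect_gt(r1_2012$d_ppb, 0)
  # R2 and R3 re-deduce their sinks against the record: concentration matches
  expect_true(all(abs(d$d_ppb[d$scenario %in% c("R2", "R3")]) < 1e-8))
  # but their heavier enteric source leaves a signature in delta13C_atm
  r2_2012 <- d[d$scenario == "R2" & d$year == 2012, ]
  expect_gt(abs(r2_2012$d_d13c_atm), 1e-3)
})
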