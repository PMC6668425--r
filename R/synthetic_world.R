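#' Configuration for the synthetic world generator
#'
#' Describes a small multi-country world of livestock production, feed
#' commodity supply and grass use with known ground truth, used to exercise
#' every pipeline stage without external data. Defaults: 10 countries (5
#' developed, 5 developing), 1961-2012, no noise.
#'
#' @param n_countries Number of countries.
#' @param years Inclusive year vector (default 1961:2012).
#' @param seed Integer RNG seed; a fixed seed gives byte-identical output.
#' @param development_status Per-country status; default splits the countries
#'   half developed, half developing.
#' @param noise List of fractional standard deviations of multiplicative
#'   lognormal noise per table (`production`, `supply`, `grass`, `me`); all 0
#'   by default so downstream recovery is exact.
#' @param c4_fraction_range Range the per-country C4 grass fraction is drawn
#'   from.
#' @param millet_sorghum_share,sugarcane_share C4 sub-shares of the
#'   other-cereals and others commodity groups.
#' @param q_so_to_grass_ratio Ratio of true stover + occasional feed to grass
#'   feed; must be positive (it fixes the latent other-feed truth from which
#'   the ME series is derived).
#' @param co2_decline Total decline of the delta13C-CO2 series from 1960 to
#'   2012, permil (default 1.3).
#' @param energy,emission,isotope Parameter lists used as the generator's
#'   ground truth (defaults are the central values).
#'
#' @return A list of class `synthetic_world_config`.
#' @export
synthetic_world_config <- function(n_countries = 10,
                                   years = 1961:2012,
                                   seed = 1,
                                   development_status = NULL,
                                   noise = list(production = 0, supply = 0,
                                                grass = 0, me = 0),
                                   c4_fraction_range = c(0.05, 0.7),
                                   millet_sorghum_share = 0.2,
                                   sugarcane_share = 0.25,
                                   q_so_to_grass_ratio = 0.45,
                                   co2_decline = 1.3,
                                   energy = energy_params(),
                                   emission = emission_params(),
                                   isotope = isotope_params()) {
  stopifnot(n_countries >= 1, length(years) >= 1)
  if (min(years) > max(years)) stop("invalid year range", call. = FALSE)
  if (is.null(development_status)) {
    development_status <- rep(c("developed", "developing"),
                              length.out = n_countries)
  }
  stopifnot(length(development_status) == n_countries,
            all(development_status %in% c("developed", "developing")))
  if (any(c4_fraction_range < 0) || any(c4_fraction_range > 1)) {
    stop("c4_fraction_range must lie in [0, 1]", call. = FALSE)
  }
  for (nm in c("production", "supply", "grass", "me")) {
    if (is.null(noise[[nm]])) noise[[nm]] <- 0
    if (noise[[nm]] < 0) stop("noise sd must be >= 0", call. = FALSE)
  }
  structure(
    list(n_countries = n_countries, years = sort(years), seed = seed,
         development_status = development_status, noise = noise,
         c4_fraction_range = c4_fraction_range,
         millet_sorghum_share = millet_sorghum_share,
         sugarcane_share = sugarcane_share,
         q_so_to_grass_ratio = q_so_to_grass_ratio,
         co2_decline = co2_decline,
         energy = energy, emission = emission, isotope = isotope),
    class = "synthetic_world_config"
  )
}

# multiplicative lognormal noise with unit median
lnoise <- function(n, sd) {
  if (sd <= 0) return(rep(1, n))
  exp(stats::rnorm(n, 0, sd))
}

#' Generate a synthetic livestock world with known ground truth
#'
#' Draws country production trajectories, computes monogastric feed demand
#' with the package's own FCR and intensity rules, adds a chosen positive
#' ruminant concentrate residual to form the commodity supply, generates grass
#' use with per-country C4 fractions, fixes a positive latent stover +
#' occasional feed series and derives the ruminant metabolizable energy series
#' that makes the energy balance close on it exactly. With zero noise, running
#' the allocation and energy modules on the generated tables reproduces the
#' ground truth to machine precision.
#'
#' @param config A [synthetic_world_config()].
#'
#' @return A list with tibbles `production`, `supply`, `me_series`,
#'   `grass_use`, `intensity_anchors`, the `co2_series`, and `ground_truth`
#'   (per country x year: species feed totals, ruminant concentrate pools,
#'   grass, other feeds, ME, delta13C_diet and F_CH4), plus the `config`.
#' @export
generate_livestock_world <- function(config = synthetic_world_config()) {
  stopifnot(inherits(config, "synthetic_world_config"))
  set.seed(config$seed)
  years <- config$years
  n_y <- length(years)
  countries <- sprintf("C%02d", seq_len(config$n_countries))
  status <- stats::setNames(config$development_status, countries)

  co2_series <- generate_co2_isotope_series(
    years = min(1960, min(years)):max(2012, max(years)),
    decline = config$co2_decline)

  grid <- tidyr::expand_grid(country = countries, year = years)
  grid$status <- status[grid$country]

  # per-country levels and growth rates
  lv <- tibble::tibble(
    country = countries,
    chickens0 = stats::runif(length(countries), 2e6, 2e7),
    pigs0 = stats::runif(length(countries), 2e5, 2e6),
    laying0 = stats::runif(length(countries), 1e6, 1e7),
    g_poultry = stats::runif(length(countries), 0.02, 0.05),
    g_pig = stats::runif(length(countries), 0.01, 0.04),
    g_laying = stats::runif(length(countries), 0.015, 0.04),
    anchor2000 = ifelse(status == "developed",
                        stats::runif(length(countries), 0.7, 0.95),
                        stats::runif(length(countries), 0.3, 0.8)),
    c4_grass_fraction = stats::runif(length(countries),
                                     config$c4_fraction_range[1],
                                     config$c4_fraction_range[2]),
    grass0 = stats::runif(length(countries), 5e8, 5e9),
    g_grass = stats::runif(length(countries), 0.005, 0.02),
    resid0 = stats::runif(length(countries), 5e7, 5e8),
    g_resid = stats::runif(length(countries), 0.005, 0.025)
  )
  g <- dplyr::left_join(grid, lv, by = "country")
  t_rel <- g$year - min(years)

  production <- dplyr::bind_rows(
    tibble::tibble(country = g$country, year = g$year, species = "chickens",
                   n = g$chickens0 * (1 + g$g_poultry)^t_rel, yield = 1.4),
    tibble::tibble(country = g$country, year = g$year, species = "ducks",
                   n = 0.1 * g$chickens0 * (1 + g$g_poultry)^t_rel,
                   yield = 1.8),
    tibble::tibble(country = g$country, year = g$year,
                   species = "laying_hens",
                   n = g$laying0 * (1 + g$g_laying)^t_rel, yield = 12),
    tibble::tibble(country = g$country, year = g$year, species = "pig",
                   n = g$pigs0 * (1 + g$g_pig)^t_rel, yield = 60)
  )
  production$n <- production$n *
    lnoise(nrow(production), config$noise$production)

  # monogastric demand with the package's own rules
  weights <- live_weight_totals(production)
  weights$status <- status[weights$country]
  anchors <- stats::setNames(lv$anchor2000, lv$country)
  f_int <- mapply(function(ctry, yr) {
    farming_intensity_at(yr, anchors[[ctry]], status[[ctry]])
  }, weights$country, weights$year)
  requirements <- tibble::tibble(
    country = weights$country, year = weights$year,
    q_poultry_meat = feed_requirement(
      weights$weight_poultry_meat,
      fcr_at("poultry", weights$year, weights$status), f_int),
    q_eggs = feed_requirement(
      weights$weight_egg, fcr_at("egg", weights$year, weights$status), f_int),
    q_pig = feed_requirement(
      weights$weight_pig, fcr_at("pig", weights$year, weights$status), f_int)
  )

  shares <- feed_composition_shares()
  resid_shares <- c(maize = 0.30, other_cereals = 0.25, oilseeds = 0.08,
                    cakes = 0.15, brans = 0.10, pulses = 0.05, others = 0.07)
  resid_shares <- resid_shares / sum(resid_shares)

  demand_long <- tidyr::expand_grid(
    dplyr::select(requirements, "country", "year"),
    group = commodity_groups())
  demand_long <- dplyr::left_join(demand_long, requirements,
                                  by = c("country", "year"))
  sh <- function(sp, grp) {
    s <- shares$share[shares$species == sp][
      match(grp, shares$group[shares$species == sp])]
    ifelse(is.na(s), 0, s)
  }
  demand_long$demand <-
    demand_long$q_poultry_meat * sh("poultry_meat", demand_long$group) +
    demand_long$q_eggs * sh("eggs", demand_long$group) +
    demand_long$q_pig * sh("pig", demand_long$group)

  resid_total <- g$resid0 * (1 + g$g_resid)^t_rel
  resid_tbl <- tibble::tibble(country = g$country, year = g$year,
                              resid_total = resid_total)
  supply <- dplyr::left_join(demand_long, resid_tbl,
                             by = c("country", "year"))
  supply$residual_true <- supply$resid_total * resid_shares[supply$group]
  supply$supply <- (supply$demand + supply$residual_true) *
    lnoise(nrow(supply), config$noise$supply)
  supply_out <- supply[, c("country", "year", "group", "supply")]

  grass_use <- tibble::tibble(
    country = g$country, year = g$year,
    q_grass = g$grass0 * (1 + g$g_grass)^t_rel *
      lnoise(nrow(g), config$noise$grass),
    c4_grass_fraction = g$c4_grass_fraction
  )

  # latent other-feed truth and the ME series that closes on it
  q_so_true <- grass_use$q_grass * config$q_so_to_grass_ratio
  if (any(q_so_true <= 0)) {
    bad <- which(q_so_true <= 0)[1]
    stop("config yields non-positive latent other feeds for ",
         g$country[bad], " in ", g$year[bad], call. = FALSE)
  }
  ep <- config$energy
  q_conc_true <- resid_total
  me <- q_so_true * ep$e_ge_feed * ep$f_de_so * rem(ep$f_de_so) +
    q_conc_true * ep$e_ge_feed * ep$f_de_concentrates *
      rem(ep$f_de_concentrates) +
    grass_use$q_grass * ep$e_ge_feed * ep$f_de_grass * rem(ep$f_de_grass)
  me_series <- tibble::tibble(country = g$country, year = g$year,
                              me = me * lnoise(nrow(g), config$noise$me))

  # ground truth through the full pipeline at the generator's parameters
  q_c4_conc <- q_conc_true * (resid_shares[["maize"]] +
    config$millet_sorghum_share * resid_shares[["other_cereals"]] +
    config$sugarcane_share * resid_shares[["others"]])
  basket <- assemble_diet_basket(
    q_conc_c3 = q_conc_true - q_c4_conc, q_conc_c4 = q_c4_conc,
    q_grass = grass_use$q_grass,
    c4_grass_fraction = grass_use$c4_grass_fraction, q_so = q_so_true)
  d13c_diet <- diet_delta13c(basket, config$isotope, year = g$year,
                             series = co2_series)
  ge <- gross_energy(basket, ep$e_ge_feed)
  f_ch4 <- enteric_ch4(ge, config$emission)

  ground_truth <- tibble::tibble(
    country = g$country, year = g$year,
    q_poultry_meat = requirements$q_poultry_meat,
    q_eggs = requirements$q_eggs,
    q_pig = requirements$q_pig,
    q_concentrates = q_conc_true,
    q_c4_concentrates = q_c4_conc,
    q_c3_concentrates = q_conc_true - q_c4_conc,
    q_grass = grass_use$q_grass,
    c4_grass_fraction = grass_use$c4_grass_fraction,
    q_so = q_so_true,
    me = me,
    d13c_diet = d13c_diet,
    ge = ge,
    f_ch4 = f_ch4
  )

  list(production = production, supply = supply_out, me_series = me_series,
       grass_use = grass_use,
       intensity_anchors = tibble::tibble(country = countries,
                                          status = unname(status[countries]),
                                          anchor2000 = unname(anchors[countries])),
       co2_series = co2_series,
       ground_truth = ground_truth,
       config = config)
}

#' Generate a declining atmospheric delta13C-CO2 series
#'
#' A monotonically declining annual series emulating the observed record: the
#' default drops 1.3 permil between 1960 and 2012 (linearly), anchored at the
#' endpoints.
#'
#' @param years Year vector; must cover 1960-2012.
#' @param decline Total 1960-to-2012 decline in permil (default 1.3; 0 gives a
#'   flat series).
#' @param value_1960 Series value in 1960, permil (default -6.9).
#' @param shape `"linear"` only for now.
#'
#' @return A tibble `year`, `d13c_co2`.
#' @export
generate_co2_isotope_series <- function(years = 1960:2012, decline = 1.3,
                                        value_1960 = -6.9,
                                        shape = c("linear")) {
  shape <- match.arg(shape)
  if (min(years) > 1960 || max(years) < 2012) {
    stop("year range must cover 1960-2012", call. = FALSE)
  }
  slope <- -decline / (2012 - 1960)
  tibble::tibble(year = years,
                 d13c_co2 = value_1960 + slope * (years - 1960))
}

#' Generate synthetic diet-to-methane regression observations
#'
#' Draws diet signatures over a realistic span and produces methane
#' signatures on a known line plus Gaussian noise, with per-point
#' uncertainties attached (the diet values are generated noiseless but carry
#' the stated measurement uncertainty, as real observations do).
#'
#' @param n_obs Number of observations (>= 3).
#' @param slope,intercept True line (permil intercept).
#' @param sd_noise Gaussian noise sd on delta13C_CH4, permil (>= 0).
#' @param seed Optional seed.
#' @param diet_range Span of delta13C_diet values (default -30 to -12 permil).
#' @param sd_diet Attached per-point diet uncertainty (default 0.5 permil).
#'
#' @return An observation tibble compatible with
#'   [fit_diet_ch4_regression()].
#' @export
generate_regression_observations <- function(n_obs = 43, slope = 0.91,
                                             intercept = -43.49,
                                             sd_noise = 4.2, seed = NULL,
                                             diet_range = c(-30, -12),
                                             sd_diet = 0.5) {
  if (n_obs < 3) stop("need n_obs >= 3", call. = FALSE)
  if (sd_noise < 0) stop("sd_noise must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x <- stats::runif(n_obs, diet_range[1], diet_range[2])
  y <- slope * x + intercept + stats::rnorm(n_obs, 0, sd_noise)
  tibble::tibble(
    species = rep_len(c("cattle", "sheep", "goat"), n_obs),
    d13c_diet = x, sd_diet = sd_diet,
    d13c_ch4 = y, sd_ch4 = max(sd_noise, 1e-12),
    year = rep_len(1995:2012, n_obs),
    source_id = paste0("synth", seq_len(n_obs)),
    provenance = "reported"
  )
}

#' Default methane source components and delta13C signatures
#'
#' Fourteen components: five natural (held constant over history) and nine
#' anthropogenic (fossil fuel, waste/landfill, rice, enteric fermentation,
#' manure, and four burning classes). The enteric default of -62 permil is
#' the conventional prior inventory value; the other signatures are
#' representative literature defaults shipped as synthetic stand-ins.
#'
#' @return A tibble `component`, `d13c`, `natural`.
#' @export
default_source_signatures <- function() {
  tibble::tribble(
    ~component,                 ~d13c, ~natural,
    "wetlands",                 -59.0, TRUE,
    "termites",                 -63.0, TRUE,
    "oceans",                   -40.0, TRUE,
    "wild_animals",             -62.0, TRUE,
    "geologic",                 -38.0, TRUE,
    "fossil_fuel",              -44.0, FALSE,
    "waste_landfill",           -55.0, FALSE,
    "rice",                     -62.0, FALSE,
    "enteric",                  -62.0, FALSE,
    "manure",                   -55.0, FALSE,
    "ag_waste_burning",         -25.0, FALSE,
    "forest_burning",           -27.0, FALSE,
    "c3_grass_burning",         -27.0, FALSE,
    "c4_savanna_burning",       -12.0, FALSE
  )
}

#' Generate synthetic one-box model inputs
#'
#' Builds a 14-component source inventory over 1700-2012 (natural components
#' constant, anthropogenic components growing) and a concentration record
#' consistent with it: the record is produced by integrating the box model
#' forward from a 1700 steady state with a known sink history, so the
#' deduce-then-forward round trip has an exact reference.
#'
#' @param seed Integer seed.
#' @param lambda_true Constant total-sink value used to synthesise the record
#'   (yr^-1, default 1/9.1).
#' @param steady If `TRUE`, hold all sources at their 1700 values so the
#'   record is constant at `S / lambda / conversion`.
#' @param growth Annual growth rate of anthropogenic sources after 1850
#'   (default 0.012).
#' @param constants A [box_constants()] list.
#'
#' @return A list with `inventory` (long tibble `year`, `component`, `flux`,
#'   `d13c`), `record` (`year`, `ppb`), `signatures` and `lambda_true`.
#' @export
generate_atmosphere_inputs <- function(seed = 1, lambda_true = 1 / 9.1,
                                       steady = FALSE, growth = 0.012,
                                       constants = box_constants()) {
  set.seed(seed)
  sig <- default_source_signatures()
  years <- 1700:2012
  anchors <- tibble::tribble(
    ~component,         ~flux,
    "wetlands",         160,
    "termites",         20,
    "oceans",           10,
    "wild_animals",     10,
    "geologic",         30,
    "fossil_fuel",      1,
    "waste_landfill",   2,
    "rice",             12,
    "enteric",          8,
    "manure",           2,
    "ag_waste_burning", 4,
    "forest_burning",   3,
    "c3_grass_burning", 4,
    "c4_savanna_burning", 5
  )
  natural <- sig$component[sig$natural]
  inv <- dplyr::bind_rows(lapply(seq_len(nrow(anchors)), function(i) {
    comp <- anchors$component[i]
    f0 <- anchors$flux[i]
    flux <- if (comp %in% natural || steady) {
      rep(f0, length(years))
    } else {
      ifelse(years <= 1850, f0, f0 * (1 + growth)^(years - 1850))
    }
    tibble::tibble(year = years, component = comp, flux = flux)
  }))
  inv$d13c <- sig$d13c[match(inv$component, sig$component)]

  src <- inventory_sources(inv, constants)
  lambda <- rep(lambda_true, length(years) - 1)
  c0 <- src$s_total[1] / lambda_true
  init <- steady_state_1700(src$s12[1], src$s13[1], c0, constants)
  traj <- run_forward(years, src$s12[-length(years)], src$s13[-length(years)],
                      rep(init$lambda12, length(years) - 1),
                      rep(init$lambda13, length(years) - 1),
                      init$c12, init$c13, constants)
  list(inventory = inv,
       record = tibble::tibble(year = traj$year, ppb = traj$ppb),
       signatures = sig,
       lambda_true = lambda_true)
}
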