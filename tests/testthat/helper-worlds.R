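# Shared helpers for the test suite.

# Recompute the monogastric feed requirements from a synthetic world's
# observable tables, using only exported functions (the same path the
# pipeline takes).
recompute_requirements <- function(world) {
  weights <- live_weight_totals(world$production)
  anchors <- world$intensity_anchors
  idx <- match(weights$country, anchors$country)
  weights$status <- anchors$status[idx]
  f_int <- mapply(function(ctry, yr) {
    i <- match(ctry, anchors$country)
    farming_intensity_at(yr, anchors$anchor2000[i], anchors$status[i])
  }, weights$country, weights$year)
  tibble::tibble(
    country = weights$country,
    year = weights$year,
    q_poultry_meat = feed_requirement(
      weights$weight_poultry_meat,
      fcr_at("poultry", weights$year, weights$status), f_int),
    q_eggs = feed_requirement(
      weights$weight_egg,
      fcr_at("egg", weights$year, weights$status), f_int),
    q_pig = feed_requirement(
      weights$weight_pig,
      fcr_at("pig", weights$year, weights$status), f_int)
  )
}

# A one-country-one-year commodity supply table with a uniform supply level.
flat_supply <- function(level = 1000, country = "A", year = 2000) {
  tibble::tibble(country = country, year = year,
                 group = commodity_groups(), supply = level)
}

# A minimal requirements row.
simple_requirements <- function(q_poultry = 0, q_eggs = 0, q_pig = 0,
                                country = "A", year = 2000) {
  tibble::tibble(country = country, year = year,
                 q_poultry_meat = q_poultry, q_eggs = q_eggs, q_pig = q_pig)
}

# Per-year total and per-component source series from a long inventory,
# using only exported functions.
inventory_totals <- function(inventory, constants = box_constants()) {
  split <- isotopologue_split(inventory$flux, inventory$d13c, constants)
  agg <- function(x) as.numeric(rowsum(x, inventory$year))
  years <- sort(unique(inventory$year))
  tibble::tibble(
    year = years,
    s_total = agg(inventory$flux),
    s12 = agg(split$s12),
    s13 = agg(split$s13),
    d13c_source = agg(inventory$flux * inventory$d13c) / agg(inventory$flux)
  )
}
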