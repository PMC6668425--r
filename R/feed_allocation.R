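#' Feed conversion ratio at a given year
#'
#' Evaluates the linear-in-time FCR schedule for a species, with the
#' developing-country multiplier applied after the time trend. Extrapolation
#' beyond the anchor is floored at `floor_frac` of the anchor value.
#'
#' @param species `"poultry"`, `"egg"` or `"pig"` (vectorised).
#' @param year Calendar year(s) in 1961-2012.
#' @param status `"developed"` or `"developing"` (vectorised).
#' @param schedule A [fcr_schedule()].
#'
#' @return Numeric vector of FCR values (kg DM per kg product).
#' @examples
#' fcr_at("poultry", 2005, "developed") # 1.95
#' fcr_at("pig", 1995, "developed")     # 3.28
#' @export
fcr_at <- function(species, year, status, schedule = fcr_schedule()) {
  n <- max(length(species), length(year), length(status))
  species <- rep_len(as.character(species), n)
  year <- rep_len(year, n)
  status <- rep_len(as.character(status), n)
  if (any(year < 1961 | year > 2012)) {
    stop("year must be within 1961-2012", call. = FALSE)
  }
  bad <- setdiff(species, c("poultry", "egg", "pig"))
  if (length(bad)) {
    stop("unknown species: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  if (!all(status %in% c("developed", "developing"))) {
    stop("status must be 'developed' or 'developing'", call. = FALSE)
  }
  base <- vapply(species, function(s) schedule[[s]]$base, numeric(1))
  anchor <- vapply(species, function(s) schedule[[s]]$anchor, numeric(1))
  rate <- vapply(species, function(s) schedule[[s]]$rate, numeric(1))
  fcr <- base + rate * (year - anchor)
  fcr <- pmax(fcr, schedule$floor_frac * base)
  mult <- ifelse(status == "developing", schedule$developing_multiplier, 1)
  unname(fcr * mult)
}

#' Farming intensity at a given year
#'
#' Fraction of monogastric production raised on commodity feed (the remainder
#' is backyard production on local resources). Developed countries hold their
#' year-2000 anchor for all years; developing countries follow a logistic
#' intensification curve through the year-2000 anchor, capped at `cap`. The
#' logistic rate is chosen (per country) so that the 1961 intensity is
#' `f1961_frac` of the anchor, unless `rate` is supplied.
#'
#' @param year Calendar year(s).
#' @param anchor2000 Year-2000 intensity anchor in `[0, 1]`.
#' @param status `"developed"` or `"developing"`.
#' @param cap Upper bound for developing-country intensity (default 0.95).
#' @param f1961_frac Target ratio f(1961)/f(2000) used to calibrate the
#'   logistic rate (default 0.4).
#' @param rate Optional logistic rate (yr^-1); overrides the calibration.
#'
#' @return Numeric vector of intensities in `[0, cap]`.
#' @export
farming_intensity_at <- function(year, anchor2000, status,
                                 cap = 0.95, f1961_frac = 0.4, rate = NULL) {
  if (any(anchor2000 < 0 | anchor2000 > 1)) {
    stop("anchor intensity must lie in [0, 1]", call. = FALSE)
  }
  status <- match.arg(status, c("developed", "developing"))
  if (status == "developed") {
    return(rep_len(anchor2000, length(year)))
  }
  anchor <- min(anchor2000, cap - 1e-9)
  if (anchor <= 0) {
    return(rep_len(0, length(year)))
  }
  # logistic f(y) = cap / (1 + exp(-r (y - m))), constrained f(2000) = anchor
  midpoint_for <- function(r) 2000 - stats::qlogis(anchor / cap) / r
  if (is.null(rate)) {
    target <- f1961_frac * anchor
    gap <- function(r) {
      m <- midpoint_for(r)
      cap * stats::plogis(r * (1961 - m)) - target
    }
    rate <- stats::uniroot(gap, c(1e-6, 2), tol = 1e-12)$root
  }
  m <- midpoint_for(rate)
  cap * stats::plogis(rate * (year - m))
}

#' Live-weight totals from production statistics
#'
#' Converts carcass-weight production to live weight using dressing
#' percentages (70% poultry, 60% pigs); egg production needs no dressing
#' conversion. Poultry species (chickens, ducks, geese, turkeys, other birds)
#' are summed.
#'
#' @param production A long tibble with columns `country`, `year`, `species`,
#'   `n` (head) and `yield` (kg carcass, kg eggs, or kg milk per head).
#'   Species whose name starts with `"laying"` are laying birds; `"pig"` is
#'   pigs; everything else listed in `poultry_species` is meat poultry.
#' @param dressing A [dressing_fractions()] list.
#' @param poultry_species Character vector naming the meat-poultry species.
#'
#' @return A tibble with columns `country`, `year`, `weight_poultry_meat`,
#'   `weight_egg`, `weight_pig` (kg live weight or kg eggs).
#' @export
live_weight_totals <- function(production,
                               dressing = dressing_fractions(),
                               poultry_species = c("chickens", "ducks",
                                                   "geese", "turkeys",
                                                   "other_birds")) {
  production <- tibble::as_tibble(production)
  stopifnot(all(c("country", "year", "species", "n", "yield") %in%
                  names(production)))
  if (any(production$n < 0) || any(production$yield < 0)) {
    stop("head counts and yields must be non-negative", call. = FALSE)
  }
  kind <- dplyr::case_when(
    production$species %in% poultry_species ~ "weight_poultry_meat",
    startsWith(production$species, "laying") ~ "weight_egg",
    production$species == "pig" ~ "weight_pig",
    TRUE ~ NA_character_
  )
  df <- production[!is.na(kind), ]
  df$kind <- kind[!is.na(kind)]
  df$mass <- df$n * df$yield
  df$mass <- ifelse(df$kind == "weight_poultry_meat",
                    df$mass / dressing$poultry,
                    ifelse(df$kind == "weight_pig",
                           df$mass / dressing$pig, df$mass))
  out <- df |>
    dplyr::group_by(.data$country, .data$year, .data$kind) |>
    dplyr::summarise(mass = sum(.data$mass), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "kind", values_from = "mass",
                       values_fill = 0)
  for (col in c("weight_poultry_meat", "weight_egg", "weight_pig")) {
    if (!col %in% names(out)) out[[col]] <- 0
  }
  out[, c("country", "year", "weight_poultry_meat", "weight_egg",
          "weight_pig")]
}

#' Commodity feed requirement
#'
#' `Q = Weight x FCR x f_intensity`: the concentrate feed (kg dry matter)
#' needed to produce a live-weight (or egg) output, discounted by the farming
#' intensity (backyard production consumes no feed commodities).
#'
#' @param weight Live weight or egg production, kg.
#' @param fcr Feed conversion ratio, kg DM per kg.
#' @param f_intensity Farming intensity in `[0, 1]`.
#'
#' @return Feed requirement in kg dry matter.
#' @export
feed_requirement <- function(weight, fcr, f_intensity) {
  if (any(weight < 0) || any(fcr < 0) || any(f_intensity < 0)) {
    stop("inputs must be non-negative", call. = FALSE)
  }
  weight * fcr * f_intensity
}

#' Allocate concentrate feed supply to poultry, pigs and ruminants
#'
#' The supply of each commodity group is served in priority order: poultry
#' meat and eggs first, then pigs, with ruminants receiving everything that
#' remains. Species draw on commodity groups according to fixed composition
#' shares. If demand exceeds supply in a group at some stage the available
#' quantity is allocated pro-rata within that stage and the shortfall is
#' flagged; the ruminant residual is never negative.
#'
#' @param supply Long tibble with columns `country`, `year`, `group`,
#'   `supply` (kg DM) covering the seven commodity groups.
#' @param requirements Tibble with columns `country`, `year`,
#'   `q_poultry_meat`, `q_eggs`, `q_pig` (total kg DM per species).
#' @param shares A [feed_composition_shares()] table.
#'
#' @return A tibble, one row per country x year x group, with columns
#'   `alloc_poultry_meat`, `alloc_eggs`, `alloc_pig`, `residual_ruminant`,
#'   `supply` and logical `shortfall`. Allocations sum to supply exactly in
#'   every group.
#' @export
allocate_concentrates <- function(supply, requirements,
                                  shares = feed_composition_shares()) {
  supply <- tibble::as_tibble(supply)
  requirements <- tibble::as_tibble(requirements)
  stopifnot(all(c("country", "year", "group", "supply") %in% names(supply)),
            all(c("country", "year", "q_poultry_meat", "q_eggs", "q_pig") %in%
                  names(requirements)))
  if (any(supply$supply < 0)) stop("supply must be >= 0", call. = FALSE)

  share_of <- function(sp, grp) {
    s <- shares$share[shares$species == sp][match(grp,
          shares$group[shares$species == sp])]
    ifelse(is.na(s), 0, s)
  }

  df <- dplyr::left_join(supply, requirements, by = c("country", "year"))
  df$q_poultry_meat[is.na(df$q_poultry_meat)] <- 0
  df$q_eggs[is.na(df$q_eggs)] <- 0
  df$q_pig[is.na(df$q_pig)] <- 0

  dem_poultry <- df$q_poultry_meat * share_of("poultry_meat", df$group)
  dem_eggs <- df$q_eggs * share_of("eggs", df$group)
  dem_pig <- df$q_pig * share_of("pig", df$group)

  # stage 1: poultry meat + eggs, pro-rata under shortfall
  stage1 <- dem_poultry + dem_eggs
  scale1 <- ifelse(stage1 > df$supply & stage1 > 0, df$supply / stage1, 1)
  alloc_poultry <- dem_poultry * scale1
  alloc_eggs <- dem_eggs * scale1
  left <- df$supply - alloc_poultry - alloc_eggs

  # stage 2: pigs
  scale2 <- ifelse(dem_pig > left & dem_pig > 0, left / dem_pig, 1)
  alloc_pig <- dem_pig * scale2
  residual <- pmax(left - alloc_pig, 0)

  tibble::tibble(
    country = df$country, year = df$year, group = df$group,
    supply = df$supply,
    alloc_poultry_meat = alloc_poultry,
    alloc_eggs = alloc_eggs,
    alloc_pig = alloc_pig,
    residual_ruminant = residual,
    shortfall = scale1 < 1 | scale2 < 1
  )
}

#' Split the ruminant concentrate residual into C3 and C4 feeds
#'
#' The C4 concentrate pool is maize plus the millet and sorghum part of the
#' other-cereals group plus the sugarcane part of the others group; everything
#' else is C3. Sub-shares are held at their pre-allocation values.
#'
#' @param allocation Output of [allocate_concentrates()] (per-group residuals).
#' @param millet_sorghum_share Fraction of the other-cereals group that is
#'   millet + sorghum, per country x year or a scalar.
#' @param sugarcane_share Fraction of the others group that is sugarcane.
#'
#' @return A tibble with one row per country x year: `q_concentrates`,
#'   `q_c4_concentrates`, `q_c3_concentrates`.
#' @export
split_ruminant_concentrates_c3c4 <- function(allocation,
                                             millet_sorghum_share = 0,
                                             sugarcane_share = 0) {
  if (any(millet_sorghum_share < 0) || any(millet_sorghum_share > 1) ||
      any(sugarcane_share < 0) || any(sugarcane_share > 1)) {
    stop("sub-shares must lie in [0, 1]", call. = FALSE)
  }
  wide <- allocation |>
    dplyr::select("country", "year", "group", "residual_ruminant") |>
    tidyr::pivot_wider(names_from = "group",
                       values_from = "residual_ruminant", values_fill = 0)
  for (g in commodity_groups()) if (!g %in% names(wide)) wide[[g]] <- 0
  total <- rowSums(wide[, commodity_groups()])
  q_c4 <- wide$maize + millet_sorghum_share * wide$other_cereals +
    sugarcane_share * wide$others
  tibble::tibble(
    country = wide$country, year = wide$year,
    q_concentrates = total,
    q_c4_concentrates = q_c4,
    q_c3_concentrates = total - q_c4
  )
}
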