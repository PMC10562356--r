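## Stand-level silvicultural triggering and stochastic regional allocation of
## scenario harvest targets.

#' Default harvest rules
#'
#' Species-specific triggers in the spirit of national silvicultural
#' guidelines: a clearcut is due when mean diameter OR dominant height OR
#' stand age exceeds its trigger (configurable combinator), a thinning when
#' basal area exceeds the thinning trigger. All numbers are configuration,
#' not estimates.
#'
#' @param species data.frame with columns species, clearcut_dbh (cm),
#'   clearcut_height (m), clearcut_age (y), thin_ba (m2 ha-1), thin_removal
#'   (fraction in (0,1)).
#' @param clearcut_combinator `"or"` (any trigger) or `"and"` (all triggers).
#' @param energy_wood_fraction fraction of harvest residues removed as energy
#'   wood.
#' @return list of class `fc_harvest_rules`.
#' @export
harvest_rules <- function(species = data.frame(
                            species = c("pine", "spruce", "birch"),
                            clearcut_dbh = c(26, 25, 23),
                            clearcut_height = c(25, 24, 22),
                            clearcut_age = c(80, 70, 60),
                            thin_ba = c(26, 24, 22),
                            thin_removal = c(0.30, 0.30, 0.30),
                            stringsAsFactors = FALSE),
                          clearcut_combinator = c("or", "and"),
                          energy_wood_fraction = 0.5) {
  clearcut_combinator <- match.arg(clearcut_combinator)
  if (any(species$thin_removal <= 0 | species$thin_removal >= 1)) {
    stop("thin_removal must be in (0,1)", call. = FALSE)
  }
  if (any(species[, c("clearcut_dbh", "clearcut_height", "clearcut_age",
                      "thin_ba")] <= 0)) {
    stop("harvest triggers must be positive", call. = FALSE)
  }
  structure(list(species = species,
                 clearcut_combinator = clearcut_combinator,
                 energy_wood_fraction = energy_wood_fraction),
            class = "fc_harvest_rules")
}

dominant_species <- function(stand) {
  sp <- cbind(stand$prop_pine, stand$prop_spruce, stand$prop_birch)
  c("pine", "spruce", "birch")[max.col(sp, ties.method = "first")]
}

#' Determine the eligible silvicultural action per pixel
#'
#' Clearcut if the dominant species' clearcut triggers (diameter, height,
#' age, combined by the configured OR/AND) are met; otherwise thinning if
#' basal area exceeds the thinning trigger; otherwise none. Protected and
#' poorly productive land is never harvested.
#'
#' @param stand an `fc_stand` (vectorised over rows).
#' @param rules an [harvest_rules()] object.
#' @return character vector in \{"none", "thinning", "clearcut"\}.
#' @export
eligible_action <- function(stand, rules = harvest_rules()) {
  sp <- match(dominant_species(stand), rules$species$species)
  rs <- rules$species
  cc_d <- stand$dbh >= rs$clearcut_dbh[sp]
  cc_h <- stand$height >= rs$clearcut_height[sp]
  cc_a <- stand$age >= rs$clearcut_age[sp]
  cc <- if (rules$clearcut_combinator == "or") cc_d | cc_h | cc_a else cc_d & cc_h & cc_a
  thin <- stand$basal_area >= rs$thin_ba[sp]
  action <- ifelse(cc, "clearcut", ifelse(thin, "thinning", "none"))
  action[stand$land_class != "productive"] <- "none"
  action
}

#' Harvest scenario definition
#'
#' @param label one of NoHarv, LowHarv, BaseHarv, MaxHarv (target multipliers
#'   0, 0.6, 1.0, 1.2 on the historical base level).
#' @param projection_years years the scenario multiplier applies to.
#' @return list of class `fc_scenario` with `label` and `multiplier`.
#' @export
harvest_scenario <- function(label = c("BaseHarv", "NoHarv", "LowHarv", "MaxHarv"),
                             projection_years = 2022:2050) {
  label <- match.arg(label)
  mult <- c(NoHarv = 0, LowHarv = 0.6, BaseHarv = 1.0, MaxHarv = 1.2)[[label]]
  structure(list(label = label, multiplier = mult,
                 projection_years = projection_years),
            class = "fc_scenario")
}

#' Scenario target volume
#'
#' Target = scenario multiplier x base level, where the projection-period
#' base level is the 2015--2021 average of the statistics.
#'
#' @param base_level non-negative base harvest level.
#' @param scenario an [harvest_scenario()] or a scenario label.
#' @return the target level.
#' @export
scenario_targets <- function(base_level, scenario) {
  if (base_level < 0) stop("base_level must be >= 0", call. = FALSE)
  if (is.character(scenario)) scenario <- harvest_scenario(scenario)
  scenario$multiplier * base_level
}

#' Sample a country-level harvest target
#'
#' Normal with mean at the statistical or scenario level and standard
#' deviation 2% of the mean, truncated at zero; drawn per simulation-year
#' and wood type.
#'
#' @param mean_level non-negative mean target.
#' @param sd_frac standard deviation as a fraction of the mean.
#' @return one sampled target. Uses the current RNG state.
#' @export
sample_country_target <- function(mean_level, sd_frac = 0.02) {
  if (mean_level < 0) stop("mean_level must be >= 0", call. = FALSE)
  if (mean_level == 0) return(0)
  max(stats::rnorm(1, mean_level, sd_frac * mean_level), 0)
}

#' Allocate a country target to regions
#'
#' @param country_target country-level target volume.
#' @param shares regional historical shares, summing to 1.
#' @return vector of regional targets summing to the country target.
#' @export
allocate_country_to_regions <- function(country_target, shares) {
  if (abs(sum(shares) - 1) > 1e-9) {
    stop("regional shares must sum to 1", call. = FALSE)
  }
  shares * country_target
}

#' Allocate a regional harvest target over pixels
#'
#' Visits the eligible pixels in a uniformly random order, executing each
#' pixel's triggered action in full, and stops at the first pixel after
#' which the cumulative harvested volume (round wood + energy wood) reaches
#' the regional target; overshoot is bounded by that pixel's yield. If the
#' eligible pixels are exhausted first, the remainder is an explicit
#' shortfall and no further harvesting happens. Clearcut stemwood is round
#' wood; the energy-wood fraction of residues is energy wood; the remaining
#' residues go to the litter flux returned for the soil model.
#'
#' @param stand an `fc_stand`.
#' @param region_target regional target volume, m3 (round + energy jointly).
#' @param rules an [harvest_rules()].
#' @param rep_area_ha hectares each pixel represents (region area / sample
#'   size).
#' @param params an `fc_params`.
#' @return list of class `fc_harvest_outcome`: `stand` (post-harvest),
#'   `target`, `realized_round`, `realized_energy` (m3), `shortfall` (m3),
#'   `harvested_ids`, `actions`, and per-pixel vectors `harvested_c`
#'   (kgC ha-1 removed) and `residue_litter_c` (kgC ha-1 to litter).
#'   Uses the current RNG state for the permutation.
#' @export
allocate_regional_harvest <- function(stand, region_target, rules, rep_area_ha,
                                      params = default_parameter_set()) {
  if (region_target < 0) stop("region_target must be >= 0", call. = FALSE)
  cb <- params$crobas
  n <- nrow(stand)
  harvested_c <- numeric(n)
  residue_litter_c <- numeric(n)
  out <- list(stand = stand, target = region_target, realized_round = 0,
              realized_energy = 0, shortfall = max(0, region_target),
              harvested_ids = integer(0), actions = character(0),
              harvested_c = harvested_c, residue_litter_c = residue_litter_c)
  class(out) <- "fc_harvest_outcome"
  if (region_target == 0) return(out)

  action <- eligible_action(stand, rules)
  idx <- which(action != "none")
  if (length(idx) == 0) return(out)

  sp <- match(dominant_species(stand), rules$species$species)
  removal <- ifelse(action == "clearcut", 1, rules$species$thin_removal[sp])
  ef <- rules$energy_wood_fraction

  stem_c <- stand$stem_vol * cb[["c_per_m3"]]
  resid_c_full <- pmax(0, stand$tree_c - stem_c)
  round_vol <- removal * stand$stem_vol * rep_area_ha                 # m3
  energy_vol <- removal * ef * resid_c_full / cb[["c_per_m3"]] * rep_area_ha

  perm <- idx[sample.int(length(idx))]
  cum <- cumsum(round_vol[perm] + energy_vol[perm])
  k <- match(TRUE, cum >= region_target)
  if (is.na(k)) k <- length(perm)                                    # shortfall
  take <- perm[seq_len(k)]

  realized_round <- sum(round_vol[take])
  realized_energy <- sum(energy_vol[take])
  shortfall <- max(0, region_target - (realized_round + realized_energy))

  f <- removal[take]
  harvested_c[take] <- f * (stem_c[take] + ef * resid_c_full[take])
  residue_litter_c[take] <- f * (1 - ef) * resid_c_full[take]

  st <- stand
  st$tree_c[take] <- st$tree_c[take] - f * (stem_c[take] + resid_c_full[take])
  st$stem_vol[take] <- st$stem_vol[take] * (1 - f)
  st$basal_area[take] <- st$basal_area[take] * (1 - f)
  st$n_stems[take] <- st$n_stems[take] * (1 - f)

  cc <- take[action[take] == "clearcut"]
  if (length(cc)) {
    st$tree_c[cc] <- 0
    st$stem_vol[cc] <- 0
    st$basal_area[cc] <- 0
    st$dbh[cc] <- 0
    st$height[cc] <- 1.3
    st$age[cc] <- 0
    st$n_stems[cc] <- 2000
    st$gv_c[cc] <- st$gv_c[cc]        # ground vegetation persists
  }
  if (any(st$tree_c < -1e-6)) stop("harvest removed more carbon than standing stock",
                                   call. = FALSE)
  st$tree_c <- pmax(st$tree_c, 0)

  out$stand <- st
  out$realized_round <- realized_round
  out$realized_energy <- realized_energy
  out$shortfall <- shortfall
  out$harvested_ids <- take
  out$actions <- action[take]
  out$harvested_c <- harvested_c
  out$residue_litter_c <- residue_litter_c
  out
}
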