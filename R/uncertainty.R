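## Monte Carlo engine: samples every uncertainty element once per
## simulation, holds it fixed across regions and years (harvest-target
## deviates vary by year but not by region), and orchestrates the
## n_sim x scenario x region ensemble.

#' Sample initial stand age
#'
#' Normal with age-dependent standard deviation, sigma = 0.1 mu, truncated
#' at zero: the sampling law puts 95% of 100-year stands in about 80--120
#' years and of 10-year stands in about 8--12 years. A zero mean returns
#' zero.
#'
#' @param mean_age non-negative mean age(s), vectorised.
#' @return sampled ages. Uses the current RNG state.
#' @export
sample_initial_age <- function(mean_age) {
  if (any(mean_age < 0)) stop("mean_age must be >= 0", call. = FALSE)
  pmax(0, stats::rnorm(length(mean_age), mean_age, 0.1 * mean_age))
}

#' Default site-type confusion model
#'
#' Row-stochastic 5x5 matrix: the recorded class keeps `accuracy`
#' probability, the remainder splits over the adjacent classes (renormalised
#' at the edges).
#'
#' @param accuracy diagonal probability in (0,1\].
#' @return 5x5 matrix, rows = recorded class, columns = sampled class.
#' @export
default_confusion_matrix <- function(accuracy = 0.7) {
  m <- matrix(0, 5, 5)
  for (i in 1:5) {
    nb <- intersect(c(i - 1, i + 1), 1:5)
    m[i, i] <- accuracy
    m[i, nb] <- (1 - accuracy) / length(nb)
  }
  m
}

#' Resample pixel site types
#'
#' Draws a new fertility class for each pixel from a confusion distribution
#' conditioned on the recorded class and, optionally, the sampled stand
#' structure: structurally large stands (height, diameter, basal area above
#' the sample median, low pine share) tilt the row towards richer classes.
#' The draw happens once, at the start of a simulation, and the result is
#' held constant for the whole simulated period.
#'
#' @param site_type recorded classes (integer 1..5).
#' @param confusion_model row-stochastic 5x5 matrix.
#' @param structure optional data.frame with mean_height, mean_dbh,
#'   basal_area, prop_pine enabling the structural tilt.
#' @param tilt strength of the structural tilt (0 disables).
#' @return integer vector of sampled classes. Uses the current RNG state.
#' @export
sample_site_type <- function(site_type, confusion_model = default_confusion_matrix(),
                             structure = NULL, tilt = 0.3) {
  if (any(abs(rowSums(confusion_model) - 1) > 1e-9) || any(confusion_model < 0)) {
    stop("confusion model rows must be probability vectors", call. = FALSE)
  }
  n <- length(site_type)
  p <- confusion_model[site_type, , drop = FALSE]
  if (!is.null(structure) && tilt > 0) {
    size <- scale(0.4 * structure$mean_height + 0.3 * structure$mean_dbh +
                    0.3 * structure$basal_area)[, 1] - 0.5 * structure$prop_pine
    ## positive size score shifts mass towards class 1 (most fertile)
    w <- outer(size, 1:5, function(s, k) exp(-tilt * s * (k - 3)))
    p <- p * w
    p <- p / rowSums(p)
  }
  cum <- t(apply(p, 1, cumsum))
  u <- stats::runif(n)
  as.integer(rowSums(u > cum) + 1L)
}

#' Simulation configuration
#'
#' @param n_sim simulations per scenario grid (>= 1).
#' @param n_pixels mean pixels sampled per region and simulation; each
#'   region's sample size is proportional to its area share (floor 50).
#' @param years simulated calendar years (contiguous).
#' @param hist_years years driven by historical harvest statistics.
#' @param master_seed integer master seed; the engine derives one stream per
#'   simulation and one sub-stream per region from it.
#' @param spin_up_tolerance,spin_up_max_cycles soil spin-up control.
#' @param confusion_accuracy diagonal of the site-type confusion model.
#' @param reference_area_Mha forest area (million ha) the country harvest
#'   statistics refer to; converts statistic volumes to a harvest intensity
#'   applied to the synthetic landscape area.
#' @param rules an [harvest_rules()].
#' @param mortality_mode passed to [grow_stand()].
#' @return list of class `fc_sim_config`.
#' @export
simulation_config <- function(n_sim = 50, n_pixels = 500,
                              years = 2015:2050, hist_years = 2015:2021,
                              master_seed = 1L,
                              spin_up_tolerance = 1e-4,
                              spin_up_max_cycles = 300,
                              confusion_accuracy = 0.7,
                              reference_area_Mha = 20.3,
                              rules = harvest_rules(),
                              mortality_mode = "expected") {
  if (n_sim < 1) stop("n_sim must be >= 1", call. = FALSE)
  if (any(diff(years) != 1)) stop("years must be contiguous", call. = FALSE)
  structure(as.list(environment()), class = "fc_sim_config")
}

#' Scenario grid
#'
#' @param rcps RCP labels.
#' @param harvests harvest-scenario labels.
#' @return data.frame with one row per rcp x harvest combination.
#' @export
scenario_grid <- function(rcps = "RCP4.5",
                          harvests = c("NoHarv", "LowHarv", "BaseHarv", "MaxHarv")) {
  stopifnot(all(rcps %in% RCP_LABELS))
  expand.grid(rcp = rcps, harv = harvests, stringsAsFactors = FALSE,
              KEEP.OUT.ATTRS = FALSE)
}

#' Draw the per-simulation uncertainty bundle
#'
#' One GCM (uniform over the five), one row resampled with replacement from
#' each parameter pool, a crown-height factor ~ Normal(1, 0.1^2), an
#' emission-coefficient table draw, a peat carbon stock draw, and the
#' harvest-target deviates (standard-normal, per simulated year and wood
#' type). Everything is fixed for the whole simulation over all regions and
#' scenarios; only the harvest deviates vary by year.
#'
#' @param pools an `fc_pools`.
#' @param config an `fc_sim_config`.
#' @return list of class `fc_draw`. Uses the current RNG state.
#' @export
draw_simulation_settings <- function(pools, config) {
  if (any(vapply(pools[c("crobas", "preles", "yasso")], nrow, 1L) < 1)) {
    stop("parameter pools must be non-empty", call. = FALSE)
  }
  idx <- c(crobas = sample.int(nrow(pools$crobas), 1),
           preles = sample.int(nrow(pools$preles), 1),
           yasso = sample.int(nrow(pools$yasso), 1))
  ny <- length(config$years)
  structure(list(
    gcm = sample(GCM_LABELS, 1),
    idx = idx,
    params = parameter_set(pools, idx),
    crown_height_factor = stats::rnorm(1, 1, 0.1),
    emission_table = sample_emission_coefficients(),
    peat_stock = sample_peat_stock(),
    harvest_z = matrix(stats::rnorm(2 * ny), ny, 2,
                       dimnames = list(config$years, c("round", "energy")))
  ), class = "fc_draw")
}

## country target volumes (m3, scaled to the synthetic landscape area) for
## one year; identical across harvest scenarios during the historical period
country_targets_m3 <- function(year, scenario, stats, draw, config, landscape_area_ha) {
  iy <- as.character(year)
  z <- draw$harvest_z[iy, ]
  if (year %in% config$hist_years) {
    mr <- stats$round_wood[match(year, stats$years)]
    me <- stats$energy_wood[match(year, stats$years)]
  } else {
    mult <- harvest_scenario(scenario)$multiplier
    mr <- mult * mean(stats$round_wood)
    me <- mult * mean(stats$energy_wood)
  }
  intensity <- function(mm3, z1) {
    if (mm3 == 0) return(0)
    max(mm3 * (1 + 0.02 * z1), 0) * 1e6 / (config$reference_area_Mha * 1e6)
  }
  (intensity(mr, z[1]) + intensity(me, z[2])) * landscape_area_ha
}

## simulate one region under one scenario from prepared initial state
simulate_region_scenario <- function(stand0, pools0, weather, rcp, harv,
                                     draw, landscape, config, region_share,
                                     region_area_ha, landscape_area_ha) {
  params <- draw$params
  cb <- params$crobas
  years <- config$years
  n <- nrow(stand0)
  mineral <- stand0$soil_class == "mineral"
  organic <- !mineral
  ef <- organic_soil_emissions(stand0$site_type, draw$emission_table)
  ef$co2[mineral] <- 0; ef$ch4[mineral] <- 0; ef$n2o[mineral] <- 0
  ef_co2_c <- ef$co2 * 10 * 12 / 44        # gCO2 m-2 -> kgC ha-1
  rep_area <- region_area_ha / n

  st <- stand0
  pools <- pools0
  res <- vector("list", length(years))
  for (k in seq_along(years)) {
    y <- years[k]
    wy <- weather[weather$year == y, ]
    gpp <- annual_gpp(st, wy, params)
    step <- grow_stand(st, gpp, params, mortality_mode = config$mortality_mode)
    st <- step$stand

    country_t <- country_targets_m3(y, harv, landscape$harvest_stats, draw,
                                    config, landscape_area_ha)
    region_t <- region_share * country_t
    outcome <- allocate_regional_harvest(st, region_t, config$rules, rep_area,
                                         params)
    st <- outcome$stand

    litter_in <- step$flux$litter + step$flux$mort_litter +
      outcome$residue_litter_c
    rh <- numeric(n)
    soil_step <- mineral_soil_step(pools[mineral, , drop = FALSE],
                                   litter_in[mineral],
                                   list(mean_tair = mean(wy$tair)), params)
    pools[mineral, ] <- soil_step$pools
    rh[mineral] <- soil_step$respiration
    ## organic soils: static peat stock; litter passes through, the CO2
    ## emission coefficient replaces the dynamic soil flux
    rh[organic] <- litter_in[organic] + ef_co2_c[organic]

    nep <- (step$flux$npp - rh) / 10        # kgC ha-1 -> gC m-2
    soil_c <- numeric(n)
    soil_c[mineral] <- rowSums(pools[mineral, , drop = FALSE])
    soil_c[organic] <- draw$peat_stock
    harvested <- outcome$harvested_c        # kgC ha-1 per pixel

    m <- function(x) mean(x)
    nep_m <- m(nep); n2o_m <- m(ef$n2o); ch4_m <- m(ef$ch4)
    harv_m <- m(harvested)
    res[[k]] <- data.frame(
      year = y,
      nep = nep_m, nee = -nep_m, n2o = n2o_m, ch4 = ch4_m,
      gpp = m(step$flux$gpp), npp = m(step$flux$npp), rh = m(rh),
      tree_c = m(st$tree_c), gv_c = m(st$gv_c), soil_c = m(soil_c),
      ecosystem_c = m(st$tree_c + st$gv_c + soil_c),
      harvested_c = harv_m,
      nbe = compute_nbe(nep_m, harv_m, n2o_m, ch4_m),
      target_m3 = outcome$target, realized_m3 = outcome$realized_round +
        outcome$realized_energy, shortfall_m3 = outcome$shortfall)
  }
  do.call(rbind, res)
}

#' Run the Monte Carlo ensemble
#'
#' For each simulation: draws the uncertainty bundle once (GCM, parameter
#' rows, crown-height factor, emission coefficients, peat stock, harvest
#' deviates); per region draws an independent area-weighted pixel sample
#' with perturbed ages and resampled site types, initialises the stand and
#' spins up the mineral soil under historical weather and harvest pressure;
#' then simulates every scenario of the grid from that shared initial state
#' (historical statistics drive 2015--2021 identically across harvest
#' scenarios; scenario targets apply afterwards). Seeding is hierarchical
#' (master seed, per-simulation stream, per-region sub-stream), so results
#' are reproducible bit-for-bit and invariant to scenario order.
#'
#' @param landscape an `fc_landscape`.
#' @param scenarios a [scenario_grid()] data.frame (or a single
#'   [harvest_scenario()] label with default RCP4.5).
#' @param config an `fc_sim_config`.
#' @return list of class `fc_ensemble`: `outputs` (data.frame: rcp, harv,
#'   region, year, sim, output columns), `features` (one row per sim x
#'   region x scenario), `region_areas` (named, km2), `failed` (sim ids),
#'   `config`, `scenarios`.
#' @export
run_monte_carlo <- function(landscape, scenarios = scenario_grid(), config = simulation_config()) {
  if (is.character(scenarios)) scenarios <- scenario_grid(harvests = scenarios)
  stopifnot(inherits(landscape, "fc_landscape"), inherits(config, "fc_sim_config"))
  regions <- landscape$regions
  nr <- length(regions)
  region_ids <- vapply(regions, function(r) r$region_id, character(1))
  region_areas <- stats::setNames(
    vapply(regions, function(r) r$total_area_km2, numeric(1)), region_ids)
  landscape_area_ha <- sum(region_areas) * 100
  shares <- vapply(regions, function(r) r$harvest_share, numeric(1))
  confusion <- default_confusion_matrix(config$confusion_accuracy)
  ## pixel sample sizes proportional to region area (mean = config$n_pixels),
  ## so smaller regions carry more sampling uncertainty, as they should
  n_px <- pmax(50L, as.integer(round(
    config$n_pixels * nr * region_areas / sum(region_areas))))

  ## hierarchical seeds, all below 2^31
  set.seed(config$master_seed)
  sim_seeds <- sample.int(.Machine$integer.max - 1, config$n_sim)
  region_seeds <- matrix(sample.int(.Machine$integer.max - 1, config$n_sim * nr),
                         config$n_sim, nr)
  scen_seeds <- matrix(sample.int(.Machine$integer.max - 1, config$n_sim * nr),
                       config$n_sim, nr)

  ## historical weather for the spin-up (fixed, GCM-independent)
  hist_weather <- generate_weather(config$hist_years, "GFDL", "RCP4.5",
                                   seed = landscape$weather_seed + 7L,
                                   config = landscape$weather_config)
  hs <- landscape$harvest_stats
  hist_pressure <- 0.025 * (hs$round_wood + hs$energy_wood) /
    mean(hs$round_wood + hs$energy_wood)

  weather_cache <- new.env(parent = emptyenv())
  get_weather <- function(rcp, gcm) {
    key <- paste(rcp, gcm, sep = "|")
    if (is.null(weather_cache[[key]])) {
      weather_cache[[key]] <- generate_weather(config$years, gcm, rcp,
                                               seed = landscape$weather_seed,
                                               config = landscape$weather_config)
    }
    weather_cache[[key]]
  }

  outputs <- list()
  features <- list()
  failed <- integer(0)
  for (i in seq_len(config$n_sim)) {
    ok <- tryCatch({
      set.seed(sim_seeds[i])
      draw <- draw_simulation_settings(landscape$pools, config)
      feat_base <- c(
        list(sim = i, gcm = draw$gcm, crown_height_factor = draw$crown_height_factor),
        stats::setNames(as.list(draw$params$crobas),
                        paste0("pCrob_", names(draw$params$crobas))),
        stats::setNames(as.list(draw$params$preles),
                        paste0("pPrel_", names(draw$params$preles))),
        stats::setNames(as.list(draw$params$yasso),
                        paste0("pYas_", names(draw$params$yasso))),
        stats::setNames(as.list(draw$emission_table$value),
                        paste0("pECorg_et", 1:5)),
        list(pHarv_round = mean(draw$harvest_z[!rownames(draw$harvest_z) %in%
                                                 config$hist_years, "round"]),
             pHarv_energy = mean(draw$harvest_z[!rownames(draw$harvest_z) %in%
                                                  config$hist_years, "energy"])))
      for (r in seq_len(nr)) {
        set.seed(region_seeds[i, r])
        px <- sample_pixels(regions[[r]], n_px[r])
        px$mean_age <- sample_initial_age(px$mean_age)
        px$site_type <- sample_site_type(px$site_type, confusion, structure = px)
        stand0 <- initialize_stand(px, draw$crown_height_factor, draw$params)
        spun <- spin_up_soil(stand0, hist_weather, hist_pressure, draw$params,
                             tolerance = config$spin_up_tolerance,
                             max_cycles = config$spin_up_max_cycles)
        vol0 <- mean(stand0$stem_vol)
        age0 <- mean(stand0$age)
        for (s in seq_len(nrow(scenarios))) {
          rcp <- scenarios$rcp[s]; harv <- scenarios$harv[s]
          ## weather generation seeds its own stream; sequence it before the
          ## scenario stream so matched scenarios consume identical draws
          wth <- get_weather(rcp, draw$gcm)
          set.seed(scen_seeds[i, r])
          tab <- simulate_region_scenario(
            stand0, spun$pools, wth, rcp, harv,
            draw, landscape, config, shares[r],
            region_areas[r] * 100, landscape_area_ha)
          tab <- cbind(data.frame(rcp = rcp, harv = harv,
                                  region = region_ids[r], sim = i,
                                  stringsAsFactors = FALSE), tab)
          outputs[[length(outputs) + 1]] <- tab
          features[[length(features) + 1]] <- data.frame(
            c(list(rcp = rcp, harv = harv, region = region_ids[r],
                   vol0 = vol0, age0 = age0), feat_base),
            stringsAsFactors = FALSE)
        }
      }
      TRUE
    }, error = function(e) {
      message("simulation ", i, " failed: ", conditionMessage(e))
      FALSE
    })
    if (!ok) failed <- c(failed, i)
  }
  structure(list(outputs = do.call(rbind, outputs),
                 features = do.call(rbind, features),
                 region_areas = region_areas,
                 failed = failed,
                 config = config, scenarios = scenarios),
            class = "fc_ensemble")
}
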