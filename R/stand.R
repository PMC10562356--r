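## Surrogate annual stand carbon model.
##
## The process chain is: daily weather -> multiplicative light-use-efficiency
## GPP -> fixed-fraction autotrophic respiration -> NPP -> turnover litter,
## crowding (Reineke) and random mortality -> stem-carbon driven structural
## growth. It preserves the driver -> GPP -> allocation -> litter contract a
## regional uncertainty pipeline needs, not the internal physiology of a
## calibrated growth model.

#' Initialize stand states from segments
#'
#' Builds the per-pixel dynamic state from segment structure: crown height
#' from a linear height/diameter/species form scaled by the crown-height
#' factor, stem volume as basal area x height x a form factor reduced with
#' crown ratio, and tree carbon from stem volume via the carbon density per
#' stem volume and the stem fraction of whole-tree carbon.
#'
#' @param segments data.frame of segment rows (as from [sample_pixels()]),
#'   whose `mean_age` and `site_type` may already carry sampled perturbations.
#' @param crown_height_factor positive multiplier on the estimated crown height.
#' @param params an `fc_params`.
#' @return data.frame of class `fc_stand`, one row per pixel.
#' @export
initialize_stand <- function(segments, crown_height_factor = 1, params = default_parameter_set()) {
  if (crown_height_factor <= 0) {
    stop("crown_height_factor must be > 0", call. = FALSE)
  }
  cb <- params$crobas
  n <- nrow(segments)
  ba <- segments$basal_area
  h <- segments$mean_height
  dbh <- segments$mean_dbh

  crown_height <- crown_height_factor *
    pmax(0, 0.40 * h + 0.03 * dbh - 1.2 * segments$prop_spruce + 0.6)
  crown_ratio <- ifelse(h > 0, pmin(1, crown_height / pmax(h, 1e-9)), 0)
  form_eff <- cb[["form_factor"]] * (1 - 0.25 * crown_ratio)
  stem_vol <- ba * h * form_eff                       # m3 ha-1
  stem_c <- stem_vol * cb[["c_per_m3"]]               # kgC ha-1
  tree_c <- stem_c / cb[["stem_frac"]]

  n_stems <- ifelse(dbh > 0.5, ba / (pi * (dbh / 200)^2), 2000)
  light <- exp(-params$preles[["k_light"]] * ba)
  gv_c <- ground_vegetation_biomass(segments$site_type, light, params)

  out <- data.frame(
    pixel_id = seq_len(n),
    tree_c = tree_c, gv_c = gv_c,
    basal_area = ba, dbh = dbh, height = h,
    age = segments$mean_age,
    prop_pine = segments$prop_pine, prop_spruce = segments$prop_spruce,
    prop_birch = segments$prop_birch,
    stem_vol = stem_vol, n_stems = n_stems,
    crown_height = crown_height, crown_ratio = crown_ratio,
    site_type = segments$site_type,
    soil_class = segments$soil_class, land_class = segments$land_class,
    stringsAsFactors = FALSE)
  class(out) <- c("fc_stand", "data.frame")
  out
}

#' Ground vegetation biomass
#'
#' Equilibrium ground-vegetation carbon as a function of site fertility class
#' and below-canopy light: a fertility-dependent ceiling approached as a
#' concave function of light, above a fixed floor.
#'
#' @param site_type integer 1..5 (1 = most fertile), vectorised.
#' @param below_canopy_light light fraction in \[0,1\], vectorised.
#' @param params an `fc_params` (uses the growth-pool `gv_max` ceiling).
#' @return biomass, kgC ha-1.
#' @export
ground_vegetation_biomass <- function(site_type, below_canopy_light,
                                      params = default_parameter_set()) {
  if (any(below_canopy_light < 0 | below_canopy_light > 1)) {
    stop("below_canopy_light must be in [0, 1]", call. = FALSE)
  }
  if (any(!site_type %in% 1:5)) stop("site_type must be in 1..5", call. = FALSE)
  gv_min <- 100
  site_scale <- c(1, 0.85, 0.7, 0.5, 0.33)[site_type]
  gv_min + (params$crobas[["gv_max"]] * site_scale - gv_min) * below_canopy_light^0.7
}

## daily weather -> scalar driver sum shared by all pixels of a region-year
gpp_driver_sum <- function(weather_year, pp) {
  if (nrow(weather_year) != 365) {
    stop("weather year must have exactly 365 days", call. = FALSE)
  }
  f_temp <- pmin(1, pmax(0, (weather_year$tair - pp[["t_min"]]) /
                            (pp[["t_sat"]] - pp[["t_min"]])))
  f_vpd <- exp(-pp[["k_vpd"]] * pmax(0, weather_year$vpd))
  f_co2 <- (weather_year$co2 / (weather_year$co2 + pp[["k_co2"]]))
  ## soft water modifier from exponentially smoothed precipitation
  s <- as.numeric(stats::filter(0.1 * weather_year$precip, 0.9,
                                method = "recursive",
                                init = mean(weather_year$precip)))
  f_water <- s / (s + pp[["w0"]])
  sum(weather_year$rad * f_temp * f_vpd * f_co2 * f_water)
}

#' Annual gross primary production
#'
#' GPP = light-use efficiency x absorbed-light fraction x the annual sum of
#' daily radiation times multiplicative modifiers (temperature ramp, VPD
#' exponential decay, saturating CO2 response, soft water modifier from
#' smoothed precipitation), all modifiers in \[0,1\]. The daily driver part is
#' common to all pixels of a region; only the canopy absorption differs.
#'
#' @param stand an `fc_stand`.
#' @param weather_year 365-day slice of an `fc_weather`.
#' @param params an `fc_params`.
#' @return per-pixel GPP, kgC ha-1 yr-1 (vector).
#' @export
annual_gpp <- function(stand, weather_year, params) {
  pp <- params$preles
  S <- gpp_driver_sum(weather_year, pp)           # MJ m-2 yr-1, modifier-weighted
  fapar <- 1 - exp(-pp[["k_light"]] * stand$basal_area)
  ## regeneration floor: seedlings and ground flora keep a clearcut pixel alive
  fapar <- pmax(fapar, 0.05)
  pp[["lue"]] * fapar * S * 10                    # gC m-2 -> kgC ha-1
}

## invert V = BA * h(BA) * form for BA by fixed-point iteration; h from dbh
## allometry with stem count fixed, so the map is monotone and contracts fast
solve_structure <- function(stem_vol, n_stems, crown_ratio, cb, ba_start) {
  crown_ratio <- pmin(1, pmax(0, crown_ratio))
  form_eff <- cb[["form_factor"]] * (1 - 0.25 * crown_ratio)
  ba <- pmax(ba_start, 0.05)
  for (k in 1:6) {
    dbh <- 200 * sqrt(ba / (pi * pmax(n_stems, 1)))
    h <- 1.3 + cb[["height_coef"]] * dbh^0.85
    ba <- stem_vol / (h * form_eff)
  }
  dbh <- 200 * sqrt(ba / (pi * pmax(n_stems, 1)))
  h <- 1.3 + cb[["height_coef"]] * dbh^0.85
  list(basal_area = ba, dbh = dbh, height = h)
}

#' Advance a stand one year
#'
#' Allocates GPP to autotrophic respiration and NPP, routes turnover litter
#' and mortality litter (Reineke crowding above the density ceiling
#' `reineke_intercept * dbh^-reineke_slope`, plus a small random-mortality
#' loss, expected-value mode by default), grows structure from the allocated
#' stemwood carbon, and updates ground vegetation towards its light- and
#' fertility-dependent equilibrium. The annual carbon identity
#' `delta(tree C + ground vegetation C) = NPP - litter - mortality litter`
#' holds exactly; harvest removals are applied separately by the management
#' layer.
#'
#' @param stand an `fc_stand`.
#' @param gpp per-pixel GPP, kgC ha-1 yr-1 (from [annual_gpp()]).
#' @param params an `fc_params`.
#' @param mortality_mode `"expected"` (deterministic fractional loss) or
#'   `"bernoulli"` (whole-pixel random death at the same rate).
#' @return list with the advanced `stand` and `flux`, a data.frame of
#'   per-pixel gpp, ra, npp, litter, mort_litter (kgC ha-1 yr-1).
#' @export
grow_stand <- function(stand, gpp, params, mortality_mode = c("expected", "bernoulli")) {
  if (any(gpp < 0)) stop("gpp must be non-negative", call. = FALSE)
  mortality_mode <- match.arg(mortality_mode)
  cb <- params$crobas
  n <- nrow(stand)

  ## ground vegetation: relax towards equilibrium; production is its own NPP
  light <- exp(-params$preles[["k_light"]] * stand$basal_area)
  gv_target <- ground_vegetation_biomass(stand$site_type, light, params)
  gv_turn <- 0.25
  gv_litter <- gv_turn * stand$gv_c
  gv_npp <- pmax(0, gv_target - stand$gv_c + gv_litter)
  gv_new <- stand$gv_c + gv_npp - gv_litter
  gv_gpp <- gv_npp / (1 - cb[["resp_frac"]])

  gpp_tot <- gpp + gv_gpp
  ra <- cb[["resp_frac"]] * gpp_tot
  npp <- gpp_tot - ra
  tree_npp <- npp - gv_npp

  litterfall <- cb[["litter_turnover"]] * stand$tree_c

  ## mortality: crowding + random
  n_max <- cb[["reineke_intercept"]] * pmax(stand$dbh, 1)^(-cb[["reineke_slope"]])
  crowd_frac <- pmax(0, 1 - n_max / pmax(stand$n_stems, 1e-9))
  crowd_frac[stand$n_stems <= n_max] <- 0
  rand_frac <- if (mortality_mode == "expected") {
    rep(cb[["mort_rate"]], n)
  } else {
    as.numeric(stats::runif(n) < cb[["mort_rate"]])
  }
  mort_frac <- pmin(0.95, crowd_frac + rand_frac)
  mort_litter <- mort_frac * stand$tree_c

  tree_raw <- stand$tree_c + tree_npp - litterfall - mort_litter
  tree_new <- pmax(tree_raw, 0)
  ## fractional losses are < 1 so tree_raw stays non-negative; if numerical
  ## noise ever floors it, shrink litter by the same amount (no carbon vanishes)
  litterfall <- litterfall - (tree_new - tree_raw)

  ## structure from stem carbon: stems shrink with mortality, stem volume
  ## follows the stem share of new growth; turnover litter is non-stem tissue
  n_stems_new <- stand$n_stems * (1 - mort_frac)
  d_stem_c <- cb[["alloc_stem"]] * tree_npp
  stem_vol_new <- pmax(0, stand$stem_vol * (1 - mort_frac) +
                          d_stem_c / cb[["c_per_m3"]])
  geo <- solve_structure(stem_vol_new, n_stems_new, stand$crown_ratio, cb,
                         stand$basal_area)

  out <- stand
  out$tree_c <- tree_new
  out$gv_c <- gv_new
  out$stem_vol <- stem_vol_new
  out$n_stems <- n_stems_new
  out$basal_area <- geo$basal_area
  out$dbh <- geo$dbh
  out$height <- geo$height
  out$crown_height <- out$crown_ratio * geo$height
  out$age <- stand$age + 1

  flux <- data.frame(gpp = gpp_tot, ra = ra, npp = npp,
                     litter = litterfall + gv_litter,
                     mort_litter = mort_litter)
  list(stand = out, flux = flux)
}
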