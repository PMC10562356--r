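#' @keywords internal
"_PACKAGE"

GCM_LABELS <- c("CanESM2", "CNRM", "GFDL", "HadGEM2", "MIROC")
RCP_LABELS <- c("RCP2.6", "RCP4.5", "RCP8.5")
SOIL_CLASSES <- c("mineral", "drained_organic")
LAND_CLASSES <- c("productive", "poorly_productive", "protected")

#' Region generation settings
#'
#' Bundles the targets a synthetic region is generated around: segment count,
#' mean basal area and age, the regional species mixture, the share of
#' drained organic soils and of non-harvestable land, and the segment-area
#' distribution. Segment areas follow a truncated log-normal (right-skewed,
#' like real stand mosaics) bounded to the observed national extremes
#' 0.026--540 ha with a median near 0.8 ha.
#'
#' @param n_segments number of segments to generate.
#' @param mean_basal_area target mean basal area, m2 ha-1.
#' @param mean_age target mean stand age, years.
#' @param species_mix named fractions (pine, spruce, birch) summing to 1.
#' @param organic_fraction expected fraction of segments on drained organic soil.
#' @param protected_fraction expected fraction of protected segments.
#' @param poorly_productive_fraction expected fraction of poorly productive segments.
#' @param area_meanlog,area_sdlog log-normal parameters of segment area (ha).
#' @param area_bounds truncation bounds of segment area (ha).
#' @param site_type_probs probabilities of site fertility classes 1..5.
#' @param region_id,name identifiers carried onto the region.
#' @param harvest_share region's share of the country harvest (set by the
#'   landscape builder; defaults to 1 for a stand-alone region).
#' @return a list of class `fc_region_config`.
#' @export
region_config <- function(n_segments = 1000,
                          mean_basal_area = 16,
                          mean_age = 56,
                          species_mix = c(pine = 0.50, spruce = 0.33, birch = 0.17),
                          organic_fraction = 0.10,
                          protected_fraction = 0.05,
                          poorly_productive_fraction = 0.05,
                          area_meanlog = log(0.8),
                          area_sdlog = 1.1,
                          area_bounds = c(0.026, 540),
                          site_type_probs = c(0.10, 0.25, 0.35, 0.22, 0.08),
                          region_id = "R1",
                          name = "Synthetic region",
                          harvest_share = 1) {
  if (abs(sum(species_mix) - 1) > 1e-9) {
    stop("species_mix proportions must sum to 1", call. = FALSE)
  }
  if (n_segments < 0) stop("n_segments must be >= 0", call. = FALSE)
  structure(as.list(environment()), class = "fc_region_config")
}

rdirichlet1 <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Generate a synthetic forest region
#'
#' Draws a population of homogeneous forest segments with the statistical
#' structure of segmented national-forest-inventory data: right-skewed areas,
#' basal area and age around regional means, Dirichlet species proportions
#' around the regional mixture, ordinal site fertility classes 1..5, a
#' mineral / drained-organic soil split and a land-class split.
#'
#' @param config a [region_config()].
#' @param seed integer seed; generation is bit-reproducible for a fixed seed.
#' @return a list of class `fc_region` with elements `region_id`, `name`,
#'   `segments` (a data.frame, one row per segment), `total_area_km2`,
#'   `harvest_share`.
#' @export
generate_region <- function(config, seed = 1L) {
  stopifnot(inherits(config, "fc_region_config"))
  n <- config$n_segments
  if (n == 0) stop("cannot generate an empty region (n_segments = 0)", call. = FALSE)
  set.seed(seed)

  ## truncated log-normal areas (rejection; the bounds are far in the tails)
  area <- stats::rlnorm(n, config$area_meanlog, config$area_sdlog)
  bad <- area < config$area_bounds[1] | area > config$area_bounds[2]
  while (any(bad)) {
    area[bad] <- stats::rlnorm(sum(bad), config$area_meanlog, config$area_sdlog)
    bad <- area < config$area_bounds[1] | area > config$area_bounds[2]
  }

  ## age and basal area: gamma marginals around the regional means, cv 0.45
  cv <- 0.45
  age <- stats::rgamma(n, shape = 1 / cv^2, scale = config$mean_age * cv^2)
  ba <- stats::rgamma(n, shape = 1 / cv^2, scale = config$mean_basal_area * cv^2)

  ## structure loosely tied to age; floors keep young stands plausible
  height <- pmin(32, 1.3 + 0.30 * age * exp(stats::rnorm(n, 0, 0.15)))
  dbh <- pmax(0, height * stats::runif(n, 1.0, 1.4) - 1)

  sp <- rdirichlet1(n, 8 * pmax(config$species_mix, 1e-6))
  site_type <- sample.int(5, n, replace = TRUE, prob = config$site_type_probs)
  soil_class <- ifelse(stats::runif(n) < config$organic_fraction,
                       "drained_organic", "mineral")
  u <- stats::runif(n)
  land_class <- ifelse(u < config$protected_fraction, "protected",
                ifelse(u < config$protected_fraction + config$poorly_productive_fraction,
                       "poorly_productive", "productive"))

  segments <- data.frame(
    segment_id = sprintf("%s_s%06d", config$region_id, seq_len(n)),
    area = area,
    basal_area = ba,
    mean_dbh = dbh,
    mean_height = height,
    mean_age = age,
    prop_pine = sp[, 1],
    prop_spruce = sp[, 2],
    prop_birch = sp[, 3],
    site_type = as.integer(site_type),
    soil_class = soil_class,
    land_class = land_class,
    stringsAsFactors = FALSE
  )
  region <- structure(
    list(region_id = config$region_id,
         name = config$name,
         segments = segments,
         total_area_km2 = sum(area) / 100,
         harvest_share = config$harvest_share),
    class = "fc_region")
  validate_region(region)
  region
}

#' Validate a region object
#'
#' Checks the segment-level invariants (positive areas, species proportions in
#' \[0,1\] summing to 1, integer site types in 1..5, known soil and land
#' classes) and the region-level area bookkeeping.
#'
#' @param region an `fc_region`.
#' @return the region, invisibly; errors describe the violated invariant.
#' @export
validate_region <- function(region) {
  s <- region$segments
  if (nrow(s) == 0) stop("region has no segments", call. = FALSE)
  if (any(s$area <= 0)) stop("segment areas must be > 0", call. = FALSE)
  p <- s$prop_pine + s$prop_spruce + s$prop_birch
  if (any(abs(p - 1) > 1e-9)) stop("species proportions must sum to 1", call. = FALSE)
  if (any(s$prop_pine < 0 | s$prop_spruce < 0 | s$prop_birch < 0)) {
    stop("species proportions must be in [0,1]", call. = FALSE)
  }
  if (any(s$site_type %% 1 != 0 | s$site_type < 1 | s$site_type > 5)) {
    stop("site_type must be an integer in 1..5", call. = FALSE)
  }
  if (!all(s$soil_class %in% SOIL_CLASSES)) stop("unknown soil_class", call. = FALSE)
  if (!all(s$land_class %in% LAND_CLASSES)) stop("unknown land_class", call. = FALSE)
  if (abs(region$total_area_km2 - sum(s$area) / 100) > 1e-3 * region$total_area_km2) {
    stop("total_area_km2 inconsistent with segment areas", call. = FALSE)
  }
  invisible(region)
}

#' Sample pixels from a region with area weights
#'
#' Draws `n_pixels` segment references with replacement, each segment selected
#' with probability proportional to its area, emulating a representative
#' pixel sample of the regional forest area.
#'
#' @param region an `fc_region`.
#' @param n_pixels number of pixels (>= 0).
#' @return a data.frame of `n_pixels` segment rows (repeats allowed). Uses the
#'   current RNG state; seed upstream for reproducibility.
#' @export
sample_pixels <- function(region, n_pixels) {
  if (n_pixels == 0) return(region$segments[0, , drop = FALSE])
  s <- region$segments
  if (nrow(s) == 0) stop("cannot sample pixels from an empty region", call. = FALSE)
  idx <- sample.int(nrow(s), n_pixels, replace = TRUE, prob = s$area)
  out <- s[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Weather generation settings
#'
#' The generator is a sinusoidal seasonal cycle with AR(1) daily noise and a
#' linear climate trend. RCPs differ in warming slope and CO2 trajectory,
#' GCMs in a level offset and a slope multiplier, so an ensemble spreads the
#' way a multi-model climate ensemble does.
#'
#' @param t_mean,t_amp mean annual temperature and seasonal amplitude, deg C.
#' @param t_noise_sd,t_noise_ar daily temperature AR(1) noise sd and coefficient.
#' @param rad_mean,rad_amp daily radiation mean and seasonal amplitude, MJ m-2 d-1.
#' @param precip_prob,precip_mean wet-day probability and mean wet-day depth, mm.
#' @param trend_onset first year the RCP trend applies.
#' @param warming_slopes named warming slopes per RCP, deg C per year.
#' @param co2_slopes named CO2 growth per RCP, ppm per year.
#' @param co2_base ambient CO2 at the first simulation year, ppm.
#' @param gcm_offsets,gcm_slope_mult named per-GCM temperature offsets (deg C)
#'   and warming-slope multipliers.
#' @return list of class `fc_weather_config`.
#' @export
weather_config <- function(t_mean = 3.5, t_amp = 13,
                           t_noise_sd = 2.8, t_noise_ar = 0.7,
                           rad_mean = 10.5, rad_amp = 9.8,
                           precip_prob = 0.45, precip_mean = 4.0,
                           trend_onset = 2020,
                           warming_slopes = c("RCP2.6" = 0.010,
                                              "RCP4.5" = 0.030,
                                              "RCP8.5" = 0.060),
                           co2_slopes = c("RCP2.6" = 0.4,
                                          "RCP4.5" = 1.9,
                                          "RCP8.5" = 3.6),
                           co2_base = 400,
                           gcm_offsets = c(CanESM2 = 0.8, CNRM = -0.4, GFDL = 0,
                                           HadGEM2 = 1.2, MIROC = -0.8),
                           gcm_slope_mult = c(CanESM2 = 1.15, CNRM = 0.90, GFDL = 1.0,
                                              HadGEM2 = 1.25, MIROC = 0.85)) {
  structure(as.list(environment()), class = "fc_weather_config")
}

#' Generate daily scenario weather
#'
#' Produces a deterministic (for fixed seed and labels) daily weather series
#' of radiation, air temperature, vapour pressure deficit, precipitation and
#' ambient CO2 for one GCM x RCP combination over the requested years.
#'
#' @param years vector of calendar years (non-empty).
#' @param gcm one of CanESM2, CNRM, GFDL, HadGEM2, MIROC.
#' @param rcp one of RCP2.6, RCP4.5, RCP8.5.
#' @param seed integer seed.
#' @param config a [weather_config()].
#' @return data.frame of class `fc_weather` with columns year, doy, rad
#'   (MJ m-2 d-1), tair (deg C), vpd (kPa), precip (mm d-1), co2 (ppm);
#'   attributes `gcm` and `rcp`.
#' @export
generate_weather <- function(years, gcm, rcp, seed = 1L, config = weather_config()) {
  if (length(years) == 0) stop("years must be non-empty", call. = FALSE)
  if (!gcm %in% GCM_LABELS) stop("unknown gcm label: ", gcm, call. = FALSE)
  if (!rcp %in% RCP_LABELS) stop("unknown rcp label: ", rcp, call. = FALSE)
  ## label-specific deterministic stream
  set.seed(as.integer((seed * 97 + match(gcm, GCM_LABELS) * 131 +
                         match(rcp, RCP_LABELS) * 17) %% .Machine$integer.max))
  cfg <- config
  nd <- 365L
  ny <- length(years)
  doy <- rep(seq_len(nd), ny)
  year <- rep(years, each = nd)
  season <- sin(2 * pi * (doy - 105) / 365)

  ar1 <- function(n, sd, phi) {
    as.numeric(stats::filter(stats::rnorm(n, 0, sd * sqrt(1 - phi^2)),
                             phi, method = "recursive"))
  }
  n <- nd * ny
  dyrs <- pmax(0, year - cfg$trend_onset)
  warm <- cfg$warming_slopes[[rcp]] * cfg$gcm_slope_mult[[gcm]] * dyrs +
    cfg$gcm_offsets[[gcm]]
  tair <- cfg$t_mean + cfg$t_amp * season + warm + ar1(n, cfg$t_noise_sd, cfg$t_noise_ar)
  rad <- pmax(0, cfg$rad_mean + cfg$rad_amp * season + ar1(n, 1.6, 0.5))
  vpd <- pmax(0, 0.12 + 0.030 * tair + ar1(n, 0.10, 0.4))
  precip <- stats::rbinom(n, 1, cfg$precip_prob) * stats::rexp(n, 1 / cfg$precip_mean)
  co2 <- cfg$co2_base + cfg$co2_slopes[[rcp]] * pmax(0, year - min(2015, min(years)))

  out <- data.frame(year = year, doy = doy, rad = rad, tair = tair,
                    vpd = vpd, precip = precip, co2 = co2)
  attr(out, "gcm") <- gcm
  attr(out, "rcp") <- rcp
  class(out) <- c("fc_weather", "data.frame")
  out
}

#' Generate country harvest statistics
#'
#' Emulates the realised national harvest statistics of 2015--2021: annual
#' round-wood removals inside configurable bounds (default 68--78 Mm3 yr-1)
#' and energy-wood removals inside 7.2--10.2 Mm3 yr-1, plus regional
#' historical shares (normalised weights).
#'
#' @param seed integer seed.
#' @param years statistic years.
#' @param round_wood_bounds,energy_wood_bounds bounds in Mm3 yr-1.
#' @param region_weights positive weights, one per region (default: one region).
#' @return list of class `fc_harvest_stats` with `years`, `round_wood`,
#'   `energy_wood` (Mm3 yr-1) and `shares` (sum to 1).
#' @export
generate_harvest_statistics <- function(seed = 1L, years = 2015:2021,
                                        round_wood_bounds = c(68, 78),
                                        energy_wood_bounds = c(7.2, 10.2),
                                        region_weights = 1) {
  set.seed(seed)
  ny <- length(years)
  structure(list(
    years = years,
    round_wood = stats::runif(ny, round_wood_bounds[1], round_wood_bounds[2]),
    energy_wood = stats::runif(ny, energy_wood_bounds[1], energy_wood_bounds[2]),
    shares = region_weights / sum(region_weights)
  ), class = "fc_harvest_stats")
}

## generator means/sds and support bounds for the three posterior-like pools
pool_spec <- function() {
  list(
    crobas = data.frame(
      name = c("resp_frac", "alloc_stem", "stem_frac", "litter_turnover",
               "mort_rate", "reineke_intercept", "reineke_slope",
               "form_factor", "c_per_m3", "height_coef", "gv_max"),
      mean = c(0.50, 0.35, 0.65, 0.022, 0.008, 175000, 1.605, 0.45, 195, 1.10, 1800),
      sd   = c(0.030, 0.030, 0.040, 0.0035, 0.0020, 15000, 0.050, 0.030, 10, 0.080, 220),
      lo   = c(0.20, 0.10, 0.30, 1e-4, 0, 5e4, 1.2, 0.20, 120, 0.5, 400),
      hi   = c(0.70, 0.60, 0.90, 0.08, 0.05, 4e5, 2.0, 0.70, 280, 2.0, 4000)),
    preles = data.frame(
      name = c("lue", "t_min", "t_sat", "k_vpd", "k_co2", "w0", "k_light"),
      mean = c(0.95, -4.0, 14.0, 0.35, 300, 0.70, 0.13),
      sd   = c(0.080, 0.70, 1.20, 0.050, 30, 0.10, 0.010),
      lo   = c(0.3, -10, 5, 0.01, 50, 0.05, 0.03),
      hi   = c(2.5, 2, 25, 1.0, 800, 3.0, 0.4)),
    yasso = data.frame(
      name = c("k_fast", "k_slow", "k_humus", "t_fast_slow", "t_slow_humus", "q10"),
      mean = c(0.45, 0.045, 0.0045, 0.25, 0.06, 1.8),
      sd   = c(0.060, 0.0060, 0.0008, 0.040, 0.010, 0.15),
      lo   = c(0.05, 0.005, 5e-4, 0, 0, 1.0),
      hi   = c(1.5, 0.5, 0.05, 0.8, 0.5, 3.5))
  )
}

#' Generate posterior-like parameter pools
#'
#' Builds the three parameter populations (growth model, photosynthesis
#' model, soil model) that the Monte Carlo engine resamples with replacement.
#' Each pool is a matrix of correlated multivariate-normal vectors (pairwise
#' correlation 0.3 inside a pool) clamped to physical support bounds,
#' emulating calibrated posterior samples.
#'
#' @param n_per_pool number of vectors per pool (>= 1).
#' @param seed integer seed.
#' @return list of class `fc_pools` with matrices `crobas`, `preles`,
#'   `yasso` (rows = samples, named columns) and the generator spec as
#'   attribute `spec`.
#' @export
generate_parameter_pools <- function(n_per_pool = 300, seed = 1L) {
  if (n_per_pool < 1) stop("n_per_pool must be >= 1", call. = FALSE)
  set.seed(seed)
  spec <- pool_spec()
  draw_pool <- function(sp) {
    p <- nrow(sp)
    R <- matrix(0.3, p, p); diag(R) <- 1
    L <- chol(R)
    z <- matrix(stats::rnorm(n_per_pool * p), n_per_pool, p) %*% L
    x <- sweep(sweep(z, 2, sp$sd, `*`), 2, sp$mean, `+`)
    x <- pmin(pmax(x, matrix(sp$lo, n_per_pool, p, byrow = TRUE)),
              matrix(sp$hi, n_per_pool, p, byrow = TRUE))
    colnames(x) <- sp$name
    x
  }
  structure(list(crobas = draw_pool(spec$crobas),
                 preles = draw_pool(spec$preles),
                 yasso = draw_pool(spec$yasso)),
            spec = spec, class = "fc_pools")
}

#' Assemble a parameter set from pool rows
#'
#' @param pools an `fc_pools`.
#' @param idx named or positional list/vector of row indices
#'   (crobas, preles, yasso).
#' @return list of class `fc_params` with named-vector elements `crobas`,
#'   `preles`, `yasso` and the row ids in `ids`.
#' @export
parameter_set <- function(pools, idx = c(crobas = 1L, preles = 1L, yasso = 1L)) {
  structure(list(crobas = pools$crobas[idx[["crobas"]], ],
                 preles = pools$preles[idx[["preles"]], ],
                 yasso = pools$yasso[idx[["yasso"]], ],
                 ids = idx),
            class = "fc_params")
}

#' Pool-mean parameter set
#'
#' Deterministic parameter set at the generator means; useful as a baseline
#' and in worked examples.
#' @return an `fc_params`.
#' @export
default_parameter_set <- function() {
  spec <- pool_spec()
  structure(list(crobas = stats::setNames(spec$crobas$mean, spec$crobas$name),
                 preles = stats::setNames(spec$preles$mean, spec$preles$name),
                 yasso = stats::setNames(spec$yasso$mean, spec$yasso$name),
                 ids = c(crobas = NA, preles = NA, yasso = NA)),
            class = "fc_params")
}

#' Generate a complete synthetic landscape
#'
#' Convenience builder for the full study setting: several regions spanning
#' the observed national ranges of mean basal area (11--18 m2 ha-1) and mean
#' age (44--91 y) along a south--north gradient, country harvest statistics
#' with area-informed regional shares, and the three parameter pools.
#'
#' @param n_regions number of regions (default 4, the test-scale layout; any
#'   count up to 18 gradients the same way).
#' @param segments_per_region segments in each region. A scalar is scaled by
#'   region (factors 0.5x to 2x along the gradient) so region areas are
#'   heterogeneous; a vector is used as given.
#' @param seed integer master seed.
#' @param n_pool parameter-pool size.
#' @return list of class `fc_landscape`: `regions` (list of `fc_region`),
#'   `harvest_stats`, `pools`, `weather_config`, `weather_seed`.
#' @export
generate_landscape <- function(n_regions = 4, segments_per_region = 1000,
                               seed = 1L, n_pool = 300) {
  ## south (fertile, spruce-rich) -> north (poor, pine-rich) gradient
  g <- if (n_regions == 1) 0 else (seq_len(n_regions) - 1) / (n_regions - 1)
  if (length(segments_per_region) == 1) {
    ## heterogeneous region sizes, growing northwards (as the real layout does)
    segments_per_region <- pmax(50L, as.integer(round(
      segments_per_region * (0.5 + 1.5 * g))))
  }
  segments_per_region <- rep_len(segments_per_region, n_regions)
  ba <- 17 - 5 * g          # 17 .. 12 m2/ha
  age <- 50 + 35 * g        # 50 .. 85 y
  pine <- 0.40 + 0.30 * g
  spruce <- 0.42 - 0.30 * g
  organic <- 0.06 + 0.14 * g
  regions <- vector("list", n_regions)
  for (i in seq_len(n_regions)) {
    cfg <- region_config(
      n_segments = segments_per_region[i],
      mean_basal_area = ba[i], mean_age = age[i],
      species_mix = c(pine = pine[i], spruce = spruce[i],
                      birch = 1 - pine[i] - spruce[i]),
      organic_fraction = organic[i],
      region_id = sprintf("%02d", i),
      name = sprintf("Synthetic region %02d", i))
    regions[[i]] <- generate_region(cfg, seed = seed + i)
  }
  areas <- vapply(regions, function(r) r$total_area_km2, numeric(1))
  ## harvest intensity per area declines northwards
  wts <- areas * (1.3 - 0.6 * g)
  stats <- generate_harvest_statistics(seed = seed + 1000L, region_weights = wts)
  for (i in seq_len(n_regions)) regions[[i]]$harvest_share <- stats$shares[i]
  structure(list(regions = regions,
                 harvest_stats = stats,
                 pools = generate_parameter_pools(n_pool, seed = seed + 2000L),
                 weather_config = weather_config(),
                 weather_seed = seed + 3000L),
            class = "fc_landscape")
}

#' Write / read a segment table as CSV
#'
#' @param region an `fc_region`.
#' @param path output file.
#' @return `write_segments`: the path, invisibly. `read_segments`: a
#'   data.frame of segments.
#' @export
write_segments <- function(region, path) {
  utils::write.csv(region$segments, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
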