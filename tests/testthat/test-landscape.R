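test_that("generated regions satisfy segment and region invariants", {
  cfg <- region_config(n_segments = 2000, mean_basal_area = 16, mean_age = 56)
  r <- generate_region(cfg, seed = 3)
  s <- r$segments
  expect_true(all(s$area >= 0.026 & s$area <= 540))
  expect_true(all(abs(s$prop_pine + s$prop_spruce + s$prop_birch - 1) < 1e-9))
  expect_true(all(s$site_type %in% 1:5))
  expect_equal(r$total_area_km2, sum(s$area) / 100)
  # right-skewed areas
  expect_gt(mean(s$area), median(s$area))
})

test_that("regional means hit configured targets at n = 5000", {
  r <- generate_region(region_config(n_segments = 5000, mean_basal_area = 16,
                                     mean_age = 56), seed = 1)
  expect_gt(mean(r$segments$basal_area), 15)
  expect_lt(mean(r$segments$basal_area), 17)
  expect_gt(mean(r$segments$mean_age), 53)
  expect_lt(mean(r$segments$mean_age), 59)
})

test_that("organic-soil fraction recovers the configured rate", {
  r <- generate_region(region_config(n_segments = 1e4, organic_fraction = 0.3),
                       seed = 5)
  frac <- mean(r$segments$soil_class == "drained_organic")
  expect_lt(abs(frac - 0.3), 0.02)  # ~4 binomial sd at n = 1e4
})

test_that("degenerate and invalid region configs error", {
  expect_error(generate_region(region_config(n_segments = 0)), "empty")
  expect_error(region_config(species_mix = c(pine = 0.6, spruce = 0.6,
                                             birch = 0.1)), "sum to 1")
})

test_that("region generation is reproducible bit-for-bit", {
  cfg <- region_config(n_segments = 500)
  expect_identical(generate_region(cfg, seed = 9), generate_region(cfg, seed = 9))
})

test_that("landscape summaries stay inside the observed national ranges", {
  ls <- generate_landscape(n_regions = 4, segments_per_region = 1000, seed = 2)
  for (r in ls$regions) {
    expect_gt(mean(r$segments$basal_area), 11)
    expect_lt(mean(r$segments$basal_area), 18)
    expect_gt(mean(r$segments$mean_age), 44)
    expect_lt(mean(r$segments$mean_age), 91)
  }
  expect_equal(sum(vapply(ls$regions, function(r) r$harvest_share, numeric(1))),
               1, tolerance = 1e-9)
})

test_that("area-weighted pixel sampling matches segment area weights", {
  cfg <- region_config(n_segments = 2, area_meanlog = 0)
  r <- generate_region(cfg, seed = 1)
  r$segments$area <- c(9, 1)
  r$total_area_km2 <- 0.1
  set.seed(42)
  px <- sample_pixels(r, 1e5)
  f1 <- mean(px$segment_id == r$segments$segment_id[1])
  expect_lt(abs(f1 - 0.9), 0.005)  # > 99% binomial band

  # chi-square goodness of fit over several segments
  r6 <- generate_region(region_config(n_segments = 6), seed = 8)
  set.seed(7)
  px6 <- sample_pixels(r6, 1e5)
  obs <- table(factor(px6$segment_id, levels = r6$segments$segment_id))
  p <- r6$segments$area / sum(r6$segments$area)
  expect_gt(stats::chisq.test(obs, p = p)$p.value, 0.01)
})

test_that("pixel sampling edge cases behave", {
  r <- generate_region(region_config(n_segments = 1), seed = 1)
  expect_equal(nrow(sample_pixels(r, 0)), 0)
  set.seed(1)
  px <- sample_pixels(r, 50)
  expect_true(all(px$segment_id == r$segments$segment_id[1]))
  r0 <- r; r0$segments <- r$segments[0, ]
  expect_error(sample_pixels(r0, 5), "empty region")
})

test_that("weather generation is deterministic and label-validated", {
  w1 <- generate_weather(2015:2020, "GFDL", "RCP4.5", seed = 3)
  w2 <- generate_weather(2015:2020, "GFDL", "RCP4.5", seed = 3)
  expect_identical(w1, w2)
  expect_error(generate_weather(2015, "FOO", "RCP4.5"), "unknown gcm")
  expect_error(generate_weather(2015, "GFDL", "RCP9"), "unknown rcp")
  expect_error(generate_weather(integer(0), "GFDL", "RCP4.5"), "non-empty")
})

test_that("weather obeys physical bounds and scenario trends", {
  w85 <- generate_weather(2015:2050, "CanESM2", "RCP8.5", seed = 3)
  w26 <- generate_weather(2015:2050, "CanESM2", "RCP2.6", seed = 3)
  expect_true(all(w85$rad >= 0 & w85$vpd >= 0 & w85$precip >= 0 & w85$co2 > 0))
  expect_true(all(diff(w85$co2) >= 0))
  last_decade <- function(w) mean(w$tair[w$year >= 2041])
  expect_gt(last_decade(w85), last_decade(w26))
})

test_that("harvest statistics sit inside the statistic bounds", {
  hs <- generate_harvest_statistics(seed = 4, region_weights = c(1, 1))
  expect_true(all(hs$round_wood >= 68 & hs$round_wood <= 78))
  expect_true(all(hs$energy_wood >= 7.2 & hs$energy_wood <= 10.2))
  expect_equal(hs$shares, c(0.5, 0.5))
  expect_length(hs$round_wood, 7)
})

test_that("parameter pools have the requested size, support and determinism", {
  p <- generate_parameter_pools(300, seed = 5)
  expect_equal(vapply(p[c("crobas", "preles", "yasso")], nrow, 1L),
               c(crobas = 300L, preles = 300L, yasso = 300L))
  expect_identical(p, generate_parameter_pools(300, seed = 5))
  expect_error(generate_parameter_pools(0), ">= 1")
  spec <- attr(p, "spec")
  for (pool in names(spec)) {
    sp <- spec[[pool]]
    expect_true(all(t(p[[pool]]) >= sp$lo & t(p[[pool]]) <= sp$hi))
  }
})

test_that("pool marginal means recover generator means at n = 1e4", {
  p <- generate_parameter_pools(1e4, seed = 6)
  spec <- attr(p, "spec")
  for (pool in names(spec)) {
    sp <- spec[[pool]]
    tol <- 5 * sp$sd / sqrt(1e4) + 1e-12
    expect_true(all(abs(colMeans(p[[pool]]) - sp$mean) < tol),
                label = paste("pool", pool, "marginal means"))
  }
})

test_that("segment tables round-trip through CSV", {
  r <- generate_region(region_config(n_segments = 20), seed = 1)
  f <- tempfile(fileext = ".csv")
  write_segments(r, f)
  s2 <- read_segments(f)
  expect_equal(s2$basal_area, r$segments$basal_area, tolerance = 1e-9)
  expect_equal(s2$soil_class, r$segments$soil_class)
})
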