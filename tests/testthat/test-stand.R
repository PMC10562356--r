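segment_row <- function(basal_area = 20, mean_height = 18, mean_dbh = 22,
                        mean_age = 60, prop_pine = 1, prop_spruce = 0,
                        prop_birch = 0, site_type = 3,
                        soil_class = "mineral", land_class = "productive") {
  data.frame(basal_area = basal_area, mean_height = mean_height,
             mean_dbh = mean_dbh, mean_age = mean_age,
             prop_pine = prop_pine, prop_spruce = prop_spruce,
             prop_birch = prop_birch, site_type = site_type,
             soil_class = soil_class, land_class = land_class,
             stringsAsFactors = FALSE)
}

test_that("crown height scales exactly with the crown-height factor", {
  seg <- segment_row()
  s1 <- initialize_stand(seg, crown_height_factor = 1.0)
  s2 <- initialize_stand(seg, crown_height_factor = 1.2)
  expect_equal(s2$crown_height, 1.2 * s1$crown_height, tolerance = 1e-12)
  expect_error(initialize_stand(seg, crown_height_factor = 0), "> 0")
})

test_that("initial volume and tree carbon follow the stated allometry", {
  p <- default_parameter_set()
  s <- initialize_stand(segment_row(), params = p)
  # hand computation with the documented surrogate coefficients
  ch <- 0.40 * 18 + 0.03 * 22 + 0.6
  form_eff <- p$crobas[["form_factor"]] * (1 - 0.25 * min(1, ch / 18))
  v <- 20 * 18 * form_eff
  expect_equal(s$stem_vol, v, tolerance = 1e-12)
  expect_equal(s$tree_c, v * p$crobas[["c_per_m3"]] / p$crobas[["stem_frac"]],
               tolerance = 1e-12)
  # zero basal area -> zero volume and carbon
  s0 <- initialize_stand(segment_row(basal_area = 0))
  expect_equal(s0$stem_vol, 0)
  expect_equal(s0$tree_c, 0)
})

test_that("GPP vanishes without radiation and is linear in LUE", {
  st <- make_stand()
  p <- default_parameter_set()
  expect_equal(annual_gpp(st, flat_weather_year(rad = 0), p), 0)
  w <- flat_weather_year()
  g1 <- annual_gpp(st, w, p)
  p2 <- params_with(preles = list(lue = 2 * p$preles[["lue"]]))
  expect_equal(annual_gpp(st, w, p2), 2 * g1, tolerance = 1e-12)
  expect_gt(g1, 0)
  expect_error(annual_gpp(st, w[1:100, ], p), "365")
})

test_that("GPP increases monotonically with CO2", {
  st <- make_stand()
  p <- default_parameter_set()
  g_low <- annual_gpp(st, flat_weather_year(co2 = 380), p)
  g_high <- annual_gpp(st, flat_weather_year(co2 = 560), p)
  expect_gt(g_high, g_low)
})

test_that("ground vegetation responds to light and fertility as documented", {
  expect_error(ground_vegetation_biomass(3, 1.2), "\\[0, 1\\]")
  expect_error(ground_vegetation_biomass(7, 0.5), "1..5")
  # light 0 -> configured floor
  expect_equal(ground_vegetation_biomass(3, 0), 100)
  expect_gte(ground_vegetation_biomass(2, 1), ground_vegetation_biomass(2, 0.5))
  expect_gte(ground_vegetation_biomass(1, 0.8), ground_vegetation_biomass(5, 0.8))
})

test_that("annual carbon-flux identity is exact over random states", {
  set.seed(31)
  n <- 1e4
  st <- make_stand(n,
                   tree_c = runif(n, 0, 2e5), gv_c = runif(n, 0, 3000),
                   basal_area = runif(n, 0, 40), dbh = runif(n, 1, 40),
                   height = runif(n, 1.4, 30), age = runif(n, 0, 150),
                   stem_vol = runif(n, 0, 400), n_stems = runif(n, 100, 4000),
                   site_type = sample(1:5, n, TRUE))
  pools <- generate_parameter_pools(20, seed = 2)
  for (k in 1:3) {
    p <- parameter_set(pools, c(crobas = k, preles = k, yasso = k))
    gpp <- annual_gpp(st, flat_weather_year(), p)
    step <- grow_stand(st, gpp, p)
    lhs <- (step$stand$tree_c + step$stand$gv_c) - (st$tree_c + st$gv_c)
    rhs <- step$flux$npp - step$flux$litter - step$flux$mort_litter
    expect_lt(max(abs(lhs - rhs) / pmax(abs(rhs), 1)), 1e-9)
    expect_equal(step$flux$npp, step$flux$gpp - step$flux$ra, tolerance = 1e-12)
    expect_true(all(step$stand$age == st$age + 1))
  }
})

test_that("crowding mortality activates only above the Reineke ceiling", {
  p <- params_with(crobas = list(mort_rate = 0))
  sparse <- make_stand(n_stems = 200, dbh = 25)
  step <- grow_stand(sparse, annual_gpp(sparse, flat_weather_year(), p), p)
  expect_equal(step$flux$mort_litter, 0)
  nmax <- p$crobas[["reineke_intercept"]] * 25^(-p$crobas[["reineke_slope"]])
  dense <- make_stand(n_stems = 2.5 * nmax, dbh = 25)
  step2 <- grow_stand(dense, annual_gpp(dense, flat_weather_year(), p), p)
  expect_gt(step2$flux$mort_litter, 0)
  expect_error(grow_stand(sparse, -1, p), "non-negative")
})

test_that("structure grows monotonically with allocated stem carbon", {
  p <- params_with(crobas = list(mort_rate = 0))
  st <- make_stand()
  w <- flat_weather_year()
  lo <- grow_stand(st, 0.5 * annual_gpp(st, w, p), p)$stand
  hi <- grow_stand(st, 2.0 * annual_gpp(st, w, p), p)$stand
  expect_gt(hi$basal_area, lo$basal_area)
  expect_gt(hi$dbh, lo$dbh)
  expect_gt(hi$height, lo$height)
})

test_that("multi-year trajectory matches an independently coded scalar recurrence", {
  p <- default_parameter_set()
  cb <- p$crobas; pp <- p$preles
  w <- flat_weather_year()

  ## independent scalar re-implementation of the documented equations
  s_driver <- function(w) {
    ft <- min(1, max(0, (w$tair[1] - pp[["t_min"]]) / (pp[["t_sat"]] - pp[["t_min"]])))
    fv <- exp(-pp[["k_vpd"]] * w$vpd[1])
    fc <- w$co2[1] / (w$co2[1] + pp[["k_co2"]])
    # flat precipitation: the smoother is at its fixed point all year
    fw <- w$precip[1] / (w$precip[1] + pp[["w0"]])
    365 * w$rad[1] * ft * fv * fc * fw
  }
  S <- s_driver(w)
  scalar_step <- function(state) {
    fapar <- max(1 - exp(-pp[["k_light"]] * state$ba), 0.05)
    gpp <- pp[["lue"]] * fapar * S * 10
    light <- exp(-pp[["k_light"]] * state$ba)
    gvt <- 100 + (cb[["gv_max"]] * 0.7 - 100) * light^0.7   # site type 3
    gv_lit <- 0.25 * state$gv
    gv_npp <- max(0, gvt - state$gv + gv_lit)
    gv <- state$gv + gv_npp - gv_lit
    tree_npp <- (1 - cb[["resp_frac"]]) * gpp
    lf <- cb[["litter_turnover"]] * state$w
    mort <- cb[["mort_rate"]]
    nmax <- cb[["reineke_intercept"]] * max(state$dbh, 1)^(-cb[["reineke_slope"]])
    if (state$n > nmax) mort <- min(0.95, mort + 1 - nmax / state$n)
    ml <- mort * state$w
    w_new <- state$w + tree_npp - lf - ml
    n_new <- state$n * (1 - mort)
    v_new <- max(0, state$v * (1 - mort) + cb[["alloc_stem"]] * tree_npp / cb[["c_per_m3"]])
    form_eff <- cb[["form_factor"]] * (1 - 0.25 * state$cr)
    ba <- max(state$ba, 0.05)
    for (i in 1:6) {
      dbh <- 200 * sqrt(ba / (pi * max(n_new, 1)))
      h <- 1.3 + cb[["height_coef"]] * dbh^0.85
      ba <- v_new / (h * form_eff)
    }
    dbh <- 200 * sqrt(ba / (pi * max(n_new, 1)))
    list(w = w_new, gv = gv, v = v_new, n = n_new, ba = ba, dbh = dbh,
         cr = state$cr)
  }

  st <- make_stand()
  state <- list(w = st$tree_c, gv = st$gv_c, v = st$stem_vol, n = st$n_stems,
                ba = st$basal_area, dbh = st$dbh, cr = st$crown_ratio)
  traj_pkg <- numeric(30); traj_ora <- numeric(30)
  for (t in 1:30) {
    step <- grow_stand(st, annual_gpp(st, w, p), p)
    st <- step$stand
    state <- scalar_step(state)
    traj_pkg[t] <- st$tree_c
    traj_ora[t] <- state$w
  }
  expect_equal(traj_pkg, traj_ora, tolerance = 1e-8)
})
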