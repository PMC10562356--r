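## Post-processing of Monte Carlo ensembles: redundancy-index attribution of
## output variance to uncertainty sources (Stewart-Love total redundancy via
## canonical correlation), empirical-CDF risk probabilities and
## interquantile-range diagnostics.

#' Stewart-Love redundancy index
#'
#' Canonical correlation analysis between a feature block and an output
#' block; the redundancy of the outputs given the features is
#' `sum_k rho_k^2 * mean(loadings_k^2)`, where `rho_k` are the canonical
#' correlations and the loadings are correlations of the (standardised)
#' outputs with their k-th canonical variate. For a single feature column
#' and a single output this reduces to the squared Pearson correlation. The
#' value is clamped to \[0,1\] against numerical noise; it has no absolute
#' interpretation and is meant to be compared across features.
#'
#' @param feature_columns numeric vector or matrix (rows = simulations).
#' @param output_vector numeric vector or matrix of outputs.
#' @return redundancy index in \[0,1\].
#' @export
redundancy_index <- function(feature_columns, output_vector) {
  X <- as.matrix(feature_columns)
  Y <- as.matrix(output_vector)
  if (nrow(X) != nrow(Y)) stop("row counts differ", call. = FALSE)
  if (nrow(X) < 3) stop("need at least 3 rows", call. = FALSE)
  if (any(apply(Y, 2, stats::var) <= 0)) {
    stop("output variance is zero; redundancy undefined", call. = FALSE)
  }
  keep <- apply(X, 2, stats::var) > 0
  if (!any(keep)) stop("all feature columns are constant", call. = FALSE)
  X <- scale(X[, keep, drop = FALSE])
  Y <- scale(Y)
  cc <- stats::cancor(X, Y, xcenter = FALSE, ycenter = FALSE)
  ## canonical variates of the Y block and output loadings on them
  V <- Y %*% cc$ycoef
  rho2 <- cc$cor^2
  rd <- 0
  for (k in seq_along(rho2)) {
    lo <- suppressWarnings(stats::cor(Y, V[, k]))
    rd <- rd + rho2[k] * mean(lo^2, na.rm = TRUE)
  }
  min(max(rd, 0), 1)
}

#' Build the feature matrix for attribution
#'
#' One row per retained simulation: region-level initial mean volume and age
#' (vol0, age0), one-hot encoded categorical drivers (RCP, Harv, GCM; first
#' level dropped), the sampled scalar parameter values of the growth,
#' photosynthesis and soil pools, the emission-coefficient draws (pECorg)
#' and the harvest-target deviates (pHarv). Constant columns are dropped and
#' recorded in attribute `dropped`. The NoHarv scenario is excluded by
#' default since it would dominate the analysis.
#'
#' @param ensemble an `fc_ensemble` from [run_monte_carlo()].
#' @param year evaluation year.
#' @param output_variable output column name (e.g. `"nbe"`).
#' @param region region id, or `NULL` for the area-weighted country level.
#' @param exclude_noharv drop NoHarv rows (default TRUE).
#' @return list with `features` (numeric matrix), `output` (vector),
#'   `groups` (named list mapping feature-set names to column names).
#' @export
encode_features <- function(ensemble, year, output_variable = "nbe",
                            region = NULL, exclude_noharv = TRUE) {
  out <- ensemble$outputs
  if (!output_variable %in% names(out)) {
    stop("unknown output variable: ", output_variable, call. = FALSE)
  }
  if (!year %in% out$year) stop("year not simulated: ", year, call. = FALSE)
  feats <- ensemble$features
  if (exclude_noharv) feats <- feats[feats$harv != "NoHarv", , drop = FALSE]
  sel <- out$year == year & out$harv %in% unique(feats$harv)
  out <- out[sel, , drop = FALSE]

  key <- function(d) paste(d$rcp, d$harv, d$sim, sep = "|")
  if (is.null(region)) {
    areas <- ensemble$region_areas
    sp <- split(out, key(out))
    y <- vapply(sp, function(d) {
      as.numeric(aggregate_country(d[[output_variable]], areas[d$region]))
    }, numeric(1))
    ## country-level vol0/age0: area-weighted over regions per (rcp,harv,sim)
    fr <- split(feats, key(feats))
    fs <- do.call(rbind, lapply(fr, function(d) d[1, , drop = FALSE]))
    fs$vol0 <- vapply(fr, function(d) as.numeric(
      aggregate_country(d$vol0, areas[d$region])), numeric(1))
    fs$age0 <- vapply(fr, function(d) as.numeric(
      aggregate_country(d$age0, areas[d$region])), numeric(1))
    y <- y[rownames(fs)]
  } else {
    out <- out[out$region == region, , drop = FALSE]
    fs <- feats[feats$region == region, , drop = FALSE]
    rownames(fs) <- key(fs)
    y <- stats::setNames(out[[output_variable]], key(out))[rownames(fs)]
  }

  onehot <- function(x, prefix) {
    lev <- sort(unique(x))
    if (length(lev) < 2) return(NULL)
    m <- sapply(lev[-1], function(l) as.numeric(x == l))
    colnames(m) <- paste0(prefix, lev[-1])
    m
  }
  par_cols <- grep("^(pCrob_|pPrel_|pYas_|pECorg_|pHarv_)", names(fs), value = TRUE)
  X <- cbind(vol0 = fs$vol0, age0 = fs$age0,
             onehot(fs$rcp, "RCP_"), onehot(fs$harv, "Harv_"),
             onehot(fs$gcm, "GCM_"),
             as.matrix(fs[, par_cols, drop = FALSE]))
  X <- as.matrix(X)
  const <- apply(X, 2, function(c) stats::var(c) == 0)
  dropped <- colnames(X)[const]
  X <- X[, !const, drop = FALSE]

  groups <- list(
    vol0 = "vol0", age0 = "age0",
    RCP = grep("^RCP_", colnames(X), value = TRUE),
    Harv = grep("^Harv_", colnames(X), value = TRUE),
    GCM = grep("^GCM_", colnames(X), value = TRUE),
    pCrob = grep("^pCrob_", colnames(X), value = TRUE),
    pPrel = grep("^pPrel_", colnames(X), value = TRUE),
    pYas = grep("^pYas_", colnames(X), value = TRUE),
    pECorg = grep("^pECorg_", colnames(X), value = TRUE),
    pHarv = grep("^pHarv_", colnames(X), value = TRUE))
  groups <- Filter(length, groups)
  structure(list(features = X, output = as.numeric(y), groups = groups),
            dropped = dropped)
}

#' Attribute output variance to uncertainty sources
#'
#' Computes the per-feature-column redundancy index of each requested output
#' at each evaluation year (univariate, the squared-correlation special
#' case) and reports, for multi-parameter sets (pCrob, pPrel, pYas, pECorg,
#' pHarv), the per-set maximum over its member columns.
#'
#' @param ensemble an `fc_ensemble`.
#' @param years evaluation years.
#' @param outputs output column names.
#' @param regions region ids to tabulate, plus the country level
#'   (`"country"`) always.
#' @return data.frame with columns level, year, output, feature, rd_ind.
#' @export
attribute_sources <- function(ensemble, years = c(2015, 2035, 2050),
                              outputs = c("nbe", "nee", "ecosystem_c"),
                              regions = NULL) {
  levels <- c(list(country = NULL),
              stats::setNames(as.list(regions), regions))
  res <- list()
  for (lv in names(levels)) {
    for (yr in years) {
      for (ov in outputs) {
        enc <- encode_features(ensemble, yr, ov, region = levels[[lv]])
        if (length(enc$output) < 3 || stats::var(enc$output) <= 0 ||
            ncol(enc$features) == 0) next
        for (g in names(enc$groups)) {
          cols <- enc$groups[[g]]
          rd <- max(vapply(cols, function(cn)
            redundancy_index(enc$features[, cn], enc$output), numeric(1)))
          res[[length(res) + 1]] <- data.frame(
            level = lv, year = yr, output = ov, feature = g, rd_ind = rd,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(level = character(0), year = numeric(0),
                      output = character(0), feature = character(0),
                      rd_ind = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

#' Empirical CDF probability
#'
#' Probability that a sampled output is at or below a threshold:
#' `(# samples <= t) / n`.
#'
#' @param samples non-empty numeric vector.
#' @param threshold query value(s).
#' @return probability in \[0,1\], vectorised over `threshold`.
#' @export
ecdf_probability <- function(samples, threshold) {
  if (length(samples) == 0) stop("samples must be non-empty", call. = FALSE)
  vapply(threshold, function(t) mean(samples <= t), numeric(1))
}

#' Central interquantile range width
#'
#' Width of the central `level` interval of the empirical distribution,
#' using linear interpolation of order statistics (quantile type 7).
#'
#' @param samples non-empty numeric vector.
#' @param level coverage in (0,1), default 0.95.
#' @return non-negative width.
#' @export
interquantile_range <- function(samples, level = 0.95) {
  if (length(samples) == 0) stop("samples must be non-empty", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0,1)", call. = FALSE)
  q <- stats::quantile(samples, c((1 - level) / 2, (1 + level) / 2),
                       names = FALSE, type = 7)
  q[2] - q[1]
}

#' Risk curves per region and scenario
#'
#' Tabulates the empirical CDF of an output at a given year for every
#' region x scenario cell, plus the central 95% range width.
#'
#' @param ensemble an `fc_ensemble`.
#' @param year evaluation year.
#' @param output output column name.
#' @param thresholds query thresholds; default: deciles of the pooled sample.
#' @return list with `curves` (data.frame region, rcp, harv, threshold,
#'   probability) and `widths` (data.frame region, rcp, harv, width95).
#' @export
risk_curves <- function(ensemble, year, output = "nbe", thresholds = NULL) {
  d <- ensemble$outputs
  d <- d[d$year == year, , drop = FALSE]
  if (is.null(thresholds)) {
    thresholds <- stats::quantile(d[[output]], seq(0.05, 0.95, by = 0.1),
                                  names = FALSE)
  }
  cells <- unique(d[, c("region", "rcp", "harv")])
  curves <- list(); widths <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- d$region == cells$region[i] & d$rcp == cells$rcp[i] &
      d$harv == cells$harv[i]
    x <- d[[output]][sel]
    curves[[i]] <- data.frame(cells[i, , drop = FALSE], threshold = thresholds,
                              probability = ecdf_probability(x, thresholds),
                              row.names = NULL)
    widths[[i]] <- data.frame(cells[i, , drop = FALSE],
                              width95 = interquantile_range(x), row.names = NULL)
  }
  list(curves = do.call(rbind, curves), widths = do.call(rbind, widths))
}
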