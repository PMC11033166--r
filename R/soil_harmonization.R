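#' Reclassify ordinal soil-fertility class to a nitrogen flux
#'
#' The four-level nutrient-availability classification (class 1 = highest
#' availability) is converted to plant-available nitrogen values of 100, 65,
#' 40 and 20 kg/ha/yr.
#'
#' @param sq1_class Integer class 1..4.
#' @param values Flux values (kg/ha/yr) for classes 1..4, highest first.
#' @return Plant-available nitrogen flux (kg/ha/yr), vectorized.
#' @export
reclassify_fertility <- function(sq1_class, values = c(100, 65, 40, 20)) {
  stopifnot(length(values) == 4L)
  if (any(is.na(sq1_class)) || any(!(sq1_class %in% 1:4))) {
    stop("fertility class must be in 1..4")
  }
  values[as.integer(sq1_class)]
}

#' Topsoil nitrogen pool from layered content and bulk density
#'
#' Sums relative nitrogen content (g/kg) times bulk density (kg/m3) times
#' layer thickness over soil layers, truncating layers at 0.30 m depth. The
#' per-layer product content/1000 * density * thickness is in kg/m2; the
#' total is converted to kg/ha (x 10,000).
#'
#' @param layers A data.frame with columns `n_content` (g/kg), `bulk_density`
#'   (kg/m3), `top` and `bottom` (m, top < bottom, non-overlapping).
#' @return Nitrogen pool in kg/ha over 0-0.30 m.
#' @export
nitrogen_pool <- function(layers) {
  if (is.null(layers) || nrow(layers) == 0L) return(0)
  stopifnot(all(c("n_content", "bulk_density", "top", "bottom") %in%
                  names(layers)))
  if (any(layers$n_content < 0) || any(layers$bulk_density < 0)) {
    stop("negative nitrogen content or bulk density")
  }
  top <- pmin(layers$top, 0.30)
  bottom <- pmin(layers$bottom, 0.30)
  thickness <- pmax(bottom - top, 0)
  kg_m2 <- sum(layers$n_content / 1000 * layers$bulk_density * thickness)
  kg_m2 * 1e4
}

#' Pseudo-mineralization rate
#'
#' Coarse annual mineralization rate obtained by dividing the
#' fertility-derived plant-available nitrogen flux by the topsoil nitrogen
#' pool.
#'
#' @param fertility Nitrogen flux (kg/ha/yr).
#' @param pool Topsoil nitrogen pool (kg/ha), > 0.
#' @return Rate in 1/yr, vectorized.
#' @export
pseudo_rate <- function(fertility, pool) {
  if (any(pool <= 0)) stop("nitrogen pool must be positive")
  fertility / pool
}

#' Calibrate the pseudo-mineralization GLM
#'
#' Fits a Gamma GLM with log link relating per-cell pseudo-mineralization
#' rates to mean annual temperature, annual precipitation, temperature
#' seasonality and soil pH. Rates are strictly positive and covariate
#' effects multiplicative, which the Gamma/log family represents naturally.
#' Reports the deviance explained D2 = 1 - residual/null deviance.
#'
#' @param data A data.frame with columns `rate` (1/yr, > 0), `mat` (degrees
#'   C), `anp` (mm), `seas` (seasonality index) and `ph`.
#' @return An object of class `rate_glm` wrapping the fitted [stats::glm]
#'   with the D2 diagnostic.
#' @export
fit_rate_glm <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("rate", "mat", "anp", "seas", "ph") %in% names(data)))
  if (nrow(data) < 50L) stop("need at least 50 cells to calibrate the GLM")
  if (any(data$rate <= 0)) stop("rates must be strictly positive")
  fit <- stats::glm(rate ~ mat + anp + seas + ph, data = data,
                    family = stats::Gamma(link = "log"),
                    control = stats::glm.control(epsilon = 1e-12,
                                                 maxit = 100))
  if (!fit$converged) stop("pseudo-mineralization GLM did not converge")
  structure(list(fit = fit,
                 coefficients = stats::coef(fit),
                 d2 = 1 - fit$deviance / fit$null.deviance),
            class = "rate_glm")
}

#' @export
print.rate_glm <- function(x, ...) {
  cat("<rate_glm> Gamma(log) pseudo-mineralization model, D2 =",
      format(x$d2, digits = 4), "\n")
  print(x$coefficients)
  invisible(x)
}

#' Predict plant-available nitrogen from the pool and the rate model
#'
#' Multiplies the topsoil nitrogen pool by the pseudo-mineralization rate
#' predicted from the climate/pH covariates.
#'
#' @param pool Nitrogen pool (kg/ha), >= 0.
#' @param covariates A data.frame (or one-row list) with `mat`, `anp`,
#'   `seas`, `ph`.
#' @param model A `rate_glm` from [fit_rate_glm()].
#' @return Plant-available nitrogen (kg/ha/yr), >= 0.
#' @export
predict_available_n <- function(pool, covariates, model) {
  stopifnot(inherits(model, "rate_glm"), all(pool >= 0))
  covariates <- as.data.frame(covariates)
  rate <- stats::predict(model$fit, newdata = covariates, type = "response")
  unname(pool * rate)
}

#' Default ordinal-rating lookup tables
#'
#' Five-level descriptive ratings (very poor .. very rich, very dry .. very
#' wet) mapped to quantitative values. Editable; shipped defaults span the
#' stratification ranges used for the coverage analysis.
#'
#' @return A list with elements `fertility` (kg/ha/yr) and `water` (WHC mm),
#'   each a named numeric vector of length 5.
#' @export
default_rating_lookup <- function() {
  list(
    fertility = c(very_poor = 15, poor = 30, medium = 50, rich = 80,
                  very_rich = 110),
    water = c(very_dry = 40, dry = 75, medium = 125, moist = 165,
              very_moist = 200)
  )
}

#' Complete a quantitative soil vector for a simulation location
#'
#' Fields present in the metadata are used verbatim. Missing water holding
#' capacity, texture and depth are filled from the nearest soil-grid cell.
#' Missing plant-available nitrogen is taken from a descriptive fertility
#' rating when one is given (via the ordinal lookup), otherwise estimated as
#' nitrogen pool x modelled pseudo-mineralization rate at the nearest cell.
#' A descriptive water rating fills a missing WHC the same way.
#'
#' @param meta A one-row list/data.frame with `latitude`, `longitude` and
#'   optional `whc`, `sand`, `silt`, `clay`, `depth`, `available_n`,
#'   `fertility_rating`, `water_rating`.
#' @param grids A `soil_grids` object (see [gen_soil_grids()]) with per-cell
#'   soil and climate-covariate fields.
#' @param model A `rate_glm`, required only when nitrogen must be estimated.
#' @param rating_lookup Ordinal lookup, see [default_rating_lookup()].
#' @return A list of class `soil_vector` with `whc` (mm), `sand`, `silt`,
#'   `clay` (percent), `depth` (mm), `available_n` (kg/ha/yr).
#' @export
complete_soil_vector <- function(meta, grids, model = NULL,
                                 rating_lookup = default_rating_lookup()) {
  meta <- as.list(meta)
  get <- function(field) {
    v <- meta[[field]]
    if (is.null(v) || length(v) == 0L || is.na(v)) NA_real_ else as.numeric(v)
  }
  cells <- grids$cells
  lat <- as.numeric(meta$latitude)
  lon <- as.numeric(meta$longitude)
  if (lat < min(cells$lat) - grids$resolution ||
      lat > max(cells$lat) + grids$resolution ||
      lon < min(cells$lon) - grids$resolution ||
      lon > max(cells$lon) + grids$resolution) {
    needed <- c("whc", "sand", "silt", "clay", "depth", "available_n")
    missing <- needed[vapply(needed, function(f) is.na(get(f)), TRUE)]
    if (length(missing) > 0L) {
      stop("location outside soil grids and field missing: ",
           paste(missing, collapse = ", "))
    }
  }
  d <- geosphere::distHaversine(cbind(cells$lon, cells$lat), c(lon, lat))
  cell <- cells[which.min(d), ]

  whc <- get("whc")
  if (is.na(whc) && !is.null(meta$water_rating) && !is.na(meta$water_rating) &&
      nzchar(meta$water_rating)) {
    whc <- unname(rating_lookup$water[[meta$water_rating]])
  }
  if (is.na(whc)) whc <- cell$whc

  sand <- get("sand"); silt <- get("silt"); clay <- get("clay")
  if (is.na(sand) || is.na(silt) || is.na(clay)) {
    sand <- cell$sand; silt <- cell$silt; clay <- cell$clay
  }
  depth <- get("depth")
  if (is.na(depth)) depth <- cell$depth

  available_n <- get("available_n")
  if (is.na(available_n) && !is.null(meta$fertility_rating) &&
      !is.na(meta$fertility_rating) && nzchar(meta$fertility_rating)) {
    available_n <- unname(rating_lookup$fertility[[meta$fertility_rating]])
  }
  if (is.na(available_n)) {
    if (is.null(model)) {
      stop("available_n missing and no rate model supplied")
    }
    available_n <- predict_available_n(
      cell$pool, cell[c("mat", "anp", "seas", "ph")], model)
  }
  structure(list(whc = whc, sand = sand, silt = silt, clay = clay,
                 depth = depth, available_n = available_n),
            class = "soil_vector")
}
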