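#' Fill mean height from minimum and maximum
#'
#' Arithmetic mean of minimum and maximum height, used when a model reports
#' only those two statistics.
#'
#' @param min,max Heights in metres, 0 <= min <= max.
#' @return Mean height (m), vectorized.
#' @export
mean_from_min_max <- function(min, max) {
  if (any(min < 0) || any(min > max)) stop("need 0 <= min <= max")
  (min + max) / 2
}

#' Default allometric dominant-height factors
#'
#' Species for which dominant height is derived from maximum tree height by
#' a species-specific allometric factor (dominant = factor x max). The
#' factors themselves are a configurable calibration input; the shipped
#' defaults are a documented placeholder of 0.95 for all six species and
#' should be replaced with calibrated values where available.
#'
#' @return Named numeric vector, species name -> factor.
#' @export
default_allometric_factors <- function() {
  c("Pinus sylvestris" = 0.95, "Abies alba" = 0.95, "Larix decidua" = 0.95,
    "Picea abies" = 0.95, "Fagus sylvatica" = 0.95, "Quercus robur" = 0.95)
}

#' Calibrate the maximum-from-mean height model
#'
#' Linear mixed model with maximum height as response, mean height as
#' predictor, and random intercept and slope for species; fitted by REML.
#' Used to predict maximum height for simulations that report only mean
#' height.
#'
#' @param calibration A data.frame with columns `species`, `mean`, `max`
#'   (m); at least two species with three rows each.
#' @return An object of class `max_height_model` wrapping the [lme4::lmer]
#'   fit.
#' @export
fit_max_from_mean <- function(calibration) {
  stopifnot(is.data.frame(calibration),
            all(c("species", "mean", "max") %in% names(calibration)))
  n_sp <- length(unique(calibration$species))
  if (n_sp < 2L) stop("species random effect unidentifiable with < 2 species")
  if (min(table(calibration$species)) < 3L) {
    stop("need at least 3 calibration rows per species")
  }
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(max ~ mean + (1 + mean | species), data = calibration,
               REML = TRUE,
               control = lme4::lmerControl(
                 check.conv.singular = "ignore",
                 check.nobs.vs.nRE = "ignore"))))
  structure(list(fit = fit,
                 fixef = lme4::fixef(fit),
                 species = unique(as.character(calibration$species))),
            class = "max_height_model")
}

#' Predict maximum height from mean height
#'
#' Uses the species-specific (conditional) prediction when the species was
#' in the calibration set, and the population-level fixed-effect prediction
#' otherwise. The result is floored at the mean so the height ordering is
#' preserved.
#'
#' @param mean Mean height (m), >= 0.
#' @param species Species name.
#' @param model A `max_height_model` from [fit_max_from_mean()].
#' @return Predicted maximum height (m).
#' @export
predict_max_from_mean <- function(mean, species, model) {
  stopifnot(inherits(model, "max_height_model"), all(mean >= 0))
  nd <- data.frame(mean = mean, species = species)
  known <- species %in% model$species
  pred <- numeric(length(mean))
  if (any(known)) {
    pred[known] <- stats::predict(model$fit, newdata = nd[known, ,
                                                          drop = FALSE])
  }
  if (any(!known)) {
    pred[!known] <- stats::predict(model$fit, newdata = nd[!known, ,
                                                           drop = FALSE],
                                   re.form = NA)
  }
  pmax(unname(pred), mean)
}

#' Calibrate the dominant-height mixed model
#'
#' Linear mixed model with dominant height as response, mean and maximum
#' height as predictors, and uncorrelated random slopes on both predictors
#' for species (no random intercept correlation); fitted by REML. Used for
#' species without a calibrated allometric factor.
#'
#' @param calibration A data.frame with columns `species`, `mean`, `max`,
#'   `dominant` (m); at least two species with three rows each.
#' @return An object of class `dominant_height_model`.
#' @export
fit_dominant_height_model <- function(calibration) {
  stopifnot(is.data.frame(calibration),
            all(c("species", "mean", "max", "dominant") %in%
                  names(calibration)))
  n_sp <- length(unique(calibration$species))
  if (n_sp < 2L) stop("species random effect unidentifiable with < 2 species")
  if (min(table(calibration$species)) < 3L) {
    stop("need at least 3 calibration rows per species")
  }
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(dominant ~ mean + max + (0 + mean | species) +
                 (0 + max | species),
               data = calibration, REML = TRUE,
               control = lme4::lmerControl(
                 check.conv.singular = "ignore",
                 check.nobs.vs.nRE = "ignore"))))
  structure(list(fit = fit,
                 fixef = lme4::fixef(fit),
                 species = unique(as.character(calibration$species))),
            class = "dominant_height_model")
}

#' Linear predictor of the dominant-height model (before clamping)
#' @keywords internal
.predict_dominant <- function(mean, max, species, model) {
  nd <- data.frame(mean = mean, max = max, species = species)
  known <- species %in% model$species
  pred <- numeric(length(mean))
  if (any(known)) {
    pred[known] <- stats::predict(model$fit,
                                  newdata = nd[known, , drop = FALSE])
  }
  if (any(!known)) {
    pred[!known] <- stats::predict(model$fit,
                                   newdata = nd[!known, , drop = FALSE],
                                   re.form = NA)
  }
  unname(pred)
}

#' Harmonize height statistics to dominant stand height
#'
#' Converts whatever height statistics a model reports (any non-empty subset
#' of minimum, mean, maximum) into dominant stand height:
#' \itemize{
#'   \item mean and maximum present: species with a calibrated allometric
#'     factor use dominant = factor x max; all other species use the
#'     dominant-height mixed model.
#'   \item minimum and maximum only: the mean is filled as (min + max) / 2,
#'     then as above.
#'   \item mean only: maximum is first predicted with the
#'     maximum-from-mean mixed model, then as above.
#' }
#' To be robust against outliers the result is clamped to the interval
#' \[0.8 x max, max\], where max is the reported or predicted maximum.
#'
#' @param min,mean,max Height statistics in metres; pass `NA` for statistics
#'   the model does not report. At least one must be present per stand.
#'   Vectorized over stands.
#' @param species Species name (of the dominant species of the stand).
#' @param dominant_model A `dominant_height_model`.
#' @param max_model A `max_height_model` (needed on the mean-only path).
#' @param allometric_factors Named factor table, see
#'   [default_allometric_factors()].
#' @return Dominant stand height (m), same length as the inputs.
#' @export
dominant_height <- function(min = NA, mean = NA, max = NA, species,
                            dominant_model, max_model = NULL,
                            allometric_factors =
                              default_allometric_factors()) {
  n <- base::max(length(min), length(mean), length(max), length(species))
  min <- rep_len(as.numeric(min), n)
  mean <- rep_len(as.numeric(mean), n)
  max <- rep_len(as.numeric(max), n)
  species <- rep_len(as.character(species), n)
  if (any(is.na(min) & is.na(mean) & is.na(max))) {
    stop("at least one height statistic must be present")
  }
  fill <- is.na(mean) & !is.na(min) & !is.na(max)
  if (any(fill)) mean[fill] <- mean_from_min_max(min[fill], max[fill])
  need_max <- is.na(max)
  if (any(need_max)) {
    if (any(is.na(mean[need_max]))) {
      stop("cannot derive mean height from minimum alone")
    }
    if (is.null(max_model)) {
      stop("mean-only input requires a maximum-from-mean model")
    }
    max[need_max] <- predict_max_from_mean(mean[need_max],
                                           species[need_max], max_model)
  }
  # max-only stands: no mean information, centre of the min-max span
  fill <- is.na(mean)
  if (any(fill)) {
    lo <- ifelse(is.na(min[fill]), max[fill], min[fill])
    mean[fill] <- mean_from_min_max(lo, max[fill])
  }
  fac <- allometric_factors[species]
  raw <- numeric(n)
  kahn <- !is.na(fac)
  raw[kahn] <- unname(fac[kahn]) * max[kahn]
  if (any(!kahn)) {
    raw[!kahn] <- .predict_dominant(mean[!kahn], max[!kahn], species[!kahn],
                                    dominant_model)
  }
  pmin(pmax(raw, 0.8 * max), max)
}
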