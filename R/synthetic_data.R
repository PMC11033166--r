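# Synthetic data with known ground truth: scenario catalogues, contributor
# simulation sets, soil grids and height-calibration tables. The generators
# define the study conditions under which the pipeline is exercised; every
# generated entity carries a truth record so recovery can be tested.

.MONTH_LENGTHS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
.MONTH_OF_DOY <- rep.int(seq_len(12L), .MONTH_LENGTHS)

# saturation vapour pressure (kPa) over water, Magnus form
.svp <- function(temp_c) 0.6108 * exp(17.27 * temp_c / (temp_c + 237.3))

#' Default per-scenario climate trend specification
#'
#' Linear trends of mean annual temperature (degrees C per year) and annual
#' precipitation (relative fraction per year) for each scenario x GCM
#' combination. The representative-pathway families span a broad warming
#' gradient (about 1, 2, 4.5 and 7 degrees C per century for historical,
#' RCP2.6, RCP4.5 and RCP8.5) and the synthetic GCMs span a wet-to-dry
#' precipitation gradient (+20, 0, -20 percent per century) plus a small
#' warming offset, mirroring the idea of selecting circulation models that
#' cover a broad range of temperature and precipitation conditions.
#'
#' @param gcms Character vector of GCM labels.
#' @param rcps Character vector of RCP labels (subset of rcp26/rcp45/rcp85;
#'   unknown labels get the RCP4.5 trend).
#' @return A data.frame with columns `family`, `gcm`, `t_slope` (degC/yr),
#'   `p_slope` (fraction/yr).
#' @export
default_trend_spec <- function(gcms = paste0("GCM-", LETTERS[1:3]),
                               rcps = c("rcp26", "rcp45", "rcp85")) {
  fam_t <- c(historical = 1.0, rcp26 = 2.0, rcp45 = 4.5, rcp85 = 7.0)
  fam_p <- c(historical = 0, rcp26 = 4, rcp45 = -6, rcp85 = -12)
  gcm_t <- seq(0, by = 0.3, length.out = length(gcms))
  gcm_p <- seq(20, by = -20, length.out = length(gcms))
  fams <- c("historical", rcps)
  grid <- expand.grid(family = fams, gcm = gcms, stringsAsFactors = FALSE)
  ft <- ifelse(grid$family %in% names(fam_t), fam_t[grid$family],
               fam_t[["rcp45"]])
  fp <- ifelse(grid$family %in% names(fam_p), fam_p[grid$family],
               fam_p[["rcp45"]])
  gi <- match(grid$gcm, gcms)
  data.frame(family = grid$family, gcm = grid$gcm,
             t_slope = (ft + gcm_t[gi]) / 100,
             p_slope = (fp + gcm_p[gi]) / 100 / 100)
}

.gen_trajectory <- function(scenario_id, cell, years, t_slope, p_slope) {
  n_years <- length(years)
  n_days <- n_years * 365L
  doy <- rep.int(seq_len(365L), n_years)
  yr_idx <- rep(seq_len(n_years), each = 365L)

  # temperature: latitudinal baseline + seasonal sinusoid + trend + AR(1)
  mat0 <- 14 - 0.35 * (cell$lat - 40)
  amp <- 9 + 0.2 * (cell$lat - 40)
  seasonal <- amp * sin(2 * pi * (doy - 110) / 365)
  trend <- t_slope * (yr_idx - 1)
  phi <- 0.6; sigma <- 2.5
  eps <- stats::rnorm(n_days, sd = sigma * sqrt(1 - phi^2))
  ar <- stats::filter(eps, phi, method = "recursive")
  tas <- mat0 + seasonal + trend + as.numeric(ar)

  # precipitation: Bernoulli occurrence x Gamma intensity; the yearly mean
  # intensity carries the (multiplicative) precipitation trend
  anp0 <- 700 + 8 * (cell$lat - 48) + 4 * (cell$lon - 10)
  anp0 <- base::max(anp0, 350)
  p_wet <- 0.45; shape <- 2
  anp_y <- anp0 * pmax(1 + p_slope * (yr_idx - 1), 0.05)
  scale <- anp_y / (365 * p_wet * shape)
  wet <- stats::runif(n_days) < p_wet
  prec <- numeric(n_days)
  prec[wet] <- stats::rgamma(sum(wet), shape = shape, scale = scale[wet])

  # radiation: clear-sky seasonal curve damped by cloud on wet days
  rad_clear <- pmax(170 + 130 * sin(2 * pi * (doy - 110) / 365), 25)
  rad <- rad_clear * ifelse(wet, 0.50, 0.95)

  # VPD from saturation pressure and a wet/dry relative-humidity split
  rh <- ifelse(wet, 0.85, 0.65)
  vpd <- pmax(.svp(tas) * (1 - rh), 0)

  to_mat <- function(x) matrix(x, nrow = n_years, ncol = 365L, byrow = TRUE)
  tas_m <- to_mat(tas); prec_m <- to_mat(prec)
  rad_m <- to_mat(rad); vpd_m <- to_mat(vpd)
  annual <- data.frame(year = years,
                       mat = rowMeans(tas_m),
                       anp = rowSums(prec_m))
  structure(list(scenario_id = scenario_id, cell_id = cell$cell_id,
                 years = years, tas = tas_m, prec = prec_m, rad = rad_m,
                 vpd = vpd_m, annual = annual),
            class = "climate_trajectory")
}

#' @export
print.climate_trajectory <- function(x, ...) {
  cat("<climate_trajectory>", x$scenario_id, "@", x$cell_id, "|",
      length(x$years), "years", min(x$years), "-", max(x$years), "| MAT",
      format(mean(x$annual$mat), digits = 3), "degC, ANP",
      format(mean(x$annual$anp), digits = 4), "mm\n")
  invisible(x)
}

#' Generate a synthetic scenario catalogue
#'
#' Builds one daily climate trajectory (tas, prec, rad, vpd; 365 days per
#' year, no leap days) per scenario x grid cell. Scenarios are the cross of
#' `historical` plus the requested RCP families with `n_gcm` synthetic
#' circulation models. Daily weather: sinusoidal seasonal temperature cycle
#' with AR(1) noise and a linear warming trend; Bernoulli-Gamma
#' precipitation with a multiplicative trend; clear-sky radiation damped on
#' wet days; VPD from saturation vapour pressure at a wet/dry humidity.
#'
#' @param n_gcm Number of synthetic GCMs (>= 1).
#' @param rcp_list RCP family labels (may be empty for historical only).
#' @param years Integer vector of consecutive calendar years.
#' @param grid_spec List with `lat_min`, `lat_max`, `lon_min`, `lon_max`
#'   (degrees) and `resolution` (degrees, > 0; default 0.11).
#' @param trend_spec Trend table as from [default_trend_spec()].
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @return An object of class `scenario_catalogue`: list with `trajectories`
#'   (named `"scenario_id|cell_id"`), `grid` (data.frame of cells), `years`,
#'   `scenario_ids`, `trend_spec`, `resolution`.
#' @export
gen_scenario_catalogue <- function(n_gcm = 3,
                                   rcp_list = c("rcp26", "rcp45", "rcp85"),
                                   years = 2011:2100,
                                   grid_spec = list(lat_min = 46,
                                                    lat_max = 46.11,
                                                    lon_min = 8,
                                                    lon_max = 8.11,
                                                    resolution = 0.11),
                                   trend_spec = NULL,
                                   seed = 1L) {
  stopifnot(n_gcm >= 1, length(years) >= 1)
  res <- grid_spec$resolution %||% 0.11
  if (res <= 0) stop("grid resolution must be positive")
  if (grid_spec$lat_max < grid_spec$lat_min ||
      grid_spec$lon_max < grid_spec$lon_min) {
    stop("empty grid extent")
  }
  gcms <- paste0("GCM-", LETTERS[seq_len(n_gcm)])
  if (is.null(trend_spec)) trend_spec <- default_trend_spec(gcms, rcp_list)
  fams <- c("historical", rcp_list)
  for (f in fams) for (g in gcms) {
    if (!any(trend_spec$family == f & trend_spec$gcm == g)) {
      stop("trend_spec missing entry for ", f, " x ", g)
    }
  }
  lats <- seq(grid_spec$lat_min + res / 2, grid_spec$lat_max, by = res)
  lons <- seq(grid_spec$lon_min + res / 2, grid_spec$lon_max, by = res)
  grid <- expand.grid(lat = lats, lon = lons)
  grid$cell_id <- sprintf("cell_%03d", seq_len(nrow(grid)))
  grid <- grid[c("cell_id", "lat", "lon")]

  scen <- expand.grid(family = fams, gcm = gcms, stringsAsFactors = FALSE)
  scen$scenario_id <- paste(scen$family, scen$gcm, sep = "_")
  scen <- scen[order(scen$scenario_id), ]

  set.seed(seed)
  trajectories <- list()
  for (i in seq_len(nrow(scen))) {
    tr <- trend_spec[trend_spec$family == scen$family[i] &
                       trend_spec$gcm == scen$gcm[i], ]
    for (j in seq_len(nrow(grid))) {
      key <- paste(scen$scenario_id[i], grid$cell_id[j], sep = "|")
      trajectories[[key]] <- .gen_trajectory(
        scen$scenario_id[i], grid[j, ], years,
        t_slope = tr$t_slope[1], p_slope = tr$p_slope[1])
    }
  }
  structure(list(trajectories = trajectories, grid = grid, years = years,
                 scenario_ids = scen$scenario_id, trend_spec = trend_spec,
                 resolution = res),
            class = "scenario_catalogue")
}

#' @export
print.scenario_catalogue <- function(x, ...) {
  cat("<scenario_catalogue>", length(x$scenario_ids), "scenarios x",
      nrow(x$grid), "cells,", length(x$years), "years (",
      min(x$years), "-", max(x$years), ")\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default height-reporting profiles of synthetic contributor models
#'
#' Each profile names the subset of height statistics a synthetic "forest
#' model" reports, emulating the heterogeneity of contributed outputs.
#' @return Named list of character vectors.
#' @export
default_profiles <- function() {
  list(full = c("min", "mean", "max"),
       mean_only = "mean",
       min_max = c("min", "max"))
}

#' Generate a synthetic contributor simulation set
#'
#' Draws `n_sims` simulations, each forced by exactly one catalogue
#' trajectory after applying a per-simulation temperature offset and
#' precipitation factor (the truth record) plus bounded observation noise.
#' Species basal-area shares follow a bounded random walk on the simplex
#' (shares sum to <= 1); heights follow an asymptotic growth curve with
#' min <= mean <= max; LAI saturates with mean height. The simulation table
#' is long: species rows carry (species, share), one stand row per year
#' (empty species) carries heights and LAI, with columns reported according
#' to the simulation's model profile. Metadata packs the annual temperature
#' and precipitation series as ';'-separated strings ordered by year.
#'
#' @param catalogue A `scenario_catalogue`.
#' @param n_sims Number of simulations (>= 1).
#' @param species_pool Character vector of Latin binomials.
#' @param profiles Named list of height-reporting profiles, see
#'   [default_profiles()]; each must be a non-empty subset of min/mean/max.
#' @param seed Integer seed.
#' @param noise_sd_t Sd (degrees C) of annual-temperature observation noise.
#' @param noise_rel_p Relative sd of annual-precipitation observation noise.
#' @param offset_range Range of the true temperature offset (degrees C).
#' @param factor_range Range of the true precipitation factor (> 0).
#' @param soil_mix Probabilities that a simulation's metadata carries full
#'   numeric soil fields, descriptive ratings only, or no soil information.
#' @return A list with `simulations` (long data.frame), `metadata`
#'   (one row per simulation) and `truth` (list with `simulations` truth
#'   table and `annual_components` per-year true state components).
#' @export
gen_simulation_set <- function(catalogue, n_sims = 50,
                               species_pool = c("Picea abies",
                                                "Fagus sylvatica",
                                                "Pinus sylvestris",
                                                "Quercus robur",
                                                "Abies alba"),
                               profiles = default_profiles(),
                               seed = 1L,
                               noise_sd_t = 0.1,
                               noise_rel_p = 0.02,
                               offset_range = c(-2, 2),
                               factor_range = c(0.85, 1.15),
                               soil_mix = c(numeric = 0.5, ratings = 0.3,
                                            none = 0.2)) {
  stopifnot(inherits(catalogue, "scenario_catalogue"), n_sims >= 1,
            length(species_pool) >= 1)
  for (pn in names(profiles)) {
    p <- profiles[[pn]]
    if (length(p) == 0L || !all(p %in% c("min", "mean", "max"))) {
      stop("profile ", sQuote(pn),
           " must report a non-empty subset of min/mean/max heights")
    }
  }
  set.seed(seed)
  years <- catalogue$years
  n_years <- length(years)
  keys <- names(catalogue$trajectories)
  lookup <- default_rating_lookup()

  sim_rows <- list(); meta_rows <- list(); truth_rows <- list()
  comp_rows <- list()
  for (s in seq_len(n_sims)) {
    sim_id <- sprintf("sim_%04d", s)
    key <- sample(keys, 1L)
    traj <- catalogue$trajectories[[key]]
    cell <- catalogue$grid[catalogue$grid$cell_id == traj$cell_id, ]
    offset <- stats::runif(1, offset_range[1], offset_range[2])
    factor <- stats::runif(1, factor_range[1], factor_range[2])
    annual_t <- traj$annual$mat + offset + stats::rnorm(n_years, 0, noise_sd_t)
    annual_p <- traj$annual$anp * factor *
      (1 + stats::rnorm(n_years, 0, noise_rel_p))
    annual_p <- pmax(annual_p, 1)

    family <- if (startsWith(traj$scenario_id, "historical")) "baseline"
              else "RCP"

    # species shares: bounded random walk on the simplex
    k <- sample(seq_len(min(3L, length(species_pool))), 1L)
    sp <- sample(species_pool, k)
    w <- stats::rgamma(k, shape = 2)
    props <- w / sum(w)
    total <- stats::runif(1, 0.8, 1.0)
    shares <- matrix(0, n_years, k, dimnames = list(NULL, sp))
    for (y in seq_len(n_years)) {
      if (y > 1L) {
        props <- pmax(props + stats::rnorm(k, 0, 0.02), 0.001)
        props <- props / sum(props)
        total <- min(base::max(total + stats::rnorm(1, 0, 0.01), 0.7), 1.0)
      }
      shares[y, ] <- props * total
    }

    # stand development: asymptotic height growth, LAI saturating with height
    h_asym <- stats::runif(1, 25, 40)
    age0 <- stats::runif(1, 5, 40)
    r_max <- stats::runif(1, 1.15, 1.35)
    r_min <- stats::runif(1, 0.6, 0.8)
    h_mean <- h_asym * (1 - exp(-0.03 * (age0 + seq_len(n_years))))
    h_max <- h_mean * r_max
    h_min <- h_mean * r_min
    lai <- pmax(6.5 * (1 - exp(-0.12 * h_mean)) +
                  stats::rnorm(n_years, 0, 0.15), 0)

    profile_name <- sample(names(profiles), 1L)
    prof <- profiles[[profile_name]]
    stand <- data.frame(source_id = "synthetic", simulation_id = sim_id,
                        year = years, species = "", share = NA_real_,
                        height_min = if ("min" %in% prof) h_min else NA_real_,
                        height_mean = if ("mean" %in% prof) h_mean
                                      else NA_real_,
                        height_max = if ("max" %in% prof) h_max else NA_real_,
                        lai = lai)
    spl <- data.frame(source_id = "synthetic", simulation_id = sim_id,
                      year = rep(years, each = k),
                      species = rep(sp, times = n_years),
                      share = as.vector(t(shares)),
                      height_min = NA_real_, height_mean = NA_real_,
                      height_max = NA_real_, lai = NA_real_)
    sim_rows[[s]] <- rbind(stand, spl)

    soil_kind <- sample(names(soil_mix), 1L, prob = soil_mix)
    tex <- stats::rgamma(3, shape = c(4, 4, 2))
    tex <- 100 * tex / sum(tex)
    meta_rows[[s]] <- data.frame(
      source_id = "synthetic", simulation_id = sim_id,
      latitude = cell$lat + stats::runif(1, -1, 1) * catalogue$resolution / 2,
      longitude = cell$lon + stats::runif(1, -1, 1) * catalogue$resolution / 2,
      trajectory_family = family,
      rcp_hint = "", gcm_hint = "",
      annual_temperature = paste(signif(annual_t, 8), collapse = ";"),
      annual_precipitation = paste(signif(annual_p, 8), collapse = ";"),
      whc = if (soil_kind == "numeric") stats::runif(1, 50, 200) else NA_real_,
      sand = if (soil_kind == "numeric") tex[1] else NA_real_,
      silt = if (soil_kind == "numeric") tex[2] else NA_real_,
      clay = if (soil_kind == "numeric") tex[3] else NA_real_,
      depth = if (soil_kind == "numeric") stats::runif(1, 300, 1500)
              else NA_real_,
      available_n = if (soil_kind == "numeric") stats::runif(1, 20, 110)
                    else NA_real_,
      water_rating = if (soil_kind == "ratings")
        sample(names(lookup$water), 1L) else "",
      fertility_rating = if (soil_kind == "ratings")
        sample(names(lookup$fertility), 1L) else "",
      management = sample(c("none", "business-as-usual"), 1L),
      model_name = paste0("synthmodel_", profile_name),
      model_level = sample(c("stand", "landscape"), 1L))

    truth_rows[[s]] <- data.frame(simulation_id = sim_id,
                                  scenario_id = traj$scenario_id,
                                  cell_id = traj$cell_id,
                                  offset = offset, factor = factor,
                                  profile = profile_name)
    comp_rows[[s]] <- data.frame(simulation_id = sim_id, year = years,
                                 h_mean = h_mean, h_max = h_max,
                                 h_min = h_min, lai = lai,
                                 total_share = rowSums(shares))
  }
  list(simulations = do.call(rbind, sim_rows),
       metadata = do.call(rbind, meta_rows),
       truth = list(simulations = do.call(rbind, truth_rows),
                    annual_components = do.call(rbind, comp_rows)))
}

#' Default true coefficients of the pseudo-mineralization model
#'
#' Log-link coefficients producing rates of roughly 0.004-0.03 per year over
#' the synthetic covariate ranges.
#' @return Named numeric vector (intercept, mat, anp, seas, ph).
#' @export
default_glm_truth <- function() {
  c(intercept = -5.2, mat = 0.04, anp = -3e-4, seas = -8e-4, ph = 0.08)
}

#' Generate synthetic soil grids with a known nitrogen model
#'
#' Builds a cell grid carrying soil fields (fertility class, layered
#' nitrogen content and bulk density, pH, WHC, texture, depth) and climate
#' covariates in which the pseudo-mineralization Gamma/log GLM is the true
#' data-generating model: the true rate at each cell is
#' `exp(X %*% glm_truth)`, the continuous fertility flux layer is
#' `rate * pool` with multiplicative lognormal noise, and the four-level
#' fertility class is the nearest reclassification value. The flux layer is
#' kept continuous (the class layer is its quantized view) so that model
#' calibration on the grids can be checked against the known coefficients.
#'
#' @param grid_spec List with `lat_min`, `lat_max`, `lon_min`, `lon_max`,
#'   `resolution` (degrees).
#' @param glm_truth Named coefficients, see [default_glm_truth()].
#' @param seed Integer seed.
#' @param noise_sdlog Sd of the lognormal noise on the fertility flux.
#' @return An object of class `soil_grids`: list with `cells` (data.frame),
#'   `layers` (per-cell soil layers), `truth` (coefficients and per-cell
#'   true rates), `resolution`.
#' @export
gen_soil_grids <- function(grid_spec = list(lat_min = 44, lat_max = 52,
                                            lon_min = 5, lon_max = 13,
                                            resolution = 0.5),
                           glm_truth = default_glm_truth(),
                           seed = 1L,
                           noise_sdlog = 0.05) {
  stopifnot(all(is.finite(glm_truth)), length(glm_truth) == 5L)
  res <- grid_spec$resolution
  if (is.null(res) || res <= 0) stop("grid resolution must be positive")
  lats <- seq(grid_spec$lat_min + res / 2, grid_spec$lat_max, by = res)
  lons <- seq(grid_spec$lon_min + res / 2, grid_spec$lon_max, by = res)
  if (length(lats) == 0L || length(lons) == 0L) stop("empty grid extent")
  set.seed(seed)
  cells <- expand.grid(lat = lats, lon = lons)
  n <- nrow(cells)
  cells$cell_id <- sprintf("soil_%04d", seq_len(n))

  cells$mat <- 14 - 0.35 * (cells$lat - 40) + stats::rnorm(n, 0, 0.8)
  cells$anp <- pmax(700 + 8 * (cells$lat - 48) + 4 * (cells$lon - 10) +
                      stats::rnorm(n, 0, 60), 200)
  cells$seas <- pmax(550 + 25 * (cells$lat - 48) + stats::rnorm(n, 0, 60), 50)
  cells$ph <- stats::runif(n, 4.0, 7.5)

  layers <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(cell_id = cells$cell_id[i],
               top = c(0, 0.15), bottom = c(0.15, 0.30),
               n_content = stats::runif(2, 1.0, 4.0),
               bulk_density = stats::runif(2, 1100, 1600))
  }))
  cells$pool <- vapply(cells$cell_id, function(id) {
    nitrogen_pool(layers[layers$cell_id == id, ])
  }, 0)

  X <- cbind(1, cells$mat, cells$anp, cells$seas, cells$ph)
  rate_true <- exp(as.vector(X %*% glm_truth))
  flux <- rate_true * cells$pool * exp(stats::rnorm(n, 0, noise_sdlog))
  reclass <- c(100, 65, 40, 20)
  cells$fertility_flux <- flux
  cells$sq1_class <- vapply(flux, function(f) which.min(abs(reclass - f)), 0L)

  tex <- t(vapply(seq_len(n), function(i) {
    w <- stats::rgamma(3, shape = c(5, 4, 2))
    100 * w / sum(w)
  }, numeric(3)))
  cells$sand <- tex[, 1]; cells$silt <- tex[, 2]; cells$clay <- tex[, 3]
  cells$whc <- stats::runif(n, 30, 230)
  cells$depth <- stats::runif(n, 200, 1600)

  structure(list(cells = cells, layers = layers,
                 truth = list(coefficients = glm_truth,
                              rate_true = rate_true,
                              available_n_true = rate_true * cells$pool),
                 resolution = res),
            class = "soil_grids")
}

#' @export
print.soil_grids <- function(x, ...) {
  cat("<soil_grids>", nrow(x$cells), "cells at", x$resolution,
      "deg resolution\n")
  invisible(x)
}

#' Default true coefficients of the per-species height relations
#'
#' For each species, dominant height is `c_mean * mean + c_max * max` (no
#' intercept); the per-species deviations emulate allometric differences.
#'
#' @param species_list Character vector of species.
#' @param spread Sd of the per-species coefficient deviations (0 gives a
#'   pure fixed-effect truth).
#' @param seed Integer seed for the deviations.
#' @return A data.frame with columns `species`, `c_mean`, `c_max`.
#' @export
default_height_truth <- function(species_list, spread = 0.03, seed = 99L) {
  set.seed(seed)
  n <- length(species_list)
  data.frame(species = species_list,
             c_mean = 0.10 + stats::rnorm(n, 0, spread),
             c_max = 0.85 + stats::rnorm(n, 0, spread))
}

#' Generate a synthetic height-calibration table
#'
#' Emulates yield-table stand data: per stand, a mean height, a maximum and
#' minimum in fixed proportion bands, and a dominant height generated from
#' the per-species truth coefficients applied to (mean, max) plus Gaussian
#' noise.
#'
#' @param n_stands Stands per species (>= 2).
#' @param species_list Character vector of species (>= 1).
#' @param coeff_truth Truth table from [default_height_truth()].
#' @param noise_sd Residual sd of dominant height (m, >= 0).
#' @param seed Integer seed.
#' @return A data.frame with columns `species`, `min`, `mean`, `max`,
#'   `dominant` (all metres).
#' @export
gen_height_calibration <- function(n_stands = 200,
                                   species_list,
                                   coeff_truth =
                                     default_height_truth(species_list),
                                   noise_sd = 0.5,
                                   seed = 1L) {
  stopifnot(n_stands >= 2, length(species_list) >= 1, noise_sd >= 0)
  coeff_truth <- coeff_truth  # force before seeding (default truth seeds too)
  set.seed(seed)
  out <- do.call(rbind, lapply(species_list, function(sp) {
    co <- coeff_truth[coeff_truth$species == sp, ]
    if (nrow(co) != 1L) stop("coeff_truth missing species ", sQuote(sp))
    mean_h <- stats::runif(n_stands, 5, 35)
    max_h <- mean_h * stats::runif(n_stands, 1.1, 1.4)
    min_h <- mean_h * stats::runif(n_stands, 0.6, 0.9)
    dom <- co$c_mean * mean_h + co$c_max * max_h +
      stats::rnorm(n_stands, 0, noise_sd)
    data.frame(species = sp, min = min_h, mean = mean_h, max = max_h,
               dominant = pmax(dom, 0.1))
  }))
  rownames(out) <- NULL
  out
}
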