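# Trajectory selection, level adjustment, year matching and daily-vector
# assembly. The matching index is dT + 0.1 * dP with dT in degrees C per
# century and dP as relative precipitation change in percent per century
# (trend level) or percent difference (year level), so the 0.1 weight reads
# "a 10 percent precipitation difference trades against 1 degree C".

#' Temperature and precipitation trend slopes of an annual series
#'
#' OLS slope of annual mean temperature on year (degrees C per year) and
#' OLS slope of annual precipitation on year divided by the series mean
#' (relative trend, fraction per year).
#'
#' @param annual_t Annual mean temperatures (degrees C).
#' @param annual_p Annual precipitation sums (mm).
#' @param years Year vector (defaults to 1..n); must not be constant.
#' @return List with `t_slope` (degC/yr) and `p_slope` (fraction/yr).
#' @export
trend_slopes <- function(annual_t, annual_p,
                         years = seq_along(annual_t)) {
  stopifnot(length(annual_t) == length(annual_p),
            length(annual_t) == length(years))
  if (length(years) < 3L) stop("need at least 3 years for a trend")
  if (stats::var(years) == 0) stop("constant year vector")
  xc <- years - mean(years)
  sxx <- sum(xc^2)
  t_slope <- sum(xc * annual_t) / sxx
  p_mean <- mean(annual_p)
  if (p_mean <= 0) stop("non-positive mean precipitation")
  p_slope <- sum(xc * annual_p) / sxx / p_mean
  list(t_slope = t_slope, p_slope = p_slope)
}

#' Trend-matching index between two slope pairs
#'
#' `|dT| + weight * |dP|` with dT the temperature-slope difference in
#' degrees C per century and dP the relative precipitation-slope difference
#' in percent per century.
#'
#' @param sim_slopes,cand_slopes Slope pairs from [trend_slopes()].
#' @param weight Precipitation weight (default 0.1).
#' @return Non-negative index; zero iff the slopes are equal.
#' @export
trajectory_distance <- function(sim_slopes, cand_slopes, weight = 0.1) {
  stopifnot(is.finite(sim_slopes$t_slope), is.finite(cand_slopes$t_slope),
            is.finite(sim_slopes$p_slope), is.finite(cand_slopes$p_slope))
  d_t <- (sim_slopes$t_slope - cand_slopes$t_slope) * 100
  d_p <- (sim_slopes$p_slope - cand_slopes$p_slope) * 100 * 100
  abs(d_t) + weight * abs(d_p)
}

.parse_series <- function(x) {
  if (is.character(x)) as.numeric(strsplit(x, ";", fixed = TRUE)[[1]])
  else as.numeric(x)
}

.candidate_ids <- function(meta, scenario_ids) {
  family <- meta$trajectory_family
  rcp <- meta$rcp_hint %||% ""
  gcm <- meta$gcm_hint %||% ""
  if (is.na(rcp)) rcp <- ""
  if (is.na(gcm)) gcm <- ""
  ids <- if (identical(family, "baseline")) {
    grep("^historical_", scenario_ids, value = TRUE)
  } else {
    grep("^historical_", scenario_ids, value = TRUE, invert = TRUE)
  }
  if (nzchar(rcp)) ids <- grep(paste0("^", rcp, "_"), ids, value = TRUE)
  if (nzchar(gcm)) ids <- grep(paste0("_", gcm, "$"), ids, value = TRUE)
  ids
}

#' Nearest catalogue grid cell to a location
#'
#' Great-circle (haversine) distance between the location and the cell
#' centres.
#'
#' @param latitude,longitude Location in degrees.
#' @param catalogue A `scenario_catalogue`.
#' @return The `cell_id` of the nearest cell.
#' @export
nearest_cell <- function(latitude, longitude, catalogue) {
  g <- catalogue$grid
  d <- geosphere::distHaversine(cbind(g$lon, g$lat), c(longitude, latitude))
  g$cell_id[which.min(d)]
}

#' Select the best-matching scenario trajectory for a simulation
#'
#' Candidates are restricted by the metadata's trajectory family (baseline
#' simulations match historical trajectories only; scenario families match
#' the non-historical trajectories) and, when present, by RCP and GCM hints.
#' Among the candidates at the grid cell nearest the simulation location,
#' the trajectory minimizing [trajectory_distance()] between the
#' simulation's and the candidate's annual trend slopes is chosen; ties go
#' to the lexicographically smaller scenario id.
#'
#' @param meta One metadata row (list/data.frame) with `latitude`,
#'   `longitude`, `trajectory_family`, optional `rcp_hint`/`gcm_hint`, and
#'   annual series `annual_temperature`, `annual_precipitation`
#'   (numeric vectors or ';'-packed strings).
#' @param catalogue A `scenario_catalogue`.
#' @param weight Precipitation weight of the index.
#' @return List with `scenario_id`, `cell_id`, `distance`, and the scored
#'   `candidates` data.frame.
#' @export
select_trajectory <- function(meta, catalogue, weight = 0.1) {
  meta <- as.list(meta)
  ids <- .candidate_ids(meta, catalogue$scenario_ids)
  if (length(ids) == 0L) stop("no candidate trajectories after hint filtering")
  annual_t <- .parse_series(meta$annual_temperature)
  annual_p <- .parse_series(meta$annual_precipitation)
  sim_slopes <- trend_slopes(annual_t, annual_p)
  cell <- nearest_cell(meta$latitude, meta$longitude, catalogue)
  dist <- vapply(ids, function(id) {
    traj <- catalogue$trajectories[[paste(id, cell, sep = "|")]]
    if (is.null(traj)) return(NA_real_)
    cand <- trend_slopes(traj$annual$mat, traj$annual$anp, traj$annual$year)
    trajectory_distance(sim_slopes, cand, weight)
  }, 0)
  if (all(is.na(dist))) stop("no candidate trajectories at cell ", cell)
  scored <- data.frame(scenario_id = ids, distance = dist)
  scored <- scored[order(scored$distance, scored$scenario_id), ]
  list(scenario_id = scored$scenario_id[1], cell_id = cell,
       distance = scored$distance[1], candidates = scored)
}

#' Adjust a trajectory to the simulation's climate level
#'
#' Adds the temperature offset `delta = sim_mat - traj_mat` to every daily
#' temperature and multiplies every daily precipitation by
#' `f = sim_anp / traj_anp`; radiation and VPD are unchanged. Means are
#' computed over the simulation period intersected with the trajectory
#' period (the full trajectory period when they do not overlap, e.g. for
#' simulations counting years from 1). After adjustment the trajectory's
#' period-mean MAT equals `sim_mat` and its period-mean ANP equals
#' `sim_anp`.
#'
#' @param traj A `climate_trajectory`.
#' @param sim_mat Simulation mean annual temperature over its period
#'   (degrees C).
#' @param sim_anp Simulation mean annual precipitation sum (mm), > 0.
#' @param sim_years Optional simulation year vector used to pick the
#'   overlapping trajectory years.
#' @return List with the adjusted `trajectory`, `delta` (degC) and
#'   `factor` (unitless, > 0).
#' @export
adjust_trajectory <- function(traj, sim_mat, sim_anp, sim_years = NULL) {
  stopifnot(inherits(traj, "climate_trajectory"))
  idx <- seq_along(traj$years)
  if (!is.null(sim_years)) {
    ov <- which(traj$years %in% sim_years)
    if (length(ov) > 0L) idx <- ov
  }
  traj_mat <- mean(traj$annual$mat[idx])
  traj_anp <- mean(traj$annual$anp[idx])
  if (traj_anp <= 0) stop("trajectory has zero precipitation")
  delta <- sim_mat - traj_mat
  f <- sim_anp / traj_anp
  adj <- traj
  adj$tas <- traj$tas + delta
  adj$prec <- traj$prec * f
  adj$annual$mat <- traj$annual$mat + delta
  adj$annual$anp <- traj$annual$anp * f
  list(trajectory = adj, delta = delta, factor = f)
}

#' Year-matching index between a simulation year and a scenario year
#'
#' `|T_sim - T_scen| + weight * |100 * (P_sim / P_scen - 1)|`: the additive
#' mean-temperature difference combined with the multiplicative
#' precipitation difference expressed in percent.
#'
#' @param t_sim,p_sim Simulation-year mean temperature (degC) and
#'   precipitation sum (mm, > 0).
#' @param t_scen,p_scen Scenario-year values (`p_scen` > 0); vectorized over
#'   scenario years.
#' @param weight Precipitation weight (default 0.1).
#' @return Non-negative index.
#' @export
year_distance <- function(t_sim, p_sim, t_scen, p_scen, weight = 0.1) {
  if (any(p_sim <= 0) || any(p_scen <= 0)) {
    stop("precipitation must be positive")
  }
  abs(t_sim - t_scen) + weight * abs(100 * (p_sim / p_scen - 1))
}

#' Match each simulation year to a scenario year
#'
#' For every simulation year the year-matching index against every year of
#' the (level-adjusted) trajectory is computed; among the three best
#' matching years (ties resolved towards the earlier year) one is sampled
#' uniformly with replacement. Sampling uses the current R random-number
#' state; seed it for reproducibility.
#'
#' @param sim_annual A data.frame with columns `year`, `t` (degC), `p` (mm).
#' @param traj The adjusted `climate_trajectory`.
#' @param weight Precipitation weight.
#' @param n_best Size of the candidate pool (default 3).
#' @return A data.frame with `sim_year`, `scen_year`, `distance` (of the
#'   sampled year).
#' @export
match_years <- function(sim_annual, traj, weight = 0.1, n_best = 3L) {
  stopifnot(inherits(traj, "climate_trajectory"),
            all(c("year", "t", "p") %in% names(sim_annual)))
  if (length(traj$years) < n_best) {
    stop("trajectory must have at least ", n_best, " years")
  }
  out <- lapply(seq_len(nrow(sim_annual)), function(i) {
    d <- year_distance(sim_annual$t[i], sim_annual$p[i],
                       traj$annual$mat, traj$annual$anp, weight)
    ord <- order(d, traj$annual$year)[seq_len(n_best)]
    pick <- ord[sample.int(n_best, 1L)]
    data.frame(sim_year = sim_annual$year[i],
               scen_year = traj$annual$year[pick],
               distance = d[pick])
  })
  do.call(rbind, out)
}

#' Assemble the daily climate vectors for one simulation year
#'
#' Copies the mapped scenario year's 365 daily values of temperature,
#' precipitation, radiation and VPD out of the adjusted trajectory.
#'
#' @param traj The adjusted `climate_trajectory`.
#' @param mapping Year mapping from [match_years()].
#' @param sim_year The simulation year to assemble.
#' @return List of four numeric vectors `tas`, `prec`, `rad`, `vpd`, each of
#'   length 365.
#' @export
assemble_daily <- function(traj, mapping, sim_year) {
  row <- which(mapping$sim_year == sim_year)
  if (length(row) != 1L) stop("no year mapping for simulation year ", sim_year)
  yi <- which(traj$years == mapping$scen_year[row])
  if (length(yi) != 1L) stop("mapped year not in trajectory")
  list(tas = traj$tas[yi, ], prec = traj$prec[yi, ],
       rad = traj$rad[yi, ], vpd = traj$vpd[yi, ])
}
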