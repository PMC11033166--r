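# End-to-end orchestration: validate contributions, encode vegetation
# states, harmonize heights, match climate trajectories, complete soil
# vectors, write per-scenario SQLite databases and a coverage report.

#' Pipeline configuration
#'
#' Collects every tunable constant of the harmonization in one object.
#' Defaults are the published conventions: dominance above 66 percent of
#' basal area, admixture at or above 20 percent, LAI class edges 2 and 4,
#' 2-m height bins, matching weight 0.1, fertility reclassification values
#' 100/65/40/20 kg/ha/yr.
#'
#' @param seed Pipeline seed; all randomized steps derive from it.
#' @param weight Precipitation weight of the matching index.
#' @param dominance_threshold,admixture_threshold Composition thresholds
#'   (fractions in (0, 1)).
#' @param lai_edges Two LAI class edges.
#' @param height_bin_width Height bin width (m, > 0).
#' @param fertility_values Reclassification values for fertility classes
#'   1..4 (kg/ha/yr).
#' @param rating_lookup Ordinal rating lookup, see
#'   [default_rating_lookup()].
#' @param allometric_factors Species factor table, see
#'   [default_allometric_factors()].
#' @param height_calibration Calibration table (species, min, mean, max,
#'   dominant) for the dominant-height mixed model; see
#'   [gen_height_calibration()].
#' @return A list of class `harmonization_config`.
#' @export
harmonization_config <- function(seed = 1L,
                                 weight = 0.1,
                                 dominance_threshold = 0.66,
                                 admixture_threshold = 0.20,
                                 lai_edges = c(2, 4),
                                 height_bin_width = 2,
                                 fertility_values = c(100, 65, 40, 20),
                                 rating_lookup = default_rating_lookup(),
                                 allometric_factors =
                                   default_allometric_factors(),
                                 height_calibration = NULL) {
  stopifnot(dominance_threshold > 0, dominance_threshold < 1,
            admixture_threshold > 0, admixture_threshold < 1,
            height_bin_width > 0, weight >= 0)
  structure(list(seed = as.integer(seed), weight = weight,
                 dominance_threshold = dominance_threshold,
                 admixture_threshold = admixture_threshold,
                 lai_edges = lai_edges,
                 height_bin_width = height_bin_width,
                 fertility_values = fertility_values,
                 rating_lookup = rating_lookup,
                 allometric_factors = allometric_factors,
                 height_calibration = height_calibration),
            class = "harmonization_config")
}

# deterministic 31-bit string hash for per-simulation RNG substreams
.id_hash <- function(id) {
  codes <- utf8ToInt(id)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

.stand_rows <- function(records) {
  records[is.na(records$species) | !nzchar(records$species), ]
}

.species_rows <- function(records) {
  records[!is.na(records$species) & nzchar(records$species), ]
}

# max-from-mean model calibrated on the contributed rows that report both
# statistics, keyed by the stand's leading species; falls back to the
# configured calibration table when the contributed data cannot support a
# mixed model
.fit_max_model <- function(records, config) {
  stand <- .stand_rows(records)
  sp <- .species_rows(records)
  both <- stand[!is.na(stand$height_mean) & !is.na(stand$height_max), ]
  if (nrow(both) > 0L && nrow(sp) > 0L) {
    lead <- stats::aggregate(share ~ simulation_id + year, data = sp,
                             FUN = max)
    key <- paste(sp$simulation_id, sp$year)
    lead$species <- sp$species[match(
      paste(lead$simulation_id, lead$year, lead$share),
      paste(sp$simulation_id, sp$year, sp$share))]
    both$species <- lead$species[match(paste(both$simulation_id, both$year),
                                       paste(lead$simulation_id, lead$year))]
    both <- both[!is.na(both$species), ]
    cal <- data.frame(species = both$species, mean = both$height_mean,
                      max = both$height_max)
    enough <- length(unique(cal$species)) >= 2L &&
      min(table(cal$species)) >= 3L
    if (enough) return(fit_max_from_mean(cal))
  }
  if (is.null(config$height_calibration)) {
    stop("no usable mean+max data and no height calibration table configured")
  }
  fit_max_from_mean(config$height_calibration)
}

.harmonize_one <- function(id, records, meta, catalogue, grids, rate_model,
                           dom_model, max_model, config) {
  rec <- records[records$simulation_id == id, ]
  stand <- .stand_rows(rec)
  stand <- stand[order(stand$year), ]
  sp <- .species_rows(rec)
  years <- stand$year
  annual_t <- .parse_series(meta$annual_temperature)
  annual_p <- .parse_series(meta$annual_precipitation)

  soil <- complete_soil_vector(meta, grids, rate_model,
                               config$rating_lookup)

  sel <- select_trajectory(meta, catalogue, config$weight)
  traj <- catalogue$trajectories[[paste(sel$scenario_id, sel$cell_id,
                                        sep = "|")]]
  adj <- adjust_trajectory(traj, mean(annual_t), mean(annual_p), years)
  set.seed((config$seed + .id_hash(id)) %% 2147483647L)
  mapping <- match_years(
    data.frame(year = years, t = annual_t, p = annual_p),
    adj$trajectory, config$weight)

  n <- length(years)
  comps <- vector("list", n)
  lead <- character(n)
  for (i in seq_len(n)) {
    shr <- sp[sp$year == years[i], ]
    shares <- stats::setNames(shr$share, shr$species)
    comp <- classify_composition(shares, config$dominance_threshold,
                                 config$admixture_threshold)
    comps[[i]] <- comp
    lead[i] <- if (!is.na(comp$dominant)) comp$dominant
      else if (length(shares) > 0L) names(shares)[which.max(shares)]
      else "__none__"
  }
  dom_heights <- dominant_height(min = stand$height_min,
                                 mean = stand$height_mean,
                                 max = stand$height_max,
                                 species = lead,
                                 dominant_model = dom_model,
                                 max_model = max_model,
                                 allometric_factors =
                                   config$allometric_factors)
  states <- character(n)
  climate <- matrix(NA_real_, n, 4L * 365L)
  for (i in seq_len(n)) {
    bin <- height_bin(dom_heights[i], config$height_bin_width)
    states[i] <- encode_state(vegetation_state(
      comps[[i]], lai_class(stand$lai[i], config$lai_edges), bin$lower))
    day <- assemble_daily(adj$trajectory, mapping, years[i])
    climate[i, ] <- c(day$tas, day$prec, day$rad, day$vpd)
  }
  colnames(climate) <- c(paste0("tas_", 1:365), paste0("prec_", 1:365),
                         paste0("rad_", 1:365), paste0("vpd_", 1:365))
  fixed <- data.frame(SourceID = stand$source_id,
                      SimulationID = id, Year = years,
                      vegetation_state = states,
                      dominant_height = dom_heights,
                      LAI = stand$lai,
                      WHC = soil$whc, TextureSand = soil$sand,
                      TextureSilt = soil$silt, TextureClay = soil$clay,
                      SoilDepth = soil$depth,
                      AvailableNitrogen = soil$available_n,
                      Scenario = sel$scenario_id)
  list(rows = cbind(fixed, as.data.frame(climate)),
       scenario_id = sel$scenario_id, cell_id = sel$cell_id,
       mapping = mapping, soil = soil)
}

#' Run the full harmonization pipeline
#'
#' Validates each contributed simulation, excludes (and logs) failures,
#' harmonizes the rest and writes one SQLite database per climate scenario,
#' a metadata database, a coverage report CSV, the resolved configuration
#' and a run log into `out_dir`. Every validated simulation-year yields
#' exactly one harmonized row in exactly one scenario database; a rerun
#' with identical inputs, configuration and seed reproduces the state
#' strings, soil vectors and year mappings.
#'
#' @param records,metadata Contributed tables (see [read_contribution()]).
#' @param catalogue A `scenario_catalogue`.
#' @param grids A `soil_grids` object.
#' @param config A `harmonization_config`; must carry a
#'   `height_calibration` table (or the contributed data must support the
#'   max-from-mean fit).
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output and returns the rows in memory only.
#' @return A list of class `harmonization_result`: `rows` (all harmonized
#'   rows), `per_scenario` (row counts), `excluded` (failing simulation
#'   ids), `coverage` (climate/soil coverage report), `mappings` (year
#'   mappings per simulation), `log` (character vector).
#' @export
run_harmonization <- function(records, metadata, catalogue, grids,
                              config = harmonization_config(),
                              out_dir = NULL) {
  stopifnot(inherits(config, "harmonization_config"),
            inherits(catalogue, "scenario_catalogue"),
            inherits(grids, "soil_grids"))
  log <- character(0)
  say <- function(...) log <<- c(log, paste0(...))

  report <- validate_contribution(records, metadata)
  excluded <- failing_ids(report)
  ids <- setdiff(unique(metadata$simulation_id), excluded)
  ids <- intersect(ids, unique(records$simulation_id))
  say("validation: ", length(ids), " simulations accepted, ",
      length(excluded), " excluded",
      if (length(excluded) > 0L)
        paste0(" (", paste(excluded, collapse = ", "), ")") else "")

  rates <- pseudo_rate(grids$cells$fertility_flux, grids$cells$pool)
  rate_model <- fit_rate_glm(data.frame(rate = rates,
                                        mat = grids$cells$mat,
                                        anp = grids$cells$anp,
                                        seas = grids$cells$seas,
                                        ph = grids$cells$ph))
  say("soil: pseudo-mineralization GLM calibrated on ",
      nrow(grids$cells), " cells, D2 = ", format(rate_model$d2, digits = 3))

  if (is.null(config$height_calibration)) {
    stop("config$height_calibration is required")
  }
  dom_model <- fit_dominant_height_model(config$height_calibration)
  max_model <- .fit_max_model(records[records$simulation_id %in% ids, ],
                              config)
  say("height: dominant-height and max-from-mean mixed models fitted")

  results <- list()
  for (id in ids) {
    meta <- metadata[metadata$simulation_id == id, ][1, ]
    res <- tryCatch(
      .harmonize_one(id, records, meta, catalogue, grids, rate_model,
                     dom_model, max_model, config),
      error = function(e) e)
    if (inherits(res, "error")) {
      say("warning: simulation ", id, " failed: ", conditionMessage(res))
      excluded <- c(excluded, id)
    } else {
      results[[id]] <- res
    }
  }
  rows <- do.call(rbind, lapply(results, `[[`, "rows"))
  rownames(rows) <- NULL
  per_scenario <- table(vapply(results, `[[`, "", "scenario_id"))
  say("harmonized ", nrow(rows), " simulation-years into ",
      length(per_scenario), " scenario database(s)")

  coverage <- .coverage_report(results, metadata, catalogue, grids)
  say("coverage: climate ", format(coverage$climate_pct, digits = 4),
      "%, soil ", format(coverage$soil_pct, digits = 4), "%")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (scen in names(per_scenario)) {
      db_rows <- rows[rows$Scenario == scen, ]
      write_harmonized_db(db_rows, scen,
                          file.path(out_dir, paste0(scen, ".sqlite")))
    }
    .write_metadata_db(results, metadata,
                       file.path(out_dir, "metadata.sqlite"))
    utils::write.csv(coverage$table,
                     file.path(out_dir, "coverage.csv"), row.names = FALSE)
    writeLines(.config_text(config), file.path(out_dir, "config_used.txt"))
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  structure(list(rows = rows, per_scenario = per_scenario,
                 excluded = unique(excluded), coverage = coverage,
                 mappings = lapply(results, `[[`, "mapping"),
                 validation = report, log = log),
            class = "harmonization_result")
}

#' @export
print.harmonization_result <- function(x, ...) {
  cat("<harmonization_result> ", nrow(x$rows), " rows, ",
      length(x$per_scenario), " scenarios, ", length(x$excluded),
      " excluded; climate coverage ",
      format(x$coverage$climate_pct, digits = 4), "%, soil coverage ",
      format(x$coverage$soil_pct, digits = 4), "%\n", sep = "")
  invisible(x)
}

.monthly_means <- function(tas_matrix) {
  # mean over years of the 12 monthly means of a daily matrix (years x 365)
  daily <- colMeans(tas_matrix)
  vapply(split(daily, .MONTH_OF_DOY), mean, 0)
}

.historical_climate_of_cell <- function(catalogue, cell_id) {
  hist_ids <- grep("^historical_", catalogue$scenario_ids, value = TRUE)
  traj <- catalogue$trajectories[[paste(hist_ids[1], cell_id, sep = "|")]]
  list(mat = mean(traj$annual$mat), anp = mean(traj$annual$anp),
       seas = seasonality(.monthly_means(traj$tas)))
}

.coverage_report <- function(results, metadata, catalogue, grids) {
  # climate space: strata of the matched grid cells' historical climate,
  # referenced against all catalogue cells, area-weighted by cos(latitude)
  ref_clim <- do.call(rbind, lapply(seq_len(nrow(catalogue$grid)),
                                    function(j) {
    cl <- .historical_climate_of_cell(catalogue, catalogue$grid$cell_id[j])
    cs <- climate_stratum(cl$mat, cl$anp, cl$seas)
    data.frame(cell_id = catalogue$grid$cell_id[j], stratum = cs$stratum,
               weight = cos(catalogue$grid$lat[j] * pi / 180))
  }))
  occ_cells <- unique(vapply(results, `[[`, "", "cell_id"))
  occupied_clim <- unique(ref_clim$stratum[ref_clim$cell_id %in% occ_cells])
  climate_pct <- coverage_fraction(occupied_clim, ref_clim)

  # soil space: strata of the completed soil vectors, referenced against the
  # soil grid cells
  cells <- grids$cells
  ref_soil <- data.frame(
    stratum = soil_stratum(texture_class(cells$sand, cells$silt, cells$clay),
                           cells$whc,
                           grids$truth$available_n_true)$stratum,
    weight = cos(cells$lat * pi / 180))
  occupied_soil <- unique(vapply(results, function(r) {
    s <- r$soil
    soil_stratum(texture_class(s$sand, s$silt, s$clay), s$whc,
                 s$available_n)$stratum
  }, ""))
  soil_pct <- coverage_fraction(occupied_soil, ref_soil)

  list(climate_pct = climate_pct, soil_pct = soil_pct,
       occupied_climate = occupied_clim, occupied_soil = occupied_soil,
       table = data.frame(space = c("climate", "soil"),
                          occupied_strata = c(length(occupied_clim),
                                              length(occupied_soil)),
                          covered_area_pct = c(climate_pct, soil_pct)))
}

.write_metadata_db <- function(results, metadata, path) {
  meta <- metadata[metadata$simulation_id %in% names(results), ]
  soil <- do.call(rbind, lapply(names(results), function(id) {
    s <- results[[id]]$soil
    data.frame(simulation_id = id, WHC = s$whc, TextureSand = s$sand,
               TextureSilt = s$silt, TextureClay = s$clay,
               SoilDepth = s$depth, AvailableNitrogen = s$available_n,
               Scenario = results[[id]]$scenario_id)
  }))
  keep <- intersect(c("source_id", "simulation_id", "latitude", "longitude",
                      "trajectory_family", "management", "model_name",
                      "model_level"), names(meta))
  out <- merge(meta[keep], soil, by = "simulation_id")
  if (file.exists(path)) unlink(path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbWriteTable(con, "metadata", out)
  invisible(path)
}

.config_text <- function(config) {
  c("# resolved harmonization configuration",
    paste0("seed: ", config$seed),
    paste0("weight: ", config$weight),
    paste0("dominance_threshold: ", config$dominance_threshold),
    paste0("admixture_threshold: ", config$admixture_threshold),
    paste0("lai_edges: ", paste(config$lai_edges, collapse = ", ")),
    paste0("height_bin_width: ", config$height_bin_width),
    paste0("fertility_values: ",
           paste(config$fertility_values, collapse = ", ")),
    paste0("allometric_factors: ",
           paste(names(config$allometric_factors),
                 config$allometric_factors, sep = "=", collapse = "; ")),
    paste0("height_calibration_rows: ",
           if (is.null(config$height_calibration)) 0
           else nrow(config$height_calibration)))
}
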