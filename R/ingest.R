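# Contributor-table ingest and the harmonized SQLite databases.
#
# Canonical contributor dialect: the simulation file is long, with species
# rows carrying (species, share) and one stand row per year (empty species)
# carrying heights and LAI; the metadata file has one row per simulation
# with the annual temperature/precipitation series packed as ';'-separated
# strings ordered by year. UTF-8, comma-delimited, decimal point.

.SIM_COLUMNS <- c("source_id", "simulation_id", "year", "species", "share",
                  "height_min", "height_mean", "height_max", "lai")
.META_COLUMNS <- c("source_id", "simulation_id", "latitude", "longitude",
                   "trajectory_family", "annual_temperature",
                   "annual_precipitation")

#' Read a contributor simulation/metadata pair
#'
#' Reads and types the two contributed CSV files. Unknown columns are kept
#' but ignored downstream; missing mandatory columns raise a schema error
#' naming the column; unparseable numeric values raise a row-level error.
#'
#' @param sim_path Path to the simulation data CSV.
#' @param meta_path Path to the metadata CSV.
#' @return List with `records` (long simulation data.frame) and `metadata`
#'   (one row per simulation; annual series stay ';'-packed and can be
#'   unpacked with [annual_series()]).
#' @export
read_contribution <- function(sim_path, meta_path) {
  for (p in c(sim_path, meta_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  records <- utils::read.csv(sim_path, stringsAsFactors = FALSE,
                             colClasses = "character")
  missing <- setdiff(.SIM_COLUMNS, names(records))
  if (length(missing) > 0L) {
    stop("simulation file missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  num_cols <- c("year", "share", "height_min", "height_mean", "height_max",
                "lai")
  for (col in num_cols) {
    raw <- records[[col]]
    parsed <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(raw) & is.na(parsed))
    if (length(bad) > 0L) {
      stop("unparseable numeric in column ", sQuote(col), " at row ", bad[1])
    }
    records[[col]] <- parsed
  }
  records$year <- as.integer(records$year)

  metadata <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  missing <- setdiff(.META_COLUMNS, names(metadata))
  if (length(missing) > 0L) {
    stop("metadata file missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  list(records = records, metadata = metadata)
}

#' Unpack a ';'-separated annual series
#' @param x Packed string (or numeric vector, returned as is).
#' @return Numeric vector.
#' @export
annual_series <- function(x) .parse_series(x)

.looks_binomial <- function(species) {
  vapply(species, function(s) {
    parts <- strsplit(trimws(s), "\\s+")[[1]]
    length(parts) >= 2L && all(nchar(parts[1:2]) >= 2L)
  }, TRUE)
}

#' Validate a contribution
#'
#' Runs the contribution checks: (a) records and metadata reference exactly
#' the same simulation ids, one metadata row each; (b) years are continuous
#' (no gaps, no duplicates) within each simulation, and the packed annual
#' climate series cover every simulation year; (c) every simulation-year
#' provides the required indicators — species shares resolvable, at least
#' one height statistic, and LAI; (d) species are reported at species level
#' (Latin binomials, not plant-functional-type labels). Failures are
#' reported, never raised.
#'
#' @param records,metadata As returned by [read_contribution()].
#' @return A data.frame of class `validation_report` with columns `check`,
#'   `status`, `ids`, `message`; attribute `pass` is TRUE iff every check
#'   passed.
#' @export
validate_contribution <- function(records, metadata) {
  checks <- list()
  add <- function(check, ok, ids, msg_fail, msg_pass) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, status = if (ok) "pass" else "fail",
      ids = paste(ids, collapse = ","),
      message = if (ok) msg_pass else msg_fail)
  }

  rec_ids <- unique(records$simulation_id)
  meta_ids <- metadata$simulation_id
  orphans <- setdiff(rec_ids, meta_ids)
  childless <- setdiff(meta_ids, rec_ids)
  dup <- meta_ids[duplicated(meta_ids)]
  bad_ids <- unique(c(orphans, childless, dup))
  add("id_match", length(bad_ids) == 0L, bad_ids,
      "simulation ids without a unique metadata match",
      "records and metadata ids match one-to-one")

  gap_ids <- character(0); series_ids <- character(0)
  indicator_ids <- character(0)
  for (id in intersect(rec_ids, meta_ids)) {
    rec <- records[records$simulation_id == id, ]
    yrs <- sort(unique(rec$year))
    if (length(yrs) == 0L || any(diff(yrs) != 1L)) gap_ids <- c(gap_ids, id)
    m <- metadata[metadata$simulation_id == id, ][1, ]
    at <- .parse_series(m$annual_temperature)
    ap <- .parse_series(m$annual_precipitation)
    if (length(at) != length(yrs) || length(ap) != length(yrs) ||
        any(is.na(at)) || any(is.na(ap))) {
      series_ids <- c(series_ids, id)
    }
    stand <- rec[is.na(rec$species) | !nzchar(rec$species), ]
    ok_ind <- nrow(stand) == length(yrs) &&
      all(!is.na(stand$lai)) &&
      all(!is.na(stand$height_min) | !is.na(stand$height_mean) |
            !is.na(stand$height_max))
    if (!ok_ind) indicator_ids <- c(indicator_ids, id)
  }
  add("year_continuity", length(gap_ids) == 0L, gap_ids,
      "years with gaps or duplicates", "annual series are continuous")
  add("annual_climate_series", length(series_ids) == 0L, series_ids,
      "annual T/P series do not cover every simulation year",
      "annual climate series complete")
  add("required_indicators", length(indicator_ids) == 0L, indicator_ids,
      "missing species shares, height statistic or LAI",
      "species shares, height and LAI present for every year")

  sp_rows <- records[!is.na(records$species) & nzchar(records$species), ]
  bad_sp <- unique(sp_rows$species[!.looks_binomial(sp_rows$species)])
  add("species_level", length(bad_sp) == 0L, bad_sp,
      "non-binomial species labels (functional types are not accepted)",
      "all species reported as Latin binomials")

  share_bad <- unique(sp_rows$simulation_id[
    is.na(sp_rows$share) | sp_rows$share < 0 | sp_rows$share > 1])
  if (nrow(sp_rows) > 0L && any(!is.na(sp_rows$share))) {
    sums <- stats::aggregate(share ~ simulation_id + year, data = sp_rows,
                             FUN = sum)
    share_bad <- unique(c(share_bad,
                          sums$simulation_id[sums$share > 1 + 1e-6]))
  }
  add("share_range", length(share_bad) == 0L, share_bad,
      "shares outside [0,1] or summing above 1",
      "basal-area shares within bounds")

  report <- do.call(rbind, checks)
  attr(report, "pass") <- all(report$status == "pass")
  class(report) <- c("validation_report", class(report))
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", if (attr(x, "pass")) "PASS" else "FAIL", "\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  [%s] %-22s %s\n", x$status[i], x$check[i],
                if (x$status[i] == "fail" && nzchar(x$ids[i]))
                  paste0(x$message[i], " (", x$ids[i], ")")
                else x$message[i]))
  }
  invisible(x)
}

#' Did a validation report pass overall?
#' @param report A `validation_report`.
#' @return TRUE iff every check passed.
#' @export
validation_passed <- function(report) isTRUE(attr(report, "pass"))

#' Simulation ids failing any validation check
#' @param report A `validation_report`.
#' @return Character vector of offending ids.
#' @export
failing_ids <- function(report) {
  unique(unlist(strsplit(report$ids[report$status == "fail"], ",")))
}

.DB_FIXED_COLUMNS <- c("SourceID", "SimulationID", "Year", "vegetation_state",
                       "dominant_height", "LAI", "WHC", "TextureSand",
                       "TextureSilt", "TextureClay", "SoilDepth",
                       "AvailableNitrogen", "Scenario")

#' Column names of the harmonized database table
#'
#' The fixed identification/vegetation/soil/scenario columns followed by the
#' 4 x 365 wide daily climate columns `tas_1..tas_365`, `prec_1..prec_365`,
#' `rad_1..rad_365`, `vpd_1..vpd_365`.
#' @return Character vector of 1473 column names.
#' @export
harmonized_columns <- function() {
  c(.DB_FIXED_COLUMNS,
    paste0("tas_", 1:365), paste0("prec_", 1:365),
    paste0("rad_", 1:365), paste0("vpd_", 1:365))
}

#' Write harmonized rows to a per-scenario SQLite database
#'
#' Creates (overwrites) an SQLite file with a single table `simulations`
#' whose columns follow the harmonized schema. All rows must belong to the
#' given scenario.
#'
#' @param rows A data.frame with the columns of [harmonized_columns()].
#' @param scenario Scenario label the database represents.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_harmonized_db <- function(rows, scenario, path) {
  cols <- harmonized_columns()
  missing <- setdiff(cols, names(rows))
  if (length(missing) > 0L) {
    stop("rows missing column(s): ", paste(utils::head(missing, 5),
                                           collapse = ", "))
  }
  if (nrow(rows) > 0L && any(rows$Scenario != scenario)) {
    stop("rows from a different scenario than ", sQuote(scenario))
  }
  rows <- rows[cols]
  if (file.exists(path)) unlink(path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbWriteTable(con, "simulations", rows)
  invisible(path)
}

#' Read a harmonized SQLite database
#'
#' @param path Path to a database written by [write_harmonized_db()].
#' @return The `simulations` table as a data.frame; a missing column raises
#'   a schema error.
#' @export
read_harmonized_db <- function(path) {
  if (!file.exists(path)) stop("database not found: ", path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  if (!"simulations" %in% DBI::dbListTables(con)) {
    stop("database has no 'simulations' table")
  }
  rows <- DBI::dbReadTable(con, "simulations")
  missing <- setdiff(harmonized_columns(), names(rows))
  if (length(missing) > 0L) {
    stop("database missing column(s): ", paste(utils::head(missing, 5),
                                               collapse = ", "))
  }
  rows
}
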