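#' Temperature seasonality index
#'
#' Standard deviation of the twelve monthly mean temperatures, multiplied by
#' 100 (the convention used for bioclimatic seasonality layers). The
#' population standard deviation (divisor n) is used.
#'
#' @param monthly_means Numeric vector of exactly 12 monthly mean
#'   temperatures (degrees C).
#' @return Seasonality index (unitless).
#' @export
seasonality <- function(monthly_means) {
  stopifnot(is.numeric(monthly_means))
  if (length(monthly_means) != 12L) {
    stop("seasonality requires exactly 12 monthly means")
  }
  if (any(is.na(monthly_means))) stop("missing monthly means")
  100 * sqrt(mean((monthly_means - mean(monthly_means))^2))
}

# Bin edges as printed interval lists; intervals are half-open [low, high),
# so a value on an edge falls into the upper bin.
.mat_edges <- c(-2, 2, 4, 6, 8, 10, 12, 14, 18)
.anp_edges <- c(400, 550, 750, 1000, 1400, 2000)
.seas_edges <- c(200, 400, 500, 600, 700, 900)
.whc_edges <- c(50, 100, 150, 180)
.n_edges <- c(20, 40, 65, 100)

.bin_index <- function(x, edges) {
  # number of edges <= x, plus 1: values on an edge go to the upper bin
  findInterval(x, edges, left.open = FALSE) + 1L
}

#' Climate stratum of a location
#'
#' Assigns mean annual temperature (ten bins with edges -2, 2, 4, 6, 8, 10,
#' 12, 14, 18 degrees C), annual precipitation sum (seven bins with edges
#' 400, 550, 750, 1000, 1400, 2000 mm) and temperature seasonality (seven
#' bins with edges 200, 400, 500, 600, 700, 900) to their stratified bins.
#' All intervals are half-open \[low, high).
#'
#' @param mat Mean annual temperature (degrees C).
#' @param anp Annual precipitation sum (mm).
#' @param seas Temperature seasonality index (see [seasonality()]).
#' @return A data.frame with integer columns `mat_bin` (1..10), `anp_bin`
#'   (1..7), `seas_bin` (1..7) and a `stratum` key string; one row per input.
#' @export
climate_stratum <- function(mat, anp, seas) {
  stopifnot(is.finite(mat), is.finite(anp), is.finite(seas))
  mat_bin <- .bin_index(mat, .mat_edges)
  anp_bin <- .bin_index(anp, .anp_edges)
  seas_bin <- .bin_index(seas, .seas_edges)
  data.frame(mat_bin = mat_bin, anp_bin = anp_bin, seas_bin = seas_bin,
             stratum = paste(mat_bin, anp_bin, seas_bin, sep = "-"))
}

#' European Soil Database style texture class
#'
#' Classifies soil texture from sand/silt/clay percentages into five classes
#' from coarse (1) to very fine (5), following the European Soil Database
#' scheme: coarse (clay < 18%, sand > 65%), medium, medium-fine (clay < 35%,
#' sand < 15%), fine (35% <= clay < 60%), very fine (clay >= 60%). The
#' clay/sand thresholds are configurable.
#'
#' @param sand,silt,clay Texture percentages, summing to 100 within 1.
#' @param thresholds Named list of cutoffs: `clay_very_fine` (60),
#'   `clay_fine` (35), `clay_coarse` (18), `sand_coarse` (65),
#'   `sand_medium_fine` (15).
#' @return Integer texture class 1..5 (vectorized).
#' @export
texture_class <- function(sand, silt, clay,
                          thresholds = list(clay_very_fine = 60,
                                            clay_fine = 35,
                                            clay_coarse = 18,
                                            sand_coarse = 65,
                                            sand_medium_fine = 15)) {
  total <- sand + silt + clay
  if (any(is.na(total)) || any(abs(total - 100) > 1)) {
    stop("texture fractions must sum to 100 within 1")
  }
  t <- thresholds
  ifelse(clay >= t$clay_very_fine, 5L,
  ifelse(clay >= t$clay_fine, 4L,
  ifelse(clay < t$clay_coarse & sand > t$sand_coarse, 1L,
  ifelse(sand < t$sand_medium_fine, 3L, 2L))))
}

#' Soil stratum of a location
#'
#' Combines the texture class with stratified bins of water holding capacity
#' (edges 50, 100, 150, 180 mm) and plant-available nitrogen (edges 20, 40,
#' 65, 100 kg/ha/yr), half-open intervals.
#'
#' @param texture_class Integer texture class 1..5 (see [texture_class()]).
#' @param whc Water holding capacity (mm).
#' @param available_n Plant-available nitrogen (kg/ha/yr).
#' @return A data.frame with `texture_class`, `whc_bin`, `n_bin` and a
#'   `stratum` key string; one row per input.
#' @export
soil_stratum <- function(texture_class, whc, available_n) {
  stopifnot(is.finite(whc), is.finite(available_n), whc >= 0,
            available_n >= 0, texture_class %in% 1:5)
  whc_bin <- .bin_index(whc, .whc_edges)
  n_bin <- .bin_index(available_n, .n_edges)
  data.frame(texture_class = as.integer(texture_class), whc_bin = whc_bin,
             n_bin = n_bin,
             stratum = paste(texture_class, whc_bin, n_bin, sep = "-"))
}

#' Fraction of a reference area covered by occupied strata
#'
#' Given the set of strata occupied by simulations and a reference grid in
#' which every cell carries its stratum key and an area weight (typically
#' cos(latitude) of the cell centre, supplied by the caller), returns the
#' percentage of total reference area whose stratum is occupied.
#'
#' @param occupied Character vector of occupied stratum keys.
#' @param reference A data.frame with columns `stratum` and `weight`
#'   (weights > 0).
#' @return Covered area fraction in percent (0..100).
#' @export
coverage_fraction <- function(occupied, reference) {
  stopifnot(is.data.frame(reference),
            all(c("stratum", "weight") %in% names(reference)))
  if (nrow(reference) == 0L) stop("empty reference grid")
  if (any(reference$weight <= 0)) stop("weights must be positive")
  covered <- reference$stratum %in% occupied
  100 * sum(reference$weight[covered]) / sum(reference$weight)
}
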