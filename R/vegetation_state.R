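#' Four-letter species code
#'
#' Builds the canonical species code from a Latin binomial: the first two
#' letters of the genus followed by the first two letters of the epithet.
#' Dominant species are written in uppercase (`"Pinus sylvestris"` ->
#' `"PISY"`), admixed species in lowercase (`"Fagus sylvatica"` -> `"fasy"`).
#'
#' @param name Species name as `"Genus epithet"`; surrounding whitespace is
#'   trimmed and case is ignored. Both words must have at least two letters.
#' @param role Either `"dominant"` or `"admixed"`; controls capitalization.
#' @return A four-character code.
#' @examples
#' species_code("Pinus sylvestris", "dominant")  # "PISY"
#' species_code("Fagus sylvatica", "admixed")    # "fasy"
#' @export
species_code <- function(name, role = c("dominant", "admixed")) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, !is.na(name))
  parts <- strsplit(trimws(name), "\\s+")[[1]]
  if (length(parts) < 2L) {
    stop("species name must contain genus and epithet: ", sQuote(name))
  }
  genus <- parts[[1]]
  epithet <- parts[[2]]
  if (nchar(genus) < 2L || nchar(epithet) < 2L) {
    stop("genus and epithet must each have >= 2 characters: ", sQuote(name))
  }
  code <- paste0(substr(genus, 1L, 2L), substr(epithet, 1L, 2L))
  if (role == "dominant") toupper(code) else tolower(code)
}

#' Classify stand composition into dominant and admixed species
#'
#' A species is dominant when its basal-area share exceeds
#' `dominance_threshold` (strictly), and admixed when its share is at least
#' `admixture_threshold`. Since shares sum to at most 1, at most one species
#' can be dominant. Admixed species are ordered by descending share, ties
#' broken alphabetically by species code.
#'
#' @param shares Named numeric vector of basal-area shares (fractions in
#'   \[0, 1\]) with species names (`"Genus epithet"`) as names; the shares
#'   must sum to at most 1 (tolerance 1e-6).
#' @param dominance_threshold Share above which a species is dominant
#'   (default 0.66, applied as strictly greater).
#' @param admixture_threshold Minimum share of an admixed species
#'   (default 0.20, applied as greater or equal).
#' @return A list of class `composition_state` with elements `dominant`
#'   (species name or `NA`) and `admixed` (character vector of species names,
#'   possibly empty).
#' @examples
#' classify_composition(c("Picea abies" = 0.70, "Fagus sylvatica" = 0.25))
#' @export
classify_composition <- function(shares,
                                 dominance_threshold = 0.66,
                                 admixture_threshold = 0.20) {
  if (length(shares) == 0L) {
    return(structure(list(dominant = NA_character_, admixed = character(0)),
                     class = "composition_state"))
  }
  stopifnot(is.numeric(shares), !is.null(names(shares)))
  if (any(is.na(shares))) stop("missing share values")
  if (any(shares < 0)) stop("negative basal-area share")
  if (sum(shares) > 1 + 1e-6) stop("shares sum to more than 1")
  dominant <- names(shares)[shares > dominance_threshold]
  dominant <- if (length(dominant) == 1L) dominant else NA_character_
  is_adm <- shares >= admixture_threshold &
    (is.na(dominant) | names(shares) != dominant)
  adm <- shares[is_adm]
  if (length(adm) > 0L) {
    codes <- vapply(names(adm), species_code, "", role = "admixed")
    adm <- adm[order(-adm, codes)]
  }
  structure(list(dominant = dominant, admixed = names(adm)),
            class = "composition_state")
}

#' Leaf-area-index class
#'
#' Maps LAI to class 1 (sparse, LAI < 2), class 2 (moderate, 2 <= LAI <= 4)
#' or class 3 (dense, LAI > 4).
#'
#' @param lai Leaf area index (m2/m2), non-negative.
#' @param edges Class edges: class 1 below `edges[1]`, class 2 up to and
#'   including `edges[2]`, class 3 above.
#' @return Integer class 1, 2 or 3 (vectorized).
#' @export
lai_class <- function(lai, edges = c(2, 4)) {
  stopifnot(is.numeric(lai), length(edges) == 2L, edges[1] < edges[2])
  if (any(is.na(lai)) || any(lai < 0)) stop("lai must be non-negative")
  ifelse(lai < edges[1], 1L, ifelse(lai <= edges[2], 2L, 3L))
}

#' Two-metre dominant-height bin
#'
#' Assigns a dominant height to its 2-m bin. Bins are half-open
#' \[lower, upper): a height exactly on a boundary falls into the upper bin.
#'
#' @param height Dominant height in metres, non-negative.
#' @param width Bin width in metres (default 2).
#' @return A list with integer `lower` and `upper` (= lower + width); for a
#'   vector input, a two-column matrix.
#' @export
height_bin <- function(height, width = 2L) {
  stopifnot(is.numeric(height), width > 0)
  if (any(is.na(height)) || any(height < 0)) {
    stop("height must be non-negative")
  }
  width <- as.integer(width)
  lower <- width * as.integer(floor(height / width))
  if (length(height) == 1L) {
    list(lower = lower, upper = lower + width)
  } else {
    cbind(lower = lower, upper = lower + width)
  }
}

#' Assemble a vegetation state
#'
#' Bundles composition, LAI class and height bin into a `vegetation_state`
#' object, the unit that [encode_state()] serializes.
#'
#' @param composition A `composition_state` from [classify_composition()].
#' @param lai_class Integer 1, 2 or 3.
#' @param height_lower Lower edge of the 2-m height bin (even, >= 0).
#' @return An object of class `vegetation_state`.
#' @export
vegetation_state <- function(composition, lai_class, height_lower) {
  stopifnot(inherits(composition, "composition_state"),
            lai_class %in% 1:3,
            height_lower >= 0, height_lower %% 2 == 0)
  structure(list(composition = composition,
                 lai_class = as.integer(lai_class),
                 height_lower = as.integer(height_lower),
                 height_upper = as.integer(height_lower) + 2L),
            class = "vegetation_state")
}

#' @export
print.vegetation_state <- function(x, ...) {
  cat("<vegetation_state> ", encode_state(x), "\n", sep = "")
  invisible(x)
}

#' Encode a vegetation state as its canonical string
#'
#' The string is the uppercase dominant code followed by lowercase admixed
#' codes, an underscore, the LAI class, and the height-bin edges, e.g.
#' `"PIABfasy_3_20_22"` for a stand dominated by Picea abies with admixed
#' Fagus sylvatica, a dense canopy and a dominant height between 20 and 22 m.
#' When no species is dominant the composition block is the concatenated
#' lowercase admixed codes; when additionally no species reaches the
#' admixture threshold, the literal token `"mixd"` is used.
#'
#' @param state A `vegetation_state`.
#' @return The state string.
#' @export
encode_state <- function(state) {
  stopifnot(inherits(state, "vegetation_state"))
  comp <- state$composition
  block <- ""
  if (!is.na(comp$dominant)) {
    block <- species_code(comp$dominant, "dominant")
  }
  if (length(comp$admixed) > 0L) {
    block <- paste0(block, paste(
      vapply(comp$admixed, species_code, "", role = "admixed"),
      collapse = ""))
  }
  if (block == "") block <- "mixd"
  paste(block, state$lai_class, state$height_lower, state$height_upper,
        sep = "_")
}

#' Parse a vegetation-state string
#'
#' Exact inverse of [encode_state()] up to species codes: the composition is
#' returned as codes (the full Latin names are not recoverable from a code).
#'
#' @param text A state string such as `"PIABfasy_3_20_22"`.
#' @return A list of class `decoded_state` with `dominant` (4-letter
#'   uppercase code or `NA`), `admixed` (lowercase codes), `lai_class`,
#'   `height_lower`, `height_upper`.
#' @export
decode_state <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  parts <- strsplit(text, "_", fixed = TRUE)[[1]]
  if (length(parts) != 4L) {
    stop("malformed state string (expected 4 '_'-separated fields): ",
         sQuote(text))
  }
  block <- parts[[1]]
  lai <- suppressWarnings(as.integer(parts[[2]]))
  lower <- suppressWarnings(as.integer(parts[[3]]))
  upper <- suppressWarnings(as.integer(parts[[4]]))
  if (is.na(lai) || !(lai %in% 1:3)) {
    stop("LAI class out of range in ", sQuote(text))
  }
  if (is.na(lower) || is.na(upper) || upper != lower + 2L || lower < 0L ||
      lower %% 2L != 0L) {
    stop("invalid height bin in ", sQuote(text))
  }
  dominant <- NA_character_
  admixed <- character(0)
  if (block != "mixd") {
    if (nchar(block) == 0L || nchar(block) %% 4L != 0L) {
      stop("composition block length must be a multiple of 4 at position 1 in ",
           sQuote(text))
    }
    codes <- substring(block, seq(1L, nchar(block), by = 4L),
                       seq(4L, nchar(block), by = 4L))
    is_upper <- codes == toupper(codes) & codes != tolower(codes)
    is_lower <- codes == tolower(codes)
    if (any(!is_upper & !is_lower)) {
      stop("mixed-case species code at position ",
           4L * (which(!is_upper & !is_lower)[1] - 1L) + 1L,
           " in ", sQuote(text))
    }
    if (any(is_upper)) {
      if (sum(is_upper) > 1L || which(is_upper) != 1L) {
        stop("dominant (uppercase) code must be unique and first in ",
             sQuote(text))
      }
      dominant <- codes[1L]
      admixed <- codes[-1L]
    } else {
      admixed <- codes
    }
  }
  structure(list(dominant = dominant, admixed = admixed,
                 lai_class = lai, height_lower = lower,
                 height_upper = upper),
            class = "decoded_state")
}

#' One-call state string for a stand-year
#'
#' Convenience wrapper combining [classify_composition()], [lai_class()],
#' [height_bin()] and [encode_state()].
#'
#' @inheritParams classify_composition
#' @param lai Leaf area index (m2/m2).
#' @param dominant_height Dominant stand height (m).
#' @return The canonical state string.
#' @examples
#' stand_state(c("Picea abies" = 0.70, "Fagus sylvatica" = 0.25),
#'             lai = 4.5, dominant_height = 21)
#' @export
stand_state <- function(shares, lai, dominant_height,
                        dominance_threshold = 0.66,
                        admixture_threshold = 0.20) {
  comp <- classify_composition(shares, dominance_threshold,
                               admixture_threshold)
  bin <- height_bin(dominant_height)
  encode_state(vegetation_state(comp, lai_class(lai), bin$lower))
}
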