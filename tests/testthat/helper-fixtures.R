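# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# full default catalogue: 12 scenarios, one 0.11-degree cell, 90 years
fixture_catalogue <- function() {
  cached("catalogue", function() gen_scenario_catalogue(seed = 42))
}

# small catalogue for cheap structural tests
small_catalogue <- function() {
  cached("small_catalogue", function() {
    gen_scenario_catalogue(n_gcm = 2, rcp_list = "rcp85",
                           years = 2011:2040, seed = 7)
  })
}

fixture_simset <- function() {
  cached("simset", function() {
    gen_simulation_set(fixture_catalogue(), n_sims = 50, seed = 7)
  })
}

fixture_grids <- function() {
  cached("grids", function() gen_soil_grids(seed = 3))
}

fixture_calibration_species <- function() {
  c("Alnus glutinosa", "Betula pendula", "Carpinus betulus",
    "Fraxinus excelsior", "Tilia cordata", "Acer pseudoplatanus",
    "Picea abies", "Fagus sylvatica", "Pinus sylvestris", "Quercus robur",
    "Abies alba")
}

fixture_dom_model <- function() {
  cached("dom_model", function() {
    cal <- gen_height_calibration(60, fixture_calibration_species(),
                                  seed = 5)
    fit_dominant_height_model(cal)
  })
}

fixture_max_model <- function() {
  cached("max_model", function() {
    cal <- gen_height_calibration(60, fixture_calibration_species(),
                                  seed = 5)
    fit_max_from_mean(cal)
  })
}

# a random valid vegetation_state for round-trip property tests
random_state <- function() {
  pool <- c("Picea abies", "Fagus sylvatica", "Pinus sylvestris",
            "Quercus robur", "Abies alba", "Larix decidua")
  k <- sample(0:3, 1)
  shares <- c()
  if (k > 0) {
    sp <- sample(pool, k)
    if (runif(1) < 0.5) {
      shares <- stats::setNames(c(0.70, 0.22, 0.05)[seq_len(k)] *
                                  runif(1, 0.9, 1), sp)
    } else {
      w <- runif(k, 0.05, 0.4)
      shares <- stats::setNames(w / max(sum(w), 1), sp)
    }
  }
  comp <- classify_composition(shares)
  vegetation_state(comp, sample(1:3, 1), 2 * sample(0:24, 1))
}
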