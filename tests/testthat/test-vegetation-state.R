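test_that("species codes follow the 2+2 rule with role-dependent case", {
  expect_identical(species_code("Pinus sylvestris", "dominant"), "PISY")
  expect_identical(species_code("Fagus sylvatica", "admixed"), "fasy")
  expect_identical(species_code("Quercus robur", "dominant"), "QURO")
  expect_identical(species_code("  picea ABIES ", "admixed"), "piab")
  expect_error(species_code("Picea", "dominant"), "genus and epithet")
  expect_error(species_code("Quercus x", "dominant"), "2 characters")
})

test_that("composition classification applies the dominance and admixture thresholds", {
  comp <- classify_composition(c("Picea abies" = 0.70,
                                 "Fagus sylvatica" = 0.25,
                                 "Abies alba" = 0.05))
  expect_identical(comp$dominant, "Picea abies")
  expect_identical(comp$admixed, "Fagus sylvatica")

  # no species above 66%: all >= 20% are admixed, ordered by descending share
  comp <- classify_composition(c("Pinus sylvestris" = 0.50,
                                 "Fagus sylvatica" = 0.30,
                                 "Quercus robur" = 0.20))
  expect_true(is.na(comp$dominant))
  expect_identical(comp$admixed, c("Pinus sylvestris", "Fagus sylvatica",
                                   "Quercus robur"))

  # thresholds are strict (>) for dominance and inclusive (>=) for admixture
  comp <- classify_composition(c("Picea abies" = 0.66,
                                 "Fagus sylvatica" = 0.20))
  expect_true(is.na(comp$dominant))
  expect_identical(comp$admixed, c("Picea abies", "Fagus sylvatica"))

  empty <- classify_composition(c())
  expect_true(is.na(empty$dominant))
  expect_length(empty$admixed, 0)

  expect_error(classify_composition(c("Picea abies" = -0.1)), "negative")
  expect_error(classify_composition(c("Picea abies" = 0.7,
                                      "Abies alba" = 0.5)), "sum")
})

test_that("composition is invariant to the ordering of the share map", {
  shares <- c("Picea abies" = 0.4, "Fagus sylvatica" = 0.3,
              "Quercus robur" = 0.25)
  for (i in 1:10) {
    perm <- sample(shares)
    expect_identical(classify_composition(perm),
                     classify_composition(shares))
  }
})

test_that("LAI classes split at 2 and 4 with closed middle class", {
  expect_identical(lai_class(0.0), 1L)
  expect_identical(lai_class(1.99), 1L)
  expect_identical(lai_class(2.0), 2L)
  expect_identical(lai_class(4.0), 2L)
  expect_identical(lai_class(4.01), 3L)
  expect_identical(lai_class(4.5), 3L)
  expect_error(lai_class(-0.1), "non-negative")
  # monotone non-decreasing
  x <- sort(runif(200, 0, 8))
  expect_true(all(diff(lai_class(x)) >= 0))
})

test_that("height bins are half-open 2-m intervals", {
  expect_identical(height_bin(21.0), list(lower = 20L, upper = 22L))
  expect_identical(height_bin(0.0), list(lower = 0L, upper = 2L))
  expect_identical(height_bin(20.0), list(lower = 20L, upper = 22L))
  expect_error(height_bin(-1), "non-negative")
  # oracle: floor arithmetic on random heights
  h <- runif(500, 0, 60)
  bins <- height_bin(h)
  expect_equal(bins[, "lower"], 2 * floor(h / 2))
  expect_true(all(h >= bins[, "lower"] & h < bins[, "upper"]))
})

test_that("state strings encode composition, LAI class and height bin", {
  comp <- classify_composition(c("Picea abies" = 0.70,
                                 "Fagus sylvatica" = 0.25))
  st <- vegetation_state(comp, 3L, 20L)
  expect_identical(encode_state(st), "PIABfasy_3_20_22")

  # no dominant: lowercase block in share order
  comp <- classify_composition(c("Pinus sylvestris" = 0.45,
                                 "Fagus sylvatica" = 0.35))
  expect_identical(encode_state(vegetation_state(comp, 2L, 10L)),
                   "pisyfasy_2_10_12")

  # no species at the admixture threshold: the mixd token
  comp <- classify_composition(c("Pinus sylvestris" = 0.1))
  expect_identical(encode_state(vegetation_state(comp, 1L, 0L)),
                   "mixd_1_0_2")
})

test_that("decoding inverts encoding and rejects malformed strings", {
  d <- decode_state("PIABfasy_3_20_22")
  expect_identical(d$dominant, "PIAB")
  expect_identical(d$admixed, "fasy")
  expect_identical(d$lai_class, 3L)
  expect_identical(c(d$height_lower, d$height_upper), c(20L, 22L))

  d <- decode_state("PISY_1_0_2")
  expect_identical(d$dominant, "PISY")
  expect_length(d$admixed, 0)

  expect_error(decode_state("PIAB_5_20_22"), "out of range")
  expect_error(decode_state("PIAB_3_20"), "malformed")
  expect_error(decode_state("PIABfas_3_20_22"), "multiple of 4")
  expect_error(decode_state("piabFASY_3_20_22"), "first")

  # property: decode(encode(s)) preserves all state components
  set.seed(421)
  for (i in 1:50) {
    s <- random_state()
    d <- decode_state(encode_state(s))
    expect_identical(d$lai_class, s$lai_class)
    expect_identical(d$height_lower, s$height_lower)
    if (!is.na(s$composition$dominant)) {
      expect_identical(d$dominant,
                       species_code(s$composition$dominant, "dominant"))
    } else {
      expect_true(is.na(d$dominant))
    }
    expect_identical(d$admixed,
                     unname(vapply(s$composition$admixed, species_code, "",
                                   role = "admixed")))
  }
})

test_that("at most one species can exceed the dominance threshold", {
  set.seed(99)
  for (i in 1:200) {
    k <- sample(1:5, 1)
    w <- runif(k)
    shares <- w / sum(w) * runif(1, 0.5, 1)
    expect_lte(sum(shares > 0.66), 1)
  }
})
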