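test_that("a constant five-layer grid loads with every cell on land", {
  dir <- withr::local_tempdir()
  ls0 <- uniform_landscape(10L, 10L, mp = 10, burning = 0)
  paths <- write_landscape(ls0, dir)
  ls <- load_landscape(paths)
  expect_s3_class(ls, "harrier_landscape")
  expect_equal(sum(ls$land), 100L)
})

test_that("write/load round-trips layer values and georeference", {
  dir <- withr::local_tempdir()
  ls0 <- generate_synthetic_landscape(
    landscape_spec(15L, 12L, seed = 11, sea_margin = 2L,
                   origin_easting = 55000, origin_northing = 12000))
  paths <- write_landscape(ls0, dir)
  ls <- load_landscape(paths)
  for (layer in c("mp", "burning", "suitability", "heath", "altitude"))
    expect_equal(ls[[layer]], ls0[[layer]], tolerance = 1e-10)
  expect_identical(ls$land, ls0$land)
  expect_equal(ls$origin_easting, 55000)
  expect_equal(ls$origin_northing, 12000)
  expect_equal(ls$cellsize, 1000)
})

test_that("mismatched or invalid layers are rejected by name", {
  dir <- withr::local_tempdir()
  ls0 <- uniform_landscape(10L, 10L)
  paths <- write_landscape(ls0, dir)
  # dimension mismatch in one layer
  write_asc(matrix(30, 9, 10), paths["heath"])
  expect_error(load_landscape(paths), "heath")
  # out-of-range burning value
  paths <- write_landscape(ls0, dir)
  write_asc(matrix(5, 10, 10), paths["burning"])
  expect_error(load_landscape(paths), "burning")
  # non-integer burning value
  write_asc(matrix(1.5, 10, 10), paths["burning"])
  expect_error(load_landscape(paths), "non-integer")
  # georeference mismatch
  paths <- write_landscape(ls0, dir)
  write_asc(matrix(30, 10, 10), paths["heath"], origin_easting = 99)
  expect_error(load_landscape(paths), "georeference")
})

test_that("suitability thresholds are inclusive and match the stated rules", {
  p <- harrier_params()  # MINHEATH 20.0, MAXALT 600
  ls <- uniform_landscape(5L, 5L, heath = 20.0, suitability = 0.5,
                          altitude = 600)
  expect_true(is_suitable(ls, 3, 3, p))          # both thresholds inclusive
  ls <- uniform_landscape(5L, 5L, suitability = 0)
  expect_false(is_suitable(ls, 3, 3, p))         # zero suitability excluded
  ls <- uniform_landscape(5L, 5L, suitability = 1e-7)
  expect_true(is_suitable(ls, 3, 3, p))          # effectively any value > 0
  ls <- uniform_landscape(5L, 5L, heath = 19.99)
  expect_false(is_suitable(ls, 3, 3, p))
  ls <- uniform_landscape(5L, 5L, altitude = 600.1)
  expect_false(is_suitable(ls, 3, 3, p))
  # off-grid and sea cells are unsuitable, not errors
  ls <- uniform_landscape(5L, 5L, sea_margin = 1L)
  expect_false(is_suitable(ls, 0, 3, p))
  expect_false(is_suitable(ls, 6, 3, p))
  expect_false(is_suitable(ls, 1, 1, p))
})

test_that("suitability is monotone in heath, suitability and altitude", {
  p <- harrier_params()
  set.seed(101)
  for (rep in 1:200) {
    heath <- runif(1, 0, 40); suit <- runif(1, 0, 0.5)
    alt <- runif(1, 0, 1200)
    ls <- uniform_landscape(3L, 3L, heath = heath, suitability = suit,
                            altitude = alt)
    base <- is_suitable(ls, 2, 2, p)
    better <- uniform_landscape(3L, 3L, heath = heath + runif(1, 0, 50),
                                suitability = suit + runif(1, 0, 1),
                                altitude = alt * runif(1, 0, 1))
    if (base) expect_true(is_suitable(better, 2, 2, p))
  }
})

test_that("grouse moor is burning index strictly above the threshold", {
  p <- harrier_params()  # GMBIT 2
  expect_true(is_grouse_moor(uniform_landscape(3L, 3L, burning = 3), 2, 2, p))
  expect_false(is_grouse_moor(uniform_landscape(3L, 3L, burning = 2), 2, 2, p))
  p0 <- harrier_params(GMBIT = 0L)
  expect_false(is_grouse_moor(uniform_landscape(3L, 3L, burning = 0), 2, 2, p0))
  expect_true(is_grouse_moor(uniform_landscape(3L, 3L, burning = 1), 2, 2, p0))
})

test_that("synthetic generation is reproducible and honours the spec", {
  spec <- landscape_spec(30L, 25L, seed = 7)
  a <- generate_synthetic_landscape(spec)
  b <- generate_synthetic_landscape(spec)
  expect_identical(a, b)

  land <- a$land
  expect_true(all(a$mp[land] >= 0 & a$mp[land] <= 43.5))
  expect_true(all(a$burning[land] %in% 0:4))
  expect_true(all(a$heath[land] >= 0 & a$heath[land] <= 100))
  expect_true(all(a$suitability[land] >= 0))

  p <- harrier_params()
  uni <- uniform_landscape(10L, 10L, mp = 10, burning = 0, heath = 30,
                           suitability = 1, altitude = 200)
  expect_equal(landscape_summary(uni, p)$fraction_suitable, 1)
  expect_false(any(is_grouse_moor(uni, rep(1:10, 10), rep(1:10, each = 10),
                                  p)))
  gm <- uniform_landscape(10L, 10L, burning = 3)
  expect_true(all(is_grouse_moor(gm, rep(1:10, 10), rep(1:10, each = 10), p)))
})

test_that("infeasible landscape specs are rejected", {
  expect_error(landscape_spec(10L, 10L, burning_block = 50L), "larger")
  expect_error(landscape_spec(10L, 10L, sea_margin = 5L), "no land")
  expect_error(landscape_spec(10L, 10L, burning_probs = c(1, 1)), "five")
})
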