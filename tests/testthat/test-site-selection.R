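test_that("dispersal decision follows last year's outcome and widowhood", {
  # failed or first-year birds always disperse
  expect_true(must_disperse(FALSE, "M"))
  expect_true(must_disperse(FALSE, "F"))
  # successful pair with both alive stays
  expect_false(must_disperse(TRUE, "M", mate_alive = TRUE))
  expect_false(must_disperse(TRUE, "F", mate_alive = TRUE))
  # only widowed successful females re-disperse
  expect_false(must_disperse(TRUE, "M", mate_alive = FALSE))
  expect_true(must_disperse(TRUE, "F", mate_alive = FALSE))
})

test_that("carrying capacity is zero without prey and saturates at one", {
  p <- harrier_params()  # KSCALE 10
  expect_equal(cell_k(0, p), 0)
  expect_equal(cell_k(1e6, p), 1)
  expect_equal(cell_k(10, p), 0.5)     # 0.5 * 10 / 10
  grid <- seq(0, 50, by = 0.25)
  k <- cell_k(grid, p)
  expect_true(all(diff(k) >= 0))
  expect_true(all(k >= 0 & k <= 1))
  expect_error(cell_k(-1, p), "non-negative")
})

test_that("distance weight is exp(-k d), decreasing, one at the origin", {
  expect_equal(distance_weight(0, 0.5), 1)
  expect_equal(distance_weight(9, 0.04), exp(-0.36), tolerance = 1e-12)
  d <- seq(0, 60, by = 3)
  expect_true(all(diff(distance_weight(d, 0.9)) < 0))
})

test_that("male LS-square score matches the hand-computed value", {
  # 9x9 square, all suitable, K_i = 0.5 each, MP_i = 10, 20 resident males:
  # T = 810, K_eff = 40.5, score = 810 * (40.5 - 20) / 40.5 = 410
  p <- harrier_params()
  ls <- tiny_landscape(9L, mp = 10)
  occ <- new_occupancy(ls)
  set.seed(3)
  taken <- sample(81L, 20L)
  occ$male[cbind((taken - 1L) %% 9L + 1L, (taken - 1L) %/% 9L + 1L)] <-
    seq_len(20L)
  expect_equal(ls_square_score_male(ls, occ, 5, 5, p), 410)
  # empty square: occupancy factor is one, score = T
  expect_equal(ls_square_score_male(ls, new_occupancy(ls), 5, 5, p), 810)
  # no suitable cells: zero
  expect_equal(ls_square_score_male(barren_landscape(9L), occ, 5, 5, p), 0)
})

test_that("adding a resident male never increases a square's score", {
  p <- harrier_params()
  set.seed(21)
  ls <- generate_synthetic_landscape(landscape_spec(20L, 20L, seed = 5))
  for (rep in 1:30) {
    occ <- new_occupancy(ls)
    n0 <- sample(0:40, 1)
    cells <- sample(400L, n0 + 1L)
    xy <- cbind((cells - 1L) %% 20L + 1L, (cells - 1L) %/% 20L + 1L)
    if (n0 > 0) occ$male[xy[seq_len(n0), , drop = FALSE]] <- seq_len(n0)
    cx <- sample(5:16, 1); cy <- sample(5:16, 1)
    before <- ls_square_score_male(ls, occ, cx, cy, p)
    occ$male[xy[n0 + 1L, 1L], xy[n0 + 1L, 2L]] <- n0 + 1L
    expect_lte(ls_square_score_male(ls, occ, cx, cy, p), before)
  }
})

test_that("female LS-square score counts unpaired resident males", {
  p <- harrier_params()
  ls <- tiny_landscape(9L)
  occ <- new_occupancy(ls)
  expect_equal(ls_square_score_female(occ, 5, 5, p), 0L)
  # 3 paired males + 2 lone males -> 2
  for (i in 1:5) occ$male[i, 1] <- i
  for (i in 1:3) occ$female[i, 1] <- 10L + i
  expect_equal(ls_square_score_female(occ, 5, 5, p), 2L)
  # 81 lone males
  occ2 <- new_occupancy(ls)
  occ2$male[] <- seq_len(81L)
  expect_equal(ls_square_score_female(occ2, 5, 5, p), 81L)
})

test_that("fast cached scoring equals the enumeration reference", {
  p <- harrier_params()
  ls <- generate_synthetic_landscape(landscape_spec(25L, 25L, seed = 13))
  cache <- selection_cache(ls, p)
  set.seed(31)
  occ <- new_occupancy(ls)
  cells <- sample(625L, 60L)
  occ$male[cbind((cells - 1L) %% 25L + 1L, (cells - 1L) %/% 25L + 1L)] <-
    seq_len(60L)
  occ$female[cbind((cells[1:20] - 1L) %% 25L + 1L,
                   (cells[1:20] - 1L) %/% 25L + 1L)] <- 100L + 1:20
  nbox <- harrierIBM:::.box_counts(occ$male != 0L, cache$hl, cache$pad)
  lbox <- harrierIBM:::.box_counts(occ$male != 0L & occ$female == 0L,
                                   cache$hl, cache$pad)
  for (b in list(c(3, 3), c(13, 12), c(25, 1), c(20, 25))) {
    fast_m <- harrierIBM:::.male_square_scores(cache, b[1], b[2], nbox)
    fast_f <- harrierIBM:::.female_square_scores(cache, b[1], b[2], lbox)
    cx <- b[1] + p$LOCDIM * cache$ivec
    cy <- b[2] + p$LOCDIM * cache$jvec
    ref_m <- vapply(seq_along(cx), function(s)
      ls_square_score_male(ls, occ, cx[s], cy[s], p), numeric(1))
    ref_f <- vapply(seq_along(cx), function(s)
      as.numeric(ls_square_score_female(occ, cx[s], cy[s], p)), numeric(1))
    expect_equal(fast_m, ref_m, tolerance = 1e-9)
    expect_equal(fast_f, ref_f)
  }
})

test_that("long-distance dispersal lands on land or stays put", {
  p <- harrier_params()
  # island of one land cell surrounded by sea: all nine attempts must fail
  island <- tiny_landscape(21L, sea_margin = 10L)
  set.seed(5)
  for (rep in 1:20)
    expect_equal(long_distance_dispersal(11L, 11L, "M", island, p),
                 c(11L, 11L))
  # on a huge all-land grid the realised distances match the sex-specific
  # normal (zero-truncation shifts the male mean up by ~2 km)
  big <- uniform_landscape(900L, 900L, mp = 10)
  set.seed(6)
  n <- 20000L
  dests <- matrix(0L, n, 2L)
  for (i in seq_len(n))
    dests[i, ] <- long_distance_dispersal(450L, 450L, "M", big, p)
  d <- sqrt((dests[, 1] - 450)^2 + (dests[, 2] - 450)^2)
  expect_gt(mean(d), 145); expect_lt(mean(d), 158)
  expect_gt(sd(d), 58); expect_lt(sd(d), 70)
  set.seed(7)
  for (i in seq_len(n))
    dests[i, ] <- long_distance_dispersal(450L, 450L, "F", big, p)
  d <- sqrt((dests[, 1] - 450)^2 + (dests[, 2] - 450)^2)
  expect_gt(mean(d), 96); expect_lt(mean(d), 106)
})

test_that("cell selection respects occupancy, natal-site and suitability", {
  p <- harrier_params()
  ls <- tiny_landscape(9L, mp = 10)
  # female: the only male-occupied cell is her natal cell -> no choice
  occ <- new_occupancy(ls)
  occ <- set_resident(occ, 5, 5, "M", 1L)
  expect_null(select_cell(ls, occ, 5, 5, "F", natal_x = 5, natal_y = 5,
                          params = p))
  expect_false(is.null(select_cell(ls, occ, 5, 5, "F", natal_x = 1,
                                   natal_y = 1, params = p)))
  # male: every cell already occupied -> no choice
  occ2 <- new_occupancy(ls)
  occ2$male[] <- seq_len(81L)
  expect_null(select_cell(ls, occ2, 5, 5, "M", params = p))
  # barren square -> no choice for anyone
  expect_null(select_cell(barren_landscape(9L), new_occupancy(ls), 5, 5, "M",
                          params = p))
})

test_that("LS-square selection picks the only scoring square, or none", {
  p <- harrier_params()
  # a single suitable 9x9 island in an otherwise barren grid
  big <- 45L
  mp <- matrix(10, big, big); heath <- matrix(5, big, big)
  heath[19:27, 19:27] <- 30
  ls <- harrier_landscape(mp = mp, burning = matrix(0, big, big),
                          suitability = matrix(1, big, big), heath = heath,
                          altitude = matrix(200, big, big))
  occ <- new_occupancy(ls)
  set.seed(8)
  for (rep in 1:10) {
    sq <- select_ls_square(ls, occ, 23L, 23L, "M", p$KDISTFM, p)
    expect_equal(sq, c(23L, 23L))
  }
  # nothing suitable anywhere -> NULL
  expect_null(select_ls_square(barren_landscape(30L), new_occupancy(ls),
                               15L, 15L, "M", p$KDISTFM, p))
  # female with no lone male anywhere -> NULL
  expect_null(select_ls_square(ls, occ, 23L, 23L, "F", p$KDISTFF, p))
})

test_that("roulette frequencies over squares follow the weighted scores", {
  # two scoring squares with known weighted scores ~3:1
  p <- harrier_params()
  big <- 45L
  mp <- matrix(0, big, big)
  mp[19:27, 19:27] <- 30          # central square, T = 81*30
  mp[19:27, 28:36] <- 10          # square one step north, T = 81*10
  ls <- harrier_landscape(mp = mp, burning = matrix(0, big, big),
                          suitability = matrix(1, big, big),
                          heath = matrix(30, big, big),
                          altitude = matrix(200, big, big))
  occ <- new_occupancy(ls)
  cache <- selection_cache(ls, p)
  # exact weights for a bird at the centre (distance weighting included):
  # both squares K-saturated and empty, so score = T
  w_centre <- 81 * 30 * distance_weight(0, p$KDISTFM)
  w_north <- 81 * 10 * distance_weight(9, p$KDISTFM)
  probs <- c(w_centre, w_north) / (w_centre + w_north)
  set.seed(9)
  n <- 4000L
  north <- 0L
  for (i in seq_len(n)) {
    sq <- select_ls_square(ls, occ, 23L, 23L, "M", p$KDISTFM, p)
    if (sq[2] == 32L) north <- north + 1L else expect_equal(sq, c(23L, 23L))
  }
  pval <- stats::chisq.test(c(n - north, north), p = probs)$p.value
  expect_gt(pval, 1e-3)
})

test_that("the selection pass forms pairs and respects territoriality", {
  p <- harrier_params(PLDD = 0)
  ls <- tiny_landscape(20L, mp = 40)   # K = 1 everywhere

  # zero suitable cells: every disperser ends a non-breeder, no pairs
  barren <- barren_landscape(20L)
  pop <- place_birds(id = 1:10, age = 3L, sex = rep(c("M", "F"), 5),
                     status = STATUS[["nonbreeder"]], success = FALSE,
                     x = sample(1:20, 10, TRUE), y = sample(1:20, 10, TRUE))
  out <- run_site_selection(pop, barren, new_occupancy(barren), p)
  expect_equal(out$n_pairs, 0L)
  expect_true(all(out$pop$adults$status == STATUS[["nonbreeder"]]))

  # one lone resident male + one dispersing adult female in range -> a pair
  pop <- place_birds(id = 1L, age = 3L, sex = "M",
                     status = STATUS[["potential"]], success = TRUE,
                     x = 10L, y = 10L)
  occ <- new_occupancy(ls)
  reg <- register_resident(pop, occ, 1L)
  pop <- place_birds(id = 2L, age = 3L, sex = "F",
                     status = STATUS[["nonbreeder"]], success = FALSE,
                     x = 12L, y = 12L, natal_x = 1L, natal_y = 1L,
                     pop = reg$pop)
  set.seed(10)
  out <- run_site_selection(pop, ls, reg$occ, p)
  expect_equal(out$n_pairs, 1L)
  a <- out$pop$adults
  expect_true(all(a$status == STATUS[["breeder"]]))
  expect_equal(a$x[a$sex == 2], 10L)
  expect_equal(a$y[a$sex == 2], 10L)

  # saturation: equal sexes of eligible adults pair up completely
  set.seed(11)
  n2 <- 12L
  pop <- place_birds(id = seq_len(2 * n2), age = 3L,
                     sex = rep(c("M", "F"), each = n2),
                     status = STATUS[["nonbreeder"]], success = FALSE,
                     x = as.integer(sample(3:18, 2 * n2, TRUE)),
                     y = as.integer(sample(3:18, 2 * n2, TRUE)),
                     natal_x = 1L, natal_y = 20L)
  ls2 <- tiny_landscape(20L, mp = 40)
  ls2$heath[1, 20] <- 0   # keep every female's natal cell unsuitable
  out <- run_site_selection(pop, ls2, new_occupancy(ls2), p)
  expect_equal(out$n_pairs, n2)
  validate_state(out$pop, out$occ)

  # no two males share a cell; every breeding female has a co-resident male
  occm <- out$occ$male
  expect_true(all(table(occm[occm != 0L]) == 1L))
})
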