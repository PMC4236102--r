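# helper: a population of n breeding pairs on a constant landscape, with
# both members resident (as left by site selection)
paired_population <- function(n, ls) {
  occ <- new_occupancy(ls)
  cells <- sample(ls$ncols * ls$nrows, n)
  x <- as.integer((cells - 1L) %% ls$ncols + 1L)
  y <- as.integer((cells - 1L) %/% ls$ncols + 1L)
  pop <- new_population()
  pop$adults <- rbind(
    make_birds(id = seq_len(n), age = 2L, sex = SEX_M,
               status = STATUS[["breeder"]], success = FALSE,
               x = x, y = y, resident = TRUE),
    make_birds(id = n + seq_len(n), age = 2L, sex = SEX_F,
               status = STATUS[["breeder"]], success = FALSE,
               x = x, y = y, resident = TRUE))
  occ$male[cbind(x, y)] <- seq_len(n)
  occ$female[cbind(x, y)] <- n + seq_len(n)
  list(pop = pop, occ = occ)
}

test_that("persecution kills breeding females at the burning-specific rate", {
  n <- 10000L
  set.seed(41)
  for (case in list(list(burning = 3, pmf = 1.0, expect = 0.45),
                    list(burning = 1, pmf = 1.0, expect = 0.20),
                    list(burning = 3, pmf = 0.0, expect = 0.00),
                    list(burning = 4, pmf = 2.0, expect = 1.00))) {
    ls <- uniform_landscape(110L, 110L, burning = case$burning)
    st <- paired_population(n, ls)
    p <- harrier_params(PMF = case$pmf)
    out <- apply_persecution(st$pop, ls, p)
    rate <- out$deaths / n
    tol <- 3 * sqrt(case$expect * (1 - case$expect) / n) + 1e-9
    expect_lt(abs(rate - case$expect), tol + 1e-12)
    # males and non-breeders are untouched
    a <- out$pop$adults
    expect_true(all(a$status[a$sex == SEX_M] == STATUS[["breeder"]]))
    dead <- a$status == STATUS[["dead_persecuted"]]
    expect_true(all(a$sex[dead] == SEX_F))
  }
})

test_that("nest failure, the one-fledgling floor and brood sizes are right", {
  set.seed(42)
  ls <- uniform_landscape(110L, 110L, burning = 3)  # grouse moor
  p <- harrier_params()

  # certain failure: all mothers and mates become failed breeders
  st <- paired_population(200L, ls)
  out <- reproduce(st$pop, ls, st$occ,
                   harrier_params(PFAILGMOOR = 100), next_id = 10000L)
  a <- out$pop$adults
  expect_true(all(a$status == STATUS[["failed"]]))
  expect_false(any(a$success))
  expect_equal(nrow(out$pop$juvs), 0L)
  expect_equal(out$fled_gmoor, 0L)

  # certain success with a near-zero Poisson mean: every brood is exactly 1
  st <- paired_population(300L, ls)
  out <- reproduce(st$pop, ls, st$occ,
                   harrier_params(PFAILGMOOR = 0, MFLEDGEGMOOR = 1e-9),
                   next_id = 10000L)
  expect_equal(nrow(out$pop$juvs), 300L)
  expect_true(all(out$pop$adults$success))

  # fledglings inherit the nest cell as natal and current cell
  j <- out$pop$juvs
  expect_true(all(j$natal_x == j$x & j$natal_y == j$y))
  expect_true(all(j$age == 0L & j$status == STATUS[["juvenile"]]))

  # mean fledglings per successful grouse-moor female: E[max(1, Pois(4.26))]
  # = 4.26 + exp(-4.26)  (closed-form oracle)
  n <- 60000L
  ls_big <- uniform_landscape(260L, 260L, burning = 3)
  st <- paired_population(n, ls_big)
  out <- reproduce(st$pop, ls_big, st$occ, harrier_params(PFAILGMOOR = 0),
                   next_id = 10000L)
  mean_brood <- nrow(out$pop$juvs) / n
  oracle <- 4.26 + exp(-4.26)
  expect_lt(abs(mean_brood - oracle), 3 * 2.1 / sqrt(n))

  # fledgling sex ratio is even
  frac_m <- mean(out$pop$juvs$sex == SEX_M)
  expect_lt(abs(frac_m - 0.5), 3 * 0.5 / sqrt(nrow(out$pop$juvs)))
})

test_that("persecuted females do not reproduce and their mates share failure", {
  set.seed(43)
  ls <- uniform_landscape(110L, 110L, burning = 4)
  p <- harrier_params(PMF = 2.0)  # 100% persecution on burning 4
  st <- paired_population(50L, ls)
  out <- apply_persecution(st$pop, ls, p)
  expect_equal(out$deaths, 50L)
  rep_ <- reproduce(out$pop, ls, st$occ, p, next_id = 1000L)
  expect_equal(nrow(rep_$pop$juvs), 0L)
  expect_equal(rep_$succ_gmoor + rep_$succ_other, 0L)
  a <- rep_$pop$adults
  expect_false(any(a$success))
})

test_that("winter mortality splits adults and juveniles and promotes", {
  set.seed(44)
  ls <- uniform_landscape(60L, 60L)
  pop <- new_population()
  n <- 10000L
  pop$juvs <- make_birds(id = seq_len(n), age = 0L, sex = SEX_M,
                         status = STATUS[["juvenile"]], success = FALSE,
                         x = 1L, y = 1L)
  out <- apply_winter_mortality(pop, harrier_params())  # JMmort 64
  surv <- nrow(out$pop$adults) / n
  expect_lt(abs(surv - 0.36), 3 * sqrt(0.36 * 0.64 / n))
  expect_equal(nrow(out$pop$juvs), 0L)
  expect_true(all(out$pop$adults$age == 1L))
  expect_true(all(out$pop$adults$status == STATUS[["nonbreeder"]]))

  # zero mortality: only ages change
  pop <- new_population()
  pop$adults <- make_birds(id = 1:10, age = 2L, sex = rep(c(1L, 2L), 5),
                           status = STATUS[["nonbreeder"]], success = FALSE,
                           x = 1L, y = 1L)
  p0 <- harrier_params(AMmort = 0, AFmort = 0, JMmort = 0, JFmort = 0)
  out <- apply_winter_mortality(pop, p0)
  expect_equal(nrow(out$pop$adults), 10L)
  expect_true(all(out$pop$adults$age == 3L))
  expect_equal(out$deaths, 0L)

  # total mortality: extinction after clean-up
  p1 <- harrier_params(AMmort = 100, AFmort = 100, JMmort = 100,
                       JFmort = 100)
  out <- apply_winter_mortality(pop, p1)
  expect_true(all(out$pop$adults$status == STATUS[["dead_natural"]]))
  cleaned <- clean_up(out$pop, new_occupancy(ls))
  expect_equal(nrow(cleaned$pop$adults), 0L)
})

test_that("clean-up removes the dead, frees their cells, keeps the rest", {
  set.seed(45)
  ls <- uniform_landscape(20L)
  st <- paired_population(5L, ls)
  a <- st$pop$adults
  # kill 4 of the 10 adults, among them the resident male of pair 1
  a$status[c(1, 3, 7, 9)] <- STATUS[["dead_natural"]]
  st$pop$adults <- a
  dead_male <- a[1, ]
  out <- clean_up(st$pop, st$occ)
  expect_equal(nrow(out$pop$adults), 6L)
  expect_setequal(out$pop$adults$id, a$id[-c(1, 3, 7, 9)])
  expect_equal(out$occ$male[dead_male$x, dead_male$y], 0L)
  # the widow stays resident and must disperse next spring
  widow_id <- a$id[a$sex == SEX_F & a$x == dead_male$x & a$y == dead_male$y]
  widow <- out$pop$adults[out$pop$adults$id == widow_id, ]
  expect_true(widow$resident)
  expect_true(must_disperse(TRUE, "F",
                            mate_alive = out$occ$male[widow$x, widow$y] != 0L))
})

test_that("implied first-year survival reproduces the published arithmetic", {
  # 86% mortality over ages 0-2 with 72% yearling survival implies ~19%
  expect_equal(infer_first_year_survival(0.86, 0.72), 0.14 / 0.72)
  expect_equal(round(infer_first_year_survival(0.86, 0.72), 2), 0.19)
  expect_equal(infer_first_year_survival(0.0, 1.0), 1.0)
  expect_equal(infer_first_year_survival(0.5, 0.5), 1.0)
  expect_error(infer_first_year_survival(0.2, 0.5), "inconsistent")
})
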