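# Persecution mortality, reproduction, winter mortality and clean-up.

#' Apply persecution mortality to breeding females
#'
#' Each breeding female (status 3) dies with probability
#' `PERSmort[burning index of her cell] * PMF` (clamped at 1).  Persecution
#' applies at every burning-index level, not only above the grouse-moor
#' threshold; breeding males and non-breeders are never persecuted.  Dead
#' females get status 6 and keep their residency slot until clean-up.
#'
#' @param pop population list.
#' @param landscape a `harrier_landscape`.
#' @param params a `harrier_params`.
#' @return List with updated `pop` and `deaths` (count), plus
#'   `deaths_gmoor`/`deaths_other` split by habitat class of the nest cell.
#' @export
apply_persecution <- function(pop, landscape, params) {
  a <- pop$adults
  at_risk <- which(a$sex == SEX_F & a$status == STATUS[["breeder"]])
  deaths_g <- 0L; deaths_o <- 0L
  if (length(at_risk)) {
    b <- landscape$burning[cbind(a$x[at_risk], a$y[at_risk])]
    p <- pmin(1, params$PERSmort[b + 1L] / 100 * params$PMF)
    die <- stats::runif(length(at_risk)) < p
    if (any(die)) {
      idx <- at_risk[die]
      a$status[idx] <- STATUS[["dead_persecuted"]]
      gm <- is_grouse_moor(landscape, a$x[idx], a$y[idx], params)
      deaths_g <- sum(gm); deaths_o <- sum(!gm)
    }
  }
  pop$adults <- a
  list(pop = pop, deaths = deaths_g + deaths_o,
       deaths_gmoor = deaths_g, deaths_other = deaths_o)
}

#' Reproduction of surviving breeding females
#'
#' Each surviving breeding female (status 3, age >= 1) fails completely with
#' probability `PFAILGMOOR` (nest on grouse moor) or `PFAILOTHER`; failed
#' pairs get status 4 and zero fledglings.  Otherwise the brood size is drawn
#' from a Poisson with mean `MFLEDGEGMOOR`/`MFLEDGEOTHER` and a draw of zero
#' is set to one (the nest is already successful).  Fledglings are created as
#' age-0 juveniles in the parents' cell with even sex odds.  The `success`
#' flag of both pair members records this year's outcome: it is what makes a
#' successful pair keep its territory next spring.
#'
#' @param pop population list.
#' @param landscape a `harrier_landscape`.
#' @param occ an `occupancy_grid` (to locate each female's mate).
#' @param params a `harrier_params`.
#' @param next_id first id for the new fledglings.
#' @return List with updated `pop`, `next_id`, and the habitat-class tallies
#'   `succ_gmoor`, `succ_other`, `fled_gmoor`, `fled_other`.
#' @export
reproduce <- function(pop, landscape, occ, params, next_id) {
  a <- pop$adults
  # this year's outcome overwrites last year's success flags
  a$success <- logical(nrow(a))
  mothers <- which(a$sex == SEX_F & a$status == STATUS[["breeder"]] &
                     a$age >= 1L)
  succ_g <- 0L; succ_o <- 0L; fled_g <- 0L; fled_o <- 0L
  if (length(mothers)) {
    gm <- is_grouse_moor(landscape, a$x[mothers], a$y[mothers], params)
    pfail <- ifelse(gm, params$PFAILGMOOR, params$PFAILOTHER) / 100
    fail <- stats::runif(length(mothers)) < pfail
    nfled <- integer(length(mothers))
    if (any(!fail)) {
      mu <- ifelse(gm[!fail], params$MFLEDGEGMOOR, params$MFLEDGEOTHER)
      nfled[!fail] <- pmax(1L, stats::rpois(sum(!fail), mu))
    }
    a$status[mothers[fail]] <- STATUS[["failed"]]
    a$success[mothers[!fail]] <- TRUE
    # the mate shares the outcome
    mate_id <- occ$male[cbind(a$x[mothers], a$y[mothers])]
    mate_row <- match(mate_id, a$id)
    ok <- !is.na(mate_row)
    a$success[mate_row[ok]] <- a$success[mothers[ok]]
    a$status[mate_row[ok & fail]] <- STATUS[["failed"]]

    succ_g <- sum(!fail & gm); succ_o <- sum(!fail & !gm)
    fled_g <- sum(nfled[gm]); fled_o <- sum(nfled[!gm])

    tot <- sum(nfled)
    if (tot > 0L) {
      px <- rep(a$x[mothers], nfled); py <- rep(a$y[mothers], nfled)
      kids <- make_birds(id = seq.int(next_id, length.out = tot),
                         age = 0L,
                         sex = ifelse(stats::runif(tot) < 0.5, SEX_M, SEX_F),
                         status = STATUS[["juvenile"]], success = FALSE,
                         x = px, y = py)
      pop$juvs <- rbind(pop$juvs, kids)
      next_id <- next_id + tot
    }
  }
  pop$adults <- a
  list(pop = pop, next_id = next_id,
       succ_gmoor = succ_g, succ_other = succ_o,
       fled_gmoor = fled_g, fled_other = fled_o)
}

#' Apply winter mortality and promote surviving juveniles
#'
#' Living adults die with probability `AMmort`/`AFmort` by sex, juveniles
#' with `JMmort`/`JFmort`.  The dead are flagged (status 5) but not removed.
#' All survivors age by one year; surviving juveniles are appended to the
#' adult collection as age-1 non-breeders and the juvenile collection is
#' emptied.
#'
#' @param pop population list.
#' @param params a `harrier_params`.
#' @return List with updated `pop` and `deaths` (adults + juveniles).
#' @export
apply_winter_mortality <- function(pop, params) {
  a <- pop$adults
  alive <- a$status < STATUS[["dead_natural"]]
  p_ad <- ifelse(a$sex == SEX_M, params$AMmort, params$AFmort) / 100
  die_ad <- alive & stats::runif(nrow(a)) < p_ad
  a$status[die_ad] <- STATUS[["dead_natural"]]
  survived <- alive & !die_ad
  a$age[survived] <- a$age[survived] + 1L

  j <- pop$juvs
  die_j <- logical(nrow(j))
  if (nrow(j)) {
    p_j <- ifelse(j$sex == SEX_M, params$JMmort, params$JFmort) / 100
    die_j <- stats::runif(nrow(j)) < p_j
    recruits <- j[!die_j, , drop = FALSE]
    if (nrow(recruits)) {
      recruits$age <- 1L
      recruits$status <- STATUS[["nonbreeder"]]
      a <- rbind(a, recruits)
    }
  }
  pop$adults <- a
  pop$juvs <- pop$juvs[0L, , drop = FALSE]
  list(pop = pop, deaths = sum(die_ad) + sum(die_j))
}

#' End-of-year clean-up
#'
#' Removes dead adults from the population, vacates the residency slots of
#' dead residents, and shuffles the adult processing order for next year.
#'
#' @param pop population list.
#' @param occ an `occupancy_grid`.
#' @return List with updated `pop` and `occ`.
#' @export
clean_up <- function(pop, occ) {
  a <- pop$adults
  occ <- clear_dead_residency(occ, a)
  a <- a[a$status < STATUS[["dead_natural"]], , drop = FALSE]
  if (nrow(a) > 1L) a <- a[sample.int(nrow(a)), , drop = FALSE]
  rownames(a) <- NULL
  pop$adults <- a
  list(pop = pop, occ = occ)
}

#' First-year survival implied by a multi-year mortality estimate
#'
#' Given a mortality estimate spanning ages 0-2 and an assumed survival from
#' age 1 to 2, returns the implied survival from 0 to 1 under independence of
#' annual survival rates: `(1 - mortality_0_to_2) / survival_1_to_2`.
#'
#' @param mortality_0_to_2 fraction in (0, 1]: mortality from fledging to age
#'   two.
#' @param survival_1_to_2 fraction in (0, 1]: annual survival of yearlings.
#' @return Implied first-year survival fraction.
#' @examples
#' infer_first_year_survival(0.86, 0.72)  # ~0.19
#' @export
infer_first_year_survival <- function(mortality_0_to_2, survival_1_to_2) {
  stopifnot(mortality_0_to_2 >= 0, mortality_0_to_2 <= 1,
            survival_1_to_2 > 0, survival_1_to_2 <= 1)
  s <- (1 - mortality_0_to_2) / survival_1_to_2
  if (s > 1)
    stop("inconsistent inputs: implied first-year survival exceeds 1")
  s
}
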