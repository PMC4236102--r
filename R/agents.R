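# Birds, the population container and the residency registry.
#
# The population is a plain data frame, one bird per row, split into `adults`
# (age >= 1) and `juvs` (age < 1, present only between reproduction and the
# end-of-year promotion).  The only mutable cell state is the occupancy grid:
# one optional resident male and one optional resident female per cell.

#' Bird status codes
#'
#' Integer breeding-status codes used throughout the simulator:
#' 0 juvenile; 1 non-breeder; 2 male potential breeder / female dispersed but
#' will not breed this year; 3 breeder; 4 failed breeder; 5 dead (natural,
#' winter); 6 dead (persecuted).
#' @export
STATUS <- c(juvenile = 0L, nonbreeder = 1L, potential = 2L, breeder = 3L,
            failed = 4L, dead_natural = 5L, dead_persecuted = 6L)

# sexes are stored as integers for speed
SEX_M <- 1L
SEX_F <- 2L

#' Construct bird records
#'
#' @param id integer ids (unique across the population).
#' @param age years (integer, >= 0).
#' @param sex `"M"`/`"F"` or the integer codes 1/2.
#' @param status integer status code (see [STATUS]).
#' @param success did the bird breed successfully in the previous year?
#' @param x,y current cell indices.
#' @param natal_x,natal_y natal cell indices (default: current cell).
#' @param resident is the bird registered as a cell resident?
#' @return A data frame, one row per bird.
#' @export
make_birds <- function(id, age, sex, status, success, x, y,
                       natal_x = x, natal_y = y, resident = FALSE) {
  sex <- if (is.character(sex)) ifelse(sex == "M", SEX_M, SEX_F)
         else as.integer(sex)
  n <- length(id)
  data.frame(id = as.integer(id), age = as.integer(rep_len(age, n)),
             sex = rep_len(sex, n),
             status = as.integer(rep_len(status, n)),
             success = rep_len(as.logical(success), n),
             natal_x = as.integer(rep_len(natal_x, n)),
             natal_y = as.integer(rep_len(natal_y, n)),
             x = as.integer(rep_len(x, n)), y = as.integer(rep_len(y, n)),
             resident = rep_len(as.logical(resident), n))
}

#' Empty population
#' @return List with `adults` and `juvs`, both empty bird data frames.
#' @export
new_population <- function() {
  empty <- make_birds(integer(0), integer(0), integer(0), integer(0),
                      logical(0), integer(0), integer(0))
  list(adults = empty, juvs = empty)
}

#' Empty occupancy grid
#'
#' @param landscape a `harrier_landscape` (fixes the grid dimensions).
#' @return An `occupancy_grid`: integer matrices `male` and `female` holding
#'   the resident bird id per cell (0 = vacant).
#' @export
new_occupancy <- function(landscape) {
  z <- matrix(0L, landscape$ncols, landscape$nrows)
  structure(list(male = z, female = z), class = "occupancy_grid")
}

#' Register a bird as the resident of a cell
#'
#' Each cell holds at most one resident of each sex; registering into an
#' occupied slot is an error (territory exclusivity / monogamy).
#'
#' @param occ an `occupancy_grid`.
#' @param x,y cell indices.
#' @param sex 1 (male) or 2 (female), or `"M"`/`"F"`.
#' @param id bird id.
#' @return The updated `occupancy_grid`.
#' @export
set_resident <- function(occ, x, y, sex, id) {
  slot <- if (identical(sex, "M") || identical(sex, SEX_M)) "male" else "female"
  if (occ[[slot]][x, y] != 0L)
    stop("cell (", x, ", ", y, ") already has a resident ", slot)
  occ[[slot]][x, y] <- as.integer(id)
  occ
}

#' Clear the residency slots of dead birds
#'
#' For every dead bird that is registered as the resident of its cell, the
#' slot for its sex is vacated; the other sex's slot is untouched.
#'
#' @param occ an `occupancy_grid`.
#' @param birds data frame of bird rows (only dead, resident rows act).
#' @return The updated `occupancy_grid`.
#' @export
clear_dead_residency <- function(occ, birds) {
  dead <- birds$status %in% c(STATUS[["dead_natural"]],
                              STATUS[["dead_persecuted"]]) & birds$resident
  if (!any(dead)) return(occ)
  d <- birds[dead, ]
  for (i in seq_len(nrow(d))) {
    slot <- if (d$sex[i] == SEX_M) "male" else "female"
    if (occ[[slot]][d$x[i], d$y[i]] == d$id[i])
      occ[[slot]][d$x[i], d$y[i]] <- 0L
  }
  occ
}

#' Check the structural invariants of a simulation state
#'
#' Verifies id uniqueness, the residency registry (each resident's recorded
#' cell holds its id; at most one resident per sex per cell), and pair
#' symmetry (every breeding female shares her cell with a resident male).
#' Used by the test-suite; cheap enough to run every simulated year.
#'
#' @param pop population list (`adults`, `juvs`).
#' @param occ an `occupancy_grid`.
#' @param pairs also check pair symmetry; this invariant holds from site
#'   selection until clean-up, but not after clean-up (a breeding female's
#'   mate may have died over winter, which is exactly what triggers her
#'   dispersal next spring).
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_state <- function(pop, occ, pairs = TRUE) {
  ids <- c(pop$adults$id, pop$juvs$id)
  if (anyDuplicated(ids)) stop("duplicate bird ids")
  a <- pop$adults
  res <- a[a$resident & a$status < STATUS[["dead_natural"]], ]
  for (i in seq_len(nrow(res))) {
    slot <- if (res$sex[i] == SEX_M) "male" else "female"
    if (occ[[slot]][res$x[i], res$y[i]] != res$id[i])
      stop("bird ", res$id[i], " marked resident but not registered at (",
           res$x[i], ", ", res$y[i], ")")
  }
  reg <- c(occ$male[occ$male != 0L], occ$female[occ$female != 0L])
  if (anyDuplicated(reg)) stop("a bird is resident in more than one cell")
  if (!all(reg %in% a$id[a$resident]))
    stop("occupancy grid holds an id with no matching resident bird")
  bf <- if (pairs) a[a$sex == SEX_F & a$status == STATUS[["breeder"]], ]
        else a[0L, ]
  for (i in seq_len(nrow(bf)))
    if (occ$male[bf$x[i], bf$y[i]] == 0L)
      stop("breeding female ", bf$id[i], " has no resident male in her cell")
  invisible(TRUE)
}

#' Flat bird table of the current population
#'
#' Adults and juveniles combined, one row per bird, suitable for a per-year
#' CSV dump (`utils::write.csv`).
#'
#' @param pop population list (`adults`, `juvs`).
#' @return Data frame with columns `id`, `age`, `sex` (`"M"`/`"F"`),
#'   `status`, `x`, `y`.
#' @export
bird_table <- function(pop) {
  b <- rbind(pop$adults, pop$juvs)
  data.frame(id = b$id, age = b$age,
             sex = ifelse(b$sex == SEX_M, "M", "F"),
             status = b$status, x = b$x, y = b$y)
}
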