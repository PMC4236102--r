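# Annual cycle and multi-replicate runs.
#
# One simulated year runs, in order: breeding site selection -> pair census
# (the observation step: persecuted females are still alive and counted) ->
# persecution mortality -> reproduction (with the habitat-class breeding
# tallies) -> winter mortality -> clean-up.  The first simulated year is
# calendar year `start_year` (1989 by default), so simulation years 10, 16
# and 22 report as 1998, 2004 and 2010.

#' Initialise a simulation state
#'
#' @param landscape a `harrier_landscape`.
#' @param regions a `region_spec`.
#' @param params a `harrier_params`.
#' @return A list of class `harrier_state` holding the landscape, the
#'   selection cache, the population, the occupancy grid, the id counter and
#'   the year counter.
#' @export
new_sim_state <- function(landscape, regions, params = harrier_params()) {
  ini <- initialise_population(landscape, regions, params)
  nb <- release_nonbreeders(ini$pop, landscape, regions, params, ini$next_id)
  structure(list(landscape = landscape, regions = regions, params = params,
                 cache = selection_cache(landscape, params),
                 pop = nb$pop, occ = ini$occ, next_id = nb$next_id,
                 year = 0L),
            class = "harrier_state")
}

#' Advance the simulation by one year
#'
#' @param state a `harrier_state`.
#' @param validate run [validate_state()] after site selection and after
#'   clean-up (used by the test-suite).
#' @return List with the updated `state`, the year's `record` (one-row data
#'   frame) and `presence` (logical pair-presence matrix at census).
#' @export
run_year <- function(state, validate = FALSE) {
  params <- state$params
  sel <- run_site_selection(state$pop, state$landscape, state$occ, params,
                            state$cache)
  state$pop <- sel$pop; state$occ <- sel$occ
  if (validate) validate_state(state$pop, state$occ)

  cen <- census_pairs(state$pop, state$occ, state$landscape, state$regions,
                      params)
  presence <- matrix(FALSE, state$landscape$ncols, state$landscape$nrows)
  presence[cen$cells] <- TRUE

  pers <- apply_persecution(state$pop, state$landscape, params)
  state$pop <- pers$pop

  rep_ <- reproduce(state$pop, state$landscape, state$occ, params,
                    state$next_id)
  state$pop <- rep_$pop; state$next_id <- rep_$next_id

  wm <- apply_winter_mortality(state$pop, params)
  state$pop <- wm$pop

  cu <- clean_up(state$pop, state$occ)
  state$pop <- cu$pop; state$occ <- cu$occ
  if (validate) validate_state(state$pop, state$occ, pairs = FALSE)

  state$year <- state$year + 1L
  record <- data.frame(
    year = state$year,
    pairs_total = cen$total, pairs_gmoor = cen$gmoor,
    pairs_other = cen$other,
    pers_deaths = pers$deaths,
    succ_gmoor = rep_$succ_gmoor, succ_other = rep_$succ_other,
    fled_gmoor = rep_$fled_gmoor, fled_other = rep_$fled_other,
    winter_deaths = wm$deaths,
    n_adults_end = nrow(state$pop$adults))
  if (length(cen$by_region))
    record[paste0("pairs_", names(cen$by_region))] <-
      as.list(as.integer(cen$by_region))
  list(state = state, record = record, presence = presence)
}

#' Run a replicated multi-year simulation
#'
#' Each replicate gets an independent RNG stream derived from `base_seed` and
#' the replicate number, so the same configuration and seed reproduce the run
#' exactly and replicates are mutually independent.
#'
#' @param landscape a `harrier_landscape`.
#' @param regions a `region_spec`.
#' @param params a `harrier_params`.
#' @param years simulated years per replicate.
#' @param replicates number of replicates.
#' @param base_seed integer seed.
#' @param start_year calendar year of simulation year 1.
#' @param snapshot_years calendar years whose pair-presence matrices are
#'   accumulated into density maps (set `NULL` to skip).
#' @param validate run the structural invariant checks every year.
#' @param verbose log the national pair total for every simulated year via
#'   `message()`.
#' @return A list of class `harrier_sim`: `records` (one row per replicate
#'   and year; columns include `replicate`, `year`, `calendar`,
#'   `pairs_total`, `pairs_gmoor`, `pairs_other`, per-region pair counts,
#'   the habitat-class success/fledgling tallies and end-of-year population
#'   size), `density` (per snapshot year, the across-replicate *sum* of
#'   presence matrices; divide by `replicates` for the mean — see
#'   [density_matrix()]), and the run settings.
#' @export
run_simulation <- function(landscape, regions, params = harrier_params(),
                           years = 50L, replicates = 20L, base_seed = 1L,
                           start_year = 1989L,
                           snapshot_years = c(1989L, 1998L, 2004L, 2010L,
                                              2013L, 2030L),
                           validate = FALSE, verbose = FALSE) {
  stopifnot(years >= 1L, replicates >= 1L)
  records <- NULL
  density <- list()
  for (key in as.character(snapshot_years))
    density[[key]] <- matrix(0, landscape$ncols, landscape$nrows)
  for (r in seq_len(replicates)) {
    set.seed(replicate_seed(base_seed, r))
    state <- new_sim_state(landscape, regions, params)
    for (t in seq_len(years)) {
      yr <- run_year(state, validate = validate)
      state <- yr$state
      if (verbose)
        message(sprintf("replicate %d year %d (%d): %d breeding pairs",
                        r, state$year, start_year + state$year - 1L,
                        yr$record$pairs_total))
      rec <- cbind(replicate = r, yr$record,
                   calendar = start_year + state$year - 1L)
      records <- rbind(records, rec)
      key <- as.character(start_year + state$year - 1L)
      if (!is.null(density[[key]]))
        density[[key]] <- density[[key]] + yr$presence
    }
  }
  structure(list(records = records, density = density,
                 replicates = replicates, years = years,
                 base_seed = base_seed, start_year = start_year,
                 snapshot_years = snapshot_years, params = params),
            class = "harrier_sim")
}

#' Replicate seed stream
#'
#' Deterministic per-replicate seed derived from the base seed; kept below
#' 2^31 so it is always a valid R integer seed.
#'
#' @param base_seed integer.
#' @param replicate replicate number (1-based).
#' @return Integer seed.
#' @export
replicate_seed <- function(base_seed, replicate) {
  as.integer((as.double(base_seed) + 104729 * as.double(replicate)) %%
               2147483647)
}

#' @export
print.harrier_sim <- function(x, ...) {
  cat(sprintf("<harrier_sim> %d years x %d replicates (seed %d)\n",
              x$years, x$replicates, x$base_seed))
  last <- x$records[x$records$year == max(x$records$year), "pairs_total"]
  cat(sprintf("  final-year national pairs: mean %.1f (range %d-%d)\n",
              mean(last), min(last), max(last)))
  invisible(x)
}
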