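# Elasticity analysis and the persecution x juvenile-mortality factorial.

#' Elasticity of a response to a parameter perturbation
#'
#' The ratio of the proportional change in the response (e.g. breeding pairs,
#' `BP`) to the proportional change in the parameter, both divided by their
#' values at the lower end of the perturbed range:
#' `((BP+ - BP-) / BP-) / ((P+ - P-) / P-)`.
#'
#' @param bp_minus,bp_plus response at the lower / upper parameter value.
#' @param p_minus,p_plus the lower / upper parameter values.
#' @return The elasticity value.
#' @export
elasticity <- function(bp_minus, bp_plus, p_minus, p_plus) {
  if (bp_minus <= 0) stop("elasticity undefined: response at P- is not > 0")
  if (p_minus <= 0) stop("elasticity undefined: P- is not > 0")
  if (p_plus == p_minus) stop("elasticity undefined: no parameter change")
  ((bp_plus - bp_minus) / bp_minus) / ((p_plus - p_minus) / p_minus)
}

#' Perturbed parameter values for an elasticity scenario
#'
#' Returns the baseline value varied by the given fraction either side
#' (default 10%).  Integer-valued parameters are rounded to the nearest
#' integer and the adjusted difference is used; if rounding collapses the two
#' values onto the baseline (as happens for small integers such as the
#' grouse-moor threshold), the perturbation falls back to plus/minus one unit
#' and the result is flagged.
#'
#' @param params a `harrier_params`.
#' @param parameter name of a scalar parameter.
#' @param frac perturbation fraction (default 0.1).
#' @return List with `p_minus`, `p_plus` and `integer_fallback` (logical).
#' @export
perturb_param <- function(params, parameter, frac = 0.1) {
  if (!parameter %in% names(params) || length(params[[parameter]]) != 1L)
    stop("'", parameter, "' is not a scalar model parameter")
  p0 <- params[[parameter]]
  p_minus <- p0 - p0 * frac
  p_plus <- p0 + p0 * frac
  fallback <- FALSE
  if (parameter %in% .integer_params) {
    p_minus <- round(p_minus); p_plus <- round(p_plus)
    if (p_minus == p_plus) {
      warning("rounding collapsed the perturbation of ", parameter,
              "; falling back to a unit step (p0 - 1, p0 + 1)")
      p_minus <- p0 - 1L; p_plus <- p0 + 1L
      fallback <- TRUE
    }
  }
  list(p_minus = p_minus, p_plus = p_plus, integer_fallback = fallback)
}

# mean response per requested calendar year across replicates
.mean_response <- function(sim, years, response) {
  rec <- sim$records[sim$records$calendar %in% years, , drop = FALSE]
  vapply(years, function(yy) {
    d <- rec[rec$calendar == yy, , drop = FALSE]
    if (response == "pairs_total") {
      mean(d$pairs_total)
    } else if (response == "fledglings_per_pair") {
      ratio <- (d$fled_gmoor + d$fled_other) / d$pairs_total
      mean(ratio[is.finite(ratio)])
    } else {
      mean(d[[response]])
    }
  }, numeric(1))
}

#' Run a one-parameter elasticity experiment
#'
#' Runs the scenario at `P - P/10` and at `P + P/10` (only the named
#' parameter varies; integer parameters are rounded with an adjusted step,
#' falling back to a unit step if rounding collapses the perturbation), with
#' the same replicate seed stream for both levels, and evaluates the
#' elasticity of the response at the requested calendar years.
#'
#' @param landscape a `harrier_landscape`.
#' @param regions a `region_spec`.
#' @param params baseline `harrier_params`.
#' @param parameter name of the parameter to perturb (e.g. `"MAXALT"`,
#'   `"MINHEATH"`, `"PMF"`, `"JMmort"`, `"GMBIT"`).
#' @param years calendar years at which the response is evaluated.
#' @param response `"pairs_total"` (default), `"fledglings_per_pair"`, or any
#'   numeric record column.
#' @param sim_years,replicates,base_seed,start_year run controls (see
#'   [run_simulation()]).
#' @param frac perturbation fraction.
#' @return Data frame with one row per year: the parameter levels, the mean
#'   responses at both levels, the elasticity, and the integer-fallback flag.
#' @export
run_elasticity_experiment <- function(landscape, regions,
                                      params = harrier_params(),
                                      parameter,
                                      years = c(1998L, 2004L, 2010L, 2030L),
                                      response = "pairs_total",
                                      sim_years = 50L, replicates = 20L,
                                      base_seed = 1L, start_year = 1989L,
                                      frac = 0.1) {
  covered <- seq.int(start_year, start_year + sim_years - 1L)
  if (!all(years %in% covered))
    stop("evaluation year(s) ",
         paste(setdiff(years, covered), collapse = ", "),
         " fall outside the simulated calendar range ", min(covered), "-",
         max(covered))
  pert <- perturb_param(params, parameter, frac)
  run_at <- function(value) {
    p <- params
    p[[parameter]] <- value
    p <- validate_params(unclass(p))
    sim <- run_simulation(landscape, regions, p, years = sim_years,
                          replicates = replicates, base_seed = base_seed,
                          start_year = start_year, snapshot_years = NULL)
    .mean_response(sim, years, response)
  }
  bp_minus <- run_at(pert$p_minus)
  bp_plus <- run_at(pert$p_plus)
  el <- vapply(seq_along(years), function(i)
    elasticity(bp_minus[i], bp_plus[i], pert$p_minus, pert$p_plus),
    numeric(1))
  data.frame(parameter = parameter, response = response, year = years,
             p_minus = pert$p_minus, p_plus = pert$p_plus,
             bp_minus = bp_minus, bp_plus = bp_plus, elasticity = el,
             integer_fallback = pert$integer_fallback)
}

#' Persecution x juvenile-mortality factorial experiment
#'
#' Runs every combination of the persecution mortality factor and the
#' juvenile winter mortality (applied to both sexes), recording the mean
#' national breeding-pair count at the requested calendar years.
#'
#' @param landscape a `harrier_landscape`.
#' @param regions a `region_spec`.
#' @param params baseline `harrier_params`.
#' @param pmf_values persecution mortality factors (default 0, 0.5, 1, 1.5, 2).
#' @param juv_mort_values juvenile winter mortalities in percent (default
#'   0, 16, 32, 48, 64, 80, 96).
#' @param years calendar years reported.
#' @param sim_years,replicates,base_seed,start_year run controls.
#' @return Data frame with columns `PMF`, `juv_mort`, `year`, `mean_pairs`.
#' @export
run_factorial_grid <- function(landscape, regions,
                               params = harrier_params(),
                               pmf_values = c(0, 0.5, 1, 1.5, 2),
                               juv_mort_values = c(0, 16, 32, 48, 64, 80, 96),
                               years = c(1998L, 2004L, 2010L, 2030L),
                               sim_years = 50L, replicates = 20L,
                               base_seed = 1L, start_year = 1989L) {
  covered <- seq.int(start_year, start_year + sim_years - 1L)
  if (!all(years %in% covered))
    stop("evaluation year(s) ",
         paste(setdiff(years, covered), collapse = ", "),
         " fall outside the simulated calendar range ", min(covered), "-",
         max(covered))
  out <- NULL
  for (pmf in pmf_values) {
    for (jm in juv_mort_values) {
      p <- params
      p$PMF <- pmf; p$JMmort <- jm; p$JFmort <- jm
      p <- validate_params(unclass(p))
      sim <- run_simulation(landscape, regions, p, years = sim_years,
                            replicates = replicates, base_seed = base_seed,
                            start_year = start_year, snapshot_years = NULL)
      mp <- .mean_response(sim, years, "pairs_total")
      out <- rbind(out, data.frame(PMF = pmf, juv_mort = jm, year = years,
                                   mean_pairs = mp))
    }
  }
  out
}
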