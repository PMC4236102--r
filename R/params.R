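# Model parameters.  Names follow the conventional mnemonics used for this
# model family: thresholds (MAXALT, MINHEATH), search geometry (LANDDIM,
# LOCDIM), distance-weighting k's, long-distance dispersal (LDD*), breeding
# (PBREED1*, PFAIL*, MFLEDGE*), grouse-moor threshold (GMBIT), winter
# mortality (A*mort, J*mort) and persecution (PERSmort, PMF).
# Percentages are stored as percentages (0-100) and converted to
# probabilities internally.

.param_defaults <- function() {
  list(
    MAXALT       = 600,    # m; maximum suitable mean altitude
    MINHEATH     = 20.0,   # ha; minimum heath area for a suitable cell
    SUITMIN      = 1e-7,   # minimum suitability index (effectively > 0)
    LANDDIM      = 11L,    # LS squares per side of the search area
    LOCDIM       = 9L,     # cells per side of one LS square
    KDISTNM      = 0.04,   # distance-weighting k, post-natal males
    KDISTNF      = 0.50,   # post-natal females
    KDISTFM      = 0.50,   # post-failure males
    KDISTFF      = 0.90,   # post-failure females
    PLDD         = 5.0,    # % of first-years making an LDD movement
    LDDMEANM     = 150.0,  # km; LDD distance mean, males
    LDDSDM       = 67.0,   # km; LDD distance sd, males
    LDDMEANF     = 100.0,  # km; LDD distance mean, females
    LDDSDF       = 42.0,   # km; LDD distance sd, females
    PBREED1M     = 13.0,   # % of first-year males breeding
    PBREED1F     = 80.0,   # % of first-year females breeding
    PFAILGMOOR   = 63,     # % complete nest failure on grouse moor
    PFAILOTHER   = 40,     # % complete nest failure elsewhere
    MFLEDGEGMOOR = 4.26,   # mean fledglings per successful female, grouse moor
    MFLEDGEOTHER = 3.99,   # mean fledglings per successful female, elsewhere
    GMBIT        = 2L,     # burning index above which a cell is grouse moor
    AMmort       = 22,     # % adult male winter mortality
    AFmort       = 22,     # % adult female winter mortality
    JMmort       = 64,     # % juvenile male winter mortality
    JFmort       = 64,     # % juvenile female winter mortality
    PERSmort     = c(0, 20, 40, 45, 50),  # % female persecution mortality
                                          # by burning index 0..4
    PMF          = 1.0,    # persecution mortality multiplier
    KSCALE       = 10.0,   # half-scale of the cell carrying-capacity curve:
                           # K_i = min(1, 0.5 * MP_i / KSCALE)
    NBRATIO      = 42,     # % non-breeder augmentation at initialisation
    INITAGEMIN   = 2L,     # released breeder ages drawn uniformly on
    INITAGEMAX   = 5L      #   {INITAGEMIN, ..., INITAGEMAX}
  )
}

# Parameters that must stay integer-valued when perturbed in experiments.
.integer_params <- c("GMBIT", "LANDDIM", "LOCDIM", "INITAGEMIN", "INITAGEMAX")

#' Model parameters
#'
#' Build the full parameter set of the simulator, starting from the default
#' values and overriding any subset by name.  Percentages (mortalities,
#' failure probabilities, `PLDD`, `PBREED1M`/`PBREED1F`, `NBRATIO`) are given
#' on the 0-100 scale.
#'
#' @param ... named parameter overrides, e.g. `harrier_params(PMF = 0.5)`.
#'   Unknown names are an error.
#' @return A named list of class `harrier_params`.
#' @details The only free shape in the model is the cell carrying-capacity
#'   curve `K_i`, a saturating function of half the meadow pipit index
#'   (the factor 0.5 converts a per-2-km transect count to a per-km one).
#'   The default is piecewise linear, `K_i = min(1, 0.5 * MP_i / KSCALE)`,
#'   reaching the one-territorial-male-per-cell ceiling at `MP = 2 * KSCALE`.
#'   See the package vignette for the rationale and for guidance on
#'   substituting other monotone saturating curves.
#' @examples
#' p <- harrier_params(PMF = 0.5, JMmort = 48)
#' p$PERSmort   # percent persecution mortality for burning index 0..4
#' @export
harrier_params <- function(...) {
  p <- .param_defaults()
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("all parameter overrides must be named")
    unknown <- setdiff(names(over), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(over)] <- over
  }
  validate_params(p)
}

#' @keywords internal
validate_params <- function(p) {
  stopifnot(is.list(p))
  missing <- setdiff(names(.param_defaults()), names(p))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  pct <- c("PLDD", "PBREED1M", "PBREED1F", "PFAILGMOOR", "PFAILOTHER",
           "AMmort", "AFmort", "JMmort", "JFmort", "NBRATIO")
  for (nm in pct) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 100)
      stop("parameter ", nm, " must be a percentage in [0, 100]")
  }
  if (!is.numeric(p$PERSmort) || length(p$PERSmort) != 5L ||
      any(is.na(p$PERSmort)) || any(p$PERSmort < 0) || any(p$PERSmort > 100))
    stop("PERSmort must be five percentages in [0, 100] (burning index 0..4)")
  if (!is.numeric(p$PMF) || length(p$PMF) != 1L || is.na(p$PMF) || p$PMF < 0)
    stop("PMF must be a non-negative scalar")
  for (nm in c("LANDDIM", "LOCDIM")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v != as.integer(v) ||
        v < 1 || as.integer(v) %% 2L != 1L)
      stop("parameter ", nm, " must be an odd positive integer")
    p[[nm]] <- as.integer(v)
  }
  for (nm in c("LDDSDM", "LDDSDF"))
    if (p[[nm]] <= 0) stop("parameter ", nm, " must be > 0")
  for (nm in c("MFLEDGEGMOOR", "MFLEDGEOTHER", "KSCALE"))
    if (p[[nm]] <= 0) stop("parameter ", nm, " must be > 0")
  if (p$GMBIT != as.integer(p$GMBIT))
    stop("GMBIT must be an integer")
  p$GMBIT <- as.integer(p$GMBIT)
  if (p$INITAGEMAX < p$INITAGEMIN)
    stop("INITAGEMAX must be >= INITAGEMIN")
  class(p) <- "harrier_params"
  p
}

#' @export
print.harrier_params <- function(x, ...) {
  cat("<harrier_params>\n")
  for (nm in names(x))
    cat(sprintf("  %-12s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}
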