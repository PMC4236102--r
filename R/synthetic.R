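# Synthetic landscape generation.
#
# The real input layers (meadow pipit abundance, heather burning, habitat
# suitability, heath area, altitude for Great Britain) are not distributed;
# the generator produces layers with the same value ranges and spatial
# granularity so the simulator can be exercised and tested: a spatially
# autocorrelated prey field bounded by mp_max, a blockwise integer burning
# index 0-4 (management operates at the 10-km scale), smoothed heath and
# suitability fields and a low-skewed altitude field.  It emulates ranges
# and granularity only, not the statistical models behind the real layers.

#' Specification for a synthetic landscape
#'
#' @param ncols,nrows grid dimensions (cells).
#' @param origin_easting,origin_northing,cellsize georeference (m).
#' @param mp_max maximum meadow pipit index (default 43.5, the upper bound of
#'   the abundance model used for the real prey layer).
#' @param mp_smooth,heath_smooth,suit_smooth,alt_smooth spatial
#'   autocorrelation length (cells) of the respective random fields.
#' @param heath_max maximum heath area per cell (ha, at most 100).
#' @param burning_block side (cells) of the square blocks sharing one burning
#'   index value; the real index is constant within 10-km squares.
#' @param burning_probs probabilities of burning index 0..4 per block.
#' @param alt_max maximum altitude (m).
#' @param sea_margin width (cells) of a NODATA ring around the grid (0 for
#'   none); used to emulate coastline for dispersal tests.
#' @param mp,burning,heath,suitability,altitude optional scalar overrides: a
#'   given value makes that layer constant (useful for uniform test
#'   landscapes).
#' @param seed optional integer; when given, generation is reproducible and
#'   leaves the caller's RNG state untouched.
#' @return A list of class `landscape_spec`.
#' @export
landscape_spec <- function(ncols = 100L, nrows = 100L,
                           origin_easting = 0, origin_northing = 0,
                           cellsize = 1000,
                           mp_max = 43.5, mp_smooth = 5L,
                           heath_max = 100, heath_smooth = 5L,
                           suit_smooth = 5L, alt_smooth = 8L,
                           burning_block = 10L,
                           burning_probs = c(0.55, 0.15, 0.12, 0.10, 0.08),
                           alt_max = 1300,
                           sea_margin = 0L,
                           mp = NULL, burning = NULL, heath = NULL,
                           suitability = NULL, altitude = NULL,
                           seed = NULL) {
  spec <- list(ncols = as.integer(ncols), nrows = as.integer(nrows),
               origin_easting = origin_easting,
               origin_northing = origin_northing, cellsize = cellsize,
               mp_max = mp_max, mp_smooth = as.integer(mp_smooth),
               heath_max = heath_max, heath_smooth = as.integer(heath_smooth),
               suit_smooth = as.integer(suit_smooth),
               alt_smooth = as.integer(alt_smooth),
               burning_block = as.integer(burning_block),
               burning_probs = burning_probs, alt_max = alt_max,
               sea_margin = as.integer(sea_margin),
               mp = mp, burning = burning, heath = heath,
               suitability = suitability, altitude = altitude, seed = seed)
  if (spec$ncols < 1L || spec$nrows < 1L) stop("grid dimensions must be >= 1")
  if (is.null(spec$burning) &&
      spec$burning_block > max(spec$ncols, spec$nrows))
    stop("burning_block (", spec$burning_block,
         ") is larger than the grid (", spec$ncols, "x", spec$nrows, ")")
  if (length(spec$burning_probs) != 5L || any(spec$burning_probs < 0) ||
      sum(spec$burning_probs) <= 0)
    stop("burning_probs must be five non-negative weights for indices 0..4")
  if (2L * spec$sea_margin >= min(spec$ncols, spec$nrows))
    stop("sea_margin leaves no land cells")
  if (spec$mp_max < 0 || spec$heath_max < 0 || spec$heath_max > 100)
    stop("mp_max must be >= 0 and heath_max in [0, 100]")
  class(spec) <- "landscape_spec"
  spec
}

# moving-average smoother applied along both dimensions, repeated twice so
# the kernel is approximately Gaussian with sd ~ w/2
.smooth_field <- function(m, w) {
  if (w <= 1L) return(m)
  box1d <- function(v) {
    cs <- cumsum(c(0, v))
    n <- length(v); h <- w %/% 2L
    lo <- pmax(seq_len(n) - h, 1L); hi <- pmin(seq_len(n) + h, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  for (pass in 1:2) {
    m <- apply(m, 2L, box1d)
    m <- t(apply(m, 1L, box1d))
  }
  m
}

.scaled_noise <- function(nc, nr, smooth, lo, hi) {
  f <- .smooth_field(matrix(stats::runif(nc * nr), nc, nr), smooth)
  rng <- range(f)
  if (rng[2] > rng[1]) f <- (f - rng[1]) / (rng[2] - rng[1]) else f[] <- 0.5
  lo + f * (hi - lo)
}

#' Generate a synthetic landscape
#'
#' Produces a [harrier_landscape()] from a [landscape_spec()].  Generation is
#' reproducible: the same spec and seed give bit-identical layers.
#'
#' @param spec a `landscape_spec`.
#' @return A `harrier_landscape`.
#' @export
generate_synthetic_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  if (!is.null(spec$seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
  }
  nc <- spec$ncols; nr <- spec$nrows
  const <- function(v) matrix(as.numeric(v), nc, nr)

  mp <- if (!is.null(spec$mp)) const(spec$mp) else
    .scaled_noise(nc, nr, spec$mp_smooth, 0, spec$mp_max)
  heath <- if (!is.null(spec$heath)) const(spec$heath) else
    .scaled_noise(nc, nr, spec$heath_smooth, 0, spec$heath_max)
  suit <- if (!is.null(spec$suitability)) const(spec$suitability) else
    .scaled_noise(nc, nr, spec$suit_smooth, 0, 1)
  alt <- if (!is.null(spec$altitude)) const(spec$altitude) else
    spec$alt_max * .scaled_noise(nc, nr, spec$alt_smooth, 0, 1)^2

  if (!is.null(spec$burning)) {
    if (spec$burning != floor(spec$burning) ||
        spec$burning < 0 || spec$burning > 4)
      stop("constant burning override must be an integer in 0..4")
    burning <- const(spec$burning)
  } else {
    bb <- spec$burning_block
    nbx <- ceiling(nc / bb); nby <- ceiling(nr / bb)
    blocks <- matrix(sample(0:4, nbx * nby, replace = TRUE,
                            prob = spec$burning_probs), nbx, nby)
    bx <- ((seq_len(nc) - 1L) %/% bb) + 1L
    by <- ((seq_len(nr) - 1L) %/% bb) + 1L
    burning <- matrix(blocks[cbind(rep(bx, nr), rep(by, each = nc))], nc, nr)
    burning <- burning + 0.0
  }

  if (spec$sea_margin > 0L) {
    sm <- spec$sea_margin
    sea <- matrix(FALSE, nc, nr)
    sea[c(seq_len(sm), nc - seq_len(sm) + 1L), ] <- TRUE
    sea[, c(seq_len(sm), nr - seq_len(sm) + 1L)] <- TRUE
    mp[sea] <- NA; heath[sea] <- NA; suit[sea] <- NA
    alt[sea] <- NA; burning[sea] <- NA
  }

  harrier_landscape(mp = mp, burning = burning, suitability = suit,
                    heath = heath, altitude = alt,
                    origin_easting = spec$origin_easting,
                    origin_northing = spec$origin_northing,
                    cellsize = spec$cellsize)
}

#' Uniform landscape helper
#'
#' Shorthand for a constant landscape: every land cell shares the same
#' meadow pipit index, burning index, heath area, suitability and altitude.
#'
#' @param ncols,nrows grid dimensions.
#' @param mp,burning,heath,suitability,altitude the constant layer values.
#' @param sea_margin width of a NODATA ring (cells).
#' @return A `harrier_landscape`.
#' @export
uniform_landscape <- function(ncols = 50L, nrows = 50L, mp = 10,
                              burning = 0, heath = 30, suitability = 1,
                              altitude = 200, sea_margin = 0L) {
  generate_synthetic_landscape(landscape_spec(
    ncols = ncols, nrows = nrows, mp = mp, burning = burning,
    heath = heath, suitability = suitability, altitude = altitude,
    sea_margin = sea_margin))
}

#' Summarise a landscape against thresholds
#'
#' @param landscape a `harrier_landscape`.
#' @param params a `harrier_params`.
#' @return List with `fraction_suitable` (of land cells) and
#'   `burning_histogram` (counts of burning index 0..4 on land).
#' @export
landscape_summary <- function(landscape, params = harrier_params()) {
  suit <- suitability_mask(landscape, params)
  land <- landscape$land
  list(
    fraction_suitable = if (any(land)) sum(suit) / sum(land) else 0,
    burning_histogram = table(factor(landscape$burning[land], levels = 0:4)))
}
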