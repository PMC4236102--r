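# Declarative run configuration (YAML), fixtures and provenance hashing.
#
# A configuration file is a flat YAML document with up to five sections:
#   landscape: files: {mp:, burning:, suitability:, heath:, altitude:}
#              | synthetic: {<landscape_spec arguments>}
#   regions:   file: <tsv path> | inline: [{name:, xmin:, ymin:, xmax:,
#              ymax:, pairs:, role:}, ...]
#   params:    <harrier_params overrides>
#   run:       years:, replicates:, base_seed:, start_year:, snapshot_years:
#   output:    dir:
# An empty file is a valid configuration: every parameter takes its default.

.run_defaults <- function() {
  list(years = 50L, replicates = 20L, base_seed = 1L, start_year = 1989L,
       snapshot_years = c(1989L, 1998L, 2004L, 2010L, 2013L, 2030L))
}

#' Load and validate a run configuration
#'
#' @param path YAML file path.
#' @return A list of class `harrier_config` with elements `landscape`
#'   (source description), `regions`, `params` (a full `harrier_params`),
#'   `run` and `output`.  Unknown keys anywhere are an error naming the key.
#' @export
load_config <- function(path) {
  raw <- if (file.exists(path)) yaml::read_yaml(path) else
    stop("no such file: ", path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw),
                     c("landscape", "regions", "params", "run", "output"))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))

  params <- do.call(harrier_params, as.list(raw$params))

  run <- .run_defaults()
  if (!is.null(raw$run)) {
    unknown <- setdiff(names(raw$run), names(run))
    if (length(unknown))
      stop("unknown run key(s): ", paste(unknown, collapse = ", "))
    run[names(raw$run)] <- raw$run
  }
  if (run$years < 1L || run$replicates < 1L)
    stop("run years and replicates must be >= 1")

  land <- raw$landscape
  if (!is.null(land)) {
    unknown <- setdiff(names(land), c("files", "synthetic"))
    if (length(unknown))
      stop("unknown landscape key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(land)) land <- list(synthetic = list())

  structure(list(landscape = land, regions = raw$regions, params = params,
                 run = run, output = raw$output),
            class = "harrier_config")
}

#' Write a configuration file
#' @param config a `harrier_config` (or plain list in the same shape).
#' @param path output YAML path.
#' @export
write_config <- function(config, path) {
  cfg <- list(landscape = config$landscape, regions = config$regions,
              params = unclass(config$params), run = config$run,
              output = config$output)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Materialise the landscape described by a configuration
#' @param config a `harrier_config`.
#' @return A `harrier_landscape`.
#' @export
build_landscape <- function(config) {
  land <- config$landscape
  if (!is.null(land$files)) return(load_landscape(land$files))
  generate_synthetic_landscape(do.call(landscape_spec,
                                       as.list(land$synthetic)))
}

#' Materialise the region table described by a configuration
#'
#' With no `regions` section, a single whole-grid region releasing 50 pairs
#' is used so that an empty configuration is runnable end to end.
#'
#' @param config a `harrier_config`.
#' @param landscape the built `harrier_landscape`.
#' @return A `region_spec`.
#' @export
build_regions <- function(config, landscape) {
  rg <- config$regions
  if (is.null(rg))
    return(region_spec("all", 1L, 1L, landscape$ncols, landscape$nrows,
                       pairs = 50L))
  if (!is.null(rg$file)) return(read_regions(rg$file))
  if (!is.null(rg$inline)) {
    d <- do.call(rbind, lapply(rg$inline, as.data.frame))
    if (is.null(d$role)) d$role <- "both"
    if (is.null(d$pairs)) d$pairs <- 0L
    return(region_spec(d$name, d$xmin, d$ymin, d$xmax, d$ymax, d$pairs,
                       d$role))
  }
  stop("regions section must contain 'file' or 'inline'")
}

#' Run a full simulation from a configuration
#'
#' @param config a `harrier_config` (or a path to one).
#' @param out optional output directory overriding `config$output$dir`;
#'   outputs are written only when one of the two is given.
#' @return The `harrier_sim` result, invisibly when outputs are written.
#' @export
run_config <- function(config, out = NULL) {
  if (is.character(config)) config <- load_config(config)
  landscape <- build_landscape(config)
  regions <- build_regions(config, landscape)
  sim <- run_simulation(landscape, regions, config$params,
                        years = config$run$years,
                        replicates = config$run$replicates,
                        base_seed = config$run$base_seed,
                        start_year = config$run$start_year,
                        snapshot_years = config$run$snapshot_years)
  dir <- if (!is.null(out)) out else config$output$dir
  if (!is.null(dir)) {
    write_outputs(sim, dir)
    return(invisible(sim))
  }
  sim
}

#' Deterministic configuration hash for provenance
#'
#' A short polynomial hash of the YAML serialisation, recorded in the header
#' of every output file so runs can be matched to their configuration.
#'
#' @param obj any serialisable configuration object.
#' @return An 8-character hexadecimal string.
#' @export
config_hash <- function(obj) {
  txt <- yaml::as.yaml(obj)
  bytes <- as.integer(charToRaw(txt))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a named small test fixture
#'
#' Deterministic landscape/region/configuration assets for testing and
#' examples.  Available fixtures: `"uniform-suitable"` (20 x 20, every cell
#' suitable, burning 0), `"grouse-moor-only"` (every cell suitable, burning
#' 3), `"two-region"` (two rectangles partitioning the grid), and
#' `"sea-ring"` (a land island surrounded by NODATA sea, for long-distance
#' dispersal tests).
#'
#' @param name fixture name.
#' @param dir output directory.
#' @return Named list with the written `landscape` paths, `regions` path and
#'   `config` path.
#' @export
make_fixture <- function(name, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ls <- switch(
    name,
    "uniform-suitable" = uniform_landscape(20L, 20L, mp = 10, burning = 0),
    "grouse-moor-only" = uniform_landscape(20L, 20L, mp = 10, burning = 3),
    "two-region" = uniform_landscape(20L, 20L, mp = 10, burning = 0),
    "sea-ring" = uniform_landscape(21L, 21L, mp = 10, burning = 0,
                                   sea_margin = 6L),
    stop("unknown fixture name: ", name))
  regions <- switch(
    name,
    "two-region" = region_spec(c("west", "east"), c(1L, 11L), c(1L, 1L),
                               c(10L, 20L), c(20L, 20L), pairs = c(5L, 5L)),
    "sea-ring" = region_spec("island", 7L, 7L, 15L, 15L, pairs = 5L),
    region_spec("all", 1L, 1L, ls$ncols, ls$nrows, pairs = 10L))
  paths <- write_landscape(ls, dir, prefix = paste0(name, "-"))
  rpath <- file.path(dir, paste0(name, "-regions.tsv"))
  write_regions(regions, rpath)
  cpath <- file.path(dir, paste0(name, "-config.yaml"))
  yaml::write_yaml(list(landscape = list(files = as.list(paths)),
                        regions = list(file = rpath),
                        run = list(years = 10L, replicates = 2L,
                                   base_seed = 1L)),
                   cpath)
  list(landscape = paths, regions = rpath, config = cpath)
}
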