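# The static five-layer 1-km raster landscape.
#
# Layers are stored as numeric matrices indexed [x, y] with x the easting
# column (1..ncols, west to east) and y the northing row (1..nrows, south to
# north).  Map coordinates relate to indices via
#   easting  = origin_easting  + (x - 1) * cellsize   (cell SW corner)
# and the cell centre sits at + cellsize/2.  ESRI ASCII grids store rows
# north-to-south, so the reader/writer flip row order.

.layer_names <- c("mp", "burning", "suitability", "heath", "altitude")

#' Construct a landscape from five layer matrices
#'
#' @param mp,burning,suitability,heath,altitude numeric matrices of identical
#'   dimensions, indexed `[x, y]` (easting column, northing row counted from
#'   the south).  `NA` cells are sea/no-data; the land mask is the set of
#'   cells where all five layers have data.
#' @param origin_easting,origin_northing map coordinates (m) of the SW corner.
#' @param cellsize cell side in metres (1000 for the 1-km model grid).
#' @return An object of class `harrier_landscape`: a list with the five layer
#'   matrices, the logical `land` mask, and the grid georeference
#'   (`ncols`, `nrows`, `origin_easting`, `origin_northing`, `cellsize`).
#' @export
harrier_landscape <- function(mp, burning, suitability, heath, altitude,
                              origin_easting = 0, origin_northing = 0,
                              cellsize = 1000) {
  layers <- list(mp = mp, burning = burning, suitability = suitability,
                 heath = heath, altitude = altitude)
  dims <- dim(mp)
  for (nm in .layer_names) {
    l <- layers[[nm]]
    if (!is.matrix(l) || !is.numeric(l))
      stop("layer '", nm, "' must be a numeric matrix")
    if (!identical(dim(l), dims))
      stop("layer '", nm, "' dimensions ", paste(dim(l), collapse = "x"),
           " do not match the mp layer (", paste(dims, collapse = "x"), ")")
  }
  land <- Reduce(`&`, lapply(layers, function(l) !is.na(l)))
  b <- burning[land]
  if (any(b != floor(b)))
    stop("burning layer contains non-integer values on land cells")
  if (any(b < 0 | b > 4))
    stop("burning index must be in {0,1,2,3,4}; found values outside 0..4")
  if (any(layers$mp[land] < 0))
    stop("mp layer contains negative values")
  if (any(layers$suitability[land] < 0))
    stop("suitability layer contains negative values")
  if (any(layers$heath[land] < 0 | layers$heath[land] > 100))
    stop("heath layer must be in [0, 100] ha")
  structure(
    c(layers,
      list(land = land,
           ncols = dims[1L], nrows = dims[2L],
           origin_easting = origin_easting,
           origin_northing = origin_northing,
           cellsize = cellsize)),
    class = "harrier_landscape")
}

#' @export
print.harrier_landscape <- function(x, ...) {
  cat(sprintf("<harrier_landscape> %d cols x %d rows, cellsize %g m\n",
              x$ncols, x$nrows, x$cellsize))
  cat(sprintf("  origin (easting, northing): (%g, %g)\n",
              x$origin_easting, x$origin_northing))
  cat(sprintf("  land cells: %d of %d\n", sum(x$land), length(x$land)))
  invisible(x)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @return list with `values` (matrix indexed `[x, y]`, y counted from the
#'   south, NODATA as `NA`), `origin_easting`, `origin_northing`, `cellsize`.
#' @export
read_asc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, n = 7L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(tok) == 2L && grepl("^[A-Za-z_]+$", tok[1L]) &&
        !is.na(suppressWarnings(as.numeric(tok[2L])))) {
      hdr[[tolower(tok[1L])]] <- as.numeric(tok[2L])
      n_hdr <- n_hdr + 1L
    } else break
  }
  for (req in c("ncols", "nrows"))
    if (is.null(hdr[[req]])) stop(path, ": missing header field ", req)
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  if (!is.null(hdr$xllcorner)) {
    xll <- hdr$xllcorner; yll <- hdr$yllcorner
  } else if (!is.null(hdr$xllcenter)) {
    xll <- hdr$xllcenter - hdr$cellsize / 2
    yll <- hdr$yllcenter - hdr$cellsize / 2
  } else stop(path, ": missing xllcorner/xllcenter header")
  cellsize <- if (is.null(hdr$cellsize)) 1000 else hdr$cellsize
  vals <- scan(path, what = numeric(), skip = n_hdr, quiet = TRUE)
  if (length(vals) != ncols * nrows)
    stop(path, ": expected ", ncols * nrows, " values, found ", length(vals))
  if (!is.null(hdr$nodata_value))
    vals[vals == hdr$nodata_value] <- NA_real_
  # file rows run north -> south; build [x, y] with y from the south
  m <- matrix(vals, nrow = ncols, ncol = nrows)   # column = one file row
  m <- m[, nrows:1L, drop = FALSE]
  list(values = m, origin_easting = xll, origin_northing = yll,
       cellsize = cellsize)
}

#' Write an ESRI ASCII grid
#'
#' @param values matrix indexed `[x, y]`, y counted from the south; `NA`
#'   written as the NODATA value.
#' @param path output file path.
#' @param origin_easting,origin_northing,cellsize georeference.
#' @param nodata NODATA value to use (default -9999).
#' @export
write_asc <- function(values, path, origin_easting = 0, origin_northing = 0,
                      cellsize = 1000, nodata = -9999) {
  nc <- nrow(values); nr <- ncol(values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", nc), paste("nrows", nr),
    paste("xllcorner", format(origin_easting, scientific = FALSE)),
    paste("yllcorner", format(origin_northing, scientific = FALSE)),
    paste("cellsize", format(cellsize, scientific = FALSE)),
    paste("NODATA_value", nodata)), con)
  v <- values[, nr:1L, drop = FALSE]   # back to north-first rows
  v[is.na(v)] <- nodata
  for (j in seq_len(nr))
    writeLines(paste(format(v[, j], trim = TRUE, scientific = FALSE,
                            digits = 15), collapse = " "), con)
  invisible(path)
}

#' Load the five-layer landscape from raster files
#'
#' Reads the five co-registered ESRI ASCII grid layers and assembles the
#' landscape.  The land mask is the set of cells where all five layers have
#' data; any georeference or dimension mismatch is an error naming the
#' offending layer.
#'
#' @param paths named character vector or list with elements `mp`, `burning`,
#'   `suitability`, `heath`, `altitude` giving the file paths.
#' @return A `harrier_landscape`.
#' @export
load_landscape <- function(paths) {
  paths <- as.list(paths)
  missing <- setdiff(.layer_names, names(paths))
  if (length(missing))
    stop("missing layer path(s): ", paste(missing, collapse = ", "))
  ref <- NULL
  layers <- list()
  for (nm in .layer_names) {
    g <- read_asc(paths[[nm]])
    if (is.null(ref)) {
      ref <- g
    } else {
      if (!identical(dim(g$values), dim(ref$values)))
        stop("layer '", nm, "' (", paths[[nm]], ") dimensions ",
             paste(dim(g$values), collapse = "x"),
             " do not match layer 'mp' (",
             paste(dim(ref$values), collapse = "x"), ")")
      if (g$origin_easting != ref$origin_easting ||
          g$origin_northing != ref$origin_northing ||
          g$cellsize != ref$cellsize)
        stop("layer '", nm, "' (", paths[[nm]],
             ") georeference does not match layer 'mp'")
    }
    layers[[nm]] <- g$values
  }
  harrier_landscape(mp = layers$mp, burning = layers$burning,
                    suitability = layers$suitability, heath = layers$heath,
                    altitude = layers$altitude,
                    origin_easting = ref$origin_easting,
                    origin_northing = ref$origin_northing,
                    cellsize = ref$cellsize)
}

#' Write the five landscape layers as ESRI ASCII grids
#'
#' @param landscape a `harrier_landscape`.
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix; files are `<prefix><layer>.asc`.
#' @return Named character vector of the five paths (invisibly usable as the
#'   `paths` argument of [load_landscape()]).
#' @export
write_landscape <- function(landscape, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  for (nm in .layer_names) {
    p <- file.path(dir, paste0(prefix, nm, ".asc"))
    write_asc(landscape[[nm]], p,
              origin_easting = landscape$origin_easting,
              origin_northing = landscape$origin_northing,
              cellsize = landscape$cellsize)
    out[nm] <- p
  }
  invisible(out)
}

#' Is a cell suitable as a nesting territory?
#'
#' A cell is suitable when it is on land, its heath area is at least
#' `MINHEATH` (inclusive), its suitability index is at least `SUITMIN`
#' (effectively any value above zero) and its mean altitude is at most
#' `MAXALT` (inclusive).  Off-grid coordinates are unsuitable, not an error.
#'
#' @param landscape a `harrier_landscape`.
#' @param x,y integer cell indices (vectorised, recycled together).
#' @param params a `harrier_params`.
#' @return Logical vector.
#' @export
is_suitable <- function(landscape, x, y, params) {
  n <- max(length(x), length(y))
  x <- rep_len(as.integer(x), n); y <- rep_len(as.integer(y), n)
  ok <- x >= 1L & x <= landscape$ncols & y >= 1L & y <= landscape$nrows
  res <- logical(n)
  if (any(ok)) {
    idx <- cbind(x[ok], y[ok])
    res[ok] <- landscape$land[idx] &
      landscape$heath[idx] >= params$MINHEATH &
      landscape$suitability[idx] >= params$SUITMIN &
      landscape$altitude[idx] <= params$MAXALT
    res[is.na(res)] <- FALSE
  }
  res
}

#' Is a cell heavily managed grouse moor?
#'
#' True when the heather-burning index strictly exceeds `GMBIT`.
#' Off-grid or sea cells are not grouse moor.
#'
#' @inheritParams is_suitable
#' @return Logical vector.
#' @export
is_grouse_moor <- function(landscape, x, y, params) {
  n <- max(length(x), length(y))
  x <- rep_len(as.integer(x), n); y <- rep_len(as.integer(y), n)
  ok <- x >= 1L & x <= landscape$ncols & y >= 1L & y <= landscape$nrows
  res <- logical(n)
  if (any(ok)) {
    idx <- cbind(x[ok], y[ok])
    v <- landscape$burning[idx] > params$GMBIT
    v[is.na(v)] <- FALSE
    res[ok] <- v
  }
  res
}

#' Logical suitability mask for a whole landscape
#' @inheritParams is_suitable
#' @return Logical matrix indexed `[x, y]`.
#' @keywords internal
suitability_mask <- function(landscape, params) {
  m <- landscape$land &
    landscape$heath >= params$MINHEATH &
    landscape$suitability >= params$SUITMIN &
    landscape$altitude <= params$MAXALT
  m[is.na(m)] <- FALSE
  m
}
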