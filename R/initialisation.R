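# Year-0 population from regional release specifications.

#' Region specification table
#'
#' Builds (or validates) the rectangular-region table used for releases and
#' for regional pair counting.  A region may span several rows (several
#' rectangles sharing one name).
#'
#' @param name region names.
#' @param xmin,xmax,ymin,ymax rectangle bounds in cell indices (inclusive).
#' @param pairs breeding pairs to release into the region (0 for
#'   counting-only regions).
#' @param role `"init"`, `"count"` or `"both"` (default): whether the region
#'   is used for releases, for output counting, or both.
#' @return A data frame of class `region_spec`.
#' @export
region_spec <- function(name, xmin, ymin, xmax, ymax, pairs = 0L,
                        role = "both") {
  r <- data.frame(name = as.character(name),
                  xmin = as.integer(xmin), ymin = as.integer(ymin),
                  xmax = as.integer(xmax), ymax = as.integer(ymax),
                  pairs = as.integer(pairs),
                  role = rep_len(as.character(role), length(name)))
  if (any(r$xmax < r$xmin) || any(r$ymax < r$ymin))
    stop("region rectangle has max < min")
  if (!all(r$role %in% c("init", "count", "both")))
    stop("region role must be one of 'init', 'count', 'both'")
  class(r) <- c("region_spec", "data.frame")
  r
}

#' Read / write a region table
#'
#' Plain tab-separated text with columns `name, xmin, ymin, xmax, ymax,
#' pairs, role`.
#' @param path file path.
#' @return A `region_spec`.
#' @export
read_regions <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "#")
  region_spec(d$name, d$xmin, d$ymin, d$xmax, d$ymax, d$pairs, d$role)
}

#' @rdname read_regions
#' @param regions a `region_spec`.
#' @export
write_regions <- function(regions, path) {
  utils::write.table(as.data.frame(regions), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Approximate Great Britain release regions
#'
#' The default 1988/89 regional release counts (71 Orkney, 20 Hebrides,
#' 85 North Highlands, 148 West Highlands, 109 East Highlands, 80 Southern
#' Uplands, 18 England, 27 Wales; 558 pairs in total) with *approximate*
#' rectangular boundaries on the British National Grid model extent
#' (599 x 1205 cells; origin easting 55000, northing 12000).  The exact
#' boundaries used with the original national data set are not published;
#' these rectangles are coarse, mutually disjoint stand-ins (so regional
#' counts never double-count a pair) and fully overridable via
#' configuration.
#'
#' @return A `region_spec`.
#' @export
gb_default_regions <- function() {
  region_spec(
    name = c("Orkney", "Hebrides", "NorthHighlands", "WestHighlands",
             "EastHighlands", "SouthernUplands", "England", "Wales"),
    xmin = c(265, 25, 145, 75, 226, 145, 245, 145),
    ymin = c(973, 688, 828, 688, 688, 508, 288, 158),
    xmax = c(345, 74, 275, 225, 345, 345, 405, 244),
    ymax = c(1033, 968, 972, 827, 827, 637, 507, 307),
    pairs = c(71, 20, 85, 148, 109, 80, 18, 27),
    role = "both")
}

#' Release the initial breeding pairs
#'
#' For each initialisation region, draws `pairs` distinct random land cells
#' inside its rectangle(s) and releases one male-female pair per cell.  Both
#' members are registered as residents, flagged as having bred successfully
#' last summer, with ages drawn uniformly from
#' `{INITAGEMIN, ..., INITAGEMAX}`.
#'
#' @param landscape a `harrier_landscape`.
#' @param regions a `region_spec`.
#' @param params a `harrier_params`.
#' @return List with `pop`, `occ` and `next_id`.
#' @export
initialise_population <- function(landscape, regions, params) {
  pop <- new_population()
  occ <- new_occupancy(landscape)
  next_id <- 1L
  init <- regions[regions$role %in% c("init", "both") & regions$pairs > 0L, ,
                  drop = FALSE]
  for (nm in unique(init$name)) {
    rr <- init[init$name == nm, , drop = FALSE]
    cells <- .region_land_cells(landscape, rr)
    want <- sum(rr$pairs)
    if (nrow(cells) < want)
      stop("region '", nm, "' needs ", want, " distinct cells but only ",
           nrow(cells), " land cells are available")
    pick <- cells[sample.int(nrow(cells), want), , drop = FALSE]
    ages_m <- sample(params$INITAGEMIN:params$INITAGEMAX, want, replace = TRUE)
    ages_f <- sample(params$INITAGEMIN:params$INITAGEMAX, want, replace = TRUE)
    males <- make_birds(id = seq.int(next_id, length.out = want),
                        age = ages_m, sex = SEX_M,
                        status = STATUS[["breeder"]], success = TRUE,
                        x = pick[, 1L], y = pick[, 2L], resident = TRUE)
    next_id <- next_id + want
    females <- make_birds(id = seq.int(next_id, length.out = want),
                          age = ages_f, sex = SEX_F,
                          status = STATUS[["breeder"]], success = TRUE,
                          x = pick[, 1L], y = pick[, 2L], resident = TRUE)
    next_id <- next_id + want
    for (k in seq_len(want)) {
      occ <- set_resident(occ, pick[k, 1L], pick[k, 2L], SEX_M, males$id[k])
      occ <- set_resident(occ, pick[k, 1L], pick[k, 2L], SEX_F, females$id[k])
    }
    pop$adults <- rbind(pop$adults, males, females)
  }
  list(pop = pop, occ = occ, next_id = next_id)
}

#' Release the non-breeding component
#'
#' Adds `round(NBRATIO% * regional pairs)` male-female non-breeder pairs per
#' initialisation region: age 1, non-breeder status, never registered as
#' residents, at random land cells of the region (cells may repeat).
#'
#' @param pop population list (breeders already released).
#' @param landscape a `harrier_landscape`.
#' @param regions a `region_spec`.
#' @param params a `harrier_params`.
#' @param next_id first id for the new birds.
#' @return List with `pop` and `next_id`.
#' @export
release_nonbreeders <- function(pop, landscape, regions, params, next_id) {
  init <- regions[regions$role %in% c("init", "both") & regions$pairs > 0L, ,
                  drop = FALSE]
  ratio <- params$NBRATIO / 100
  for (nm in unique(init$name)) {
    rr <- init[init$name == nm, , drop = FALSE]
    n_nb <- round(ratio * sum(rr$pairs))
    if (n_nb == 0L) next
    cells <- .region_land_cells(landscape, rr)
    if (!nrow(cells))
      stop("region '", nm, "' has no land cells for non-breeder release")
    pick <- cells[sample.int(nrow(cells), n_nb, replace = TRUE), ,
                  drop = FALSE]
    nb <- rbind(
      make_birds(id = seq.int(next_id, length.out = n_nb), age = 1L,
                 sex = SEX_M, status = STATUS[["nonbreeder"]],
                 success = FALSE, x = pick[, 1L], y = pick[, 2L]),
      make_birds(id = seq.int(next_id + n_nb, length.out = n_nb), age = 1L,
                 sex = SEX_F, status = STATUS[["nonbreeder"]],
                 success = FALSE, x = pick[, 1L], y = pick[, 2L]))
    next_id <- next_id + 2L * n_nb
    pop$adults <- rbind(pop$adults, nb)
  }
  list(pop = pop, next_id = next_id)
}

# all land cells inside the rectangles of one region (one row per cell)
.region_land_cells <- function(landscape, rects) {
  out <- NULL
  for (i in seq_len(nrow(rects))) {
    xs <- max(1L, rects$xmin[i]):min(landscape$ncols, rects$xmax[i])
    ys <- max(1L, rects$ymin[i]):min(landscape$nrows, rects$ymax[i])
    gx <- rep(xs, times = length(ys)); gy <- rep(ys, each = length(xs))
    on_land <- landscape$land[cbind(gx, gy)]
    out <- rbind(out, cbind(gx[on_land], gy[on_land]))
  }
  unique(out)
}
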