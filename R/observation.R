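# Output statistics: pair censuses, breeding statistics, density maps.

#' Census of breeding pairs
#'
#' Counts females that meet the breeding conditions — age one or more,
#' resident in their cell with a resident male present — nationally, split by
#' habitat class (grouse moor vs other), and within each counting region.
#' Called between site selection and persecution, so females that are about
#' to be killed are still counted as attempting pairs.
#'
#' @param pop population list.
#' @param occ an `occupancy_grid`.
#' @param landscape a `harrier_landscape`.
#' @param regions a `region_spec` (or `NULL` for no regional counts).
#' @param params a `harrier_params`.
#' @return List with `total`, `gmoor`, `other`, `by_region` (named integer)
#'   and `cells` (two-column matrix of pair cell indices).
#' @export
census_pairs <- function(pop, occ, landscape, regions = NULL, params) {
  idx <- which(occ$male != 0L & occ$female != 0L)
  px <- as.integer((idx - 1L) %% nrow(occ$male) + 1L)
  py <- as.integer((idx - 1L) %/% nrow(occ$male) + 1L)
  if (length(idx)) {
    fem_age <- pop$adults$age[match(occ$female[idx], pop$adults$id)]
    keep <- !is.na(fem_age) & fem_age >= 1L
    px <- px[keep]; py <- py[keep]
  }
  gm <- is_grouse_moor(landscape, px, py, params)
  by_region <- integer(0)
  if (!is.null(regions)) {
    cnt <- regions[regions$role %in% c("count", "both"), , drop = FALSE]
    for (nm in unique(cnt$name)) {
      rr <- cnt[cnt$name == nm, , drop = FALSE]
      inside <- rep(FALSE, length(px))
      for (i in seq_len(nrow(rr)))
        inside <- inside | (px >= rr$xmin[i] & px <= rr$xmax[i] &
                              py >= rr$ymin[i] & py <= rr$ymax[i])
      by_region[nm] <- sum(inside)
    }
  }
  list(total = length(px), gmoor = sum(gm), other = sum(!gm),
       by_region = by_region, cells = cbind(x = px, y = py))
}

#' Breeding statistics from simulation records
#'
#' The proportion of successful breeding attempts and the mean number of
#' fledglings per breeding female per year, for one habitat class.  The
#' denominator is the pair census taken before persecution, so persecuted
#' females count as failed attempts that produce no fledglings.  Per-year
#' ratios are averaged across all year-by-replicate records with a non-zero
#' denominator.
#'
#' @param records the `records` data frame of a [run_simulation()] result (or
#'   the result itself).
#' @param habitat `"gmoor"` or `"other"`.
#' @param years optional calendar years to restrict the average to.
#' @return List with `prop_successful`, `fledglings_per_female`,
#'   `n_female_years` (total breeding females in the included records) and
#'   `n_records`.
#' @export
breeding_statistics <- function(records, habitat = c("gmoor", "other"),
                                years = NULL) {
  habitat <- match.arg(habitat)
  if (is.list(records) && !is.data.frame(records) &&
      !is.null(records$records)) records <- records$records
  if (!is.null(years)) records <- records[records$calendar %in% years, ,
                                          drop = FALSE]
  att <- records[[paste0("pairs_", habitat)]]
  succ <- records[[paste0("succ_", habitat)]]
  fled <- records[[paste0("fled_", habitat)]]
  keep <- att > 0L
  if (!any(keep))
    return(list(prop_successful = NaN, fledglings_per_female = NaN,
                n_female_years = 0L, n_records = 0L))
  list(prop_successful = mean(succ[keep] / att[keep]),
       fledglings_per_female = mean(fled[keep] / att[keep]),
       n_female_years = sum(att[keep]), n_records = sum(keep))
}

#' Mean pair-density map for a snapshot year
#'
#' Mean occupancy of each cell across replicates (a cell is occupied when a
#' breeding pair was censused there), optionally block-averaged to 10-km
#' squares so that e.g. 0.01 means one of the 100 cells of the square is
#' occupied on average.
#'
#' @param sim a [run_simulation()] result with recorded snapshots.
#' @param year calendar year (must be one of the snapshot years).
#' @param aggregate 1 (cell scale) or 10 (10-km block means).
#' @return Numeric matrix indexed `[x, y]`.
#' @export
density_matrix <- function(sim, year, aggregate = 1L) {
  key <- as.character(year)
  if (is.null(sim$density[[key]]))
    stop("year ", year, " was not a snapshot year of this run")
  m <- sim$density[[key]] / sim$replicates
  if (aggregate == 1L) return(m)
  b <- as.integer(aggregate)
  nbx <- ceiling(nrow(m) / b); nby <- ceiling(ncol(m) / b)
  bx <- ((seq_len(nrow(m)) - 1L) %/% b) + 1L
  by <- ((seq_len(ncol(m)) - 1L) %/% b) + 1L
  # block means via two rowsum passes (rows then columns)
  s1 <- rowsum(m, bx)                      # nbx x ncol
  s2 <- t(rowsum(t(s1), by))               # nbx x nby
  cnt <- tabulate(bx, nbx) %o% tabulate(by, nby)
  s2 / cnt
}

#' Write simulation outputs to disk
#'
#' One tidy per-year CSV per replicate, an across-replicate summary CSV
#' (mean and standard error of the national pair count per year), and one
#' ESRI ASCII density grid per snapshot year.  Every file starts with a
#' `#`-comment header carrying the configuration hash for provenance.
#'
#' @param sim a [run_simulation()] result.
#' @param dir output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_outputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(sim$params)
  hdr <- paste0("# config_hash: ", hash)
  for (r in unique(sim$records$replicate)) {
    p <- file.path(dir, sprintf("records_rep%02d.csv", r))
    writeLines(hdr, p)
    suppressWarnings(utils::write.table(
      sim$records[sim$records$replicate == r, , drop = FALSE], p,
      sep = ",", row.names = FALSE, append = TRUE, quote = FALSE))
  }
  agg <- stats::aggregate(pairs_total ~ calendar, data = sim$records,
                          FUN = function(v) c(mean = mean(v),
                                              se = stats::sd(v) /
                                                sqrt(length(v))))
  summ <- data.frame(calendar = agg$calendar,
                     pairs_mean = agg$pairs_total[, "mean"],
                     pairs_se = agg$pairs_total[, "se"])
  p <- file.path(dir, "summary.csv")
  writeLines(hdr, p)
  suppressWarnings(utils::write.table(summ, p, sep = ",", row.names = FALSE,
                                      append = TRUE, quote = FALSE))
  for (key in names(sim$density))
    write_asc(sim$density[[key]] / sim$replicates,
              file.path(dir, paste0("density_", key, ".asc")))
  invisible(dir)
}
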