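# Two-stage breeding-site selection.
#
# Stage 1: a dispersing bird scores every landscape-scale (LS) square in a
# LANDDIM x LANDDIM block of LS squares centred on its cell (each LS square
# is LOCDIM x LOCDIM cells, the central one centred on the bird), weights
# the scores by an inverse-exponential function of distance, and picks one
# square by roulette-wheel sampling.  Stage 2: it picks a cell within the
# square with probability proportional to the meadow pipit index of the
# eligible cells.  Males score squares by prey abundance discounted by the
# occupancy of the square relative to its prey-based carrying capacity;
# females score squares by the number of unpaired resident males.
#
# Performance: the landscape is static, so the static per-square sums
# (carrying capacity K, suitability-gated prey index, suitable-cell count)
# are precomputed for every possible square centre — including centres up to
# (LOCDIM-1)/2 cells off-grid, whose squares keep their on-grid cells — via
# summed-area tables.  The only dynamic term, the per-square count of
# resident (or unpaired) males, is kept as an incrementally updated box-count
# matrix.  Scoring a bird's LANDDIM^2 squares is then a vector of array
# lookups.  The exported per-square scoring functions use direct enumeration
# and serve as the reference implementation the fast path is tested against.

# ---- summed-area tables -----------------------------------------------------

.sat <- function(m) {
  nc <- nrow(m); nr <- ncol(m)
  cs <- matrix(0, nc, nr)
  for (j in seq_len(nr)) cs[, j] <- cumsum(m[, j])
  for (i in seq_len(nc)) cs[i, ] <- cumsum(cs[i, ])
  S <- matrix(0, nc + 1L, nr + 1L)
  S[-1L, -1L] <- cs
  S
}

# sums over [x1..x2] x [y1..y2] clamped to the grid; vectorised over blocks
.block_sums <- function(S, x1, x2, y1, y2) {
  nc <- nrow(S) - 1L; nr <- ncol(S) - 1L
  x1 <- pmax(x1, 1L); y1 <- pmax(y1, 1L)
  x2 <- pmin(x2, nc); y2 <- pmin(y2, nr)
  out <- numeric(length(x1))
  ok <- x1 <= x2 & y1 <= y2
  if (any(ok)) {
    out[ok] <- S[cbind(x2[ok] + 1L, y2[ok] + 1L)] -
      S[cbind(x1[ok], y2[ok] + 1L)] -
      S[cbind(x2[ok] + 1L, y1[ok])] +
      S[cbind(x1[ok], y1[ok])]
  }
  out
}

# box sums of a cell matrix for every centre in the padded range
# [1-pad .. nc+pad] x [1-pad .. nr+pad]; element [cx+pad, cy+pad]
.box_counts <- function(m, hl, pad) {
  S <- .sat(m)
  nc <- nrow(m); nr <- ncol(m)
  cx <- rep(seq.int(1L - pad, nc + pad), times = nr + 2L * pad)
  cy <- rep(seq.int(1L - pad, nr + pad), each = nc + 2L * pad)
  matrix(.block_sums(S, cx - hl, cx + hl, cy - hl, cy + hl),
         nc + 2L * pad, nr + 2L * pad)
}

#' Precompute the static parts of site-selection scoring
#'
#' @param landscape a `harrier_landscape`.
#' @param params a `harrier_params`.
#' @return An opaque cache list consumed by [run_site_selection()].
#' @keywords internal
#' @export
selection_cache <- function(landscape, params) {
  suit <- suitability_mask(landscape, params)
  mp0 <- landscape$mp
  mp0[is.na(mp0)] <- 0
  K <- cell_k(mp0, params)
  K[!landscape$land] <- 0
  mps <- mp0 * suit
  hl <- (params$LOCDIM - 1L) %/% 2L
  pad <- hl
  Tsq <- .box_counts(mps, hl, pad)
  Ksq <- .box_counts(K, hl, pad)
  Ssq <- .box_counts(suit + 0, hl, pad)
  Keff <- Ksq * Ssq / params$LOCDIM^2
  valid <- Ssq > 0 & Keff > 0
  TdivK <- matrix(0, nrow(Tsq), ncol(Tsq))
  TdivK[valid] <- Tsq[valid] / Keff[valid]
  Keff[!valid] <- 0             # zero K_eff makes the score vanish
  half <- (params$LANDDIM - 1L) %/% 2L
  ivec <- rep(seq.int(-half, half), each = params$LANDDIM)
  jvec <- rep(seq.int(-half, half), times = params$LANDDIM)
  dvec <- params$LOCDIM * sqrt(ivec^2 + jvec^2)
  W <- list(NM = exp(-params$KDISTNM * dvec),
            NF = exp(-params$KDISTNF * dvec),
            FM = exp(-params$KDISTFM * dvec),
            FF = exp(-params$KDISTFF * dvec))
  list(suit = suit, K = K, mps = mps,
       TdivK = TdivK, Keff = Keff,
       LOCDIM = params$LOCDIM, LANDDIM = params$LANDDIM,
       half = half, hl = hl, pad = pad,
       pnc = landscape$ncols + 2L * pad, pnr = landscape$nrows + 2L * pad,
       ivec = ivec, jvec = jvec, dvec = dvec, W = W,
       ncols = landscape$ncols, nrows = landscape$nrows)
}

# linear indices into the padded per-centre matrices for the LANDDIM^2 square
# centres around (bx, by); 0 marks centres outside the padded range
.centre_index <- function(cache, bx, by) {
  px <- bx + cache$LOCDIM * cache$ivec + cache$pad
  py <- by + cache$LOCDIM * cache$jvec + cache$pad
  ok <- px >= 1L & px <= cache$pnc & py >= 1L & py <= cache$pnr
  idx <- integer(length(px))
  idx[ok] <- px[ok] + (py[ok] - 1L) * cache$pnc
  idx
}

# fast male scores of the LANDDIM^2 LS squares around (bx, by); `nbox` is the
# padded box-count matrix of resident males
.male_square_scores <- function(cache, bx, by, nbox) {
  idx <- .centre_index(cache, bx, by)
  score <- numeric(length(idx))
  ok <- idx > 0L
  li <- idx[ok]
  score[ok] <- cache$TdivK[li] * pmax(0, cache$Keff[li] - nbox[li])
  score
}

# fast female scores: count of unpaired resident males per square
.female_square_scores <- function(cache, bx, by, lbox) {
  idx <- .centre_index(cache, bx, by)
  score <- numeric(length(idx))
  ok <- idx > 0L
  score[ok] <- lbox[idx[ok]]
  score
}

# ---- exported operations ----------------------------------------------------

#' Cell carrying capacity from the meadow pipit index
#'
#' `K_i = min(1, 0.5 * MP_i / KSCALE)`: a saturating function of half the
#' meadow pipit index (the 0.5 converts a per-2-km transect count to a
#' per-km one), capped at one territorial male per cell.
#'
#' @param mp_index non-negative meadow pipit index (vectorised).
#' @param params a `harrier_params` (uses `KSCALE`).
#' @return Values in `[0, 1]`, non-decreasing in `mp_index`.
#' @export
cell_k <- function(mp_index, params) {
  if (any(mp_index < 0, na.rm = TRUE))
    stop("mp_index must be non-negative")
  pmin(0.5 * mp_index / params$KSCALE, 1)
}

#' Inverse-exponential distance weight
#'
#' @param d Euclidean distance in cells from the bird to the centre of an LS
#'   square (>= 0).
#' @param k distance-weighting parameter (one of `KDISTNM`, `KDISTNF`,
#'   `KDISTFM`, `KDISTFF`).
#' @return `exp(-k * d)`, in `(0, 1]`.
#' @export
distance_weight <- function(d, k) {
  stopifnot(all(d >= 0))
  exp(-k * d)
}

#' Should a bird disperse this spring?
#'
#' A bird disperses unless it bred successfully last year; a successful
#' female whose mate died during the winter also disperses (a successful
#' male whose mate died stays).
#'
#' @param success logical: bred successfully in the previous year.
#' @param sex 1/`"M"` male, 2/`"F"` female (vectorised).
#' @param mate_alive logical: is last year's mate still alive (only consulted
#'   for successful females).
#' @return Logical vector.
#' @export
must_disperse <- function(success, sex, mate_alive = TRUE) {
  sex <- if (is.character(sex)) ifelse(sex == "M", SEX_M, SEX_F)
         else as.integer(sex)
  !success | (sex == SEX_F & !mate_alive)
}

#' Long-distance dispersal of a first-year bird
#'
#' Draws a distance from the sex-specific normal distribution (truncated at
#' zero by redrawing) and a uniform direction; if the destination cell is on
#' land the bird moves there.  Up to nine attempts are made; if all fail the
#' position is unchanged.
#'
#' @param x,y current cell indices.
#' @param sex 1/`"M"` or 2/`"F"`.
#' @param landscape a `harrier_landscape`.
#' @param params a `harrier_params`.
#' @return Integer `c(x, y)` of the (possibly unchanged) position.
#' @export
long_distance_dispersal <- function(x, y, sex, landscape, params) {
  male <- identical(sex, "M") || identical(sex, SEX_M) || identical(sex, 1)
  mu <- if (male) params$LDDMEANM else params$LDDMEANF
  sd <- if (male) params$LDDSDM else params$LDDSDF
  for (attempt in 1:9) {
    d <- stats::rnorm(1L, mu, sd)
    while (d < 0) d <- stats::rnorm(1L, mu, sd)
    theta <- stats::runif(1L, 0, 2 * pi)
    tx <- as.integer(round(x + d * cos(theta)))
    ty <- as.integer(round(y + d * sin(theta)))
    if (tx >= 1L && tx <= landscape$ncols && ty >= 1L &&
        ty <= landscape$nrows && isTRUE(landscape$land[tx, ty]))
      return(c(tx, ty))
  }
  c(as.integer(x), as.integer(y))
}

#' Male score of one LS square (reference implementation)
#'
#' Direct enumeration of the LOCDIM x LOCDIM cells of the LS square centred
#' at `(cx, cy)`: the suitability-gated sum of meadow pipit indices `T`, the
#' effective carrying capacity `K_eff` (sum of cell `K_i` over all cells of
#' the square, multiplied by the proportion of suitable cells), and the
#' number of resident males `N`, combined as
#' `T * max(0, K_eff - N) / K_eff`.  The score is zero when the square
#' contains no suitable cell or `K_eff` is zero.
#'
#' @param landscape a `harrier_landscape`.
#' @param occ an `occupancy_grid`.
#' @param cx,cy centre cell of the LS square (may be partly off-grid;
#'   off-grid cells contribute nothing).
#' @param params a `harrier_params`.
#' @return Non-negative scalar score.
#' @export
ls_square_score_male <- function(landscape, occ, cx, cy, params) {
  hl <- (params$LOCDIM - 1L) %/% 2L
  xs <- (cx - hl):(cx + hl); ys <- (cy - hl):(cy + hl)
  xs <- xs[xs >= 1L & xs <= landscape$ncols]
  ys <- ys[ys >= 1L & ys <= landscape$nrows]
  if (!length(xs) || !length(ys)) return(0)
  gx <- rep(xs, times = length(ys)); gy <- rep(ys, each = length(xs))
  suit <- is_suitable(landscape, gx, gy, params)
  n_suit <- sum(suit)
  if (n_suit == 0L) return(0)
  mp <- landscape$mp[cbind(gx, gy)]
  mp[is.na(mp)] <- 0
  K <- cell_k(mp, params)
  Keff <- sum(K) * n_suit / params$LOCDIM^2
  if (Keff <= 0) return(0)
  N <- sum(occ$male[cbind(gx, gy)] != 0L)
  sum(mp * suit) * max(0, Keff - N) / Keff
}

#' Female score of one LS square
#'
#' The number of cells in the LS square centred at `(cx, cy)` that hold a
#' resident male but no resident female.
#'
#' @inheritParams ls_square_score_male
#' @return Non-negative integer count.
#' @export
ls_square_score_female <- function(occ, cx, cy, params) {
  hl <- (params$LOCDIM - 1L) %/% 2L
  nc <- nrow(occ$male); nr <- ncol(occ$male)
  xs <- (cx - hl):(cx + hl); ys <- (cy - hl):(cy + hl)
  xs <- xs[xs >= 1L & xs <= nc]; ys <- ys[ys >= 1L & ys <= nr]
  if (!length(xs) || !length(ys)) return(0L)
  m <- occ$male[xs, ys, drop = FALSE]; f <- occ$female[xs, ys, drop = FALSE]
  sum(m != 0L & f == 0L)
}

# roulette draw: index proportional to non-negative weights, 0L if all zero
.roulette <- function(w) {
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0) return(0L)
  sample.int(length(w), 1L, prob = w)
}

#' Select an LS square for a dispersing bird
#'
#' Scores the LANDDIM x LANDDIM block of LS squares centred on `(x, y)`
#' (male or female scoring by `sex`), multiplies by the distance weight
#' `exp(-kdist * d)` with `d` the centre-to-centre distance in cells, and
#' draws one square with probability proportional to the weighted score.
#'
#' @param landscape a `harrier_landscape`.
#' @param occ an `occupancy_grid`.
#' @param x,y the bird's cell.
#' @param sex `"M"`/`"F"` or 1/2.
#' @param kdist the distance-weighting parameter appropriate to the bird
#'   (natal vs post-failure, by sex).
#' @param params a `harrier_params`.
#' @return `c(cx, cy)` of the chosen square's centre cell, or `NULL` when
#'   every weighted score is zero.
#' @export
select_ls_square <- function(landscape, occ, x, y, sex, kdist, params) {
  male <- identical(sex, "M") || identical(sex, SEX_M) || identical(sex, 1)
  half <- (params$LANDDIM - 1L) %/% 2L
  ivec <- rep(seq.int(-half, half), each = params$LANDDIM)
  jvec <- rep(seq.int(-half, half), times = params$LANDDIM)
  cx <- x + params$LOCDIM * ivec; cy <- y + params$LOCDIM * jvec
  score <- vapply(seq_along(cx), function(s) {
    if (male) ls_square_score_male(landscape, occ, cx[s], cy[s], params)
    else as.numeric(ls_square_score_female(occ, cx[s], cy[s], params))
  }, numeric(1))
  w <- score * distance_weight(params$LOCDIM * sqrt(ivec^2 + jvec^2), kdist)
  s <- .roulette(w)
  if (s == 0L) NULL else c(cx[s], cy[s])
}

#' Select a territory cell within an LS square
#'
#' Eligible cells (for males: suitable and without a resident male; for
#' females: suitable, holding a resident male, without a resident female and
#' not the female's natal cell) are drawn with probability proportional to
#' their meadow pipit index.  There is no distance or carrying-capacity
#' weighting at this stage.
#'
#' @param landscape a `harrier_landscape`.
#' @param occ an `occupancy_grid`.
#' @param cx,cy centre of the selected LS square.
#' @param sex `"M"`/`"F"` or 1/2.
#' @param natal_x,natal_y the bird's natal cell (used for females only).
#' @param params a `harrier_params`.
#' @return `c(x, y)` of the chosen cell, or `NULL` if no cell scores above
#'   zero.
#' @export
select_cell <- function(landscape, occ, cx, cy, sex,
                        natal_x = NA, natal_y = NA, params) {
  male <- identical(sex, "M") || identical(sex, SEX_M) || identical(sex, 1)
  hl <- (params$LOCDIM - 1L) %/% 2L
  xs <- (cx - hl):(cx + hl); ys <- (cy - hl):(cy + hl)
  xs <- xs[xs >= 1L & xs <= landscape$ncols]
  ys <- ys[ys >= 1L & ys <= landscape$nrows]
  if (!length(xs) || !length(ys)) return(NULL)
  gx <- rep(xs, times = length(ys)); gy <- rep(ys, each = length(xs))
  idx <- cbind(gx, gy)
  suit <- is_suitable(landscape, gx, gy, params)
  elig <- if (male) {
    suit & occ$male[idx] == 0L
  } else {
    e <- suit & occ$male[idx] != 0L & occ$female[idx] == 0L
    if (!is.na(natal_x)) e <- e & !(gx == natal_x & gy == natal_y)
    e
  }
  mp <- landscape$mp[idx]
  mp[is.na(mp)] <- 0
  w <- mp * elig
  s <- .roulette(w)
  if (s == 0L) NULL else c(gx[s], gy[s])
}

# ---- the full sub-model -----------------------------------------------------

#' Run the breeding-site-selection sub-model for one year
#'
#' Determines which birds disperse, vacates their residencies, processes all
#' male dispersers (in stored adult order) and then all female dispersers,
#' applying first-year long-distance dispersal and first-year breeding
#' eligibility, and finally flags co-resident pairs as breeders (status 3).
#'
#' @param pop population list (`adults`, `juvs`).
#' @param landscape a `harrier_landscape`.
#' @param occ an `occupancy_grid`.
#' @param params a `harrier_params`.
#' @param cache optional [selection_cache()] (rebuilt when `NULL`).
#' @return List with updated `pop`, `occ`, and `n_pairs` (cells holding both
#'   residents after selection).
#' @export
run_site_selection <- function(pop, landscape, occ, params, cache = NULL) {
  if (is.null(cache)) cache <- selection_cache(landscape, params)
  a <- pop$adults
  n <- nrow(a)
  id <- a$id; age <- a$age; sex <- a$sex; status <- a$status
  success <- a$success; nx <- a$natal_x; ny <- a$natal_y
  x <- a$x; y <- a$y; res <- a$resident
  occ_m <- occ$male; occ_f <- occ$female
  mps <- cache$mps; hl <- cache$hl
  ncg <- cache$ncols; nrg <- cache$nrows

  # who stays: successful males; successful females whose mate survived
  mate_alive <- rep(TRUE, n)
  fem_res <- sex == SEX_F & res
  mate_alive[fem_res] <- occ_m[cbind(x[fem_res], y[fem_res])] != 0L
  disperse <- must_disperse(success, sex, mate_alive)

  # vacate the residencies of all dispersers before anyone scores
  for (i in which(disperse & res)) {
    if (sex[i] == SEX_M) {
      if (occ_m[x[i], y[i]] == id[i]) occ_m[x[i], y[i]] <- 0L
    } else {
      if (occ_f[x[i], y[i]] == id[i]) occ_f[x[i], y[i]] <- 0L
    }
    res[i] <- FALSE
  }
  status[!disperse] <- STATUS[["potential"]]

  p_ldd <- params$PLDD / 100
  p_b1m <- params$PBREED1M / 100
  p_b1f <- params$PBREED1F / 100

  # hoisted cache fields (the per-bird loop is the simulator's hot path)
  TdivK <- cache$TdivK; Keff <- cache$Keff
  pad <- cache$pad; pnc <- cache$pnc; pnr <- cache$pnr
  ivL <- cache$LOCDIM * cache$ivec; jvL <- cache$LOCDIM * cache$jvec
  W_NM <- cache$W$NM; W_NF <- cache$W$NF
  W_FM <- cache$W$FM; W_FF <- cache$W$FF
  nsq <- length(ivL)
  status_nb <- STATUS[["nonbreeder"]]
  status_pot <- STATUS[["potential"]]
  status_br <- STATUS[["breeder"]]

  # box counts of resident males per LS-square centre (stayers now)
  nbox <- .box_counts(occ_m != 0L, hl, pad)

  # ---- male pass
  for (i in which(disperse & sex == SEX_M)) {
    firstyear <- age[i] == 1L
    if (firstyear && stats::runif(1L) < p_ldd) {
      xy <- long_distance_dispersal(x[i], y[i], SEX_M, landscape, params)
      x[i] <- xy[1L]; y[i] <- xy[2L]
    }
    eligible <- !firstyear || stats::runif(1L) < p_b1m
    px <- x[i] + ivL + pad; py <- y[i] + jvL + pad
    ok <- px >= 1L & px <= pnc & py >= 1L & py <= pnr
    w <- numeric(nsq)
    li <- px[ok] + (py[ok] - 1L) * pnc
    w[ok] <- TdivK[li] * pmax(0, Keff[li] - nbox[li])
    w <- w * (if (firstyear) W_NM else W_FM)
    s <- .roulette(w)
    if (s == 0L) { status[i] <- status_nb; next }
    cx <- x[i] + ivL[s]; cy <- y[i] + jvL[s]
    xs <- max(cx - hl, 1L):min(cx + hl, ncg)
    ys <- max(cy - hl, 1L):min(cy + hl, nrg)
    wcell <- mps[xs, ys, drop = FALSE] * (occ_m[xs, ys, drop = FALSE] == 0L)
    sc <- .roulette(wcell)
    if (sc == 0L) { status[i] <- status_nb; next }
    tx <- xs[(sc - 1L) %% length(xs) + 1L]
    ty <- ys[(sc - 1L) %/% length(xs) + 1L]
    x[i] <- tx; y[i] <- ty
    if (eligible) {
      occ_m[tx, ty] <- id[i]
      res[i] <- TRUE
      status[i] <- status_pot
      xr <- (tx - hl + pad):(tx + hl + pad)
      yr <- (ty - hl + pad):(ty + hl + pad)
      nbox[xr, yr] <- nbox[xr, yr] + 1
    } else {
      status[i] <- status_nb
    }
  }

  # box counts of unpaired resident males per LS-square centre
  lbox <- .box_counts(occ_m != 0L & occ_f == 0L, hl, pad)

  # ---- female pass
  for (i in which(disperse & sex == SEX_F)) {
    firstyear <- age[i] == 1L
    if (firstyear && stats::runif(1L) < p_ldd) {
      xy <- long_distance_dispersal(x[i], y[i], SEX_F, landscape, params)
      x[i] <- xy[1L]; y[i] <- xy[2L]
    }
    eligible <- !firstyear || stats::runif(1L) < p_b1f
    Wf <- if (firstyear) W_NF else W_FF
    px <- x[i] + ivL + pad; py <- y[i] + jvL + pad
    ok <- px >= 1L & px <= pnc & py >= 1L & py <= pnr
    w <- numeric(nsq)
    w[ok] <- lbox[px[ok] + (py[ok] - 1L) * pnc]
    w <- w * Wf
    if (sum(w) <= 0) {
      # one random LS-square step, then a second and final attempt
      dxs <- c(-1, 0, 1, -1, 1, -1, 0, 1) * cache$LOCDIM
      dys <- c(-1, -1, -1, 0, 0, 1, 1, 1) * cache$LOCDIM
      okd <- which(x[i] + dxs >= 1L & x[i] + dxs <= ncg &
                     y[i] + dys >= 1L & y[i] + dys <= nrg)
      if (length(okd)) {
        k <- okd[sample.int(length(okd), 1L)]
        x[i] <- x[i] + dxs[k]; y[i] <- y[i] + dys[k]
      }
      px <- x[i] + ivL + pad; py <- y[i] + jvL + pad
      ok <- px >= 1L & px <= pnc & py >= 1L & py <= pnr
      w <- numeric(nsq)
      w[ok] <- lbox[px[ok] + (py[ok] - 1L) * pnc]
      w <- w * Wf
      if (sum(w) <= 0) { status[i] <- status_nb; next }
    }
    s <- .roulette(w)
    cx <- x[i] + ivL[s]; cy <- y[i] + jvL[s]
    xs <- max(cx - hl, 1L):min(cx + hl, ncg)
    ys <- max(cy - hl, 1L):min(cy + hl, nrg)
    wcell <- mps[xs, ys, drop = FALSE] *
      (occ_m[xs, ys, drop = FALSE] != 0L) *
      (occ_f[xs, ys, drop = FALSE] == 0L)
    # a female never settles in her natal cell
    if (nx[i] >= xs[1L] && nx[i] <= xs[length(xs)] &&
        ny[i] >= ys[1L] && ny[i] <= ys[length(ys)])
      wcell[nx[i] - xs[1L] + 1L, ny[i] - ys[1L] + 1L] <- 0
    sc <- .roulette(wcell)
    if (sc == 0L) { status[i] <- status_nb; next }
    tx <- xs[(sc - 1L) %% length(xs) + 1L]
    ty <- ys[(sc - 1L) %/% length(xs) + 1L]
    x[i] <- tx; y[i] <- ty
    if (eligible) {
      occ_f[tx, ty] <- id[i]
      res[i] <- TRUE
      status[i] <- status_br
      xr <- (tx - hl + pad):(tx + hl + pad)
      yr <- (ty - hl + pad):(ty + hl + pad)
      lbox[xr, yr] <- lbox[xr, yr] - 1
    } else {
      # moved to the chosen cell but will not breed this year
      status[i] <- status_pot
    }
  }

  # ---- pair sweep: co-resident male + female are breeders
  pair_idx <- which(occ_m != 0L & occ_f != 0L)
  if (length(pair_idx)) {
    pair_ids <- c(occ_m[pair_idx], occ_f[pair_idx])
    status[match(pair_ids, id)] <- STATUS[["breeder"]]
  }

  a$age <- age; a$status <- status; a$x <- x; a$y <- y; a$resident <- res
  pop$adults <- a
  list(pop = pop,
       occ = structure(list(male = occ_m, female = occ_f),
                       class = "occupancy_grid"),
       n_pairs = length(pair_idx))
}
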