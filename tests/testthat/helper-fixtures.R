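# Shared fixture builders: small landscapes and hand-made populations.

# a tiny all-suitable landscape with constant layers
tiny_landscape <- function(n = 20L, mp = 10, burning = 0, heath = 30,
                           suitability = 1, altitude = 200, sea_margin = 0L) {
  uniform_landscape(n, n, mp = mp, burning = burning, heath = heath,
                    suitability = suitability, altitude = altitude,
                    sea_margin = sea_margin)
}

# a landscape where no cell is suitable (heath below threshold)
barren_landscape <- function(n = 20L) {
  uniform_landscape(n, n, mp = 10, burning = 0, heath = 5,
                    suitability = 1, altitude = 200)
}

# population of adult birds placed by hand; all fields overridable
place_birds <- function(..., pop = new_population()) {
  rows <- make_birds(...)
  pop$adults <- rbind(pop$adults, rows)
  pop
}

# register an existing adult as resident of its current cell
register_resident <- function(pop, occ, id) {
  i <- match(id, pop$adults$id)
  occ <- set_resident(occ, pop$adults$x[i], pop$adults$y[i],
                      pop$adults$sex[i], id)
  pop$adults$resident[i] <- TRUE
  list(pop = pop, occ = occ)
}

# chi-squared goodness-of-fit p-value of observed index draws vs probs
roulette_gof <- function(draws, probs) {
  obs <- tabulate(draws, length(probs))
  keep <- probs > 0
  stats::chisq.test(obs[keep], p = probs[keep] / sum(probs[keep]))$p.value
}
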