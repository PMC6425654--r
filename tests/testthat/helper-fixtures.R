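# Shared fixture builders (all data generated in code; nothing on disk).

# minimal panel-only structure over given sample ids
panel_structure <- function(samples, id = "PANEL", ptype = "panel_HW") {
  population_structure(
    data.frame(sample = samples, population = id),
    data.frame(population = id, ptype = ptype))
}

# an easy five-cluster marker: equal group sizes at given means
hard_cluster_signals <- function(mu = asin(sqrt((0:4) / 4)), per_group = 20,
                                 sigma = 0.02, seed = 1) {
  set.seed(seed)
  y <- rep(mu, each = per_group) + stats::rnorm(5 * per_group, 0, sigma)
  y <- pmin(pmax(y, 0), pi / 2)
  ids <- sprintf("s%03d", seq_along(y))
  marker_signals("mfix", ids, ratio = sin(y)^2)
}

# the 25-cell table of expected F1 segregation ratios, nulliplex..quadruplex
# parents, frozen from the published reference table
REFERENCE_SEGREGATION <- local({
  cells <- list(
    "0x0" = c(1, 0, 0, 0, 0), "0x1" = c(1, 1, 0, 0, 0),
    "0x2" = c(1, 4, 1, 0, 0), "0x3" = c(0, 1, 1, 0, 0),
    "0x4" = c(0, 0, 1, 0, 0),
    "1x1" = c(1, 2, 1, 0, 0), "1x2" = c(1, 5, 5, 1, 0),
    "1x3" = c(0, 1, 2, 1, 0), "1x4" = c(0, 0, 1, 1, 0),
    "2x2" = c(1, 8, 18, 8, 1), "2x3" = c(0, 1, 5, 5, 1),
    "2x4" = c(0, 0, 1, 4, 1),
    "3x3" = c(0, 0, 1, 2, 1), "3x4" = c(0, 0, 0, 1, 1),
    "4x4" = c(0, 0, 0, 0, 1))
  lapply(cells, as.integer)
})
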