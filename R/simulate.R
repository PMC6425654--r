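# Synthetic marker data with the statistical structure the mixture model
# assumes: per-population dosage draws (HW panel / F1 segregation / fixed
# parental dosage), Gaussian noise on the transformed scale, mapped back to
# a two-channel signal pair of unit total intensity.

#' Specification of a synthetic dataset
#'
#' @param n_markers Number of markers to simulate.
#' @param populations List of population descriptors, each a list with
#'   `id`, `ptype` (`panel_free`, `panel_HW`, `F1`, `parent`), `n`
#'   (sample count; replicate count for parents) and optionally
#'   `allele_freq` (HW panels; drawn per marker from U(0.1, 0.9) when
#'   absent), `parents` (F1: ids of the two parent populations),
#'   `family` (parent: id of its F1), `dosage` (parent: fixed dosage;
#'   drawn uniformly per marker when absent).
#' @param mu_truth Optional explicit 5-vector of true component means;
#'   default derives them from `mean_param`.
#' @param mean_param List(`c_a`, `c_b`, `k`) for [mu_from_background()];
#'   default zero background, linear response (the equally-spaced ideal).
#' @param sigma Noise SD on the transformed scale (default 0.04).
#' @param na_rate Per-sample probability of a missing signal pair
#'   (default 0.02).
#' @param seed Integer master seed; expands deterministically to
#'   per-marker seeds.
#' @return Object of class `sim_spec`.
#' @export
sim_spec <- function(n_markers = 1L, populations, mu_truth = NULL,
                     mean_param = list(c_a = 0, c_b = 0, k = 0),
                     sigma = 0.04, na_rate = 0.02, seed = 1L) {
  stopifnot(n_markers >= 1, sigma > 0, na_rate >= 0, na_rate <= 1)
  if (is.null(mu_truth)) {
    mu_truth <- mu_from_background(mean_param$c_a, mean_param$c_b,
                                   mean_param$k)
  }
  stopifnot(length(mu_truth) == 5, all(diff(mu_truth) > 0))
  for (p in populations) {
    stopifnot(!is.null(p$id), !is.null(p$ptype), p$n >= 0)
  }
  base::structure(
    list(n_markers = as.integer(n_markers), populations = populations,
         mu_truth = mu_truth, mean_param = mean_param, sigma = sigma,
         na_rate = na_rate, seed = as.integer(seed)),
    class = "sim_spec")
}

# population_structure implied by a sim_spec, with deterministic sample ids
structure_from_spec <- function(spec) {
  assignments <- NULL
  defs <- NULL
  for (p in spec$populations) {
    ids <- sprintf("%s_%03d", p$id, seq_len(p$n))
    assignments <- rbind(assignments,
                         data.frame(sample = ids, population = p$id,
                                    stringsAsFactors = FALSE))
    defs <- rbind(defs, data.frame(
      population = p$id, ptype = p$ptype,
      link1 = if (p$ptype == "F1") p$parents[1]
              else if (p$ptype == "parent") p$family else NA_character_,
      link2 = if (p$ptype == "F1") p$parents[2] else NA_character_,
      stringsAsFactors = FALSE))
  }
  population_structure(assignments, defs)
}

#' Simulate one marker
#'
#' Dosages are drawn per population (HW panel: tetraploid Hardy-Weinberg
#' proportions; F1: tetrasomic segregation of the parents' dosages;
#' parent: its fixed dosage across all replicates; free panel: uniform over
#' 0..4).  The transformed response is y = mu(dosage) + N(0, sigma^2),
#' clamped to \[0, pi/2\], and mapped back to a signal pair of unit total
#' intensity so that [transform_ratio()] recovers y exactly.
#'
#' @param spec A [sim_spec()].
#' @param marker_id Marker name.
#' @param seed Seed for this marker (default: the spec's master seed).
#' @return List with `signals` ([marker_signals()]), `structure`
#'   ([population_structure()]), `truth` (named dosage vector) and
#'   `parental_dosages` (named vector over parent populations).
#' @export
simulate_marker <- function(spec, marker_id = "m1", seed = spec$seed) {
  set.seed(seed)
  struct <- structure_from_spec(spec)
  pops <- stats::setNames(spec$populations,
                          vapply(spec$populations, `[[`, character(1), "id"))
  # draw marker-level population parameters first (parents before F1s)
  parent_dosage <- list()
  freq <- list()
  for (p in spec$populations) {
    if (p$ptype == "parent") {
      parent_dosage[[p$id]] <- if (!is.null(p$dosage)) p$dosage
                               else sample(0:4, 1)
    } else if (p$ptype == "panel_HW") {
      freq[[p$id]] <- if (!is.null(p$allele_freq)) p$allele_freq
                      else stats::runif(1, 0.1, 0.9)
    }
  }
  truth <- integer(0)
  for (p in spec$populations) {
    d <- switch(p$ptype,
      parent = rep(parent_dosage[[p$id]], p$n),
      F1 = {
        dp <- c(parent_dosage[[p$parents[1]]], parent_dosage[[p$parents[2]]])
        sample(0:4, p$n, replace = TRUE,
               prob = f1_segregation(dp[1], dp[2])$proportions)
      },
      panel_HW = sample(0:4, p$n, replace = TRUE,
                        prob = hw_proportions(freq[[p$id]])),
      panel_free = sample(0:4, p$n, replace = TRUE))
    truth <- c(truth, d)
  }
  samples <- struct$assignments$sample
  names(truth) <- samples
  y <- spec$mu_truth[truth + 1] + stats::rnorm(length(truth), 0, spec$sigma)
  y <- pmin(pmax(y, 0), pi / 2)
  ratio <- sin(y)^2
  na <- stats::runif(length(y)) < spec$na_rate
  sa <- ifelse(na, NA_real_, 1 - ratio)
  sb <- ifelse(na, NA_real_, ratio)
  list(signals = marker_signals(marker_id, samples, signal_a = sa,
                                signal_b = sb),
       structure = struct,
       truth = truth,
       parental_dosages = unlist(parent_dosage))
}

#' Simulate a multi-marker dataset
#'
#' Expands the master seed into one deterministic seed per marker and calls
#' [simulate_marker()] for each.  True parental dosages are collected as a
#' prior table usable by [fit_marker()].
#'
#' @param spec A [sim_spec()].
#' @return List with `signals` (named list of [marker_signals()]),
#'   `structure`, `truth` (marker x sample integer matrix) and `priors`
#'   (data.frame of the true parental dosages).
#' @export
simulate_dataset <- function(spec) {
  set.seed(spec$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, spec$n_markers)
  ids <- sprintf("snp%04d", seq_len(spec$n_markers))
  signals <- list()
  truth <- NULL
  priors <- NULL
  struct <- NULL
  for (i in seq_len(spec$n_markers)) {
    sim <- simulate_marker(spec, ids[i], seeds[i])
    signals[[ids[i]]] <- sim$signals
    struct <- sim$structure
    truth <- rbind(truth, sim$truth)
    if (length(sim$parental_dosages)) {
      priors <- rbind(priors, data.frame(
        marker = ids[i], population = names(sim$parental_dosages),
        dosage = unname(sim$parental_dosages), stringsAsFactors = FALSE))
    }
  }
  rownames(truth) <- ids
  list(signals = signals, structure = struct, truth = truth, priors = priors)
}

#' Standard test-cross layout
#'
#' A [sim_spec()] mirroring the archetypal array experiment: one large
#' tetraploid full-sib family with its two parents replicated about a dozen
#' times each, plus an unstructured panel assumed in Hardy-Weinberg
#' equilibrium.  The default is a reduced-scale version (200 offspring,
#' 12 + 13 parental replicates, 60 panel samples = 285 samples);
#' `full_scale = TRUE` uses the full population sizes (975 offspring,
#' 12 + 13 replicates, 222 panel samples).
#'
#' @param n_markers Number of markers.
#' @param n_f1,n_parent1,n_parent2,n_panel Population sizes; `n_panel = 0`
#'   drops the panel population.
#' @param full_scale Use the full-size layout.
#' @param parental_dosages Optional length-2 vector fixing the parents'
#'   dosages for every marker (default: drawn per marker).
#' @param ... Passed to [sim_spec()] (`sigma`, `na_rate`, `seed`, ...).
#' @return A [sim_spec()].
#' @export
make_test_layout <- function(n_markers = 1L, n_f1 = 200L, n_parent1 = 12L,
                             n_parent2 = 13L, n_panel = 60L,
                             full_scale = FALSE,
                             parental_dosages = NULL, ...) {
  if (full_scale) {
    n_f1 <- 975L; n_parent1 <- 12L; n_parent2 <- 13L; n_panel <- 222L
  }
  d1 <- if (!is.null(parental_dosages)) parental_dosages[1]
  d2 <- if (!is.null(parental_dosages)) parental_dosages[2]
  pops <- list(
    list(id = "F1FAM", ptype = "F1", n = n_f1, parents = c("P1", "P2")),
    list(id = "P1", ptype = "parent", n = n_parent1, family = "F1FAM",
         dosage = d1),
    list(id = "P2", ptype = "parent", n = n_parent2, family = "F1FAM",
         dosage = d2))
  if (n_panel > 0) {
    pops <- c(pops, list(list(id = "PANEL", ptype = "panel_HW", n = n_panel)))
  }
  sim_spec(n_markers = n_markers, populations = pops, ...)
}
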