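#' Run configuration
#'
#' Collects the tunable parameters of the calling pipeline.  Defaults follow
#' the published settings: posterior call threshold 0.75, single-category
#' peak threshold 0.9, maximum missing-call fraction 0.25, and the extreme
#' (2.5%) / adjacent (15%) triggers of the model re-evaluation heuristic.
#'
#' @param call_threshold Minimum posterior probability to call a dosage.
#' @param peak_threshold Marker rejected when the largest called-dosage
#'   class exceeds this fraction of called samples.
#' @param na_fraction_max Marker rejected when the missing-call fraction
#'   exceeds this.
#' @param extreme_trigger Re-evaluate when an extreme component carries less
#'   than this overall fraction of samples...
#' @param adjacent_trigger ...while its neighbour carries more than this.
#' @param em_tol Absolute log-likelihood convergence tolerance.
#' @param em_max_iter Maximum EM iterations.
#' @param min_samples Minimum observed samples required to fit a marker.
#' @param sigma2_floor Lower bound on the common component variance.
#' @param fixed_eps Leak probability per non-prior class in the spiked
#'   `p_fixed` proportions (guards replicated parents against outliers).
#' @param seed Integer seed threaded through the synthetic-data generator.
#' @param threads Number of worker processes for the batch driver.
#' @param plot Reserved; diagnostic plotting switch for the batch driver.
#' @return List of class `run_config`.
#' @export
run_config <- function(call_threshold = 0.75, peak_threshold = 0.9,
                       na_fraction_max = 0.25, extreme_trigger = 0.025,
                       adjacent_trigger = 0.15, em_tol = 1e-6,
                       em_max_iter = 500L, min_samples = 10L,
                       sigma2_floor = 1e-6, fixed_eps = 0.02,
                       seed = 1L, threads = 1L, plot = FALSE) {
  stopifnot(call_threshold > 0, call_threshold <= 1,
            peak_threshold > 0, peak_threshold <= 1,
            em_tol > 0, em_max_iter >= 1, min_samples >= 1)
  structure(list(call_threshold = call_threshold,
                 peak_threshold = peak_threshold,
                 na_fraction_max = na_fraction_max,
                 extreme_trigger = extreme_trigger,
                 adjacent_trigger = adjacent_trigger,
                 em_tol = em_tol, em_max_iter = as.integer(em_max_iter),
                 min_samples = as.integer(min_samples),
                 sigma2_floor = sigma2_floor, fixed_eps = fixed_eps,
                 seed = as.integer(seed), threads = as.integer(threads),
                 plot = plot),
            class = "run_config")
}

ideal_mu <- function() mu_from_background(0, 0, 0)

# quantile-style seeding: hard-assign y by cutting at the ratio midpoints
# arcsin(sqrt((j + 0.5)/4)), take class means (ideal mean where a class is
# empty), pooled within-class variance
seed_mu_sigma <- function(y) {
  yo <- y[!is.na(y)]
  bounds <- asin(sqrt(((0:3) + 0.5) / 4))
  cls <- findInterval(yo, bounds)  # 0..4
  mu <- ideal_mu()
  for (j in 0:4) {
    if (any(cls == j)) mu[j + 1] <- mean(yo[cls == j])
  }
  s2 <- sum((yo - mu[cls + 1])^2) / length(yo)
  list(mu = mu, sigma2 = max(s2, 1e-4))
}

# default starting model given constraints; fixed_dosages: named integer
# vector pop -> known parental dosage (p_fixed populations)
default_start <- function(y, pop, pi_constraint, fixed_dosages = NULL,
                          mu_constraint = "free", fixed_eps = 0.02) {
  ms <- seed_mu_sigma(y)
  mu <- ms$mu
  mean_param <- NULL
  if (mu_constraint != "free") {
    mean_param <- fit_mean_param(mu, rep(1, 5), mu_constraint)
    mu <- mu_from_background(mean_param$c_a, mean_param$c_b, mean_param$k)
  }
  pi <- list()
  for (pid in names(pi_constraint)) {
    pi[[pid]] <- switch(pi_constraint[[pid]],
      p_HW = {
        yp <- y[pop == pid & !is.na(y)]
        p0 <- if (length(yp)) min(max(mean(sin(yp)^2), 0.01), 0.99) else 0.5
        hw_proportions(p0)
      },
      p_fixed = spiked_pi(fixed_dosages[[pid]], fixed_eps),
      rep(0.2, 5))
    names(pi[[pid]]) <- as.character(0:4)
  }
  mixture_model(mu, ms$sigma2, pi, mu_constraint,
                unlist(pi_constraint), mean_param)
}

#' Fit the constrained mixture model by EM
#'
#' Alternates [e_step()] and the two M-steps until the observed-data
#' log-likelihood changes by less than `config$em_tol` or `em_max_iter`
#' iterations are reached.  The reported log-likelihood, BIC and posterior
#' matrix always correspond to the returned parameter values.
#'
#' @param signals A [marker_signals()].
#' @param structure A [population_structure()] covering every sample.
#' @param mu_constraint Mean-constraint variant (see [mixture_model()]).
#' @param pi_constraints Named character vector population -> constraint
#'   (`p_free`, `p_HW`, `p_fixed`, `p_F1`).
#' @param fixed_dosages Named integer vector population -> known dosage,
#'   required for every `p_fixed` population.
#' @param start Optional starting [mixture_model()]; default is data-driven
#'   seeding.
#' @param config A [run_config()].
#' @param exclude_component Optional dosage (0 or 4) whose mixing
#'   proportion is forced to zero in every population (used by the model
#'   re-evaluation heuristic).
#' @return List with elements `model` (fitted [mixture_model()], including
#'   `loglik`, `bic`, `n_params`, `n_iter`, `converged`, `loglik_trace`)
#'   and `posteriors` (n x 5 matrix).
#' @export
run_em <- function(signals, structure, mu_constraint = "free",
                   pi_constraints = NULL, fixed_dosages = NULL,
                   start = NULL, config = run_config(),
                   exclude_component = NULL) {
  y <- signals$y
  pop <- unname(pop_of(structure)[signals$sample_ids])
  if (anyNA(pop)) {
    stop("sample(s) missing from the population structure: ",
         paste(utils::head(signals$sample_ids[is.na(pop)], 5L),
               collapse = ", "), call. = FALSE)
  }
  if (is.null(pi_constraints)) {
    pids <- unique(pop)
    pi_constraints <- stats::setNames(rep("p_free", length(pids)), pids)
  }
  n_obs <- sum(!is.na(y))
  if (n_obs < config$min_samples) {
    stop("fewer than min_samples (", config$min_samples, ") observations",
         call. = FALSE)
  }
  fixed_pi <- NULL
  fixed_pops <- names(pi_constraints)[pi_constraints == "p_fixed"]
  if (length(fixed_pops)) {
    if (!all(fixed_pops %in% names(fixed_dosages))) {
      stop("p_fixed population(s) need fixed_dosages", call. = FALSE)
    }
    fixed_pi <- lapply(stats::setNames(fixed_pops, fixed_pops),
                       function(p) spiked_pi(fixed_dosages[[p]],
                                             config$fixed_eps))
  }
  model <- if (is.null(start)) {
    default_start(y, pop, as.list(pi_constraints), fixed_dosages,
                  mu_constraint, config$fixed_eps)
  } else start
  excl <- if (is.null(exclude_component)) integer(0) else exclude_component + 1L
  zero_excluded <- function(pi) {
    if (!length(excl)) return(pi)
    lapply(pi, function(p) { p[excl] <- 0; p / sum(p) })
  }
  model$pi <- zero_excluded(model$pi)

  trace <- numeric(0)
  posteriors <- NULL
  converged <- FALSE
  iter <- 0L
  repeat {
    es <- em_e_step(y, pop, model)
    posteriors <- es$posteriors
    trace <- c(trace, es$loglik)
    if (iter > 0L &&
        abs(es$loglik - trace[length(trace) - 1L]) < config$em_tol) {
      converged <- TRUE
      break
    }
    if (iter >= config$em_max_iter) break
    iter <- iter + 1L
    mss <- em_m_step_mu_sigma(y, posteriors, mu_constraint, model$mu,
                              model$mean_param, config$sigma2_floor)
    model$mu <- mss$mu
    model$sigma2 <- mss$sigma2
    model$mean_param <- mss$mean_param
    if (is.unsorted(model$mu, strictly = TRUE)) {
      # label switching: re-sort components, carry posteriors along
      o <- order(model$mu)
      model$mu <- model$mu[o]
      posteriors <- posteriors[, o, drop = FALSE]
      model$pi <- lapply(model$pi, function(p) stats::setNames(p[o],
                                                               as.character(0:4)))
    }
    model$pi <- zero_excluded(
      em_m_step_pi(posteriors, pop, structure, as.list(pi_constraints),
                   fixed_pi, model$pi, y, model$mu, model$sigma2))
  }
  dimnames(posteriors) <- list(signals$sample_ids, as.character(0:4))
  model$loglik <- trace[length(trace)]
  model$loglik_trace <- trace
  model$n_iter <- iter
  model$converged <- converged
  model$n_obs <- n_obs
  model$n_params <- as.integer(
    1L + MEAN_NPARAMS[[mu_constraint]] +
      sum(PI_NPARAMS[unlist(pi_constraints)]))
  model$bic <- -2 * model$loglik + model$n_params * log(n_obs)
  list(model = model, posteriors = posteriors)
}
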