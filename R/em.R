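# Five-component normal mixture EM for transformed signal ratios of one
# marker.  Component means and the common variance are shared across all
# subpopulations; mixing proportions are population-specific and follow one
# of four constraint regimes (p_free, p_HW, p_fixed, p_F1).

MU_CONSTRAINTS <- c("free",
                    "background_equal_linear", "background_unequal_linear",
                    "background_equal_quadratic", "background_unequal_quadratic")
PI_CONSTRAINTS <- c("p_free", "p_HW", "p_fixed", "p_F1")

# free parameters counted towards BIC (shared variance counted separately)
MEAN_NPARAMS <- c(free = 5,
                  background_equal_linear = 2,
                  background_unequal_linear = 3,
                  background_equal_quadratic = 3,
                  background_unequal_quadratic = 4)
PI_NPARAMS <- c(p_free = 4, p_HW = 1, p_fixed = 0, p_F1 = 0)

#' Component means implied by a signal-response parameterization
#'
#' The two channel signals are modelled as affine-in-dosage responses with
#' nonnegative backgrounds and optional quadratic curvature:
#' f_B(j) = c_b + j (1 + k j) and f_A(j) = c_a + (4 - j)(1 + k (4 - j)),
#' giving mu_j = arcsin(sqrt(f_B(j) / (f_A(j) + f_B(j)))).  With zero
#' backgrounds and no curvature this reduces to the equally-proportioned
#' ideal arcsin(sqrt(j/4)).  The implied means are strictly increasing for
#' any c_a, c_b, k >= 0.
#'
#' @param c_a,c_b Background signal for channel a resp. b (>= 0).
#' @param k Curvature of the dose-response (>= 0; 0 means linear).
#' @return Numeric 5-vector of strictly increasing means in (0, pi/2).
#' @export
mu_from_background <- function(c_a = 0, c_b = 0, k = 0) {
  j <- 0:4
  f_b <- c_b + j * (1 + k * j)
  f_a <- c_a + (4 - j) * (1 + k * (4 - j))
  # clamp guards finite-difference steps marginally below the zero bound
  asin(sqrt(pmin(pmax(f_b / (f_a + f_b), 0), 1)))
}

spiked_pi <- function(dosage, eps = 0.02) {
  p <- rep(eps, 5)
  p[dosage + 1] <- 1 - 4 * eps
  names(p) <- as.character(0:4)
  p
}

#' Construct a five-component mixture model
#'
#' @param mu Strictly increasing 5-vector of component means (transformed
#'   scale).
#' @param sigma2 Common component variance (> 0).
#' @param pi Named list: population id -> 5-vector of mixing proportions
#'   (each summing to 1).
#' @param mu_constraint One of `"free"`, `"background_equal_linear"`,
#'   `"background_unequal_linear"`, `"background_equal_quadratic"`,
#'   `"background_unequal_quadratic"`.
#' @param pi_constraint Named character vector: population id -> one of
#'   `"p_free"`, `"p_HW"`, `"p_fixed"`, `"p_F1"`.
#' @param mean_param Optional list with `c_a`, `c_b`, `k` for constrained
#'   mean variants.
#' @return Object of class `mixture_model`.
#' @export
mixture_model <- function(mu, sigma2, pi, mu_constraint = "free",
                          pi_constraint = NULL, mean_param = NULL) {
  mu_constraint <- match.arg(mu_constraint, MU_CONSTRAINTS)
  stopifnot(length(mu) == 5, all(diff(mu) > 0), sigma2 > 0)
  if (is.null(pi_constraint)) {
    pi_constraint <- stats::setNames(rep("p_free", length(pi)), names(pi))
  }
  stopifnot(all(pi_constraint %in% PI_CONSTRAINTS),
            setequal(names(pi), names(pi_constraint)))
  for (p in pi) stopifnot(length(p) == 5, abs(sum(p) - 1) < 1e-9)
  structure(
    list(mu = as.numeric(mu), sigma2 = as.numeric(sigma2), pi = pi,
         mu_constraint = mu_constraint, pi_constraint = pi_constraint,
         mean_param = mean_param, loglik = NA_real_, n_params = NA_integer_,
         bic = NA_real_, n_iter = 0L, converged = FALSE, n_obs = NA_integer_,
         loglik_trace = numeric(0)),
    class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("mixture_model (%s): mu = %s, sigma = %.4f\n",
              x$mu_constraint, paste(sprintf("%.3f", x$mu), collapse = ", "),
              sqrt(x$sigma2)))
  for (p in names(x$pi)) {
    cat(sprintf("  %s [%s]: %s\n", p, x$pi_constraint[p],
                paste(sprintf("%.3f", x$pi[[p]]), collapse = " ")))
  }
  if (!is.na(x$loglik)) {
    cat(sprintf("  loglik %.4f, BIC %.4f (%d params, %d obs), %d iter, %s\n",
                x$loglik, x$bic, x$n_params, x$n_obs, x$n_iter,
                if (x$converged) "converged" else "not converged"))
  }
  invisible(x)
}

#' Mixture density at given transformed values
#'
#' Evaluates f(y) = sum_j pi_j Normal(y; mu_j, sigma2) using the mixing
#' proportions of one population.
#'
#' @param y Numeric vector on the transformed scale.
#' @param model A [mixture_model()].
#' @param population_id Which population's mixing proportions to use.
#' @return Numeric vector of densities.
#' @export
mixture_density <- function(y, model, population_id) {
  if (!population_id %in% names(model$pi)) {
    stop("unknown population: ", population_id, call. = FALSE)
  }
  p <- model$pi[[population_id]]
  sd <- sqrt(model$sigma2)
  out <- numeric(length(y))
  for (j in 1:5) out <- out + p[j] * stats::dnorm(y, model$mu[j], sd)
  out
}

# core E-step on plain vectors; returns posteriors (n x 5, NA rows where y
# missing) and the observed-data log-likelihood
em_e_step <- function(y, pop, model) {
  n <- length(y)
  obs <- !is.na(y)
  if (!any(obs)) stop("no observations", call. = FALSE)
  sd <- sqrt(model$sigma2)
  pi_mat <- do.call(rbind, model$pi)          # pops x 5
  logpi <- log(pi_mat)[match(pop, names(model$pi)), , drop = FALSE]
  ll <- vapply(1:5, function(j) stats::dnorm(y, model$mu[j], sd, log = TRUE),
               numeric(n))
  a <- ll + logpi
  post <- matrix(NA_real_, n, 5)
  m <- apply(a[obs, , drop = FALSE], 1, max)
  e <- exp(a[obs, , drop = FALSE] - m)
  rs <- rowSums(e)
  post[obs, ] <- e / rs
  list(posteriors = post, loglik = sum(m + log(rs)))
}

#' E-step: posterior dosage-class probabilities
#'
#' Computes p_ij = pi_j f_j(y_i) / sum_k pi_k f_k(y_i) for every sample,
#' using the mixing proportions of the sample's own population.
#'
#' @param signals A [marker_signals()].
#' @param structure A [population_structure()] covering the samples.
#' @param model A [mixture_model()].
#' @return Matrix n x 5 (rows named by sample, columns by dosage 0..4);
#'   rows with missing y are all-`NA`.  Attribute `loglik` holds the
#'   observed-data log-likelihood.
#' @export
e_step <- function(signals, structure, model) {
  pop <- pop_of(structure)[signals$sample_ids]
  res <- em_e_step(signals$y, pop, model)
  dimnames(res$posteriors) <- list(signals$sample_ids, as.character(0:4))
  base::structure(res$posteriors, loglik = res$loglik)
}

# modal dosage of a population from summed posteriors; ties broken toward
# the dosage nearest the posterior-mean dosage, then toward the lower dosage
modal_dosage <- function(posteriors, rows) {
  s <- colSums(posteriors[rows, , drop = FALSE], na.rm = TRUE)
  if (sum(s) <= 0) return(NA_integer_)
  cand <- which(s >= max(s) - 1e-12) - 1L
  if (length(cand) > 1L) {
    mean_d <- sum((0:4) * s) / sum(s)
    cand <- cand[order(abs(cand - mean_d), cand)]
  }
  cand[1L]
}

# the 15 distinct F1 segregation rows (unordered parental pairs)
seg_rows <- local({
  rows <- NULL
  make <- function() {
    if (!is.null(rows)) return(rows)
    out <- list()
    for (d1 in 0:4) for (d2 in d1:4) {
      out[[paste(d1, d2, sep = "x")]] <- f1_segregation(d1, d2)$proportions
    }
    rows <<- out
    out
  }
  make
})

# core pi M-step; fixed_pi: named list pop -> 5-vector for p_fixed pops.
# y / mu / sigma2 are needed for the p_F1 likelihood guard: the parental
# modal plug-in row is used only when it does not lower that population's
# observed log-likelihood (it is not an ascent step in general), with the
# best-fitting segregation row as fallback, so the EM stays monotone.
em_m_step_pi <- function(posteriors, pop, structure, pi_constraint,
                         fixed_pi, current_pi, y, mu, sigma2) {
  obs <- !is.na(posteriors[, 1])
  sd <- sqrt(sigma2)
  pop_ll <- function(p, rows) {
    dens <- 0
    for (j in 1:5) dens <- dens + p[j] * stats::dnorm(y[rows], mu[j], sd)
    sum(log(dens))
  }
  out <- current_pi
  for (pid in names(pi_constraint)) {
    rows <- which(obs & pop == pid)
    ctype <- pi_constraint[[pid]]
    if (ctype == "p_fixed") {
      out[[pid]] <- fixed_pi[[pid]]
    } else if (ctype == "p_F1") {
      parents <- f1_parents(structure, pid)
      d <- vapply(parents, function(pp) {
        prow <- which(obs & pop == pp)
        if (length(prow)) modal_dosage(posteriors, prow)
        else if (!is.null(fixed_pi[[pp]])) which.max(fixed_pi[[pp]]) - 1L
        else NA_integer_
      }, integer(1))
      if (anyNA(d)) {
        warning("F1 population '", pid, "' has parents without samples or ",
                "priors; mixing proportions estimated freely", call. = FALSE)
        if (length(rows)) out[[pid]] <- colMeans(posteriors[rows, , drop = FALSE])
      } else {
        plug <- f1_segregation(d[1], d[2])$proportions
        if (!length(rows) || pop_ll(plug, rows) >=
              pop_ll(current_pi[[pid]], rows) - 1e-9) {
          out[[pid]] <- plug
        } else {
          cand <- c(list(current = current_pi[[pid]]), seg_rows())
          ll <- vapply(cand, pop_ll, numeric(1), rows = rows)
          out[[pid]] <- cand[[which.max(ll)]]
        }
      }
    } else if (length(rows) == 0L) {
      # no observed samples: keep current proportions
    } else if (ctype == "p_free") {
      out[[pid]] <- colMeans(posteriors[rows, , drop = FALSE])
    } else if (ctype == "p_HW") {
      pm <- colSums(posteriors[rows, , drop = FALSE])
      p_hat <- sum((0:4) * pm) / (4 * sum(pm))
      out[[pid]] <- hw_proportions(min(max(p_hat, 0), 1))
    }
    names(out[[pid]]) <- as.character(0:4)
  }
  out
}

#' M-step for the mixing proportions
#'
#' Updates the per-population mixing proportions from the current
#' posteriors under each population's constraint: `p_free` takes the mean
#' posterior, `p_HW` estimates the allele frequency from the posterior mean
#' dosage and applies tetraploid Hardy-Weinberg proportions, `p_fixed`
#' keeps the supplied (spiked) parental vector, and `p_F1` sets the
#' expected tetrasomic segregation ratio for the modal dosages of the
#' linked parent populations.
#'
#' @param posteriors Posterior matrix as returned by [e_step()].
#' @param signals The [marker_signals()] the posteriors were computed from.
#' @param structure A [population_structure()].
#' @param model The current [mixture_model()] (provides constraints and the
#'   proportions to keep where a population has no data).
#' @param fixed_pi Named list population -> 5-vector for `p_fixed`
#'   populations.
#' @return Named list of updated 5-vectors.
#' @export
m_step_pi <- function(posteriors, signals, structure, model,
                      fixed_pi = NULL) {
  pop <- pop_of(structure)[signals$sample_ids]
  em_m_step_pi(posteriors, pop, structure, as.list(model$pi_constraint),
               fixed_pi, model$pi, signals$y, model$mu, model$sigma2)
}

# weighted least-squares fit of (c_a, c_b, k) to component targets;
# always at least as good as `current` because `current` is a start
fit_mean_param <- function(target, weights, variant, current = NULL) {
  layout <- switch(variant,
    background_equal_linear = list(par = "c", k = FALSE),
    background_unequal_linear = list(par = c("c_a", "c_b"), k = FALSE),
    background_equal_quadratic = list(par = c("c", "k"), k = TRUE),
    background_unequal_quadratic = list(par = c("c_a", "c_b", "k"), k = TRUE),
    stop("not a constrained mean variant: ", variant, call. = FALSE))
  npar <- length(layout$par)
  unpack <- function(theta) {
    if (variant == "background_equal_linear") c(theta[1], theta[1], 0)
    else if (variant == "background_unequal_linear") c(theta[1], theta[2], 0)
    else if (variant == "background_equal_quadratic") c(theta[1], theta[1], theta[2])
    else theta
  }
  objective <- function(theta) {
    p <- unpack(theta)
    sum(weights * (target - mu_from_background(p[1], p[2], p[3]))^2)
  }
  starts <- list(rep(0.01, npar), rep(0.2, npar), rep(0.8, npar))
  if (!is.null(current)) {
    cur <- switch(variant,
      background_equal_linear = current$c_a,
      background_unequal_linear = c(current$c_a, current$c_b),
      background_equal_quadratic = c(current$c_a, current$k),
      background_unequal_quadratic = c(current$c_a, current$c_b, current$k))
    starts <- c(list(cur), starts)
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, objective, method = "L-BFGS-B",
                   lower = rep(0, npar), upper = rep(20, npar)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("mean-parameter optimization failed", call. = FALSE)
  p <- unpack(best$par)
  list(c_a = p[1], c_b = p[2], k = p[3])
}

# core mu/sigma M-step
em_m_step_mu_sigma <- function(y, posteriors, mu_constraint, current_mu,
                               current_param, sigma2_floor = 1e-6) {
  obs <- !is.na(y) & !is.na(posteriors[, 1])
  p <- posteriors[obs, , drop = FALSE]
  yo <- y[obs]
  w <- colSums(p)
  if (mu_constraint == "free") {
    mu <- current_mu
    nz <- w > 1e-12
    mu[nz] <- colSums(p * yo)[nz] / w[nz]
    param <- NULL
  } else {
    target <- current_mu
    nz <- w > 1e-12
    target[nz] <- colSums(p * yo)[nz] / w[nz]
    param <- fit_mean_param(target, w, mu_constraint, current_param)
    mu <- mu_from_background(param$c_a, param$c_b, param$k)
  }
  resid2 <- (matrix(yo, nrow(p), 5) - matrix(mu, nrow(p), 5, byrow = TRUE))^2
  sigma2 <- max(sum(p * resid2) / sum(w), sigma2_floor)
  list(mu = mu, sigma2 = sigma2, mean_param = param)
}

#' M-step for component means and common variance
#'
#' Under the free variant each mean is the posterior-weighted average of
#' the observations (label order re-enforced by the EM driver).  Under the
#' constrained variants the background/curvature parameters are fitted by
#' bounded weighted least squares and the means derived via
#' [mu_from_background()].  The common variance is the posterior-weighted
#' mean squared residual, floored at `sigma2_floor`.
#'
#' @param signals A [marker_signals()].
#' @param posteriors Posterior matrix from [e_step()].
#' @param mu_constraint Mean-constraint variant name.
#' @param current Optional list(`c_a`,`c_b`,`k`) used as optimizer start.
#' @param current_mu Current means (fallback for empty components).
#' @param sigma2_floor Variance floor.
#' @return List with `mu`, `sigma2`, `mean_param`.
#' @export
m_step_mu_sigma <- function(signals, posteriors, mu_constraint = "free",
                            current = NULL,
                            current_mu = mu_from_background(),
                            sigma2_floor = 1e-6) {
  em_m_step_mu_sigma(signals$y, posteriors, mu_constraint, current_mu,
                     current, sigma2_floor)
}
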