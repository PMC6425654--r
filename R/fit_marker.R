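# Per-marker model grid, BIC selection, parental-prior arbitration, extreme-
# component re-evaluation, dosage calling and marker-level filtering.

#' Enumerate the constraint combinations tried for one marker
#'
#' The grid is the cartesian product of the five mean-constraint variants
#' with up to three mixing-proportion configurations, in this fixed order:
#' \enumerate{
#'   \item `all_free`: every population `p_free`;
#'   \item `structured`: HW panels `p_HW`, F1 families `p_F1`, parents
#'     `p_free` (skipped when identical to `all_free`);
#'   \item `parental_fixed`: as `structured` but parent populations with a
#'     dosage prior set to `p_fixed` (only when priors are present).
#' }
#' With priors present the grid therefore always contains both prior-using
#' and prior-free configurations, so an erroneous prior can be outvoted by
#' BIC.
#'
#' @param structure A [population_structure()].
#' @param priors_present Logical: are parental dosage priors available for
#'   this marker?
#' @return List of combos, each a list with `mu_constraint`,
#'   `pi_constraints` (named character), `uses_prior`, `label`.
#' @export
build_model_grid <- function(structure, priors_present = FALSE) {
  pops <- structure$populations
  base_free <- stats::setNames(rep("p_free", nrow(pops)), pops$population)
  structured <- stats::setNames(
    c(panel_free = "p_free", panel_HW = "p_HW", F1 = "p_F1",
      parent = "p_free")[pops$ptype],
    pops$population)
  configs <- list(list(pi = base_free, uses_prior = FALSE, name = "all_free"))
  if (!identical(unname(structured), unname(base_free))) {
    configs <- c(configs, list(list(pi = structured, uses_prior = FALSE,
                                    name = "structured")))
  }
  if (priors_present && any(pops$ptype == "parent")) {
    fixed <- structured
    fixed[pops$ptype == "parent"] <- "p_fixed"
    configs <- c(configs, list(list(pi = fixed, uses_prior = TRUE,
                                    name = "parental_fixed")))
  }
  grid <- list()
  for (mc in MU_CONSTRAINTS) {
    for (cf in configs) {
      grid[[length(grid) + 1L]] <- list(mu_constraint = mc,
                                        pi_constraints = cf$pi,
                                        uses_prior = cf$uses_prior,
                                        label = paste(mc, cf$name, sep = "/"))
    }
  }
  grid
}

#' Starting model seeded from parental dosage priors
#'
#' When the two parents of an F1 family have (distinct) known dosages and
#' observed replicate samples, their sample means of y pin two component
#' means; the remaining three follow the least-squares line through the two
#' (dosage, mean) points, clipped into (0, pi/2).  Equal parental dosages
#' pin a single mean on top of the default data-driven seeding.  Returns
#' `NULL` (caller falls back to default seeding) when no F1 family has two
#' priors or the parents lack observed samples.
#'
#' @param signals A [marker_signals()].
#' @param structure A [population_structure()].
#' @param fixed_dosages Named integer vector: parent population -> dosage.
#' @param mu_constraint Mean-constraint variant for the start.
#' @param pi_constraints Named character vector of constraints.
#' @param config A [run_config()].
#' @return A [mixture_model()] start, or `NULL`.
#' @export
starting_model_from_priors <- function(signals, structure, fixed_dosages,
                                       mu_constraint = "free",
                                       pi_constraints = NULL,
                                       config = run_config()) {
  pop <- pop_of(structure)[signals$sample_ids]
  f1s <- pops_of_type(structure, "F1")
  pinned <- NULL
  for (f1 in f1s) {
    parents <- f1_parents(structure, f1)
    if (!all(parents %in% names(fixed_dosages))) next
    means <- vapply(parents, function(pp) {
      yp <- signals$y[pop == pp & !is.na(signals$y)]
      if (length(yp)) mean(yp) else NA_real_
    }, numeric(1))
    if (anyNA(means)) next
    pinned <- list(dosage = unname(fixed_dosages[parents]),
                   mean = unname(means))
    break
  }
  if (is.null(pinned)) return(NULL)
  start <- default_start(signals$y, pop, as.list(pi_constraints),
                         fixed_dosages, "free", config$fixed_eps)
  mu <- start$mu
  if (pinned$dosage[1] != pinned$dosage[2]) {
    d <- pinned$dosage
    m <- pinned$mean
    slope <- (m[2] - m[1]) / (d[2] - d[1])
    if (slope <= 0) return(NULL)  # priors contradict the signal; use default
    mu <- m[1] + slope * ((0:4) - d[1])
  } else {
    mu[pinned$dosage[1] + 1] <- mean(pinned$mean)
  }
  mu <- pmin(pmax(mu, 0.02), pi / 2 - 0.02)
  for (j in 2:5) if (mu[j] <= mu[j - 1]) mu[j] <- mu[j - 1] + 0.02
  mean_param <- NULL
  if (mu_constraint != "free") {
    mean_param <- fit_mean_param(mu, rep(1, 5), mu_constraint)
    mu <- mu_from_background(mean_param$c_a, mean_param$c_b, mean_param$k)
  }
  mixture_model(mu, start$sigma2, start$pi, mu_constraint,
                unlist(pi_constraints), mean_param)
}

#' Select the best fitted model by BIC
#'
#' Minimum BIC among converged fits; ties broken by fewer parameters, then
#' by the fixed grid order.
#'
#' @param fits List of fit results as returned by [run_em()] (each with a
#'   `model` element); non-converged or failed entries are skipped.
#' @return The winning element of `fits`, or `NULL` when none converged.
#' @export
select_model <- function(fits) {
  ok <- which(vapply(fits, function(f) {
    !is.null(f) && !is.null(f$model) && isTRUE(f$model$converged)
  }, logical(1)))
  if (!length(ok)) return(NULL)
  bic <- vapply(fits[ok], function(f) f$model$bic, numeric(1))
  np <- vapply(fits[ok], function(f) f$model$n_params, numeric(1))
  fits[[ok[order(bic, np, seq_along(ok))[1]]]]
}

# population-size weighted overall mixing proportions
overall_proportions <- function(model, signals, structure) {
  pop <- pop_of(structure)[signals$sample_ids]
  pop <- pop[!is.na(signals$y)]
  n <- table(factor(pop, levels = names(model$pi)))
  w <- as.numeric(n) / sum(n)
  colSums(do.call(rbind, model$pi) * w)
}

#' Re-evaluate a model with a sparse extreme component
#'
#' A fitted extreme dosage class (0 or 4) holding less than
#' `extreme_trigger` (default 2.5%) of all samples while its neighbour
#' holds more than `adjacent_trigger` (default 15%) is an implausible
#' configuration for both F1 families and HW panels; the model is then
#' refitted with that component's mixing proportion forced to zero in every
#' population, and the refit kept only if it improves BIC.
#'
#' @param fit A fit result from [run_em()].
#' @param signals,structure,combo,fixed_dosages,config The fitting context
#'   (`combo` as produced by [build_model_grid()]).
#' @return A fit result (the original or the accepted refit, with
#'   `reevaluated` flag).
#' @export
reevaluate_extremes <- function(fit, signals, structure, combo,
                                fixed_dosages = NULL,
                                config = run_config()) {
  frac <- overall_proportions(fit$model, signals, structure)
  triggered <- c(
    if (frac[1] < config$extreme_trigger && frac[2] > config$adjacent_trigger) 0L,
    if (frac[5] < config$extreme_trigger && frac[4] > config$adjacent_trigger) 4L)
  best <- fit
  best$reevaluated <- FALSE
  for (d in triggered) {
    refit <- tryCatch(
      run_em(signals, structure, combo$mu_constraint, combo$pi_constraints,
             fixed_dosages = fixed_dosages, start = fit$model,
             config = config, exclude_component = d),
      error = function(e) NULL)
    if (!is.null(refit) && isTRUE(refit$model$converged) &&
        refit$model$bic < best$model$bic) {
      best <- refit
      best$reevaluated <- TRUE
    }
  }
  best
}

#' Call dosages and apply marker-level filters
#'
#' Per sample, the dosage with maximal posterior probability is called when
#' that posterior reaches `call_threshold`; otherwise the call is missing.
#' The marker is then filtered: status `rejected_too_many_na` when the
#' missing-call fraction exceeds `na_fraction_max` (default 25%), else
#' `rejected_single_category` when the largest called-dosage class exceeds
#' `peak_threshold` (default 90%) of the called samples, else `called`.
#'
#' @param model The selected [mixture_model()].
#' @param posteriors Posterior matrix for all samples.
#' @param config A [run_config()].
#' @return List with `calls` (named integer vector, `NA` where uncalled),
#'   `max_posterior` and `status`.
#' @export
call_dosages <- function(model, posteriors, config = run_config()) {
  n <- nrow(posteriors)
  calls <- rep(NA_integer_, n)
  maxp <- rep(NA_real_, n)
  obs <- !is.na(posteriors[, 1])
  maxp[obs] <- apply(posteriors[obs, , drop = FALSE], 1, max)
  best <- max.col(replace(posteriors, is.na(posteriors), -1), "first")
  callable <- obs & maxp >= config$call_threshold
  calls[callable] <- best[callable] - 1L
  names(calls) <- rownames(posteriors)
  names(maxp) <- rownames(posteriors)
  na_frac <- mean(is.na(calls))
  status <- if (na_frac > config$na_fraction_max) {
    "rejected_too_many_na"
  } else {
    tab <- tabulate(calls + 1L, 5L)
    if (max(tab) / sum(tab) > config$peak_threshold) {
      "rejected_single_category"
    } else "called"
  }
  list(calls = calls, max_posterior = maxp, status = status)
}

#' Fit, select and call a single marker
#'
#' Runs the full per-marker pipeline: enumerate the constraint grid
#' ([build_model_grid()]), fit every combination by EM (prior-seeded
#' starting values where available), select the converged fit with minimal
#' BIC, apply the extreme-component re-evaluation, and call dosages with
#' marker-level filtering.
#'
#' @param signals A [marker_signals()].
#' @param structure A [population_structure()].
#' @param priors Optional data.frame of parental dosage priors (columns
#'   `marker`, `population`, `dosage`) as read by [read_parental_priors()].
#' @param config A [run_config()].
#' @return Object of class `marker_result`: list with `marker_id`, `status`
#'   (`called`, `rejected_single_category`, `rejected_too_many_na`,
#'   `no_model`), `selected_model`, `calls`, `max_posterior`, `posteriors`,
#'   `models_tried` (data.frame), `used_parental_prior`, `reevaluated`.
#' @export
fit_marker <- function(signals, structure, priors = NULL,
                       config = run_config()) {
  no_model <- function(tried) {
    base::structure(
      list(marker_id = signals$marker_id, status = "no_model",
           selected_model = NULL,
           calls = stats::setNames(rep(NA_integer_,
                                       length(signals$sample_ids)),
                                   signals$sample_ids),
           max_posterior = NULL, posteriors = NULL,
           models_tried = tried, used_parental_prior = FALSE,
           reevaluated = FALSE),
      class = "marker_result")
  }
  tried0 <- data.frame(label = character(0), bic = numeric(0),
                       converged = logical(0), stringsAsFactors = FALSE)
  if (sum(!is.na(signals$y)) < config$min_samples) return(no_model(tried0))

  fixed_dosages <- NULL
  if (!is.null(priors) && nrow(priors)) {
    pr <- priors[priors$marker == signals$marker_id &
                   priors$population %in% pops_of_type(structure, "parent"), ,
                 drop = FALSE]
    if (nrow(pr)) fixed_dosages <- stats::setNames(pr$dosage, pr$population)
  }
  grid <- build_model_grid(structure, !is.null(fixed_dosages))
  fits <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    combo <- grid[[i]]
    start <- NULL
    if (combo$uses_prior) {
      start <- tryCatch(
        starting_model_from_priors(signals, structure, fixed_dosages,
                                   combo$mu_constraint, combo$pi_constraints,
                                   config),
        error = function(e) NULL)
    }
    fits[[i]] <- tryCatch(
      suppressWarnings(
        run_em(signals, structure, combo$mu_constraint, combo$pi_constraints,
               fixed_dosages = if (combo$uses_prior) fixed_dosages,
               start = start, config = config)),
      error = function(e) NULL)
    if (!is.null(fits[[i]])) fits[[i]]$combo <- combo
  }
  tried <- data.frame(
    label = vapply(grid, `[[`, character(1), "label"),
    bic = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$model$bic,
                 numeric(1)),
    converged = vapply(fits, function(f) !is.null(f) &&
                         isTRUE(f$model$converged), logical(1)),
    stringsAsFactors = FALSE)
  sel <- select_model(fits)
  if (is.null(sel)) return(no_model(tried))
  sel <- reevaluate_extremes(sel, signals, structure, sel$combo,
                             if (sel$combo$uses_prior) fixed_dosages,
                             config)
  cd <- call_dosages(sel$model, sel$posteriors, config)
  base::structure(
    list(marker_id = signals$marker_id, status = cd$status,
         selected_model = sel$model, calls = cd$calls,
         max_posterior = cd$max_posterior, posteriors = sel$posteriors,
         models_tried = tried, used_parental_prior = sel$combo$uses_prior,
         reevaluated = isTRUE(sel$reevaluated)),
    class = "marker_result")
}

#' @export
print.marker_result <- function(x, ...) {
  cat(sprintf("marker_result '%s': %s", x$marker_id, x$status))
  if (!is.null(x$selected_model)) {
    cat(sprintf(" (%s, BIC %.1f, %d/%d calls)",
                x$models_tried$label[which.min(x$models_tried$bic)],
                x$selected_model$bic, sum(!is.na(x$calls)), length(x$calls)))
  }
  cat("\n")
  invisible(x)
}
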