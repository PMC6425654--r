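make_model <- function(mu = asin(sqrt((0:4) / 4)), sigma2 = 0.0016,
                       pi = list(PANEL = rep(0.2, 5)),
                       constraint = c(PANEL = "p_free")) {
  mixture_model(mu, sigma2, pi, "free", constraint)
}

test_that("mixture density matches brute-force evaluation and integrates
           to 1", {
  model <- make_model(pi = list(PANEL = c(0.1, 0.3, 0.2, 0.25, 0.15)))
  y <- seq(-0.2, 1.8, by = 0.05)
  expect_equal(mixture_density(y, model, "PANEL"),
               oracle_mixture_density(y, model$mu, model$sigma2,
                                      model$pi$PANEL))
  # single effective component: density at its mean is the normal mode
  m1 <- make_model(pi = list(PANEL = c(0, 0, 1, 0, 0)))
  expect_equal(mixture_density(m1$mu[3], m1, "PANEL"),
               1 / sqrt(2 * pi * m1$sigma2))
  q <- stats::integrate(mixture_density, -1, 3, model = model,
                        population_id = "PANEL")
  expect_equal(q$value, 1, tolerance = 1e-6)
  expect_error(mixture_density(0.5, model, "NOPE"), "unknown population")
})

test_that("e_step reproduces the posterior formula, rows sum to 1, missing
           rows stay missing", {
  set.seed(11)
  y <- c(runif(40, 0, pi / 2), NA, NA)
  ids <- sprintf("s%02d", seq_along(y))
  sig <- marker_signals("m", ids, ratio = c(sin(y[1:40])^2, NA, NA))
  struct <- panel_structure(ids)
  model <- make_model(pi = list(PANEL = c(0.1, 0.3, 0.2, 0.25, 0.15)),
                      constraint = c(PANEL = "p_HW"))
  post <- e_step(sig, struct, model)
  expect_equal(rowSums(post[1:40, ]), rep(1, 40), ignore_attr = TRUE)
  expect_true(all(is.na(post[41:42, ])))
  expect_equal(unname(post[1:40, ]),
               oracle_posteriors(sig$y, model$mu, model$sigma2,
                                 model$pi$PANEL)[1:40, ])
  # a point at a well-separated component mean is assigned to it
  m2 <- make_model(sigma2 = 1e-4)
  sig2 <- marker_signals("m", "s1", ratio = sin(m2$mu[3])^2)
  p2 <- e_step(sig2, panel_structure("s1"), m2)
  expect_gt(p2[1, 3], 0.999)
  sigNA <- marker_signals("m", c("a", "b"), ratio = c(NA, NA))
  expect_error(e_step(sigNA, panel_structure(c("a", "b")), m2),
               "no observations")
})

test_that("pi M-step honours each constraint type", {
  ids <- sprintf("s%02d", 1:30)
  pop <- c(rep("F1FAM", 10), rep("P1", 5), rep("P2", 5), rep("PAN", 10))
  struct <- population_structure(
    data.frame(sample = ids, population = pop),
    data.frame(population = c("F1FAM", "P1", "P2", "PAN"),
               ptype = c("F1", "parent", "parent", "panel_HW"),
               link1 = c("P1", "F1FAM", "F1FAM", NA),
               link2 = c("P2", NA, NA, NA)))
  # offspring ratios consistent with a 2x4 cross (mostly triplex), so the
  # plug-in segregation row passes the likelihood guard
  sig <- marker_signals("m", ids,
                        ratio = c(rep(0.75, 10), rep(0.5, 5), rep(1, 5),
                                  rep(0.5, 10)))
  # posteriors: parents certain at dosage 2 and 4; panel mean dosage 2
  post <- matrix(0, 30, 5, dimnames = list(ids, 0:4))
  post[1:10, ] <- 0.2
  post[11:15, 3] <- 1
  post[16:20, 5] <- 1
  post[21:30, ] <- matrix(c(1, 4, 6, 4, 1) / 16, 10, 5, byrow = TRUE)
  model <- mixture_model(asin(sqrt((0:4) / 4)), 0.001,
                         pi = list(F1FAM = rep(0.2, 5), P1 = rep(0.2, 5),
                                   P2 = rep(0.2, 5), PAN = rep(0.2, 5)),
                         pi_constraint = c(F1FAM = "p_F1", P1 = "p_free",
                                           P2 = "p_free", PAN = "p_HW"))
  new_pi <- m_step_pi(post, sig, struct, model)
  # parents modal (2, 4) -> published pattern 0:0:1:4:1
  expect_equal(unname(new_pi$F1FAM), c(0, 0, 1, 4, 1) / 6)
  expect_equal(unname(new_pi$P1), c(0, 0, 1, 0, 0))
  # HW panel: posterior mean dosage 2 -> p = 0.5
  expect_equal(unname(new_pi$PAN), c(1, 4, 6, 4, 1) / 16)
  for (p in new_pi) expect_equal(sum(p), 1)

  # p_free with all mass in class 0
  post0 <- post
  post0[21:30, ] <- 0
  post0[21:30, 1] <- 1
  model$pi_constraint[["PAN"]] <- "p_free"
  expect_equal(unname(m_step_pi(post0, sig, struct, model)$PAN),
               c(1, 0, 0, 0, 0))
})

test_that("mu/sigma M-step: free means are weighted group means; zero
           background recovers the ideal spacing", {
  y <- c(0.2, 0.5, 0.8, 1.1, 1.4)
  sig <- marker_signals("m", paste0("s", 1:5), ratio = sin(y)^2)
  post <- diag(5)
  upd <- m_step_mu_sigma(sig, post, "free")
  expect_equal(upd$mu, y, tolerance = 1e-12)
  expect_equal(mu_from_background(0, 0, 0), asin(sqrt((0:4) / 4)))
  # implied means strictly increasing for random nonneg parameters
  set.seed(3)
  for (i in 1:25) {
    mu <- mu_from_background(runif(1, 0, 5), runif(1, 0, 5), runif(1, 0, 2))
    expect_true(all(diff(mu) > 0))
  }
})

test_that("constrained mean fit recovers known background parameters", {
  truth <- list(c_a = 0.4, c_b = 0.15, k = 0.3)
  spec <- sim_spec(populations = list(list(id = "PANEL",
                                           ptype = "panel_free", n = 500)),
                   mean_param = truth, sigma = 0.02, na_rate = 0, seed = 5)
  sim <- simulate_marker(spec, "m", 5)
  fit <- run_em(sim$signals, sim$structure,
                mu_constraint = "background_unequal_quadratic")
  expect_true(fit$model$converged)
  expect_equal(fit$model$mean_param$c_a, truth$c_a, tolerance = 0.1)
  expect_equal(fit$model$mean_param$c_b, truth$c_b, tolerance = 0.1)
  expect_equal(fit$model$mean_param$k, truth$k, tolerance = 0.15)
  expect_equal(fit$model$mu,
               mu_from_background(truth$c_a, truth$c_b, truth$k),
               tolerance = 0.02)
})

test_that("run_em recovers well-separated components and reports a
           consistent BIC", {
  spec <- sim_spec(populations = list(list(id = "PANEL",
                                           ptype = "panel_free", n = 500)),
                   sigma = 0.03, na_rate = 0, seed = 9)
  sim <- simulate_marker(spec, "m", 9)
  fit <- run_em(sim$signals, sim$structure)
  expect_true(fit$model$converged)
  expect_equal(fit$model$mu, spec$mu_truth, tolerance = 0.02)
  calls <- apply(fit$posteriors, 1, which.max) - 1
  expect_gte(mean(calls == sim$truth), 0.99)
  expect_equal(fit$model$n_params, 1L + 5L + 4L)
  expect_equal(fit$model$bic,
               -2 * fit$model$loglik + fit$model$n_params * log(500))
  # posterior rows sum to 1
  expect_equal(unname(rowSums(fit$posteriors)), rep(1, 500))
})

test_that("one-component degenerate data converges with one dominant
           proportion", {
  set.seed(21)
  ids <- sprintf("s%03d", 1:80)
  sig <- marker_signals("m", ids,
                        ratio = pmin(pmax(rnorm(80, 0.5, 0.02), 0), 1))
  fit <- run_em(sig, panel_structure(ids, ptype = "panel_free"))
  expect_true(fit$model$converged)
  expect_gt(max(fit$model$pi$PANEL), 0.95)
})

test_that("EM log-likelihood is monotone for every constraint combination
           (property over random fixtures)", {
  worst <- Inf
  for (i in 1:6) {
    spec <- make_test_layout(n_markers = 1, n_f1 = 80, n_parent1 = 6,
                             n_parent2 = 6, n_panel = 40, sigma = 0.06,
                             na_rate = 0.02, seed = 100 + i)
    sim <- simulate_marker(spec, "m", 100 + i)
    fx <- sim$parental_dosages
    for (combo in build_model_grid(sim$structure, TRUE)) {
      fit <- tryCatch(
        suppressWarnings(run_em(sim$signals, sim$structure,
                                combo$mu_constraint, combo$pi_constraints,
                                fixed_dosages = fx)),
        error = function(e) NULL)
      if (is.null(fit)) next
      worst <- min(worst, min(diff(fit$model$loglik_trace)))
      for (p in fit$model$pi) expect_equal(sum(p), 1, tolerance = 1e-9)
      # p_F1 proportions always equal a tetrasomic segregation row
      for (pid in names(combo$pi_constraints)) {
        if (combo$pi_constraints[[pid]] == "p_F1") {
          match_any <- any(vapply(REFERENCE_SEGREGATION, function(r) {
            isTRUE(all.equal(unname(fit$model$pi[[pid]]), r / sum(r)))
          }, logical(1)))
          expect_true(match_any)
        }
      }
    }
  }
  expect_gte(worst, -1e-8)
})

test_that("single-population p_free fit agrees with the textbook oracle", {
  spec <- sim_spec(populations = list(list(id = "PANEL",
                                           ptype = "panel_free", n = 200)),
                   sigma = 0.04, na_rate = 0, seed = 31)
  sim <- simulate_marker(spec, "m", 31)
  start <- tetradose:::default_start(sim$signals$y, rep("PANEL", 200),
                                     list(PANEL = "p_free"))
  cfg <- run_config(em_tol = 1e-9, em_max_iter = 1000)
  fit <- run_em(sim$signals, sim$structure, start = start, config = cfg)
  ora <- oracle_gmm_em(sim$signals$y, start$mu, start$sigma2,
                       start$pi$PANEL, tol = 1e-9)
  expect_equal(fit$model$loglik, ora$loglik, tolerance = 1e-6)
  expect_equal(fit$model$mu, ora$mu, tolerance = 1e-4)
})
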