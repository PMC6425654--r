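test_that("model grid composition follows the declared configurations", {
  samples <- sprintf("s%02d", 1:10)
  panel <- panel_structure(samples)
  grid <- build_model_grid(panel, priors_present = FALSE)
  expect_length(grid, 10)  # 5 mean variants x {all_free, structured}
  expect_true(all(vapply(grid, function(g) !g$uses_prior, logical(1))))

  free_panel <- panel_structure(samples, ptype = "panel_free")
  expect_length(build_model_grid(free_panel, FALSE), 5)

  spec <- make_test_layout(n_f1 = 10, n_parent1 = 2, n_parent2 = 2,
                           n_panel = 5)
  fam <- tetradose:::structure_from_spec(spec)
  grid <- build_model_grid(fam, priors_present = TRUE)
  expect_length(grid, 15)
  uses <- vapply(grid, `[[`, logical(1), "uses_prior")
  expect_equal(sum(uses), 5)
  # prior-using configs fix the parents, prior-free ones leave them free
  fixed <- grid[[which(uses)[1]]]$pi_constraints
  expect_equal(unname(fixed[c("P1", "P2")]), c("p_fixed", "p_fixed"))
  expect_equal(unname(fixed["F1FAM"]), "p_F1")
  free <- grid[[which(!uses)[1]]]$pi_constraints
  expect_true(all(free == "p_free"))
})

test_that("prior-seeded starting means follow the two-point regression", {
  # two parents with known dosages 0 and 4 and tight replicate clusters
  ids <- c(sprintf("p1_%d", 1:6), sprintf("p2_%d", 1:6),
           sprintf("o%02d", 1:30))
  pop <- c(rep("P1", 6), rep("P2", 6), rep("F1FAM", 30))
  struct <- population_structure(
    data.frame(sample = ids, population = pop),
    data.frame(population = c("F1FAM", "P1", "P2"),
               ptype = c("F1", "parent", "parent"),
               link1 = c("P1", "F1FAM", "F1FAM"),
               link2 = c("P2", NA, NA)))
  y <- c(rep(0.1, 6), rep(1.45, 6), runif(30, 0, pi / 2))
  sig <- marker_signals("m", ids, ratio = sin(y)^2)
  start <- starting_model_from_priors(
    sig, struct, c(P1 = 0L, P2 = 4L), "free",
    c(F1FAM = "p_F1", P1 = "p_fixed", P2 = "p_fixed"))
  expect_equal(start$mu, c(0.1, 0.4375, 0.775, 1.1125, 1.45))
  # pinned p_fixed proportions are spiked at the prior dosage
  expect_equal(unname(which.max(start$pi$P1)) - 1L, 0L)
  expect_equal(unname(which.max(start$pi$P2)) - 1L, 4L)

  # equal priors: default seeding with the shared mean pinned
  start2 <- starting_model_from_priors(
    sig, struct, c(P1 = 2L, P2 = 2L), "free",
    c(F1FAM = "p_F1", P1 = "p_fixed", P2 = "p_fixed"))
  expect_equal(start2$mu[3], mean(c(0.1, 1.45)))
  expect_true(all(diff(start2$mu) > 0))
})

test_that("BIC selection prefers converged fits, fewer parameters on ties,
           and grid order last", {
  mk <- function(bic, np, conv = TRUE) {
    list(model = list(bic = bic, n_params = np, converged = conv))
  }
  fits <- list(mk(100, 10), mk(90, 7), mk(80, 12, conv = FALSE))
  expect_equal(select_model(fits)$model$bic, 90)
  fits <- list(mk(90, 10), mk(90, 7))
  expect_equal(select_model(fits)$model$n_params, 7)
  fits <- list(mk(90, 7), mk(90, 7))
  expect_identical(select_model(fits), fits[[1]])
  expect_null(select_model(list(mk(1, 1, FALSE))))
})

test_that("extreme-component re-evaluation triggers on the published
           thresholds and keeps the better model", {
  # trigger logic via the overall proportions helper
  samples <- sprintf("s%03d", 1:100)
  struct <- panel_structure(samples, ptype = "panel_free")
  sig <- marker_signals("m", samples, ratio = rep(0.5, 100))
  mk_model <- function(p) {
    mixture_model(asin(sqrt((0:4) / 4)), 0.001, list(PANEL = p),
                  "free", c(PANEL = "p_free"))
  }
  frac <- function(p) {
    tetradose:::overall_proportions(mk_model(p), sig, struct)
  }
  cfg <- run_config()
  trig <- function(p) {
    f <- frac(p)
    c(f[1] < cfg$extreme_trigger && f[2] > cfg$adjacent_trigger,
      f[5] < cfg$extreme_trigger && f[4] > cfg$adjacent_trigger)
  }
  expect_equal(trig(c(0.01, 0.20, 0.40, 0.30, 0.09)), c(TRUE, FALSE))
  expect_equal(trig(c(0.10, 0.20, 0.40, 0.20, 0.10)), c(FALSE, FALSE))
  expect_equal(trig(c(0.01, 0.05, 0.45, 0.40, 0.09)), c(FALSE, FALSE))

  # a 4-cluster marker (no nulliplex) whose 5-component fit wrongly leaks
  # mass into dosage 0 is repaired by the refit
  set.seed(77)
  truth <- sample(1:4, 400, replace = TRUE, prob = c(0.25, 0.3, 0.3, 0.15))
  mu <- asin(sqrt((0:4) / 4))
  y <- pmin(pmax(mu[truth + 1] + rnorm(400, 0, 0.05), 0), pi / 2)
  ids <- sprintf("s%03d", 1:400)
  sig4 <- marker_signals("m4", ids, ratio = sin(y)^2)
  struct4 <- panel_structure(ids, ptype = "panel_free")
  combo <- list(mu_constraint = "free",
                pi_constraints = c(PANEL = "p_free"), uses_prior = FALSE)
  fit <- run_em(sig4, struct4)
  refit <- reevaluate_extremes(fit, sig4, struct4, combo)
  expect_lte(refit$model$bic, fit$model$bic)
  if (refit$reevaluated) expect_equal(unname(refit$model$pi$PANEL[1]), 0)
})

test_that("dosage calling applies the posterior threshold and the two
           marker-level filters", {
  post <- rbind(c(0.01, 0.02, 0.95, 0.01, 0.01),
                c(0.10, 0.30, 0.60, 0.00, 0.00),
                c(NA, NA, NA, NA, NA))
  rownames(post) <- c("a", "b", "c")
  model <- mixture_model(asin(sqrt((0:4) / 4)), 0.001,
                         list(P = rep(0.2, 5)), "free", c(P = "p_free"))
  cd <- call_dosages(model, post, run_config(na_fraction_max = 0.9))
  expect_equal(unname(cd$calls), c(2L, NA, NA))  # 0.6 < 0.75 stays uncalled
  expect_equal(unname(cd$max_posterior), c(0.95, 0.6, NA))

  # 95 of 100 calls in one class -> single-category rejection
  post2 <- matrix(0, 100, 5, dimnames = list(sprintf("s%d", 1:100), NULL))
  post2[1:95, 1] <- 1
  post2[96:100, 3] <- 1
  expect_equal(call_dosages(model, post2)$status, "rejected_single_category")
  # exactly 90% is not "more than 90%"
  post3 <- post2
  post3[91:100, 3] <- 1
  post3[91:100, 1] <- 0
  expect_equal(call_dosages(model, post3)$status, "called")
  # missing-call fraction above 25% -> NA rejection
  post4 <- post2
  post4[1:30, ] <- NA
  expect_equal(call_dosages(model, post4)$status, "rejected_too_many_na")
})

test_that("fit_marker is deterministic and handles degenerate input", {
  spec <- make_test_layout(n_markers = 1, n_f1 = 60, n_parent1 = 5,
                           n_parent2 = 5, n_panel = 30, seed = 55,
                           parental_dosages = c(1, 3))
  sim <- simulate_marker(spec, "m", 55)
  priors <- data.frame(marker = "m", population = c("P1", "P2"),
                       dosage = c(1L, 3L))
  r1 <- fit_marker(sim$signals, sim$structure, priors)
  r2 <- fit_marker(sim$signals, sim$structure, priors)
  expect_identical(r1$calls, r2$calls)
  expect_identical(r1$models_tried, r2$models_tried)
  expect_s3_class(r1, "marker_result")
  expect_true(r1$status %in% c("called", "rejected_single_category",
                               "rejected_too_many_na", "no_model"))
  if (r1$status == "called") expect_false(is.null(r1$selected_model))

  # too few observations -> no_model
  tiny <- marker_signals("t", c("a", "b"), ratio = c(0.1, 0.9))
  rt <- fit_marker(tiny, panel_structure(c("a", "b")))
  expect_equal(rt$status, "no_model")
  expect_null(rt$selected_model)
})

test_that("on true F1 markers the segregation-constrained model usually
           wins the BIC comparison (power check)", {
  wins <- 0L
  n_rep <- 20L
  for (i in seq_len(n_rep)) {
    spec <- make_test_layout(n_markers = 1, n_f1 = 300, n_parent1 = 5,
                             n_parent2 = 5, n_panel = 0, sigma = 0.04,
                             na_rate = 0, seed = 500 + i,
                             parental_dosages = c(2, 2))
    sim <- simulate_marker(spec, "m", 500 + i)
    f1 <- run_em(sim$signals, sim$structure, "free",
                 c(F1FAM = "p_F1", P1 = "p_free", P2 = "p_free"))
    fr <- run_em(sim$signals, sim$structure, "free",
                 c(F1FAM = "p_free", P1 = "p_free", P2 = "p_free"))
    if (f1$model$bic < fr$model$bic) wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.8)
})
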