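# Likelihood, optimisation, ensemble MCMC and credible bands.

make_toy_problem <- function(dr_scale = 1, noiseless = TRUE, seed = 44,
                             free = list(apm = c(50, 70),
                                         pqic_thickness = c(30, 70)),
                             fit_scale = FALSE, fit_background = FALSE) {
  sc <- builtin_scenarios()$bilayer_pqic
  sc$seed <- seed
  sc$n_points <- 40
  sim <- simulate_experiment(sc, noiseless = noiseless)
  if (dr_scale != 1) {
    sim <- lapply(sim, function(d) {
      d$curve$dr <- d$curve$dr * dr_scale
      d
    })
  }
  fit_problem("pqic", sc$truth, free = free, datasets = sim,
              fit_scale = fit_scale, fit_background = fit_background)
}

test_that("likelihood matches a hand-rolled loop on a tiny dataset", {
  p <- pqic_model_params()
  q <- c(0.02, 0.05, 0.1)
  solv <- solvent(1)
  st <- build_pqic_stack(p, solv)
  r_model <- reflectivity(st, q)
  r_data <- r_model * c(1.05, 0.9, 1.2)
  dr <- r_model * 0.1
  curve <- reflectivity_curve(q, r_data, dr = dr, dq_over_q = 0)
  prob <- fit_problem("pqic", p, free = list(apm = c(50, 70)),
                      datasets = list(list(curve = curve, solvent = solv)),
                      fit_scale = FALSE, fit_background = FALSE)
  th <- c(apm = p$apm)
  manual <- 0
  for (i in seq_along(q)) {
    manual <- manual + 0.5 * ((r_model[i] - r_data[i]) / dr[i])^2
  }
  expect_equal(neg_log_likelihood(prob, th), manual, tolerance = 1e-12)
  # doubling every dr quarters the data term
  curve2 <- curve; curve2$dr <- 2 * dr
  prob2 <- fit_problem("pqic", p, free = list(apm = c(50, 70)),
                       datasets = list(list(curve = curve2, solvent = solv)),
                       fit_scale = FALSE, fit_background = FALSE)
  expect_equal(neg_log_likelihood(prob2, th), manual / 4, tolerance = 1e-12)
})

test_that("noiseless data yield a likelihood minimum at the truth", {
  prob <- make_toy_problem(noiseless = TRUE)
  truth <- c(apm = 60, pqic_thickness = 50)
  nll_truth <- neg_log_likelihood(prob, truth)
  expect_lt(nll_truth, 1e-10)
  set.seed(9)
  for (i in 1:100) {
    perturbed <- truth + runif(2, -1, 1) * c(5, 10)
    perturbed <- pmin(pmax(perturbed, prob$lower), prob$upper)
    if (max(abs(perturbed - truth)) < 1e-6) next
    expect_gt(neg_log_likelihood(prob, perturbed), nll_truth)
  }
})

test_that("out-of-bounds parameters return +Inf, and order does not matter", {
  prob <- make_toy_problem()
  expect_identical(neg_log_likelihood(prob, c(apm = 45, pqic_thickness = 50)),
                   Inf)
  # dataset ordering leaves the likelihood unchanged
  prob_rev <- fit_problem("pqic", prob$params, free = prob$free,
                          datasets = rev(prob$datasets),
                          fit_scale = FALSE, fit_background = FALSE)
  th <- c(apm = 58, pqic_thickness = 55)
  expect_equal(neg_log_likelihood(prob, th),
               neg_log_likelihood(prob_rev, th))
})

test_that("refitting from the optimum returns the optimum", {
  prob <- make_toy_problem(noiseless = FALSE)
  fv1 <- fit(prob)
  # restarting exactly at a converged point can abort the line search;
  # the contract is only that the optimum does not move
  fv2 <- suppressWarnings(fit(prob, start = fv1$par))
  expect_equal(fv2$par, fv1$par, tolerance = 1e-5)
  expect_lte(fv2$value, fv1$value + 1e-8)
})

test_that("fitting a bare substrate with a bilayer model empties the bilayer", {
  sc <- builtin_scenarios()$bare_substrate
  sc$n_points <- 40
  sim <- simulate_experiment(sc)
  start <- pqic_model_params(sio2_thickness = 12, sio2_hydration = 0.08,
                             bilayer_coverage = 0.5,
                             pqic_volume_fraction = 0, pqic_thickness = 0)
  prob <- fit_problem("pqic", start,
                      free = list(bilayer_coverage = c(0, 1)),
                      datasets = sim,
                      fit_scale = FALSE, fit_background = FALSE)
  fv <- fit(prob)
  expect_lt(fv$par[["bilayer_coverage"]], 0.05)
})

test_that("posterior sampling is seed-deterministic and prior-recovering", {
  # flat likelihood: infinite error bars carry no information, so the
  # posterior reproduces the flat prior within Monte-Carlo error
  prob <- make_toy_problem(dr_scale = Inf)
  post <- suppressWarnings(
    sample_posterior(prob, n_walkers = 10, n_steps = 600, burn_in = 200,
                     seed = 3)
  )
  draws <- post$draws[, "apm"]
  expect_true(all(draws >= 50 & draws <= 70))
  expect_equal(mean(draws), 60, tolerance = 0.03)          # uniform mean
  expect_equal(stats::sd(draws), 20 / sqrt(12), tolerance = 0.12)
  # identical seed, identical draws
  post2 <- suppressWarnings(
    sample_posterior(prob, n_walkers = 10, n_steps = 600, burn_in = 200,
                     seed = 3)
  )
  expect_identical(post$draws, post2$draws)
  expect_true(post$metadata$acceptance_fraction > 0)
})

test_that("posterior concentrates near the truth on noisy synthetic data", {
  prob <- make_toy_problem(noiseless = FALSE, seed = 77)
  fv <- fit(prob)
  post <- suppressWarnings(
    sample_posterior(prob, start = fv$par, n_walkers = 12, n_steps = 500,
                     burn_in = 200, seed = 10)
  )
  m <- colMeans(post$draws)
  s <- apply(post$draws, 2, stats::sd)
  expect_lt(abs(m[["apm"]] - 60), 3 * s[["apm"]] + 0.5)
  expect_lt(abs(m[["pqic_thickness"]] - 50), 3 * s[["pqic_thickness"]] + 0.5)
  # the reflectivity band brackets the best-fit curve pointwise
  band <- credible_band(post, function(th) {
    model_curves(prob, th)[[1]]
  }, max_draws = 300)
  best <- model_curves(prob, fv$par)[[1]]
  inside <- mean(best >= band$lower - 1e-12 & best <= band$upper + 1e-12)
  expect_gt(inside, 0.9)
})

test_that("credible bands have the right width and degenerate correctly", {
  set.seed(21)
  draws <- cbind(x = rnorm(20000, mean = 5, sd = 2))
  fake <- structure(list(draws = draws, log_prob = rep(0, nrow(draws)),
                         metadata = list()),
                    class = "posterior_samples")
  b <- credible_band(fake, "x", max_draws = nrow(draws))
  # central 65% of a normal: mean +/- 0.935 sigma
  z <- qnorm(0.825)
  expect_equal(b$lower, 5 - z * 2, tolerance = 0.03)
  expect_equal(b$upper, 5 + z * 2, tolerance = 0.03)
  expect_equal(z, 0.935, tolerance = 0.001)
  # constant functional: zero width
  b0 <- credible_band(fake, function(th) 7)
  expect_equal(b0$lower, b0$upper)
  expect_error(credible_band(fake, "x", level = 1.2), "level")
})

test_that("joint multi-contrast fitting beats single-contrast fitting", {
  # recovery spread of the protein-layer thickness over refits from
  # perturbed starts: sharing geometry across contrasts constrains the fit
  sc <- builtin_scenarios()$bilayer_pqic
  sc$n_points <- 40
  recover <- function(datasets, start_thick) {
    start <- sc$truth
    start$pqic_thickness <- start_thick
    prob <- fit_problem("pqic", start,
                        free = list(pqic_thickness = c(30, 70),
                                    pqic_volume_fraction = c(0.05, 0.5),
                                    head_hydration = c(0, 0.7)),
                        datasets = datasets,
                        fit_scale = FALSE, fit_background = FALSE)
    fit(prob)$par[["pqic_thickness"]]
  }
  sim <- simulate_experiment(sc)
  starts <- c(38, 45, 62)
  err_joint <- abs(vapply(starts, function(s0) recover(sim, s0),
                          numeric(1)) - 50)
  err_single <- abs(vapply(starts, function(s0) {
    recover(sim[2], s0)    # 80% D2O contrast alone
  }, numeric(1)) - 50)
  expect_lt(mean(err_joint), mean(err_single) + 1e-8)
  expect_lt(max(err_joint), 2)
})
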