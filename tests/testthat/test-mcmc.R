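small_sim <- function(seed = 7) simulate_atlas(tiny_scenario(seed = seed))

test_that("initialization forces detected latents and overdisperses parameters", {
  sim <- small_sim(3)
  cl <- sim$data$checklists
  det <- cl[cl$detected == 1L, ]
  for (seed in c(1, 2)) {
    st <- initialize_state(sim$data, c(5, 5), seed = seed)
    for (r in seq_len(nrow(det))) {
      expect_equal(st$latent$X[det$cell[r], det$season[r]], 1L)
      expect_equal(st$latent$Z[det$cell[r], det$season[r], det$year[r]], 1L)
    }
    # hierarchy holds at the start
    for (s in 1:2) for (t in 1:2)
      expect_true(all(st$latent$Z[, s, t] <= st$latent$X[, s]))
  }
  s1 <- initialize_state(sim$data, c(5, 5), seed = 1)
  s1b <- initialize_state(sim$data, c(5, 5), seed = 1)
  s2 <- initialize_state(sim$data, c(5, 5), seed = 2)
  expect_identical(s1$params$a0, s1b$params$a0)
  expect_false(identical(s1$params$a0, s2$params$a0))
})

test_that("chains are reproducible and thinning halves the retained draws", {
  sim <- small_sim(5)
  cfg <- mcmc_config(n_chains = 2, n_burnin = 100, n_iter = 100, seed = 9)
  f1 <- fit_atlas(sim$data, cfg)
  f2 <- fit_atlas(sim$data, cfg)
  expect_identical(f1$scalars, f2$scalars)
  expect_identical(f1$X_marginal, f2$X_marginal)

  cfg2 <- mcmc_config(n_chains = 1, n_burnin = 100, n_iter = 100, thin = 2,
                      seed = 9)
  f3 <- fit_atlas(sim$data, cfg2)
  expect_equal(nrow(f3$scalars[[1]]), 50)
})

test_that("posterior objects satisfy their structural invariants", {
  sim <- small_sim(5)
  fit <- fit_atlas(sim$data, mcmc_config(n_chains = 2, n_burnin = 200,
                                         n_iter = 200, seed = 4))
  # SDs remain strictly positive after sweeps
  for (p in fit$final_params) {
    expect_true(all(c(p$tau_b, p$sigma_eps, p$sigma_phi, p$sigma_gamma,
                      p$sigma_omega, p$tau_det, p$spline$sigma_u) > 0))
    # CAR fields are re-centered
    expect_lt(abs(mean(p$b)), 1e-8)
    expect_lt(abs(mean(p$b_det1)), 1e-8)
  }
  # latent marginals live in [0,1]; forced ones are exactly 1
  expect_true(all(fit$X_marginal >= 0 & fit$X_marginal <= 1))
  cl <- sim$data$checklists
  det <- cl[cl$detected == 1L, ]
  for (r in seq_len(nrow(det)))
    expect_equal(fit$X_marginal[det$cell[r], det$season[r]], 1)
  # interval ordering per cell; the mean lies inside the interval for the
  # continuous occupancy-level quantities (zero-inflated use probabilities
  # can legitimately concentrate >97.5% of their mass at zero)
  cs <- fit$cell_summary
  expect_true(all(cs$q2.5 <= cs$q97.5 + 1e-9))
  cont <- cs[cs$quantity %in% c("occ1", "persistence", "colonization"), ]
  expect_true(all(cont$q2.5 <= cont$mean + 1e-9))
  expect_true(all(cont$mean <= cont$q97.5 + 1e-9))
  # posterior summary covers every tracked scalar with finite mean
  expect_true(all(is.finite(fit$summary$mean)))
})

test_that("latent blocked-Gibbs marginals match exact enumeration on a tiny instance", {
  inst <- two_cell_instance(n_lists = c(2, 1))
  exact <- enumerate_latent_posterior(inst$data, inst$params)
  fit <- fit_atlas(inst$data,
                   mcmc_config(n_chains = 1, n_burnin = 500,
                               n_iter = 20000, seed = 2,
                               update_blocks = character(0),
                               store_derived = FALSE, store_latent = TRUE),
                   n_observers = c(1, 1),
                   init_params = inst$params)
  ld <- fit$latent_draws[[1]]
  # layout: X (2 cells x 2 seasons), then Z slots
  for (i in 1:2) {
    xm <- mean(ld[, i])
    se <- batch_se(ld[, i])
    expect_lt(abs(xm - exact$X[i, 1]), 3 * se + 1e-3)
    zm <- mean(ld[, 4 + i])
    se_z <- batch_se(ld[, 4 + i])
    expect_lt(abs(zm - exact$Z[i, 1, 1]), 3 * se_z + 1e-3)
  }
})

test_that("split-Rhat and ESS behave on known chains", {
  set.seed(1)
  same <- list(matrix(rnorm(4000), 2000, 2), matrix(rnorm(4000), 2000, 2))
  r <- rhat(same)
  expect_true(all(abs(r - 1) < 0.02))
  e <- ess(same)
  expect_true(all(e > 1500))
  shifted <- list(matrix(rnorm(2000), ncol = 1),
                  matrix(rnorm(2000, mean = 3), ncol = 1))
  expect_gt(rhat(shifted)[1], 1.5)
  # strongly autocorrelated chain has a small ESS
  x <- as.numeric(stats::arima.sim(list(ar = 0.99), 2000))
  expect_lt(ess(list(matrix(x, ncol = 1)))[1], 300)
  # constant (never-updated) parameters give NA, not spurious values
  expect_true(is.na(rhat(list(matrix(1, 100, 1), matrix(1, 100, 1)))[1]))
})

test_that("a non-finite starting state aborts with the offending term named", {
  inst <- two_cell_instance(n_lists = c(1, 0))
  inst$data$checklists$detected <- 1L
  bad_latent <- latent_state(matrix(0L, 2, 2), array(0L, dim = c(2, 2, 1)))
  expect_error(
    fit_atlas(inst$data,
              mcmc_config(n_chains = 1, n_burnin = 10, n_iter = 10,
                          seed = 1, update_blocks = character(0)),
              n_observers = c(1, 1), init_params = inst$params,
              init_latent = bad_latent),
    "non-finite log posterior.*observation")
})
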