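make_small <- function(seed = 7) simulate_atlas(tiny_scenario(seed = seed))

test_that("first-period occupancy probability follows the logit predictor", {
  lat <- build_lattice(2, 2)
  hab <- matrix(0.125, 4, 8)
  sp <- spline_spec(hab, knots = matrix(c(0.05, 0.3), 8, 2, byrow = TRUE))
  p0 <- atlas_params(lat, sp, n_observers = c(1, 1))
  expect_equal(occupancy1_prob(1, p0, hab, lat), 0.5)
  p2 <- atlas_params(lat, sp, n_observers = c(1, 1), a0 = 2)
  expect_equal(occupancy1_prob(1, p2, hab, lat), invlogit(2),
               tolerance = 1e-12)
  expect_equal(round(occupancy1_prob(1, p2, hab, lat), 4), 0.8808)
  pb <- p0
  pb$b[1] <- 1
  expect_gt(occupancy1_prob(1, pb, hab, lat), occupancy1_prob(1, p0, hab, lat))
})

test_that("neighborhood occupancy is the occupied fraction of queen neighbors", {
  lat <- build_lattice(3, 3)
  X1 <- rep(0, 9)
  X1[c(1, 2, 3)] <- 1  # three of the center's eight neighbors
  expect_equal(neighborhood_occupancy(X1, 5, lat), 3 / 8)
  expect_equal(neighborhood_occupancy(rep(0, 9), 1, lat), 0)
  expect_equal(neighborhood_occupancy(rep(1, 9), 5, lat), 1)
})

test_that("autologistic transitions are monotone in D with intercepts on the probability scale", {
  lat <- build_lattice(2, 2)
  hab <- matrix(0.125, 4, 8)
  sp <- spline_spec(hab, knots = matrix(c(0.05, 0.3), 8, 2, byrow = TRUE))
  p <- atlas_params(lat, sp, n_observers = c(1, 1),
                    gamma0 = logit(0.15), phi_slope = 4)
  expect_equal(transition_probs(1, 0, p)$gamma, 0.15, tolerance = 1e-12)
  expect_equal(transition_probs(1, 0.5, p)$phi, invlogit(2),
               tolerance = 1e-12)
  ds <- seq(0, 1, 0.1)
  phis <- vapply(ds, function(d) transition_probs(1, d, p)$phi, numeric(1))
  expect_true(all(diff(phis) > 0))
})

test_that("second-period occupancy picks the branch of the Markov transition", {
  expect_equal(occupancy2_prob(1, 0.95, 0.2), 0.95)
  expect_equal(occupancy2_prob(0, 0.95, 0.2), 0.2)
  expect_equal(occupancy2_prob(0, 0.4, 0.4), occupancy2_prob(1, 0.4, 0.4))
})

test_that("use probability respects the occupancy hierarchy and year structure", {
  lat <- build_lattice(2, 2)
  hab <- matrix(0.125, 4, 8)
  sp <- spline_spec(hab, knots = matrix(c(0.05, 0.3), 8, 2, byrow = TRUE))
  p <- atlas_params(lat, sp, n_observers = c(1, 1), mu_init = c(0.7, 0.5))
  expect_equal(use_prob(0, NULL, 1, 1, 1, p), 0)
  expect_equal(use_prob(0, 1, 1, 1, 2, p), 0)
  expect_equal(use_prob(1, NULL, 1, 1, 1, p), 0.7)
  expect_equal(use_prob(1, 1, 1, 1, 2, p), 0.5)   # exploitation, all zero
  expect_equal(use_prob(1, 0, 1, 1, 2, p), 0.5)   # appropriation, all zero
  expect_error(use_prob(1, 1, 1, 1, 1, p), "absent")
  expect_error(use_prob(1, NULL, 1, 1, 2, p), "required")
})

test_that("protocol-2 outcome probabilities enumerate and normalize", {
  pr <- checklist_outcome_probs(0.5, 0.25, 2)
  expect_equal(pr, c(0.5, 0.25, 0.0625, 0.1875))
  expect_equal(sum(pr), 1)
  for (m in 2:10) for (p1 in c(0.1, 0.5, 0.9)) for (p2 in c(0.2, 0.8))
    expect_equal(sum(checklist_outcome_probs(p1, p2, m)), 1,
                 tolerance = 1e-12)
})

test_that("checklist likelihood matches the outcome enumeration and closed-world rule", {
  lat <- build_lattice(2, 2)
  hab <- matrix(0.125, 4, 8)
  sp <- spline_spec(hab, knots = matrix(c(0.05, 0.3), 8, 2, byrow = TRUE))
  p <- atlas_params(lat, sp, n_observers = c(2, 2),
                    delta = logit(0.25))  # p' = 0.5, p'' = 0.25
  rec1 <- list(protocol = 1L, cell = 1L, season = 1L, year = 1L,
               observer = 1L, month = 7L, detected = 0L)
  expect_equal(checklist_likelihood(rec1, 0, p), 1)
  rec1$detected <- 1L
  expect_error(checklist_likelihood(rec1, 0, p), "corrupted latent")
  expect_equal(checklist_likelihood(rec1, 1, p), 0.5)

  probs <- checklist_outcome_probs(0.5, 0.25, 2)
  base <- list(protocol = 2L, cell = 1L, season = 2L, year = 1L,
               observer = 1L, month = 7L, m_hours = 2L)
  r_h1 <- c(base, detected = 1L, detected_intense = 1L, first_hour = 1L)
  r_h2 <- c(base, detected = 1L, detected_intense = 1L, first_hour = 2L)
  r_aft <- c(base, detected = 1L, detected_intense = 0L)
  r_no <- c(base, detected = 0L)
  expect_equal(checklist_likelihood(r_h1, 1, p), probs[1])
  expect_equal(checklist_likelihood(r_h2, 1, p), probs[2])
  expect_equal(checklist_likelihood(r_aft, 1, p), probs[3])
  expect_equal(checklist_likelihood(r_no, 1, p), probs[4])
})

test_that("complete-data log posterior enforces forcing and matches the hand sum", {
  inst <- two_cell_instance(n_lists = c(1, 0))
  inst$data$checklists$detected <- 1L
  # Z = 1 without X = 1 is impossible
  Zbad <- array(0L, dim = c(2, 2, 1)); Zbad[1, 1, 1] <- 1L
  expect_equal(complete_data_log_posterior(
    inst$data, latent_state(matrix(0L, 2, 2), Zbad), inst$params,
    default_priors()), -Inf)
  # detection with Z = 0 is impossible
  Z0 <- array(0L, dim = c(2, 2, 1))
  X10 <- matrix(c(1L, 0L, 0L, 0L), 2, 2)
  expect_equal(complete_data_log_posterior(
    inst$data, latent_state(X10, Z0), inst$params, default_priors()), -Inf)
  # forced configuration: likelihood part is log q1 + log(1-q2') + log mu + log p
  Zok <- array(0L, dim = c(2, 2, 1)); Zok[1, 1, 1] <- 1L
  lat <- latent_state(X10, Zok)
  sdata <- atlasdyn:::prepare_sampler_data(inst$data, inst$params,
                                           default_priors())
  parts <- atlasdyn:::cpp_log_posterior(
    sdata, atlasdyn:::params_to_cpp(inst$params),
    atlasdyn:::latent_to_cpp(lat, inst$data$years))
  q <- invlogit(inst$params$a0)
  expect_equal(parts$occupancy1, log(q) + log(1 - q), tolerance = 1e-9)
  expect_equal(parts$use, log(0.6), tolerance = 1e-9)
  expect_equal(parts$observation, log(0.5), tolerance = 1e-9)
})

test_that("the R and compiled accumulations of the log posterior agree", {
  sim <- make_small(3)
  pri <- default_priors()
  sdata <- atlasdyn:::prepare_sampler_data(sim$data, sim$params, pri)
  lpR <- complete_data_log_posterior(sim$data, sim$latent, sim$params, pri)
  lpC <- atlasdyn:::cpp_log_posterior(
    sdata, atlasdyn:::params_to_cpp(sim$params),
    atlasdyn:::latent_to_cpp(sim$latent, sim$data$years))
  expect_equal(lpR, lpC$total, tolerance = 1e-8)

  # and on perturbed parameter/latent states
  set.seed(5)
  for (rep in 1:3) {
    p2 <- sim$params
    p2$a0 <- rnorm(1); p2$b <- p2$b + rnorm(length(p2$b), 0, 0.3)
    p2$delta <- rnorm(1); p2$mu_init <- runif(2, 0.2, 0.8)
    st <- initialize_state(sim$data, c(5, 5), seed = rep,
                           spline = sim$params$spline)
    lpR <- complete_data_log_posterior(sim$data, st$latent, p2, pri)
    lpC <- atlasdyn:::cpp_log_posterior(
      sdata, atlasdyn:::params_to_cpp(p2),
      atlasdyn:::latent_to_cpp(st$latent, sim$data$years))
    expect_equal(lpR, lpC$total, tolerance = 1e-8)
  }
})

test_that("the log posterior is invariant to relabeling observers with their effects", {
  sim <- make_small(11)
  pri <- default_priors()
  base <- complete_data_log_posterior(sim$data, sim$latent, sim$params, pri)
  perm <- sample(length(sim$params$omega1))
  p2 <- sim$params
  p2$omega1 <- p2$omega1[perm]
  d2 <- sim$data
  d2$checklists$observer[d2$checklists$protocol == 1L] <-
    match(d2$checklists$observer[d2$checklists$protocol == 1L], perm)
  swapped <- complete_data_log_posterior(d2, sim$latent, p2, pri)
  expect_equal(base, swapped, tolerance = 1e-10)
})

test_that("checklist validation rejects inconsistent records row by row", {
  lat <- build_lattice(2, 2)
  hab <- matrix(0.125, 4, 8)
  ok <- data.frame(protocol = 2L, cell = 1L, season = 2L, year = 1L,
                   observer = 1L, month = 3L, detected = 1L, m_hours = 3L,
                   detected_intense = 1L, first_hour = 2L)
  expect_silent(atlas_data(lat, hab, ok, years = c(2L, 2L)))
  bad_fh <- ok; bad_fh$first_hour <- 5L
  expect_error(atlas_data(lat, hab, bad_fh, years = c(2L, 2L)),
               "row 1.*first_hour")
  bad_m <- ok; bad_m$m_hours <- 1L
  expect_error(atlas_data(lat, hab, bad_m, years = c(2L, 2L)),
               "row 1.*m_hours")
  bad_p1 <- ok; bad_p1$protocol <- 1L
  expect_error(atlas_data(lat, hab, bad_p1, years = c(2L, 2L)),
               "protocol-1 rows")
})
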