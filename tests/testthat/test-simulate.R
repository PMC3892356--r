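test_that("habitat tables are simplex-valued, smooth in space, and reproducible", {
  lat <- build_lattice(8, 8)
  h1 <- simulate_habitat(lat, seed = 4)
  h2 <- simulate_habitat(lat, seed = 4)
  h3 <- simulate_habitat(lat, seed = 5)
  expect_equal(dim(h1), c(64, 8))
  expect_true(all(abs(rowSums(h1) - 1) < 1e-9))
  expect_true(all(h1 >= 0))
  expect_identical(h1, h2)
  expect_false(identical(h1, h3))

  # spatial autocorrelation: correlation between a cell's value and its
  # neighborhood mean, against a permutation null, averaged over seeds
  nb_cor <- function(hab) {
    mean(sapply(seq_len(ncol(hab)), function(h) {
      x <- hab[, h]
      nbm <- vapply(lat$adjacency, function(nb) mean(x[nb]), numeric(1))
      suppressWarnings(cor(x, nbm))
    }), na.rm = TRUE)
  }
  set.seed(99)
  obs <- perm <- numeric(12)
  for (s in seq_along(obs)) {
    hab <- simulate_habitat(lat, seed = 1000 + s)
    obs[s] <- nb_cor(hab)
    perm[s] <- nb_cor(hab[sample(nrow(hab)), ])
  }
  expect_gt(mean(obs), 0.5)
  expect_gt(mean(obs), mean(perm) + 0.3)
})

test_that("saturated links and frozen dynamics behave deterministically", {
  lat <- build_lattice(5, 5)
  hab <- simulate_habitat(lat, seed = 2)
  sp <- spline_spec(hab)
  p_all <- atlas_params(lat, sp, n_observers = c(2, 2), a0 = 10)
  tr <- simulate_truth(lat, hab, p_all, seed = 3)
  expect_true(all(tr$latent$X[, 1] == 1))

  p_frozen <- atlas_params(lat, sp, n_observers = c(2, 2),
                           phi0 = 40, gamma0 = -40)
  tr2 <- simulate_truth(lat, hab, p_frozen, seed = 5)
  expect_identical(tr2$latent$X[, 2], tr2$latent$X[, 1])
})

test_that("colonization frequency increases with neighborhood occupancy", {
  lat <- build_lattice(7, 7)
  hab <- simulate_habitat(lat, seed = 6)
  sp <- spline_spec(hab)
  p <- atlas_params(lat, sp, n_observers = c(2, 2), a0 = 0,
                    gamma0 = -2, gamma_slope = 4)
  lowD <- highD <- c(0, 0)  # colonizations, trials
  for (s in 1:40) {
    tr <- simulate_truth(lat, hab, p, seed = 100 + s)
    empty <- which(tr$latent$X[, 1] == 0)
    D <- tr$truth$D[empty]
    col <- tr$latent$X[empty, 2]
    lowD <- lowD + c(sum(col[D <= 0.3]), sum(D <= 0.3))
    highD <- highD + c(sum(col[D >= 0.7]), sum(D >= 0.7))
  }
  expect_gt(highD[1] / highD[2], lowD[1] / lowD[2])
})

test_that("checklists obey the closed-world and protocol rules", {
  sc <- tiny_scenario(seed = 21)
  lat <- build_lattice(sc$n_rows, sc$n_cols)
  hab <- simulate_habitat(lat, seed = 21)
  sp <- spline_spec(hab)
  p <- reference_true_params(lat, sp, sc$years, sc$n_observers, seed = 21)
  # no use anywhere: no detections can occur
  none <- latent_state(matrix(0L, lat$n_cells, 2),
                       array(0L, dim = c(lat$n_cells, 2, 4)))
  cl0 <- simulate_checklists(none, p, sc, seed = 1)
  expect_true(all(cl0$detected == 0))
  # record invariants hold
  expect_silent(atlas_data(lat, hab, cl0, years = sc$years))

  # delta -> -Inf analogue: post-intense detection suppressed
  all_used <- latent_state(matrix(1L, lat$n_cells, 2),
                           array(1L, dim = c(lat$n_cells, 2, 4)))
  p_nodelta <- p
  p_nodelta$delta <- -40
  cl1 <- simulate_checklists(all_used, p_nodelta, sc, seed = 2)
  p2 <- cl1[cl1$protocol == 2L & cl1$detected == 1L, ]
  expect_true(all(p2$detected_intense == 1))
})

test_that("protocol-2 outcome frequencies match the analytic distribution", {
  lat <- build_lattice(5, 5)
  hab <- simulate_habitat(lat, seed = 31)
  sp <- spline_spec(hab)
  # p' = 0.5 per hour, p'' = 0.25 after the intense period, m = 2 always
  p <- atlas_params(lat, sp, years = c(1L, 1L), n_observers = c(1, 1),
                    p_status = matrix(0, 2, 2), delta = logit(0.25),
                    omega2 = 0, b_det2 = rep(0, 25))
  sc <- scenario_config(n_rows = 5, n_cols = 5, years = c(1, 1),
                        n_observers = c(1, 1), mean_checklists = 800,
                        coverage_prob = 1, mean_extra_hours = 0, seed = 31)
  all_used <- latent_state(matrix(1L, 25, 2), array(1L, dim = c(25, 2, 1)))
  cl <- simulate_checklists(all_used, p, sc, seed = 8)
  cl2 <- cl[cl$protocol == 2L, ]
  N <- nrow(cl2)
  expect_gt(N, 10000)
  obs <- c(mean(cl2$detected == 1 & !is.na(cl2$first_hour) & cl2$first_hour == 1),
           mean(cl2$detected == 1 & !is.na(cl2$first_hour) & cl2$first_hour == 2),
           mean(cl2$detected == 1 & cl2$detected_intense == 0, na.rm = TRUE),
           mean(cl2$detected == 0))
  expected <- checklist_outcome_probs(0.5, 0.25, 2)
  se <- sqrt(expected * (1 - expected) / N)
  expect_true(all(abs(obs - expected) < 3 * se))
})

test_that("a full simulated scenario is reproducible and internally consistent", {
  s1 <- simulate_atlas(tiny_scenario(seed = 13))
  s2 <- simulate_atlas(tiny_scenario(seed = 13))
  expect_identical(s1$data$checklists, s2$data$checklists)
  expect_identical(s1$latent$X, s2$latent$X)
  # detections imply use and occupancy in the truth
  cl <- s1$data$checklists
  det <- cl[cl$detected == 1L, ]
  for (r in seq_len(nrow(det))) {
    expect_equal(s1$latent$Z[det$cell[r], det$season[r], det$year[r]], 1L)
    expect_equal(s1$latent$X[det$cell[r], det$season[r]], 1L)
  }
})
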