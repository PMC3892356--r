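# Shared fixtures: tiny scenarios and an exact enumeration oracle for the
# latent posterior on instances small enough to enumerate.

tiny_scenario <- function(seed = 7, n_rows = 4, n_cols = 4, years = c(2, 2),
                          n_observers = c(5, 5), ...) {
  scenario_config(n_rows = n_rows, n_cols = n_cols, years = years,
                  n_observers = n_observers, seed = seed, ...)
}

default_priors <- function() list(sd_fixed = 10, sd_upper = 5,
                                  sd_upper_dyn = 1, sd_dyn = 2.5)

# A 2-cell, single-period, single-year instance with fixed parameters and
# only nondetection checklists, so every latent configuration has positive
# probability and the posterior can be enumerated exactly.
two_cell_instance <- function(p_det_logit = 0, mu_init = 0.6, a0 = 0.4,
                              n_lists = c(2, 0)) {
  lat <- build_lattice(1, 2)
  habitat <- matrix(0.25, 2, 4)
  cl <- data.frame(protocol = 1L,
                   cell = rep(1:2, n_lists),
                   season = 1L, year = 1L, observer = 1L, month = 7L,
                   detected = 0L, m_hours = NA_integer_,
                   detected_intense = NA_integer_,
                   first_hour = NA_integer_)
  data <- atlas_data(lat, habitat, cl, years = c(1L, 0L))
  sp <- spline_spec(habitat, knots = matrix(c(0.2, 0.6), 4, 2, byrow = TRUE))
  params <- atlas_params(lat, sp, years = c(1L, 0L), n_observers = c(1L, 1L),
                         a0 = a0, mu_init = c(mu_init, 0.5),
                         p_status = matrix(p_det_logit, 2, 2))
  list(data = data, params = params)
}

# Exact posterior over all latent configurations by brute-force enumeration,
# built on the R reference likelihood (independent of the compiled sampler).
enumerate_latent_posterior <- function(data, params) {
  lat <- data$lattice
  n <- lat$n_cells
  years <- params$years
  n_seasons <- if (years[2] > 0) 2L else 1L
  # enumerate X (n x n_seasons) and Z jointly
  nx <- n * n_seasons
  nz <- n * sum(years)
  grid <- expand.grid(rep(list(0:1), nx + nz))
  w <- numeric(nrow(grid))
  post_X <- matrix(0, n, n_seasons)
  post_Z <- array(0, dim = c(n, n_seasons, max(years)))
  for (r in seq_len(nrow(grid))) {
    v <- as.integer(grid[r, ])
    X <- matrix(0L, n, 2)
    X[, seq_len(n_seasons)] <- v[seq_len(nx)]
    Z <- array(0L, dim = c(n, 2, max(years, 1)))
    k <- nx
    for (s in seq_len(n_seasons)) for (t in seq_len(years[s]))
      for (i in seq_len(n)) {
        k <- k + 1
        Z[i, s, t] <- v[k]
      }
    lp <- complete_data_log_posterior(data, latent_state(X, Z), params,
                                      default_priors())
    w[r] <- lp
  }
  w <- exp(w - max(w))
  w <- w / sum(w)
  for (r in seq_len(nrow(grid))) {
    v <- as.integer(grid[r, ])
    post_X <- post_X + matrix(v[seq_len(nx)], n, n_seasons) * w[r]
    k <- nx
    for (s in seq_len(n_seasons)) for (t in seq_len(years[s]))
      for (i in seq_len(n)) {
        k <- k + 1
        post_Z[i, s, t] <- post_Z[i, s, t] + v[k] * w[r]
      }
  }
  list(X = post_X, Z = post_Z)
}

# batch-means Monte-Carlo standard error of the mean of a (possibly
# autocorrelated) 0/1 draw sequence
batch_se <- function(x, n_batches = 50) {
  bs <- floor(length(x) / n_batches)
  means <- vapply(seq_len(n_batches),
                  function(b) mean(x[((b - 1) * bs + 1):(b * bs)]),
                  numeric(1))
  stats::sd(means) / sqrt(n_batches)
}
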