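#' Scenario configuration for the synthetic atlas simulator
#'
#' Bundles the study design (grid size, years per period, observer pools,
#' effort law) with the generating parameter values. The defaults describe
#' the package's reference recovery scenario: a 15 x 15 grid observed over
#' two atlas periods of 4 years each, a species whose range margin crosses
#' the grid and is expanding (high persistence, colonization rising steeply
#' with neighborhood occupancy), heterogeneous observers, uneven coverage
#' (a quarter of the cells poorly surveyed), and the two protocols' distinct
#' effort records (protocol 2 logs at least 2 hours of intense birding and
#' the hour of first detection).
#'
#' @param n_rows,n_cols grid dimensions.
#' @param years years per period `c(T1, T2)`.
#' @param n_observers observers per period.
#' @param mean_checklists mean checklists per well-covered cell-year.
#' @param poor_mean mean checklists per poorly-covered cell-year.
#' @param coverage_prob probability that a cell is well covered.
#' @param mean_extra_hours protocol-2 intense birding lasts `2 + X` hours
#'   with `X` Poisson with this mean.
#' @param true_params function `(lattice, spline) -> atlas_params` giving the
#'   generating values, or `NULL` for the reference values (see
#'   [reference_true_params()]).
#' @param seed integer master seed.
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(n_rows = 15L, n_cols = 15L, years = c(4L, 4L),
                            n_observers = c(40L, 40L), mean_checklists = 5,
                            poor_mean = 0.5, coverage_prob = 0.75,
                            mean_extra_hours = 1, true_params = NULL,
                            seed = 1L) {
  stopifnot(n_rows >= 1, n_cols >= 1, all(years >= 0), years[1] >= 1,
            all(n_observers >= 1), mean_checklists > 0, coverage_prob > 0,
            coverage_prob <= 1)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 years = as.integer(years),
                 n_observers = as.integer(n_observers),
                 mean_checklists = mean_checklists, poor_mean = poor_mean,
                 coverage_prob = coverage_prob,
                 mean_extra_hours = mean_extra_hours,
                 true_params = true_params, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Reference generating parameter values
#'
#' The generating values of the shipped recovery scenario. They describe a
#' conspicuous resident species expanding across a range margin that lies
#' inside the grid (occupancy near one in the core, near zero beyond the
#' margin, about half the cells occupied overall, so both persistence and
#' colonization transitions are observed in numbers): high
#' persistence (phi about 0.9-0.97 across neighborhood-occupancy levels),
#' colonization low in isolation and rising steeply with neighborhood
#' occupancy (gamma_slope = 4), high and stable within-period use, higher
#' detectability in the breeding season (logit differences 0.39 per
#' checklist for protocol 1 and 0.06 per hour for protocol 2), and moderate
#' spatial, observer and cell-level heterogeneity. CAR fields are drawn from
#' their sum-to-zero prior; all other random-effect vectors from their
#' zero-mean Normal priors.
#'
#' @param lattice an `atlas_lattice`.
#' @param spline a `spline_spec` for the habitat table.
#' @param years years per period.
#' @param n_observers observers per period.
#' @param seed seed for the random-effect draws.
#' @return an `atlas_params` with all generating values filled in.
#' @export
reference_true_params <- function(lattice, spline, years = c(4L, 4L),
                                  n_observers = c(40L, 40L), seed = 1L) {
  set.seed(as.integer(seed))
  n <- lattice$n_cells
  H <- length(spline$beta)
  spline$beta <- c(1.0, -1.0, 0.5, rep(0, H - 3))
  spline$u <- matrix(0, H, 2)
  spline$u[1, ] <- c(1.0, -1.0)
  spline$sigma_u <- rep(0.5, H)
  tau_b <- 0.75
  b <- sample_intrinsic_car(lattice, tau_b^2,
                            rng_seed = seed + 11L)$values
  bd1 <- sample_intrinsic_car(lattice, 0.5^2, rng_seed = seed + 12L)$values
  bd2 <- sample_intrinsic_car(lattice, 0.5^2, rng_seed = seed + 13L)$values
  atlas_params(
    lattice, spline, years = years, n_observers = n_observers,
    a0 = 0, b = b, tau_b = tau_b,
    eps = stats::rnorm(n, 0, 0.25), sigma_eps = 0.25,
    phi0 = 2.0, phi_slope = 1.0, gamma0 = -3.0, gamma_slope = 4.0,
    phi_cell = stats::rnorm(n, 0, 0.3), gamma_cell = stats::rnorm(n, 0, 0.3),
    sigma_phi = 0.3, sigma_gamma = 0.3,
    mu_init = c(0.8, 0.85),
    psi0 = c(2.0, 2.0), theta0 = c(0.5, 0.5),
    psi_cell = matrix(stats::rnorm(2 * n, 0, 0.3), n, 2),
    theta_cell = matrix(stats::rnorm(2 * n, 0, 0.3), n, 2),
    sigma_psi_cell = 0.3, sigma_theta_cell = 0.3,
    psi_year = list(stats::rnorm(max(years[1] - 1, 0), 0, 0.2),
                    stats::rnorm(max(years[2] - 1, 0), 0, 0.2)),
    theta_year = list(stats::rnorm(max(years[1] - 1, 0), 0, 0.2),
                      stats::rnorm(max(years[2] - 1, 0), 0, 0.2)),
    sigma_psi_year = 0.2, sigma_theta_year = 0.2,
    p_status = matrix(c(0.39, -0.94, 0.0, -1.0), 2, 2,
                      dimnames = list(c("protocol1", "protocol2"),
                                      c("breeding", "nonbreeding"))),
    delta = 0.5,
    omega1 = stats::rnorm(n_observers[1], 0, 0.3),
    omega2 = stats::rnorm(n_observers[2], 0, 0.3),
    sigma_omega = c(0.3, 0.3),
    b_det1 = bd1, b_det2 = bd2, tau_det = c(0.5, 0.5))
}

#' Simulate a spatially smooth habitat table
#'
#' Generates per-cell proportions of `n_hab` habitat categories by passing
#' low-rank smooth Gaussian surfaces (low-frequency cosine bases with random
#' coefficients) through a softmax, so that neighboring cells have similar
#' composition and every row sums to 1.
#'
#' @param lattice an `atlas_lattice`.
#' @param seed integer seed.
#' @param n_hab number of habitat categories.
#' @return numeric matrix `n_cells` x `n_hab`, rows summing to 1.
#' @export
simulate_habitat <- function(lattice, seed, n_hab = 8L) {
  set.seed(as.integer(seed))
  r <- lattice$row / max(lattice$n_rows - 1, 1)
  c_ <- lattice$col / max(lattice$n_cols - 1, 1)
  basis <- cbind(1, cos(pi * r), cos(pi * c_), cos(pi * r) * cos(pi * c_),
                 cos(2 * pi * r), cos(2 * pi * c_))
  G <- basis %*% matrix(stats::rnorm(ncol(basis) * n_hab, 0, 1.2),
                        ncol(basis), n_hab)
  E <- exp(G - apply(G, 1, max))
  E / rowSums(E)
}

#' Forward-simulate the latent ecological process
#'
#' Draws the first-period occupancy field from the occupancy GAM (the CAR
#' and unstructured effects held in `params`), computes the neighborhood
#' occupancy covariate D from the realized field, draws the second-period
#' occupancy from the autologistic persistence/colonization model, and then
#' the yearly use chains. All intermediate probabilities are recorded so
#' recovery checks can compare against the exact generating quantities.
#'
#' @param lattice an `atlas_lattice`.
#' @param habitat cells x habitats matrix.
#' @param params an `atlas_params` holding the generating values.
#' @param seed integer seed.
#' @return list with `latent` (a `latent_state`) and `truth` (per-cell
#'   `q1`, `D`, `phi`, `gamma`, `q2`, and the use-probability array `mu`).
#' @export
simulate_truth <- function(lattice, habitat, params, seed) {
  set.seed(as.integer(seed))
  n <- lattice$n_cells
  years <- params$years
  n_seasons <- if (years[2] > 0) 2L else 1L
  q1 <- vapply(seq_len(n), occupancy1_prob, numeric(1),
               params = params, habitat = habitat, lattice = lattice)
  X <- matrix(0L, n, 2)
  X[, 1] <- stats::rbinom(n, 1, q1)
  D <- phi <- gam <- q2 <- rep(NA_real_, n)
  if (n_seasons == 2) {
    for (i in seq_len(n)) {
      D[i] <- neighborhood_occupancy(X[, 1], i, lattice)
      tr <- transition_probs(i, D[i], params)
      phi[i] <- tr$phi; gam[i] <- tr$gamma
      q2[i] <- occupancy2_prob(X[i, 1], tr$phi, tr$gamma)
    }
    X[, 2] <- stats::rbinom(n, 1, q2)
  }
  Z <- array(0L, dim = c(n, 2, max(years, 1L)))
  mu <- array(0, dim = c(n, 2, max(years, 1L)))
  for (s in seq_len(n_seasons)) for (i in seq_len(n)) {
    for (t in seq_len(years[s])) {
      zp <- if (t == 1) NULL else Z[i, s, t - 1]
      mu[i, s, t] <- use_prob(X[i, s], zp, i, s, t, params)
      Z[i, s, t] <- stats::rbinom(1, 1, mu[i, s, t])
    }
  }
  list(latent = latent_state(X, Z),
       truth = list(q1 = q1, D = D, phi = phi, gamma = gam, q2 = q2,
                    mu = mu))
}

#' Simulate checklists from the observation model
#'
#' For each cell-year, draws a heterogeneous number of checklists (Poisson,
#' with well- and poorly-covered cells per the scenario's coverage mixture),
#' assigns observers uniformly from the period's pool and months uniformly
#' over the year, and draws each checklist outcome: protocol 1 as a single
#' Bernoulli detection, protocol 2 hour by hour at the hourly rate during the
#' intense period, then the post-intense period at its own rate.
#'
#' @param latent a `latent_state` (from [simulate_truth()]).
#' @param params the generating `atlas_params`.
#' @param scenario a `scenario_config`.
#' @param seed integer seed.
#' @return a checklist data.frame (see [atlas_data()]).
#' @export
simulate_checklists <- function(latent, params, scenario, seed) {
  set.seed(as.integer(seed))
  years <- params$years
  n <- nrow(latent$X)
  n_seasons <- if (years[2] > 0) 2L else 1L
  covered <- stats::rbinom(n, 1, scenario$coverage_prob)
  rate <- ifelse(covered == 1, scenario$mean_checklists, scenario$poor_mean)
  out <- vector("list", n_seasons)
  for (s in seq_len(n_seasons)) {
    Ts <- years[s]
    # counts per (cell, year), cell varying fastest
    nc <- stats::rpois(n * Ts, rep(rate, Ts))
    cell <- rep(rep(seq_len(n), Ts), nc)
    year <- rep(rep(seq_len(Ts), each = n), nc)
    N <- length(cell)
    if (N == 0) next
    obs <- sample.int(scenario$n_observers[s], N, replace = TRUE)
    month <- sample.int(12L, N, replace = TRUE)
    st_col <- ifelse(checklist_status(month) == "breeding", 1L, 2L)
    z <- latent$Z[cbind(cell, s, year)]
    if (s == 1L) {
      p <- invlogit(params$p_status[1, ][st_col] + params$omega1[obs] +
                      params$b_det1[cell])
      det <- as.integer(stats::rbinom(N, 1, p) * z)
      out[[s]] <- data.frame(protocol = 1L, cell = cell, season = s,
                             year = year, observer = obs, month = month,
                             detected = det, m_hours = NA_integer_,
                             detected_intense = NA_integer_,
                             first_hour = NA_integer_)
    } else {
      m <- 2L + stats::rpois(N, scenario$mean_extra_hours)
      lp <- params$p_status[2, ][st_col] + params$omega2[obs] +
        params$b_det2[cell]
      p1 <- invlogit(lp)
      p2 <- invlogit(lp + params$delta)
      # hour of first detection under independent hourly Bernoulli trials
      fh <- stats::rgeom(N, p1) + 1L
      det_int <- as.integer(z == 1L & fh <= m)
      after <- as.integer(z == 1L & fh > m & stats::rbinom(N, 1, p2) == 1L)
      det <- as.integer(det_int == 1L | after == 1L)
      out[[s]] <- data.frame(protocol = 2L, cell = cell, season = s,
                             year = year, observer = obs, month = month,
                             detected = det, m_hours = m,
                             detected_intense = ifelse(det == 1L, det_int,
                                                       NA_integer_),
                             first_hour = ifelse(det_int == 1L, fh,
                                                 NA_integer_))
    }
  }
  cl <- do.call(rbind, out)
  if (is.null(cl))
    cl <- data.frame(protocol = integer(0), cell = integer(0),
                     season = integer(0), year = integer(0),
                     observer = integer(0), month = integer(0),
                     detected = integer(0), m_hours = integer(0),
                     detected_intense = integer(0), first_hour = integer(0))
  rownames(cl) <- NULL
  cl
}

#' Simulate a complete synthetic atlas data set
#'
#' Runs habitat, truth and checklist simulation for a scenario and returns
#' everything needed to fit and to score recovery.
#'
#' @param scenario a `scenario_config`.
#' @return list with `data` (an `atlas_data`), `params` (generating values),
#'   `latent` (true latent states), `truth` (generating probabilities) and
#'   `scenario`.
#' @export
simulate_atlas <- function(scenario = scenario_config()) {
  lattice <- build_lattice(scenario$n_rows, scenario$n_cols)
  habitat <- simulate_habitat(lattice, seed = scenario$seed)
  spline <- spline_spec(habitat)
  params <- if (is.null(scenario$true_params))
    reference_true_params(lattice, spline, scenario$years,
                          scenario$n_observers, seed = scenario$seed)
  else scenario$true_params(lattice, spline)
  tr <- simulate_truth(lattice, habitat, params,
                       seed = scenario$seed + 101L)
  cl <- simulate_checklists(tr$latent, params, scenario,
                            seed = scenario$seed + 202L)
  data <- atlas_data(lattice, habitat, cl, years = scenario$years)
  list(data = data, params = params, latent = tr$latent, truth = tr$truth,
       scenario = scenario)
}
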