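#' Inverse-logit and logit links
#' @param x numeric.
#' @return numeric of the same length.
#' @export
invlogit <- function(x) 1 / (1 + exp(-x))

#' @rdname invlogit
#' @export
logit <- function(x) log(x / (1 - x))

# log(invlogit(x)), numerically stable
log_invlogit <- function(x) ifelse(x > 0, -log1p(exp(-x)), x - log1p(exp(x)))

# log Bernoulli(y; invlogit(eta))
lbern_logit <- function(y, eta) log_invlogit(ifelse(y == 1, eta, -eta))

#' Model parameter container
#'
#' Collects every parameter of the three-level model in one list. Components:
#'
#' * First-period occupancy: `a0` (intercept), `spline` (a [spline_spec()]
#'   holding the habitat-smooth coefficients), `b` + `tau_b` (intrinsic CAR
#'   field values and conditional SD), `eps` + `sigma_eps` (unstructured
#'   cell effects).
#' * Between-period dynamics (autologistic): `phi0`, `gamma0` (persistence /
#'   colonization intercepts), `phi_cell`, `gamma_cell` (+ `sigma_phi`,
#'   `sigma_gamma`), `phi_slope`, `gamma_slope` (scalar slopes on the
#'   neighborhood-occupancy covariate D).
#' * Use level: `mu_init` (initial-use probability per period),
#'   `psi0`/`theta0` (exploitation / appropriation intercepts per period),
#'   `psi_cell`/`theta_cell` (cells x periods, SDs `sigma_psi_cell`,
#'   `sigma_theta_cell`), `psi_year`/`theta_year` (lists, one vector of
#'   T_s - 1 year effects per period, SDs `sigma_psi_year`,
#'   `sigma_theta_year`).
#' * Observation: `p_status` (2 x 2 matrix, rows = protocol, cols =
#'   breeding/nonbreeding; protocol 1 on the per-checklist scale, protocol 2
#'   on the per-hour scale), `delta` (logit-scale offset of the
#'   post-intense-period detection probability), `omega1`/`omega2` observer
#'   effects (+ `sigma_omega`, length 2), `b_det1`/`b_det2` detection CAR
#'   fields (+ `tau_det`, length 2, conditional SDs).
#'
#' @param lattice an `atlas_lattice`.
#' @param spline a `spline_spec`.
#' @param years integer vector `c(T1, T2)` of years per period (`T2 = 0`
#'   collapses the model to a single period with no dynamics level).
#' @param n_observers integer vector `c(K1, K2)` of observers per protocol.
#' @param ... named overrides for any component.
#' @return an object of class `atlas_params`.
#' @export
atlas_params <- function(lattice, spline, years = c(4L, 4L),
                         n_observers = c(1L, 1L), ...) {
  n <- lattice$n_cells
  p <- list(
    a0 = 0, spline = spline,
    b = rep(0, n), tau_b = 1,
    eps = rep(0, n), sigma_eps = 0.5,
    phi0 = 0, gamma0 = 0, phi_slope = 0, gamma_slope = 0,
    phi_cell = rep(0, n), gamma_cell = rep(0, n),
    sigma_phi = 0.5, sigma_gamma = 0.5,
    mu_init = c(0.5, 0.5),
    psi0 = c(0, 0), theta0 = c(0, 0),
    psi_cell = matrix(0, n, 2), theta_cell = matrix(0, n, 2),
    sigma_psi_cell = 0.5, sigma_theta_cell = 0.5,
    psi_year = list(rep(0, max(years[1] - 1L, 0L)),
                    rep(0, max(years[2] - 1L, 0L))),
    theta_year = list(rep(0, max(years[1] - 1L, 0L)),
                      rep(0, max(years[2] - 1L, 0L))),
    sigma_psi_year = 1, sigma_theta_year = 1,
    p_status = matrix(0, 2, 2,
                      dimnames = list(c("protocol1", "protocol2"),
                                      c("breeding", "nonbreeding"))),
    delta = 0,
    omega1 = rep(0, n_observers[1]), omega2 = rep(0, n_observers[2]),
    sigma_omega = c(1, 1),
    b_det1 = rep(0, n), b_det2 = rep(0, n), tau_det = c(1, 1),
    years = as.integer(years)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  validate_params(p, n)
  structure(p, class = "atlas_params")
}

validate_params <- function(p, n) {
  sds <- c(p$tau_b, p$sigma_eps, p$sigma_phi, p$sigma_gamma,
           p$sigma_psi_cell, p$sigma_theta_cell, p$sigma_psi_year,
           p$sigma_theta_year, p$sigma_omega, p$tau_det, p$spline$sigma_u)
  if (any(sds <= 0)) stop("all SD / tau parameters must be positive")
  if (any(p$mu_init <= 0 | p$mu_init >= 1))
    stop("mu_init must lie strictly in (0, 1)")
  if (length(p$b) != n || length(p$eps) != n)
    stop("per-cell effect vectors must have one entry per cell")
  invisible(p)
}

#' First-period occupancy probability
#'
#' Inverse-logit of the GAM predictor: intercept + habitat smooths + spatial
#' CAR effect + unstructured effect.
#'
#' @param cell cell index (1-based) or id string.
#' @param params an `atlas_params`.
#' @param habitat cells x habitats matrix of proportions.
#' @param lattice the `atlas_lattice`.
#' @return probability in (0, 1).
#' @export
occupancy1_prob <- function(cell, params, habitat, lattice) {
  i <- resolve_cell(lattice, cell)
  eta <- params$a0 + params$b[i] + params$eps[i]
  for (h in seq_len(ncol(habitat)))
    eta <- eta + smooth_value(habitat[i, h], params$spline, h)
  invlogit(eta)
}

#' Neighborhood occupancy covariate D
#'
#' The proportion of a cell's first-order (queen) neighbors occupied during
#' the first period; the autologistic covariate of the persistence and
#' colonization models.
#'
#' @param X1 binary first-period occupancy vector (one entry per cell).
#' @param cell cell index or id.
#' @param lattice the `atlas_lattice`.
#' @return proportion in \[0, 1\].
#' @export
neighborhood_occupancy <- function(X1, cell, lattice) {
  i <- resolve_cell(lattice, cell)
  nb <- lattice$adjacency[[i]]
  sum(X1[nb]) / length(nb)
}

#' Persistence and colonization probabilities
#'
#' Autologistic transitions between atlas periods:
#' `phi = invlogit(phi0 + phi_cell[i] + phi_slope * D)` and
#' `gamma = invlogit(gamma0 + gamma_cell[i] + gamma_slope * D)`.
#'
#' @param cell cell index.
#' @param D_i neighborhood occupancy in \[0, 1\].
#' @param params an `atlas_params`.
#' @return list with `phi` and `gamma`.
#' @export
transition_probs <- function(cell, D_i, params) {
  i <- as.integer(cell)
  list(phi = invlogit(params$phi0 + params$phi_cell[i] +
                        params$phi_slope * D_i),
       gamma = invlogit(params$gamma0 + params$gamma_cell[i] +
                          params$gamma_slope * D_i))
}

#' Second-period occupancy probability
#'
#' First-order Markov transition: an occupied cell persists with probability
#' `phi`, an empty cell is colonized with probability `gamma`.
#'
#' @param X1_i binary first-period state of the cell.
#' @param phi,gamma transition probabilities.
#' @return probability.
#' @export
occupancy2_prob <- function(X1_i, phi, gamma) X1_i * phi + (1 - X1_i) * gamma

#' Yearly use probability
#'
#' Use is nested under occupancy: an unoccupied cell is never used. In the
#' first year of a period an occupied cell is used with probability
#' `mu_init[s]`; in later years use follows exploitation (`psi`, continued
#' use) or appropriation (`theta`, use after a year of non-use) dynamics.
#' The year effect for the transition into year `t` is indexed `t - 1`.
#'
#' @param X_is binary occupancy of the cell in period `season`.
#' @param Z_prev previous-year use (must be `NULL` exactly when `year == 1`).
#' @param cell cell index.
#' @param season period (1 or 2).
#' @param year year within the period (1-based).
#' @param params an `atlas_params`.
#' @return probability.
#' @export
use_prob <- function(X_is, Z_prev, cell, season, year, params) {
  if (year < 1L) stop("year must be >= 1")
  if (year == 1L && !is.null(Z_prev))
    stop("Z_prev must be absent for year 1")
  if (year > 1L && is.null(Z_prev))
    stop("Z_prev is required for year > 1")
  if (X_is == 0) return(0)
  if (year == 1L) return(params$mu_init[season])
  i <- as.integer(cell)
  tt <- year - 1L  # transition index
  psi <- invlogit(params$psi0[season] + params$psi_cell[i, season] +
                    params$psi_year[[season]][tt])
  theta <- invlogit(params$theta0[season] + params$theta_cell[i, season] +
                      params$theta_year[[season]][tt])
  Z_prev * psi + (1 - Z_prev) * theta
}

#' Protocol-2 checklist outcome distribution
#'
#' Given use, a protocol-2 checklist of `m` intense-birding hours has `m + 2`
#' possible outcomes: first detection in hour h (h = 1..m, probability
#' `(1-p1)^(h-1) p1`, hours being independent Bernoulli trials at the hourly
#' rate `p1`), detection only after the intense period (`(1-p1)^m p2`), or no
#' detection (`(1-p1)^m (1-p2)`). The probabilities sum to one analytically.
#'
#' @param p1 hourly detection probability during intense birding.
#' @param p2 detection probability over the whole post-intense period.
#' @param m integer >= 2, hours of intense birding.
#' @return numeric vector of length `m + 2`: hours 1..m, after-period, none.
#' @export
checklist_outcome_probs <- function(p1, p2, m) {
  m <- as.integer(m)
  stopifnot(m >= 2L)
  c((1 - p1)^(seq_len(m) - 1L) * p1, (1 - p1)^m * p2, (1 - p1)^m * (1 - p2))
}

checklist_status <- function(month) ifelse(month %in% 6:11,
                                           "breeding", "nonbreeding")

#' Likelihood of one checklist outcome
#'
#' Conditional on the cell-year use state `Z`. With `Z = 0` the species
#' cannot be detected (no false positives): a nondetection has probability 1
#' and a detection probability 0. With `Z = 1`, protocol 1 is a Bernoulli
#' per-checklist detection; protocol 2 uses the hour-structured model of
#' [checklist_outcome_probs()] with `p1 = invlogit(lp)` and
#' `p2 = invlogit(lp + delta)` where `lp` is the hourly detection logit.
#'
#' @param record a list or one-row data.frame with fields `protocol`, `cell`
#'   (index), `season`, `year`, `observer` (index within protocol), `month`,
#'   `detected`, and for protocol 2 `m_hours`, `detected_intense`,
#'   `first_hour`.
#' @param Z binary use state of the record's cell-year.
#' @param params an `atlas_params`.
#' @return the probability of the observed outcome.
#' @export
checklist_likelihood <- function(record, Z, params) {
  r <- as.list(record)
  status_col <- if (checklist_status(r$month) == "breeding") 1L else 2L
  if (Z == 0) {
    if (r$detected == 1)
      stop("corrupted latent state: detection with Z = 0 ",
           "(detections must force Z = 1 upstream)")
    return(1)
  }
  i <- as.integer(r$cell)
  if (r$protocol == 1L) {
    p <- invlogit(params$p_status[1L, status_col] + params$omega1[r$observer] +
                    params$b_det1[i])
    return(if (r$detected == 1) p else 1 - p)
  }
  lp <- params$p_status[2L, status_col] + params$omega2[r$observer] +
    params$b_det2[i]
  p1 <- invlogit(lp)
  p2 <- invlogit(lp + params$delta)
  m <- as.integer(r$m_hours)
  if (r$detected == 0) return((1 - p1)^m * (1 - p2))
  if (r$detected_intense == 1) {
    h <- as.integer(r$first_hour)
    return((1 - p1)^(h - 1L) * p1)
  }
  (1 - p1)^m * p2
}

#' Latent state container
#'
#' @param X binary matrix cells x periods (season-scale occupancy).
#' @param Z binary array cells x periods x max-years (yearly use); entries
#'   beyond a period's year count are ignored.
#' @return an object of class `latent_state`.
#' @export
latent_state <- function(X, Z) {
  X <- as.matrix(X)
  structure(list(X = X, Z = Z), class = "latent_state")
}

#' Complete-data log posterior
#'
#' The joint log density of latent states, data and parameters: first-period
#' occupancy Bernoulli terms, second-period Markov transition terms, yearly
#' use terms, all checklist likelihood terms, the intrinsic CAR log densities
#' (on the sum-to-zero subspace, `-(N-1) log(tau) - Q/(2 tau^2)` with Q the
#' pairwise-difference quadratic form), zero-mean Normal log densities for
#' every random-effect block, and the hyperprior log densities (Normal(0,
#' `sd_fixed`^2) on fixed effects, Uniform(0, `sd_upper`) on SDs, Uniform(0,1)
#' on `mu_init`). Returns `-Inf` when the latent state violates a forcing
#' constraint (use without occupancy, or detection without use).
#'
#' This is the reference (naive-accumulation) implementation; the compiled
#' sampler carries its own accumulation and the two are cross-checked.
#'
#' @param data an `atlas_data` (see [atlas_data()]).
#' @param latent a `latent_state`.
#' @param params an `atlas_params`.
#' @param priors list with `sd_fixed` (default 10), `sd_upper` (default 5)
#'   and `sd_upper_dyn` (default 1): the SDs of the per-cell
#'   persistence/colonization effects get the tighter Uniform(0,
#'   `sd_upper_dyn`) prior, because a single between-period transition per
#'   cell carries no information about them.
#' @return a scalar log density (up to terms constant in all arguments).
#' @export
complete_data_log_posterior <- function(data, latent, params,
                                        priors = list(sd_fixed = 10,
                                                      sd_upper = 5,
                                                      sd_upper_dyn = 1,
                                                      sd_dyn = 2.5)) {
  lat <- data$lattice
  n <- lat$n_cells
  years <- params$years
  n_seasons <- if (years[2] > 0L) 2L else 1L
  X <- latent$X
  Z <- latent$Z
  lp <- 0

  # forcing constraints
  for (s in seq_len(n_seasons)) for (i in seq_len(n))
    for (t in seq_len(years[s]))
      if (Z[i, s, t] == 1 && X[i, s] == 0) return(-Inf)

  # level 1: occupancy
  for (i in seq_len(n)) {
    q1 <- occupancy1_prob(i, params, data$habitat, lat)
    lp <- lp + ifelse(X[i, 1] == 1, log(q1), log(1 - q1))
  }
  if (n_seasons == 2L) {
    for (i in seq_len(n)) {
      D <- neighborhood_occupancy(X[, 1], i, lat)
      tr <- transition_probs(i, D, params)
      q2 <- occupancy2_prob(X[i, 1], tr$phi, tr$gamma)
      lp <- lp + ifelse(X[i, 2] == 1, log(q2), log(1 - q2))
    }
  }

  # level 2: use
  for (s in seq_len(n_seasons)) for (i in seq_len(n)) {
    for (t in seq_len(years[s])) {
      zp <- if (t == 1L) NULL else Z[i, s, t - 1L]
      mu <- use_prob(X[i, s], zp, i, s, t, params)
      z <- Z[i, s, t]
      if (z == 1 && mu <= 0) return(-Inf)
      lp <- lp + ifelse(z == 1, log(mu), log(1 - mu))
    }
  }

  # level 3: checklists
  cl <- data$checklists
  if (nrow(cl) > 0) for (r in seq_len(nrow(cl))) {
    rec <- cl[r, ]
    z <- Z[rec$cell, rec$season, rec$year]
    if (rec$detected == 1 && z == 0) return(-Inf)
    lp <- lp + log(checklist_likelihood(rec, z, params))
  }

  # priors
  sf <- priors$sd_fixed
  su <- priors$sd_upper
  ldn <- function(x, sd) sum(stats::dnorm(x, 0, sd, log = TRUE))
  car_lp <- function(vals, tau) {
    Q <- 0
    for (i in seq_len(n)) for (k in lat$adjacency[[i]])
      if (k > i) Q <- Q + (vals[i] - vals[k])^2
    -(n - 1) * log(tau) - Q / (2 * tau^2)
  }
  sud <- if (is.null(priors$sd_upper_dyn)) 1 else priors$sd_upper_dyn
  sds <- c(params$tau_b,
           params$sigma_psi_year, params$sigma_theta_year, params$sigma_omega,
           params$tau_det, params$spline$sigma_u)
  if (any(sds <= 0 | sds >= su)) return(-Inf)
  # SDs of per-cell effects seen through a handful of Bernoulli trials
  sds_cell <- c(params$sigma_eps, params$sigma_phi, params$sigma_gamma,
                params$sigma_psi_cell, params$sigma_theta_cell)
  if (any(sds_cell <= 0 | sds_cell >= sud)) return(-Inf)
  if (any(params$mu_init <= 0 | params$mu_init >= 1)) return(-Inf)
  sp <- params$spline
  sl <- if (is.null(priors$sd_dyn)) 2.5 else priors$sd_dyn
  lp <- lp +
    ldn(c(params$a0, sp$beta,
          params$psi0[seq_len(n_seasons)],
          params$theta0[seq_len(n_seasons)], as.vector(params$p_status),
          params$delta), sf) +
    ldn(c(params$phi0, params$gamma0, params$phi_slope,
          params$gamma_slope), sl) +
    sum(stats::dnorm(sp$u, 0, rep(sp$sigma_u, 2), log = TRUE)) +
    car_lp(params$b, params$tau_b) +
    ldn(params$eps, params$sigma_eps) +
    ldn(params$phi_cell, params$sigma_phi) +
    ldn(params$gamma_cell, params$sigma_gamma) +
    ldn(params$psi_cell[, seq_len(n_seasons)], params$sigma_psi_cell) +
    ldn(params$theta_cell[, seq_len(n_seasons)], params$sigma_theta_cell) +
    ldn(unlist(params$psi_year), params$sigma_psi_year) +
    ldn(unlist(params$theta_year), params$sigma_theta_year) +
    ldn(params$omega1, params$sigma_omega[1]) +
    ldn(params$omega2, params$sigma_omega[2]) +
    car_lp(params$b_det1, params$tau_det[1]) +
    car_lp(params$b_det2, params$tau_det[2])
  lp
}

#' Assemble an atlas data set
#'
#' Bundles the lattice, the habitat covariate table and the checklist table
#' into the object the fitting and simulation functions consume. Checklist
#' rows are validated against the record invariants (see
#' [read_checklists()] for the file-level equivalent).
#'
#' @param lattice an `atlas_lattice`.
#' @param habitat cells x habitats matrix of proportions (rows sum to 1).
#' @param checklists data.frame with columns `protocol`, `cell` (1-based
#'   index) or `cell_id`, `season`, `year`, `observer` (1-based index within
#'   protocol), `month`, `detected`, `m_hours`, `detected_intense`,
#'   `first_hour` (protocol-2 fields `NA` for protocol 1).
#' @param years integer vector `c(T1, T2)`.
#' @return an object of class `atlas_data`.
#' @export
atlas_data <- function(lattice, habitat, checklists, years) {
  habitat <- as.matrix(habitat)
  stopifnot(nrow(habitat) == lattice$n_cells)
  if (!"cell" %in% names(checklists) && "cell_id" %in% names(checklists))
    checklists$cell <- match(checklists$cell_id, lattice$cell_id)
  validate_checklists(checklists, lattice, years)
  structure(list(lattice = lattice, habitat = habitat,
                 checklists = checklists, years = as.integer(years)),
            class = "atlas_data")
}

validate_checklists <- function(cl, lattice, years) {
  if (nrow(cl) == 0) return(invisible(cl))
  bad <- function(cond, msg) {
    w <- which(cond)
    if (length(w)) stop(sprintf("checklist row %d: %s", w[1], msg))
  }
  bad(is.na(cl$cell) | cl$cell < 1 | cl$cell > lattice$n_cells,
      "unknown cell_id")
  bad(!cl$protocol %in% c(1L, 2L), "protocol must be 1 or 2")
  bad(!cl$season %in% c(1L, 2L), "season must be 1 or 2")
  bad(cl$year < 1 | cl$year > years[cl$season], "year outside period range")
  bad(!cl$month %in% 1:12, "month must be in 1..12")
  bad(!cl$detected %in% c(0L, 1L), "detected must be 0/1")
  p2 <- cl$protocol == 2L
  bad(p2 & (is.na(cl$m_hours) | cl$m_hours < 2),
      "protocol 2 requires m_hours >= 2")
  bad(p2 & cl$detected == 0 &
        !(is.na(cl$detected_intense) | cl$detected_intense == 0),
      "detected_intense without detected")
  bad(p2 & cl$detected == 1 & is.na(cl$detected_intense),
      "protocol-2 detection needs detected_intense")
  di <- p2 & !is.na(cl$detected_intense) & cl$detected_intense == 1
  bad(di & (is.na(cl$first_hour) | cl$first_hour < 1 |
              cl$first_hour > cl$m_hours),
      "first_hour must lie in 1..m_hours")
  bad(p2 & !is.na(cl$first_hour) & (is.na(cl$detected_intense) |
                                      cl$detected_intense == 0),
      "first_hour present without detected_intense")
  bad(!p2 & (!is.na(cl$m_hours) | !is.na(cl$detected_intense) |
               !is.na(cl$first_hour)),
      "protocol-1 rows must not carry protocol-2 fields")
  invisible(cl)
}
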