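#' MCMC configuration
#'
#' @param n_chains number of chains.
#' @param n_burnin burn-in sweeps per chain (discarded; proposal scales adapt
#'   during burn-in only, so post-burn-in kernels are fixed and ergodic).
#' @param n_iter retained sweeps per chain (before thinning).
#' @param thin thinning interval.
#' @param seed master seed; each chain's stream is split from it.
#' @param adapt adapt random-walk proposal scales during burn-in.
#' @param update_latent resample the latent X/Z states each sweep.
#' @param update_blocks character vector of parameter blocks to update, or
#'   `NULL` for all. Block names: `a0`, `spline`, `sigma_u`, `b_car`,
#'   `tau_b`, `eps`, `sigma_eps`, `dyn_intercepts`, `dyn_cells`,
#'   `dyn_sigmas`, `mu_init`, `use_intercepts`, `use_cells`, `use_years`,
#'   `use_sigmas`, `p_status`, `delta`, `observers`, `obs_sigmas`, `b_det`,
#'   `tau_det`. Blocks left out stay fixed at their initial values (used by
#'   the oracle tests with known parameters).
#' @param store_derived keep per-cell derived probability draws (needed for
#'   cell-level summaries; costs memory on large grids).
#' @param store_latent keep per-iteration latent draws (tiny problems only).
#' @param priors hyperprior constants: `sd_fixed` (Normal SD for logit-scale
#'   fixed effects, default 10), `sd_upper` (upper bound of the Uniform
#'   priors on random-effect and CAR SDs, default 5) and `sd_upper_dyn`
#'   (tighter bound, default 1, for the SDs of per-cell random effects that
#'   are observed through at most a few Bernoulli trials each:
#'   `sigma_eps`, `sigma_phi`, `sigma_gamma`, `sigma_psi_cell`,
#'   `sigma_theta_cell`), and `sd_dyn` (Normal SD, default 2.5, a weakly
#'   informative prior for the four transition coefficients `phi0`,
#'   `gamma0`, `phi_slope`, `gamma_slope`, whose likelihood — one
#'   between-period transition per cell — is too weak for a near-flat
#'   prior).
#' @return a list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3L, n_burnin = 2000L, n_iter = 2000L,
                        thin = 1L, seed = 1L, adapt = TRUE,
                        update_latent = TRUE, update_blocks = NULL,
                        store_derived = TRUE, store_latent = FALSE,
                        priors = list(sd_fixed = 10, sd_upper = 5,
                                      sd_upper_dyn = 1, sd_dyn = 2.5)) {
  stopifnot(n_chains >= 1L, n_burnin >= 0L, n_iter >= 1L, thin >= 1L)
  structure(list(n_chains = as.integer(n_chains),
                 n_burnin = as.integer(n_burnin),
                 n_iter = as.integer(n_iter), thin = as.integer(thin),
                 seed = as.integer(seed), adapt = isTRUE(adapt),
                 update_latent = isTRUE(update_latent),
                 update_blocks = update_blocks,
                 store_derived = isTRUE(store_derived),
                 store_latent = isTRUE(store_latent),
                 priors = priors),
            class = "mcmc_config")
}

all_update_blocks <- function() {
  c("a0", "spline", "sigma_u", "b_car", "tau_b", "eps", "sigma_eps",
    "dyn_intercepts", "dyn_cells", "dyn_sigmas", "mu_init",
    "use_intercepts", "use_cells", "use_years", "use_sigmas", "p_status",
    "delta", "observers", "obs_sigmas", "b_det", "tau_det")
}

chain_seed <- function(seed, chain) {
  as.integer((as.numeric(seed) + (chain - 1) * 104729) %% 21474830)
}

# ---- marshalling ----------------------------------------------------------

csr_index <- function(groups, n_groups) {
  # groups: 1-based group per item; returns 0-based ptr/idx CSR
  ord <- order(groups)
  counts <- tabulate(groups, nbins = n_groups)
  list(ptr = as.integer(c(0L, cumsum(counts))),
       idx = as.integer(ord - 1L))
}

prepare_sampler_data <- function(data, params, priors) {
  lat <- data$lattice
  n <- lat$n_cells
  years <- data$years
  T1 <- years[1]; T2 <- years[2]; Tt <- T1 + T2
  adj_ptr <- c(0L, cumsum(lat$n_i))
  adj_idx <- as.integer(unlist(lat$adjacency) - 1L)
  sd_mat <- spline_design(data$habitat, params$spline)
  H <- ncol(data$habitat)
  col_hab <- c(rep(0L, H), rep(seq_len(H), each = 2L))
  cl <- data$checklists
  C <- nrow(cl)
  K1 <- max(1L, length(params$omega1))
  K2 <- max(1L, length(params$omega2))
  slot <- ifelse(cl$season == 1L, cl$year - 1L, T1 + cl$year - 1L)
  cyi <- (cl$cell - 1L) * Tt + slot  # 0-based
  cy_csr <- csr_index(cyi + 1L, n * Tt)
  p1 <- which(cl$protocol == 1L)
  p2 <- which(cl$protocol == 2L)
  obs_csr <- function(rows, K) {
    if (length(rows) == 0)
      return(list(ptr = integer(K + 1L), idx = integer(0)))
    o <- csr_index(cl$observer[rows], K)
    o$idx <- as.integer(rows[o$idx + 1L] - 1L)
    o
  }
  cell_csr <- function(rows) {
    if (length(rows) == 0)
      return(list(ptr = integer(n + 1L), idx = integer(0)))
    o <- csr_index(cl$cell[rows], n)
    o$idx <- as.integer(rows[o$idx + 1L] - 1L)
    o
  }
  obs1 <- obs_csr(p1, K1); obs2 <- obs_csr(p2, K2)
  cp1 <- cell_csr(p1); cp2 <- cell_csr(p2)
  Zforce <- integer(n * Tt)
  Xforce <- integer(2L * n)
  det <- which(cl$detected == 1L)
  Zforce[cyi[det] + 1L] <- 1L
  Xforce[(cl$cell[det] - 1L) + (cl$season[det] - 1L) * n + 1L] <- 1L
  na0 <- function(x) { x[is.na(x)] <- 0L; as.integer(x) }
  list(n_cells = n, T1 = T1, T2 = T2,
       adj_ptr = as.integer(adj_ptr), adj_idx = adj_idx,
       n_nb = as.integer(lat$n_i),
       sdesign = sd_mat, col_hab = col_hab, n_hab = H,
       K1 = K1, K2 = K2,
       cl_cell = as.integer(cl$cell - 1L),
       cl_season = as.integer(cl$season - 1L),
       cl_year = as.integer(cl$year - 1L),
       cl_prot = as.integer(cl$protocol - 1L),
       cl_status = as.integer(checklist_status(cl$month) == "nonbreeding"),
       cl_obs = as.integer(cl$observer - 1L),
       cl_det = as.integer(cl$detected),
       cl_m = na0(cl$m_hours), cl_int = na0(cl$detected_intense),
       cl_fh = na0(cl$first_hour),
       cy_ptr = cy_csr$ptr, cy_ord = cy_csr$idx,
       obs1_ptr = obs1$ptr, obs1_idx = obs1$idx,
       obs2_ptr = obs2$ptr, obs2_idx = obs2$idx,
       cp1_ptr = cp1$ptr, cp1_idx = cp1$idx,
       cp2_ptr = cp2$ptr, cp2_idx = cp2$idx,
       Zforce = Zforce, Xforce = Xforce,
       sd_fixed = priors$sd_fixed, sd_upper = priors$sd_upper,
       sd_upper_dyn = if (is.null(priors$sd_upper_dyn)) 1 else
         priors$sd_upper_dyn,
       sd_dyn = if (is.null(priors$sd_dyn)) 2.5 else priors$sd_dyn)
}

params_to_cpp <- function(params) {
  p <- unclass(params)
  p$coef <- spline_coef(params$spline)
  p$sigma_u <- params$spline$sigma_u
  p$psi_year <- as.numeric(unlist(params$psi_year))
  p$theta_year <- as.numeric(unlist(params$theta_year))
  p$psi_cell <- as.numeric(params$psi_cell)
  p$theta_cell <- as.numeric(params$theta_cell)
  p$delta <- params$delta
  p
}

cpp_to_params <- function(cpp, template) {
  p <- template
  H <- length(p$spline$beta)
  p$spline$beta <- cpp$coef[seq_len(H)]
  p$spline$u <- matrix(cpp$coef[-seq_len(H)], H, 2, byrow = TRUE)
  p$spline$sigma_u <- cpp$sigma_u
  n <- length(p$b)
  for (nm in c("a0", "tau_b", "sigma_eps", "b", "eps", "phi0", "gamma0",
               "phi_slope", "gamma_slope", "sigma_phi", "sigma_gamma",
               "phi_cell", "gamma_cell", "mu_init", "psi0", "theta0",
               "sigma_psi_cell", "sigma_theta_cell", "sigma_psi_year",
               "sigma_theta_year", "p_status", "delta", "omega1", "omega2",
               "sigma_omega", "b_det1", "b_det2", "tau_det"))
    p[[nm]] <- cpp[[nm]]
  p$p_status <- matrix(cpp$p_status, 2, 2,
                       dimnames = dimnames(template$p_status))
  p$psi_cell <- matrix(cpp$psi_cell, n, 2)
  p$theta_cell <- matrix(cpp$theta_cell, n, 2)
  ny1 <- length(template$psi_year[[1]])
  p$psi_year <- list(cpp$psi_year[seq_len(ny1)],
                     cpp$psi_year[setdiff(seq_along(cpp$psi_year),
                                          seq_len(ny1))])
  p$theta_year <- list(cpp$theta_year[seq_len(ny1)],
                       cpp$theta_year[setdiff(seq_along(cpp$theta_year),
                                              seq_len(ny1))])
  p
}

latent_to_cpp <- function(latent, years) {
  Tt <- sum(years)
  n <- nrow(latent$X)
  Zv <- integer(n * Tt)
  for (s in seq_len(2)) {
    if (years[s] == 0) next
    for (t in seq_len(years[s])) {
      slot <- if (s == 1) t - 1L else years[1] + t - 1L
      Zv[(seq_len(n) - 1L) * Tt + slot + 1L] <- latent$Z[, s, t]
    }
  }
  list(X = as.integer(latent$X), Z = Zv)
}

cpp_to_latent <- function(cpp, n, years) {
  Tt <- sum(years)
  X <- matrix(cpp$X, n, 2)
  Z <- array(0L, dim = c(n, 2, max(years, 1L)))
  for (s in 1:2) {
    if (years[s] == 0) next
    for (t in seq_len(years[s])) {
      slot <- if (s == 1) t - 1L else years[1] + t - 1L
      Z[, s, t] <- cpp$Z[(seq_len(n) - 1L) * Tt + slot + 1L]
    }
  }
  latent_state(X, Z)
}

scalar_names <- function(H, years) {
  py1 <- max(years[1] - 1L, 0L); py2 <- max(years[2] - 1L, 0L)
  yr <- function(pre) c(if (py1 > 0) paste0(pre, "_1_", seq_len(py1)),
                        if (py2 > 0) paste0(pre, "_2_", seq_len(py2)))
  c("a0", paste0("beta_", seq_len(H)),
    paste0("u_", rep(seq_len(H), each = 2), "_", rep(1:2, H)),
    paste0("sigma_u_", seq_len(H)),
    "tau_b", "sigma_eps", "phi0", "gamma0", "phi_slope", "gamma_slope",
    "sigma_phi", "sigma_gamma", "mu_init_1", "mu_init_2",
    "psi0_1", "psi0_2", "theta0_1", "theta0_2",
    "sigma_psi_cell", "sigma_theta_cell", "sigma_psi_year",
    "sigma_theta_year", yr("psi_year"), yr("theta_year"),
    "p_1_breeding", "p_1_nonbreeding", "p_2_breeding", "p_2_nonbreeding",
    "delta", "sigma_omega_1", "sigma_omega_2", "tau_det_1", "tau_det_2")
}

# ---- initialization -------------------------------------------------------

#' Initialize latent states and parameters for one chain
#'
#' Latent occupancy and use are set to 1 wherever a detection forces them;
#' unforced latents start at 1 with probability 1/2. Parameters are drawn
#' from overdispersed starting distributions (distinct across chain seeds).
#'
#' @param data an `atlas_data`.
#' @param n_observers integer vector `c(K1, K2)`.
#' @param seed integer seed for this chain's initialization.
#' @param spline optional `spline_spec` to reuse (knots and centers are
#'   data-determined and shared across chains); built from the habitat table
#'   when omitted.
#' @return list with `latent` (a `latent_state`) and `params`
#'   (an `atlas_params`).
#' @export
initialize_state <- function(data, n_observers, seed, spline = NULL) {
  set.seed(as.integer(seed))
  lat <- data$lattice
  n <- lat$n_cells
  years <- data$years
  sp <- if (is.null(spline)) spline_spec(data$habitat) else spline
  rn <- function(k = 1, sd = 1) stats::rnorm(k, 0, sd)
  params <- atlas_params(
    lat, sp, years = years, n_observers = n_observers,
    a0 = rn(), tau_b = stats::runif(1, 0.3, 1.5),
    b = rep(0, n), eps = rn(n, 0.1),
    sigma_eps = stats::runif(1, 0.1, 0.9),
    phi0 = rn(), gamma0 = rn(), phi_slope = rn(), gamma_slope = rn(),
    phi_cell = rn(n, 0.1), gamma_cell = rn(n, 0.1),
    sigma_phi = stats::runif(1, 0.1, 0.9),
    sigma_gamma = stats::runif(1, 0.1, 0.9),
    mu_init = stats::runif(2, 0.2, 0.8),
    psi0 = rn(2), theta0 = rn(2),
    psi_cell = matrix(rn(2 * n, 0.1), n, 2),
    theta_cell = matrix(rn(2 * n, 0.1), n, 2),
    sigma_psi_cell = stats::runif(1, 0.1, 0.9),
    sigma_theta_cell = stats::runif(1, 0.1, 0.9),
    sigma_psi_year = stats::runif(1, 0.3, 1.5),
    sigma_theta_year = stats::runif(1, 0.3, 1.5),
    psi_year = list(rn(max(years[1] - 1, 0), 0.1),
                    rn(max(years[2] - 1, 0), 0.1)),
    theta_year = list(rn(max(years[1] - 1, 0), 0.1),
                      rn(max(years[2] - 1, 0), 0.1)),
    p_status = matrix(rn(4), 2, 2), delta = rn(),
    omega1 = rn(n_observers[1], 0.1), omega2 = rn(n_observers[2], 0.1),
    sigma_omega = stats::runif(2, 0.3, 1.5),
    b_det1 = rep(0, n), b_det2 = rep(0, n),
    tau_det = stats::runif(2, 0.3, 1.5))
  params$spline$beta <- rn(ncol(data$habitat), 0.5)
  params$spline$sigma_u <- stats::runif(ncol(data$habitat), 0.3, 1.5)

  X <- matrix(stats::rbinom(2 * n, 1, 0.5), n, 2)
  Z <- array(0L, dim = c(n, 2, max(years, 1L)))
  for (s in 1:2) for (t in seq_len(years[s]))
    Z[, s, t] <- stats::rbinom(n, 1, 0.5)
  cl <- data$checklists
  det <- cl[cl$detected == 1L, , drop = FALSE]
  if (nrow(det) > 0) {
    for (r in seq_len(nrow(det))) {
      X[det$cell[r], det$season[r]] <- 1L
      Z[det$cell[r], det$season[r], det$year[r]] <- 1L
    }
  }
  # respect the hierarchy at the start
  for (s in 1:2) for (t in seq_len(years[s]))
    Z[, s, t] <- Z[, s, t] * X[, s]
  list(latent = latent_state(X, Z), params = params)
}

# ---- main fitting routine -------------------------------------------------

#' Fit the three-level dynamic occupancy model by MCMC
#'
#' Runs the Metropolis-within-Gibbs sampler: each sweep resamples every
#' unforced latent occupancy/use indicator from its exact Bernoulli full
#' conditional, then updates every continuous parameter block by (adaptive)
#' random-walk Metropolis; the initial-use probabilities have conjugate Beta
#' updates, and each intrinsic CAR field is re-centered to sum to zero after
#' its sweep. Chains are independent, with seeds split from the master seed.
#'
#' @param data an `atlas_data`.
#' @param config an `mcmc_config`.
#' @param n_observers observers per protocol `c(K1, K2)`; defaults to the
#'   maxima observed in the checklists.
#' @param init_params optional `atlas_params` used as the starting value for
#'   every chain (parameters named in `config$update_blocks` still move);
#'   by default each chain draws its own overdispersed start.
#' @param init_latent optional `latent_state` start (defaults to the forced
#'   initialization of [initialize_state()]).
#' @return an `atlas_fit` object: per-chain scalar draws (`$scalars`, list of
#'   iterations x parameters matrices), posterior latent marginals
#'   (`$X_marginal`, `$Z_marginal`), a parameter summary table (`$summary`:
#'   mean, sd, quantiles, split-Rhat, effective sample size), per-cell
#'   derived-probability summaries (`$cell_summary`), and the final states.
#' @export
fit_atlas <- function(data, config = mcmc_config(), n_observers = NULL,
                      init_params = NULL, init_latent = NULL) {
  stopifnot(inherits(data, "atlas_data"), inherits(config, "mcmc_config"))
  cl <- data$checklists
  if (is.null(n_observers)) {
    k <- function(p) {
      o <- cl$observer[cl$protocol == p]
      if (length(o)) max(o) else 1L
    }
    n_observers <- c(k(1L), k(2L))
  }
  blocks <- config$update_blocks
  if (is.null(blocks)) blocks <- all_update_blocks()
  tpl_spline <- if (!is.null(init_params)) init_params$spline else NULL
  template <- if (!is.null(init_params)) init_params else
    initialize_state(data, n_observers, chain_seed(config$seed, 1))$params
  cpp_cfg <- list(n_burnin = config$n_burnin, n_iter = config$n_iter,
                  thin = config$thin, adapt = config$adapt,
                  update_latent = config$update_latent,
                  store_derived = config$store_derived,
                  store_latent = config$store_latent,
                  update_blocks = blocks)
  sdata <- prepare_sampler_data(data, template, config$priors)
  snames <- scalar_names(ncol(data$habitat), data$years)

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    cs <- chain_seed(config$seed, ch)
    st <- initialize_state(data, n_observers, cs, spline = tpl_spline)
    if (!is.null(init_params)) st$params <- init_params
    if (!is.null(init_latent)) st$latent <- init_latent
    lp0 <- cpp_log_posterior(sdata, params_to_cpp(st$params),
                             latent_to_cpp(st$latent, data$years))
    if (!is.finite(lp0$total)) {
      bad <- names(lp0)[!vapply(lp0, is.finite, logical(1))]
      bad <- setdiff(bad, "total")
      stop("non-finite log posterior at initialization; offending term(s): ",
           paste(bad, collapse = ", "))
    }
    set.seed(cs)
    out <- run_sampler_cpp(sdata, params_to_cpp(st$params),
                           latent_to_cpp(st$latent, data$years), cpp_cfg)
    colnames(out$scalars) <- snames
    chains[[ch]] <- out
  }

  scalars <- lapply(chains, `[[`, "scalars")
  n <- data$lattice$n_cells
  Xm <- Reduce(`+`, lapply(chains, `[[`, "X_mean")) / config$n_chains
  Zm <- Reduce(`+`, lapply(chains, `[[`, "Z_mean")) / config$n_chains
  summ <- summarize_scalars(scalars)
  cell_summ <- NULL
  if (config$store_derived)
    cell_summ <- summarize_cells(lapply(chains, `[[`, "derived"),
                                 data$lattice, data$years)
  structure(list(
    scalars = scalars,
    derived = if (config$store_derived) lapply(chains, `[[`, "derived"),
    latent_draws = if (config$store_latent)
      lapply(chains, `[[`, "latent_draws"),
    X_marginal = matrix(Xm, n, 2),
    Z_marginal = Zm,
    summary = summ, cell_summary = cell_summ,
    final_params = lapply(chains, function(o)
      cpp_to_params(o$final_params, template)),
    final_latent = lapply(chains, function(o)
      cpp_to_latent(o$final_latent, n, data$years)),
    config = config, years = data$years, n_observers = n_observers),
    class = "atlas_fit")
}

#' @export
print.atlas_fit <- function(x, ...) {
  cat(sprintf("atlas_fit: %d chains x %d retained draws, %d parameters\n",
              length(x$scalars), nrow(x$scalars[[1]]),
              ncol(x$scalars[[1]])))
  cat(sprintf("max split-Rhat (moving params): %.3f\n",
              max(x$summary$rhat, na.rm = TRUE)))
  invisible(x)
}

# ---- diagnostics ----------------------------------------------------------

#' Split-chain potential scale reduction factor
#'
#' Gelman-Rubin diagnostic computed after splitting each chain in half.
#' Returns `NA` for parameters with (numerically) zero variance, e.g. blocks
#' held fixed.
#'
#' @param draws list of matrices (one per chain, iterations x parameters) or
#'   a single matrix/vector.
#' @return named numeric vector of Rhat values.
#' @export
rhat <- function(draws) {
  if (!is.list(draws)) draws <- list(as.matrix(draws))
  halves <- list()
  for (m in draws) {
    m <- as.matrix(m)
    h <- floor(nrow(m) / 2)
    halves <- c(halves, list(m[seq_len(h), , drop = FALSE],
                             m[h + seq_len(h), , drop = FALSE]))
  }
  nh <- length(halves)
  niter <- nrow(halves[[1]])
  means <- sapply(halves, colMeans)
  vars <- sapply(halves, function(m) apply(m, 2, stats::var))
  means <- matrix(means, ncol = nh)
  vars <- matrix(vars, ncol = nh)
  W <- rowMeans(vars)
  B <- niter * apply(means, 1, stats::var)
  out <- sqrt((niter - 1) / niter + B / (niter * W))
  out[W < 1e-12] <- NA_real_
  names(out) <- colnames(as.matrix(draws[[1]]))
  out
}

#' Effective sample size
#'
#' Autocorrelation-based ESS pooled across chains, truncating the
#' autocorrelation sum at the first negative paired (Geyer) sum.
#'
#' @inheritParams rhat
#' @return named numeric vector of ESS values.
#' @export
ess <- function(draws) {
  if (!is.list(draws)) draws <- list(as.matrix(draws))
  draws <- lapply(draws, as.matrix)
  P <- ncol(draws[[1]])
  niter <- nrow(draws[[1]])
  m <- length(draws)
  out <- numeric(P)
  for (j in seq_len(P)) {
    acfs <- sapply(draws, function(d) {
      x <- d[, j]
      if (stats::var(x) < 1e-12) return(rep(NA_real_, min(niter - 1, 200)))
      stats::acf(x, lag.max = min(niter - 1, 200), plot = FALSE,
                 demean = TRUE)$acf[-1]
    })
    acfs <- matrix(acfs, ncol = m)
    if (all(is.na(acfs))) { out[j] <- NA_real_; next }
    rho <- rowMeans(acfs)
    s <- 0
    k <- 1
    while (k + 1 <= length(rho)) {
      pair <- rho[k] + rho[k + 1]
      if (pair < 0) break
      s <- s + pair
      k <- k + 2
    }
    out[j] <- m * niter / (1 + 2 * s)
  }
  names(out) <- colnames(draws[[1]])
  out
}

summarize_scalars <- function(scalars) {
  all <- do.call(rbind, scalars)
  qs <- t(apply(all, 2, stats::quantile, probs = c(0.025, 0.5, 0.975)))
  data.frame(param = colnames(all), mean = colMeans(all),
             sd = apply(all, 2, stats::sd),
             q2.5 = qs[, 1], q50 = qs[, 2], q97.5 = qs[, 3],
             rhat = rhat(scalars), ess = ess(scalars),
             row.names = NULL)
}

summarize_cells <- function(derived, lattice, years) {
  all <- do.call(rbind, derived)
  n <- lattice$n_cells
  Tt <- sum(years)
  quant <- c("occ1", "persistence", "colonization", "occ2",
             unlist(lapply(1:2, function(s)
               if (years[s] > 0) paste0("use_", s, "_", seq_len(years[s])))))
  res <- vector("list", length(quant))
  for (q in seq_along(quant)) {
    cols <- (q - 1) * n + seq_len(n)
    m <- all[, cols, drop = FALSE]
    res[[q]] <- data.frame(
      cell_id = lattice$cell_id, quantity = quant[q],
      mean = colMeans(m),
      q2.5 = apply(m, 2, stats::quantile, probs = 0.025),
      q97.5 = apply(m, 2, stats::quantile, probs = 0.975),
      row.names = NULL)
  }
  do.call(rbind, res)
}
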