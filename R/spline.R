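#' Knot placement for the habitat smooths
#'
#' Each habitat covariate enters the first-period occupancy predictor through
#' a low-rank penalized spline with two knots. Knots are placed at the
#' empirical terciles (33.3rd and 66.7th percentiles, type-7 quantiles) of the
#' observed covariate values; exact ties between the two knots are broken by
#' nudging the upper knot upward by 1e-6.
#'
#' @param covariate_values numeric vector of proportions in \[0, 1\]; at least
#'   3 distinct values are required (otherwise the smooth degenerates).
#' @return numeric vector of two strictly increasing knot locations.
#' @export
place_knots <- function(covariate_values) {
  x <- covariate_values[!is.na(covariate_values)]
  if (length(unique(x)) < 3L)
    stop("need at least 3 distinct covariate values to place two knots")
  k <- unname(stats::quantile(x, probs = c(1 / 3, 2 / 3), type = 7))
  if (k[2] <= k[1]) k[2] <- k[1] + 1e-6
  k
}

#' Build the spline specification for a habitat covariate table
#'
#' Computes, for each of the habitat columns, the two tercile knots and the
#' covariate mean used for centering. Coefficients (`beta`, the fixed linear
#' slope per habitat; `u`, the two penalized truncated-basis coefficients;
#' `sigma_u`, the per-habitat penalty SD) are stored alongside and default to
#' zero slopes / unit penalty; model fitting treats them as parameters.
#'
#' @param habitat numeric matrix (cells x habitats) of proportions in \[0,1\].
#' @param beta,u,sigma_u optional coefficient values: `beta` length-H numeric,
#'   `u` an H x 2 matrix, `sigma_u` length-H positive numeric.
#' @param knots optional H x 2 matrix of knot locations, overriding the
#'   tercile rule (needed e.g. on tables with too few distinct values).
#' @return an object of class `spline_spec` with fields `knots` (H x 2),
#'   `center` (length H), `beta`, `u`, `sigma_u`.
#' @export
spline_spec <- function(habitat, beta = NULL, u = NULL, sigma_u = NULL,
                        knots = NULL) {
  habitat <- as.matrix(habitat)
  H <- ncol(habitat)
  if (is.null(knots)) knots <- t(apply(habitat, 2, place_knots))
  knots <- matrix(knots, H, 2)
  if (any(knots[, 2] <= knots[, 1])) stop("knots must be strictly increasing")
  center <- colMeans(habitat)
  if (is.null(beta)) beta <- rep(0, H)
  if (is.null(u)) u <- matrix(0, H, 2)
  if (is.null(sigma_u)) sigma_u <- rep(1, H)
  u <- matrix(u, H, 2)
  stopifnot(length(beta) == H, length(sigma_u) == H, all(sigma_u > 0))
  structure(list(knots = knots, center = as.numeric(center),
                 beta = as.numeric(beta), u = u,
                 sigma_u = as.numeric(sigma_u)),
            class = "spline_spec")
}

#' Evaluate one habitat smooth
#'
#' The smooth for habitat h is the centered truncated-linear ("broken stick")
#' spline
#' \deqn{f_h(x) = \beta_h (x - \bar x_h) + u_{h1}(x - \kappa_{h1})_+ +
#'   u_{h2}(x - \kappa_{h2})_+}
#' where \eqn{(\cdot)_+} is the positive part, \eqn{\bar x_h} the covariate
#' mean stored in the spec and \eqn{\kappa_{hj}} the knots. It is continuous
#' and piecewise linear; with all coefficients zero it is identically zero.
#'
#' @param x covariate value(s) in \[0, 1\] (vectorized).
#' @param spec a `spline_spec`.
#' @param habitat habitat column index (1-based).
#' @return numeric vector of smooth values (logit-scale contribution).
#' @export
smooth_value <- function(x, spec, habitat) {
  stopifnot(inherits(spec, "spline_spec"))
  h <- as.integer(habitat)
  if (h < 1L || h > length(spec$beta)) stop("invalid habitat index")
  spec$beta[h] * (x - spec$center[h]) +
    spec$u[h, 1] * pmax(x - spec$knots[h, 1], 0) +
    spec$u[h, 2] * pmax(x - spec$knots[h, 2], 0)
}

#' Spline design matrix for the occupancy predictor
#'
#' Expands the habitat table into the design matrix whose columns are, for
#' each habitat h: the centered covariate, then the two truncated-linear
#' basis columns. Column order is all centered covariates (1..H), then the
#' 2H truncated columns (h1 knot1, h1 knot2, h2 knot1, ...).
#'
#' @param habitat cells x habitats matrix.
#' @param spec a `spline_spec` built from (or compatible with) `habitat`.
#' @return numeric matrix with `3 * H` columns.
#' @keywords internal
spline_design <- function(habitat, spec) {
  habitat <- as.matrix(habitat)
  H <- ncol(habitat)
  X_lin <- sweep(habitat, 2, spec$center)
  X_tr <- matrix(0, nrow(habitat), 2 * H)
  for (h in seq_len(H)) {
    X_tr[, 2 * h - 1] <- pmax(habitat[, h] - spec$knots[h, 1], 0)
    X_tr[, 2 * h]     <- pmax(habitat[, h] - spec$knots[h, 2], 0)
  }
  cbind(X_lin, X_tr)
}

spline_coef <- function(spec) c(spec$beta, as.vector(t(spec$u)))
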