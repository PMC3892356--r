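#' Build a regular lattice with queen adjacency
#'
#' Constructs the spatial backbone of the model: a rectangular grid of cells
#' enumerated row-major, with first-order queen neighborhoods (cells sharing
#' an edge or a corner are neighbors). All spatial terms in the model — the
#' intrinsic CAR random fields and the neighborhood-occupancy covariate of the
#' autologistic dynamics — are defined on this structure.
#'
#' @param n_rows,n_cols positive integers; the grid must contain at least two
#'   cells (single-cell grids have no neighborhood structure and are rejected).
#' @return An object of class `atlas_lattice`: a list with `n_cells`,
#'   `n_rows`, `n_cols`, `cell_id` (character ids, row-major), `row`/`col`
#'   (0-based integer coordinates), `adjacency` (list of integer neighbor
#'   indices per cell) and `n_i` (per-cell neighbor counts).
#' @examples
#' lat <- build_lattice(3, 3)
#' lat$n_i  # corners 3, edges 5, center 8
#' @export
build_lattice <- function(n_rows, n_cols) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("n_rows and n_cols must be positive integers")
  if (n_rows * n_cols < 2L)
    stop("single-cell grids are rejected: no neighborhood structure")
  n <- n_rows * n_cols
  row <- rep(seq_len(n_rows) - 1L, each = n_cols)
  col <- rep(seq_len(n_cols) - 1L, times = n_rows)
  adjacency <- vector("list", n)
  for (i in seq_len(n)) {
    r <- row[i]; c <- col[i]
    nb <- integer(0)
    for (dr in -1L:1L) for (dc in -1L:1L) {
      if (dr == 0L && dc == 0L) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 0L && rr < n_rows && cc >= 0L && cc < n_cols)
        nb <- c(nb, rr * n_cols + cc + 1L)
    }
    adjacency[[i]] <- sort(nb)
  }
  structure(list(
    n_cells = n, n_rows = n_rows, n_cols = n_cols,
    cell_id = paste0("c", seq_len(n) - 1L),
    row = row, col = col,
    adjacency = adjacency,
    n_i = vapply(adjacency, length, integer(1))
  ), class = "atlas_lattice")
}

#' @export
print.atlas_lattice <- function(x, ...) {
  cat(sprintf("atlas_lattice: %d x %d grid (%d cells), queen adjacency\n",
              x$n_rows, x$n_cols, x$n_cells))
  invisible(x)
}

#' Intrinsic-CAR structure matrix
#'
#' Returns K = diag(n_i) - W, the (improper) precision structure of the
#' intrinsic CAR model on the lattice; the field's precision is K / tau2.
#'
#' @param lattice an `atlas_lattice`.
#' @return a dense `n_cells` x `n_cells` numeric matrix.
#' @export
car_structure_matrix <- function(lattice) {
  stopifnot(inherits(lattice, "atlas_lattice"))
  n <- lattice$n_cells
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- lattice$adjacency[[i]]
    K[i, nb] <- -1
    K[i, i] <- length(nb)
  }
  K
}

#' Construct a CAR random field
#'
#' A container for one intrinsic CAR spatial random effect: per-cell values on
#' the logit scale, a conditional variance parameter `tau2`, and the lattice
#' the field lives on. The model uses three such fields: one in the
#' first-period occupancy predictor and one in each protocol's detection
#' predictor.
#'
#' @param values numeric vector, one entry per lattice cell.
#' @param tau2 positive conditional variance parameter.
#' @param lattice the `atlas_lattice` the field is defined on.
#' @return an object of class `car_field`.
#' @export
car_field <- function(values, tau2, lattice) {
  stopifnot(inherits(lattice, "atlas_lattice"))
  if (length(values) != lattice$n_cells)
    stop("values must have exactly one entry per lattice cell")
  if (!is.numeric(tau2) || length(tau2) != 1L || tau2 <= 0)
    stop("tau2 must be a positive scalar")
  structure(list(values = as.numeric(values), tau2 = as.numeric(tau2),
                 lattice = lattice),
            class = "car_field")
}

#' Full conditional of one cell of an intrinsic CAR field
#'
#' Under the intrinsic CAR model, the effect of cell i given all other cells
#' is Gaussian with mean equal to the average of its neighbors' values and
#' variance `tau2 / n_i`: the conditional variance is inversely proportional
#' to the number of neighbors.
#'
#' @param field a `car_field`.
#' @param cell a cell index (1-based integer) or a `cell_id` string.
#' @return a list with elements `mean` and `variance`.
#' @export
car_full_conditional <- function(field, cell) {
  stopifnot(inherits(field, "car_field"))
  lat <- field$lattice
  i <- resolve_cell(lat, cell)
  nb <- lat$adjacency[[i]]
  list(mean = mean(field$values[nb]), variance = field$tau2 / length(nb))
}

resolve_cell <- function(lattice, cell) {
  if (is.character(cell)) {
    i <- match(cell, lattice$cell_id)
    if (is.na(i)) stop("unknown cell identifier: ", cell)
    return(i)
  }
  i <- as.integer(cell)
  if (is.na(i) || i < 1L || i > lattice$n_cells)
    stop("unknown cell identifier: ", cell)
  i
}

#' Draw an intrinsic CAR field constrained to sum to zero
#'
#' The intrinsic CAR prior is improper (its structure matrix K = diag(n_i) - W
#' has a one-dimensional null space spanned by the constant vector on a
#' connected lattice). A proper draw is obtained by eigendecomposing K,
#' sampling each non-null eigencomponent with variance `tau2` / eigenvalue,
#' and setting the null-space (constant) component to zero — which enforces
#' the sum-to-zero identifiability constraint by construction. The resulting
#' covariance is `tau2` times the Moore-Penrose pseudoinverse of K.
#'
#' Used by the simulator to draw spatial fields from their prior; MCMC never
#' needs joint draws (it uses the full conditionals).
#'
#' @param lattice an `atlas_lattice`.
#' @param tau2 positive conditional variance parameter.
#' @param rng_seed integer seed; draws are deterministic given the seed.
#' @return a `car_field` whose values sum to zero (within numerical tolerance).
#' @export
sample_intrinsic_car <- function(lattice, tau2, rng_seed) {
  stopifnot(inherits(lattice, "atlas_lattice"))
  if (tau2 <= 0) stop("tau2 must be positive")
  K <- car_structure_matrix(lattice)
  ee <- eigen(K, symmetric = TRUE)
  tol <- 1e-8 * max(ee$values)
  null_dim <- sum(ee$values < tol)
  if (null_dim > 1L)
    stop("disconnected lattice: structure matrix has ", null_dim,
         " null eigenvalues")
  keep <- ee$values >= tol
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(rng_seed))
  z <- stats::rnorm(sum(keep))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  values <- ee$vectors[, keep, drop = FALSE] %*%
    (z * sqrt(tau2 / ee$values[keep]))
  values <- drop(values)
  values <- values - mean(values)  # remove residual round-off in the null component
  car_field(values, tau2, lattice)
}
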