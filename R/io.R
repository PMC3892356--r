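#' Read and write the grid CSV
#'
#' The grid file has columns `cell_id,row,col` with 0-based integer
#' coordinates describing a complete rectangle; adjacency is always derived
#' from the coordinates, never read.
#'
#' @param path file path.
#' @return [read_grid_csv()] returns an `atlas_lattice` (with the file's
#'   cell ids); [write_grid_csv()] writes and returns the path invisibly.
#' @export
read_grid_csv <- function(path) {
  if (!file.exists(path)) stop("grid file not found: ", path)
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "row", "col")
  if (!all(need %in% names(g)))
    stop("grid CSV must have columns cell_id,row,col")
  if (anyDuplicated(g$cell_id)) stop("duplicate cell_id in grid CSV")
  n_rows <- max(g$row) + 1L
  n_cols <- max(g$col) + 1L
  if (nrow(g) != n_rows * n_cols || min(g$row) != 0L || min(g$col) != 0L)
    stop("grid CSV must describe a complete 0-based rectangle")
  lat <- build_lattice(n_rows, n_cols)
  ord <- order(g$row * n_cols + g$col)
  lat$cell_id <- as.character(g$cell_id[ord])
  lat
}

#' @rdname read_grid_csv
#' @param lattice an `atlas_lattice`.
#' @export
write_grid_csv <- function(lattice, path) {
  utils::write.csv(data.frame(cell_id = lattice$cell_id,
                              row = lattice$row, col = lattice$col),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write the habitat CSV
#'
#' Columns `cell_id,hab_1,...,hab_H`: per-cell habitat proportions in
#' \[0, 1\] summing to 1 within 1e-6 per row. Rows are matched to the
#' lattice by `cell_id`.
#'
#' @param path file path.
#' @param lattice the `atlas_lattice` the table belongs to.
#' @return [read_habitat_csv()] returns a cells x habitats matrix in lattice
#'   cell order.
#' @export
read_habitat_csv <- function(path, lattice) {
  if (!file.exists(path)) stop("habitat file not found: ", path)
  h <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (names(h)[1] != "cell_id") stop("habitat CSV must start with cell_id")
  idx <- match(lattice$cell_id, h$cell_id)
  if (anyNA(idx)) stop("habitat CSV is missing cells: ",
                       lattice$cell_id[which(is.na(idx))[1]])
  m <- as.matrix(h[idx, -1, drop = FALSE])
  if (any(m < -1e-9 | m > 1 + 1e-9))
    stop("habitat proportions must lie in [0, 1]")
  bad <- which(abs(rowSums(m) - 1) > 1e-6)
  if (length(bad)) stop("habitat row for cell ", lattice$cell_id[bad[1]],
                        " does not sum to 1")
  rownames(m) <- lattice$cell_id
  m
}

#' @rdname read_habitat_csv
#' @param habitat cells x habitats matrix.
#' @export
write_habitat_csv <- function(habitat, lattice, path) {
  d <- data.frame(cell_id = lattice$cell_id, habitat)
  names(d) <- c("cell_id", paste0("hab_", seq_len(ncol(habitat))))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write the checklist CSV
#'
#' Columns `protocol,cell_id,season,year,observer_id,month,detected,
#' m_hours,detected_intense,first_hour`; protocol-2-only fields are empty
#' for protocol-1 rows. Months 1-12 map to breeding status internally
#' (June-November = breeding). Validation failures are reported with the
#' offending row number.
#'
#' @param path file path.
#' @param lattice the `atlas_lattice` (for cell_id resolution).
#' @param years years per period `c(T1, T2)`.
#' @return a validated checklist data.frame with internal `cell` and
#'   `observer` indices attached; empty file gives an empty set (with a
#'   warning).
#' @export
read_checklists <- function(path, lattice, years) {
  if (!file.exists(path)) stop("checklist file not found: ", path)
  cl <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = list(observer_id = "character",
                                          cell_id = "character"))
  if (nrow(cl) == 0) {
    warning("checklist file is empty: ", path)
    return(data.frame(protocol = integer(0), cell_id = character(0),
                      season = integer(0), year = integer(0),
                      observer_id = character(0), month = integer(0),
                      detected = integer(0), m_hours = integer(0),
                      detected_intense = integer(0),
                      first_hour = integer(0), cell = integer(0),
                      observer = integer(0)))
  }
  need <- c("protocol", "cell_id", "season", "year", "observer_id", "month",
            "detected", "m_hours", "detected_intense", "first_hour")
  miss <- setdiff(need, names(cl))
  if (length(miss)) stop("checklist CSV is missing columns: ",
                         paste(miss, collapse = ", "))
  for (v in c("protocol", "season", "year", "month", "detected", "m_hours",
              "detected_intense", "first_hour"))
    cl[[v]] <- suppressWarnings(as.integer(cl[[v]]))
  cl$cell <- match(cl$cell_id, lattice$cell_id)
  # observer index within protocol, by order of appearance
  cl$observer <- NA_integer_
  for (p in 1:2) {
    r <- which(cl$protocol == p)
    if (length(r))
      cl$observer[r] <- match(cl$observer_id[r], unique(cl$observer_id[r]))
  }
  validate_checklists(cl, lattice, years)
  cl$status <- checklist_status(cl$month)
  cl
}

#' @rdname read_checklists
#' @param checklists checklist data.frame (internal `cell`/`observer`
#'   indices or `cell_id`/`observer_id` columns).
#' @export
write_checklists <- function(checklists, lattice, path) {
  cl <- checklists
  if (!"cell_id" %in% names(cl)) cl$cell_id <- lattice$cell_id[cl$cell]
  if (!"observer_id" %in% names(cl))
    cl$observer_id <- sprintf("obs%03d", cl$observer)
  out <- cl[, c("protocol", "cell_id", "season", "year", "observer_id",
                "month", "detected", "m_hours", "detected_intense",
                "first_hour")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a simulated scenario to disk
#'
#' Emits the grid, habitat and checklist CSVs, a truth JSON (latent states,
#' generating probabilities and parameters) and the scenario JSON into a
#' directory.
#'
#' @param sim result of [simulate_atlas()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_scenario_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lat <- sim$data$lattice
  write_grid_csv(lat, file.path(dir, "grid.csv"))
  write_habitat_csv(sim$data$habitat, lat, file.path(dir, "habitat.csv"))
  write_checklists(sim$data$checklists, lat,
                   file.path(dir, "checklists.csv"))
  truth <- list(X = sim$latent$X, Z = sim$latent$Z,
                truth = sim$truth,
                params = serialize_params(sim$params))
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA,
                       auto_unbox = TRUE)
  sc <- sim$scenario
  sc$true_params <- NULL
  jsonlite::write_json(unclass(sc), file.path(dir, "scenario.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

serialize_params <- function(p) {
  out <- unclass(p)
  out$spline <- unclass(p$spline)
  out
}

#' Read a run configuration
#'
#' JSON with fields `grid`, `habitat`, `checklists` (paths, resolved
#' relative to the config file), `years`, an optional `mcmc` block
#' (`n_chains`, `n_burnin`, `n_iter`, `thin`, `seed`), an optional `priors`
#' block and `outdir`. All referenced files must exist and validate before
#' any sampling starts.
#'
#' @param path path to the JSON config.
#' @return list with `data` (an `atlas_data`), `config` (an `mcmc_config`)
#'   and `outdir`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("run config not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("grid", "habitat", "checklists", "years"))
    if (is.null(cfg[[f]])) stop("run config is missing field: ", f)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  lat <- read_grid_csv(resolve(cfg$grid))
  hab <- read_habitat_csv(resolve(cfg$habitat), lat)
  years <- as.integer(cfg$years)
  cl <- read_checklists(resolve(cfg$checklists), lat, years)
  data <- atlas_data(lat, hab, cl, years)
  m <- cfg$mcmc
  mc <- mcmc_config(
    n_chains = if (!is.null(m$n_chains)) m$n_chains else 3L,
    n_burnin = if (!is.null(m$n_burnin)) m$n_burnin else 2000L,
    n_iter = if (!is.null(m$n_iter)) m$n_iter else 2000L,
    thin = if (!is.null(m$thin)) m$thin else 1L,
    seed = if (!is.null(m$seed)) m$seed else 1L,
    priors = if (!is.null(cfg$priors)) cfg$priors else
      list(sd_fixed = 10, sd_upper = 5))
  list(data = data, config = mc,
       outdir = if (!is.null(cfg$outdir)) cfg$outdir else "atlasdyn-out")
}

#' Write posterior summary tables
#'
#' Writes the parameter summary (`param,mean,sd,q2.5,q50,q97.5,rhat,ess`)
#' and, when available, the per-cell map table
#' (`cell_id,quantity,mean,q2.5,q97.5`).
#'
#' @param fit an `atlas_fit`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_posterior_csvs <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(fit$summary, file.path(dir, "posterior_summary.csv"),
                   row.names = FALSE)
  if (!is.null(fit$cell_summary))
    utils::write.csv(fit$cell_summary, file.path(dir, "cell_summary.csv"),
                     row.names = FALSE)
  invisible(dir)
}
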