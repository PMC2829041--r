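#' Load a run configuration file
#'
#' Reads a YAML (or JSON) configuration for a simulation run. The `params`
#' block holds parameter overrides applied on top of the packaged base
#' case; the remaining keys control the run itself. Unknown keys are
#' rejected by name so typos fail loudly.
#'
#' @param path Configuration file path (`.yaml`/`.yml`/`.json`), or `NULL`
#'   for all defaults with base-case parameters.
#' @return A list with elements `params` (an `adhesion_params`), `t_end`
#'   (default 1000 min), `seed` (default 1), `N_star` (default 3), `dt_out`
#'   (0.5 min), `burn_in` (100 min), `n_sub` (20), `v_scale` (10 nm/s),
#'   `low` (1 nm/s), `high` (5 nm/s) and `window` (20 samples).
#' @export
load_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path)
    if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  }
  if (is.null(cfg)) cfg <- list()
  defaults <- list(t_end = 1000, seed = 1, N_star = 3, dt_out = 0.5,
                   burn_in = 100, n_sub = 20, v_scale = 10,
                   low = 1, high = 5, window = 20)
  bad <- setdiff(names(cfg), c("params", names(defaults)))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  out <- utils::modifyList(defaults, cfg[setdiff(names(cfg), "params")])
  out$params <- do.call(base_case_params, as.list(cfg$params))
  out
}

#' Write / read a trajectory as CSV
#'
#' Columns are `t,N,S,M,X,R,P,v` for count trajectories and
#' `t,n,s,m,x,r,p,v` for deterministic (density) trajectories; the reader
#' detects which by the column names.
#'
#' @param traj An `adhesim_trajectory` data.frame.
#' @param path Output CSV path.
#' @return `path` invisibly (writer); an `adhesim_trajectory` (reader).
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "adhesim_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  counts <- c("t", "N", "S", "M", "X", "R", "P", "v")
  dens <- c("t", "n", "s", "m", "x", "r", "p", "v")
  units <- if (identical(names(df), counts)) "counts"
  else if (identical(names(df), dens)) "densities"
  else stop("unrecognized trajectory columns in ", path)
  structure(df, class = c("adhesim_trajectory", "data.frame"), units = units)
}

#' Write / read a velocity map as CSV
#'
#' Long format with one row per cell: `y_index, t_index, y, t, v, mask`.
#'
#' @param map A [velocity_map()].
#' @param path CSV path.
#' @return `path` invisibly (writer); a `velocity_map` (reader).
#' @export
write_velocity_map_csv <- function(map, path) {
  stopifnot(inherits(map, "velocity_map"))
  ny <- nrow(map$v); nt <- ncol(map$v)
  df <- data.frame(y_index = rep(seq_len(ny), nt),
                   t_index = rep(seq_len(nt), each = ny),
                   y = rep(map$y, nt), t = rep(map$t, each = ny),
                   v = as.vector(map$v), mask = as.vector(map$mask))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_velocity_map_csv
#' @export
read_velocity_map_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("y_index", "t_index", "y", "t", "v", "mask")
  if (!all(need %in% names(df))) stop("unrecognized velocity-map columns in ", path)
  ny <- max(df$y_index); nt <- max(df$t_index)
  if (nrow(df) != ny * nt) stop("incomplete velocity-map grid in ", path)
  ord <- order(df$t_index, df$y_index)
  df <- df[ord, ]
  velocity_map(matrix(df$v, ny, nt), mask = matrix(as.logical(df$mask), ny, nt),
               t = df$t[seq(1, nrow(df), by = ny)], y = df$y[seq_len(ny)])
}

#' Write a fixed-point table as JSON
#'
#' @param fp An `adhesim_fixed_points` object from [find_fixed_points()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fixed_points_json <- function(fp, path) {
  stopifnot(inherits(fp, "adhesim_fixed_points"))
  jsonlite::write_json(list(n_fixed_points = nrow(fp),
                            points = as.data.frame(fp)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# internal: stable md5 over a canonical JSON rendering of the parameters
params_hash <- function(params) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  save_params(params, tmp)
  unname(tools::md5sum(tmp))
}

#' Write run metadata as JSON
#'
#' Records the provenance of a simulation output: package version, method,
#' seed, an md5 hash of the canonical parameter file, the full parameter
#' set, and any extra fields.
#'
#' @param path Output JSON path.
#' @param method Simulation method label (e.g. `"FRM"`, `"NSM"`).
#' @param seed Integer RNG seed used.
#' @param params The `adhesion_params` used.
#' @param ... Further named scalar fields to record.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(path, method, seed, params, ...) {
  lst <- list(package = "adhesim",
              version = as.character(utils::packageVersion("adhesim")),
              method = method, seed = seed,
              params_hash = params_hash(params))
  extra <- list(...)
  lst <- c(lst, extra)
  plist <- unclass(params)
  plist$K_ratios <- NULL
  plist$rate_constants <- lapply(plist$rate_constants, as.list)
  lst$params <- plist
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
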