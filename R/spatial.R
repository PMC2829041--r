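#' One-dimensional periodic lattice along the leading edge
#'
#' Discretizes the leading edge into `n_sub` well-mixed subvolumes on a
#' ring. The node spacing is tied to the Rac length constant,
#' `L_r = sqrt(D_r / k_d_r)`, so that the hop frequency per direction,
#' `D_r / L_r^2`, equals the Rac deactivation rate `k_d_r`. With the
#' base-case values `D_r = 15` um^2/min and `k_d_r = 4` /min this gives a
#' spacing of ~1.94 um and a hop frequency of 4 /min.
#'
#' @param n_sub Number of subvolumes (integer `>= 1`).
#' @param D_r Rac diffusion coefficient (um^2/min, `>= 0`). Only active Rac
#'   diffuses; all other species are immobile adhesion components.
#' @param k_d_r Rac deactivation rate constant (1/min, `> 0`).
#' @param spacing_um Node spacing; defaults to the Rac length constant and
#'   must be supplied explicitly in the degenerate zero-diffusion case
#'   (`D_r = 0` gives hop rate 0 and fully decoupled subvolumes, but no
#'   intrinsic length scale).
#' @return An object of class `adhesim_lattice` with fields `n_sub`,
#'   `spacing_um`, `length_um`, `hop_rate` (per direction, 1/min), `D_r`
#'   and `k_d_r`.
#' @export
build_lattice <- function(n_sub = 20, D_r = 15, k_d_r = 4, spacing_um = NULL) {
  if (length(n_sub) != 1 || !is.finite(n_sub) || n_sub < 1 ||
      abs(n_sub - round(n_sub)) > 1e-9)
    stop("n_sub must be a positive integer")
  if (!is.finite(D_r) || D_r < 0)
    stop("D_r must be non-negative")
  if (!is.finite(k_d_r) || k_d_r <= 0) stop("k_d_r must be positive")
  if (D_r == 0 && is.null(spacing_um))
    stop("D_r = 0 leaves the node spacing undefined; supply spacing_um ",
         "explicitly for a decoupled lattice")
  spacing <- if (is.null(spacing_um)) sqrt(D_r / k_d_r) else spacing_um
  if (!is.finite(spacing) || spacing <= 0) stop("spacing_um must be positive")
  structure(list(n_sub = as.integer(round(n_sub)), spacing_um = spacing,
                 length_um = n_sub * spacing, hop_rate = D_r / spacing^2,
                 D_r = D_r, k_d_r = k_d_r),
            class = "adhesim_lattice")
}

#' @export
print.adhesim_lattice <- function(x, ...) {
  cat(sprintf(paste0("periodic 1-D lattice: %d subvolumes, spacing %.4g um",
                     " (edge length %.4g um), hop rate %.4g /min per direction\n"),
              x$n_sub, x$spacing_um, x$length_um, x$hop_rate))
  invisible(x)
}

#' Spatial stochastic simulation: Next Subvolume Method
#'
#' Simulates the molecule-number model on a 1-D periodic lattice of
#' well-mixed subvolumes. Each subvolume carries the full 18-channel
#' reaction network at scale `N_star`; active Rac additionally hops to
#' either neighbour at the lattice hop rate. The Next Subvolume Method
#' keeps per-subvolume total propensities in an indexed priority queue, so
#' each event touches only the affected subvolume(s). With `n_sub = 1` the
#' hop channels are a self-loop and the dynamics reduce exactly to the
#' single-compartment model.
#'
#' @inheritParams simulate_frm
#' @param lattice An [build_lattice()] object. Its `D_r` must equal the
#'   reaction parameters' `D_r` (the hop rate is a lattice property).
#' @param state0 Optional `n_sub x 6` integer matrix of initial counts
#'   (columns `N, S, M, X, R, P`); default all zero.
#' @return An object of class `adhesim_spatial`: a list with `t` (sample
#'   times), `counts` (list of `n_sub x length(t)` integer matrices per
#'   species), `v` (matrix of per-subvolume protrusion velocities),
#'   `lattice`, and attributes `params`, `scaling`, `seed`, `n_events`.
#' @export
simulate_nsm <- function(reactions, lattice, state0 = NULL, t_end, seed,
                         dt_out = 0.5, max_events = 1e8) {
  if (t_end <= 0) stop("t_end must be positive")
  stopifnot(inherits(lattice, "adhesim_lattice"))
  rs <- resolve_reactions(reactions)
  if (abs(lattice$D_r - rs$params$D_r) > 1e-9 * max(1, rs$params$D_r))
    stop("lattice D_r does not match params$D_r")
  if (is.null(state0)) {
    state0 <- matrix(0L, lattice$n_sub, 6)
  } else {
    state0 <- as.matrix(state0)
    if (nrow(state0) != lattice$n_sub || ncol(state0) != 6)
      stop("state0 must be an n_sub x 6 count matrix")
    apply(state0, 1, function(z) discrete_state(z[1], z[2], z[3], z[4], z[5], z[6]))
    storage.mode(state0) <- "integer"
  }
  set.seed(seed)
  raw <- .simulate_nsm_cpp(param_vector(rs$params), rs$scaling$N_star,
                           rs$scaling$K_m, rs$scaling$K_r, state0,
                           lattice$hop_rate, t_end, dt_out, max_events)
  structure(list(t = raw$t, counts = raw$counts, v = raw$v, lattice = lattice),
            class = "adhesim_spatial", params = rs$params,
            scaling = rs$scaling, seed = seed, n_events = raw$n_events)
}

#' @export
print.adhesim_spatial <- function(x, ...) {
  cat(sprintf("adhesim spatial simulation: %d subvolumes x %d samples over %g min (%g events)\n",
              x$lattice$n_sub, length(x$t), max(x$t), attr(x, "n_events")))
  invisible(x)
}

#' Extract a single-subvolume count trajectory
#'
#' @param spatial An `adhesim_spatial` result.
#' @param subvolume Subvolume index (1-based).
#' @return An `adhesim_trajectory` data.frame in count units.
#' @export
subvolume_trajectory <- function(spatial, subvolume = 1) {
  stopifnot(inherits(spatial, "adhesim_spatial"))
  k <- subvolume
  if (k < 1 || k > spatial$lattice$n_sub) stop("subvolume out of range")
  df <- data.frame(t = spatial$t,
                   N = spatial$counts$N[k, ], S = spatial$counts$S[k, ],
                   M = spatial$counts$M[k, ], X = spatial$counts$X[k, ],
                   R = spatial$counts$R[k, ], P = spatial$counts$P[k, ],
                   v = spatial$v[k, ])
  structure(df, class = c("adhesim_trajectory", "data.frame"),
            units = "counts", method = "NSM", seed = attr(spatial, "seed"),
            params = attr(spatial, "params"), scaling = attr(spatial, "scaling"),
            n_events = attr(spatial, "n_events"))
}

#' Velocity map from a spatial simulation
#'
#' Packages the per-subvolume protrusion-velocity kymograph as a
#' `velocity_map` (positions x time), the object consumed by the
#' segmentation and map I/O routines. The model's dimensionless velocity
#' (0..1) is converted to nm/s by a linear scale.
#'
#' @param spatial An `adhesim_spatial` result.
#' @param v_scale Edge speed, in nm/s, corresponding to `v = 1`
#'   (default 10).
#' @return A [velocity_map()] object.
#' @export
spatial_velocity_map <- function(spatial, v_scale = 10) {
  stopifnot(inherits(spatial, "adhesim_spatial"))
  velocity_map(spatial$v * v_scale, t = spatial$t,
               y = (seq_len(spatial$lattice$n_sub) - 1) * spatial$lattice$spacing_um)
}

#' Render a kymograph as a grayscale PNG
#'
#' Writes a positions-by-time image of either the protrusion-velocity map
#' (pixel intensity `1 - v / max`, so fast protrusion is black) or an
#' adhesion-count map scaled by its maximum. Masked velocity-map cells are
#' rendered white.
#'
#' @param x A `velocity_map` or a numeric positions-x-time matrix (e.g. a
#'   count matrix from an `adhesim_spatial` result).
#' @param path Output PNG path.
#' @param invert If `TRUE` (default) large values are dark.
#' @return `path`, invisibly.
#' @export
render_kymograph <- function(x, path, invert = TRUE) {
  if (inherits(x, "velocity_map")) {
    m <- x$v
    m[x$mask] <- NA
  } else m <- as.matrix(x)
  if (!is.numeric(m) || length(dim(m)) != 2)
    stop("x must be a velocity_map or a numeric matrix")
  top <- max(m, 0, na.rm = TRUE)
  img <- if (top > 0) pmin(pmax(m / top, 0), 1) else m * 0
  if (invert) img <- 1 - img
  img[is.na(img)] <- 1
  png::writePNG(img, target = path)
  invisible(path)
}
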