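# Phase-plane analysis: nullclines in (v, s) space, fixed points with
# stability, and fixed-point multiplicity maps over (k_ecm, E_s).
#
# All computations exploit the closed-form quasi-steady parametrization of
# the fast signaling subsystem by active Rac r (see qss_closed): at QSS
# x = r, p and n are explicit in (r, s), and v is invertible for r at given
# s, so both nullclines reduce to scalar root-finds and fixed points to a
# two-dimensional root-find in (r, s).

# internal: steady-state residuals of the slow (n, s) subsystem at a point
# of the fast quasi-steady manifold, parametrized by (r, s)
slow_residuals <- function(r, s, params) {
  q <- qss_closed(r, s, params)
  pv <- param_vector(params)
  c(pv[["k_ecm"]] * q$v - q$lam * q$n,
    pv[["k_a_s"]] * q$f * q$n - pv[["k_d_s"]] * (1 + pv[["C_s"]] * q$v) * s)
}

# internal: invert the velocity law for r at given (v, s); NA if v is
# unreachable (below the basal drive or above the saturation ceiling)
rac_from_velocity <- function(v, s, params) {
  h <- v * feedback_g(s, params)
  if (h >= 1) return(NA_real_)
  r <- params$K_v * h / (1 - h) - params$v0
  if (r < 0) NA_real_ else r
}

#' Compute a nullcline in (v, s) space
#'
#' Samples the locus `dn/dt = 0` (n-nullcline) or `ds/dt = 0` (s-nullcline)
#' under the quasi-steady assumption for the faster variables (`m = s`; `x`,
#' `r`, `p` at their steady-state relation to `n`). Curves are reported in
#' the experimentally accessible `(v, s)` plane; multivalued curves are
#' returned as multiple ordered branches.
#'
#' @param which `"n"` or `"s"`.
#' @inheritParams feedback_f
#' @param resolution Number of `v` samples (`>= 16`).
#' @param s_max Upper end of the stable-adhesion window; by default chosen
#'   adaptively as 3 times the largest s-nullcline value.
#' @return A data.frame of class `adhesim_nullcline` with columns `v`, `s`,
#'   `n`, `branch` and `residual` (the corresponding time derivative,
#'   re-evaluated through [model_rhs()]), plus attributes `which` and
#'   `params`. Zero rows (with a `diagnostic` attribute) if no solution lies
#'   in the scanned window.
#' @export
compute_nullcline <- function(which = c("n", "s"), params, resolution = 200,
                              s_max = NULL) {
  which <- match.arg(which)
  if (resolution < 16) stop("resolution must be at least 16")
  if (is.null(s_max)) s_max <- 3 * max(s_nullcline_scale(params), 1e-3)
  pv <- param_vector(params)
  resfun <- if (which == "n") {
    function(v, s) {
      r <- rac_from_velocity(v, s, params)
      if (is.na(r)) return(NA_real_)
      slow_residuals(r, s, params)[1]
    }
  } else {
    function(v, s) {
      r <- rac_from_velocity(v, s, params)
      if (is.na(r)) return(NA_real_)
      slow_residuals(r, s, params)[2]
    }
  }
  v_grid <- seq(1e-4, 1 - 1e-4, length.out = resolution)
  s_grid <- c(0, 10^seq(-4, log10(max(s_max, 1e-3)), length.out = 240))
  rows <- list()
  emit <- function(v, s) {
    r <- rac_from_velocity(v, s, params)
    q <- qss_closed(r, s, params)
    full <- c(n = q$n, s = s, m = s, x = r, r = r, p = q$p)
    rows[[length(rows) + 1]] <<- data.frame(
      v = v, s = s, n = q$n,
      residual = rhs_raw(full, params)[[which]])
  }
  if (which == "n") {
    # dn/dt can be independent of s (zero feedback gains), so the
    # n-nullcline is scanned in v at fixed s
    for (s in s_grid) {
      val <- vapply(v_grid, function(v) resfun(v, s), numeric(1))
      ok <- which(!is.na(val))
      if (length(ok) < 2) next
      vv <- val[ok]; vs <- v_grid[ok]
      flips <- which(vv[-1] * vv[-length(vv)] <= 0 & vv[-1] != vv[-length(vv)])
      for (i in flips)
        emit(uniroot(function(v) resfun(v, s), c(vs[i], vs[i + 1]),
                     tol = 1e-14)$root, s)
    }
  } else {
    for (v in v_grid) {
      val <- vapply(s_grid, function(s) resfun(v, s), numeric(1))
      ok <- which(!is.na(val))
      if (length(ok) < 2) next
      vv <- val[ok]; ss <- s_grid[ok]
      flips <- which(vv[-1] * vv[-length(vv)] <= 0 & vv[-1] != vv[-length(vv)])
      for (i in flips)
        emit(v, uniroot(function(s) resfun(v, s), c(ss[i], ss[i + 1]),
                        tol = 1e-14)$root)
    }
  }
  if (!length(rows)) {
    out <- data.frame(v = numeric(0), s = numeric(0), n = numeric(0),
                      branch = integer(0), residual = numeric(0))
    attr(out, "diagnostic") <- "no nullcline solution in the scanned window"
  } else {
    out <- do.call(rbind, rows)
    out$branch <- link_branches(out$v, out$s, s_max)
    out <- out[order(out$branch, out$v), c("v", "s", "n", "branch", "residual")]
  }
  structure(out, class = c("adhesim_nullcline", "data.frame"),
            which = which, params = params, s_max = s_max)
}

# internal: scale of the s-nullcline, used for the adaptive window (the
# largest s balancing maturation against spontaneous-plus-convective loss,
# probed over the (v, s) plane on a coarse grid)
s_nullcline_scale <- function(params) {
  best <- 0
  for (v in seq(0.02, 0.98, length.out = 25)) {
    f2 <- function(s) {
      r <- rac_from_velocity(v, s, params)
      if (is.na(r)) return(NA_real_)
      slow_residuals(r, s, params)[2]
    }
    s_hi <- 1e4
    val0 <- f2(0)
    if (is.na(val0)) next
    grid <- 10^seq(-4, log10(s_hi), length.out = 120)
    val <- vapply(grid, f2, numeric(1))
    ok <- !is.na(val)
    flips <- which(diff(sign(val[ok])) != 0)
    if (length(flips)) best <- max(best, grid[ok][max(flips) + 1])
  }
  best
}

# internal: greedy continuity-based branch assignment for nullcline samples
link_branches <- function(v, s, s_scale) {
  ord <- order(v, s)
  branch <- integer(length(v))
  active_s <- numeric(0); active_id <- integer(0)
  next_id <- 1L
  tol <- 0.12 * max(s_scale, 1)
  for (vu in unique(v[ord])) {
    idx <- which(v == vu)
    used <- logical(length(active_id))
    for (i in idx) {
      if (length(active_id)) {
        d <- abs(active_s - s[i]); d[used] <- Inf
        j <- which.min(d)
      }
      if (length(active_id) && d[j] < tol) {
        branch[i] <- active_id[j]; active_s[j] <- s[i]; used[j] <- TRUE
      } else {
        branch[i] <- next_id
        active_id <- c(active_id, next_id); active_s <- c(active_s, s[i])
        used <- c(used, TRUE)
        next_id <- next_id + 1L
      }
    }
    keep <- used
    active_id <- active_id[keep]; active_s <- active_s[keep]
  }
  branch
}

#' Locate all fixed points of the model
#'
#' Finds the intersections of the n- and s-nullclines by multi-start damped
#' Newton iteration on the two slow residuals in `(r, s)` coordinates,
#' deduplicates the roots, assembles the full six-variable state for each,
#' and labels stability from the eigenvalues of the full 6x6 Jacobian
#' (the leading reduced slow-system eigenvalues are attached for
#' phase-plane interpretation).
#'
#' @inheritParams feedback_f
#' @param r_starts,s_starts Start grids for the multi-start Newton solve.
#' @return A data.frame of class `adhesim_fixed_points` with columns
#'   `n, s, m, x, r, p, v`, `stability` (`"stable"`, `"unstable"` or
#'   `"saddle"`), `residual` (largest `|rhs|` component; points above 1e-8
#'   are flagged in column `flagged`), `eig1, eig2` (leading reduced
#'   slow-Jacobian eigenvalues, real parts) and `eig_full_max` (largest
#'   real part among the full 6x6 Jacobian eigenvalues, which determines
#'   the label).
#' @export
find_fixed_points <- function(params,
                              r_starts = 10^seq(-5, 1, length.out = 14),
                              s_starts = c(0.01, 0.1, 0.5, 2, 8, 30)) {
  roots <- list()
  for (r0 in r_starts) for (s0 in s_starts) {
    z <- newton2(function(z) slow_residuals(z[1], z[2], params), c(r0, s0))
    if (is.null(z)) next
    dup <- any(vapply(roots, function(q)
      abs(q[1] - z[1]) < 1e-6 * (1 + abs(q[1])) &&
        abs(q[2] - z[2]) < 1e-6 * (1 + abs(q[2])), logical(1)))
    if (!dup) roots[[length(roots) + 1]] <- z
  }
  if (!length(roots)) {
    out <- data.frame(n = numeric(0), s = numeric(0), m = numeric(0),
                      x = numeric(0), r = numeric(0), p = numeric(0),
                      v = numeric(0), stability = character(0),
                      residual = numeric(0), flagged = logical(0),
                      eig1 = numeric(0), eig2 = numeric(0),
                      eig_full_max = numeric(0))
    return(structure(out, class = c("adhesim_fixed_points", "data.frame"),
                     params = params))
  }
  rows <- lapply(roots, function(z) {
    r <- z[1]; s <- z[2]
    q <- qss_closed(r, s, params)
    full <- c(n = q$n, s = s, m = s, x = r, r = r, p = q$p)
    res <- max(abs(rhs_raw(full, params)))
    eig <- reduced_jacobian_eigen(r, s, params)
    eig6 <- full_jacobian_eigen(full, params)
    data.frame(n = q$n, s = s, m = s, x = r, r = r, p = q$p,
               v = q$v, stability = classify_eigen(eig6),
               residual = res, flagged = res >= 1e-8,
               eig1 = Re(eig[1]), eig2 = Re(eig[2]),
               eig_full_max = max(Re(eig6)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$v), ]
  rownames(out) <- NULL
  structure(out, class = c("adhesim_fixed_points", "data.frame"),
            params = params)
}

# internal: damped Newton with non-negativity clipping on (r, s);
# NULL unless converged to max|F| < 1e-10
newton2 <- function(F, z0, max_iter = 60) {
  z <- z0
  for (it in seq_len(max_iter)) {
    Fv <- F(z)
    if (!all(is.finite(Fv))) return(NULL)
    if (max(abs(Fv)) < 1e-11) return(z)
    eps <- pmax(abs(z), 1e-8) * 1e-7
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      zp <- z; zp[j] <- zp[j] + eps[j]
      J[, j] <- (F(zp) - Fv) / eps[j]
    }
    dz <- tryCatch(solve(J, -Fv), error = function(e) NULL)
    if (is.null(dz)) return(NULL)
    t <- 1; zn <- z
    repeat {
      cand <- pmax(z + t * dz, 0)
      Fc <- F(cand)
      if (all(is.finite(Fc)) && sum(Fc^2) < sum(Fv^2)) { zn <- cand; break }
      t <- t / 2
      if (t < 1e-7) { zn <- pmax(z + t * dz, 0); break }
    }
    if (max(abs(zn - z)) < 1e-15 * (1 + max(abs(z)))) {
      return(if (max(abs(F(zn))) < 1e-10) zn else NULL)
    }
    z <- zn
  }
  if (max(abs(F(z))) < 1e-10) z else NULL
}

# internal: eigenvalues of the reduced slow Jacobian at a fixed point.
# The slow state is (n, s); the fast manifold branch through the fixed
# point is followed by continuation in r (implicit inversion of n(r, s)).
reduced_jacobian_eigen <- function(r_star, s_star, params) {
  q0 <- qss_closed(r_star, s_star, params)
  n_star <- q0$n
  slow_rhs <- function(n, s) {
    r <- invert_n_local(n, s, r_star, params)
    q <- qss_closed(r, s, params)
    pv <- param_vector(params)
    c(pv[["k_ecm"]] * q$v - q$lam * n,
      pv[["k_a_s"]] * q$f * n - pv[["k_d_s"]] * (1 + pv[["C_s"]] * q$v) * s)
  }
  z0 <- c(n_star, s_star)
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    h <- 1e-6 * max(abs(z0[j]), 1e-4)
    zp <- z0; zm <- z0
    zp[j] <- zp[j] + h; zm[j] <- max(zm[j] - h, 0)
    J[, j] <- (slow_rhs(zp[1], zp[2]) - slow_rhs(zm[1], zm[2])) / (zp[j] - zm[j])
  }
  eigen(J, only.values = TRUE)$values
}

# internal: local Newton inversion of n(r, s) = n for r, seeded near r_ref
# so differentiation stays on the branch through the fixed point
invert_n_local <- function(n, s, r_ref, params) {
  r <- max(r_ref, 1e-12)
  for (it in 1:50) {
    fr <- qss_closed(r, s, params)$n - n
    if (abs(fr) < 1e-13 * max(1, n)) break
    h <- 1e-7 * max(r, 1e-8)
    d <- (qss_closed(r + h, s, params)$n - qss_closed(max(r - h, 0), s, params)$n) /
      (r + h - max(r - h, 0))
    step <- fr / d
    step <- sign(step) * min(abs(step), 0.5 * max(r, 1e-6))
    r <- max(r - step, 0)
  }
  r
}

classify_eigen <- function(eig) {
  re <- Re(eig)
  tol <- 1e-9 * max(1, abs(re))
  if (all(re < tol)) "stable"
  else if (any(re < -tol)) "saddle"
  else "unstable"
}

# internal: eigenvalues of the full 6x6 Jacobian of the deterministic
# right-hand side at a state, by central finite differences
full_jacobian_eigen <- function(state, params) {
  J <- matrix(0, 6, 6)
  for (j in 1:6) {
    h <- 1e-6 * max(abs(state[j]), 1e-4)
    zp <- state; zm <- state
    zp[j] <- zp[j] + h; zm[j] <- max(zm[j] - h, 0)
    J[, j] <- (rhs_raw(zp, params) - rhs_raw(zm, params)) / (zp[j] - zm[j])
  }
  eigen(J, only.values = TRUE)$values
}

#' Map fixed-point multiplicity over (k_ecm, E_s)
#'
#' Runs [find_fixed_points()] on every cell of a `(k_ecm, E_s)` grid at
#' fixed `I_n` and `C_s`, recording the number of fixed points and, for
#' monostable cells, whether the unique state is low or high protrusion
#' (`v` below/above 0.5). Cells with exactly two roots sit on a
#' saddle-node boundary and are flagged rather than rounded.
#'
#' @param k_ecm_grid,E_s_grid Strictly increasing parameter grids.
#' @param I_n,C_s Fixed feedback/removal parameters for the scan.
#' @inheritParams feedback_f
#' @return An object of class `adhesim_bifurcation_map`: a list with
#'   `k_ecm`, `E_s`, integer `multiplicity` matrix
#'   (rows = k_ecm, cols = E_s), character `regime` matrix
#'   (`"monostable_low"`, `"monostable_high"`, `"multistable"`,
#'   `"boundary"`), and the parameter set used.
#' @export
bifurcation_scan <- function(k_ecm_grid, E_s_grid, I_n = 0, C_s = 10,
                             params = base_case_params()) {
  if (is.unsorted(k_ecm_grid, strictly = TRUE) ||
      is.unsorted(E_s_grid, strictly = TRUE))
    stop("grids must be strictly increasing")
  nk <- length(k_ecm_grid); ne <- length(E_s_grid)
  mult <- matrix(NA_integer_, nk, ne)
  regime <- matrix(NA_character_, nk, ne)
  for (i in seq_len(nk)) for (j in seq_len(ne)) {
    p <- update_params(params, k_ecm = k_ecm_grid[i], E_s = E_s_grid[j],
                       I_n = I_n, C_s = C_s)
    fp <- find_fixed_points(p)
    m <- nrow(fp)
    mult[i, j] <- m
    regime[i, j] <-
      if (m >= 3) "multistable"
      else if (m == 2) "boundary"
      else if (m == 1 && fp$v[1] >= 0.5) "monostable_high"
      else "monostable_low"
  }
  structure(list(k_ecm = k_ecm_grid, E_s = E_s_grid,
                 multiplicity = mult, regime = regime,
                 I_n = I_n, C_s = C_s, params = params),
            class = "adhesim_bifurcation_map")
}

#' @export
as.data.frame.adhesim_bifurcation_map <- function(x, ...) {
  data.frame(k_ecm = rep(x$k_ecm, times = length(x$E_s)),
             E_s = rep(x$E_s, each = length(x$k_ecm)),
             multiplicity = as.vector(x$multiplicity),
             regime = as.vector(x$regime))
}

#' @export
print.adhesim_bifurcation_map <- function(x, ...) {
  cat(sprintf("Fixed-point multiplicity map: %d k_ecm x %d E_s cells (I_n = %g, C_s = %g)\n",
              length(x$k_ecm), length(x$E_s), x$I_n, x$C_s))
  cat(sprintf("  multistable cells: %d of %d\n",
              sum(x$multiplicity >= 3), length(x$multiplicity)))
  invisible(x)
}

#' Plot a multiplicity map as a heat map
#'
#' @param x An `adhesim_bifurcation_map`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.adhesim_bifurcation_map <- function(x, ...) {
  graphics::image(log10(x$k_ecm), x$E_s, x$multiplicity,
                  xlab = "log10 k_ecm (1/min)", ylab = "E_s",
                  main = "fixed-point multiplicity", ...)
  invisible(x)
}
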