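#' Myosin feedback on adhesion maturation
#'
#' The maturation-enhancement factor `f(m) = 1 + E_s * m`: a conservative
#' linear form. With `E_s = 0` the feedback is off and `f` is identically 1;
#' with `E_s > 0` it is strictly increasing in the myosin density `m`.
#'
#' @param m Dimensionless recruited-myosin density (vectorized, `>= 0`).
#' @param params An `adhesion_params` object.
#' @return Dimensionless multiplier(s) `>= 1`.
#' @export
feedback_f <- function(m, params) {
  if (any(m < 0)) stop("myosin density m must be non-negative")
  1 + params$E_s * m
}

#' Stable-adhesion inhibition of protrusion
#'
#' The protrusion-inhibition factor `g(s) = 1 + I_n * s`. With `I_n = 0` the
#' inhibition is off and `g` is identically 1. `g` divides the realized
#' protrusion velocity, so only at low stable-adhesion density are
#' appreciable velocities allowed when `I_n` is large.
#'
#' @param s Dimensionless stable-adhesion density (vectorized, `>= 0`).
#' @inheritParams feedback_f
#' @return Dimensionless multiplier(s) `>= 1`.
#' @export
feedback_g <- function(s, params) {
  if (any(s < 0)) stop("stable-adhesion density s must be non-negative")
  1 + params$I_n * s
}

#' Protrusion velocity law
#'
#' Velocity responds to active Rac in a saturable manner and is divisively
#' inhibited by stable adhesions:
#' `v = (v0 + r) / (v0 + r + K_v) / g(s)`.
#' `v` is a dimensionless fraction of the maximum attainable velocity, so
#' `v` lies in `[0, 1]`, is non-decreasing in `r`, tends to `1/g(s)` for
#' large `r`, and is non-increasing in `s` when `I_n > 0`. The small basal
#' drive `v0` keeps `v > 0` at zero Rac, which is what allows nascent
#' adhesions to form from an all-zero initial state.
#'
#' @param r Dimensionless active-Rac density (vectorized, `>= 0`).
#' @param s Dimensionless stable-adhesion density (vectorized, `>= 0`).
#' @inheritParams feedback_f
#' @return Velocity value(s) in `[0, 1]`.
#' @export
protrusion_velocity <- function(r, s, params) {
  if (any(r < 0)) stop("active-Rac density r must be non-negative")
  if (any(s < 0)) stop("stable-adhesion density s must be non-negative")
  (params$v0 + r) / (params$v0 + r + params$K_v) / feedback_g(s, params)
}

# internal: closed forms along the fast-subsystem quasi-steady manifold,
# parametrized by active Rac r (at QSS x = r) at given s. Vectorized over r.
qss_closed <- function(r, s, params) {
  pv <- param_vector(params)
  g <- 1 + pv[["I_n"]] * s
  v <- (pv[["v0"]] + r) / (pv[["v0"]] + r + pv[["K_v"]]) / g
  f <- 1 + pv[["E_s"]] * s
  lam <- pv[["k_d_n"]] * v + pv[["k_a_s"]] * f
  p <- pv[["k_a_p"]] * r * r / (pv[["k_a_p"]] * r + pv[["k_d_p"]] + pv[["k_d_x"]] + lam)
  phi <- pv[["p0"]] + p
  n <- ifelse(phi > 0,
              r * (1 + (pv[["k_d_x"]] + lam) / (pv[["k_a_x"]] * phi)),
              ifelse(r == 0, 0, Inf))
  list(v = v, f = f, g = g, lam = lam, p = p, phi = phi, n = n)
}

# internal: unvalidated right-hand side; state is c(n,s,m,x,r,p)
rhs_raw <- function(state, params) {
  pv <- param_vector(params)
  n <- state[[1]]; s <- state[[2]]; m <- state[[3]]
  x <- state[[4]]; r <- state[[5]]; p <- state[[6]]
  g <- 1 + pv[["I_n"]] * s
  v <- (pv[["v0"]] + r) / (pv[["v0"]] + r + pv[["K_v"]]) / g
  f <- 1 + pv[["E_s"]] * m
  lam <- pv[["k_d_n"]] * v + pv[["k_a_s"]] * f  # per-capita nascent loss
  c(n = pv[["k_ecm"]] * v - lam * n,
    s = pv[["k_a_s"]] * f * n - pv[["k_d_s"]] * (1 + pv[["C_s"]] * v) * s,
    m = pv[["k_d_m"]] * (s - m),
    x = pv[["k_a_x"]] * (pv[["p0"]] + p) * (n - x) - (pv[["k_d_x"]] + lam) * x,
    r = pv[["k_d_r"]] * (x - r),
    p = pv[["k_a_p"]] * r * (x - p) - (pv[["k_d_p"]] + pv[["k_d_x"]] + lam) * p)
}

#' Deterministic right-hand side of the model
#'
#' Time derivatives of the six dimensionless densities. Nascent adhesions
#' form at rate `k_ecm * v`, are turned over at `k_d_n * v * n` (both
#' coupled to protrusion) and mature at `k_a_s * f(m) * n`; stable adhesions
#' gain the maturation flux and are lost by spontaneous disassembly plus
#' convective removal, `k_d_s * (1 + C_s * v) * s`; myosin relaxes toward
#' the stable-adhesion density, `k_d_m * (s - m)`, so `m = s` at quasi-steady
#' state. The signaling subset variables `x` (phospho-paxillin-bearing
#' nascent adhesions) and `p` (the PAK-active subset of `x`) gain by
#' activation proportional to `(n - x)` and `(x - p)` respectively and share
#' the per-capita turnover/maturation loss of the nascent pool, which keeps
#' `p <= x <= n` invariant along trajectories; active Rac relaxes toward
#' `x`, `k_d_r * (x - r)`.
#'
#' @param state Named numeric vector or list with elements
#'   `n, s, m, x, r, p`, satisfying `0 <= p <= x <= n` and `s, m >= 0`.
#' @inheritParams feedback_f
#' @return Named numeric vector of time derivatives (1/min).
#' @export
model_rhs <- function(state, params) {
  state <- unlist(state)[c("n", "s", "m", "x", "r", "p")]
  if (any(!is.finite(state))) stop("non-finite state")
  tol <- 1e-9 * max(1, max(abs(state)))
  if (any(state < -tol)) stop("state densities must be non-negative")
  if (state[["x"]] > state[["n"]] + tol) stop("invariant violated: x <= n")
  if (state[["p"]] > state[["x"]] + tol) stop("invariant violated: p <= x")
  rhs_raw(pmax(state, 0), params)
}

#' Quasi-steady solution of the signaling circuit
#'
#' Solves the fast signaling subsystem (`x`, `r`, `p`) at steady state for
#' given slow densities `n` and `s`. At quasi-steady state `x` equals `r`, and both
#' `p` and `n` are explicit functions of `r`, so the problem reduces to a
#' one-dimensional root-find in `r`; all branches in the scanned window are
#' reported (the fast subsystem is multivalued near the bistable region),
#' each labeled by local stability of the fast subsystem.
#'
#' @param n,s Dimensionless nascent/stable adhesion densities (`>= 0`).
#' @inheritParams feedback_f
#' @param r_max Upper end of the scanned `r` window; extended automatically
#'   if the solution might lie beyond it.
#' @return A data.frame with one row per branch: columns `x`, `r`, `p`, `v`,
#'   `stable` (logical, fast-subsystem stability) and `residual` (largest
#'   absolute steady-state residual of the three fast equations).
#' @export
signaling_quasi_steady <- function(n, s, params, r_max = NULL) {
  if (n < 0 || s < 0) stop("n and s must be non-negative")
  roots <- numeric(0)
  if (n == 0 || params$p0 == 0) roots <- 0  # dark state is exact
  if (n > 0) {
    if (is.null(r_max)) r_max <- max(4 * n, 1)
    fn <- function(r) qss_closed(r, s, params)$n - n
    for (tries in 1:6) {
      grid <- c(0, 10^seq(log10(max(n, 1e-8)) - 6, log10(r_max), length.out = 400))
      val <- vapply(grid, fn, numeric(1))
      val[1] <- if (params$p0 > 0) -n else val[2]
      sgn <- sign(val)
      idx <- which(sgn[-1] * sgn[-length(sgn)] < 0 |
                     (sgn[-length(sgn)] != 0 & sgn[-1] == 0))
      if (length(idx) && val[length(val)] > 0) {
        for (i in idx) {
          lo <- max(grid[i], 1e-300)
          root <- uniroot(fn, c(lo, grid[i + 1]), tol = 1e-14)$root
          # polish by bisection on a tight bracket to push residual below 1e-10
          roots <- c(roots, polish_qss_root(fn, root, lo, grid[i + 1]))
        }
        break
      }
      r_max <- r_max * 10
      if (tries == 6)
        stop("signaling_quasi_steady failed to bracket a solution; residual at r_max = ",
             signif(fn(r_max), 3))
    }
  }
  roots <- sort(unique(roots))
  out <- do.call(rbind, lapply(roots, function(r) {
    q <- qss_closed(r, s, params)
    x <- r
    p <- q$p
    st <- c(n, s, s, x, r, p)
    res <- rhs_raw(st, params)[c("x", "r", "p")]
    data.frame(x = x, r = r, p = p,
               v = protrusion_velocity(r, s, params),
               stable = fast_subsystem_stable(n, s, x, r, p, params),
               residual = max(abs(res)))
  }))
  # drop spurious duplicates from grid-edge double counting
  out[!duplicated(signif(out$r, 10)), , drop = FALSE]
}

polish_qss_root <- function(fn, root, lo, hi) {
  for (i in 1:200) {
    fr <- fn(root)
    if (abs(fr) < 1e-13) break
    if (sign(fr) == sign(fn(lo))) lo <- root else hi <- root
    root <- (lo + hi) / 2
  }
  root
}

# internal: stability of the fast (x, r, p) subsystem at fixed (n, s)
fast_subsystem_stable <- function(n, s, x, r, p, params) {
  fast_rhs <- function(z) rhs_raw(c(n, s, s, z[1], z[2], z[3]), params)[c("x", "r", "p")]
  z0 <- c(x, r, p)
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    h <- 1e-7 * max(abs(z0[j]), 1e-4)
    zp <- z0; zm <- z0
    zp[j] <- zp[j] + h; zm[j] <- max(zm[j] - h, 0)
    J[, j] <- (fast_rhs(zp) - fast_rhs(zm)) / (zp[j] - zm[j])
  }
  all(Re(eigen(J, only.values = TRUE)$values) < 1e-8)
}

#' Integrate the deterministic model
#'
#' Adaptive stiff integration (lsoda; relative tolerance 1e-8, absolute
#' 1e-10) with dense output on a uniform grid. The output grid does not
#' influence the adaptive stepping.
#'
#' @param state0 Initial state: named vector with `n, s, m, x, r, p` (an
#'   all-zero start is the convention for the stochastic phenotype runs).
#' @inheritParams feedback_f
#' @param t_end Final time (min, `> 0`).
#' @param dt_out Output sampling interval (min).
#' @return An object of class `adhesim_trajectory`: a data.frame with
#'   columns `t, n, s, m, x, r, p, v` and attributes `units`
#'   (`"dimensionless"`), `method` and `params`.
#' @export
integrate_ode <- function(state0, params, t_end, dt_out = 0.5) {
  if (t_end <= 0) stop("t_end must be positive")
  state0 <- unlist(state0)[c("n", "s", "m", "x", "r", "p")]
  times <- seq(0, t_end, by = dt_out)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  sol <- deSolve::ode(
    y = state0, times = times,
    func = function(t, y, parms) list(rhs_raw(pmax(y, 0), parms)),
    parms = params, method = "lsoda", rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0)
    stop("stiff integration failed; last accepted time ",
         signif(max(sol[, "time"]), 6), " min")
  df <- as.data.frame(sol)
  names(df)[1] <- "t"
  df[-1] <- lapply(df[-1], pmax, 0)
  df$v <- protrusion_velocity(df$r, df$s, params)
  structure(df, class = c("adhesim_trajectory", "data.frame"),
            units = "dimensionless", method = "lsoda", params = params)
}
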