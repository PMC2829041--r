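#' Number-density scaling for stochastic simulation
#'
#' Converts the dimensionless model to molecule counts. Adhesion-type
#' species (`N`, `S`, `X`, `P`) use the scale `N_star` (`n = N / N_star`);
#' recruited myosin and active Rac are amplified relative to their
#' activators, `M = m * K_m * N_star` and `R = r * K_r * N_star`, with the
#' amplification ratios equal to `K_m = k_a_m / k_d_m` and
#' `K_r = k_a_r / k_d_r`. The default `K_m = K_r = 10` matches the
#' base-case rate constants; if you change one you must change the other to
#' keep the count model consistent with the density model (enforced by
#' [compile_reactions()]).
#'
#' @param N_star Integer-valued number-density scale (`>= 1`). Low values
#'   make stochastic effects prominent; large values approach the
#'   deterministic limit.
#' @param K_m,K_r Amplification ratios (`> 0`).
#' @return An object of class `scaling_spec`.
#' @export
scaling_spec <- function(N_star, K_m = 10, K_r = 10) {
  if (N_star < 1 || abs(N_star - round(N_star)) > 1e-9)
    stop("N_star must be an integer >= 1")
  if (K_m <= 0 || K_r <= 0) stop("K_m and K_r must be positive")
  structure(list(N_star = as.integer(round(N_star)), K_m = K_m, K_r = K_r),
            class = "scaling_spec")
}

#' Discrete molecule-count state
#'
#' @param N,S,M,X,R,P Non-negative integer counts with `X <= N`, `P <= X`.
#' @return Named integer vector of class `discrete_state`.
#' @export
discrete_state <- function(N = 0, S = 0, M = 0, X = 0, R = 0, P = 0) {
  z <- c(N = N, S = S, M = M, X = X, R = R, P = P)
  if (any(z < 0) || any(abs(z - round(z)) > 1e-9))
    stop("counts must be non-negative integers")
  z <- as.integer(round(z)); names(z) <- c("N", "S", "M", "X", "R", "P")
  if (z[["X"]] > z[["N"]]) stop("invariant violated: X <= N")
  if (z[["P"]] > z[["X"]]) stop("invariant violated: P <= X")
  structure(z, class = "discrete_state")
}

#' Compile the reaction-channel representation of the model
#'
#' Decomposes the deterministic rates into 18 elementary reaction channels
#' with integer stoichiometry and non-negative propensities. Turnover,
#' maturation and dephosphorylation are subset-resolved (separate channels
#' act on plain, phospho-only and PAK-bearing nascent adhesions), so the
#' summed channel drift equals the count-scaled deterministic rates at
#' every state and the invariants `P <= X <= N` are preserved without
#' clamping. Propensities equal the appropriate count scale times the
#' dimensionless rate evaluated at the mapped densities.
#'
#' @inheritParams feedback_f
#' @param scaling A [scaling_spec()]. Its `K_m`, `K_r` must equal the
#'   corresponding rate-constant ratios in `params`.
#' @return A list of class `reaction_set`; each element has `name`,
#'   `stoichiometry` (named integer vector over `N,S,M,X,R,P`) and
#'   `propensity` (a function of a count state). The parameter set and
#'   scaling are attached as attributes and used by the simulators.
#' @export
compile_reactions <- function(params, scaling) {
  stopifnot(inherits(scaling, "scaling_spec"))
  validate_params(params)
  for (sp in c("m", "r")) {
    K_req <- if (sp == "m") scaling$K_m else scaling$K_r
    if (params$rate_constants[[sp]][["k_d"]] == 0) next # inert species
    if (abs(params$K_ratios[[sp]] - K_req) > 1e-9 * max(1, K_req))
      stop("scaling K_", sp, " (", K_req, ") must equal k_a_", sp, "/k_d_", sp,
           " (", params$K_ratios[[sp]], "); change both together")
  }
  pv <- param_vector(params)
  Ns <- scaling$N_star; Km <- scaling$K_m; Kr <- scaling$K_r
  vfun <- function(z) {
    r <- z[["R"]] / (Kr * Ns); s <- z[["S"]] / Ns
    (pv[["v0"]] + r) / (pv[["v0"]] + r + pv[["K_v"]]) / (1 + pv[["I_n"]] * s)
  }
  ffun <- function(z) 1 + pv[["E_s"]] * z[["M"]] / (Km * Ns)
  sto <- function(...) {
    z <- setNames(integer(6), c("N", "S", "M", "X", "R", "P"))
    d <- c(...)
    z[names(d)] <- as.integer(d)
    z
  }
  ch <- function(name, stoichiometry, propensity)
    list(name = name, stoichiometry = stoichiometry, propensity = propensity)
  channels <- list(
    ch("nascent_formation", sto(N = 1),
       function(z) Ns * pv[["k_ecm"]] * vfun(z)),
    ch("turnover_plain", sto(N = -1),
       function(z) pv[["k_d_n"]] * vfun(z) * (z[["N"]] - z[["X"]])),
    ch("turnover_phospho", sto(N = -1, X = -1),
       function(z) pv[["k_d_n"]] * vfun(z) * (z[["X"]] - z[["P"]])),
    ch("turnover_pak", sto(N = -1, X = -1, P = -1),
       function(z) pv[["k_d_n"]] * vfun(z) * z[["P"]]),
    ch("maturation_plain", sto(N = -1, S = 1),
       function(z) pv[["k_a_s"]] * ffun(z) * (z[["N"]] - z[["X"]])),
    ch("maturation_phospho", sto(N = -1, S = 1, X = -1),
       function(z) pv[["k_a_s"]] * ffun(z) * (z[["X"]] - z[["P"]])),
    ch("maturation_pak", sto(N = -1, S = 1, X = -1, P = -1),
       function(z) pv[["k_a_s"]] * ffun(z) * z[["P"]]),
    ch("stable_disassembly", sto(S = -1),
       function(z) pv[["k_d_s"]] * z[["S"]]),
    ch("stable_convective_removal", sto(S = -1),
       function(z) pv[["k_d_s"]] * pv[["C_s"]] * vfun(z) * z[["S"]]),
    ch("myosin_recruitment", sto(M = 1),
       function(z) pv[["k_a_m"]] * z[["S"]]),
    ch("myosin_decay", sto(M = -1),
       function(z) pv[["k_d_m"]] * z[["M"]]),
    ch("paxillin_phosphorylation", sto(X = 1),
       function(z) pv[["k_a_x"]] * (pv[["p0"]] + z[["P"]] / Ns) * (z[["N"]] - z[["X"]])),
    ch("dephosphorylation_phospho", sto(X = -1),
       function(z) pv[["k_d_x"]] * (z[["X"]] - z[["P"]])),
    ch("dephosphorylation_pak", sto(X = -1, P = -1),
       function(z) pv[["k_d_x"]] * z[["P"]]),
    ch("rac_activation", sto(R = 1),
       function(z) pv[["k_a_r"]] * z[["X"]]),
    ch("rac_deactivation", sto(R = -1),
       function(z) pv[["k_d_r"]] * z[["R"]]),
    ch("pak_activation", sto(P = 1),
       function(z) pv[["k_a_p"]] * z[["R"]] * (z[["X"]] - z[["P"]]) / (Kr * Ns)),
    ch("pak_deactivation", sto(P = -1),
       function(z) pv[["k_d_p"]] * z[["P"]]))
  structure(channels, class = "reaction_set",
            params = params, scaling = scaling)
}

# internal: unify argument handling for the compartment engines
resolve_reactions <- function(reactions) {
  stopifnot(inherits(reactions, "reaction_set"))
  list(params = attr(reactions, "params"), scaling = attr(reactions, "scaling"))
}

build_trajectory <- function(raw, params, scaling, method, seed) {
  df <- data.frame(t = raw$t, raw$counts, v = raw$v)
  structure(df, class = c("adhesim_trajectory", "data.frame"),
            units = "counts", method = method, seed = seed,
            params = params, scaling = scaling, n_events = raw$n_events)
}

#' Exact stochastic simulation: First Reaction Method
#'
#' Simulates the molecule-number model in a single well-mixed leading-edge
#' compartment by the First Reaction Method: at each step every channel
#' draws a candidate firing time and the earliest fires (ties, a
#' probability-zero event, resolved toward the lowest channel index).
#' Protrusion velocity is a derived, deterministic function of the current
#' counts, recomputed after every event. State is recorded on a uniform
#' output grid (sample-and-hold).
#'
#' @param reactions A `reaction_set` from [compile_reactions()].
#' @param state0 A [discrete_state()]; default all-zero counts.
#' @param t_end Simulated duration (min, `> 0`).
#' @param seed Integer RNG seed; identical seeds give identical
#'   trajectories.
#' @param dt_out Output sampling interval (min; default 0.5).
#' @param max_events Safety cap on the number of events.
#' @return An `adhesim_trajectory` data.frame (`t, N, S, M, X, R, P, v`)
#'   with attributes `method`, `seed`, `params`, `scaling`, `n_events`.
#' @export
simulate_frm <- function(reactions, state0 = discrete_state(), t_end, seed,
                         dt_out = 0.5, max_events = 1e8) {
  if (t_end <= 0) stop("t_end must be positive")
  rs <- resolve_reactions(reactions)
  set.seed(seed)
  raw <- .simulate_frm_cpp(param_vector(rs$params), rs$scaling$N_star,
                           rs$scaling$K_m, rs$scaling$K_r,
                           as.integer(state0), t_end, dt_out, max_events)
  build_trajectory(raw, rs$params, rs$scaling, "FRM", seed)
}

#' Exact stochastic simulation: Next Reaction Method
#'
#' Distributionally equivalent to [simulate_frm()] but uses the
#' Gibson-Bruck Next Reaction Method: absolute firing times live in an
#' indexed priority queue and only channels whose propensity depends on a
#' changed species are updated after each event.
#'
#' @inheritParams simulate_frm
#' @return An `adhesim_trajectory`, as for [simulate_frm()].
#' @export
simulate_nrm <- function(reactions, state0 = discrete_state(), t_end, seed,
                         dt_out = 0.5, max_events = 1e8) {
  if (t_end <= 0) stop("t_end must be positive")
  rs <- resolve_reactions(reactions)
  set.seed(seed)
  raw <- .simulate_nrm_cpp(param_vector(rs$params), rs$scaling$N_star,
                           rs$scaling$K_m, rs$scaling$K_r,
                           as.integer(state0), t_end, dt_out, max_events)
  build_trajectory(raw, rs$params, rs$scaling, "NRM", seed)
}

#' Convert a count trajectory to dimensionless densities
#'
#' @param traj An `adhesim_trajectory` in count units.
#' @return A data.frame `t, n, s, m, x, r, p, v` of densities.
#' @export
counts_to_densities <- function(traj) {
  stopifnot(identical(attr(traj, "units"), "counts"))
  sc <- attr(traj, "scaling")
  data.frame(t = traj$t,
             n = traj$N / sc$N_star, s = traj$S / sc$N_star,
             m = traj$M / (sc$K_m * sc$N_star), x = traj$X / sc$N_star,
             r = traj$R / (sc$K_r * sc$N_star), p = traj$P / sc$N_star,
             v = traj$v)
}

#' @export
print.adhesim_trajectory <- function(x, ...) {
  cat(sprintf("adhesim trajectory: %d samples over %g min (%s units",
              nrow(x), max(x$t), attr(x, "units")))
  if (!is.null(attr(x, "method")))
    cat(sprintf("; %s, seed %s, %g events", attr(x, "method"),
                format(attr(x, "seed")), attr(x, "n_events")))
  cat(")\n")
  print.data.frame(utils::head(as.data.frame(x), 4))
  invisible(x)
}

#' Stochastic phenotype matrix
#'
#' Runs stochastic simulations from all-zero initial counts over a factorial
#' grid of ECM coupling, molecule-number scale and feedback gains, and
#' classifies each protrusion-velocity trace with [classify_trace()]. This
#' reproduces, at configurable scale, the matrix-of-phenotypes analysis of
#' leading-edge behavior: minimal protrusion at low ECM, transient and then
#' stable protrusion as ECM rises, and re-suppression at high feedback
#' gains.
#'
#' @param params_base Base `adhesion_params`.
#' @param k_ecm_list,N_star_list,E_s_list,I_n_list Grids to cross.
#' @param t_end Simulated duration per run (min; 1000 in the full-scale
#'   protocol).
#' @param seeds Integer vector: each grid cell is run once per seed.
#' @param burn_in Initial transient excluded from classification (min).
#' @param dt_out Sampling interval (min).
#' @param method `"frm"` or `"nrm"`.
#' @param out_dir Optional directory; when given, each run's `v(t)` and
#'   `S(t)` series are persisted as `trace_<i>.csv`.
#' @return A data.frame with one row per run: the varied parameters, seed,
#'   phenotype `label`, post-burn-in `mean_v` and `max_S`.
#' @export
run_phenotype_matrix <- function(params_base, k_ecm_list, N_star_list,
                                 E_s_list, I_n_list, t_end = 1000, seeds = 1,
                                 burn_in = 100, dt_out = 0.5,
                                 method = c("frm", "nrm"), out_dir = NULL) {
  method <- match.arg(method)
  if (!length(k_ecm_list) || !length(N_star_list) ||
      !length(E_s_list) || !length(I_n_list)) stop("grids must be non-empty")
  grid <- expand.grid(k_ecm = k_ecm_list, N_star = N_star_list,
                      E_s = E_s_list, I_n = I_n_list, seed = seeds,
                      KEEP.OUT.ATTRS = FALSE)
  sim <- if (method == "frm") simulate_frm else simulate_nrm
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- update_params(params_base, k_ecm = g$k_ecm, E_s = g$E_s, I_n = g$I_n)
    rx <- compile_reactions(p, scaling_spec(g$N_star))
    traj <- sim(rx, t_end = t_end, seed = g$seed, dt_out = dt_out)
    post <- traj$t >= burn_in
    lab <- classify_trace(traj$v, traj$t, burn_in = burn_in)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write.csv(data.frame(t = traj$t, v = traj$v, S = traj$S),
                file.path(out_dir, sprintf("trace_%04d.csv", i)),
                row.names = FALSE)
    }
    rows[[i]] <- data.frame(g, label = lab, mean_v = mean(traj$v[post]),
                            max_S = max(traj$S))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
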