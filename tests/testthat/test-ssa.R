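test_that("summed channel drift equals the scaled deterministic rhs", {
  set.seed(42)
  p <- base_case_params(k_ecm = 0.25, E_s = 3, I_n = 2)
  for (Ns in c(3, 50)) {
    sc <- scaling_spec(Ns)
    rx <- compile_reactions(p, sc)
    sto <- t(vapply(rx, `[[`, integer(6), "stoichiometry"))
    for (rep in 1:8) {
      z <- random_state()
      a <- vapply(rx, function(ch) ch$propensity(z), numeric(1))
      expect_true(all(a >= 0))
      drift <- as.vector(t(sto) %*% a)
      dens <- c(n = z[["N"]] / Ns, s = z[["S"]] / Ns, m = z[["M"]] / (10 * Ns),
                x = z[["X"]] / Ns, r = z[["R"]] / (10 * Ns), p = z[["P"]] / Ns)
      rhs <- model_rhs(dens, p)
      scale <- Ns * c(1, 1, 10, 1, 10, 1)  # count scale per species
      expect_equal(drift, unname(rhs * scale), tolerance = 1e-12)
    }
  }
})

test_that("R and C++ propensity routes agree and stoichiometries match", {
  set.seed(7)
  p <- base_case_params(k_ecm = 0.3, E_s = 1.5, I_n = 0.5)
  sc <- scaling_spec(5)
  rx <- compile_reactions(p, sc)
  sto_r <- t(vapply(rx, `[[`, integer(6), "stoichiometry"))
  sto_c <- adhesim:::.stoichiometry_cpp()
  expect_identical(unname(sto_r), matrix(as.integer(sto_c), nrow(sto_c)))
  pv <- adhesim:::param_vector(p)
  for (rep in 1:10) {
    z <- random_state()
    a_r <- vapply(rx, function(ch) ch$propensity(z), numeric(1))
    a_c <- adhesim:::.eval_propensities_cpp(pv, 5, 10, 10, as.numeric(z))
    expect_equal(unname(a_r), as.numeric(a_c), tolerance = 1e-13)
  }
  # X-formation propensity vanishes when every nascent adhesion is phosphorylated
  z <- discrete_state(N = 6, X = 6, P = 2, R = 3)
  i <- which(vapply(rx, `[[`, character(1), "name") == "paxillin_phosphorylation")
  expect_identical(rx[[i]]$propensity(z), 0)
})

test_that("scaling spec is validated against the parameter K-ratios", {
  p <- base_case_params()
  expect_error(scaling_spec(0), "integer")
  expect_error(scaling_spec(3, K_m = -1), "positive")
  expect_error(compile_reactions(p, scaling_spec(3, K_m = 5)), "change both")
  p5 <- update_params(p, k_a_m = 10, k_a_r = 20)  # K_m = K_r = 5
  expect_s3_class(compile_reactions(p5, scaling_spec(3, K_m = 5, K_r = 5)),
                  "reaction_set")
})

test_that("identical seeds reproduce trajectories; zero-propensity terminates", {
  p <- base_case_params(k_ecm = 0.3)
  rx <- compile_reactions(p, scaling_spec(3))
  a <- simulate_frm(rx, t_end = 50, seed = 123)
  b <- simulate_frm(rx, t_end = 50, seed = 123)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "n_events"), attr(b, "n_events"))
  c1 <- simulate_nrm(rx, t_end = 50, seed = 9)
  c2 <- simulate_nrm(rx, t_end = 50, seed = 9)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  # frozen network: k_ecm = 0, p0 = 0, all-zero start
  pz <- base_case_params(k_ecm = 0, p0 = 0)
  rz <- compile_reactions(pz, scaling_spec(3))
  for (sim in list(simulate_frm, simulate_nrm)) {
    tz <- sim(rz, t_end = 100, seed = 4)
    expect_identical(attr(tz, "n_events"), 0)
    expect_true(all(tz[, c("N", "S", "M", "X", "R", "P")] == 0))
    expect_identical(length(unique(tz$v)), 1L)
    expect_true(all(diff(tz$t) > 0))
  }
})

test_that("embedded birth-death toy matches the analytic Poisson stationary law", {
  p <- birth_death_params()
  rx <- compile_reactions(p, scaling_spec(1))
  S0 <- 4L
  mean_target <- p$rate_constants$m[["k_a"]] * S0 / p$rate_constants$m[["k_d"]] # 40
  tr <- simulate_frm(rx, discrete_state(S = S0), t_end = 1500, seed = 21,
                     dt_out = 0.25)
  expect_gt(attr(tr, "n_events"), 1e5)
  post <- tr$t >= 20
  m_bar <- mean(tr$M[post]); m_var <- var(tr$M[post])
  # Poisson: mean = variance = k_a_m S0 / k_d_m, Monte-Carlo tolerance
  expect_equal(m_bar, mean_target, tolerance = 0.05)
  expect_equal(m_var / m_bar, 1, tolerance = 0.15)
  expect_true(all(tr$S == S0))
})

test_that("FRM and NRM event-count distributions agree on the toy network", {
  p <- birth_death_params()
  rx <- compile_reactions(p, scaling_spec(1))
  nf <- vapply(1:200, function(sd)
    attr(simulate_frm(rx, discrete_state(S = 2), t_end = 10, seed = sd),
         "n_events"), numeric(1))
  nn <- vapply(1:200, function(sd)
    attr(simulate_nrm(rx, discrete_state(S = 2), t_end = 10, seed = 1000 + sd),
         "n_events"), numeric(1))
  ks <- suppressWarnings(stats::ks.test(nf, nn))
  expect_gt(ks$p.value, 0.01)
})

test_that("trajectories preserve discrete invariants and v bounds", {
  p <- base_case_params(k_ecm = 0.3, E_s = 2, I_n = 2)
  rx <- compile_reactions(p, scaling_spec(3))
  for (sim in list(simulate_frm, simulate_nrm)) {
    tr <- sim(rx, t_end = 200, seed = 31)
    expect_true(all(tr$X <= tr$N & tr$P <= tr$X))
    expect_true(all(tr[, c("N", "S", "M", "X", "R", "P")] >= 0))
    expect_true(all(tr$v >= 0 & tr$v <= 1))
    d <- counts_to_densities(tr)
    expect_equal(d$v, tr$v)
    expect_equal(d$r, tr$R / 30)
  }
})

test_that("K_m = K_r amplification does not significantly affect v", {
  means <- vapply(c(5, 10, 20), function(K) {
    p <- base_case_params(k_ecm = 0.3, k_a_m = 2 * K, k_a_r = 4 * K)
    rx <- compile_reactions(p, scaling_spec(3, K_m = K, K_r = K))
    mean(vapply(1:6, function(sd)
      mean(simulate_frm(rx, t_end = 400, seed = sd)$v), numeric(1)))
  }, numeric(1))
  expect_lt(max(means) - min(means), 0.15)
})

test_that("phenotype matrix runs the grid and persists traces", {
  p <- base_case_params()
  out_dir <- tempfile()
  res <- run_phenotype_matrix(p, k_ecm_list = c(0.03, 0.3), N_star_list = 3,
                              E_s_list = 0, I_n_list = 0, t_end = 150,
                              seeds = 1:2, out_dir = out_dir)
  expect_identical(nrow(res), 4L)
  expect_true(all(res$label %in% c("minimal_protrusion", "transient_protrusions",
                                   "stable_protrusion", "protrusion_with_pauses")))
  expect_identical(length(list.files(out_dir, pattern = "^trace_.*csv$")), 4L)
  one <- utils::read.csv(list.files(out_dir, full.names = TRUE)[1])
  expect_named(one, c("t", "v", "S"))
  expect_true(all(one$v >= 0 & one$v <= 1))
  # low k_ecm below the bistable band favors minimal protrusion
  expect_true(all(res$label[res$k_ecm == 0.03] == "minimal_protrusion"))
  unlink(out_dir, recursive = TRUE)
  expect_error(run_phenotype_matrix(p, numeric(0), 3, 0, 0), "non-empty")
})
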