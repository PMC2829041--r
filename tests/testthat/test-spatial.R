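test_that("lattice geometry follows the Rac length constant", {
  lat <- build_lattice(20, D_r = 15, k_d_r = 4)
  expect_equal(signif(lat$spacing_um, 3), 1.94)
  expect_equal(lat$hop_rate, 4)
  expect_equal(lat$length_um, 20 * lat$spacing_um)
  expect_error(build_lattice(0), "positive integer")
  expect_error(build_lattice(10, D_r = -1), "non-negative")
  expect_error(build_lattice(10, D_r = 15, k_d_r = 0), "k_d_r")
  expect_error(build_lattice(10, D_r = 0, k_d_r = 4), "spacing_um")
  lat0 <- build_lattice(10, D_r = 0, k_d_r = 4, spacing_um = 2)
  expect_identical(lat0$hop_rate, 0)
})

test_that("NSM is reproducible and respects invariants per subvolume", {
  p <- base_case_params(k_ecm = 0.3)
  rx <- compile_reactions(p, scaling_spec(3))
  lat <- build_lattice(5, D_r = 15, k_d_r = 4)
  a <- simulate_nsm(rx, lat, t_end = 60, seed = 77)
  b <- simulate_nsm(rx, lat, t_end = 60, seed = 77)
  expect_identical(a$counts, b$counts)
  expect_identical(a$v, b$v)
  expect_true(all(a$counts$X <= a$counts$N & a$counts$P <= a$counts$X))
  expect_true(all(a$v >= 0 & a$v <= 1))
  tr1 <- subvolume_trajectory(a, 3)
  expect_s3_class(tr1, "adhesim_trajectory")
  expect_identical(tr1$N, a$counts$N[3, ])
  expect_error(simulate_nsm(rx, build_lattice(5, D_r = 30, k_d_r = 4),
                            t_end = 10, seed = 1), "D_r")
})

test_that("pure diffusion conserves Rac and relaxes to uniformity", {
  p <- base_case_params(k_ecm = 0, k_d_n = 0, k_a_s = 0, k_d_s = 0,
                        k_a_m = 0, k_d_m = 0, k_a_x = 0, k_d_x = 0,
                        k_a_r = 0, k_d_r = 0, k_a_p = 0, k_d_p = 0, p0 = 0)
  rx <- compile_reactions(p, scaling_spec(1))
  n_sub <- 8
  lat <- build_lattice(n_sub, D_r = 15, k_d_r = 4)   # hop rate 4 per direction
  state0 <- matrix(0L, n_sub, 6)
  R0 <- 800L
  state0[1, 5] <- R0                                  # all Rac in one subvolume
  sp <- simulate_nsm(rx, lat, state0 = state0, t_end = 60, seed = 5)
  expect_true(all(colSums(sp$counts$R) == R0))        # exact conservation
  expect_true(all(sp$counts$N == 0 & sp$counts$S == 0 & sp$counts$P == 0))
  final <- sp$counts$R[, ncol(sp$counts$R)]           # t >> L^2 / D
  expect_gt(stats::chisq.test(final)$p.value, 0.01)
})

test_that("one-subvolume NSM matches the one-compartment engine", {
  p <- base_case_params(k_ecm = 0.3)
  rx <- compile_reactions(p, scaling_spec(3))
  lat1 <- build_lattice(1, D_r = 15, k_d_r = 4)
  v_nsm <- vapply(1:12, function(sd)
    mean(simulate_nsm(rx, lat1, t_end = 500, seed = sd)$v[1, ]), numeric(1))
  v_frm <- vapply(1:12, function(sd)
    mean(simulate_frm(rx, t_end = 500, seed = 100 + sd)$v), numeric(1))
  se <- sqrt(stats::var(v_nsm) / 12 + stats::var(v_frm) / 12)
  expect_lt(abs(mean(v_nsm) - mean(v_frm)), 2.5 * se + 1e-12)
})

test_that("zero diffusion decouples subvolumes into independent compartments", {
  p <- base_case_params(k_ecm = 0.3, D_r = 0)
  rx <- compile_reactions(p, scaling_spec(3))
  lat <- build_lattice(4, D_r = 0, k_d_r = 4, spacing_um = 1.94)
  v_sub <- unlist(lapply(1:4, function(sd)
    rowMeans(simulate_nsm(rx, lat, t_end = 500, seed = sd)$v)))
  p1 <- base_case_params(k_ecm = 0.3)
  rx1 <- compile_reactions(p1, scaling_spec(3))
  v_one <- vapply(1:16, function(sd)
    mean(simulate_frm(rx1, t_end = 500, seed = 200 + sd)$v), numeric(1))
  se <- sqrt(stats::var(v_sub) / length(v_sub) + stats::var(v_one) / 16)
  expect_lt(abs(mean(v_sub) - mean(v_one)), 2.5 * se + 1e-12)
})

test_that("velocity maps and kymographs render from spatial output", {
  p <- base_case_params(k_ecm = 0.3)
  rx <- compile_reactions(p, scaling_spec(3))
  lat <- build_lattice(6, D_r = 15, k_d_r = 4)
  sp <- simulate_nsm(rx, lat, t_end = 40, seed = 3)
  vm <- spatial_velocity_map(sp, v_scale = 10)
  expect_s3_class(vm, "velocity_map")
  expect_equal(vm$v, sp$v * 10)                       # sample-and-hold, no smoothing
  expect_equal(vm$y, (0:5) * lat$spacing_um)
  f <- tempfile(fileext = ".png")
  render_kymograph(vm, f)
  img <- png::readPNG(f)
  expect_identical(dim(img), dim(vm$v))
  expect_true(all(img >= 0 & img <= 1))
  # all-zero map renders all-white
  zero <- velocity_map(matrix(0, 4, 5))
  render_kymograph(zero, f)
  expect_true(all(png::readPNG(f) == 1))
  # adhesion map maximum pixel corresponds to the S maximum (black = max)
  render_kymograph(sp$counts$S, f)
  img_s <- png::readPNG(f)
  expect_identical(which.min(img_s), which.max(sp$counts$S))
  unlink(f)
})
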