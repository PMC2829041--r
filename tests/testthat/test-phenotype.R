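test_that("moving-average smoothing is centered and shrinks at boundaries", {
  n <- 41
  v <- numeric(n); v[21] <- 1          # impulse
  sm <- smooth_trace(v, window = 20)
  expect_equal(sm[21], 1 / 21)         # full window: 2*10 + 1 samples
  expect_equal(sum(sm > 0), 21)        # support spans the full window
  expect_equal(max(sm), sm[21])        # no phase shift
  # boundaries: window shrinks symmetrically, first/last samples untouched
  expect_equal(smooth_trace(c(5, 0, 0, 0, 0), window = 20)[1], 5)
  x <- stats::runif(30)
  expect_equal(smooth_trace(x, window = 1), x)
  expect_equal(mean(smooth_trace(rep(2, 50), 20)), 2)   # constants unchanged
  expect_error(smooth_trace(x, window = 0), "window")
})

test_that("trace classification implements the four-way rule set", {
  t <- seq(0, 400, by = 0.5)
  post <- t >= 100
  # stable protrusion: high throughout
  v <- rep(0.9, length(t))
  expect_identical(classify_trace(v, t), "stable_protrusion")
  # protrusion with pauses: high baseline, one 10-min pause (long enough to
  # survive the 20-sample smoothing window)
  v2 <- v; v2[t >= 200 & t < 210] <- 0.1
  expect_identical(classify_trace(v2, t), "protrusion_with_pauses")
  # sub-threshold dips shorter than pause_min do not count as pauses
  v3 <- v; v3[t == 200] <- 0.45
  expect_identical(classify_trace(v3, t, window = 1), "stable_protrusion")
  # minimal protrusion: low throughout
  v4 <- rep(0.05, length(t))
  expect_identical(classify_trace(v4, t), "minimal_protrusion")
  # transient protrusions: low baseline with a brief excursion peaking > 0.5
  v5 <- v4; v5[t >= 250 & t < 270] <- 0.95
  expect_identical(classify_trace(v5, t), "transient_protrusions")
  # the initial transient is not counted
  v6 <- v4; v6[t < 50] <- 1
  expect_identical(classify_trace(v6, t), "minimal_protrusion")
  expect_error(classify_trace(v4[1:10], t), "equal length")
  expect_error(classify_trace(v4, t, burn_in = 1e6), "burn_in")
})

test_that("segmentation applies the two-threshold connected-component rule", {
  v <- matrix(0, 9, 9)
  v[2:4, 2:4] <- 2           # block with a strong core
  v[3, 3] <- 8
  v[2:4, 6:8] <- 3           # block that never reaches the high threshold
  v[7, 2:8] <- 2; v[7, 5] <- 9  # line event
  map <- velocity_map(v)
  seg <- segment_protrusion_events(map, low = 1, high = 5)
  expect_identical(seg$n_events, 2L)
  expect_identical(sort(unique(as.vector(seg$labels))), c(0L, 1L, 2L))
  expect_identical(sum(seg$labels == 1), 9L)
  expect_identical(sum(seg$labels == 2), 7L)
  expect_equal(seg$events$max_v, c(8, 9))
  expect_equal(seg$events$activity[1], sum(v[2:4, 2:4] - 1))
  # weak patch contributes nothing to total activity
  expect_equal(total_protrusive_activity(map), sum(seg$events$activity))
  # diagonal contact does not merge events (4-connectivity)
  v2 <- matrix(0, 5, 5); v2[1:2, 1:2] <- 6; v2[3:4, 3:4] <- 6
  s2 <- segment_protrusion_events(velocity_map(v2))
  expect_identical(s2$n_events, 2L)
  expect_error(segment_protrusion_events(velocity_map(v), low = 6, high = 5),
               "low <= high")
})

test_that("masked cells break connectivity", {
  v <- matrix(0, 3, 9)
  v[2, ] <- 6                      # one long event along the row
  base <- segment_protrusion_events(velocity_map(v))
  expect_identical(base$n_events, 1L)
  mask <- matrix(FALSE, 3, 9); mask[2, 5] <- TRUE
  cut <- segment_protrusion_events(velocity_map(v, mask = mask))
  expect_identical(cut$n_events, 2L)  # the mask splits it in two
  expect_true(all(cut$labels[mask] == 0))
})

test_that("threshold monotonicity and transpose symmetry hold", {
  vm <- make_synthetic_velocity_map(25, 40, 4, seed = 11)
  n_loose <- segment_protrusion_events(vm, low = 1, high = 3)$n_events
  n_tight <- segment_protrusion_events(vm, low = 1, high = 8)$n_events
  expect_lte(n_tight, n_loose)
  a_low <- total_protrusive_activity(vm, low = 0.5, high = 5)
  a_high <- total_protrusive_activity(vm, low = 2, high = 5)
  expect_gte(a_low, a_high)
  seg <- segment_protrusion_events(vm)
  seg_t <- segment_protrusion_events(velocity_map(t(vm$v), mask = t(vm$mask)))
  expect_identical(seg$n_events, seg_t$n_events)
  expect_identical(sort(tabulate(seg$labels[seg$labels > 0])),
                   sort(tabulate(seg_t$labels[seg_t$labels > 0])))
})

test_that("synthetic maps carry exact ground truth and reject impossible requests", {
  vm <- make_synthetic_velocity_map(30, 50, 6, seed = 3, n_masked = 12)
  truth <- attr(vm, "truth")
  expect_identical(attr(vm, "n_events"), 6L)
  expect_identical(max(truth), 6L)
  expect_identical(sum(vm$mask), 12L)
  expect_true(all(truth[vm$mask] == 0))          # masks avoid events
  # background strictly below low, every event reaches the high threshold
  expect_true(all(vm$v[truth == 0] < 1))
  for (k in 1:6) expect_gte(max(vm$v[truth == k]), 5)
  # segmentation recovers the ground truth exactly at zero noise
  seg <- segment_protrusion_events(vm)
  expect_identical(seg$labels, canonical_labels(truth))
  expect_error(make_synthetic_velocity_map(6, 6, 50, seed = 1),
               "non-overlapping")
  expect_error(make_synthetic_velocity_map(2, 50, 1, seed = 1), "small")
})

test_that("flood fill agrees with the igraph oracle on 50 seeded maps", {
  skip_if_not_installed("igraph")
  for (seed in 1:50) {
    set.seed(seed + 5000)
    ny <- sample(8:30, 1); nt <- sample(8:40, 1)
    v <- matrix(stats::rexp(ny * nt, rate = 1 / 2), ny, nt)
    mask <- matrix(stats::runif(ny * nt) < 0.05, ny, nt)
    map <- velocity_map(v, mask = mask)
    seg <- segment_protrusion_events(map, low = 1, high = 5)
    expect_identical(canonical_labels(seg$labels),
                     oracle_events(v, mask, 1, 5))
  }
})
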