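test_that("discretisation maps continuous motion onto unit hops", {
  t_h <- seq(0, 30, by = 0.1)
  # constant position: a single site, no hops
  d0 <- discretise(make_track(t_h, rep(3, length(t_h))), L_ref = 20)
  expect_length(d0$X, 1)
  expect_length(d0$T_hop, 0)
  # uniform motion at speed v: hops at regular intervals L_ref / v
  v <- 10; L <- 20
  d1 <- discretise(make_track(t_h, v * t_h), L_ref = L)
  expect_true(all(diff(d1$X) == 1))
  expect_equal(diff(d1$T_hop), rep(L / v, length(d1$T_hop) - 1),
               tolerance = 1e-9)
  # a frame-to-frame change of several sites is split into unit hops with
  # interpolated, strictly increasing times
  d2 <- discretise(data.frame(t_h = c(0, 1), x_um = c(0, 100)), L_ref = 20)
  expect_equal(d2$X, 0:5)
  expect_true(all(diff(d2$T_hop) > 0))
  # jump-duration bookkeeping: sum(t_jump) spans first to last hop exactly
  expect_equal(sum(d1$t_jump), d1$T_hop[length(d1$T_hop)] - d1$T_hop[1])
  expect_error(discretise(make_track(t_h, v * t_h), L_ref = 0), "positive")
  expect_error(discretise(make_track(t_h, v * t_h), 20, hysteresis_um = 15),
               "hysteresis")
})

test_that("rendered lattice paths discretise back to the generating sites", {
  m0 <- population_model(noise_sd_um = 0)
  for (i in 1:20) {
    lat <- simulate_psatw_1d(0.7, -2, 150, seed = 1300 + i)
    tr <- render_continuous_track(lat, 20, m0, seed = 1600 + i)
    gen <- lat$sites[c(TRUE, diff(lat$sites) != 0)]
    expect_identical(as.integer(discretise(tr, 20)$X), as.integer(gen))
  }
  # hysteresis debouncing keeps the hop count honest under noise
  m1 <- population_model()   # sigma = 1 um
  nh <- vapply(1:30, function(i) {
    lat <- simulate_psatw_1d(0.7, -2, 150, seed = 1300 + i)
    tr <- render_continuous_track(lat, 20, m1, seed = 1600 + i)
    length(discretise(tr, 20, hysteresis_um = 2)$X) - 1L
  }, numeric(1))
  expect_lt(abs(mean(nh) - 150), 3)
})

test_that("hop classification counts conditional reversal frequencies", {
  # strictly monotonic path: every classified step is an edge step, no reversal
  cc <- classify_and_count(lattice_as_discrete(0:10))
  expect_equal(cc$n_interior, 0)
  expect_equal(cc$n_edge, 9)
  expect_equal(cc$n_rev_edge, 0)
  expect_true(is.nan(cc$p_ri_hat))
  # perfect two-site bounce: always at the frontier, always reversing
  bounce <- lattice_as_discrete(rep(c(0L, 1L), 8))
  ccb <- classify_and_count(bounce)
  expect_equal(ccb$n_interior, 0)
  expect_equal(ccb$p_re_hat, 1)
  expect_equal(ccb$n_rev_edge, ccb$n_edge)
  expect_error(classify_and_count(lattice_as_discrete(c(0L, 1L))), "2 hops")

  # law of large numbers: long simulated paths reproduce the forward formulas
  lat <- simulate_psatw_1d(0.7, -2, 1e5, seed = 77)
  cc2 <- classify_and_count(lattice_as_discrete(lat$sites))
  se_ri <- sqrt(cc2$p_ri_hat * (1 - cc2$p_ri_hat) / cc2$n_interior)
  se_re <- sqrt(cc2$p_re_hat * (1 - cc2$p_re_hat) / cc2$n_edge)
  expect_lt(abs(cc2$p_ri_hat - reversal_prob_interior(0.7)), 4 * se_ri)
  expect_lt(abs(cc2$p_re_hat - reversal_prob_edge(0.7, -2)), 4 * se_re)
})

test_that("parameter inversion is the exact inverse of the forward formulas", {
  expect_equal(invert_params(0.5, 0.5), list(k = 0, beta = 0))
  est <- invert_params(reversal_prob_interior(1), reversal_prob_edge(1, -1))
  expect_equal(est$k, 1, tolerance = 1e-12)
  expect_equal(est$beta, -1, tolerance = 1e-12)
  for (k in seq(0, 2, by = 0.25)) {
    for (beta in seq(-3, 0, by = 0.5)) {
      est <- invert_params(reversal_prob_interior(k),
                           reversal_prob_edge(k, beta))
      expect_equal(est$k, k, tolerance = 1e-12)
      expect_equal(est$beta, beta, tolerance = 1e-12)
    }
  }
  expect_error(invert_params(0, 0.5), "strictly inside")
  expect_error(invert_params(0.5, 1), "strictly inside")
})

test_that("the reference length is the median cell length", {
  t_h <- seq(0, 5, by = 0.5)
  expect_equal(choose_Lref(make_track(t_h, rep(0, 11), length_um = 20)), 20)
  tr <- make_track(t_h[1:10], rep(0, 10))
  len <- rep(c(18, 22), length.out = 10)
  tr$x_left_um <- -len / 2
  tr$x_right_um <- len / 2
  expect_equal(choose_Lref(tr), 20)
  expect_error(choose_Lref(data.frame(t_h = t_h, x_um = 0)), "edge columns")
  # synthetic tracks: chosen L_ref within 20% of the generating scale
  ds <- generate_dataset("control", n_cells = 5, seed = 31, n_hops = 80)
  for (tr in split(ds$tracks, ds$tracks$cell_id))
    expect_lt(abs(choose_Lref(tr) - 20) / 20, 0.2)
})

test_that("per-cell fits recover the generating parameters and tighten with
           track length", {
  ds <- generate_dataset("control", n_cells = 60, seed = 1, n_hops = 150)
  fit <- fit_cells(ds$tracks)
  expect_equal(nrow(fit), 60)
  expect_true(all(fit$p_ri_hat >= 0 & fit$p_ri_hat <= 1, na.rm = TRUE))
  err_k_150 <- median(abs(fit$k_hat - ds$truth$k), na.rm = TRUE)
  err_b_150 <- median(abs(fit$beta_hat - ds$truth$beta), na.rm = TRUE)
  # estimates centred on the truth (no gross bias)
  expect_lt(abs(median(fit$k_hat - ds$truth$k, na.rm = TRUE)), 0.15)
  expect_lt(abs(median(fit$beta_hat - ds$truth$beta, na.rm = TRUE)), 0.25)
  ds2 <- generate_dataset("control", n_cells = 60, seed = 1, n_hops = 1500)
  fit2 <- fit_cells(ds2$tracks)
  expect_lt(median(abs(fit2$k_hat - ds2$truth$k), na.rm = TRUE), err_k_150)
  expect_lt(median(abs(fit2$beta_hat - ds2$truth$beta), na.rm = TRUE), err_b_150)
})

test_that("degenerate reversal frequencies fall back to pseudocounts", {
  # a purely ballistic track has zero reversals everywhere: flagged, finite
  t_h <- seq(0, 50, by = 0.1)
  tr <- make_track(t_h, 8 * t_h)
  fit <- fit_cells(tr, L_ref = 20)
  expect_equal(fit$flag, "pseudocount")
  expect_true(is.finite(fit$k_hat))
  expect_true(is.finite(fit$beta_hat))
})
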