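test_that("increments recover closed-form laws for reference motions", {
  # ballistic motion x = v t: I(T, t) = v^2 t^2 at every age
  v <- 3
  P <- outer(0:400, rep(v, 50)) * 1   # 50 identical ballistic walkers
  inc <- increments(P, ages = c(0, 100), window = 60, lags = c(1, 5, 20))
  expect_equal(inc$value, v^2 * inc$lag^2, tolerance = 1e-12)
  expect_equal(inc$sem, rep(0, nrow(inc)))
  # simple random walk: I(T, t) ~ t (2D t = 1/2 per axis), age-independent
  ens <- psatw_ensemble(0, 0, 1500, 800, seed = 41)
  inc2 <- increments(ens, ages = c(0, 500), window = 300,
                     lags = c(10, 30, 100))
  for (lg in unique(inc2$lag)) {
    sub <- inc2[inc2$lag == lg, ]
    expect_lt(abs(sub$value[1] - lg), 4 * sub$sem[1])
    # no ageing within Monte-Carlo resolution
    expect_lt(abs(sub$value[1] - sub$value[2]),
              4 * sqrt(sum(sub$sem^2)))
  }
  expect_error(increments(ens, ages = 0, window = 2000), "too short")
})

test_that("msd matches closed forms and orders attractive vs free walks", {
  P <- matrix(5, nrow = 100, ncol = 10)   # stationary ensemble
  m0 <- msd(P)
  expect_equal(m0$msd, rep(0, 100))
  m1 <- msd(satw2d_ensemble(0, 400, 600, seed = 42))
  f <- fit_power_exponent(m1$step, m1$msd, window = c(10, 400))
  expect_equal(f$exponent, 1, tolerance = 0.06)
  # self-attraction uniformly suppresses late-time spreading
  ma <- msd(satw2d_ensemble(-2.5, 400, 600, seed = 43))
  late <- m1$step > 50
  expect_true(all(ma$msd[late] < m1$msd[late]))
  # unsquared option returns the mean displacement norm
  mu <- msd(P + outer(0:99, rep(1, 10)) * 0 + 3, squared = FALSE)
  expect_equal(mu$msd, rep(0, 100))
})

test_that("survival curves are proper and match first-step enumeration", {
  sc <- survival_probability(0, 0, r = 1, n_walkers = 4000, t_max = 100,
                             seed = 44)
  expect_true(all(diff(sc$curve$S) <= 0))
  expect_true(all(sc$curve$S >= 0 & sc$curve$S <= 1))
  # r = 1: the first step hits the target iff drawn toward it, so S(1) = 1/2
  S1 <- mean(sc$hit_times > 1)
  expect_lt(abs(S1 - 0.5), 4 * sqrt(0.25 / 4000))
  # the curve survives monotone resampling under bootstrap-free fitting
  expect_identical(sc$curve,
                   survival_probability(0, 0, 1, 4000, 100, seed = 44)$curve)
})

test_that("power-law fitting is exact on power laws and flags mismatch", {
  tt <- exp(seq(log(1), log(1000), length.out = 40))
  f <- fit_power_exponent(tt, 2.7 * tt^(-1.35))
  expect_equal(f$exponent, -1.35, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  # exponential decay: detectably poor power-law diagnostic
  g <- fit_power_exponent(tt, exp(-tt / 100))
  expect_lt(g$r_squared, 0.9)
  expect_error(fit_power_exponent(tt[1:4], tt[1:4]), "5 points")
  expect_error(fit_power_exponent(tt, c(0, tt[-1])), "non-positive")
  # calibration with multiplicative noise: |bias| below the standard error
  set.seed(45)
  reps <- vapply(1:40, function(i) {
    y <- 5 * tt^0.8 * exp(rnorm(40, 0, 0.1))
    fit_power_exponent(tt, y)$exponent
  }, numeric(1))
  expect_lt(abs(mean(reps) - 0.8), sd(reps) / sqrt(40) * 3)
})

test_that("theta follows exp(-beta)/2 and survival tails reproduce it", {
  expect_equal(theta_theory(0), 0.5)
  expect_equal(theta_theory(-log(2)), 1)
  b <- seq(-3, 1, by = 0.25)
  expect_true(all(diff(theta_theory(b)) < 0))
  # memoryless tail: theta ~ 1/2 at modest scale
  sc <- survival_probability(0, 0, r = 5, n_walkers = 3000, t_max = 2e4,
                             seed = 46)
  fit <- fit_survival_tail(sc, s_range = c(5e-3, 1e-1), n_boot = 60)
  expect_lt(abs(fit$exponent - 0.5), 3 * fit$se)
})

test_that("oscillation detection reads triangle-wave geometry exactly", {
  # triangle wave between 0 and A0 with period P: amplitudes A0, periods P,
  # amplitude/period = A0/P = speed/2
  A0 <- 30; P <- 4
  t_h <- seq(0, 40, by = 0.05)
  xx <- A0 * abs(2 * (t_h / P - floor(t_h / P + 0.5)))
  os <- detect_oscillations(make_track(t_h, xx), min_excursion = 10,
                            smooth_window = 1)
  expect_gt(length(os$amplitudes), 10)
  expect_equal(median(os$amplitudes), A0, tolerance = 0.01)
  expect_equal(median(os$periods), P, tolerance = 0.01)
  expect_equal(median(os$ratios), A0 / P, tolerance = 0.02)
  v <- 2 * A0 / P
  expect_equal(median(os$ratios), v / 2, tolerance = 0.02)
  # constant position: empty summary, not an error
  os0 <- detect_oscillations(make_track(t_h, rep(1, length(t_h))))
  expect_length(os0$amplitudes, 0)
  # sub-threshold wiggles are ignored
  os1 <- detect_oscillations(make_track(t_h, 3 * sin(t_h)),
                             min_excursion = 10)
  expect_length(os1$amplitudes, 0)
})

test_that("effective diffusion scales the MSD slope by 2 dim", {
  st <- 0:100
  expect_equal(effective_diffusion(data.frame(step = st, msd = 4 * 0.7 * st),
                                   dim = 2), 0.7, tolerance = 1e-12)
  m <- msd(psatw_ensemble(0, 0, 500, 1200, seed = 47))
  D <- effective_diffusion(m, window = c(50, 500), dim = 1)
  # slope errors are correlated across times, so allow a generous MC band
  expect_equal(D, 0.5, tolerance = 0.2)
  # attraction lowers the effective diffusion constant
  ma <- msd(psatw_ensemble(0, -2, 500, 1200, seed = 48))
  Da <- effective_diffusion(ma, window = c(50, 500), dim = 1)
  expect_lt(Da / D, 1)
})

test_that("standard errors shrink with ensemble size", {
  small <- increments(psatw_ensemble(0.5, -1, 800, 100, seed = 49),
                      ages = 0, window = 200, lags = c(10, 50))
  big <- increments(psatw_ensemble(0.5, -1, 800, 900, seed = 49),
                    ages = 0, window = 200, lags = c(10, 50))
  expect_true(all(big$sem < small$sem))
  s_small <- survival_probability(0, 0, 3, 400, 2000, seed = 50)
  s_big <- survival_probability(0, 0, 3, 4000, 2000, seed = 50)
  mid <- which(s_small$curve$S > 0.05 & s_small$curve$S < 0.95)
  expect_gt(mean(s_small$curve$sem[mid]), mean(s_big$curve$sem[mid]))
})
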