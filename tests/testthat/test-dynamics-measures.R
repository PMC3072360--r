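test_that("moments match brute-force summation and handle degeneracy", {
  m <- moments(c(1, 2, 3))
  expect_equal(m$S1, 2)
  expect_equal(m$S2, 1)
  expect_equal(m$S3, 0)

  expect_error(moments(rep(5, 10)), class = "morphodyn_degenerate")

  set.seed(1)
  fixtures <- list(rnorm(900), rexp(500), c(1, 2, 3, 10), runif(64))
  for (x in fixtures) {
    got <- moments(x); want <- brute_moments(x)
    for (f in c("S1", "S2", "S3", "S4"))
      expect_equal(got[[f]], want[[f]], tolerance = 1e-12)
  }

  # Gaussian white noise: shape statistics near their asymptotic nulls
  set.seed(1)
  g <- moments(rnorm(900))
  expect_lt(abs(g$S3), 0.2)
  expect_lt(abs(g$S4), 0.4)
})

test_that("periodogram peaks at the driving frequency and conserves variance", {
  n <- 900; dt <- 2
  x <- cos(2 * pi * (0:(n - 1)) * dt / 240)
  sp <- power_spectrum(x, dt = dt)
  expect_length(sp$frequencies, n %/% 2)
  f_peak <- sp$frequencies[which.max(sp$power)]
  expect_lt(abs(f_peak - 1 / 240), 1 / (n * dt) + 1e-12)  # within one bin

  # mean shift leaves the spectrum untouched
  sp_shift <- power_spectrum(x + 7, dt = dt)
  expect_equal(sp$power, sp_shift$power, tolerance = 1e-12)

  # Parseval: folded power sum equals the population variance
  set.seed(8); y <- rnorm(512)
  spy <- power_spectrum(y, dt = dt)
  m <- length(spy$power)
  folded <- 2 * sum(spy$power[1:(m - 1)]) + spy$power[m]
  expect_equal(folded, mean((y - mean(y))^2), tolerance = 1e-8)
})

test_that("spectral slope recovers canonical scaling laws", {
  # exact f^-1 spectrum -> slope -1 to machine precision
  f <- (1:200) / 1000
  spec <- structure(list(frequencies = f, power = 1 / f, n = 400, dt = 2),
                    class = "power_spectrum")
  expect_equal(as.numeric(spectral_alpha(spec)), -1, tolerance = 1e-10)

  # white noise: 20-replicate mean slope near 0
  al_w <- sapply(1:20, function(i) {
    set.seed(100 + i)
    as.numeric(spectral_alpha(power_spectrum(rnorm(4096), dt = 2)))
  })
  expect_lt(abs(mean(al_w)), 0.15)

  # random walk: 20-replicate mean slope near -2
  al_rw <- sapply(1:20, function(i) {
    set.seed(200 + i)
    as.numeric(spectral_alpha(power_spectrum(cumsum(rnorm(4096)), dt = 2)))
  })
  expect_lt(abs(mean(al_rw) + 2), 0.3)

  # positive rescaling shifts the intercept only
  set.seed(5); z <- rnorm(900)
  a1 <- as.numeric(spectral_alpha(power_spectrum(z, dt = 2)))
  a2 <- as.numeric(spectral_alpha(power_spectrum(13.7 * z, dt = 2)))
  expect_equal(a1, a2, tolerance = 1e-10)
})

test_that("slowest mode reports the lowest qualifying spectral peak", {
  n <- 960; dt <- 2  # 480 s divides the 1920 s record exactly
  t <- 0:(n - 1)
  expect_equal(slowest_mode_period(power_spectrum(cos(2 * pi * t * dt / 480), dt = dt)), 8)
  two <- cos(2 * pi * t * dt / 480) + cos(2 * pi * t * dt / 60)
  expect_equal(slowest_mode_period(power_spectrum(two, dt = dt)), 8)
  # global-max mode picks the strongest bin instead
  dom <- cos(2 * pi * t * dt / 480) + 3 * cos(2 * pi * t * dt / 60)
  expect_equal(slowest_mode_period(power_spectrum(dom, dt = dt), mode = "global_max"), 1)
})

test_that("Wolf exponent recovers the logistic-map ln 2 and zero for a sine", {
  x <- logistic_orbit(2000, seed = 11)
  lam <- as.numeric(lyapunov_wolf(x))
  expect_lt(abs(lam - log(2)), 0.1)
  # independent derivative oracle on the same orbit: mean log|f'(x)| = ln 2
  expect_lt(abs(mean(log(abs(4 - 8 * x))) - log(2)), 0.01)

  s <- sin(2 * pi * (1:1000) / 50)
  expect_lt(abs(as.numeric(lyapunov_wolf(s))), 0.05)

  expect_error(lyapunov_wolf(rep(1, 500)), class = "morphodyn_no_valid_neighbor")

  # affine maps of the series preserve neighbor ranks, hence the estimate
  expect_lt(abs(as.numeric(lyapunov_wolf(3 * x + 10)) - lam), 0.05)
})

test_that("measure battery captures failures instead of raising", {
  ens <- ensemble_data()
  ms <- ens$measures$idling[[1]]
  expect_length(ms$failures, 0)
  for (f in c("S1", "S2", "S3", "S4", "Lambda1", "alpha", "slowest_period_min"))
    expect_true(is.finite(ms[[f]]))

  const <- measure_battery(rep(2.5, 300), dt = 2)
  expect_equal(const$S1, 2.5)
  expect_equal(const$S2, 0)
  expect_true(is.na(const$S3) && is.na(const$S4) && is.na(const$Lambda1))
  expect_true(all(c("S3", "S4", "Lambda1") %in% names(const$failures)))

  # determinism: same input gives the identical measure set
  x <- ens$series$idling[[2]]
  expect_identical(unclass(measure_battery(x)), unclass(measure_battery(x)))
})

test_that("treadmilling vs idling reproduces the canonical contrast pattern", {
  ens <- ensemble_data()
  trd <- ens$measures$treadmilling; idl <- ens$measures$idling
  up <- compare_groups(trd, idl, alternative = "greater")$table
  down <- compare_groups(trd, idl, alternative = "less")$table
  expect_lt(up$p[up$measure == "SD"], 0.05)
  expect_lt(up$p[up$measure == "Skew"], 0.05)
  expect_lt(down$p[down$measure == "lambda1"], 0.05)
  expect_lt(down$p[down$measure == "alpha"], 0.05)
})
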