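test_that("delay embedding lays out lagged coordinates", {
  Y <- delay_embed(c(1, 2, 3, 4), dim = 3, tau = 1)
  expect_equal(Y, rbind(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(delay_embed(5:9, dim = 1, tau = 1), matrix(5:9, ncol = 1))
  expect_equal(nrow(delay_embed(1:10, dim = 3, tau = 2)), 6)
  expect_error(delay_embed(1:3, dim = 3, tau = 2), class = "morphodyn_too_short")
})

test_that("Broomhead-King embedding has the expected spectral structure", {
  # constant series: all eigenvalues vanish after mean removal
  bk0 <- bk_embed(rep(4, 100), M = 8)
  expect_lt(max(abs(bk0$eigenvalues)), 1e-12)

  x <- sin(2 * pi * (1:900) / 50)
  bk <- bk_embed(x, M = 8)
  # a sinusoid spans a 2-dimensional subspace of lag space
  expect_gt(sum(bk$eigenvalues[1:2]) / sum(bk$eigenvalues), 0.99)
  # eigenvalues descending and nonnegative (PSD Gram construction)
  expect_true(all(diff(bk$eigenvalues) <= 1e-12))
  expect_gt(min(bk$eigenvalues), -1e-10)
  # orthonormal eigenvectors, decomposition reproduces C_M
  V <- bk$eigenvectors
  expect_lt(max(abs(crossprod(V) - diag(8))), 1e-8)
  expect_lt(max(abs(bk$C - V %*% diag(bk$eigenvalues) %*% t(V))), 1e-8)
  # trace identity: sum of eigenvalues equals trace of the window covariance
  expect_equal(sum(bk$eigenvalues), sum(diag(bk$C)), tolerance = 1e-10)
  # ... which is M x the windowed mean square of the mean-removed series
  xm <- x - mean(x)
  X <- delay_embed(xm, 8, 1)
  expect_equal(sum(diag(bk$C)), 8 * mean(X^2), tolerance = 1e-10)

  expect_error(bk_embed(1:20, M = 8), class = "morphodyn_too_short")
})

test_that("time reversal reverses the eigenfunction trajectories up to sign", {
  set.seed(14)
  x <- sin(2 * pi * (1:400) / 60) + 0.5 * sin(2 * pi * (1:400) / 23 + 1) +
    0.05 * rnorm(400)
  bk_f <- bk_embed(x, M = 8)
  bk_r <- bk_embed(rev(x), M = 8)
  for (k in 1:3) {
    fwd <- bk_f$psi[, k]; bwd <- rev(bk_r$psi[, k])
    expect_lt(min(max(abs(fwd - bwd)), max(abs(fwd + bwd))), 1e-8)
  }
})

test_that("recurrence plots obey the Heaviside threshold geometry", {
  x <- c(1.0, 1.3, 0.9, 1.8, 1.1, 2.0, 0.95, 1.5, 1.25, 1.7)

  rp_all <- recurrence_plot(x, eps = 1e6)
  expect_true(all(rp_all$matrix == 1))
  expect_equal(recurrence_rate(rp_all)$rate, 1)

  mono <- recurrence_plot(seq(0, 5, length.out = 12), eps = 0)
  expect_true(all(mono$matrix == diag(nrow(mono$matrix))))
  expect_equal(recurrence_rate(mono)$rate, 0)

  # symmetry, unit diagonal, monotonicity in eps, shift invariance
  set.seed(3); y <- cumsum(rnorm(80))
  r1 <- recurrence_plot(y, eps = 0.5)
  r2 <- recurrence_plot(y, eps = 1.5)
  expect_identical(r1$matrix, t(r1$matrix))
  expect_true(all(diag(r1$matrix) == 1))
  expect_true(all(r1$matrix <= r2$matrix))
  expect_identical(recurrence_plot(y + 100, eps = 0.5)$matrix, r1$matrix)

  # a periodic orbit recurs at multiples of its period
  per <- recurrence_plot(cos(2 * pi * (1:300) / 50), eps = 0.05)
  prof <- recurrence_rate(per)$profile
  band <- prof$recurrence[prof$offset >= 40 & prof$offset <= 60]
  expect_equal(prof$offset[prof$offset >= 40 & prof$offset <= 60][which.max(band)], 50)
  expect_gt(prof$recurrence[prof$offset == 50],
            10 * mean(prof$recurrence[prof$offset %in% 10:30]))
})

test_that("treadmilling recurrences cluster more than idling ones", {
  ens <- ensemble_data()
  cv <- function(rs) {
    rp <- recurrence_plot(rs, eps_quantile = 0.1)
    recurrence_rate(rp)$profile_cv
  }
  cv_i <- vapply(ens$series$idling[1:5], cv, numeric(1))
  cv_t <- vapply(ens$series$treadmilling[1:5], cv, numeric(1))
  expect_gt(stats::median(cv_t), stats::median(cv_i))
})

test_that("treadmilling trajectories occupy a larger eigenfunction volume", {
  ens <- ensemble_data()
  vol <- function(rs) {
    psi <- bk_embed(rs, M = 8)$psi
    prod(apply(psi, 2, function(col) diff(range(col))))
  }
  v_i <- vapply(ens$series$idling, vol, numeric(1))
  v_t <- vapply(ens$series$treadmilling, vol, numeric(1))
  expect_gt(stats::median(v_t), stats::median(v_i))
})
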