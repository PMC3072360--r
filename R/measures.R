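#' Central moments of an R(t) series
#'
#' Computes the four distributional summaries used throughout the package:
#' the mean `S1`, the sample standard deviation `S2` (n-1 denominator), the
#' skewness `S3 = m3 / var^(3/2)` and the excess kurtosis
#' `S4 = m4 / var^2 - 3`, where `m3`, `m4` and `var` are central moments with
#' 1/n denominators (the conventional g1/g2 estimators).
#'
#' @param series an [r_series()] or numeric vector (n >= 3).
#' @return list with `S1`, `S2`, `S3`, `S4`, `m3`, `m4`, `var`.
#' @details A constant series has no defined shape statistics: `S1` and `S2`
#'   are returned but asking for `S3`/`S4` of a zero-variance series raises
#'   an error of class `morphodyn_degenerate`; [measure_battery()] converts
#'   that into a missing-with-reason field instead.
#' @export
moments <- function(series) {
  x <- as_r_values(series)
  if (length(x) < 3) md_error("morphodyn_domain", "need n >= 3")
  m <- mean(x)
  v <- mean((x - m)^2)
  out <- list(S1 = m, S2 = stats::sd(x), m3 = mean((x - m)^3),
              m4 = mean((x - m)^4), var = v)
  if (v == 0)
    md_error("morphodyn_degenerate",
             "zero-variance series: S3 and S4 undefined (S1, S2 available)",
             S1 = out$S1, S2 = out$S2)
  out$S3 <- out$m3 / v^1.5
  out$S4 <- out$m4 / v^2 - 3
  out[c("S1", "S2", "S3", "S4", "m3", "m4", "var")]
}

#' Periodogram of an R(t) series
#'
#' Raw periodogram of the mean-removed series: no taper, no detrending
#' beyond mean removal. Power is normalized so that (with the symmetric
#' negative-frequency bins folded in) it sums to the population variance of
#' the series.
#'
#' @param series an [r_series()] or numeric vector (n >= 16).
#' @param dt sampling interval in seconds; taken from the `r_series` when
#'   omitted.
#' @return list of class `power_spectrum` with `frequencies` (Hz, the
#'   `floor(n/2)` positive bins; zero frequency excluded), `power`, `n`,
#'   `dt`.
#' @export
power_spectrum <- function(series, dt = NULL) {
  x <- as_r_values(series)
  dt <- series_dt(series, dt)
  n <- length(x)
  if (n < 16) md_error("morphodyn_domain", "need n >= 16")
  x <- x - mean(x)
  m <- floor(n / 2)
  P <- (Mod(stats::fft(x))^2 / n^2)[2:(m + 1)]
  structure(list(frequencies = (1:m) / (n * dt), power = P, n = n, dt = dt),
            class = "power_spectrum")
}

#' Log-log spectral scaling exponent
#'
#' Ordinary least-squares slope of `log10(power)` on `log10(frequency)`
#' restricted to the middle third of the log-log relation. More negative
#' slopes indicate slower, more correlated fluctuations; white noise gives a
#' slope near 0 and a random walk near -2.
#'
#' The middle third is taken on the log-frequency axis by default: that is
#' the axis on which the fit is performed, and it is the band where the
#' canonical power-law references hold (a random walk recovers -2 there; in
#' the middle third by linear bin index, which sits at 1/3 to 2/3 of the
#' Nyquist frequency, the discrete-time walk spectrum
#' \eqn{1/\sin^2(\pi f / 2 f_N)} flattens to a slope near -1.5).
#'
#' @param spec a [power_spectrum()].
#' @param band `"log_frequency"` (default, middle third of the
#'   log-frequency axis) or `"index"` (middle third of the positive bins by
#'   linear index, bins `ceiling(m/3)+1 .. ceiling(2m/3)` of `m`).
#' @return scalar slope `alpha`. Zero-power bins inside the window are
#'   dropped; their count is reported via attribute `"dropped"`.
#' @export
spectral_alpha <- function(spec, band = c("log_frequency", "index")) {
  stopifnot(inherits(spec, "power_spectrum"))
  band <- match.arg(band)
  m <- length(spec$power)
  if (sum(spec$power > 0) < 9)
    md_error("morphodyn_insufficient_bins", "need >= 9 positive-power bins")
  if (band == "index") {
    w <- (ceiling(m / 3) + 1):ceiling(2 * m / 3)
  } else {
    lf <- log10(spec$frequencies)
    cuts <- lf[1] + diff(range(lf)) * c(1 / 3, 2 / 3)
    w <- which(lf > cuts[1] & lf <= cuts[2])
  }
  dropped <- sum(spec$power[w] == 0)
  w <- w[spec$power[w] > 0]
  if (length(w) < 3)
    md_error("morphodyn_insufficient_bins", "middle-third window has < 3 usable bins")
  fit <- stats::lm(log10(spec$power[w]) ~ log10(spec$frequencies[w]))
  structure(unname(stats::coef(fit)[2]), dropped = dropped)
}

#' Period of the slowest Fourier mode
#'
#' The slowest mode is taken as the lowest-frequency local maximum of the
#' periodogram whose power exceeds the spectrum's median power, so that a
#' dominant fast oscillation cannot mask a genuine slow mode. The first and
#' last bins count as local maxima when they exceed their single neighbor.
#'
#' @param spec a [power_spectrum()].
#' @param mode `"lowest_peak"` (default) or `"global_max"` (period of the
#'   strongest bin).
#' @return period in minutes.
#' @export
slowest_mode_period <- function(spec, mode = c("lowest_peak", "global_max")) {
  stopifnot(inherits(spec, "power_spectrum"))
  mode <- match.arg(mode)
  P <- spec$power; m <- length(P)
  if (mode == "global_max") {
    k <- which.max(P)
  } else {
    med <- stats::median(P)
    is_lmax <- P >= c(-Inf, P[-m]) & P >= c(P[-1], -Inf) & P > med
    if (!any(is_lmax))
      md_error("morphodyn_no_peak", "no local maximum exceeds the median power")
    k <- which(is_lmax)[1]
  }
  (1 / spec$frequencies[k]) / 60
}

#' Wolf-style leading Lyapunov exponent
#'
#' Estimates the leading Lyapunov exponent of an R(t) series from the
#' average exponential divergence of nearby trajectories in a
#' three-dimensional delay embedding, following Wolf's neighbor-tracking
#' scheme: a fiducial trajectory is followed; at each evolution interval the
#' nearest embedded neighbor within the scale bounds (and outside a Theiler
#' window of temporal neighbors) is selected, both points are evolved, the
#' log of the separation growth is accumulated, and the neighbor is replaced
#' (renormalization).
#'
#' @param series an [r_series()] or numeric vector.
#' @param dim embedding dimension (default 3).
#' @param delay embedding delay in samples (default 1).
#' @param evolve_steps evolution interval in samples (default 3).
#' @param theiler temporal exclusion window in samples (default 10).
#' @param scale_bounds `c(min, max)` separation bounds as fractions:
#'   `min * range(series)` and `max * embedded bounding-box diagonal`
#'   (defaults 1e-4 and 0.1).
#' @param max_fail_frac error when the within-bounds neighbor search fails
#'   at more than this fraction of renormalizations (default 0.2).
#' @return `Lambda1`, the accumulated log separation growth per sample step
#'   (natural log). Attribute `"fail_frac"` reports the fallback fraction.
#' @details Separations are floored at the minimum scale: a pixel-count
#'   series is quantized, so embedded points can coincide exactly and an
#'   unfloored log ratio would diverge. When no neighbor lies within the
#'   scale bounds the nearest admissible neighbor is used and the event is
#'   counted as a failure.
#' @export
lyapunov_wolf <- function(series, dim = 3, delay = 1, evolve_steps = 3,
                          theiler = 10, scale_bounds = c(1e-4, 0.1),
                          max_fail_frac = 0.2) {
  x <- as_r_values(series)
  n <- length(x)
  N <- n - (dim - 1) * delay
  if (N < 200) md_error("morphodyn_domain", "need >= 200 embedded points")
  rng <- diff(range(x))
  if (rng == 0)
    md_error("morphodyn_no_valid_neighbor", "constant series: all separations are zero")
  Y <- delay_embed(x, dim, delay)
  ext <- sqrt(sum((apply(Y, 2, max) - apply(Y, 2, min))^2))
  mins <- scale_bounds[1] * rng
  maxs <- scale_bounds[2] * ext
  fails <- 0L; total <- 0L
  last_evolvable <- N - evolve_steps
  find_nb <- function(i) {
    d <- sqrt(rowSums((Y - matrix(Y[i, ], N, dim, byrow = TRUE))^2))
    d[abs(seq_len(N) - i) <= theiler] <- Inf
    d[seq_len(N) > last_evolvable] <- Inf  # neighbor must be evolvable
    ok <- which(d >= mins & d <= maxs)
    if (length(ok)) return(ok[which.min(d[ok])])
    fails <<- fails + 1L
    which.min(d)
  }
  i <- 1L
  j <- find_nb(i)
  S <- 0; steps <- 0L
  while (i + evolve_steps <= N && j + evolve_steps <= N) {
    total <- total + 1L
    d0 <- max(sqrt(sum((Y[i, ] - Y[j, ])^2)), mins)
    d1 <- max(sqrt(sum((Y[i + evolve_steps, ] - Y[j + evolve_steps, ])^2)), mins)
    S <- S + log(d1 / d0)
    steps <- steps + evolve_steps
    i <- i + evolve_steps
    if (i > last_evolvable) break
    j <- find_nb(i)
  }
  if (total == 0L || steps == 0L)
    md_error("morphodyn_no_valid_neighbor", "series too short to evolve any pair")
  if (fails / total > max_fail_frac)
    md_error("morphodyn_no_valid_neighbor",
             sprintf("neighbor replacement failed at %.0f%% of steps", 100 * fails / total))
  structure(S / steps, fail_frac = fails / total)
}

#' Full measure battery on one R(t) series
#'
#' Computes S1-S4, the Wolf leading Lyapunov exponent, the spectral scaling
#' exponent and the slowest Fourier-mode period with default parameters.
#' Individual measure failures (degenerate series, no qualifying spectral
#' peak, neighbor starvation) are captured as missing fields with reasons
#' rather than raised: short biological recordings routinely yield
#' incomplete measure sets, and the group comparison handles missingness
#' explicitly.
#'
#' @param series an [r_series()] or numeric vector.
#' @param dt sampling interval (taken from the `r_series` when omitted).
#' @return list of class `measure_set` with fields `S1`, `S2`, `S3`, `S4`,
#'   `m3`, `m4`, `var`, `Lambda1`, `alpha`, `slowest_period_min` (NA where a
#'   measure failed), `cell_id`, `state_label`, and `failures` (named
#'   character vector of reasons).
#' @export
measure_battery <- function(series, dt = NULL) {
  x <- as_r_values(series)
  dt <- series_dt(series, dt)
  fails <- character(0)
  out <- list(S1 = mean(x), S2 = stats::sd(x), S3 = NA_real_, S4 = NA_real_,
              m3 = NA_real_, m4 = NA_real_, var = NA_real_,
              Lambda1 = NA_real_, alpha = NA_real_,
              slowest_period_min = NA_real_)
  mo <- tryCatch(moments(x), morphodyn_error = function(e) e)
  if (inherits(mo, "condition")) {
    fails["S3"] <- fails["S4"] <- conditionMessage(mo)
    out$var <- stats::var(x) * (length(x) - 1) / length(x)
  } else out[names(mo)] <- mo
  sp <- tryCatch(power_spectrum(x, dt = dt), morphodyn_error = function(e) e)
  if (inherits(sp, "condition")) {
    fails["alpha"] <- fails["slowest_period_min"] <- conditionMessage(sp)
  } else {
    al <- tryCatch(as.numeric(spectral_alpha(sp)), morphodyn_error = function(e) e)
    if (inherits(al, "condition")) fails["alpha"] <- conditionMessage(al)
    else out$alpha <- al
    pe <- tryCatch(slowest_mode_period(sp), morphodyn_error = function(e) e)
    if (inherits(pe, "condition")) fails["slowest_period_min"] <- conditionMessage(pe)
    else out$slowest_period_min <- pe
  }
  ly <- tryCatch(as.numeric(lyapunov_wolf(x)), morphodyn_error = function(e) e)
  if (inherits(ly, "condition")) fails["Lambda1"] <- conditionMessage(ly)
  else out$Lambda1 <- ly
  out$cell_id <- if (inherits(series, "r_series")) series$cell_id else "series"
  out$state_label <- if (inherits(series, "r_series")) series$state_label else "unknown"
  out$failures <- fails
  structure(out, class = "measure_set")
}

#' @export
print.measure_set <- function(x, ...) {
  cat(sprintf("<measure_set> %s [%s]\n", x$cell_id, x$state_label))
  cat(sprintf("  Mean %.4f  SD %.4f  Skew %.4f  Kurtosis %.4f\n",
              x$S1, x$S2, x$S3, x$S4))
  cat(sprintf("  Lambda1 %.4f  alpha %.4f  slowest mode %.2f min\n",
              x$Lambda1, x$alpha, x$slowest_period_min))
  if (length(x$failures))
    cat("  missing:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}

#' One-row data frame in the standard measure order
#'
#' Column order follows the conventional report table: Mean, SD, Skew,
#' Kurtosis, lambda1, alpha.
#'
#' @param ms a `measure_set`.
#' @return one-row data frame.
#' @export
measure_row <- function(ms) {
  data.frame(cell_id = ms$cell_id, state = ms$state_label,
             Mean = ms$S1, SD = ms$S2, Skew = ms$S3, Kurtosis = ms$S4,
             lambda1 = ms$Lambda1, alpha = ms$alpha,
             slowest_period_min = ms$slowest_period_min)
}
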