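#' Time-delay embedding
#'
#' Embeds a scalar series into `dim`-dimensional delay coordinates:
#' point `i` is `(x[i], x[i+tau], ..., x[i+(dim-1)tau])`.
#'
#' @param series an [r_series()] or numeric vector.
#' @param dim embedding dimension.
#' @param tau delay in samples.
#' @return matrix with `n - (dim-1)*tau` rows and `dim` columns.
#' @export
delay_embed <- function(series, dim = 3, tau = 1) {
  x <- as_r_values(series)
  n <- length(x)
  N <- n - (dim - 1) * tau
  if (N < 1) md_error("morphodyn_too_short", "series too short for this embedding")
  vapply(0:(dim - 1), function(d) x[(1:N) + d * tau], numeric(N))
}

#' Broomhead-King eigenfunction embedding
#'
#' Singular-spectrum style phase-space reconstruction: the mean-removed
#' series is formed into an `(n-M+1) x M` trajectory matrix `X` of lagged
#' windows; the `M x M` autocovariance `C_M = X'X / (n-M+1)` is
#' eigendecomposed; the eigenvectors of the three largest eigenvalues are
#' composed with the series to give the eigenfunction trajectories
#' `Psi_i = X v_i`. Projecting on leading eigenvectors discards the
#' low-variance "noise" directions, so the reconstruction is relatively
#' denoised compared with raw delay coordinates.
#'
#' @param series an [r_series()] or numeric vector with `n >= 10 M`.
#' @param M window length (default 8, a typical correlation decay interval
#'   at 2 s sampling).
#' @return list of class `bk_embedding` with `M`, `eigenvalues` (descending),
#'   `eigenvectors` (columns, orthonormal), `psi` (three-column matrix of
#'   trajectories Psi1..Psi3), `C` (the autocovariance matrix).
#' @details Each eigenvector's sign is fixed so its largest-magnitude entry
#'   is positive, making plots and tests reproducible.
#' @export
bk_embed <- function(series, M = 8) {
  x <- as_r_values(series)
  n <- length(x)
  if (n < 10 * M) md_error("morphodyn_too_short", "need n >= 10*M")
  x <- x - mean(x)
  X <- delay_embed(x, dim = M, tau = 1)
  C <- crossprod(X) / nrow(X)
  e <- eigen(C, symmetric = TRUE)
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  psi <- X %*% V[, 1:3, drop = FALSE]
  colnames(psi) <- c("Psi1", "Psi2", "Psi3")
  structure(list(M = M, eigenvalues = e$values, eigenvectors = V,
                 psi = psi, C = C),
            class = "bk_embedding")
}

#' @export
print.bk_embedding <- function(x, ...) {
  ev <- x$eigenvalues
  cat(sprintf("<bk_embedding> M = %d, n' = %d, top-3 eigenvalue share = %.1f%%\n",
              x$M, nrow(x$psi), 100 * sum(ev[1:3]) / sum(ev)))
  invisible(x)
}

#' Recurrence plot
#'
#' Binary recurrence matrix of the delay-embedded series:
#' `RP[i, j] = 1` iff the Euclidean (or maximum-norm) distance between
#' embedded points i and j is at most `eps` (Heaviside thresholding). The
#' matrix is symmetric with an all-ones main diagonal.
#'
#' @param series an [r_series()] or numeric vector.
#' @param dim embedding dimension (default 3).
#' @param tau delay in samples (default 1).
#' @param eps closeness threshold (default 1, on the scale of the series).
#'   Because R(t) scales differ across data sources, `eps_quantile` offers a
#'   scale-fair alternative.
#' @param eps_quantile if non-NULL, override `eps` with this quantile of the
#'   off-diagonal pairwise distances (e.g. 0.1).
#' @param norm `"euclidean"` or `"max"`.
#' @return list of class `recurrence_plot` with the binary `matrix`, the
#'   embedding settings and the `eps` actually used.
#' @export
recurrence_plot <- function(series, dim = 3, tau = 1, eps = 1,
                            eps_quantile = NULL,
                            norm = c("euclidean", "max")) {
  norm <- match.arg(norm)
  if (eps < 0) md_error("morphodyn_domain", "eps must be >= 0")
  Y <- delay_embed(series, dim, tau)
  N <- nrow(Y)
  D <- pairwise_dist(Y, norm)
  if (!is.null(eps_quantile)) {
    eps <- stats::quantile(D[upper.tri(D)], eps_quantile, names = FALSE)
  }
  M <- (D <= eps) + 0L
  structure(list(matrix = M, dim = dim, tau = tau, eps = eps, norm = norm,
                 n_points = N),
            class = "recurrence_plot")
}

pairwise_dist <- function(Y, norm = "euclidean") {
  if (norm == "euclidean") {
    as.matrix(stats::dist(Y))
  } else {
    N <- nrow(Y)
    D <- matrix(0, N, N)
    for (k in seq_len(ncol(Y)))
      D <- pmax(D, abs(outer(Y[, k], Y[, k], "-")))
    D
  }
}

#' @export
print.recurrence_plot <- function(x, ...) {
  cat(sprintf("<recurrence_plot> %d x %d, dim = %d, tau = %d, eps = %.4g, density = %.3f\n",
              x$n_points, x$n_points, x$dim, x$tau, x$eps, recurrence_rate(x)$rate))
  invisible(x)
}

#' Recurrence rate and diagonal recurrence profile
#'
#' The recurrence rate is the off-diagonal density of 1s in the recurrence
#' matrix. The per-diagonal profile gives, for each offset `d >= 1`, the
#' fraction of recurrent pairs at temporal separation `d`; clustering of
#' return times shows up as a high coefficient of variation of this profile,
#' homogeneous (random-like) recurrences as a low one.
#'
#' @param rp a [recurrence_plot()].
#' @return list with `rate`, `profile` (data frame `offset`, `recurrence`),
#'   and `profile_cv` (SD/mean of the profile).
#' @export
recurrence_rate <- function(rp) {
  stopifnot(inherits(rp, "recurrence_plot"))
  M <- rp$matrix
  N <- nrow(M)
  off <- row(M) - col(M)
  ut <- off < 0
  rate <- sum(M[ut]) / sum(ut)
  prof <- vapply(seq_len(N - 1), function(d) {
    i <- seq_len(N - d)
    mean(M[cbind(i, i + d)])
  }, numeric(1))
  cv <- if (mean(prof) > 0) stats::sd(prof) / mean(prof) else NA_real_
  list(rate = rate,
       profile = data.frame(offset = seq_len(N - 1), recurrence = prof),
       profile_cv = cv)
}

#' Export a recurrence plot as PNG
#'
#' Black pixels mark recurrent pairs (binary coding).
#'
#' @param rp a [recurrence_plot()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_recurrence_png <- function(rp, path) {
  stopifnot(inherits(rp, "recurrence_plot"))
  img <- 1 - rp$matrix  # 0 = black = recurrent
  png::writePNG(t(img)[, rev(seq_len(nrow(img)))], path)
  invisible(path)
}

#' Export Broomhead-King trajectories as CSV
#'
#' One `(Psi1, Psi2, Psi3)` triple per time index.
#'
#' @param bk a [bk_embedding()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_bk_csv <- function(bk, path) {
  stopifnot(inherits(bk, "bk_embedding"))
  utils::write.csv(as.data.frame(bk$psi), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
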