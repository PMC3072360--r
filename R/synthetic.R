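#' Parameters of the synthetic silhouette-movie generator
#'
#' The generator emulates 2 s-sampled, 30 min silhouette recordings of single
#' cells in one of three behavioral shape states, so that the downstream
#' analysis can be exercised end to end without microscopy data. The shape
#' model is a star-convex outline
#' \deqn{r(\theta, t) = r_0 \left(1 + \mathrm{tex}(\theta) +
#'   \sum_k a_k(t) \cos(k\theta + \phi_k)\right)}
#' with angular Fourier modes `k = 2..8` driven by Ornstein-Uhlenbeck (OU)
#' amplitude processes (mode 1 is excluded: it is a pure-translation
#' surrogate, translation enters only through explicit drift). A static
#' per-cell texture `tex` on modes 9-20 emulates each cell's individual
#' microvillus border roughness, and a lognormal jitter on `r0` emulates cell
#' size spread; together these give the between-cell baseline variation in
#' mean roundness that real cell groups show.
#'
#' State defaults:
#' \describe{
#'   \item{idling}{fast, fine border flicker: all modes OU with relaxation
#'     time `theta = 1` s and stationary amplitude `sigma = 0.02`.}
#'   \item{treadmilling}{large intermittent protrusions without net
#'     translation: protrusion modes 2-4 with `theta = 60` s,
#'     `sigma = 0.05`, multiplied x`burst_gain` (3) at the OU target level
#'     whenever a two-state telegraph process (on-rate 1/120, off-rate
#'     1/60 per second) is on; fine modes 5-8 stay fast and weak
#'     (`theta = 2` s, `sigma = 0.01`).}
#'   \item{translocating}{polarized ellipse (fixed mode-2 amplitude 0.25)
#'     with constant centroid drift 0.15 px/s along +x, on a 512 px grid so
#'     the cell stays in frame; residual border flicker as in idling.}
#'   \item{transition}{idling regime for frames before `t_switch`,
#'     treadmilling regime from `t_switch` on; OU amplitudes are continuous
#'     across the switch.}
#' }
#'
#' @param state `"idling"`, `"treadmilling"`, `"translocating"` or
#'   `"transition"`.
#' @param n number of frames (>= 2; default 900).
#' @param dt sampling interval in seconds (default 2).
#' @param r0 base radius in pixels (>= 20; default 60). Per-cell radius is
#'   `r0 * exp(rnorm(1, 0, r0_cv))`.
#' @param grid square grid side in pixels (default 256; 512 for
#'   translocating).
#' @param seed integer root seed; per-mode and per-process child streams are
#'   derived deterministically from it, so adding modes does not perturb
#'   existing streams.
#' @param modes active dynamic Fourier modes.
#' @param theta,sigma per-mode OU relaxation times (s) and stationary
#'   amplitudes (recycled to `length(modes)`).
#' @param burst_modes,burst_gain,burst_on_rate,burst_off_rate telegraph burst
#'   process: while "on", the OU stationary amplitude of `burst_modes` is
#'   multiplied by `burst_gain`.
#' @param drift_velocity centroid drift in px/s (translocating only).
#' @param drift_angle drift direction in radians (0 = +x).
#' @param ellipse_a2 fixed mode-2 amplitude of the translocating outline.
#' @param t_switch switch frame index (transition only; `0 < t_switch < n`).
#' @param r0_cv lognormal sd of the per-cell radius jitter (0 disables).
#' @param texture_range range of the per-cell static texture level (slope
#'   scale of modes `texture_modes`); `c(0, 0)` disables texture.
#' @param texture_modes static texture mode numbers.
#' @return a list of class `synthetic_params`.
#' @export
synthetic_params <- function(state = c("idling", "treadmilling",
                                       "translocating", "transition"),
                             n = 900, dt = 2, r0 = 60,
                             grid = NULL, seed = 1,
                             modes = 2:8,
                             theta = NULL, sigma = NULL,
                             burst_modes = 2:4, burst_gain = 3,
                             burst_on_rate = 1 / 120, burst_off_rate = 1 / 60,
                             drift_velocity = 0.15, drift_angle = 0,
                             ellipse_a2 = 0.25,
                             t_switch = 283,
                             r0_cv = 0.10,
                             texture_range = c(0.15, 0.55),
                             texture_modes = 9:20) {
  state <- match.arg(state)
  nm <- length(modes)
  if (is.null(grid)) grid <- if (state == "translocating") 512L else 256L
  if (is.null(theta)) theta <- switch(state,
    idling = rep(1, nm),
    treadmilling = ifelse(modes %in% burst_modes, 60, 2),
    translocating = rep(1, nm),
    transition = rep(NA_real_, nm))  # per-regime values used instead
  if (is.null(sigma)) sigma <- switch(state,
    idling = rep(0.02, nm),
    treadmilling = ifelse(modes %in% burst_modes, 0.05, 0.01),
    translocating = rep(0.02, nm),
    transition = rep(NA_real_, nm))
  p <- structure(list(
    state = state, n = as.integer(n), dt = dt, r0 = r0, grid = as.integer(grid),
    seed = as.integer(seed), modes = modes,
    theta = rep_len(theta, nm), sigma = rep_len(sigma, nm),
    burst_modes = burst_modes, burst_gain = burst_gain,
    burst_on_rate = burst_on_rate, burst_off_rate = burst_off_rate,
    drift_velocity = drift_velocity, drift_angle = drift_angle,
    ellipse_a2 = ellipse_a2, t_switch = as.integer(t_switch),
    r0_cv = r0_cv, texture_range = texture_range, texture_modes = texture_modes
  ), class = "synthetic_params")
  validate_params(p)
  p
}

validate_params <- function(p) {
  if (p$r0 < 20) md_error("morphodyn_domain", "r0 must be >= 20 px")
  if (p$n < 2) md_error("morphodyn_domain", "n must be >= 2")
  if (p$dt <= 0) md_error("morphodyn_domain", "dt must be > 0")
  if (p$state == "transition" && (p$t_switch <= 0 || p$t_switch >= p$n))
    md_error("morphodyn_domain", "t_switch must lie strictly inside 1..n")
  guard <- sum(ifelse(p$modes %in% p$burst_modes, p$sigma * p$burst_gain, p$sigma),
               na.rm = TRUE)
  if (p$state != "transition" && guard >= 0.9)
    md_error("morphodyn_domain",
             sprintf("star-convexity guard violated: sum(sigma*gain) = %.2f >= 0.9", guard))
  invisible(p)
}

# ---- deterministic child streams -------------------------------------------

# Derive a reproducible child seed from a root seed and a stream label, so
# each mode / process has its own stream and adding streams never perturbs
# existing ones.
child_seed <- function(root, id) {
  h <- 0
  for (ch in utf8ToInt(id)) h <- (h * 131 + ch) %% 2147480009
  as.integer(((root %% 2147480009) * 7919 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---- stochastic drivers ----------------------------------------------------

# Exact one-step discretization of a (possibly time-varying-amplitude) OU
# process: a[t+1] = phi a[t] + sigma[t+1] sqrt(1-phi^2) z[t+1],
# phi = exp(-dt/theta). For constant sigma the stationary variance is
# sigma^2 exactly at every step.
ou_exact <- function(n, dt, theta, sigma_t, seed, init = NULL) {
  phi <- exp(-dt / theta)
  sfac <- sqrt(1 - phi^2)
  with_seed(seed, {
    z <- stats::rnorm(n)
    a <- numeric(n)
    a[1] <- if (is.null(init)) z[1] * sigma_t[1] else init
    for (i in seq_len(n - 1) + 1) a[i] <- phi * a[i - 1] + sigma_t[i] * sfac * z[i]
    a
  })
}

# Two-state telegraph (on/off) Markov chain with exact exponential switching
# probabilities per step; starts at the stationary occupancy.
telegraph_process <- function(n, dt, on_rate, off_rate, seed) {
  p_on <- 1 - exp(-on_rate * dt)
  p_off <- 1 - exp(-off_rate * dt)
  with_seed(seed, {
    s <- integer(n)
    s[1] <- stats::rbinom(1, 1, on_rate / (on_rate + off_rate))
    u <- stats::runif(n)
    for (i in seq_len(n - 1) + 1)
      s[i] <- if (s[i - 1] == 1L) { if (u[i] < p_off) 0L else 1L } else {
        if (u[i] < p_on) 1L else 0L }
    s
  })
}

# ---- shape model -----------------------------------------------------------

#' Closed star-convex outline from Fourier mode amplitudes
#'
#' Evaluates \eqn{r(\theta) = r_0 (1 + \sum_k a_k \cos(k\theta + \phi_k))}
#' on a uniform angle grid and returns the closed polygon, vertices ordered
#' counterclockwise (angle increasing, mathematical orientation).
#'
#' @param a named or plain numeric vector of mode amplitudes (one per entry
#'   of `modes`).
#' @param phi mode phases (radians).
#' @param r0 base radius (pixels).
#' @param modes mode numbers matching `a`.
#' @param center outline center `c(x, y)` in pixel coordinates.
#' @param n_vertices number of polygon vertices.
#' @return matrix with columns `x`, `y` and attributes carrying the radial
#'   model (`r0`, `modes`, `a`, `phi`, `center`, `theta_grid`, `radius`).
#' @export
radial_boundary <- function(a, phi, r0, modes = seq_along(a) + 1,
                            center = c(0, 0), n_vertices = 720) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  r <- radial_eval(th, r0, modes, a, phi)
  if (min(r) <= 0.1 * r0)
    md_error("morphodyn_star_convexity",
             sprintf("outline radius collapses to %.2f px (< 0.1 r0)", min(r)))
  structure(cbind(x = center[1] + r * cos(th), y = center[2] + r * sin(th)),
            r0 = r0, modes = modes, a = a, phi = phi, center = center,
            theta_grid = th, radius = r, class = c("radial_polygon", "matrix"))
}

radial_eval <- function(th, r0, modes, a, phi, texture = NULL) {
  r <- rep(r0, length(th))
  for (j in seq_along(modes)) r <- r + r0 * a[j] * cos(modes[j] * th + phi[j])
  if (!is.null(texture)) r <- r + r0 * texture(th)
  r
}

#' Rasterize a star-convex polygon onto a pixel grid
#'
#' A pixel belongs to the mask iff its center lies at a radius not exceeding
#' the outline's radius at that center's angle, measured from the shape
#' center. For polygons built by [radial_boundary()] the stored radial model
#' is evaluated exactly; for other star-convex polygons the radial function
#' is linearly interpolated between vertices.
#'
#' @param polygon a `radial_polygon` or a closed star-convex polygon matrix
#'   (columns x, y) with a `center` attribute.
#' @param grid square grid side in pixels.
#' @return a [binary_mask()].
#' @export
rasterize_polygon <- function(polygon, grid) {
  center <- attr(polygon, "center")
  if (is.null(center)) center <- colMeans(polygon)
  if (!is.null(attr(polygon, "radius"))) {
    rmax <- max(attr(polygon, "radius"))
    rfun <- function(th) {
      radial_eval(th, attr(polygon, "r0"), attr(polygon, "modes"),
                  attr(polygon, "a"), attr(polygon, "phi"))
    }
  } else {
    dx <- polygon[, 1] - center[1]; dy <- polygon[, 2] - center[2]
    thv <- atan2(dy, dx); rv <- sqrt(dx^2 + dy^2)
    o <- order(thv); thv <- thv[o]; rv <- rv[o]
    rmax <- max(rv)
    rfun <- function(th) {
      th <- ((th + pi) %% (2 * pi)) - pi
      stats::approx(c(thv[length(thv)] - 2 * pi, thv, thv[1] + 2 * pi),
                    c(rv[length(rv)], rv, rv[1]), xout = th)$y
    }
  }
  if (center[1] - rmax < 1 || center[1] + rmax > grid - 2 ||
      center[2] - rmax < 1 || center[2] + rmax > grid - 2)
    md_error("morphodyn_outside_grid", "polygon does not fit inside the grid")
  g <- raster_radial(center, rmax, rfun, grid)
  binary_mask(g, validate = FALSE)
}

# core radial inclusion test on a cropped window; returns full-grid matrix
raster_radial <- function(center, rmax, rfun, grid) {
  cx <- center[1]; cy <- center[2]
  # image convention: row = y + 1 (y down); the radial model lives in y-up
  # coordinates, so flip the sign of dy for the angle
  cols <- max(1, floor(cx - rmax)):min(grid, ceiling(cx + rmax) + 2)
  rows <- max(1, floor(cy - rmax)):min(grid, ceiling(cy + rmax) + 2)
  dx <- rep(cols - 1 - cx, each = length(rows))
  dy <- rep(rows - 1 - cy, times = length(cols))
  th <- atan2(-dy, dx)
  rho <- sqrt(dx^2 + dy^2)
  inc <- rho <= rfun(th)
  g <- matrix(0L, grid, grid)
  g[cbind(rep(rows, times = length(cols)), rep(cols, each = length(rows)))[inc, , drop = FALSE]] <- 1L
  g
}

# ---- the simulator core ----------------------------------------------------

# Build the ground-truth stochastic trajectories for a recording. Returns
# amplitudes AFTER burst modulation (what the outline actually uses),
# together with phases, texture, per-cell radius, centers and the telegraph
# path. Star-convexity is enforced by rescaling the whole deviation field of
# an offending frame so its minimum radius equals 0.1 r0; clipped frames are
# counted.
synth_truth <- function(p) {
  nm <- length(p$modes)
  seed <- p$seed
  cell <- with_seed(child_seed(seed, "cell"), {
    list(r0 = p$r0 * exp(stats::rnorm(1, 0, p$r0_cv)),
         tex_level = stats::runif(1, p$texture_range[1], p$texture_range[2]),
         tex_g = abs(stats::rnorm(length(p$texture_modes))),
         tex_phi = stats::runif(length(p$texture_modes), 0, 2 * pi))
  })
  tex_b <- cell$tex_level * cell$tex_g / p$texture_modes
  phi <- with_seed(child_seed(seed, "phases"), stats::runif(nm, 0, 2 * pi))

  idle_theta <- rep(1, nm); idle_sigma <- rep(0.02, nm)
  tm_theta <- ifelse(p$modes %in% p$burst_modes, 60, 2)
  tm_sigma <- ifelse(p$modes %in% p$burst_modes, 0.05, 0.01)

  tg <- rep(0L, p$n)
  a <- matrix(0, p$n, nm)
  if (p$state == "idling" || p$state == "translocating") {
    for (j in seq_len(nm))
      a[, j] <- ou_exact(p$n, p$dt, p$theta[j], rep(p$sigma[j], p$n),
                         child_seed(seed, paste0("mode", p$modes[j])))
    if (p$state == "translocating") {
      # polarized ellipse: fixed mode-2 amplitude replaces its OU mean
      j2 <- match(2, p$modes)
      if (!is.na(j2)) a[, j2] <- a[, j2] + p$ellipse_a2
    }
  } else if (p$state == "treadmilling") {
    tg <- telegraph_process(p$n, p$dt, p$burst_on_rate, p$burst_off_rate,
                            child_seed(seed, "telegraph"))
    for (j in seq_len(nm)) {
      sig_t <- rep(p$sigma[j], p$n)
      if (p$modes[j] %in% p$burst_modes)
        sig_t <- p$sigma[j] * (1 + (p$burst_gain - 1) * tg)
      a[, j] <- ou_exact(p$n, p$dt, p$theta[j], sig_t,
                         child_seed(seed, paste0("mode", p$modes[j])))
    }
  } else { # transition: idling regime then treadmilling regime, continuous a
    n1 <- p$t_switch; n2 <- p$n - p$t_switch
    tg2 <- telegraph_process(n2, p$dt, p$burst_on_rate, p$burst_off_rate,
                             child_seed(seed, "telegraph"))
    tg <- c(rep(0L, n1), tg2)
    for (j in seq_len(nm)) {
      a1 <- ou_exact(n1, p$dt, idle_theta[j], rep(idle_sigma[j], n1),
                     child_seed(seed, paste0("mode", p$modes[j], "pre")))
      sig_t <- rep(tm_sigma[j], n2)
      if (p$modes[j] %in% p$burst_modes)
        sig_t <- tm_sigma[j] * (1 + (p$burst_gain - 1) * tg2)
      a2 <- ou_exact(n2, p$dt, tm_theta[j], sig_t,
                     child_seed(seed, paste0("mode", p$modes[j], "post")),
                     init = a1[n1])
      a[, j] <- c(a1, a2)
    }
  }

  # centers: fixed at grid middle, except translocating drift along drift_angle
  c0 <- (p$grid - 1) / 2
  centers <- matrix(c0, p$n, 2)
  if (p$state == "translocating") {
    tsec <- (seq_len(p$n) - 1) * p$dt
    total <- p$drift_velocity * (p$n - 1) * p$dt
    # start half the path back from the middle so the full track stays in frame
    centers[, 1] <- c0 + (p$drift_velocity * tsec - total / 2) * cos(p$drift_angle)
    centers[, 2] <- c0 + (p$drift_velocity * tsec - total / 2) * sin(p$drift_angle)
  }

  # Per-frame clipping of the dynamic deviation, evaluated on a dense angle
  # grid: the outline must stay star-convex (radius > 0.1 r0) and inside the
  # field of view. Offending frames have their dynamic amplitude vector
  # rescaled (never rejected, so the series length stays exact).
  thg <- seq(0, 2 * pi, length.out = 1024 + 1)[-1025]
  texv <- rep(0, length(thg))
  for (j in seq_along(p$texture_modes))
    texv <- texv + tex_b[j] * cos(p$texture_modes[j] * thg + cell$tex_phi[j])
  texmin <- min(texv); texmax <- max(texv)
  if (1 + texmin <= 0.1)
    md_error("morphodyn_star_convexity", "static texture violates star-convexity")
  # largest admissible outward deviation given the frame centers (3 px margin)
  margin <- pmin(centers[, 1], centers[, 2],
                 p$grid - 1 - centers[, 1], p$grid - 1 - centers[, 2]) - 3
  Lmax <- margin / cell$r0 - 1
  if (texmax >= min(Lmax))
    md_error("morphodyn_outside_grid",
             "static texture does not fit inside the grid; enlarge grid or reduce r0")
  cosmat <- vapply(seq_len(nm), function(j) cos(p$modes[j] * thg + phi[j]),
                   numeric(length(thg)))
  clipped <- 0L
  scale <- rep(1, p$n)
  devmax <- numeric(p$n)
  for (t in seq_len(p$n)) {
    dyn <- drop(cosmat %*% a[t, ])
    dmin <- min(dyn); dmax <- max(dyn)
    s <- 1
    if (dmin < 0) s <- min(s, (-0.9 - texmin) / dmin)
    if (dmax > 0) s <- min(s, (Lmax[t] - texmax) / dmax)
    if (s < 1) {
      scale[t] <- s
      clipped <- clipped + 1L
    }
    devmax[t] <- max(texv + scale[t] * dyn)
  }
  list(a = a * scale, phi = phi, tex_b = tex_b, tex_phi = cell$tex_phi,
       r0_cell = cell$r0, centers = centers, telegraph = tg,
       clipped_frames = clipped, scale = scale, devmax = devmax)
}

# rasterize frame t of a truth object; returns the full-grid matrix
truth_frame <- function(p, tr, t, pixcache = NULL) {
  r0 <- tr$r0_cell
  rfun <- function(th) {
    r <- rep(r0, length(th))
    for (j in seq_along(p$texture_modes))
      r <- r + r0 * tr$tex_b[j] * cos(p$texture_modes[j] * th + tr$tex_phi[j])
    for (j in seq_along(p$modes))
      r <- r + r0 * tr$a[t, j] * cos(p$modes[j] * th + tr$phi[j])
    r
  }
  # actual outline extent (dense-grid maximum plus a small sampling margin)
  rmax_bound <- r0 * (1 + tr$devmax[t]) * 1.01 + 1
  center <- tr$centers[t, ]
  if (center[1] - rmax_bound < 1 || center[1] + rmax_bound > p$grid - 2 ||
      center[2] - rmax_bound < 1 || center[2] + rmax_bound > p$grid - 2)
    md_error("morphodyn_outside_grid",
             sprintf("frame %d: outline does not fit inside the %d px grid", t, p$grid))
  if (!is.null(pixcache)) {
    # fixed-center fast path: static base radius and per-mode cosines are
    # precomputed on the cached pixel grid; one matrix-vector product per frame
    rth <- pixcache$base + drop(pixcache$dyncos %*% tr$a[t, ])
    inc <- pixcache$rho <= rth
    g <- matrix(0L, p$grid, p$grid)
    g[pixcache$idx[inc]] <- 1L
    return(g)
  }
  raster_radial(center, rmax_bound, rfun, p$grid)
}

make_pixcache <- function(p, tr) {
  if (p$state == "translocating") return(NULL)  # moving center: no fixed grid to cache
  c0 <- tr$centers[1, ]
  rmax <- min(tr$r0_cell * (1 + max(tr$devmax)) * 1.01 + 1, (p$grid - 1) / 2 - 1)
  cols <- max(1, floor(c0[1] - rmax)):min(p$grid, ceiling(c0[1] + rmax) + 2)
  rows <- max(1, floor(c0[2] - rmax)):min(p$grid, ceiling(c0[2] + rmax) + 2)
  dx <- rep(cols - 1 - c0[1], each = length(rows))
  dy <- rep(rows - 1 - c0[2], times = length(cols))
  keep <- sqrt(dx^2 + dy^2) <= rmax
  idx <- cbind(rep(rows, times = length(cols)), rep(cols, each = length(rows)))[keep, , drop = FALSE]
  th <- atan2(-dy[keep], dx[keep])
  r0 <- tr$r0_cell
  base <- rep(r0, length(th))
  for (j in seq_along(p$texture_modes))
    base <- base + r0 * tr$tex_b[j] * cos(p$texture_modes[j] * th + tr$tex_phi[j])
  dyncos <- vapply(seq_along(p$modes),
                   function(j) r0 * cos(p$modes[j] * th + tr$phi[j]),
                   numeric(length(th)))
  list(th = th, rho = sqrt(dx^2 + dy^2)[keep],
       idx = (idx[, 2] - 1L) * p$grid + idx[, 1],
       base = base, dyncos = dyncos)
}

#' Simulate a single-state synthetic silhouette recording
#'
#' Generates a seeded, state-labeled movie of binary masks together with the
#' ground-truth amplitude trajectories that produced it. Identical
#' `(params, seed)` give bit-identical recordings.
#'
#' @param params a [synthetic_params()] object.
#' @return a list of class `synthetic_recording` with `frames` (list of
#'   [binary_mask()]), `params`, and `truth` (effective amplitudes `a`
#'   (n x modes), `phi`, texture, per-cell radius, centers, telegraph path,
#'   number of star-convexity-clipped frames).
#' @seealso [simulate_roundness_series()] for the memory-light path that
#'   computes R(t) without retaining frames.
#' @export
simulate_state <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  if (params$state == "transition")
    return(simulate_transition(params))
  tr <- synth_truth(params)
  pixcache <- make_pixcache(params, tr)
  frames <- vector("list", params$n)
  for (t in seq_len(params$n)) {
    g <- truth_frame(params, tr, t, pixcache)
    frames[[t]] <- binary_mask(g, frame_index = t, timestamp = (t - 1) * params$dt,
                               validate = FALSE)
  }
  structure(list(frames = frames, params = params, truth = tr),
            class = "synthetic_recording")
}

#' Simulate an idling-to-treadmilling transition recording
#'
#' Idling regime for frames `1..t_switch-1`, treadmilling regime from
#' `t_switch` on; the OU mode amplitudes are continuous at the switch and the
#' ground-truth switch index is stored in the recording.
#'
#' @param params a [synthetic_params()] with `state = "transition"`.
#' @return a `synthetic_recording`; `truth$t_switch` holds the switch index.
#' @export
simulate_transition <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  if (params$state != "transition")
    md_error("morphodyn_domain", "params$state must be 'transition'")
  tr <- synth_truth(params)
  tr$t_switch <- params$t_switch
  pixcache <- make_pixcache(params, tr)
  frames <- vector("list", params$n)
  for (t in seq_len(params$n)) {
    g <- truth_frame(params, tr, t, pixcache)
    frames[[t]] <- binary_mask(g, frame_index = t, timestamp = (t - 1) * params$dt,
                               validate = FALSE)
  }
  structure(list(frames = frames, params = params, truth = tr),
            class = "synthetic_recording")
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf("<synthetic_recording> state = %s, n = %d frames, grid = %d px, seed = %d\n",
              x$params$state, x$params$n, x$params$grid, x$params$seed))
  invisible(x)
}

#' Simulate a recording and return its R(t) series directly
#'
#' Streams the frames of [simulate_state()] / [simulate_transition()] through
#' the roundness pipeline one at a time, so a full 900-frame movie never
#' resides in memory. Numerically identical to materializing the recording
#' and calling [roundness_series()] on its frames.
#'
#' @param params a [synthetic_params()] object.
#' @param feret also compute each frame's maximum Feret diameter (needed by
#'   [displacement_ratio()]; adds a convex-hull computation per frame).
#' @return an [r_series()]; attribute `"metrics"` holds the per-frame
#'   geometry (plus column `feret` with each frame's maximum Feret diameter
#'   when requested) and attribute `"truth"` the generator ground truth.
#' @export
simulate_roundness_series <- function(params, feret = TRUE) {
  stopifnot(inherits(params, "synthetic_params"))
  tr <- synth_truth(params)
  if (params$state == "transition") tr$t_switch <- params$t_switch
  pixcache <- make_pixcache(params, tr)
  n <- params$n
  met <- matrix(NA_real_, n, 8,
                dimnames = list(NULL, c("p", "A", "r1", "r2", "R",
                                        "centroid_x", "centroid_y", "feret")))
  for (t in seq_len(n)) {
    g <- truth_frame(params, tr, t, pixcache)
    met[t, 1:7] <- frame_geometry(g)
    if (feret) met[t, 8] <- feret_diameter(g)
  }
  met <- as.data.frame(met)
  met$time_s <- (seq_len(n) - 1) * params$dt
  rs <- r_series(met$R, dt = params$dt,
                 cell_id = sprintf("%s_seed%d", params$state, params$seed),
                 state_label = params$state)
  attr(rs, "metrics") <- met[, c("time_s", "p", "A", "r1", "r2", "R",
                                 "centroid_x", "centroid_y", "feret")]
  attr(rs, "truth") <- tr
  rs
}

#' Write a synthetic recording to disk
#'
#' Saves the frames as a multi-page TIFF (0/1 grayscale) and the generator
#' ground truth (parameter echo, amplitude trajectories, phases, telegraph
#' path, switch index if any) as JSON.
#'
#' @param rec a `synthetic_recording`.
#' @param tiff_path output TIFF path.
#' @param truth_path optional JSON path for the ground truth.
#' @return `tiff_path`, invisibly.
#' @export
write_recording <- function(rec, tiff_path, truth_path = NULL) {
  stopifnot(inherits(rec, "synthetic_recording"))
  pages <- lapply(rec$frames, function(f) f$grid * 1.0)
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 8L, compression = "none")
  if (!is.null(truth_path)) {
    tr <- rec$truth
    out <- list(
      params = unclass(rec$params),
      r0_cell = tr$r0_cell, phi = tr$phi,
      tex_b = tr$tex_b, tex_phi = tr$tex_phi,
      amplitudes = tr$a, telegraph = tr$telegraph,
      clipped_frames = tr$clipped_frames
    )
    if (!is.null(tr$t_switch)) out$t_switch <- tr$t_switch
    jsonlite::write_json(out, truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tiff_path)
}
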