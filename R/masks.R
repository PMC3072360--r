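#' Binary silhouette masks
#'
#' A `binary_mask` wraps one frame's 0/1 silhouette grid together with its
#' frame index and timestamp. The grid is an integer matrix in row-major image
#' convention: row 1 is the top of the image, pixel centers sit at 0-based
#' integer coordinates `(x = col - 1, y = row - 1)`.
#'
#' A valid mask contains exactly one 8-connected foreground component, has no
#' interior holes (background enclosed by foreground, 4-connected), a nonempty
#' foreground, and does not touch the image border (border-touching cells are
#' rejected because their perimeter and area are censored by the field of
#' view).
#'
#' @param grid integer/logical matrix of 0s and 1s (1 = cell).
#' @param frame_index integer frame number (1-based).
#' @param timestamp acquisition time in seconds.
#' @param validate check the mask invariants (single component, no holes,
#'   off-border)? Rasterized synthetic frames are constructed valid and skip
#'   the check.
#' @return an object of class `binary_mask`.
#' @seealso [extract_mask()] which builds a valid mask from an arbitrary
#'   image frame.
#' @export
binary_mask <- function(grid, frame_index = 1L, timestamp = 0, validate = TRUE) {
  grid <- mask_grid(grid)
  if (validate) validate_mask(grid)
  structure(
    list(grid = grid, height = nrow(grid), width = ncol(grid),
         frame_index = as.integer(frame_index), timestamp = as.numeric(timestamp)),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %dx%d px, frame %d, t = %gs, area %d px\n",
              x$height, x$width, x$frame_index, x$timestamp, sum(x$grid)))
  invisible(x)
}

# Accept a binary_mask, logical or 0/1 numeric matrix; return integer matrix.
mask_grid <- function(x) {
  if (inherits(x, "binary_mask")) return(x$grid)
  if (!is.matrix(x)) md_error("morphodyn_bad_mask", "mask must be a matrix or binary_mask")
  if (is.logical(x)) x <- x + 0L
  if (!all(x %in% c(0, 1))) md_error("morphodyn_bad_mask", "mask values must be 0/1")
  storage.mode(x) <- "integer"
  x
}

validate_mask <- function(g) {
  if (sum(g) == 0L) md_error("morphodyn_empty_foreground", "mask has empty foreground")
  if (mask_touches_border(g))
    md_error("morphodyn_border_touch", "foreground touches the image border")
  lab <- label_components(g)
  if (max(lab) > 1L)
    md_error("morphodyn_bad_mask", sprintf("mask has %d foreground components", max(lab)))
  if (any(fill_holes(g) != g))
    md_error("morphodyn_bad_mask", "mask has interior holes")
  invisible(TRUE)
}

mask_touches_border <- function(g) {
  any(g[1, ] == 1L) || any(g[nrow(g), ] == 1L) || any(g[, 1] == 1L) || any(g[, ncol(g)] == 1L)
}

# one 8-neighborhood dilation step, zero-padded edges
dilate8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], 0L)
  dn <- rbind(0L, m[-nr, , drop = FALSE])
  shift_lr <- function(x) list(cbind(x[, -1, drop = FALSE], 0L),
                               cbind(0L, x[, -nc, drop = FALSE]))
  s1 <- shift_lr(m); s2 <- shift_lr(up); s3 <- shift_lr(dn)
  (m | up | dn | s1[[1]] | s1[[2]] | s2[[1]] | s2[[2]] | s3[[1]] | s3[[2]]) + 0L
}

dilate4 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], 0L)
  dn <- rbind(0L, m[-nr, , drop = FALSE])
  lf <- cbind(m[, -1, drop = FALSE], 0L)
  rt <- cbind(0L, m[, -nc, drop = FALSE])
  (m | up | dn | lf | rt) + 0L
}

# grow a seed inside `inside` until the component is saturated
flood <- function(seed, inside, connectivity = 8L) {
  dil <- if (connectivity == 8L) dilate8 else dilate4
  comp <- seed
  repeat {
    grown <- (dil(comp) & inside) + 0L
    if (sum(grown) == sum(comp)) return(comp)
    comp <- grown
  }
}

# Label 8-connected foreground components; returns integer matrix of labels
# (0 = background). Components are seeded in topmost-then-leftmost order so a
# tie between equal-sized components resolves deterministically.
label_components <- function(g) {
  lab <- matrix(0L, nrow(g), ncol(g))
  remaining <- g
  k <- 0L
  while (sum(remaining) > 0L) {
    idx <- which(remaining == 1L, arr.ind = TRUE)
    # topmost row first, then leftmost column
    seed_at <- idx[order(idx[, 1], idx[, 2])[1], , drop = FALSE]
    seed <- matrix(0L, nrow(g), ncol(g))
    seed[seed_at[1, 1], seed_at[1, 2]] <- 1L
    comp <- flood(seed, remaining, 8L)
    k <- k + 1L
    lab[comp == 1L] <- k
    remaining <- remaining * (1L - comp)
  }
  lab
}

# Fill interior holes: background 4-connected to the border stays background,
# everything else becomes foreground (EBImage::fillHull implements exactly
# this Jordan-pair convention).
fill_holes <- function(g) {
  out <- EBImage::fillHull(g)
  storage.mode(out) <- "integer"
  out
}

#' Extract a clean single-cell mask from an image frame
#'
#' Thresholds a grayscale frame (binary frames pass through), keeps the
#' largest 8-connected foreground component, and fills interior holes. This is
#' the cleanup that turns a raw silhouette image into the one-component,
#' hole-free mask the geometry operations assume.
#'
#' @param frame numeric matrix; either already binary (two distinct values)
#'   or grayscale.
#' @param threshold_policy `"auto"` (binary passthrough, Otsu otherwise),
#'   `"otsu"`, or a numeric threshold in the frame's value range (foreground
#'   is `> threshold`).
#' @param frame_index,timestamp metadata forwarded to [binary_mask()].
#' @return a [binary_mask()].
#' @details If several foreground components tie for largest, the one whose
#'   topmost-leftmost pixel comes first in row-major order wins. An error of
#'   class `morphodyn_empty_foreground` is raised when no pixel passes the
#'   threshold. The cleaned mask must not touch the image border.
#' @export
extract_mask <- function(frame, threshold_policy = "auto",
                         frame_index = 1L, timestamp = 0) {
  if (!is.matrix(frame) || length(frame) == 0)
    md_error("morphodyn_bad_mask", "frame must be a nonempty matrix")
  vals <- unique(as.vector(frame))
  if (is.numeric(threshold_policy)) {
    g <- (frame > threshold_policy) + 0L
  } else if (identical(threshold_policy, "auto") && length(vals) <= 2) {
    g <- (frame > min(vals)) + 0L
    if (length(vals) == 1) g <- (frame > 0) + 0L
  } else {
    # Otsu on grayscale; EBImage expects intensities in [0, 1]
    rng <- range(frame)
    fr01 <- if (diff(rng) > 0) (frame - rng[1]) / diff(rng) else frame * 0
    thr <- EBImage::otsu(fr01, range = c(0, 1))
    g <- (fr01 > thr) + 0L
  }
  if (sum(g) == 0L)
    md_error("morphodyn_empty_foreground", "no pixel passes the threshold")
  lab <- label_components(g)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)  # first (topmost-leftmost seeded) of equal largest
  g <- (lab == keep) + 0L
  g <- fill_holes(g)
  binary_mask(g, frame_index = frame_index, timestamp = timestamp)
}

#' Area pixel count
#'
#' The cell's area \eqn{A} is the number of foreground pixels in its
#' silhouette.
#'
#' @param mask a [binary_mask()] or 0/1 matrix.
#' @return integer pixel count.
#' @export
count_area <- function(mask) {
  g <- mask_grid(mask)
  sum(g)
}

#' Perimeter pixel count
#'
#' The cell's perimeter \eqn{p} is the number of foreground pixels outlining
#' the silhouette: pixels with at least one 4-neighbor background pixel
#' (pixels outside the image count as background). This literal
#' boundary-pixel count undercounts diagonal runs relative to the geometric
#' arc length; see [roundness()] for the consequence and
#' `chain_code = TRUE` for a weighted alternative.
#'
#' @param mask a [binary_mask()] or 0/1 matrix.
#' @param chain_code if `TRUE`, weight diagonal boundary steps by
#'   \eqn{\sqrt 2} (8-connected chain-code length) instead of counting
#'   boundary pixels. Off by default; all shipped results use the literal
#'   count.
#' @return perimeter count (integer, or numeric when `chain_code = TRUE`).
#' @export
trace_perimeter <- function(mask, chain_code = FALSE) {
  g <- mask_grid(mask)
  if (!chain_code) return(sum(boundary_pixels(g)))
  chain_code_length(g)
}

# Moore-neighbor boundary trace; returns the chain length with lateral steps
# weighted 1 and diagonal steps sqrt(2). Single pixels count 1.
chain_code_length <- function(g) {
  idx <- which(g == 1L, arr.ind = TRUE)
  if (nrow(idx) == 1) return(1)
  start <- idx[order(idx[, 1], idx[, 2])[1], ]
  # 8 neighbors in clockwise order starting from west
  moves <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                 c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  at <- function(r, c) r >= 1 && r <= nrow(g) && c >= 1 && c <= ncol(g) && g[r, c] == 1L
  cur <- start
  backtrack <- 1L  # came from the west (start is topmost-leftmost)
  len <- 0
  repeat {
    found <- FALSE
    for (k in 0:7) {
      d <- ((backtrack - 1L + k) %% 8L) + 1L
      nr <- cur[1] + moves[d, 1]; nc <- cur[2] + moves[d, 2]
      if (at(nr, nc)) {
        step <- sqrt(sum(moves[d, ]^2))
        len <- len + step
        # next backtrack direction: opposite of the move we just made, +1
        backtrack <- ((d + 4L - 1L + 1L) %% 8L) + 1L
        cur <- c(nr, nc)
        found <- TRUE
        break
      }
    }
    if (!found) return(1)  # isolated pixel reached via cleanup edge case
    if (all(cur == start) && len > 0) return(len)
    if (len > 8 * length(g)) return(len)  # safety, never expected
  }
}

# foreground pixels with >= 1 background 4-neighbor
boundary_pixels <- function(g) {
  nr <- nrow(g); nc <- ncol(g)
  up <- rbind(g[-1, , drop = FALSE], 0L)
  dn <- rbind(0L, g[-nr, , drop = FALSE])
  lf <- cbind(g[, -1, drop = FALSE], 0L)
  rt <- cbind(0L, g[, -nc, drop = FALSE])
  (g == 1L & (up == 0L | dn == 0L | lf == 0L | rt == 0L)) + 0L
}

#' Relative radial roundness from perimeter and area counts
#'
#' Computes the circle-equivalent radii \eqn{r_1 = p/2\pi} (from the
#' perimeter count) and \eqn{r_2 = \sqrt{A/\pi}} (from the area count) and
#' their ratio, the relative radial roundness \eqn{R = r_1/r_2}. For exact
#' continuous-circle inputs (\eqn{p = 2\pi r}, \eqn{A = \pi r^2}) the ratio
#' is exactly 1 and \eqn{\log R = 0}, the lower anchor of the order
#' parameter. Rasterized circles do not hit 1 exactly because the
#' boundary-pixel count is not the geometric circumference.
#'
#' @param p perimeter count (> 0); may be non-integer (continuous-limit
#'   values or chain-code lengths).
#' @param A area count (> 0).
#' @return a list of class `silhouette_metrics` with fields `p`, `A`, `r1`,
#'   `r2`, `R`.
#' @examples
#' roundness(2 * pi * 10, pi * 100)$R  # exact circle -> 1
#' @export
roundness <- function(p, A) {
  if (!is.numeric(p) || !is.numeric(A) || length(p) != 1 || length(A) != 1 ||
      !is.finite(p) || !is.finite(A) || p <= 0 || A <= 0)
    md_error("morphodyn_domain", "p and A must be positive finite scalars")
  r1 <- p / (2 * pi)
  r2 <- sqrt(A / pi)
  structure(list(p = p, A = A, r1 = r1, r2 = r2, R = r1 / r2),
            class = "silhouette_metrics")
}

#' @export
print.silhouette_metrics <- function(x, ...) {
  cat(sprintf("<silhouette_metrics> p = %g, A = %g, r1 = %.3f, r2 = %.3f, R = %.4f\n",
              x$p, x$A, x$r1, x$r2, x$R))
  invisible(x)
}

#' Roundness time series from a silhouette movie
#'
#' Applies [trace_perimeter()], [count_area()] and [roundness()] to every
#' frame and assembles the order-parameter series R(t). Per-frame geometry
#' (perimeter, area, radii, centroid) is attached as the `"metrics"`
#' attribute, a data frame with one row per frame.
#'
#' @param frames list of [binary_mask()] objects or 0/1 matrices, in time
#'   order.
#' @param dt sampling interval in seconds.
#' @param cell_id,state_label series metadata, see [r_series()].
#' @param validate validate each frame's mask invariants (skipped for frames
#'   already constructed as valid `binary_mask` objects).
#' @return an [r_series()] of length `length(frames)`.
#' @export
roundness_series <- function(frames, dt = 2, cell_id = "cell",
                             state_label = "unknown", validate = TRUE) {
  if (length(frames) < 2)
    md_error("morphodyn_domain", "need at least 2 frames")
  n <- length(frames)
  met <- vector("list", n)
  for (i in seq_len(n)) {
    f <- frames[[i]]
    g <- tryCatch(
      {
        if (inherits(f, "binary_mask")) f$grid
        else { g0 <- mask_grid(f); if (validate) validate_mask(g0); g0 }
      },
      morphodyn_error = function(e)
        md_error(class(e)[1], sprintf("frame %d: %s", i, conditionMessage(e)))
    )
    met[[i]] <- frame_geometry(g)
  }
  met <- do.call(rbind, met)
  met <- as.data.frame(met)
  met$time_s <- (seq_len(n) - 1) * dt
  met <- met[, c("time_s", "p", "A", "r1", "r2", "R", "centroid_x", "centroid_y")]
  rs <- r_series(met$R, dt = dt, cell_id = cell_id, state_label = state_label)
  attr(rs, "metrics") <- met
  rs
}

# per-frame geometry on a raw grid (no validation); used by both the movie
# reader path and the streaming synthetic path
frame_geometry <- function(g) {
  A <- sum(g)
  p <- sum(boundary_pixels(g))
  idx <- which(g == 1L, arr.ind = TRUE)
  c(p = p, A = A, r1 = p / (2 * pi), r2 = sqrt(A / pi),
    R = (p / (2 * pi)) / sqrt(A / pi),
    centroid_x = mean(idx[, 2]) - 1, centroid_y = mean(idx[, 1]) - 1)
}

# maximum Feret diameter: max pairwise distance between boundary pixel
# centers, computed on the convex hull for speed
feret_diameter <- function(g) {
  b <- which(boundary_pixels(g) == 1L, arr.ind = TRUE)
  if (nrow(b) == 1) return(0)
  xy <- cbind(b[, 2] - 1, b[, 1] - 1)
  h <- grDevices::chull(xy)
  hp <- xy[h, , drop = FALSE]
  max(stats::dist(hp))
}

#' Net displacement relative to cell size, and the translocation flag
#'
#' The study's inclusion rule for non-translocating cells is that total
#' movement stays below 1.5 times the cell's maximum diameter. This computes
#' `ratio` = (maximum centroid distance from the first frame's centroid) /
#' (maximum per-frame Feret diameter), and flags the recording as
#' translocating when `ratio >= 1.5`.
#'
#' @param x a list of masks/matrices, or a per-frame metrics data frame with
#'   columns `centroid_x`, `centroid_y`, `feret` (as produced by
#'   [simulate_roundness_series()]).
#' @return list with `ratio` (dimensionless) and `translocating` (logical).
#' @export
displacement_ratio <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("centroid_x", "centroid_y", "feret") %in% names(x)))
    if (all(is.na(x$feret)))
      md_error("morphodyn_domain",
               "metrics carry no Feret diameters; rerun with feret = TRUE")
    cx <- x$centroid_x; cy <- x$centroid_y; fer <- max(x$feret, na.rm = TRUE)
  } else {
    if (length(x) < 2) md_error("morphodyn_domain", "need at least 2 frames")
    gs <- lapply(x, mask_grid)
    cen <- t(vapply(gs, function(g) {
      idx <- which(g == 1L, arr.ind = TRUE)
      c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)
    }, numeric(2)))
    cx <- cen[, 1]; cy <- cen[, 2]
    fer <- max(vapply(gs, feret_diameter, numeric(1)))
  }
  d <- sqrt((cx - cx[1])^2 + (cy - cy[1])^2)
  ratio <- if (fer > 0) max(d) / fer else 0
  list(ratio = ratio, translocating = ratio >= 1.5)
}
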