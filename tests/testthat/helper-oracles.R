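# Brute-force geometry oracles, independent of the package implementation.

# pixel-center rasterization of a disk: pixel (x, y) in iff (x-cx)^2+(y-cy)^2 <= r^2
disk_mask <- function(r, size = NULL, center = NULL) {
  if (is.null(size)) size <- 2 * ceiling(r) + 5
  if (is.null(center)) center <- c((size - 1) / 2, (size - 1) / 2)
  x <- matrix(rep(0:(size - 1), each = size), size, size)   # col index = x
  y <- matrix(rep(0:(size - 1), times = size), size, size)  # row index = y
  ((x - center[1])^2 + (y - center[2])^2 <= r^2) + 0L
}

ellipse_mask <- function(a, b, size = NULL) {
  if (is.null(size)) size <- 2 * ceiling(max(a, b)) + 5
  c0 <- (size - 1) / 2
  x <- matrix(rep(0:(size - 1), each = size), size, size)
  y <- matrix(rep(0:(size - 1), times = size), size, size)
  (((x - c0) / a)^2 + ((y - c0) / b)^2 <= 1) + 0L
}

# independent recount of area and boundary-pixel perimeter via explicit loops
brute_area <- function(g) {
  n <- 0L
  for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g))) if (g[i, j] == 1L) n <- n + 1L
  n
}

brute_perimeter <- function(g) {
  nr <- nrow(g); nc <- ncol(g)
  at <- function(i, j) if (i < 1 || i > nr || j < 1 || j > nc) 0L else g[i, j]
  n <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (g[i, j] == 1L &&
        (at(i - 1, j) == 0L || at(i + 1, j) == 0L ||
         at(i, j - 1) == 0L || at(i, j + 1) == 0L)) n <- n + 1L
  }
  n
}

# explicit-summation moments oracle
brute_moments <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  v <- sum((x - m)^2) / n
  list(S1 = m,
       S2 = sqrt(sum((x - m)^2) / (n - 1)),
       S3 = (sum((x - m)^3) / n) / v^1.5,
       S4 = (sum((x - m)^4) / n) / v^2 - 3)
}

logistic_orbit <- function(n = 2000, seed = 11) {
  set.seed(seed)
  x <- numeric(n)
  x[1] <- runif(1, 0.1, 0.9)
  for (i in 2:n) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])
  x
}
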