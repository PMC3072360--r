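test_that("extract_mask keeps the largest component and fills holes", {
  # already-binary single-component frame passes through unchanged
  g <- matrix(0L, 20, 20); g[8:12, 8:12] <- 1L
  expect_identical(extract_mask(g)$grid, g)

  # 100-px cell plus 3-px debris: only the cell survives
  g2 <- matrix(0L, 30, 30)
  g2[10:19, 10:19] <- 1L            # 100 px
  g2[3, 3:5] <- 1L                  # 3 px debris
  out <- extract_mask(g2)
  expect_equal(count_area(out), 100)
  expect_equal(sum(out$grid[3, ]), 0)

  # annulus: interior hole filled, area equals the full disk's (brute count)
  disk <- disk_mask(40)
  annulus <- disk - disk_mask(15, size = nrow(disk))
  filled <- extract_mask(annulus)
  expect_equal(count_area(filled), brute_area(disk))

  # no pixel passes threshold
  expect_error(extract_mask(matrix(0, 5, 5)), class = "morphodyn_empty_foreground")

  # Otsu on a bimodal grayscale frame recovers the bright blob
  gray <- matrix(0.2, 40, 40) + matrix(rnorm(1600, 0, 0.01), 40, 40)
  gray[15:25, 15:25] <- 0.8
  expect_equal(count_area(extract_mask(gray, "otsu")), 121)
})

test_that("area and perimeter counts match brute-force pixel oracles", {
  sq <- matrix(1L, 3, 3)
  expect_equal(count_area(sq), 9)
  expect_equal(trace_perimeter(sq), 8)  # all but the center pixel

  px <- matrix(0L, 3, 3); px[2, 2] <- 1L
  expect_equal(count_area(px), 1)
  expect_equal(trace_perimeter(px), 1)

  bar <- matrix(0L, 3, 12); bar[2, 2:11] <- 1L
  expect_equal(trace_perimeter(bar), 10)

  # rasterized disk r = 100: area within 1% of pi r^2
  d <- disk_mask(100)
  expect_lt(abs(count_area(d) / (pi * 100^2) - 1), 0.01)

  # oracle equivalence on assorted fixtures
  for (g in list(sq, bar, disk_mask(12), ellipse_mask(14, 7))) {
    expect_identical(count_area(g), brute_area(g))
    expect_identical(trace_perimeter(g), brute_perimeter(g))
  }
})

test_that("roundness anchors at 1 for continuous circles and ranks shapes", {
  # exact continuous-circle inputs
  for (r in c(1, 10, 100)) {
    m <- roundness(2 * pi * r, pi * r^2)
    expect_equal(m$r1, r)
    expect_equal(m$r2, r)
    expect_true(m$R == 1)
  }
  m1 <- roundness(2 * pi, pi)
  expect_equal(c(m1$r1, m1$r2, m1$R), c(1, 1, 1))
  expect_error(roundness(0, 10), class = "morphodyn_domain")
  expect_error(roundness(10, -1), class = "morphodyn_domain")

  # 2:1 rasterized ellipse is less round than the equal-area disk
  e <- ellipse_mask(100, 50)
  d <- disk_mask(sqrt(100 * 50))
  Re <- roundness(trace_perimeter(e), count_area(e))$R
  Rd <- roundness(trace_perimeter(d), count_area(d))$R
  expect_gt(Re, Rd)
})

test_that("R is invariant under translation and 90-degree rotation", {
  g <- matrix(0L, 60, 60)
  g[20:35, 15:40] <- 1L
  g[22:30, 20:26] <- 1L
  Rof <- function(m) roundness(trace_perimeter(m), count_area(m))$R
  shifted <- matrix(0L, 60, 60); shifted[25:40, 25:50] <- g[20:35, 15:40]
  expect_identical(Rof(shifted), Rof(g))
  rot <- t(g)[ncol(g):1, ]
  expect_identical(Rof(rot), Rof(g))
})

test_that("rasterized-disk area converges to pi r^2 and R is scale-stable", {
  ratio <- sapply(c(20, 50, 100, 200), function(r) count_area(disk_mask(r)) / (pi * r^2))
  expect_lt(abs(ratio[3] - 1), 0.02)
  expect_lt(abs(ratio[4] - 1), 0.02)
  expect_true(all(abs(diff(abs(ratio - 1))) < 0.05))  # errors shrink with r

  Rof <- function(m) roundness(trace_perimeter(m), count_area(m))$R
  expect_lt(abs(Rof(disk_mask(100)) / Rof(disk_mask(50)) - 1), 0.05)
})

test_that("R increases along equal-area ellipses of growing axis ratio", {
  A0 <- 70
  Rs <- sapply(c(1, 1.5, 2, 3), function(q) {
    e <- ellipse_mask(A0 * sqrt(q), A0 / sqrt(q))
    roundness(trace_perimeter(e), count_area(e))$R
  })
  expect_true(all(diff(Rs) > 0))
})

test_that("roundness_series preserves order and reports failing frames", {
  d <- disk_mask(15)
  rs <- roundness_series(rep(list(d), 5), dt = 2)
  expect_equal(rs$n, 5)
  expect_true(all(rs$values == rs$values[1]))
  met <- attr(rs, "metrics")
  expect_equal(met$time_s, c(0, 2, 4, 6, 8))

  two_comp <- matrix(0L, 30, 30)
  two_comp[5:10, 5:10] <- 1L; two_comp[20:25, 20:25] <- 1L
  err <- tryCatch(roundness_series(list(d, two_comp), dt = 2), error = identity)
  expect_s3_class(err, "morphodyn_error")
  expect_match(conditionMessage(err), "frame 2")

  # border-touching masks are rejected
  touching <- matrix(0L, 10, 10); touching[1:4, 3:6] <- 1L
  expect_error(roundness_series(list(d, touching), dt = 2),
               class = "morphodyn_border_touch")

  expect_error(roundness_series(list(d), dt = 2), class = "morphodyn_domain")
})

test_that("displacement ratio flags translocation at 1.5 cell diameters", {
  d <- disk_mask(15)
  same <- displacement_ratio(list(d, d, d))
  expect_equal(same$ratio, 0)
  expect_false(same$translocating)

  # disk of diameter 20 translated 40 px -> ratio exactly 2.0
  m1 <- disk_mask(10, size = 101, center = c(30, 50))
  m2 <- disk_mask(10, size = 101, center = c(70, 50))
  moved <- displacement_ratio(list(m1, m2))
  expect_equal(moved$ratio, 2.0)
  expect_true(moved$translocating)
})
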