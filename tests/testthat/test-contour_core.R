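test_that("detect_apex finds the point farthest from the mid-annular point", {
  pts <- half_ellipse_points(20, 80, n = 501L)
  apx <- detect_apex(pts, c(-20, 0), c(20, 0))
  expect_equal(unname(apx$point), c(0, 80), tolerance = 1e-8)

  # tie: two points at equal maximal distance -> earlier traversal index wins
  tie <- rbind(c(-10, 0), c(-5, 40), c(5, 40), c(10, 0))
  apx <- detect_apex(tie, c(-10, 0), c(10, 0))
  expect_identical(apx$index, 2L)

  expect_error(detect_apex(rbind(c(0, 0), c(1, 1)), c(-1, 0), c(1, 0)),
               "at least 3 points")
  expect_error(detect_apex(tie, c(1, 1), c(1, 1)), "distinct")
})

test_that("detect_apex agrees with exhaustive search on random-walk contours", {
  set.seed(42)
  for (rep in 1:5) {
    pts <- cbind(cumsum(rnorm(500)), cumsum(rnorm(500)))
    a <- pts[1, ] + c(0.1, 0)
    b <- pts[500, ] + c(-0.1, 0)
    mid <- (a + b) / 2
    brute <- which.max(apply(pts, 1L, function(p) sqrt(sum((p - mid)^2))))
    expect_identical(detect_apex(pts, a, b)$index, brute)
  }
})

test_that("cut_closed_contour keeps the apical arc and preserves points", {
  # full circle through both annuli: 60 upper (apical) points incl. the
  # annuli, 40 strictly basal points
  upper <- cbind(-30 * cos(seq(0, pi, length.out = 60L)),
                 30 * sin(seq(0, pi, length.out = 60L)))
  lower_th <- seq(pi, 2 * pi, length.out = 42L)[2:41]
  lower <- cbind(-30 * cos(lower_th), 30 * sin(lower_th))
  tr <- raw_tracing(rbind(upper, lower), view = "4CH", phase = "ED",
                    annulus_a = c(-30, 0), annulus_b = c(30, 0),
                    closed = TRUE)
  open <- cut_closed_contour(tr)

  expect_false(open$closed)
  expect_identical(nrow(open$points), 60L)
  # endpoints on the annulus-annulus chord (y = 0)
  expect_lt(abs(open$points[1, 2]), 0.01)
  expect_lt(abs(open$points[60, 2]), 0.01)
  # traversal annulus_a -> apex -> annulus_b
  expect_equal(unname(open$points[1, ]), c(-30, 0), tolerance = 1e-9)
  expect_equal(unname(open$points[60, ]), c(30, 0), tolerance = 1e-9)
  # surviving points are a subset of the input, unmoved
  key <- function(m) paste(round(m[, 1], 9), round(m[, 2], 9))
  expect_true(all(key(open$points) %in% key(tr$points)))

  # already-open tracing returned unchanged
  tro <- half_ellipse_tracing()
  expect_identical(cut_closed_contour(tro), tro)
})

test_that("cut_closed_contour rejects contours with no apical side", {
  # all points on/below the chord
  flat <- cbind(seq(-10, 10, length.out = 20L), rep(0, 20L))
  tr <- raw_tracing(flat, view = "4CH", phase = "ED",
                    annulus_a = c(-10, 0), annulus_b = c(10, 0), closed = TRUE)
  expect_error(cut_closed_contour(tr), "degenerate")
})

test_that("standardize_contour places landmarks and equidistant arms", {
  set.seed(7)
  sc <- standardize_contour(half_ellipse_tracing(n = 500L, irregular = TRUE))
  expect_identical(nrow(sc$points), 99L)
  expect_equal(unname(sc$points[1, ]), c(-20, 0), tolerance = 1e-6)
  expect_equal(unname(sc$points[99, ]), c(20, 0), tolerance = 1e-6)
  expect_equal(unname(sc$points[50, ]), c(0, 80), tolerance = 0.1)

  # within each arm consecutive chord lengths are equal within 1%
  for (arm in list(sc$points[1:50, ], sc$points[50:99, ])) {
    seg <- sqrt(diff(arm[, 1])^2 + diff(arm[, 2])^2)
    expect_lt(max(abs(seg - mean(seg))) / mean(seg), 0.01)
  }
})

test_that("standardization is idempotent to 0.01 mm", {
  set.seed(8)
  for (rep in 1:5) {
    sc <- standardize_contour(random_contour_tracing())
    sc2 <- standardize_contour(sc)
    expect_lt(max_point_dist(sc$points, sc2$points), 0.01)
  }
})

test_that("standardization auto-cuts closed tracings and flags degenerate arms", {
  # circle of radius 25 cut by the mitral chord at y = -10
  xa <- -sqrt(25^2 - 10^2)
  th0 <- atan2(-10, xa)
  th <- seq(th0, th0 + 2 * pi, length.out = 201L)[-201]
  circ <- cbind(25 * cos(th), 25 * sin(th))
  tr <- raw_tracing(circ, view = "2CH", phase = "ES",
                    annulus_a = c(xa, -10), annulus_b = c(-xa, -10),
                    closed = TRUE)
  sc <- standardize_contour(tr)
  expect_identical(nrow(sc$points), 99L)
  expect_gt(sc$points[50, 2], 24)  # apex at the top of the circle

  # a tracing whose apex coincides with an annulus has a zero-length arm
  line <- cbind(seq(0, 10, length.out = 20L), seq(0, 40, length.out = 20L))
  expect_error(standardize_contour(
    raw_tracing(line, view = "4CH", phase = "ED")), "degenerate")
})

test_that("normalize_length aligns the long axis and scales isotropically", {
  sc <- standardize_contour(half_ellipse_tracing(b = 22, L = 80, n = 400L))
  aligned <- normalize_length(sc, 80)
  expect_equal(unname(contour_midbase(aligned)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(contour_apex(aligned)), c(0, 80), tolerance = 1e-9)

  half <- normalize_length(sc, 40)
  d_full <- dist(aligned$points)
  d_half <- dist(half$points)
  expect_equal(as.numeric(d_half), as.numeric(d_full) / 2, tolerance = 1e-9)

  set.seed(11)
  for (rep in 1:20) {
    target <- runif(1, 30, 120)
    out <- normalize_length(standardize_contour(random_contour_tracing()),
                            target)
    expect_lt(abs(long_axis_length(out) - target), 0.01)
  }
})
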