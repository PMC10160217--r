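# Shared fixtures: parametric contours, rigid motions, and brute-force rank
# oracles kept independent of the package implementation.

# half-ellipse raw polyline from (-b, 0) through (0, L) to (b, 0)
half_ellipse_points <- function(b, L, n = 500L, irregular = FALSE) {
  th <- if (irregular) sort(c(0, runif(n - 2L, 0, pi), pi))
        else seq(0, pi, length.out = n)
  cbind(-b * cos(th), L * sin(th))
}

half_ellipse_tracing <- function(b = 20, L = 80, n = 500L, irregular = FALSE,
                                 view = "4CH", phase = "ED", ...) {
  raw_tracing(half_ellipse_points(b, L, n, irregular),
              view = view, phase = phase, ...)
}

# smooth random U-shaped contour with LV-like aspect ratio (apex curvature
# radius b^2/L of at least ~5 mm so the 99-point representation is faithful):
# ellipse with low-order radial perturbation, random rigid pose, irregular
# sampling
random_contour_tracing <- function(view = "4CH", phase = "ED", n = 300L) {
  L <- runif(1, 60, 90)
  b <- L / runif(1, 2.2, 3.2)
  th <- sort(c(0, runif(n - 2L, 0, pi), pi))
  wob <- 1 + 0.03 * sin(2 * th + runif(1, 0, 2 * pi)) +
    0.015 * sin(3 * th + runif(1, 0, 2 * pi))
  pts <- cbind(-b * cos(th) * wob, L * sin(th) * wob)
  ang <- runif(1, -pi, pi)
  R <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2L, byrow = TRUE)
  shift <- runif(2, -40, 40)
  pts <- sweep(pts %*% t(R), 2L, shift, `+`)
  raw_tracing(pts, view = view, phase = phase)
}

rigid_transform <- function(points, angle, shift) {
  R <- matrix(c(cos(angle), -sin(angle), sin(angle), cos(angle)), 2L,
              byrow = TRUE)
  sweep(points %*% t(R), 2L, shift, `+`)
}

apply_rigid_to_tracing <- function(tracing, angle, shift) {
  raw_tracing(rigid_transform(tracing$points, angle, shift),
              view = tracing$view, phase = tracing$phase,
              annulus_a = drop(rigid_transform(rbind(tracing$annulus_a),
                                               angle, shift)),
              annulus_b = drop(rigid_transform(rbind(tracing$annulus_b),
                                               angle, shift)),
              closed = tracing$closed,
              patient_id = tracing$patient_id,
              observer_id = tracing$observer_id)
}

max_point_dist <- function(a, b) max(sqrt(rowSums((a - b)^2)))

# ---- brute-force rank oracles ----------------------------------------------

midranks <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (1 + sum(x == xi)) / 2, numeric(1))
}

spearman_brute <- function(x, y) {
  rx <- midranks(x)
  ry <- midranks(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

kruskal_wallis_brute <- function(value, group) {
  r <- midranks(value)
  N <- length(value)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, group, function(ri) length(ri) * mean(ri)^2)) -
    3 * (N + 1)
  ties <- table(value)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

friedman_brute <- function(m) {
  # tie-free blocks x treatments matrix
  R <- t(apply(m, 1L, rank))
  n <- nrow(m)
  k <- ncol(m)
  12 / (n * k * (k + 1)) * sum(colSums(R)^2) - 3 * n * (k + 1)
}

# truth + i.i.d. normal displacement along outward normals at EVERY label
perturb_all_labels <- function(truth, sigma, observer_id = "O01") {
  nrm <- outward_normals(truth)
  standard_contour(truth$points + rnorm(99, 0, sigma) * nrm,
                   view = truth$view, phase = truth$phase,
                   patient_id = truth$patient_id, observer_id = observer_id)
}
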