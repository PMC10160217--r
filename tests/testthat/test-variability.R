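truth_4ch <- function(L = 80, b = 24) {
  make_truth_contours(L, b, b, 0.8)[["4CH_ED"]]
}

test_that("reference contour is the per-label componentwise median", {
  sc <- truth_4ch()
  expect_equal(compute_reference_contour(list(sc, sc, sc))$points, sc$points)

  # three contours differing only in the label-7 x coordinate: {1, 2, 9}
  alt <- lapply(c(1, 2, 9), function(x) {
    p <- sc$points
    p[7, 1] <- x
    standard_contour(p, view = sc$view, phase = sc$phase,
                     patient_id = sc$patient_id)
  })
  ref <- compute_reference_contour(alt)
  expect_equal(ref$points[7, 1], 2)
  expect_equal(ref$observer_id, "reference")
  expect_error(compute_reference_contour(list()), "no contours")
})

test_that("the reference converges to the truth under zero-mean noise", {
  sc <- truth_4ch()
  set.seed(3)
  obs <- lapply(1:100, function(i) perturb_all_labels(sc, 1))
  ref <- compute_reference_contour(obs)
  dev <- sqrt(rowSums((ref$points - sc$points)^2))
  expect_lt(max(dev), 1.0)  # median of 100 at sigma = 1: ~8 sd margin

  # consistency: deviation shrinks with observer count
  ref10 <- compute_reference_contour(obs[1:10])
  dev10 <- sqrt(rowSums((ref10$points - sc$points)^2))
  expect_lt(mean(dev), mean(dev10))
})

test_that("signed distances are zero at the reference and track offsets", {
  sc <- truth_4ch()
  d0 <- signed_pointwise_distances(sc, sc)
  expect_identical(nrow(d0), 98L)
  expect_false(50L %in% d0$point_label)
  expect_equal(d0$unsigned_distance, rep(0, 98))

  # reference inflated by +1 mm along its outward normals
  inflated <- standard_contour(sc$points + outward_normals(sc),
                               view = sc$view, phase = sc$phase,
                               patient_id = sc$patient_id)
  d1 <- signed_pointwise_distances(inflated, sc)
  expect_true(all(abs(d1$signed_distance - 1) < 0.05))
})

test_that("unsigned distances equal the brute-force point-pair computation", {
  sc <- truth_4ch()
  set.seed(5)
  for (rep in 1:20) {
    pert <- standard_contour(sc$points + matrix(rnorm(198, 0, 2), ncol = 2L),
                             view = sc$view, phase = sc$phase,
                             patient_id = sc$patient_id)
    d <- signed_pointwise_distances(pert, sc)
    brute <- vapply(setdiff(1:99, 50L), function(l)
      sqrt(sum((pert$points[l, ] - sc$points[l, ])^2)), numeric(1))
    expect_equal(d$unsigned_distance, brute, tolerance = 1e-12)
    expect_equal(abs(d$signed_distance), d$unsigned_distance)
  }
})

test_that("signed distances demand matching view and phase", {
  sc <- truth_4ch()
  other <- standard_contour(sc$points, view = "2CH", phase = "ED")
  expect_error(signed_pointwise_distances(sc, other), "view and phase")
})

test_that("segment mapping follows the 6-segment convention", {
  s <- segment_of_label(1L, "4CH")
  expect_identical(s$wall, "septal")
  expect_identical(s$level, "basal")
  expect_identical(segment_of_label(1L, "2CH")$wall, "inferior")
  expect_identical(segment_of_label(99L, "4CH")$wall, "lateral")
  expect_identical(segment_of_label(99L, "2CH")$wall, "anterior")
  expect_identical(segment_of_label(50L, "4CH")$wall, "apex")

  all_seg <- segment_of_label(setdiff(1:99, 50L), "4CH")
  sizes <- table(paste(all_seg$wall, all_seg$level))
  expect_identical(sort(as.integer(sizes)), c(16L, 16L, 16L, 16L, 17L, 17L))
  expect_identical(sum(sizes), 98L)
  # boundary labels
  expect_identical(segment_of_label(16L, "4CH")$level, "basal")
  expect_identical(segment_of_label(17L, "4CH")$level, "mid")
  expect_identical(segment_of_label(33L, "4CH")$level, "apical")
  expect_identical(segment_of_label(51L, "4CH")$level, "apical")
  expect_identical(segment_of_label(68L, "4CH")$level, "mid")
  expect_identical(segment_of_label(84L, "4CH")$level, "basal")
  expect_error(segment_of_label(100L, "4CH"), "1..99")
})

test_that("a zero-noise study aggregates to all-zero medians", {
  cfg <- synth_config(n_patients = 1L, n_observers = 3L,
                      sigma_wall = c(septal = 0, lateral = 0,
                                     inferior = 0, anterior = 0),
                      landmark_sigma = c(septal_inferior = 0,
                                         lateral_anterior = 0, apex = 0),
                      bias_sd = 0, seed = 9)
  st <- simulate_study(cfg)
  contours <- lapply(st$tracings, standardize_contour)
  recs <- compute_distance_records(contours, build_reference_set(contours))
  summ <- aggregate_distance_summary(recs)
  expect_true(all(summ$median_mm < 1e-9))
})

test_that("aggregation recovers an injected wall-noise ordering", {
  sc <- truth_4ch()
  seg <- segment_of_label(1:99, "4CH")
  sigma <- ifelse(seg$wall == "lateral", 4, 2)
  set.seed(13)
  contours <- lapply(1:30, function(i) {
    nrm <- outward_normals(sc)
    standard_contour(sc$points + rnorm(99, 0, sigma) * nrm,
                     view = "4CH", phase = "ED", observer_id = sprintf("O%02d", i))
  })
  recs <- compute_distance_records(contours, build_reference_set(contours))
  summ <- aggregate_distance_summary(recs)
  med <- function(region) summ$median_mm[summ$grouping == "wall" &
                                           summ$region == region]
  expect_gt(med("lateral"), med("septal"))
})

test_that("summary cells equal direct recomputation from the records", {
  cfg <- synth_config(n_patients = 2L, n_observers = 5L, seed = 21)
  st <- simulate_study(cfg)
  contours <- lapply(st$tracings, standardize_contour)
  recs <- compute_distance_records(contours, build_reference_set(contours))
  summ <- aggregate_distance_summary(recs)
  cell <- summ[summ$grouping == "wall" & summ$region == "lateral" &
                 summ$view == "4CH" & summ$phase == "ES", ]
  direct <- recs$unsigned_distance[recs$wall == "lateral" &
                                     recs$view == "4CH" & recs$phase == "ES"]
  expect_equal(cell$median_mm, median(direct))
  expect_equal(cell$q25_mm, unname(quantile(direct, 0.25)))
  expect_equal(cell$q75_mm, unname(quantile(direct, 0.75)))
  expect_identical(cell$n_points, length(direct))

  # permutation invariance in observers
  recs2 <- recs[sample(nrow(recs)), ]
  expect_equal(aggregate_distance_summary(recs2)$median_mm, summ$median_mm)
})
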