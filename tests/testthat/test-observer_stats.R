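toy_volumes <- function(scale_by_obs = NULL) {
  # 4 observers x 3 patients of identical truth geometry; optional in-plane
  # scaling of one observer's contours in both phases and views
  tc <- lapply(1:3, function(p)
    make_truth_contours(75 + 2 * p, 22, 23, 0.8,
                        patient_id = sprintf("P%02d", p)))
  contours <- list()
  for (p in 1:3) for (o in 1:4) for (k in names(tc[[p]])) {
    sc <- tc[[p]][[k]]
    s <- if (!is.null(scale_by_obs)) scale_by_obs[o] else 1
    mid <- contour_midbase(sc)
    pts <- sweep(sweep(sc$points, 2L, mid) * s, 2L, mid, `+`)
    contours[[paste(p, o, k)]] <- standard_contour(
      pts, view = sc$view, phase = sc$phase,
      patient_id = sc$patient_id, observer_id = sprintf("O%02d", o))
  }
  study_volumes(contours, n_disks = 50L)
}

test_that("identical observers have zero volume deviation", {
  dev <- volume_deviation_profile(toy_volumes())
  expect_equal(dev$edv_pct_diff, rep(0, 4))
  expect_equal(dev$esv_pct_diff, rep(0, 4))
})

test_that("a 1.1x in-plane scaled observer deviates by about +33% in volume", {
  dev <- volume_deviation_profile(toy_volumes(c(1, 1, 1, 1.1)))
  big <- dev[dev$observer_id == "O04", ]
  expect_lt(abs(big$edv_pct_diff - (1.1^3 - 1) * 100), 1.5)
  expect_lt(abs(big$esv_pct_diff - (1.1^3 - 1) * 100), 1.5)
})

test_that("symmetric inflation/deflation gives antisymmetric deviations", {
  dev <- volume_deviation_profile(toy_volumes(c(0.95, 1, 1, 1 / 0.95)))
  lo <- dev$edv_pct_diff[dev$observer_id == "O01"]
  hi <- dev$edv_pct_diff[dev$observer_id == "O04"]
  # 100 (s^3 - 1) and 100 (1/s^3 - 1) relative to the median (= truth) volume
  expect_lt(abs(lo - 100 * (0.95^3 - 1)), 1)
  expect_lt(abs(hi - 100 * (0.95^-3 - 1)), 1)
})

test_that("observers are classified by signed-distance threshold", {
  g <- classify_observers(c(2.0, -2.0, 0.3, -1.0, 1.0), threshold = 1.0)
  expect_identical(as.character(g),
                   c("large", "small", "medium", "medium", "medium"))
  expect_identical(levels(g), c("small", "medium", "large"))
  # classification partitions the observers
  expect_identical(sum(table(g)), 5L)
})

test_that("experience categories use closed-left boundaries", {
  expect_identical(as.character(experience_category(c(4.9, 5.0, 10.0, 10.1))),
                   c("<5", "5-10", "5-10", ">10"))
})

test_that("Spearman correlations match the brute-force midrank oracle", {
  inc <- data.frame(edv_ml = 1:6, esv_ml = (1:6)^2, ef_pct = 6:1)
  r <- volume_ef_correlations(inc)
  expect_equal(r$spearman_r[r$pair == "EDV~ESV"], 1)
  expect_equal(r$spearman_r[r$pair == "EDV~EF"], -1)

  set.seed(61)
  toy <- data.frame(edv_ml = c(5, 3, 3, 8, 1, 9, 3, 5),
                    esv_ml = c(2, 2, 4, 7, 1, 9, 2, 4),
                    ef_pct = c(50, 48, 44, 41, 55, 38, 48, 46))
  r <- volume_ef_correlations(toy)
  expect_equal(r$spearman_r[r$pair == "EDV~ESV"],
               spearman_brute(toy$edv_ml, toy$esv_ml), tolerance = 1e-12)
  expect_equal(r$spearman_r[r$pair == "ESV~EF"],
               spearman_brute(toy$esv_ml, toy$ef_pct), tolerance = 1e-12)

  const <- data.frame(edv_ml = rep(5, 4), esv_ml = 1:4, ef_pct = c(2, 1, 4, 3))
  # constant EDV breaks two of the three pairs, each with its own warning
  wrns <- capture_warnings(rc <- volume_ef_correlations(const))
  expect_match(wrns, "constant", all = TRUE)
  expect_length(wrns, 2L)
  expect_true(is.na(rc$spearman_r[rc$pair == "EDV~ESV"]))
  expect_error(volume_ef_correlations(inc[1:2, ]), "at least 3")
})

test_that("Kruskal-Wallis via group_ef_comparison matches the rank formula", {
  profiles <- data.frame(
    median_ef = c(44, 46, 43, 49, 50, 48, 47, 55, 53, 56, 52, 50),
    ef_diff_from_reference = c(-5, -3, -6, 0, 1, -1, -2, 6, 4, 7, 3, 1),
    size_group = factor(rep(c("small", "medium", "large"), each = 4L),
                        levels = c("small", "medium", "large")))
  res <- group_ef_comparison(profiles)
  expect_true(res$ef$applicable)
  H <- kruskal_wallis_brute(profiles$median_ef, profiles$size_group)
  expect_equal(res$ef$statistic, H, tolerance = 1e-12)
  expect_equal(res$ef$p_value, pchisq(H, df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_identical(res$ef$summary$group, c("small", "medium", "large"))
  expect_equal(res$ef$summary$median[1], median(profiles$median_ef[1:4]))

  # single nonempty group -> summaries only
  one <- profiles
  one$size_group <- factor("medium", levels = levels(profiles$size_group))
  res1 <- group_ef_comparison(one)
  expect_false(res1$ef$applicable)
  expect_true(is.na(res1$ef$p_value))
})

test_that("experience comparison reuses the omnibus machinery", {
  profiles <- data.frame(
    median_ef = c(48, 50, 49, 47, 51, 50, 49, 48, 52),
    ef_diff_from_reference = rnorm(9),
    experience_years = c(1, 3, 4, 6, 8, 9, 12, 15, NA))
  profiles$experience_category <- experience_category(profiles$experience_years)
  res <- experience_comparison(profiles)
  expect_identical(res$n_excluded, 1L)
  expect_true(res$ef$applicable)
  expect_error(experience_comparison(profiles[, 1:2]), "experience_category")
})

test_that("Friedman statistics match the textbook rank formula", {
  m <- rbind(c(3.2, 4.1, 3.9),
             c(2.8, 3.6, 3.1),
             c(3.0, 4.4, 3.3),
             c(2.5, 3.9, 2.9))
  recs <- data.frame(
    observer_id = rep(sprintf("O%d", 1:4), each = 3L),
    patient_id = "P01",
    view = "4CH", phase = "ED",
    wall = rep(c("septal", "lateral", "inferior"), times = 4L),
    level = "mid",
    unsigned_distance = as.vector(t(m)))
  res <- region_comparison(recs)
  expect_equal(res$omnibus$statistic, friedman_brute(m), tolerance = 1e-12)
  expect_equal(res$omnibus$p_value,
               pchisq(friedman_brute(m), df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_identical(res$omnibus$n_blocks, 4L)

  pw <- res$pairwise
  sl <- pw[pw$comparison == "septal vs lateral", ]
  expect_equal(sl$statistic, friedman_brute(m[, 1:2]), tolerance = 1e-12)
})

test_that("rank-balanced region distributions are not declared different", {
  # each region takes every within-block rank equally often: Friedman
  # statistic exactly 0
  m <- rbind(c(1.1, 2.2, 3.3),
             c(2.2, 3.3, 1.1),
             c(3.3, 1.1, 2.2),
             c(1.5, 2.5, 3.5),
             c(2.5, 3.5, 1.5),
             c(3.5, 1.5, 2.5))
  recs <- data.frame(
    observer_id = rep(sprintf("O%d", 1:6), each = 3L),
    patient_id = "P01", view = "4CH", phase = "ED",
    wall = rep(c("septal", "lateral", "inferior"), times = 6L),
    level = "mid",
    unsigned_distance = as.vector(t(m)))
  res <- region_comparison(recs)
  expect_equal(res$omnibus$statistic, 0, tolerance = 1e-12)
  expect_equal(res$omnibus$p_value, 1, tolerance = 1e-12)
})

test_that("observer_profiles assembles one row per observer", {
  cfg <- synth_config(n_patients = 2L, n_observers = 6L, seed = 81)
  st <- simulate_study(cfg)
  contours <- lapply(st$tracings, standardize_contour)
  recs <- compute_distance_records(contours, build_reference_set(contours))
  vols <- study_volumes(contours)
  prof <- observer_profiles(recs, vols, reference_ef = 50,
                            observers = st$observers)
  expect_identical(nrow(prof), 6L)
  expect_identical(sum(table(prof$size_group)), 6L)
  expect_equal(prof$ef_diff_from_reference, prof$median_ef - 50)
  expect_true(all(!is.na(prof$experience_category)))
})
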