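# Reference-contour estimation and segmental distance statistics.
#
# The consensus ("reference") contour for one patient/view/phase is the
# componentwise median, label by label, of all observers' standardized
# contours -- the centre of the density ("heat map") the superimposed
# contours form. Individual deviation is measured per standardized label as
# the Euclidean distance to the reference point with the same label, signed
# positive when the individual point lies outside the reference contour
# (along its local outward normal).

#' Consensus (reference) contour across observers
#'
#' @param contours list of `standard_contour` objects for one
#'   patient/view/phase (one per observer).
#' @return A `standard_contour` with `observer_id = "reference"`.
#' @export
compute_reference_contour <- function(contours) {
  if (length(contours) == 0L) stop("no contours supplied", call. = FALSE)
  stopifnot(all(vapply(contours, inherits, logical(1), "standard_contour")))
  vw <- unique(vapply(contours, `[[`, character(1), "view"))
  ph <- unique(vapply(contours, `[[`, character(1), "phase"))
  pt <- unique(vapply(contours, `[[`, character(1), "patient_id"))
  if (length(vw) != 1L || length(ph) != 1L || length(pt) != 1L) {
    stop("all contours must share one patient, view and phase", call. = FALSE)
  }
  xs <- vapply(contours, function(cc) cc$points[, 1], numeric(99))
  ys <- vapply(contours, function(cc) cc$points[, 2], numeric(99))
  pts <- cbind(unname(matrixStats_row_median(xs)),
               unname(matrixStats_row_median(ys)))
  standard_contour(pts, view = vw, phase = ph,
                   patient_id = pt, observer_id = "reference")
}

# row medians of a 99 x n matrix (n == 1 gives the matrix back)
matrixStats_row_median <- function(m) {
  if (is.null(dim(m))) return(m)
  apply(m, 1L, stats::median)
}

#' Outward unit normals of a standard contour
#'
#' Tangents are central differences along the 99-point polyline (one-sided at
#' the annuli); each normal is oriented away from the area centroid of the
#' contour closed across the mitral plane.
#'
#' @param contour a `standard_contour`.
#' @return A 99 x 2 matrix of unit normals.
#' @export
outward_normals <- function(contour) {
  P <- contour$points
  n <- nrow(P)
  tng <- rbind(P[2L, ] - P[1L, ],
               P[3:n, , drop = FALSE] - P[1:(n - 2L), , drop = FALSE],
               P[n, ] - P[n - 1L, ])
  nrm <- cbind(tng[, 2], -tng[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len < 1e-12] <- 1
  nrm <- nrm / len
  ctr <- polygon_centroid(P)
  flip <- rowSums(nrm * sweep(P, 2L, ctr)) < 0
  nrm[flip, ] <- -nrm[flip, ]
  nrm
}

polygon_centroid <- function(P) {
  # close across the mitral plane
  x <- c(P[, 1], P[1, 1])
  y <- c(P[, 2], P[1, 2])
  n <- length(x) - 1L
  cr <- x[1:n] * y[2:(n + 1)] - x[2:(n + 1)] * y[1:n]
  A <- sum(cr) / 2
  if (abs(A) < 1e-9) return(colMeans(P))
  c(sum((x[1:n] + x[2:(n + 1)]) * cr), sum((y[1:n] + y[2:(n + 1)]) * cr)) / (6 * A)
}

#' Signed pointwise distances of a contour to the reference
#'
#' For every label except the apex (label 50), the Euclidean distance between
#' the individual and the reference point at that label; positive when the
#' individual point lies on the outward side of the reference (a "larger"
#' tracing).
#'
#' @param contour,reference `standard_contour`s of the same view/phase.
#' @return Data frame with `point_label`, `unsigned_distance` and
#'   `signed_distance` (mm), 98 rows.
#' @export
signed_pointwise_distances <- function(contour, reference) {
  stopifnot(inherits(contour, "standard_contour"),
            inherits(reference, "standard_contour"))
  if (contour$view != reference$view || contour$phase != reference$phase) {
    stop("contour and reference must share view and phase", call. = FALSE)
  }
  diff <- contour$points - reference$points
  d <- sqrt(rowSums(diff^2))
  nrm <- outward_normals(reference)
  s <- sign(rowSums(diff * nrm))
  keep <- setdiff(1:99, 50L)
  data.frame(point_label = keep,
             unsigned_distance = d[keep],
             signed_distance = (s * d)[keep])
}

#' Segment and wall of a standardized point label
#'
#' Each view's contour is divided into 6 segments: three levels (basal, mid,
#' apical) on each of the two walls. Labels 1-49 form the arm starting at the
#' label-1 annulus (septal wall in 4CH, inferior in 2CH) with basal 1-16, mid
#' 17-32, apical 33-49; labels 51-99 form the other arm (lateral / anterior)
#' with apical 51-67, mid 68-83, basal 84-99. The extra point per arm goes to
#' the apical segment. Label 50 is the apex landmark and is excluded from
#' segmental statistics.
#'
#' @param point_label integer vector of labels in 1..99.
#' @param view `"2CH"` or `"4CH"` (scalar).
#' @return Data frame with `point_label`, `wall` and `level`; the apex gets
#'   `wall = level = "apex"`.
#' @export
segment_of_label <- function(point_label, view) {
  view <- match.arg(view, c("2CH", "4CH"))
  point_label <- as.integer(point_label)
  if (any(point_label < 1L | point_label > 99L)) {
    stop("point labels must lie in 1..99", call. = FALSE)
  }
  walls <- if (view == "4CH") c("septal", "lateral") else c("inferior", "anterior")
  wall <- ifelse(point_label < 50L, walls[1],
                 ifelse(point_label > 50L, walls[2], "apex"))
  level <- rep("apex", length(point_label))
  lo <- point_label < 50L
  hi <- point_label > 50L
  level[lo] <- c("basal", "mid", "apical")[findInterval(point_label[lo], c(1L, 17L, 33L))]
  level[hi] <- c("apical", "mid", "basal")[findInterval(point_label[hi], c(51L, 68L, 84L))]
  data.frame(point_label = point_label, wall = wall, level = level)
}

#' Distance records for a whole study
#'
#' Runs [signed_pointwise_distances()] for every observer contour against its
#' patient/view/phase reference and attaches segment labels.
#'
#' @param contours list of observer `standard_contour`s.
#' @param references named list of reference contours, names
#'   `"<patient>_<view>_<phase>"` as produced by [build_reference_set()].
#' @return Data frame with one row per (tracing, label): `patient_id`,
#'   `observer_id`, `view`, `phase`, `point_label`, `wall`, `level`,
#'   `unsigned_distance`, `signed_distance`.
#' @export
compute_distance_records <- function(contours, references) {
  seg <- list(`2CH` = segment_of_label(setdiff(1:99, 50L), "2CH"),
              `4CH` = segment_of_label(setdiff(1:99, 50L), "4CH"))
  normals <- lapply(references, outward_normals)
  keep <- setdiff(1:99, 50L)
  keys <- vapply(contours, function(cc)
    paste(cc$patient_id, cc$view, cc$phase, sep = "_"), character(1))
  has_ref <- keys %in% names(references)
  contours <- contours[has_ref]
  keys <- keys[has_ref]
  if (length(contours) == 0L) return(NULL)

  n <- length(contours)
  unsigned <- signed <- matrix(NA_real_, nrow = 98L, ncol = n)
  for (i in seq_len(n)) {
    cc <- contours[[i]]
    ref <- references[[keys[i]]]
    diff <- cc$points - ref$points
    d <- sqrt(rowSums(diff^2))
    s <- sign(rowSums(diff * normals[[keys[i]]]))
    unsigned[, i] <- d[keep]
    signed[, i] <- (s * d)[keep]
  }
  views <- vapply(contours, `[[`, character(1), "view")
  data.frame(
    patient_id = rep(vapply(contours, `[[`, character(1), "patient_id"),
                     each = 98L),
    observer_id = rep(vapply(contours, `[[`, character(1), "observer_id"),
                      each = 98L),
    view = rep(views, each = 98L),
    phase = rep(vapply(contours, `[[`, character(1), "phase"), each = 98L),
    point_label = rep(keep, times = n),
    wall = unlist(lapply(views, function(v) seg[[v]]$wall),
                  use.names = FALSE),
    level = unlist(lapply(views, function(v) seg[[v]]$level),
                   use.names = FALSE),
    unsigned_distance = as.vector(unsigned),
    signed_distance = as.vector(signed))
}

#' Reference set for a study
#'
#' One consensus contour per (patient, view, phase) that has at least one
#' observer tracing.
#'
#' @param contours list of observer `standard_contour`s.
#' @return Named list of reference contours keyed `"<patient>_<view>_<phase>"`.
#' @export
build_reference_set <- function(contours) {
  keys <- vapply(contours, function(cc)
    paste(cc$patient_id, cc$view, cc$phase, sep = "_"), character(1))
  lapply(split(contours, keys), compute_reference_contour)
}

#' Median/IQR distance summary by segment, wall and level
#'
#' Pools unsigned distances across patients and observers at the point level
#' and reports the median and interquartile range for every (view, phase)
#' crossed with: all segments together, each of the 6 segments, each wall,
#' and each level — the layout of a per-segment variability table.
#'
#' @param records distance records from [compute_distance_records()].
#' @return Data frame with `view`, `phase`, `grouping` (one of `"overall"`,
#'   `"wall"`, `"level"`, `"segment"`), `region`, `median_mm`, `q25_mm`,
#'   `q75_mm`, `n_points`.
#' @export
aggregate_distance_summary <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("no distance records to aggregate", call. = FALSE)
  }
  summ <- function(d, grouping, region_from) {
    key <- interaction(d$view, d$phase, region_from, drop = TRUE, sep = "\r")
    parts <- split(d$unsigned_distance, key)
    ks <- do.call(rbind, strsplit(names(parts), "\r", fixed = TRUE))
    data.frame(view = ks[, 1], phase = ks[, 2], grouping = grouping,
               region = ks[, 3],
               median_mm = vapply(parts, stats::median, numeric(1)),
               q25_mm = vapply(parts, stats::quantile, numeric(1), probs = 0.25,
                               names = FALSE),
               q75_mm = vapply(parts, stats::quantile, numeric(1), probs = 0.75,
                               names = FALSE),
               n_points = lengths(parts), row.names = NULL)
  }
  rbind(
    summ(records, "overall", rep("all", nrow(records))),
    summ(records, "wall", records$wall),
    summ(records, "level", records$level),
    summ(records, "segment", paste(records$wall, records$level, sep = "-")))
}

#' Pivot a distance summary into the 4-column study layout
#'
#' Rows: all / walls / levels; columns: 2CH-ED, 2CH-ES, 4CH-ED, 4CH-ES, each
#' cell formatted `median (q25-q75)` in mm.
#'
#' @param summary output of [aggregate_distance_summary()].
#' @param digits decimal places.
#' @return A character data frame, one row per region.
#' @export
format_distance_table <- function(summary, digits = 1) {
  s <- summary[summary$grouping %in% c("overall", "wall", "level"), ]
  s$cell <- sprintf("%.*f (%.*f-%.*f)", digits, s$median_mm,
                    digits, s$q25_mm, digits, s$q75_mm)
  cols <- c("2CH_ED", "2CH_ES", "4CH_ED", "4CH_ES")
  rows <- c("all", "anterior", "inferior", "septal", "lateral",
            "apical", "mid", "basal")
  out <- data.frame(region = rows)
  for (cl in cols) {
    vp <- strsplit(cl, "_")[[1]]
    m <- s[s$view == vp[1] & s$phase == vp[2], ]
    out[[cl]] <- m$cell[match(rows, m$region)]
  }
  out
}
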