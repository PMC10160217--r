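# Scatter analysis of the anatomical landmarks: the two mitral-annulus points
# (labels 1 and 99) and the apex (label 50). For each patient/view/phase/kind
# the cohort reference position is the componentwise median over observers;
# individual offsets from it are binned by the concentric circles of area
# 1, 4 and 9 cm^2 around the reference.

LANDMARK_KINDS <- list(
  `4CH` = c("septal_annulus", "lateral_annulus", "apex"),
  `2CH` = c("inferior_annulus", "anterior_annulus", "apex"))

# circle radii (mm) for areas 1, 4, 9 cm^2
area_bin_radii <- function() sqrt(c(1, 4, 9) * 100 / pi)

#' Landmark positions of a standard contour
#'
#' Labels 1, 99 and 50 mapped to the view-appropriate annulus kinds
#' (septal/lateral for 4CH, inferior/anterior for 2CH) and the apex.
#'
#' @param contour a `standard_contour`.
#' @return Data frame with `patient_id`, `observer_id`, `view`, `phase`,
#'   `kind`, `x`, `y` (absolute positions, mm), 3 rows.
#' @export
extract_landmarks <- function(contour) {
  stopifnot(inherits(contour, "standard_contour"))
  kinds <- LANDMARK_KINDS[[contour$view]]
  idx <- c(1L, 99L, 50L)
  data.frame(patient_id = contour$patient_id,
             observer_id = contour$observer_id,
             view = contour$view, phase = contour$phase,
             kind = kinds,
             x = contour$points[idx, 1], y = contour$points[idx, 2],
             row.names = NULL)
}

#' Cohort reference position of a landmark
#'
#' @param positions n x 2 matrix of observers' absolute positions (mm) for one
#'   patient/view/phase/kind.
#' @return Length-2 numeric: the componentwise median.
#' @export
landmark_reference_position <- function(positions) {
  positions <- as_point_matrix(positions)
  if (nrow(positions) == 0L) stop("no landmark positions supplied", call. = FALSE)
  c(x = stats::median(positions[, 1]), y = stats::median(positions[, 2]))
}

#' Landmark offsets from the per-patient reference position
#'
#' Extracts the three landmarks from every contour, computes the reference
#' position per (patient, view, phase, kind), and returns each observation's
#' offset from it. Offsets pooled across patients feed [area_bin_fractions()].
#'
#' @param contours list of observer `standard_contour`s.
#' @return Data frame with identifiers, `kind`, `dx`, `dy` (mm) and `r` (mm,
#'   Euclidean offset magnitude).
#' @export
compute_landmark_offsets <- function(contours) {
  lm <- do.call(rbind, lapply(contours, extract_landmarks))
  key <- interaction(lm$patient_id, lm$view, lm$phase, lm$kind, drop = TRUE)
  lm$dx <- NA_real_
  lm$dy <- NA_real_
  parts <- split(seq_len(nrow(lm)), key)
  for (idx in parts) {
    ref <- landmark_reference_position(cbind(lm$x[idx], lm$y[idx]))
    lm$dx[idx] <- lm$x[idx] - ref[1]
    lm$dy[idx] <- lm$y[idx] - ref[2]
  }
  lm$r <- sqrt(lm$dx^2 + lm$dy^2)
  lm[, c("patient_id", "observer_id", "view", "phase", "kind",
         "dx", "dy", "r")]
}

#' Fractions of landmark offsets within concentric 1/4/9 cm^2 circles
#'
#' Bins are the disjoint annuli between circles of area 1, 4 and 9 cm^2
#' centred on the reference position (radii 5.64, 11.28 and 16.93 mm), plus
#' everything beyond; the four percentages partition to 100.
#'
#' @param offsets n x 2 matrix of offsets (mm), or a numeric vector of offset
#'   magnitudes.
#' @return Named numeric of length 4: `lt_1cm2`, `cm2_1_to_4`, `cm2_4_to_9`,
#'   `gt_9cm2` (percent).
#' @export
area_bin_fractions <- function(offsets) {
  r <- if (is.null(dim(offsets))) abs(as.numeric(offsets))
       else sqrt(rowSums(as_point_matrix(offsets)^2))
  if (length(r) == 0L) stop("no offsets supplied", call. = FALSE)
  radii <- area_bin_radii()
  bin <- findInterval(r, radii, left.open = TRUE)  # 0..3
  pct <- 100 * tabulate(bin + 1L, nbins = 4L) / length(r)
  names(pct) <- c("lt_1cm2", "cm2_1_to_4", "cm2_4_to_9", "gt_9cm2")
  pct
}

#' Area-bin table over all landmarks
#'
#' One row per (view, phase, kind) with the four concentric-area percentages —
#' the layout of a landmark-distribution table.
#'
#' @param offsets data frame from [compute_landmark_offsets()].
#' @return Data frame with `view`, `phase`, `kind`, the four bin percentages
#'   and `n`.
#' @export
area_bin_table <- function(offsets) {
  key <- interaction(offsets$view, offsets$phase, offsets$kind,
                     drop = TRUE, sep = "\r")
  parts <- split(offsets$r, key)
  ks <- do.call(rbind, strsplit(names(parts), "\r", fixed = TRUE))
  pct <- t(vapply(parts, area_bin_fractions, numeric(4)))
  data.frame(view = ks[, 1], phase = ks[, 2], kind = ks[, 3],
             round(pct, 1), n = lengths(parts), row.names = NULL)
}

#' Register an apex observation in 3D from the two orthogonal views
#'
#' Idealizes the 2CH and 4CH planes as orthogonal planes sharing the LV long
#' axis (z): the 4CH plane is the xz-plane, the 2CH plane the yz-plane. The
#' lateral (in-plane, across-axis) apex offsets supply x and y; z is the mean
#' of the two along-axis apex positions. Contours should first be aligned and
#' scaled with [normalize_length()] so observers are comparable.
#'
#' @param apex_offset_4ch,apex_offset_2ch length-2 vectors: (lateral offset,
#'   along-axis offset) of the apex in each view's long-axis frame (mm).
#' @param long_axis_positions length-2 vector: the along-axis apex position in
#'   the 4CH and 2CH views (mm).
#' @return Named numeric (x, y, z) in mm.
#' @export
register_apex_3d <- function(apex_offset_4ch, apex_offset_2ch,
                             long_axis_positions) {
  if (length(apex_offset_4ch) != 2L || length(apex_offset_2ch) != 2L) {
    stop("apex offsets must be length-2 (lateral, along-axis) vectors; ",
         "both views are required", call. = FALSE)
  }
  stopifnot(length(long_axis_positions) == 2L)
  c(x = as.numeric(apex_offset_4ch[1]),
    y = as.numeric(apex_offset_2ch[1]),
    z = mean(as.numeric(long_axis_positions)))
}

#' 3D apex cloud for a study
#'
#' Length-normalizes every observer's ED contours to the cohort mean long
#' axis, then registers each observer-patient apex in 3D via
#' [register_apex_3d()].
#'
#' @param contours list of observer `standard_contour`s (both views present
#'   per observer-patient for the chosen phase).
#' @param phase which phase to register (default `"ED"`).
#' @return Data frame with `patient_id`, `observer_id`, `x`, `y`, `z` (mm).
#' @export
apex_cloud_3d <- function(contours, phase = c("ED", "ES")) {
  phase <- match.arg(phase)
  sel <- Filter(function(cc) cc$phase == phase, contours)
  if (length(sel) == 0L) stop("no contours for phase ", phase, call. = FALSE)
  Lbar <- mean(vapply(sel, long_axis_length, numeric(1)))
  norm <- lapply(sel, normalize_length, target_length = Lbar)
  key <- vapply(norm, function(cc)
    paste(cc$patient_id, cc$observer_id, sep = "\r"), character(1))
  out <- lapply(split(norm, key), function(pair) {
    views <- vapply(pair, `[[`, character(1), "view")
    if (!all(c("2CH", "4CH") %in% views)) return(NULL)
    a4 <- contour_apex(pair[[match("4CH", views)]])
    a2 <- contour_apex(pair[[match("2CH", views)]])
    p <- register_apex_3d(c(a4[1], a4[2]), c(a2[1], a2[2]), c(a4[2], a2[2]))
    data.frame(patient_id = pair[[1]]$patient_id,
               observer_id = pair[[1]]$observer_id,
               x = p["x"], y = p["y"], z = p["z"], row.names = NULL)
  })
  do.call(rbind, out)
}
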