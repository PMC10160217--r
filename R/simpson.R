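# Simpson method of disks: mono- and biplane LV volumes and ejection fraction.
#
# Volumes are computed in the contour's long-axis frame (mid-annular point at
# the origin, apex at (0, L)). Disk i of n sits at height (i - 0.5)/n * L
# (midpoint rule, so neither the mitral plane nor the apex contributes a
# zero-thickness end disk); its diameter is the chord between the two contour
# arms perpendicular to the long axis, with linear interpolation between the
# standardized points. A chord that misses one arm has diameter 0.

#' Perpendicular disk diameters along the long axis
#'
#' @param contour a `standard_contour`.
#' @param n_disks number of disks (>= 1); 20 is the conventional clinical
#'   choice.
#' @return A data frame with `fraction` (disk centre as a fraction of the long
#'   axis, measured from the mitral plane) and `diameter` (mm).
#' @export
disk_diameters <- function(contour, n_disks = 20L) {
  stopifnot(inherits(contour, "standard_contour"), n_disks >= 1L)
  frac <- (seq_len(n_disks) - 0.5) / n_disks
  data.frame(fraction = frac, diameter = disk_diams(contour, n_disks))
}

# diameter vector only (internal fast path for the volume functions)
disk_diams <- function(contour, n_disks) {
  fr <- long_axis_frame(contour)
  y_i <- (seq_len(n_disks) - 0.5) / n_disks * fr$L
  x1 <- arm_chord_x(fr$points[1:50, , drop = FALSE], y_i)
  x2 <- arm_chord_x(fr$points[50:99, , drop = FALSE], y_i)
  d <- abs(x2 - x1)
  d[!is.finite(d)] <- 0
  d
}

# x-coordinate where an arm crosses height y (linear interpolation along the
# arm, treating x as a function of y; non-monotone heights are resolved by
# averaging, which is exact for monotone U-shaped arms).
arm_chord_x <- function(arm, y_out) {
  ok <- !duplicated(arm[, 2])
  if (sum(ok) < 2L) return(rep(NA_real_, length(y_out)))
  stats::approx(arm[, 2], arm[, 1], xout = y_out, ties = mean, rule = 1)$y
}

#' Single-plane Simpson volume
#'
#' Stacks `n_disks` circular disks whose diameters are the perpendicular
#' chords of the contour: V = sum (pi/4) d_i^2 (L / n), converted to ml.
#'
#' @inheritParams disk_diameters
#' @return Volume in ml.
#' @export
monoplane_volume <- function(contour, n_disks = 20L) {
  d <- disk_diams(contour, n_disks)
  L <- long_axis_length(contour)
  sum(pi / 4 * d^2) * (L / n_disks) / 1000
}

#' Biplane Simpson volume from orthogonal apical views
#'
#' Disks are elliptical: diameters are sampled at the same fractional
#' positions along each view's own long axis, and the common disk height uses
#' L = max of the two long axes: V = sum (pi/4) a_i b_i (L / n), in ml.
#'
#' @param contour_4ch the 4CH `standard_contour`.
#' @param contour_2ch the 2CH `standard_contour` of the same phase.
#' @param n_disks number of disks.
#' @return Volume in ml.
#' @export
biplane_volume <- function(contour_4ch, contour_2ch, n_disks = 20L) {
  stopifnot(inherits(contour_4ch, "standard_contour"),
            inherits(contour_2ch, "standard_contour"))
  if (contour_4ch$view == "2CH" || contour_2ch$view == "4CH") {
    stop("view mismatch: biplane_volume(contour_4ch, contour_2ch) expects the ",
         "4CH contour first and the 2CH contour second", call. = FALSE)
  }
  a <- disk_diams(contour_4ch, n_disks)
  b <- disk_diams(contour_2ch, n_disks)
  L <- max(long_axis_length(contour_4ch), long_axis_length(contour_2ch))
  sum(pi / 4 * a * b) * (L / n_disks) / 1000
}

#' Ejection fraction from end-diastolic and end-systolic volumes
#'
#' @param edv end-diastolic volume (ml), > 0.
#' @param esv end-systolic volume (ml), >= 0.
#' @return EF in percent: 100 (EDV - ESV) / EDV.
#' @export
ejection_fraction <- function(edv, esv) {
  if (any(edv <= 0)) stop("EDV must be positive", call. = FALSE)
  if (any(esv < 0)) stop("ESV must be non-negative", call. = FALSE)
  100 * (edv - esv) / edv
}

#' Biplane volumes and EF for one observer-patient
#'
#' Convenience wrapper taking the four standardized contours of one
#' observer-patient (2CH/4CH x ED/ES).
#'
#' @param contours named list with elements `"4CH_ED"`, `"2CH_ED"`,
#'   `"4CH_ES"`, `"2CH_ES"`, each a `standard_contour`.
#' @param n_disks number of disks.
#' @return A one-row data frame: `edv_ml`, `esv_ml`, `ef_pct`,
#'   `long_axis_4ch`, `long_axis_2ch` (ED values, mm), `n_disks`.
#' @export
volume_result <- function(contours, n_disks = 20L) {
  need <- c("4CH_ED", "2CH_ED", "4CH_ES", "2CH_ES")
  if (!all(need %in% names(contours))) {
    stop("contours must be a named list with elements ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  edv <- biplane_volume(contours[["4CH_ED"]], contours[["2CH_ED"]], n_disks)
  esv <- biplane_volume(contours[["4CH_ES"]], contours[["2CH_ES"]], n_disks)
  data.frame(edv_ml = edv, esv_ml = esv,
             ef_pct = ejection_fraction(edv, esv),
             long_axis_4ch = long_axis_length(contours[["4CH_ED"]]),
             long_axis_2ch = long_axis_length(contours[["2CH_ED"]]),
             n_disks = n_disks)
}
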