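# ---- internal geometry helpers ---------------------------------------------

as_point_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.numeric(points) && is.null(dim(points)) && length(points) == 2L) {
    points <- matrix(points, ncol = 2L)
  }
  if (!is.matrix(points) || ncol(points) != 2L || !is.numeric(points)) {
    stop("points must be an n x 2 numeric matrix of (x, y) coordinates in mm",
         call. = FALSE)
  }
  if (!all(is.finite(points))) stop("contour points must be finite", call. = FALSE)
  dimnames(points) <- NULL
  points
}

vec_norm <- function(v) sqrt(sum(v^2))

# signed z-component of (b - a) x (p - a), row-wise over p
chord_cross <- function(a, b, p) {
  (b[1] - a[1]) * (p[, 2] - a[2]) - (b[2] - a[2]) * (p[, 1] - a[1])
}

# ---- RawTracing -------------------------------------------------------------

#' Construct a raw LV endocardial tracing
#'
#' A raw tracing is the ordered planar point list one observer drew for one
#' patient, view (2CH/4CH) and phase (ED/ES), in millimetres, together with the
#' two mitral-annulus anchor points. Some observers close the contour across
#' the mitral plane (a full loop rather than a U shape); such tracings carry
#' `closed = TRUE` and must be cut with [cut_closed_contour()] before
#' standardization.
#'
#' @param points n x 2 numeric matrix of (x, y) coordinates in mm, ordered
#'   along the endocardial border. At least 10 points.
#' @param view `"2CH"` or `"4CH"`.
#' @param phase `"ED"` or `"ES"`.
#' @param annulus_a left-hand annulus in standard apical display: the septal
#'   annulus for 4CH, inferior for 2CH. Defaults to the first point of an open
#'   tracing.
#' @param annulus_b the lateral (4CH) or anterior (2CH) annulus. Defaults to
#'   the last point of an open tracing.
#' @param closed logical; `TRUE` when the tracing loops back across the mitral
#'   plane.
#' @param patient_id,observer_id identifiers carried through the pipeline.
#' @param endpoint_tol tolerance (mm) for the open-tracing invariant that the
#'   first/last points coincide with the annuli.
#' @return An object of class `raw_tracing`.
#' @export
raw_tracing <- function(points, view, phase,
                        annulus_a = NULL, annulus_b = NULL,
                        closed = FALSE,
                        patient_id = "P01", observer_id = "O01",
                        endpoint_tol = 0.5) {
  points <- as_point_matrix(points)
  view <- match.arg(view, c("2CH", "4CH"))
  phase <- match.arg(phase, c("ED", "ES"))
  if (nrow(points) < 10L) {
    stop("a raw tracing needs at least 10 points, got ", nrow(points), call. = FALSE)
  }
  if (is.null(annulus_a)) {
    if (closed) stop("closed tracings must supply annulus_a explicitly", call. = FALSE)
    annulus_a <- points[1L, ]
  }
  if (is.null(annulus_b)) {
    if (closed) stop("closed tracings must supply annulus_b explicitly", call. = FALSE)
    annulus_b <- points[nrow(points), ]
  }
  annulus_a <- as.numeric(annulus_a)
  annulus_b <- as.numeric(annulus_b)
  if (length(annulus_a) != 2L || length(annulus_b) != 2L ||
      !all(is.finite(c(annulus_a, annulus_b)))) {
    stop("annuli must be finite length-2 (x, y) coordinates", call. = FALSE)
  }
  if (vec_norm(annulus_a - annulus_b) < 1e-9) {
    stop("the two mitral annuli must be distinct points", call. = FALSE)
  }
  if (!closed) {
    if (vec_norm(points[1L, ] - annulus_a) > endpoint_tol ||
        vec_norm(points[nrow(points), ] - annulus_b) > endpoint_tol) {
      stop("open tracing must start at annulus_a and end at annulus_b ",
           "(within ", endpoint_tol, " mm)", call. = FALSE)
    }
  }
  structure(
    list(points = points, view = view, phase = phase,
         annulus_a = annulus_a, annulus_b = annulus_b,
         closed = isTRUE(closed),
         patient_id = as.character(patient_id),
         observer_id = as.character(observer_id)),
    class = "raw_tracing")
}

#' @export
print.raw_tracing <- function(x, ...) {
  cat(sprintf("<raw_tracing> %s/%s %s-%s: %d points%s\n",
              x$patient_id, x$observer_id, x$view, x$phase,
              nrow(x$points), if (x$closed) " (closed)" else ""))
  invisible(x)
}

# ---- StandardContour --------------------------------------------------------

#' Construct a 99-point standard contour
#'
#' The canonical unit of comparison: 99 points labelled 1..99 with the annuli
#' at labels 1 and 99 and the apex at label 50; within each arm (1..50 and
#' 50..99) consecutive points are equidistant along the tracing. Usually built
#' via [standardize_contour()] rather than directly.
#'
#' @param points 99 x 2 numeric matrix (mm).
#' @param view,phase view/phase tags as in [raw_tracing()].
#' @param patient_id,observer_id provenance; `observer_id = "reference"` marks
#'   a consensus contour.
#' @return An object of class `standard_contour`.
#' @export
standard_contour <- function(points, view, phase,
                             patient_id = "P01", observer_id = "O01") {
  points <- as_point_matrix(points)
  if (nrow(points) != 99L) {
    stop("a standard contour has exactly 99 points, got ", nrow(points),
         call. = FALSE)
  }
  view <- match.arg(view, c("2CH", "4CH"))
  phase <- match.arg(phase, c("ED", "ES"))
  structure(
    list(points = points, view = view, phase = phase,
         patient_id = as.character(patient_id),
         observer_id = as.character(observer_id)),
    class = "standard_contour")
}

#' @export
print.standard_contour <- function(x, ...) {
  cat(sprintf("<standard_contour> %s/%s %s-%s: long axis %.1f mm\n",
              x$patient_id, x$observer_id, x$view, x$phase,
              long_axis_length(x)))
  invisible(x)
}

#' Landmark accessors for a standard contour
#'
#' `contour_midbase()` is the midpoint of the two annuli (labels 1 and 99),
#' `contour_apex()` the label-50 point, and `long_axis_length()` the distance
#' between them — the LV long axis used by the method of disks.
#'
#' @param contour a `standard_contour`.
#' @return A length-2 coordinate, or a scalar length in mm.
#' @export
contour_midbase <- function(contour) {
  (contour$points[1L, ] + contour$points[99L, ]) / 2
}

#' @rdname contour_midbase
#' @export
contour_apex <- function(contour) contour$points[50L, ]

#' @rdname contour_midbase
#' @export
long_axis_length <- function(contour) {
  vec_norm(contour_apex(contour) - contour_midbase(contour))
}

# ---- apex detection ---------------------------------------------------------

#' Detect the apex of a tracing
#'
#' The apex is the traversal point with the largest Euclidean distance to the
#' midpoint of the two mitral annuli. Ties are broken by the lowest traversal
#' index.
#'
#' @param points n x 2 matrix of ordered contour points (mm).
#' @param annulus_a,annulus_b the two annulus coordinates.
#' @return A list with `index` (traversal index) and `point` (x, y).
#' @export
detect_apex <- function(points, annulus_a, annulus_b) {
  points <- as_point_matrix(points)
  if (nrow(points) < 3L) {
    stop("invalid contour: apex detection needs at least 3 points", call. = FALSE)
  }
  annulus_a <- as.numeric(annulus_a)
  annulus_b <- as.numeric(annulus_b)
  if (vec_norm(annulus_a - annulus_b) < 1e-9) {
    stop("the two mitral annuli must be distinct points", call. = FALSE)
  }
  mid <- (annulus_a + annulus_b) / 2
  d2 <- (points[, 1] - mid[1])^2 + (points[, 2] - mid[2])^2
  idx <- which.max(d2)  # which.max returns the first maximum: tie-break rule
  list(index = idx, point = points[idx, ])
}

# ---- closed-contour cutting -------------------------------------------------

#' Cut a closed (circular) tracing to an open U-shaped one
#'
#' Observers occasionally trace the LV as a full loop across the mitral plane
#' instead of a U shape. The annulus-to-annulus chord (the mitral plane) splits
#' such a loop into an apical and a basal arc; this function keeps the apical
#' arc running annulus_a -> apex -> annulus_b, discards the basal points, and
#' clears the `closed` flag. Surviving points are never moved; the exact
#' annulus coordinates are inserted at the ends when the arc does not already
#' terminate there, so the output endpoints lie on the mitral chord.
#'
#' Open tracings are returned unchanged.
#'
#' @param tracing a `raw_tracing`.
#' @param tol chord-classification tolerance as a fraction of the annulus
#'   separation; points within it of the chord count as on-chord and are kept.
#' @return An open `raw_tracing`.
#' @export
cut_closed_contour <- function(tracing, tol = 1e-6) {
  stopifnot(inherits(tracing, "raw_tracing"))
  if (!tracing$closed) return(tracing)

  a <- tracing$annulus_a
  b <- tracing$annulus_b
  P <- tracing$points
  n <- nrow(P)
  cr <- chord_cross(a, b, P) / vec_norm(b - a)  # signed distance to the chord
  apx <- detect_apex(P, a, b)
  apex_side <- sign(cr[apx$index])
  if (apex_side == 0) {
    stop("degenerate contour: apex lies on the mitral chord", call. = FALSE)
  }
  keep <- cr * apex_side >= -tol * vec_norm(b - a)
  if (!any(cr * apex_side > tol * vec_norm(b - a))) {
    stop("degenerate contour: no points on the apical side of the mitral chord",
         call. = FALSE)
  }

  # contiguous cyclic run of apical-side points containing the apex
  lo <- apx$index
  while (keep[(lo - 2L) %% n + 1L] && ((lo - 2L) %% n + 1L) != apx$index) {
    lo <- (lo - 2L) %% n + 1L
  }
  hi <- apx$index
  while (keep[hi %% n + 1L] && (hi %% n + 1L) != lo) hi <- hi %% n + 1L
  idx <- if (lo <= hi) lo:hi else c(lo:n, 1L:hi)
  arc <- P[idx, , drop = FALSE]

  # orient annulus_a -> apex -> annulus_b
  if (vec_norm(arc[1L, ] - a) > vec_norm(arc[1L, ] - b)) {
    arc <- arc[rev(seq_len(nrow(arc))), , drop = FALSE]
  }
  if (vec_norm(arc[1L, ] - a) > 1e-9) arc <- rbind(a, arc)
  if (vec_norm(arc[nrow(arc), ] - b) > 1e-9) arc <- rbind(arc, b)

  raw_tracing(arc, view = tracing$view, phase = tracing$phase,
              annulus_a = a, annulus_b = b, closed = FALSE,
              patient_id = tracing$patient_id,
              observer_id = tracing$observer_id)
}

# ---- standardization --------------------------------------------------------

resample_once <- function(arm, n_out) {
  seg <- sqrt(diff(arm[, 1])^2 + diff(arm[, 2])^2)
  # drop zero-length segments (duplicated raw points) to keep approx() happy
  dup <- c(FALSE, seg < 1e-12)
  if (any(dup)) {
    arm <- arm[!dup, , drop = FALSE]
    seg <- sqrt(diff(arm[, 1])^2 + diff(arm[, 2])^2)
  }
  total <- sum(seg)
  if (nrow(arm) < 2L || total < 1e-9) {
    stop("degenerate contour: an annulus-to-apex arm has zero length", call. = FALSE)
  }
  s <- c(0, cumsum(seg))
  t <- seq(0, total, length.out = n_out)
  cbind(stats::approx(s, arm[, 1], xout = t)$y,
        stats::approx(s, arm[, 2], xout = t)$y)
}

# Equidistant resampling of one annulus-to-apex arm. A single arc-length pass
# leaves the output chords unequal by O(spacing^3 x curvature^2), so a couple
# of fixed-point iterations (each staying on the previous polyline) drive the
# chord lengths to equality; the equal-chord polyline is the fixed point of
# the resampling, which makes standardization idempotent.
resample_arm <- function(arm, n_out = 50L, iterations = 3L) {
  out <- resample_once(arm, n_out)
  for (k in seq_len(iterations)) out <- resample_once(out, n_out)
  out
}

#' Standardize a tracing to the 99-point canonical contour
#'
#' Detects the apex on the raw polyline (farthest point from the mid-annular
#' point), splits the tracing into the two annulus-to-apex arms, and resamples
#' each arm equidistantly by arc length so that labels 1 and 99 carry the
#' annuli and label 50 the apex. Closed tracings are first cut with
#' [cut_closed_contour()]. Interpolation is linear along the raw polyline.
#'
#' @param tracing a `raw_tracing` (open or closed) or a `standard_contour`
#'   (re-standardized, which reproduces it to within numerical tolerance).
#' @return A `standard_contour`.
#' @export
standardize_contour <- function(tracing) {
  if (inherits(tracing, "standard_contour")) {
    tracing <- raw_tracing(tracing$points, view = tracing$view,
                           phase = tracing$phase,
                           patient_id = tracing$patient_id,
                           observer_id = tracing$observer_id)
  }
  stopifnot(inherits(tracing, "raw_tracing"))
  if (tracing$closed) tracing <- cut_closed_contour(tracing)

  P <- tracing$points
  apx <- detect_apex(P, tracing$annulus_a, tracing$annulus_b)
  if (apx$index == 1L || apx$index == nrow(P)) {
    stop("degenerate contour: apex coincides with an annulus", call. = FALSE)
  }
  arm1 <- resample_arm(P[1:apx$index, , drop = FALSE])
  arm2 <- resample_arm(P[apx$index:nrow(P), , drop = FALSE])
  pts <- rbind(arm1[1:49, , drop = FALSE],
               P[apx$index, , drop = FALSE],  # apex exactly at label 50
               arm2[2:50, , drop = FALSE])
  standard_contour(pts, view = tracing$view, phase = tracing$phase,
                   patient_id = tracing$patient_id,
                   observer_id = tracing$observer_id)
}

# ---- length normalization ---------------------------------------------------

#' Rigidly align a contour and scale its long axis to a target length
#'
#' Translates the contour so the mid-annular point sits at the origin, rotates
#' it so the apex lies on the positive y axis, and scales isotropically so the
#' long-axis length equals `target_length`. Used before pooling contours of
#' hearts of different size (e.g. for 3D apex registration).
#'
#' @param contour a `standard_contour`.
#' @param target_length desired long-axis length in mm.
#' @return A `standard_contour` in the aligned frame.
#' @export
normalize_length <- function(contour, target_length) {
  stopifnot(inherits(contour, "standard_contour"), target_length > 0)
  mid <- contour_midbase(contour)
  v <- contour_apex(contour) - mid
  L <- vec_norm(v)
  if (L < 1e-9) stop("degenerate contour: zero-length long axis", call. = FALSE)
  u <- v / L
  R <- matrix(c(u[2], -u[1], u[1], u[2]), nrow = 2L, byrow = TRUE)  # u -> (0,1)
  pts <- sweep(contour$points, 2L, mid) %*% t(R) * (target_length / L)
  standard_contour(pts, view = contour$view, phase = contour$phase,
                   patient_id = contour$patient_id,
                   observer_id = contour$observer_id)
}

# Rotate/translate into the long-axis frame without scaling: mid-base at the
# origin, apex at (0, L). Shared by the disk sampler and the generator.
long_axis_frame <- function(contour) {
  mid <- contour_midbase(contour)
  v <- contour_apex(contour) - mid
  L <- vec_norm(v)
  if (L < 1e-9) stop("degenerate contour: zero-length long axis", call. = FALSE)
  u <- v / L
  R <- matrix(c(u[2], -u[1], u[1], u[2]), nrow = 2L, byrow = TRUE)
  list(points = sweep(contour$points, 2L, mid) %*% t(R), L = L)
}
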