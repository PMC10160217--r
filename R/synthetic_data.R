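# Synthetic multi-observer study generator.
#
# Ground truth per patient is a half-ellipse LV silhouette per view (it has a
# closed-form Simpson volume, which the test oracles use); the ES contour is
# the ED contour scaled in-plane about the mid-annular point, so the truth EF
# is 100 (1 - s^3). Observer tracings displace each truth point along its
# outward normal by a per-observer bias plus zero-mean Gaussian noise whose
# standard deviation depends on wall, level, phase and view; the annuli and
# apex additionally receive kind-specific isotropic 2D jitter. The generator
# emits raw polylines -- standardization is the pipeline's job.

#' Configuration for a synthetic multi-observer study
#'
#' Defaults emulate a study of 15 echocardiograms read by 42 cardiologists
#' (four tracings each: 2CH/4CH x ED/ES), with more tracing noise on the
#' lateral than the septal wall, on the anterior than the inferior wall, at
#' ED than at ES, in the 2CH than the 4CH view, and apically than basally,
#' and with landmark jitter largest at the apex, intermediate at the
#' lateral/anterior annulus and smallest at the septal/inferior annulus.
#'
#' @param n_patients,n_observers study scale.
#' @param long_axis_range,semi_width_range_4ch,semi_width_range_2ch uniform
#'   sampling ranges (mm) for the per-patient ED geometry.
#' @param ef_mean,ef_sd,ef_range truth EF distribution (percent): normal,
#'   truncated to `ef_range`; sets the systolic in-plane scale
#'   s = (1 - EF/100)^(1/3).
#' @param sigma_wall named numeric (mm): base tracing noise per wall region.
#' @param phase_mult,level_mult,view_mult named multipliers applied to
#'   `sigma_wall` (ED >= ES, apical > mid > basal, 2CH >= 4CH).
#' @param smooth_window centred moving-average window (points) applied to the
#'   normal noise along the contour; 0 or 1 = i.i.d. noise. A window w
#'   reduces the marginal point standard deviation by about sqrt(w).
#' @param bias_sd standard deviation (mm) of the per-observer outward bias,
#'   shared by both phases.
#' @param bias_ed_extra_sd standard deviation (mm) of an additional ED-only
#'   per-observer outward bias (0 = none). A positive value couples contour
#'   size to EF: observers tracing ED larger obtain higher EFs.
#' @param scale_bias_sd standard deviation of a per-observer multiplicative
#'   in-plane scale bias (dimensionless; 0 = none). Because it scales both
#'   phases equally it shifts contour size without moving EF.
#' @param landmark_sigma named numeric (mm): isotropic jitter per landmark
#'   bucket (`septal_inferior`, `lateral_anterior`, `apex`).
#' @param experience_probs probabilities of the `<5`, `5-10`, `>10` years
#'   experience categories; years are drawn uniformly within the category.
#'   Experience is assigned independently of tracing behaviour.
#' @param seed integer RNG seed; `simulate_study()` is reproducible given
#'   (config, seed).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_patients = 15L, n_observers = 42L,
                         long_axis_range = c(72, 95),
                         semi_width_range_4ch = c(20, 28),
                         semi_width_range_2ch = c(19, 27),
                         ef_mean = 49, ef_sd = 15, ef_range = c(15, 72),
                         sigma_wall = c(septal = 2, lateral = 3,
                                        inferior = 2.2, anterior = 3.2),
                         phase_mult = c(ED = 1, ES = 0.85),
                         level_mult = c(basal = 0.9, mid = 1, apical = 1.25),
                         view_mult = c("2CH" = 1.1, "4CH" = 1),
                         smooth_window = 0L,
                         bias_sd = 1.0, bias_ed_extra_sd = 0,
                         scale_bias_sd = 0,
                         landmark_sigma = c(septal_inferior = 2,
                                            lateral_anterior = 3, apex = 4),
                         experience_probs = c(0.40, 0.31, 0.29),
                         seed = NULL) {
  cfg <- as.list(environment())
  if (any(cfg$sigma_wall < 0) || any(cfg$landmark_sigma < 0) ||
      cfg$bias_sd < 0 || cfg$bias_ed_extra_sd < 0 || cfg$scale_bias_sd < 0) {
    stop("all noise standard deviations must be non-negative", call. = FALSE)
  }
  if (any(cfg$ef_range <= 0) || any(cfg$ef_range >= 100)) {
    stop("ef_range must lie strictly within (0, 100)", call. = FALSE)
  }
  stopifnot(n_patients >= 1L, n_observers >= 1L, smooth_window >= 0L)
  class(cfg) <- "synth_config"
  cfg
}

#' Ground-truth contours for one patient
#'
#' ED contours are half-ellipses with the view's basal semi-width and the
#' shared long axis; ES contours are the ED contours scaled in-plane by
#' `systolic_scale` about the mid-annular point. All four are standardized to
#' 99 points.
#'
#' @param long_axis ED long axis L (mm).
#' @param semi_width_4ch,semi_width_2ch basal semi-width b per view (mm).
#' @param systolic_scale in-plane systolic scale s, 0 < s <= 1; truth biplane
#'   EF is 100 (1 - s^3) up to disk discretization.
#' @param patient_id identifier.
#' @return Named list of four `standard_contour`s keyed `"<view>_<phase>"`.
#' @export
make_truth_contours <- function(long_axis, semi_width_4ch, semi_width_2ch,
                                systolic_scale, patient_id = "P01") {
  if (systolic_scale <= 0 || systolic_scale > 1) {
    stop("systolic_scale must lie in (0, 1]", call. = FALSE)
  }
  if (semi_width_4ch <= 0 || semi_width_2ch <= 0 || long_axis <= 0) {
    stop("geometry parameters must be positive", call. = FALSE)
  }
  half_ellipse <- function(b, L, view) {
    th <- seq(0, pi, length.out = 721L)
    pts <- cbind(-b * cos(th), L * sin(th))
    standardize_contour(raw_tracing(pts, view = view, phase = "ED",
                                    patient_id = patient_id,
                                    observer_id = "truth"))
  }
  ed4 <- half_ellipse(semi_width_4ch, long_axis, "4CH")
  ed2 <- half_ellipse(semi_width_2ch, long_axis, "2CH")
  scale_es <- function(ed) {
    mid <- contour_midbase(ed)
    pts <- sweep(sweep(ed$points, 2L, mid) * systolic_scale, 2L, mid, `+`)
    standard_contour(pts, view = ed$view, phase = "ES",
                     patient_id = patient_id, observer_id = "truth")
  }
  list(`4CH_ED` = ed4, `2CH_ED` = ed2,
       `4CH_ES` = scale_es(ed4), `2CH_ES` = scale_es(ed2))
}

#' Per-label noise standard deviations for one view/phase
#'
#' Maps each standardized label to its wall and level and combines the base
#' wall sigma with the level, phase and view multipliers. The apex label (50)
#' gets 0: its scatter is modelled by the landmark jitter.
#'
#' @param view,phase tracing view/phase.
#' @param config a `synth_config`.
#' @return Numeric vector of length 99 (mm).
#' @export
sigma_profile <- function(view, phase, config) {
  seg <- segment_of_label(1:99, view)
  sig <- numeric(99)
  ok <- seg$wall != "apex"
  sig[ok] <- config$sigma_wall[seg$wall[ok]] *
    config$level_mult[seg$level[ok]]
  sig * config$phase_mult[[phase]] * config$view_mult[[view]]
}

#' Perturb a truth contour into one observer's notional standard contour
#'
#' Applies the observer's multiplicative in-plane scale about the mid-annular
#' point, then displaces every non-landmark point along the truth's outward
#' normal by `bias + eps` with `eps ~ N(0, sigma_l^2)` (optionally smoothed
#' along the contour by a centred moving average), and displaces the annuli
#' and apex by `bias` along the normal plus kind-specific isotropic 2D
#' jitter. Labels are preserved, so closed-form checks can compare points
#' directly. Draws from the current RNG state.
#'
#' @param truth a `standard_contour`.
#' @param sigma length-99 (or scalar) normal-noise sd per label (mm).
#' @param bias outward displacement applied to every point (mm).
#' @param landmark_sigma length-3 named vector as in [synth_config()] (mm);
#'   0s disable landmark jitter.
#' @param smooth_window moving-average window for the noise (0/1 = i.i.d.).
#' @param scale multiplicative in-plane scale about the mid-annular point.
#' @param observer_id provenance for the output.
#' @return A `standard_contour`.
#' @export
perturb_contour <- function(truth, sigma, bias = 0,
                            landmark_sigma = c(septal_inferior = 0,
                                               lateral_anterior = 0, apex = 0),
                            smooth_window = 0L, scale = 1,
                            observer_id = "O01") {
  stopifnot(inherits(truth, "standard_contour"))
  sigma <- rep_len(sigma, 99L)
  pts <- truth$points
  if (scale != 1) {
    mid <- contour_midbase(truth)
    pts <- sweep(sweep(pts, 2L, mid) * scale, 2L, mid, `+`)
  }
  nrm <- outward_normals(truth)
  eps <- stats::rnorm(99L, 0, sigma)
  if (smooth_window > 1L) {
    w <- as.integer(smooth_window)
    eps <- as.numeric(stats::filter(eps, rep(1 / w, w), sides = 2L,
                                    circular = TRUE))
  }
  lm_idx <- c(1L, 99L, 50L)
  eps[lm_idx] <- 0
  pts <- pts + (bias + eps) * nrm
  lm_sd <- if (is.null(names(landmark_sigma))) {
    rep_len(landmark_sigma, 3L)
  } else {
    landmark_sigma[c("septal_inferior", "lateral_anterior", "apex")]
  }
  jit <- matrix(stats::rnorm(6L, 0, rep(lm_sd, 2L)), ncol = 2L)
  pts[lm_idx, ] <- pts[lm_idx, ] + jit
  standard_contour(pts, view = truth$view, phase = truth$phase,
                   patient_id = truth$patient_id, observer_id = observer_id)
}

#' Simulate one observer's raw tracing of a truth contour
#'
#' Wraps [perturb_contour()] with the observer's bias/scale parameters and the
#' config's noise model, and returns the result as a raw (unlabelled)
#' polyline: re-standardization is the analysis pipeline's job.
#'
#' @param truth a truth `standard_contour`.
#' @param observer one row of the study's observer table (needs
#'   `observer_id`, `bias`, `bias_ed_extra`, `scale`).
#' @param config a `synth_config`.
#' @return A `raw_tracing` with 99 points.
#' @export
simulate_observer_tracing <- function(truth, observer, config) {
  bias <- observer$bias + if (truth$phase == "ED") observer$bias_ed_extra else 0
  sc <- perturb_contour(
    truth,
    sigma = sigma_profile(truth$view, truth$phase, config),
    bias = bias,
    landmark_sigma = config$landmark_sigma,
    smooth_window = config$smooth_window,
    scale = observer$scale,
    observer_id = observer$observer_id)
  raw_tracing(sc$points, view = sc$view, phase = sc$phase,
              annulus_a = sc$points[1L, ], annulus_b = sc$points[99L, ],
              closed = FALSE, patient_id = sc$patient_id,
              observer_id = sc$observer_id, endpoint_tol = Inf)
}

sample_experience <- function(n, probs) {
  cat_idx <- sample.int(3L, n, replace = TRUE, prob = probs)
  lo <- c(0, 5, 10)[cat_idx]
  hi <- c(5, 10, 25)[cat_idx]
  round(stats::runif(n, lo, hi), 1)
}

#' Simulate a complete multi-observer study
#'
#' Samples per-patient geometry and per-observer parameters once, then
#' generates `n_patients x n_observers x 4` raw tracings. The ground truth is
#' retained for recovery tests; the generator never reads analysis output.
#'
#' @param config a `synth_config`.
#' @return A list of class `lv_study`: `tracings` (named list of
#'   `raw_tracing`), `observers`, `patients` (data frames), `truth` (named
#'   list of `standard_contour`, keys `"<patient>_<view>_<phase>"`) and
#'   `config`.
#' @export
simulate_study <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  np <- config$n_patients
  no <- config$n_observers
  pid <- sprintf("P%02d", seq_len(np))
  oid <- sprintf("O%02d", seq_len(no))

  ef <- stats::rnorm(np, config$ef_mean, config$ef_sd)
  ef <- pmin(pmax(ef, config$ef_range[1]), config$ef_range[2])
  patients <- data.frame(
    patient_id = pid,
    long_axis = stats::runif(np, config$long_axis_range[1],
                             config$long_axis_range[2]),
    semi_width_4ch = stats::runif(np, config$semi_width_range_4ch[1],
                                  config$semi_width_range_4ch[2]),
    semi_width_2ch = stats::runif(np, config$semi_width_range_2ch[1],
                                  config$semi_width_range_2ch[2]),
    truth_ef = ef,
    systolic_scale = (1 - ef / 100)^(1 / 3))

  observers <- data.frame(
    observer_id = oid,
    bias = stats::rnorm(no, 0, config$bias_sd),
    bias_ed_extra = if (config$bias_ed_extra_sd > 0)
      stats::rnorm(no, 0, config$bias_ed_extra_sd) else numeric(no),
    scale = if (config$scale_bias_sd > 0)
      1 + stats::rnorm(no, 0, config$scale_bias_sd) else rep(1, no),
    experience_years = sample_experience(no, config$experience_probs))

  truth <- list()
  tracings <- list()
  for (i in seq_len(np)) {
    tc <- make_truth_contours(patients$long_axis[i],
                              patients$semi_width_4ch[i],
                              patients$semi_width_2ch[i],
                              patients$systolic_scale[i],
                              patient_id = pid[i])
    names(tc) <- paste(pid[i], names(tc), sep = "_")
    truth <- c(truth, tc)
    for (key in names(tc)) {
      for (j in seq_len(no)) {
        tr <- simulate_observer_tracing(tc[[key]], observers[j, ], config)
        tracings[[paste(pid[i], oid[j],
                        tr$view, tr$phase, sep = "_")]] <- tr
      }
    }
  }
  structure(list(tracings = tracings, observers = observers,
                 patients = patients, truth = truth, config = config),
            class = "lv_study")
}

#' @export
print.lv_study <- function(x, ...) {
  cat(sprintf("<lv_study> %d patients x %d observers: %d tracings\n",
              nrow(x$patients), nrow(x$observers), length(x$tracings)))
  invisible(x)
}
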