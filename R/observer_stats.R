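# Observer-level analyses: volume over/under-estimation relative to the
# cohort, size-based grouping of observers by their overall contour
# localization, experience categories, Spearman correlations between volumes
# and EF, and the nonparametric omnibus/pairwise tests (Kruskal-Wallis,
# Friedman) used to compare groups and regions.

#' Per-observer volume deviation from the cohort median
#'
#' For each observer and phase, the median over patients of
#' 100 (V_obs - V_median) / V_median, where V_median is the cohort median
#' biplane volume of that patient/phase.
#'
#' @param volumes data frame with `patient_id`, `observer_id`, `edv_ml`,
#'   `esv_ml` (one row per observer-patient), e.g. from [study_volumes()].
#' @return Data frame with `observer_id`, `edv_pct_diff`, `esv_pct_diff`.
#' @export
volume_deviation_profile <- function(volumes) {
  if (length(unique(volumes$observer_id)) < 2L) {
    stop("volume deviation needs at least 2 observers", call. = FALSE)
  }
  pct <- function(col) {
    med <- stats::ave(volumes[[col]], volumes$patient_id, FUN = stats::median)
    d <- 100 * (volumes[[col]] - med) / med
    vapply(split(d, volumes$observer_id), stats::median, numeric(1), na.rm = TRUE)
  }
  edv <- pct("edv_ml")
  esv <- pct("esv_ml")
  data.frame(observer_id = names(edv), edv_pct_diff = unname(edv),
             esv_pct_diff = unname(esv), row.names = NULL)
}

#' Classify observers into small / medium / large tracers
#'
#' By the observer's median signed distance to the reference over all their
#' distance records: below `-threshold` mm = small, above `+threshold` =
#' large, otherwise medium (in line with the reference).
#'
#' @param median_signed_distance numeric vector (mm), one value per observer.
#' @param threshold classification threshold in mm (default 1.0).
#' @return Factor with levels `small`, `medium`, `large`.
#' @export
classify_observers <- function(median_signed_distance, threshold = 1.0) {
  stopifnot(threshold >= 0)
  g <- ifelse(median_signed_distance < -threshold, "small",
              ifelse(median_signed_distance > threshold, "large", "medium"))
  factor(g, levels = c("small", "medium", "large"))
}

#' Experience categories
#'
#' `< 5`, `5-10` (closed on both ends) and `> 10` years of echocardiography
#' experience.
#'
#' @param experience_years numeric vector of years (NA allowed).
#' @return Factor with levels `<5`, `5-10`, `>10`.
#' @export
experience_category <- function(experience_years) {
  g <- ifelse(experience_years < 5, "<5",
              ifelse(experience_years <= 10, "5-10", ">10"))
  factor(g, levels = c("<5", "5-10", ">10"))
}

#' Observer profiles
#'
#' Combines distance records, volumes and observer metadata into one table per
#' observer: overall median signed distance, size group, median biplane EF
#' over patients, EF difference from the reference-contour EF, volume
#' deviations and experience category.
#'
#' @param records distance records ([compute_distance_records()]).
#' @param volumes per observer-patient volumes ([study_volumes()]).
#' @param reference_ef scalar: the median over patients of the EF computed
#'   from the reference contours.
#' @param observers optional data frame with `observer_id` and
#'   `experience_years`.
#' @param threshold size-group threshold (mm).
#' @return Data frame, one row per observer.
#' @export
observer_profiles <- function(records, volumes, reference_ef = NA_real_,
                              observers = NULL, threshold = 1.0) {
  msd <- vapply(split(records$signed_distance, records$observer_id),
                stats::median, numeric(1))
  ef <- vapply(split(volumes$ef_pct, volumes$observer_id),
               stats::median, numeric(1))
  ids <- sort(unique(c(names(msd), names(ef))))
  prof <- data.frame(observer_id = ids,
                     median_signed_distance = unname(msd[ids]),
                     median_ef = unname(ef[ids]),
                     row.names = NULL)
  prof$size_group <- classify_observers(prof$median_signed_distance, threshold)
  prof$ef_diff_from_reference <- prof$median_ef - reference_ef
  dev <- volume_deviation_profile(volumes)
  prof <- merge(prof, dev, by = "observer_id", all.x = TRUE, sort = TRUE)
  if (!is.null(observers) && "experience_years" %in% names(observers)) {
    prof <- merge(prof,
                  observers[, c("observer_id", "experience_years")],
                  by = "observer_id", all.x = TRUE, sort = TRUE)
    prof$experience_category <- experience_category(prof$experience_years)
  }
  prof
}

# shared machinery: group medians/IQR + Kruskal-Wallis omnibus on a value
group_test <- function(value, group) {
  keep <- !is.na(value) & !is.na(group)
  value <- value[keep]
  group <- droplevels(factor(group[keep]))
  summaries <- do.call(rbind, lapply(levels(group), function(g) {
    v <- value[group == g]
    data.frame(group = g, n = length(v), median = stats::median(v),
               q25 = unname(stats::quantile(v, 0.25)),
               q75 = unname(stats::quantile(v, 0.75)))
  }))
  if (nlevels(group) >= 2L && all(table(group) >= 1L)) {
    kw <- stats::kruskal.test(value, group)
    list(summary = summaries, statistic = unname(kw$statistic),
         df = unname(kw$parameter), p_value = kw$p.value, applicable = TRUE)
  } else {
    list(summary = summaries, statistic = NA_real_, df = NA_real_,
         p_value = NA_real_, applicable = FALSE)
  }
}

#' Compare EF across contour-size groups
#'
#' Median (IQR) of the absolute EF and of the EF difference from the reference
#' EF per size group, with an independent-samples Kruskal-Wallis omnibus test
#' on each.
#'
#' @param profiles observer profiles ([observer_profiles()]).
#' @return List with `ef` and `ef_diff` components, each carrying `summary`,
#'   `statistic`, `df`, `p_value` and `applicable`.
#' @export
group_ef_comparison <- function(profiles) {
  list(ef = group_test(profiles$median_ef, profiles$size_group),
       ef_diff = group_test(profiles$ef_diff_from_reference,
                            profiles$size_group))
}

#' Compare EF across experience categories
#'
#' Same machinery as [group_ef_comparison()] with experience categories as
#' groups. Observers with missing experience are excluded (and counted).
#'
#' @param profiles observer profiles with an `experience_category` column.
#' @return List as in [group_ef_comparison()], plus `n_excluded`.
#' @export
experience_comparison <- function(profiles) {
  if (is.null(profiles$experience_category)) {
    stop("profiles carry no experience_category column", call. = FALSE)
  }
  res <- list(ef = group_test(profiles$median_ef, profiles$experience_category),
              ef_diff = group_test(profiles$ef_diff_from_reference,
                                   profiles$experience_category))
  res$n_excluded <- sum(is.na(profiles$experience_category))
  res
}

# block medians of unsigned distance per condition; blocks = observer x patient
block_medians <- function(records, condition, blocks = NULL) {
  bk <- if (is.null(blocks)) {
    paste(records$observer_id, records$patient_id, sep = "\r")
  } else blocks
  tapply(records$unsigned_distance, list(bk, condition), stats::median)
}

friedman_on_blocks <- function(m) {
  complete <- stats::complete.cases(m)
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < 2L) {
    return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                n_blocks = nrow(m), n_dropped = sum(!complete)))
  }
  fr <- stats::friedman.test(as.matrix(m))
  list(statistic = unname(fr$statistic), df = unname(fr$parameter),
       p_value = fr$p.value, n_blocks = nrow(m), n_dropped = sum(!complete))
}

#' Friedman comparison of wall regions with pairwise reductions
#'
#' Related-samples Friedman two-way analysis over blocks = (observer,
#' patient), treatments = the four wall regions (septal, lateral, inferior,
#' anterior), each summarized as the block's median unsigned distance.
#' Pairwise two-treatment Friedman reductions are reported for the named
#' contrasts: septal vs lateral, inferior vs anterior, ED vs ES, 2CH vs 4CH,
#' and apical vs basal. Incomplete blocks are dropped and counted.
#'
#' @param records distance records ([compute_distance_records()]).
#' @return List with `omnibus` (wall-region Friedman) and `pairwise`, a data
#'   frame with one row per contrast.
#' @export
region_comparison <- function(records) {
  blocks <- paste(records$observer_id, records$patient_id, sep = "\r")
  omni <- friedman_on_blocks(block_medians(records, records$wall, blocks))
  pair <- function(cond, a, b) {
    m <- block_medians(records, cond, blocks)
    keep <- intersect(c(a, b), colnames(m))
    res <- friedman_on_blocks(m[, keep, drop = FALSE])
    data.frame(comparison = paste(a, "vs", b),
               statistic = res$statistic, df = res$df, p_value = res$p_value,
               n_blocks = res$n_blocks, n_dropped = res$n_dropped)
  }
  pairwise <- rbind(
    pair(records$wall, "septal", "lateral"),
    pair(records$wall, "inferior", "anterior"),
    pair(records$phase, "ED", "ES"),
    pair(records$view, "2CH", "4CH"),
    pair(records$level, "apical", "basal"))
  list(omnibus = omni, pairwise = pairwise)
}

#' Spearman correlations between observer volumes and EF
#'
#' Rank correlations (midranks for ties) between per-observer median EDV, ESV
#' and EF.
#'
#' @param profiles_volumes data frame with one row per observer and columns
#'   `edv_ml`, `esv_ml`, `ef_pct` (per-observer medians), e.g. from
#'   [observer_median_volumes()].
#' @return Data frame with `pair`, `spearman_r` and `n`; a constant input
#'   yields `NA` with a warning.
#' @export
volume_ef_correlations <- function(profiles_volumes) {
  v <- profiles_volumes
  if (nrow(v) < 3L) stop("need at least 3 observers", call. = FALSE)
  sp <- function(x, y) {
    if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
      warning("constant input: Spearman correlation undefined")
      return(NA_real_)
    }
    stats::cor(x, y, method = "spearman")
  }
  data.frame(
    pair = c("EDV~ESV", "ESV~EF", "EDV~EF"),
    spearman_r = c(sp(v$edv_ml, v$esv_ml),
                   sp(v$esv_ml, v$ef_pct),
                   sp(v$edv_ml, v$ef_pct)),
    n = nrow(v))
}

#' Per-observer median volumes and EF
#'
#' @param volumes per observer-patient volumes ([study_volumes()]).
#' @return One row per observer with median `edv_ml`, `esv_ml`, `ef_pct`.
#' @export
observer_median_volumes <- function(volumes) {
  agg <- function(col) vapply(split(volumes[[col]], volumes$observer_id),
                              stats::median, numeric(1))
  data.frame(observer_id = names(agg("edv_ml")),
             edv_ml = unname(agg("edv_ml")),
             esv_ml = unname(agg("esv_ml")),
             ef_pct = unname(agg("ef_pct")), row.names = NULL)
}
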