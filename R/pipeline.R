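# Full-analysis orchestration: standardize -> volumes/EF -> reference ->
# distances -> segments -> landmarks -> observer statistics, with tidy CSV /
# JSON outputs.

#' Biplane volumes for every observer-patient of a study
#'
#' @param contours list of observer `standard_contour`s (4 per
#'   observer-patient).
#' @param n_disks number of Simpson disks.
#' @return Data frame, one row per complete observer-patient; incomplete sets
#'   are skipped with a warning.
#' @export
study_volumes <- function(contours, n_disks = 20L) {
  key <- vapply(contours, function(cc)
    paste(cc$patient_id, cc$observer_id, sep = "\r"), character(1))
  out <- lapply(split(contours, key), function(set) {
    vp <- vapply(set, function(cc) paste(cc$view, cc$phase, sep = "_"),
                 character(1))
    names(set) <- vp
    if (!all(c("4CH_ED", "2CH_ED", "4CH_ES", "2CH_ES") %in% vp)) {
      warning(sprintf("observer %s / patient %s: incomplete view/phase set, skipped",
                      set[[1]]$observer_id, set[[1]]$patient_id), call. = FALSE)
      return(NULL)
    }
    cbind(data.frame(patient_id = set[[1]]$patient_id,
                     observer_id = set[[1]]$observer_id),
          volume_result(set, n_disks))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the complete variability analysis
#'
#' Executes the whole pipeline on a study: standardization of all tracings,
#' biplane Simpson volumes and EF, per patient/view/phase reference contours,
#' pointwise signed distances with segmental aggregation, landmark offsets
#' with concentric-area binning, 3D apex registration, and the observer-level
#' group/experience/region statistics.
#'
#' @param study an `lv_study` (from [simulate_study()] or [read_study()]).
#' @param n_disks Simpson disk count (default 20).
#' @param size_threshold_mm small/medium/large classification threshold on
#'   the observer's median signed distance (default 1 mm).
#' @param out_dir optional output directory; when given, writes
#'   `summary_table2.csv`, `landmark_table3.csv`, `observer_profiles.csv`,
#'   `distance_records.csv`, `volumes.csv`, `tests.csv`, `apex_cloud_3d.csv`
#'   and `run_report.json`.
#' @param figures when `TRUE` (and ggplot2 is installed) also writes
#'   figure PNGs under `out_dir/figures/`.
#' @return A list with the standardized contours, reference set, distance
#'   records and summary, formatted distance table, landmark offsets and area
#'   table, volumes, reference EF, observer profiles, test results,
#'   correlations and the run report.
#' @export
run_full_analysis <- function(study, n_disks = 20L, size_threshold_mm = 1.0,
                              out_dir = NULL, figures = FALSE) {
  stopifnot(inherits(study, "lv_study"))
  stage <- "standardization"
  res <- tryCatch({
    contours <- lapply(study$tracings, standardize_contour)

    stage <- "volumes"
    volumes <- study_volumes(contours, n_disks = n_disks)

    stage <- "reference-contours"
    references <- build_reference_set(contours)
    ref_by_pat <- split(references,
                        vapply(references, `[[`, character(1), "patient_id"))
    ref_ef <- vapply(ref_by_pat, function(set) {
      vp <- vapply(set, function(cc) paste(cc$view, cc$phase, sep = "_"),
                   character(1))
      names(set) <- vp
      if (!all(c("4CH_ED", "2CH_ED", "4CH_ES", "2CH_ES") %in% vp)) {
        return(NA_real_)
      }
      volume_result(set, n_disks)$ef_pct
    }, numeric(1))
    reference_ef <- stats::median(ref_ef, na.rm = TRUE)

    stage <- "distances"
    records <- compute_distance_records(contours, references)
    summary <- aggregate_distance_summary(records)
    table2 <- format_distance_table(summary)

    stage <- "landmarks"
    landmark_offsets <- compute_landmark_offsets(contours)
    table3 <- area_bin_table(landmark_offsets)
    apex3d <- apex_cloud_3d(contours, phase = "ED")

    stage <- "observer-statistics"
    profiles <- observer_profiles(records, volumes, reference_ef = reference_ef,
                                  observers = study$observers,
                                  threshold = size_threshold_mm)
    group_ef <- group_ef_comparison(profiles)
    experience <- if (!is.null(profiles$experience_category))
      experience_comparison(profiles) else NULL
    regions <- region_comparison(records)
    correlations <- volume_ef_correlations(observer_median_volumes(volumes))

    list(contours = contours, references = references,
         records = records, summary = summary, table2 = table2,
         landmark_offsets = landmark_offsets, table3 = table3,
         apex3d = apex3d, volumes = volumes,
         reference_ef = reference_ef, profiles = profiles,
         group_ef = group_ef, experience = experience,
         regions = regions, correlations = correlations)
  }, error = function(e) {
    stop(sprintf("analysis failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  res$report <- run_report(study, res, n_disks, size_threshold_mm)
  if (!is.null(out_dir)) write_analysis_outputs(res, out_dir, figures)
  res
}

run_report <- function(study, res, n_disks, size_threshold_mm) {
  tests <- tests_table(res)
  list(
    seed = if (!is.null(study$config)) study$config$seed else NULL,
    n_patients = length(unique(res$volumes$patient_id)),
    n_observers = length(unique(res$volumes$observer_id)),
    n_tracings = length(study$tracings),
    n_missing = if (!is.null(study$missing)) nrow(study$missing) else 0L,
    n_disks = n_disks,
    size_threshold_mm = size_threshold_mm,
    overall_median_distance_mm =
      res$summary$median_mm[res$summary$grouping == "overall" &
                              res$summary$view == "4CH" &
                              res$summary$phase == "ED"][1],
    reference_ef_pct = res$reference_ef,
    mean_biplane_ef_pct = mean(res$volumes$ef_pct),
    tests = tests,
    config = if (!is.null(study$config)) unclass(study$config) else NULL)
}

tests_table <- function(res) {
  rows <- list()
  add <- function(name, statistic, df, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      test = name, statistic = statistic, df = df, p_value = p)
  }
  add("kruskal_wallis_size_group_ef", res$group_ef$ef$statistic,
      res$group_ef$ef$df, res$group_ef$ef$p_value)
  add("kruskal_wallis_size_group_ef_diff", res$group_ef$ef_diff$statistic,
      res$group_ef$ef_diff$df, res$group_ef$ef_diff$p_value)
  if (!is.null(res$experience)) {
    add("kruskal_wallis_experience_ef", res$experience$ef$statistic,
        res$experience$ef$df, res$experience$ef$p_value)
  }
  add("friedman_wall_regions", res$regions$omnibus$statistic,
      res$regions$omnibus$df, res$regions$omnibus$p_value)
  pw <- res$regions$pairwise
  for (i in seq_len(nrow(pw))) {
    add(paste0("friedman_", gsub(" ", "_", pw$comparison[i])),
        pw$statistic[i], pw$df[i], pw$p_value[i])
  }
  do.call(rbind, rows)
}

write_analysis_outputs <- function(res, out_dir, figures = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) utils::write.csv(
    df, file.path(out_dir, name), row.names = FALSE)
  wr(res$table2, "summary_table2.csv")
  wr(res$summary, "distance_summary.csv")
  wr(res$table3, "landmark_table3.csv")
  wr(res$profiles, "observer_profiles.csv")
  wr(res$records, "distance_records.csv")
  wr(res$volumes, "volumes.csv")
  wr(tests_table(res), "tests.csv")
  wr(res$apex3d, "apex_cloud_3d.csv")
  wr(res$correlations, "correlations.csv")
  jsonlite::write_json(res$report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  if (figures && requireNamespace("ggplot2", quietly = TRUE)) {
    fig_dir <- file.path(out_dir, "figures")
    dir.create(fig_dir, showWarnings = FALSE)
    save_fig <- function(p, name) {
      grDevices::png(file.path(fig_dir, name), width = 1400, height = 900,
                     res = 150)
      print(p)
      grDevices::dev.off()
    }
    save_fig(plot_segment_distances(res$summary), "segment_distances.png")
    save_fig(plot_landmark_scatter(res$landmark_offsets), "landmark_scatter.png")
  }
  invisible(out_dir)
}
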