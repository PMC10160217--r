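# File formats. A tracing travels as JSON with fields patient_id,
# observer_id, view ("2CH"/"4CH"), phase ("ED"/"ES"), closed, annulus_a,
# annulus_b and points = list of [x_mm, y_mm]. A study directory holds
# tracings/*.json, observers.csv, optionally truth/*.json (99-point contour
# sidecars) and config.yaml. Readers validate invariants and report the first
# violated one together with the file name.

#' Write / read a single tracing as JSON
#'
#' @param tracing a `raw_tracing`.
#' @param path file path.
#' @return `read_tracing_json()` returns a validated `raw_tracing`; malformed
#'   files raise an error naming the first violated invariant.
#' @export
write_tracing_json <- function(tracing, path) {
  stopifnot(inherits(tracing, "raw_tracing"))
  obj <- list(patient_id = tracing$patient_id,
              observer_id = tracing$observer_id,
              view = tracing$view, phase = tracing$phase,
              closed = tracing$closed,
              annulus_a = tracing$annulus_a,
              annulus_b = tracing$annulus_b,
              points = unname(tracing$points))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tracing_json
#' @export
read_tracing_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("patient_id", "observer_id", "view", "phase", "closed",
            "annulus_a", "annulus_b", "points")
  missing <- setdiff(need, names(obj))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing field(s) %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  tr <- tryCatch(
    raw_tracing(obj$points, view = obj$view, phase = obj$phase,
                annulus_a = obj$annulus_a, annulus_b = obj$annulus_b,
                closed = isTRUE(obj$closed),
                patient_id = obj$patient_id, observer_id = obj$observer_id),
    error = function(e) {
      stop(sprintf("%s: %s", basename(path), conditionMessage(e)),
           call. = FALSE)
    })
  tr
}

#' Write / read a 99-point contour (truth or reference sidecar) as JSON
#'
#' @param contour a `standard_contour`.
#' @param path file path.
#' @export
write_contour_json <- function(contour, path) {
  stopifnot(inherits(contour, "standard_contour"))
  obj <- list(patient_id = contour$patient_id,
              observer_id = contour$observer_id,
              view = contour$view, phase = contour$phase,
              points = unname(contour$points))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contour_json
#' @export
read_contour_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- obj$points
  if (is.null(dim(pts)) || nrow(pts) != 99L) {
    stop(sprintf("%s: a standardized contour must have exactly 99 points, got %s",
                 basename(path),
                 if (is.null(dim(pts))) length(pts) else nrow(pts)),
         call. = FALSE)
  }
  standard_contour(pts, view = obj$view, phase = obj$phase,
                   patient_id = obj$patient_id, observer_id = obj$observer_id)
}

#' Write a study to a directory
#'
#' Creates `tracings/*.json`, `observers.csv`, and (when present in the study
#' object) `truth/*.json` sidecars and `config.yaml` with the full generator
#' configuration including the seed, enabling exact re-runs.
#'
#' @param study an `lv_study` (from [simulate_study()] or [read_study()]).
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(file.path(dir, "tracings"), recursive = TRUE, showWarnings = FALSE)
  for (key in names(study$tracings)) {
    write_tracing_json(study$tracings[[key]],
                       file.path(dir, "tracings", paste0(key, ".json")))
  }
  utils::write.csv(study$observers, file.path(dir, "observers.csv"),
                   row.names = FALSE)
  if (!is.null(study$truth)) {
    dir.create(file.path(dir, "truth"), showWarnings = FALSE)
    for (key in names(study$truth)) {
      write_contour_json(study$truth[[key]],
                         file.path(dir, "truth", paste0(key, ".json")))
    }
  }
  if (!is.null(study$config)) {
    cfg <- unclass(study$config)
    cfg <- lapply(cfg, function(x) if (is.numeric(x)) unclass(x) else x)
    yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' Read a study from a directory
#'
#' Loads and validates every tracing; a missing view/phase for an
#' observer-patient is recorded in the `missing` ledger rather than treated
#' as fatal.
#'
#' @param dir study directory written by [write_study()] (or assembled by
#'   hand in the same layout).
#' @return An `lv_study` with a `missing` data frame listing absent
#'   (patient, observer, view, phase) combinations.
#' @export
read_study <- function(dir) {
  tr_dir <- file.path(dir, "tracings")
  if (!dir.exists(tr_dir)) {
    stop("no tracings/ directory under ", dir, call. = FALSE)
  }
  files <- sort(list.files(tr_dir, pattern = "\\.json$", full.names = TRUE))
  if (length(files) == 0L) {
    stop("no tracing JSON files under ", tr_dir, call. = FALSE)
  }
  tracings <- lapply(files, read_tracing_json)
  names(tracings) <- vapply(tracings, function(tr)
    paste(tr$patient_id, tr$observer_id, tr$view, tr$phase, sep = "_"),
    character(1))

  obs_path <- file.path(dir, "observers.csv")
  observers <- if (file.exists(obs_path)) {
    utils::read.csv(obs_path, stringsAsFactors = FALSE)
  } else {
    data.frame(observer_id = sort(unique(vapply(
      tracings, `[[`, character(1), "observer_id"))))
  }

  truth <- NULL
  truth_dir <- file.path(dir, "truth")
  if (dir.exists(truth_dir)) {
    tf <- sort(list.files(truth_dir, pattern = "\\.json$", full.names = TRUE))
    truth <- lapply(tf, read_contour_json)
    names(truth) <- vapply(truth, function(cc)
      paste(cc$patient_id, cc$view, cc$phase, sep = "_"), character(1))
  }
  config <- NULL
  cfg_path <- file.path(dir, "config.yaml")
  if (file.exists(cfg_path)) config <- yaml::read_yaml(cfg_path)

  pats <- sort(unique(vapply(tracings, `[[`, character(1), "patient_id")))
  obs <- sort(unique(vapply(tracings, `[[`, character(1), "observer_id")))
  grid <- expand.grid(patient_id = pats, observer_id = obs,
                      view = c("2CH", "4CH"), phase = c("ED", "ES"),
                      stringsAsFactors = FALSE)
  key <- with(grid, paste(patient_id, observer_id, view, phase, sep = "_"))
  missing <- grid[!(key %in% names(tracings)), , drop = FALSE]
  rownames(missing) <- NULL

  structure(list(tracings = tracings, observers = observers,
                 patients = data.frame(patient_id = pats),
                 truth = truth, config = config, missing = missing),
            class = "lv_study")
}
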