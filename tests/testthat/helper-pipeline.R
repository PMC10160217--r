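# Lean observer-statistics pipeline used by the simulation-heavy tests:
# standardize -> volumes -> reference -> distances -> profiles, without the
# landmark/region stages.
run_observer_stage <- function(st, n_disks = 20L, threshold = 1.0) {
  contours <- lapply(st$tracings, standardize_contour)
  vols <- study_volumes(contours, n_disks = n_disks)
  recs <- compute_distance_records(contours, build_reference_set(contours))
  prof <- observer_profiles(recs, vols, reference_ef = NA_real_,
                            observers = st$observers, threshold = threshold)
  list(contours = contours, volumes = vols, records = recs, profiles = prof)
}
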