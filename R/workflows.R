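# Umbrella workflows binding the stages into the two headline studies:
# the single-cell trace study and the compound screen. Both are pure
# functions of (configuration, seed); when an output directory is given,
# every intermediate plus the resolved configuration is written there so a
# rerun is bit-reproducible.

#' Run the single-cell trace study end to end
#'
#' Simulates a fate-labelled trace cohort, classifies every trace blind to
#' ground truth, summarizes fate fractions and S/G2(/M) durations, and
#' computes the peak-aligned mean +/- SEM profile of the cycling cells.
#'
#' @param n cohort size (default 570, the size of the tracked-cell study).
#' @param mixture a [fate_mixture()].
#' @param kinetics a [kinetics_params()].
#' @param classifier a [fate_classifier_config()].
#' @param seed top-level seed; all stage substreams derive from it.
#' @param out_dir optional output directory (created if needed): writes
#'   `fate_calls.csv`, `aligned_profile.csv`, `summary.json`,
#'   `run_config.yaml`, and optionally the traces.
#' @param write_traces also write the full trace table (large).
#' @return list: `calls` (data.frame), `summary` ([cohort_summary()]),
#'   `aligned` profile, `truth` (generator ground truth, for evaluation only),
#'   `seed`.
#' @export
run_trace_study <- function(n = 570L, mixture = fate_mixture(),
                            kinetics = kinetics_params(),
                            classifier = fate_classifier_config(),
                            seed = 1L, out_dir = NULL,
                            write_traces = FALSE) {
  cohort <- tryCatch(
    generate_trace_cohort(n, mixture, kinetics, seed = derive_seed(seed, "traces")),
    error = function(e) stop_stage("synthetic_data", conditionMessage(e)))
  calls <- tryCatch(classify_cohort(cohort, classifier),
                    error = function(e) stop_stage("trace_analysis",
                                                   conditionMessage(e)))
  summary <- cohort_summary(calls)
  cycling <- which(calls$fate != "noncycling")
  aligned <- if (length(cycling))
    align_traces(cohort$traces[cycling], classifier) else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(calls, file.path(out_dir, "fate_calls.csv"),
                     row.names = FALSE)
    if (!is.null(aligned))
      utils::write.csv(aligned$profile,
                       file.path(out_dir, "aligned_profile.csv"),
                       row.names = FALSE)
    if (write_traces) write_traces_csv(cohort, file.path(out_dir, "traces.csv"))
    .write_json(list(n = summary$n,
                     fractions_pct = as.list(summary$fractions),
                     durations = summary$durations,
                     seed = seed),
                file.path(out_dir, "summary.json"))
    write_run_config(list(trace_study = list(
      n = n, seed = seed, mixture = as.list(unclass(mixture)),
      kinetics = lapply(unclass(kinetics), function(v)
        if (is.numeric(v) && !is.null(names(v))) as.list(v) else v),
      classifier = unclass(classifier))),
      file.path(out_dir, "run_config.yaml"))
  }
  list(calls = calls, summary = summary, aligned = aligned,
       truth = cohort$truth, seed = seed)
}

#' Run the compound screen study end to end
#'
#' Simulates replicate screening plates, applies site QC, aggregates wells,
#' normalizes to the plate controls, applies treatment QC, selects the
#' lowest-CV timepoint, and ranks the retained compounds.
#'
#' @param spec a [plate_spec()] (see [default_plate_spec()]).
#' @param seed top-level seed.
#' @param selection_timepoints timepoints eligible for CV-based selection
#'   (default: all post-baseline acquisitions).
#' @param out_dir optional output directory: writes `sites.csv`, `wells.csv`,
#'   `compound_summary.csv`, `ranked_hits.csv`, `exclusions.csv`,
#'   `cv_table.csv`, `summary.json`, `run_config.yaml`.
#' @return list: `sites`, `wells`, `result` (treatment summary), `ranked`,
#'   `site_exclusions`, `selection`, `plate_map`, `truth`, `seed`.
#' @export
run_screen_study <- function(spec = default_plate_spec(), seed = 1L,
                             selection_timepoints = NULL, out_dir = NULL) {
  plate <- tryCatch(generate_plate(spec, seed = seed),
                    error = function(e) stop_stage("synthetic_data",
                                                   conditionMessage(e)))
  qc <- tryCatch(site_qc(plate$sites),
                 error = function(e) stop_stage("site_qc", conditionMessage(e)))
  wells <- tryCatch(
    normalize_to_control(aggregate_wells(qc$retained), plate$plate_map),
    error = function(e) stop_stage("screen_pipeline", conditionMessage(e)))
  result <- treatment_qc(wells)
  if (is.null(selection_timepoints)) {
    # drop the baseline acquisition when later timepoints can stand alone
    selection_timepoints <- setdiff(unique(wells$timepoint_h),
                                    min(wells$timepoint_h))
    if (length(selection_timepoints) < 2)
      selection_timepoints <- unique(wells$timepoint_h)
  }
  selection <- select_timepoint(wells, timepoints = selection_timepoints)
  ranked <- rank_hits(result, selection$timepoint_h)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(plate$sites, file.path(out_dir, "sites.csv"),
                     row.names = FALSE)
    utils::write.csv(wells, file.path(out_dir, "wells.csv"), row.names = FALSE)
    utils::write.csv(result, file.path(out_dir, "compound_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(ranked, file.path(out_dir, "ranked_hits.csv"),
                     row.names = FALSE)
    utils::write.csv(qc$exclusions, file.path(out_dir, "exclusions.csv"),
                     row.names = FALSE)
    utils::write.csv(selection$cv_table, file.path(out_dir, "cv_table.csv"),
                     row.names = FALSE)
    .write_json(list(selected_timepoint_h = selection$timepoint_h,
                     n_sites = nrow(plate$sites),
                     n_sites_excluded = nrow(qc$exclusions),
                     n_compounds_retained = nrow(ranked),
                     top_hit = ranked$compound_id[1], seed = seed),
                file.path(out_dir, "summary.json"))
    write_run_config(list(screen_study = list(
      seed = seed, n_plates = spec$n_plates,
      site_dropout_prob = spec$site_dropout_prob,
      mean_nuclei_per_site = spec$mean_nuclei_per_site,
      timepoints_h = spec$timepoints_h)),
      file.path(out_dir, "run_config.yaml"))
  }
  list(sites = plate$sites, wells = wells, result = result, ranked = ranked,
       site_exclusions = qc$exclusions, selection = selection,
       plate_map = plate$plate_map, truth = plate$truth, seed = seed)
}
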