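#' Run a complete vascular experiment: simulate, fit, infer, report
#'
#' Chains cohort simulation, (optionally) per-trace gamma-variate fitting,
#' reactivity summaries, and per-type plus pooled Deming flow-change
#' estimation, and returns a structured report with ground-truth
#' comparison and full provenance.
#'
#' @param cohorts named list of [bolus_cohort_config()]s, one per cohort
#'   (names act as genotype labels).
#' @param fit_traces if `TRUE`, traces are rendered and TTPs come from
#'   gamma-variate fits; if `FALSE` (default) the generator's measured
#'   TTPs (latent value + measurement noise) are used directly.
#' @param n_boot bootstrap draws for each flow-change CI.
#' @param seed global seed; cohort c gets `seed + c` unless its config
#'   carries its own.
#' @param out_dir optional directory; when given, the report is written as
#'   `vascular_report.json` and the vessel table as `vessels.csv`.
#' @return list of class `vascular_report`: `reactivity` (Table-1-style
#'   mean +/- SEM by genotype x vessel type), `flow` (Table-2-style flow
#'   change by genotype x vessel type with bootstrap CIs), `truth`
#'   comparison, `records`, `provenance`.
#' @export
run_vascular_experiment <- function(cohorts, fit_traces = FALSE,
                                    n_boot = 2000, seed = 1L,
                                    out_dir = NULL) {
  if (is.null(names(cohorts)) || any(!nzchar(names(cohorts))))
    stop("cohorts must be a named list of configs")
  records <- NULL
  truth_cmp <- list()
  for (ci in seq_along(cohorts)) {
    g <- names(cohorts)[ci]
    cfg <- cohorts[[ci]]
    stopifnot(inherits(cfg, "bolus_cohort_config"))
    cfg$seed <- if (is.null(cfg$seed)) seed + ci else cfg$seed
    cohort <- generate_bolus_cohort(cfg, traces = fit_traces)
    if (fit_traces) {
      tab <- fit_bolus_cohort(cohort, genotype = g)
    } else {
      tab <- cohort$truth[, c("vessel_id", "animal_id", "vessel_type",
                              "ttp_normo", "ttp_hyper")]
      tab$reactivity <- vascular_reactivity(tab$ttp_normo, tab$ttp_hyper)
      tab$genotype <- g
    }
    records <- rbind(records, tab)
    truth_cmp[[g]] <- list(
      flow_change_true = cfg$flow_change_true,
      reactivity_true_by_type = as.list(cfg$reactivity_true_by_type))
  }

  react <- group_summary(records)
  types <- unique(records$vessel_type)
  flow <- list()
  for (g in names(cohorts)) {
    rg <- records[records$genotype == g, , drop = FALSE]
    cells <- c(list(ALL = NULL), stats::setNames(as.list(types), types))
    for (nm in names(cells)) {
      f <- tryCatch(
        network_flow_change(rg, vessel_filter = cells[[nm]],
                            n_boot = n_boot,
                            seed = seed + 1000L + length(flow)),
        error = function(e) NULL)
      if (is.null(f)) next
      flow[[length(flow) + 1L]] <- data.frame(
        genotype = g, vessel_type = nm, n = f$n, slope = f$slope,
        flow_change = f$flow_change, ci_low = f$ci_low, ci_high = f$ci_high,
        stringsAsFactors = FALSE)
    }
  }
  flow <- do.call(rbind, flow)

  report <- structure(list(
    reactivity = react, flow = flow, truth = truth_cmp, records = records,
    provenance = list(seed = seed, fit_traces = fit_traces, n_boot = n_boot,
                      cohort_configs = lapply(cohorts, unclass),
                      package_version =
                        as.character(utils::packageVersion("neurovasc")))),
    class = "vascular_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_json(report, file.path(out_dir, "vascular_report.json"))
    utils::write.csv(records, file.path(out_dir, "vessels.csv"),
                     row.names = FALSE)
  }
  report
}

#' Run a complete coupling experiment: simulate LFPs, comodulograms, summary
#'
#' @param groups named list; each element a list with `coupling_depth`,
#'   `n_electrodes`, and optionally any [pac_signal_config()] override
#'   (e.g. `duration`, `sampling_rate`, `theta_freq`).
#' @param grid a [band_grid()].
#' @param n_surrogates,alpha,correction passed to [comodulogram()].
#' @param min_duration minimum analysis window, seconds.
#' @param seed global seed; electrode e of group g gets a derived seed.
#' @param out_dir optional directory for `pac_report.json`.
#' @return list of class `pac_report`: `summary` (group mean +/- SEM of
#'   electrode-level mean z), `comodulograms`, `provenance`.
#' @export
run_pac_experiment <- function(groups, grid = band_grid(),
                               n_surrogates = 50, alpha = 0.05,
                               correction = "gamma", min_duration = 120,
                               seed = 1L, out_dir = NULL) {
  if (is.null(names(groups))) stop("groups must be named")
  comods <- list()
  labels <- character(0)
  for (gi in seq_along(groups)) {
    g <- names(groups)[gi]
    gspec <- groups[[gi]]
    n_el <- gspec$n_electrodes %||% 4L
    ov <- gspec[setdiff(names(gspec), "n_electrodes")]
    for (e in seq_len(n_el)) {
      el_seed <- seed + 100000L * gi + 1000L * e
      cfg <- do.call(pac_signal_config, c(ov, list(seed = el_seed)))
      sig <- generate_pac_signal(cfg, channel_id = sprintf("%s_e%02d", g, e),
                                 genotype = g)
      rec <- sig$recording
      if (rec$sampling_rate > 1000) rec <- preprocess_lfp(rec)
      cm <- comodulogram(rec, grid = grid, n_surrogates = n_surrogates,
                         alpha = alpha, seed = el_seed + 1L,
                         correction = correction,
                         min_duration = min_duration)
      comods[[length(comods) + 1L]] <- cm
      labels <- c(labels, g)
    }
  }
  summ <- cohort_mi_summary(comods, groups = labels)
  report <- structure(list(
    summary = summ, comodulograms = comods,
    provenance = list(seed = seed, n_surrogates = n_surrogates,
                      alpha = alpha, correction = correction,
                      groups = groups,
                      package_version =
                        as.character(utils::packageVersion("neurovasc")))),
    class = "pac_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_json(report, file.path(out_dir, "pac_report.json"))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
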