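#' Configuration for a synthetic bolus-tracking cohort
#'
#' Defines the generative model of paired normocapnia/hypercapnia bolus
#' passages whose time-to-peak (TTP) dispersion contracts by a controllable
#' flow factor. For vessel i of type v:
#' \deqn{TTP_{normo,i} = \mu_v + \delta_i, \quad
#'       TTP_{hyper,i} = (1 - R_v/100)\,\mu_v + \delta_i/k + \epsilon_i}
#' with \eqn{k = 1 + F/100}, \eqn{\delta_i} a zero-mean deviation with the
#' per-type SD, and \eqn{\epsilon_i} small TTP measurement noise. The Deming
#' slope of hyper on normo TTP deviations is then \eqn{1/k}, so the
#' downstream flow estimator targets \eqn{F}.
#'
#' @param n_vessels_per_type named count per vessel type
#'   (arteriole/capillary/venule). Defaults give a 147-vessel cohort.
#' @param mean_ttp_by_type named mean TTP per type, seconds (arterioles
#'   earlier than venules).
#' @param ttp_sd_by_type named between-vessel TTP SD per type, seconds.
#' @param flow_change_true true network flow change F, percent.
#' @param reactivity_true_by_type named true reactivity per type, percent.
#' @param ttp_noise_sd SD of the TTP measurement noise epsilon, seconds.
#' @param line_period line-scan period, seconds (20 ms/line).
#' @param scan_duration scan length, seconds (line scans last 11-13 s).
#' @param noise_sd additive white fluorescence noise SD, a.u.
#' @param baseline,amplitude baseline and peak-above-baseline of each
#'   trace, a.u.
#' @param alpha_shape gamma-variate shape used for every generated trace.
#' @param t0_fraction onset time as a fraction of each vessel's TTP.
#' @param n_animals number of animals vessels are allocated to (for the
#'   hierarchical bootstrap downstream).
#' @param seed integer seed; fixed seed gives bit-identical cohorts.
#' @return an object of class `bolus_cohort_config`.
#' @export
bolus_cohort_config <- function(
    n_vessels_per_type = c(arteriole = 49, capillary = 49, venule = 49),
    mean_ttp_by_type = c(arteriole = 3, capillary = 4, venule = 5),
    ttp_sd_by_type = c(arteriole = 0.8, capillary = 1.0, venule = 1.0),
    flow_change_true = 74,
    reactivity_true_by_type = c(arteriole = 15, capillary = 13, venule = 15),
    ttp_noise_sd = 0.05,
    line_period = 0.020,
    scan_duration = 13,
    noise_sd = 5,
    baseline = 20,
    amplitude = 100,
    alpha_shape = 3,
    t0_fraction = 0.5,
    n_animals = 9,
    seed = 1L) {
  types <- c("arteriole", "capillary", "venule")
  for (nm in c("n_vessels_per_type", "mean_ttp_by_type", "ttp_sd_by_type",
               "reactivity_true_by_type")) {
    v <- get(nm)
    if (!all(types %in% names(v)))
      stop(nm, " must be named with arteriole/capillary/venule")
  }
  if (any(ttp_sd_by_type < 0) || ttp_noise_sd < 0 || noise_sd < 0)
    stop("all SDs must be non-negative")
  if (line_period <= 0) stop("line_period must be positive")
  if (flow_change_true <= -100) stop("flow_change_true must exceed -100")
  if (t0_fraction <= 0 || t0_fraction >= 1) stop("t0_fraction must be in (0,1)")
  cfg <- list(n_vessels_per_type = n_vessels_per_type[types],
              mean_ttp_by_type = mean_ttp_by_type[types],
              ttp_sd_by_type = ttp_sd_by_type[types],
              flow_change_true = flow_change_true,
              reactivity_true_by_type = reactivity_true_by_type[types],
              ttp_noise_sd = ttp_noise_sd,
              line_period = line_period, scan_duration = scan_duration,
              noise_sd = noise_sd, baseline = baseline, amplitude = amplitude,
              alpha_shape = alpha_shape, t0_fraction = t0_fraction,
              n_animals = n_animals, seed = as.integer(seed))
  class(cfg) <- "bolus_cohort_config"
  cfg
}

# zero-mean normal deviates truncated at +/- 3 SD, so every realized TTP
# stays inside the feasible scan window by construction
.rnorm_trunc3 <- function(n, sd) {
  if (sd == 0) return(rep(0, n))
  x <- stats::rnorm(n, 0, sd)
  while (any(bad <- abs(x) > 3 * sd))
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
  x
}

#' Generate a synthetic bolus-tracking cohort with known ground truth
#'
#' Draws paired normocapnic/hypercapnic TTPs under the generative model of
#' [bolus_cohort_config()] and, optionally, renders each passage as a
#' gamma-variate fluorescence trace with additive white noise. The onset
#' and scale of each curve are chosen so the analytic peak `t0 + alpha*beta`
#' equals the vessel's latent TTP exactly.
#'
#' @param cfg a [bolus_cohort_config()].
#' @param traces if `TRUE` (default) per-vessel [bolus_trace()] objects are
#'   rendered for both conditions; `FALSE` returns only the TTP-level
#'   ground truth (cheap, for large Monte Carlo runs).
#' @return an object of class `bolus_cohort`: list with `truth` (one row
#'   per vessel holding every latent value: type, animal, delta, both TTPs
#'   with and without measurement noise, true reactivity) and `traces`
#'   (named list of trace pairs, or `NULL`).
#' @export
generate_bolus_cohort <- function(cfg, traces = TRUE) {
  stopifnot(inherits(cfg, "bolus_cohort_config"))
  set.seed(cfg$seed)
  types <- names(cfg$n_vessels_per_type)
  k <- 1 + cfg$flow_change_true / 100

  rows <- lapply(types, function(v) {
    n <- cfg$n_vessels_per_type[[v]]
    if (n == 0) return(NULL)
    mu <- cfg$mean_ttp_by_type[[v]]
    delta <- .rnorm_trunc3(n, cfg$ttp_sd_by_type[[v]])
    eps <- stats::rnorm(n, 0, cfg$ttp_noise_sd)
    ttp_n <- mu + delta
    ttp_h_clean <- (1 - cfg$reactivity_true_by_type[[v]] / 100) * mu + delta / k
    ttp_h <- ttp_h_clean + eps
    data.frame(vessel_type = v, ttp_normo = ttp_n, ttp_hyper = ttp_h,
               ttp_hyper_clean = ttp_h_clean, delta = delta, eps = eps,
               mu = mu, stringsAsFactors = FALSE)
  })
  truth <- do.call(rbind, rows)
  n_tot <- nrow(truth)
  truth$vessel_id <- sprintf("v%03d", seq_len(n_tot))
  truth$animal_id <- sprintf("a%02d",
                             sample(rep_len(seq_len(cfg$n_animals), n_tot)))
  truth$reactivity_true <-
    unname(cfg$reactivity_true_by_type[truth$vessel_type])
  truth <- truth[, c("vessel_id", "animal_id", "vessel_type", "mu", "delta",
                     "eps", "ttp_normo", "ttp_hyper", "ttp_hyper_clean",
                     "reactivity_true")]

  feas <- function(ttp) {
    beta <- ttp * (1 - cfg$t0_fraction) / cfg$alpha_shape
    all(ttp > 0) && all(ttp + 3 * beta <= cfg$scan_duration)
  }
  if (!feas(truth$ttp_normo) || !feas(pmax(truth$ttp_hyper, 1e-9)))
    stop("infeasible config: a realized TTP (+3 beta margin) falls outside ",
         "the scan window; shorten TTP means/SDs or lengthen scan_duration")

  trace_list <- NULL
  if (traces) {
    tgrid <- seq(0, cfg$scan_duration, by = cfg$line_period)
    render <- function(ttp, id, vtype, cond) {
      t0 <- cfg$t0_fraction * ttp
      beta <- (ttp - t0) / cfg$alpha_shape
      y <- gamma_variate(tgrid, t0, cfg$alpha_shape, beta,
                         cfg$amplitude, cfg$baseline)
      if (cfg$noise_sd > 0)
        y <- y + stats::rnorm(length(y), 0, cfg$noise_sd)
      bolus_trace(tgrid, y, vessel_id = id, vessel_type = vtype,
                  condition = cond)
    }
    trace_list <- vector("list", n_tot)
    names(trace_list) <- truth$vessel_id
    for (i in seq_len(n_tot)) {
      trace_list[[i]] <- list(
        normocapnia = render(truth$ttp_normo[i], truth$vessel_id[i],
                             truth$vessel_type[i], "normocapnia"),
        hypercapnia = render(truth$ttp_hyper[i], truth$vessel_id[i],
                             truth$vessel_type[i], "hypercapnia"))
    }
  }
  structure(list(truth = truth, traces = trace_list, config = cfg),
            class = "bolus_cohort")
}

#' Fit every trace of a cohort and tabulate per-vessel TTPs
#'
#' Runs [fit_gamma_variate()] on both conditions of every vessel and returns
#' a vessel table ready for [network_flow_change()] and [group_summary()].
#' Non-converged fits are dropped with a message.
#'
#' @param cohort a `bolus_cohort` with rendered traces, or any named list of
#'   `list(normocapnia=, hypercapnia=)` trace pairs.
#' @param genotype optional genotype label attached to every row.
#' @param ... passed to [fit_gamma_variate()].
#' @return data.frame with vessel metadata, fitted `ttp_normo`/`ttp_hyper`
#'   and `reactivity` (percent).
#' @export
fit_bolus_cohort <- function(cohort, genotype = NA_character_, ...) {
  if (inherits(cohort, "bolus_cohort")) {
    if (is.null(cohort$traces))
      stop("cohort was generated without traces")
    pairs <- cohort$traces
    meta <- cohort$truth
  } else {
    pairs <- cohort
    meta <- NULL
  }
  res <- lapply(names(pairs), function(id) {
    fn <- fit_gamma_variate(pairs[[id]]$normocapnia, ...)
    fh <- fit_gamma_variate(pairs[[id]]$hypercapnia, ...)
    data.frame(vessel_id = id,
               ttp_normo = fn$ttp, ttp_hyper = fh$ttp,
               converged = fn$converged && fh$converged,
               rmse_normo = fn$rmse, rmse_hyper = fh$rmse,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  n_bad <- sum(!tab$converged)
  if (n_bad > 0)
    message(n_bad, " vessel(s) dropped: non-converged gamma-variate fit")
  tab <- tab[tab$converged, ]
  if (!is.null(meta)) {
    tab <- merge(meta[, c("vessel_id", "animal_id", "vessel_type")], tab,
                 by = "vessel_id")
  }
  tab$reactivity <- vascular_reactivity(tab$ttp_normo, tab$ttp_hyper)
  tab$genotype <- genotype
  tab
}
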