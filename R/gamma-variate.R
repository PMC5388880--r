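#' Peak-normalized gamma-variate bolus curve
#'
#' The classic model of an intravascular indicator bolus,
#' \eqn{F(t) = b + A \, ((t-t_0)/(\alpha\beta))^{\alpha}
#' \exp(\alpha - (t-t_0)/\beta)} for \eqn{t > t_0} and \eqn{b} otherwise.
#' The curve is normalized so that `amplitude` is the peak height above
#' baseline; the peak occurs at \eqn{t_0 + \alpha\beta}.
#'
#' @param t time points (seconds).
#' @param t0 onset time (seconds, >= 0).
#' @param alpha shape parameter (> 0, dimensionless).
#' @param beta scale parameter (seconds, > 0).
#' @param amplitude peak height above baseline (a.u.).
#' @param baseline baseline fluorescence (a.u.).
#' @return numeric vector of fluorescence values.
#' @export
gamma_variate <- function(t, t0, alpha, beta, amplitude = 1, baseline = 0) {
  stopifnot(alpha > 0, beta > 0)
  dt <- t - t0
  y <- rep(baseline, length(t))
  pos <- which(dt > 0)
  if (length(pos)) {
    r <- dt[pos] / (alpha * beta)
    y[pos] <- baseline + amplitude * exp(alpha * (log(r) + 1 - r))
  }
  y
}

#' Construct a bolus-passage trace
#'
#' A trace is one vessel's fluorescence-versus-time record under one capnia
#' condition, on a uniform time grid starting at the injection trigger.
#'
#' @param time time points, seconds from the injection trigger; strictly
#'   increasing and uniformly spaced, at least 50 samples.
#' @param fluorescence fluorescence values (a.u.), finite.
#' @param vessel_id,vessel_type,condition optional metadata;
#'   `vessel_type` one of `"arteriole"`, `"venule"`, `"capillary"`,
#'   `condition` one of `"normocapnia"`, `"hypercapnia"`.
#' @return a `data.frame` of class `bolus_trace` with columns `time` and
#'   `fluorescence` and metadata stored as attributes.
#' @export
bolus_trace <- function(time, fluorescence, vessel_id = NA_character_,
                        vessel_type = NA_character_, condition = NA_character_) {
  if (length(time) < 50L)
    stop("a bolus trace needs at least 50 samples")
  if (!all(is.finite(time)) || !all(is.finite(fluorescence)))
    stop("non-finite samples in bolus trace")
  if (length(fluorescence) != length(time))
    stop("time and fluorescence lengths differ")
  dt <- diff(time)
  if (any(dt <= 0))
    stop("time must be strictly increasing")
  if (diff(range(dt)) > 1e-6 * mean(dt))
    stop("time grid must be uniform")
  out <- data.frame(time = as.numeric(time),
                    fluorescence = as.numeric(fluorescence))
  attr(out, "vessel_id") <- vessel_id
  attr(out, "vessel_type") <- vessel_type
  attr(out, "condition") <- condition
  class(out) <- c("bolus_trace", "data.frame")
  out
}

# moving-average smoothing, used for initialization only (never for fitting)
.smooth_ma <- function(x, window = 5L) {
  k <- rep(1 / window, window)
  as.numeric(stats::filter(x, k, sides = 2)) -> s
  # fill ends with original values where the window is incomplete
  s[is.na(s)] <- x[is.na(s)]
  s
}

.gv_sse <- function(par, t, y) {
  sum((gamma_variate(t, par[3], par[4], par[5], par[2], par[1]) - y)^2)
}

#' Fit the gamma-variate model to a bolus trace
#'
#' Bounded nonlinear least squares of the gamma-variate bolus model.
#' Initialization is data-driven: the baseline starts at the median of the
#' pre-rise samples, the onset at the first time the smoothed trace exceeds
#' baseline + 3 pre-rise SD, the shape at 2, and the scale from the smoothed
#' peak location. Smoothing (5-sample moving average) is used only to pick
#' starting values. Traces with no suprathreshold rise yield a
#' non-converged result rather than an error, flagging an unusable vessel.
#'
#' @param trace a [bolus_trace()] (or data.frame with `time` and
#'   `fluorescence` columns).
#' @param truncate_recirculation if `TRUE`, the fit window is truncated at
#'   the first post-peak local minimum of the smoothed trace, discarding a
#'   possible second (recirculation) passage of the dye.
#' @return an object of class `gamma_variate_fit`: a list with entries
#'   `baseline`, `amplitude`, `t0`, `alpha`, `beta`, `ttp` (= t0 + alpha*beta),
#'   `rmse`, `converged`, and the metadata of the input trace.
#' @export
fit_gamma_variate <- function(trace, truncate_recirculation = FALSE) {
  if (!all(c("time", "fluorescence") %in% names(trace)))
    stop("trace must have time and fluorescence columns")
  t <- trace$time
  y <- trace$fluorescence
  if (!all(is.finite(t)) || !all(is.finite(y)))
    stop("non-finite samples in bolus trace")
  meta <- list(vessel_id = attr(trace, "vessel_id"),
               vessel_type = attr(trace, "vessel_type"),
               condition = attr(trace, "condition"))

  bad <- function() {
    structure(c(list(baseline = NA_real_, amplitude = NA_real_, t0 = NA_real_,
                     alpha = NA_real_, beta = NA_real_, ttp = NA_real_,
                     rmse = NA_real_, converged = FALSE), meta),
              class = "gamma_variate_fit")
  }

  n <- length(t)
  s <- .smooth_ma(y)
  # provisional pre-rise region: start at 10% of the trace and shrink if
  # the window already contains the rise (early-onset boluses)
  i_rise <- NULL
  for (n_pre in unique(pmax(5L, c(floor(0.1 * n), floor(0.04 * n), 10L)))) {
    b_pre <- stats::median(y[seq_len(n_pre)])
    sd_pre <- stats::sd(y[seq_len(n_pre)])
    if (!is.finite(sd_pre)) sd_pre <- 0
    thr <- b_pre + 3 * sd_pre
    rise <- if (sd_pre == 0)
      which(s > b_pre + 1e-12 * max(1, abs(b_pre))) else which(s > thr)
    if (length(rise)) { i_rise <- rise[1]; break }
  }
  if (is.null(i_rise)) return(bad())  # flat trace: no suprathreshold rise
  # refine pre-rise estimates from everything before the detected onset
  if (i_rise > 5L) {
    b_pre <- stats::median(y[seq_len(i_rise - 1L)])
    sd_pre <- stats::sd(y[seq_len(i_rise - 1L)])
  }
  i_peak <- which.max(s)
  if (i_peak <= i_rise) i_peak <- min(n, i_rise + 1L)
  a0 <- s[i_peak] - b_pre
  if (a0 <= 0) return(bad())

  fit_end <- n
  if (truncate_recirculation && i_peak < n - 2L) {
    post <- s[(i_peak + 1L):n]
    dmin <- which(diff(sign(diff(post))) > 0)
    if (length(dmin)) fit_end <- i_peak + dmin[1] + 1L
  }
  tt <- t[seq_len(fit_end)]
  yy <- y[seq_len(fit_end)]

  t_peak <- t[i_peak]
  t0_init <- max(t[1], min(t[max(1L, i_rise - 1L)], t_peak - 1e-3))
  alpha0 <- 2
  beta0 <- max(0.02, (t_peak - t0_init) / alpha0)
  scan_dur <- diff(range(t))

  lower <- c(b = -Inf, A = 0, t0 = max(0, t[1]), alpha = 0.1, beta = 0.01)
  upper <- c(b = Inf, A = Inf, t0 = t_peak, alpha = 20, beta = scan_dur)
  start <- list(b = b_pre, A = a0, t0 = t0_init, alpha = alpha0, beta = beta0)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      yy ~ gamma_variate(tt, t0, alpha, beta, A, b),
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12)),
    error = function(e) NULL)

  if (!is.null(fit)) {
    p <- stats::coef(fit)
    conv <- TRUE
  } else {
    # fall back to bounded quasi-Newton on the sum of squares
    op <- stats::optim(unlist(start), .gv_sse, t = tt, y = yy,
                       method = "L-BFGS-B", lower = lower, upper = upper,
                       control = list(maxit = 500, factr = 1e4))
    p <- op$par
    conv <- op$convergence == 0
  }
  names(p) <- c("b", "A", "t0", "alpha", "beta")
  pred <- gamma_variate(tt, p["t0"], p["alpha"], p["beta"], p["A"], p["b"])
  rmse <- sqrt(mean((pred - yy)^2))
  ttp <- unname(p["t0"] + p["alpha"] * p["beta"])
  if (ttp > max(t) || p["A"] <= 0) conv <- FALSE
  structure(c(list(baseline = unname(p["b"]), amplitude = unname(p["A"]),
                   t0 = unname(p["t0"]), alpha = unname(p["alpha"]),
                   beta = unname(p["beta"]), ttp = ttp, rmse = rmse,
                   converged = conv), meta),
            class = "gamma_variate_fit")
}

#' @export
print.gamma_variate_fit <- function(x, ...) {
  cat("Gamma-variate bolus fit",
      if (!x$converged) "(NOT converged)" else "", "\n")
  cat(sprintf("  ttp = %.4f s (t0 = %.3f, alpha = %.3f, beta = %.3f)\n",
              x$ttp, x$t0, x$alpha, x$beta))
  cat(sprintf("  baseline = %.3f, amplitude = %.3f, rmse = %.4g\n",
              x$baseline, x$amplitude, x$rmse))
  invisible(x)
}

#' Cerebrovascular reactivity from paired time-to-peak values
#'
#' Reactivity is the percent shortening of the bolus time-to-peak under
#' hypercapnia relative to normocapnia,
#' \eqn{100 (TTP_{normo} - TTP_{hyper}) / TTP_{normo}}. Positive values mean
#' faster bolus arrival during the CO2 challenge (flow increase).
#'
#' @param ttp_normo time-to-peak during normocapnia (seconds, > 0).
#' @param ttp_hyper time-to-peak during hypercapnia (seconds).
#' @return reactivity in percent. Vectorized.
#' @export
vascular_reactivity <- function(ttp_normo, ttp_hyper) {
  if (any(!is.finite(ttp_normo)) || any(!is.finite(ttp_hyper)))
    stop("TTP values must be finite")
  if (any(ttp_normo <= 0))
    stop("normocapnic TTP must be positive")
  100 * (ttp_normo - ttp_hyper) / ttp_normo
}

#' Classify a vessel as capillary by apparent diameter
#'
#' Vessels under 10 micrometers in apparent diameter are deemed capillaries
#' (strict inequality; a 10-micrometer vessel is not a capillary).
#'
#' @param apparent_diameter apparent diameter in micrometers (> 0).
#' @return character vector, `"capillary"` or `"non_capillary"`.
#' @export
classify_capillary <- function(apparent_diameter) {
  if (any(!is.finite(apparent_diameter)) || any(apparent_diameter <= 0))
    stop("diameter must be positive and finite")
  ifelse(apparent_diameter < 10, "capillary", "non_capillary")
}
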