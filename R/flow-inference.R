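#' Deming (errors-in-variables) regression, closed form
#'
#' Fits y = intercept + slope * x allowing measurement error in both
#' variables. With sample (co)variances \eqn{s_{xx}, s_{yy}, s_{xy}} and
#' error-variance ratio \eqn{\lambda},
#' \deqn{slope = \frac{s_{yy} - \lambda s_{xx} +
#'   \sqrt{(s_{yy} - \lambda s_{xx})^2 + 4 \lambda s_{xy}^2}}{2 s_{xy}}.}
#' \eqn{\lambda = 1} gives orthogonal regression (minimizing summed squared
#' perpendicular distances), the setting used to compare hypercapnic
#' against normocapnic transit times.
#'
#' @param x,y equal-length paired samples, n >= 3, finite.
#' @param lambda error-variance ratio var(err_y)/var(err_x); default 1.
#' @return object of class `deming_fit` with `slope`, `intercept`,
#'   `lambda`, `n`.
#' @export
deming_fit <- function(x, y, lambda = 1) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("Deming regression needs n >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite input")
  if (lambda <= 0) stop("lambda must be positive")
  sxx <- stats::var(x)
  syy <- stats::var(y)
  sxy <- stats::cov(x, y)
  if (sxy == 0) {
    if (isTRUE(all.equal(syy, lambda * sxx)))
      stop("degenerate cloud: regression direction undefined")
    stop("zero covariance: Deming slope undefined")
  }
  d <- syy - lambda * sxx
  slope <- (d + sqrt(d^2 + 4 * lambda * sxy^2)) / (2 * sxy)
  structure(list(slope = slope,
                 intercept = mean(y) - slope * mean(x),
                 lambda = lambda, n = length(x)),
            class = "deming_fit")
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf("Deming regression (lambda = %g, n = %d)\n", x$lambda, x$n))
  cat(sprintf("  slope = %.6g, intercept = %.6g\n", x$slope, x$intercept))
  if (!is.null(x$flow_change))
    cat(sprintf("  flow change = %.3g%% [%.3g, %.3g]\n",
                x$flow_change, x$ci_low, x$ci_high))
  invisible(x)
}

#' Flow change implied by a TTP-dispersion slope
#'
#' A Deming slope below 1 means hypercapnia compressed the dispersion of
#' transit times; the network flow change is the inverse of the slope,
#' expressed as percent: \eqn{100 (1/slope - 1)}.
#'
#' @param slope Deming slope of hypercapnic on normocapnic TTP.
#' @return flow change in percent; `NA` with a warning for slope <= 0.
#' @export
flow_change_from_slope <- function(slope) {
  out <- 100 * (1 / slope - 1)
  if (any(bad <- !is.na(slope) & slope <= 0)) {
    warning("non-positive slope: flow change undefined")
    out[bad] <- NA_real_
  }
  out
}

.center_pair <- function(x, y, type, center) {
  if (center == "by_type" && !is.null(type) && length(unique(type)) > 1) {
    for (v in unique(type)) {
      i <- type == v
      x[i] <- x[i] - mean(x[i])
      y[i] <- y[i] - mean(y[i])
    }
  } else {
    x <- x - mean(x)
    y <- y - mean(y)
  }
  list(x = x, y = y)
}

.flow_point <- function(xs, ys, type, lambda, center) {
  ct <- .center_pair(xs, ys, type, center)
  f <- deming_fit(ct$x, ct$y, lambda = lambda)
  if (f$slope <= 0) return(NA_real_)
  100 * (1 / f$slope - 1)
}

#' Network flow change from paired transit times
#'
#' Mean-centers the paired normocapnic/hypercapnic TTPs, fits orthogonal
#' (Deming, lambda = 1) regression, and reports the flow change
#' `100*(1/slope - 1)` with a percentile bootstrap confidence interval.
#' The bootstrap is hierarchical when several animals are present (resample
#' animals with replacement, then vessels within each sampled animal),
#' falling back to plain vessel resampling otherwise.
#'
#' Centering: the Deming slope is invariant to a common shift of all
#' points, so global centering (`center = "global"`) is purely cosmetic.
#' When several vessel types with different mean TTPs are pooled,
#' `center = "by_type"` (the default) removes each type's own mean first;
#' the slope then measures the within-network compression of transit-time
#' dispersion and is not diluted by the reactivity-scaled between-type mean
#' structure. Per-type fits (via `vessel_filter`) are identical under both.
#'
#' @param records data.frame with columns `ttp_normo`, `ttp_hyper` and
#'   optionally `vessel_type`, `animal_id`.
#' @param vessel_filter optional character vector of vessel types to keep
#'   (`NULL` = all vessels pooled).
#' @param lambda error-variance ratio, default 1 (orthogonal).
#' @param n_boot bootstrap draws (default 2000).
#' @param seed optional integer seed for the bootstrap.
#' @param conf_level confidence level for the percentile interval.
#' @param center `"by_type"` (default) or `"global"`.
#' @return `deming_fit` object extended with `flow_change`, `ci_low`,
#'   `ci_high`, `n_boot`, `degenerate` flag.
#' @export
network_flow_change <- function(records, vessel_filter = NULL, lambda = 1,
                                n_boot = 2000, seed = NULL,
                                conf_level = 0.95,
                                center = c("by_type", "global")) {
  center <- match.arg(center)
  if (!is.null(vessel_filter))
    records <- records[records$vessel_type %in% vessel_filter, , drop = FALSE]
  if (nrow(records) < 3)
    stop("need at least 3 vessels after filtering")
  x <- records$ttp_normo
  y <- records$ttp_hyper
  vtype <- records$vessel_type
  ct <- .center_pair(x, y, vtype, center)
  fit <- deming_fit(ct$x, ct$y, lambda = lambda)
  fit$degenerate <- fit$slope <= 0
  fit$flow_change <- if (fit$degenerate) NA_real_ else
    100 * (1 / fit$slope - 1)
  if (fit$degenerate)
    warning("non-positive Deming slope: flow change undefined")

  if (!is.null(seed)) set.seed(seed)
  animals <- records$animal_id
  by_animal <- !is.null(animals) && length(unique(animals)) >= 2
  if (by_animal) idx_by_a <- split(seq_along(x), animals)
  boot <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    if (by_animal) {
      a_draw <- sample(names(idx_by_a), length(idx_by_a), replace = TRUE)
      idx <- unlist(lapply(a_draw, function(a) {
        ia <- idx_by_a[[a]]
        ia[sample.int(length(ia), length(ia), replace = TRUE)]
      }), use.names = FALSE)
    } else {
      idx <- sample.int(length(x), length(x), replace = TRUE)
    }
    if (length(idx) < 3) next
    boot[b] <- tryCatch(.flow_point(x[idx], y[idx], vtype[idx],
                                    lambda, center),
                        error = function(e) NA_real_)
  }
  qs <- stats::quantile(boot, probs = c((1 - conf_level) / 2,
                                        1 - (1 - conf_level) / 2),
                        na.rm = TRUE, names = FALSE)
  fit$ci_low <- qs[1]
  fit$ci_high <- qs[2]
  fit$n_boot <- n_boot
  fit$conf_level <- conf_level
  fit
}

#' Linear regression of reactivity on vascular amyloid load
#'
#' Ordinary least squares of per-vessel reactivity (percent) on vascular
#' amyloid load (percent of vessel surface), as used to relate arteriolar
#' hypercapnic reactivity to amyloid burden.
#'
#' @param records data.frame with columns `reactivity` and `amyloid_load`
#'   (arterioles with a measured load).
#' @return list with `slope`, `se`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
reactivity_amyloid_regression <- function(records) {
  r <- records[is.finite(records$amyloid_load) &
                 is.finite(records$reactivity), , drop = FALSE]
  if (nrow(r) < 3) stop("need at least 3 vessels with amyloid load")
  if (stats::var(r$amyloid_load) == 0)
    stop("zero variance in amyloid load")
  fit <- stats::lm(reactivity ~ amyloid_load, data = r)
  sm <- summary(fit)
  co <- sm$coefficients
  list(slope = co["amyloid_load", "Estimate"],
       se = co["amyloid_load", "Std. Error"],
       intercept = co["(Intercept)", "Estimate"],
       r_squared = sm$r.squared,
       p_value = co["amyloid_load", "Pr(>|t|)"],
       n = nrow(r))
}

#' Mean and SEM of reactivity by genotype and vessel type
#'
#' Tabulates arithmetic mean and standard error of the mean of per-vessel
#' reactivity for every genotype x vessel-type cell, plus an ALL-vessels
#' row per genotype. Cells with a single vessel report `NA` SEM; empty
#' cells are omitted with a warning.
#'
#' @param records data.frame with `reactivity`, `vessel_type` and
#'   optionally `genotype`.
#' @return data.frame with columns `genotype`, `vessel_type`, `n`,
#'   `mean_reactivity`, `sem_reactivity`.
#' @export
group_summary <- function(records) {
  if (is.null(records$genotype)) records$genotype <- "all"
  gts <- unique(records$genotype)
  types <- unique(records$vessel_type)
  out <- list()
  for (g in gts) {
    rg <- records[records$genotype == g, , drop = FALSE]
    cells <- c(list(ALL = rg$reactivity),
               lapply(stats::setNames(types, types),
                      function(v) rg$reactivity[rg$vessel_type == v]))
    for (nm in names(cells)) {
      vals <- cells[[nm]]
      if (!length(vals)) {
        warning("empty group omitted: ", g, " / ", nm)
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        genotype = g, vessel_type = nm, n = length(vals),
        mean_reactivity = mean(vals),
        sem_reactivity = if (length(vals) > 1)
          stats::sd(vals) / sqrt(length(vals)) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
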