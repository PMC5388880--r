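# Independent oracles used across the suite. Each deliberately takes the
# dumbest correct route (exhaustive scan, flood fill, normal equations) so
# it shares no code path with the implementation it checks.

# recursive flood fill labeling (8- or 4-connectivity)
oracle_flood_fill <- function(mask, connectivity = 8) {
  m <- mask != 0
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8) {
    offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                  dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    offs <- cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  nxt <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!m[r0, c0] || lab[r0, c0] > 0L) next
    nxt <- nxt + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        r <- p[1] + offs[k, 1]; c <- p[2] + offs[k, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            m[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# orthogonal regression slope by 1-D minimization over the line angle of
# the summed squared perpendicular distances
oracle_perp_slope <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sse <- function(theta) {
    # distance of (xc, yc) to the line through origin at angle theta
    sum((yc * cos(theta) - xc * sin(theta))^2)
  }
  op <- stats::optimize(sse, c(-pi / 2 + 1e-9, pi / 2 - 1e-9),
                        tol = 1e-14)
  tan(op$minimum)
}

# OLS slope/intercept/SE/R2 straight from the normal equations
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 * n / (n * sxx - sx^2))
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, se = se, r_squared = r2)
}

# dense grid search over (t0, alpha, beta) minimizing SSE of the
# gamma-variate model; amplitude/baseline profiled by least squares
oracle_gv_ttp <- function(t, y, t0_grid, alpha_grid, beta_grid) {
  best <- list(sse = Inf)
  for (t0 in t0_grid) for (a in alpha_grid) for (b in beta_grid) {
    g <- gamma_variate(t, t0, a, b)
    X <- cbind(1, g)
    cf <- tryCatch(qr.solve(X, y), error = function(e) NULL)
    if (is.null(cf)) next
    sse <- sum((y - X %*% cf)^2)
    if (sse < best$sse)
      best <- list(sse = sse, ttp = t0 + a * b)
  }
  best$ttp
}

# convenience: band grid cell containing a (phase, amplitude) frequency pair
peak_contains <- function(pk, f_phase, f_amp) {
  pk$phase_band[1] <= f_phase && f_phase <= pk$phase_band[2] &&
    pk$amplitude_band[1] <= f_amp && f_amp <= pk$amplitude_band[2]
}
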