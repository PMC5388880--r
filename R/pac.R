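#' Construct an LFP recording
#'
#' @param samples voltage samples (a.u.), finite.
#' @param sampling_rate sampling rate in Hz.
#' @param channel_id,animal_id,genotype optional metadata labels.
#' @return object of class `lfp_recording`.
#' @export
lfp_recording <- function(samples, sampling_rate, channel_id = NA_character_,
                          animal_id = NA_character_, genotype = NA_character_) {
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (!all(is.finite(samples))) stop("non-finite samples")
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 channel_id = channel_id, animal_id = animal_id,
                 genotype = genotype),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("LFP recording: %.1f s at %g Hz (%d samples)\n",
              length(x$samples) / x$sampling_rate, x$sampling_rate,
              length(x$samples)))
  invisible(x)
}

#' Low-pass filter and decimate a raw LFP recording
#'
#' Zero-phase low-pass FIR (windowed-sinc, Hamming) at `cutoff` Hz followed
#' by decimation to `target_rate` (the low-pass doubles as the anti-alias
#' filter). Recordings already sampled below twice the cutoff skip the
#' low-pass with a warning; recordings at or below the target rate are
#' returned unchanged.
#'
#' @param rec an [lfp_recording()].
#' @param cutoff low-pass cutoff, Hz (default 500).
#' @param target_rate analysis sampling rate after decimation, Hz.
#' @return a new `lfp_recording` at the analysis rate.
#' @export
preprocess_lfp <- function(rec, cutoff = 500, target_rate = 1000) {
  stopifnot(inherits(rec, "lfp_recording"))
  fs <- rec$sampling_rate
  x <- rec$samples
  if (fs < 2 * cutoff) {
    warning("sampling rate below twice the cutoff: low-pass skipped")
  } else {
    x <- .fir_filtfilt(x, .fir_lowpass(fs, cutoff))
  }
  if (fs > target_rate) {
    fac <- round(fs / target_rate)
    x <- x[seq(1L, length(x), by = fac)]
    fs <- fs / fac
  }
  lfp_recording(x, fs, rec$channel_id, rec$animal_id, rec$genotype)
}

.band_analytic <- function(rec, band, cycles = 3, taps = NULL) {
  stopifnot(inherits(rec, "lfp_recording"))
  fs <- rec$sampling_rate
  if (band[2] >= fs / 2) stop("band above Nyquist")
  h <- .fir_bandpass(fs, band[1], band[2], cycles = cycles, taps = taps)
  if (length(h) >= length(rec$samples))
    stop("recording too short for the requested band filter")
  xf <- .fir_filtfilt(rec$samples, h)
  z <- .analytic_signal(xf)
  attr(z, "edge") <- length(h)
  z
}

#' Instantaneous phase of a frequency band
#'
#' Zero-phase band-pass FIR filtering followed by the analytic-signal
#' angle. The first and last `filter length` samples carry edge transients;
#' their count is attached as attribute `"edge"` and they are excluded from
#' downstream coupling estimation (see [pac_valid()]).
#'
#' @param rec an [lfp_recording()].
#' @param band numeric `(low, high)` in Hz, inside Nyquist.
#' @param cycles filter order in cycles of the band's low edge (default 3).
#' @param taps optional explicit FIR length, overriding `cycles` (used for
#'   amplitude bands whose selectivity must match the band width rather
#'   than the absolute frequency).
#' @return numeric vector of wrapped phases (radians) with attr `"edge"`.
#' @export
band_phase <- function(rec, band, cycles = 3, taps = NULL) {
  z <- .band_analytic(rec, band, cycles, taps)
  out <- Arg(z)
  attr(out, "edge") <- attr(z, "edge")
  out
}

#' Amplitude envelope of a frequency band
#'
#' As [band_phase()] but returns the analytic-signal modulus (>= 0).
#' @inheritParams band_phase
#' @return numeric envelope vector with attr `"edge"`.
#' @export
band_amplitude <- function(rec, band, cycles = 3, taps = NULL) {
  z <- .band_analytic(rec, band, cycles, taps)
  out <- Mod(z)
  attr(out, "edge") <- attr(z, "edge")
  out
}

#' Drop filter edge transients from a band series
#'
#' @param x output of [band_phase()] or [band_amplitude()].
#' @param edge samples to drop at each end; defaults to the series' own
#'   `"edge"` attribute.
#' @return the valid central region as a plain numeric vector.
#' @export
pac_valid <- function(x, edge = attr(x, "edge")) {
  if (is.null(edge)) edge <- 0L
  n <- length(x)
  as.numeric(x[(edge + 1L):(n - edge)])
}

#' Canolty modulation index
#'
#' The amplitude envelope of the fast band and the instantaneous phase of
#' the slow band form a complex-valued composite signal
#' \eqn{a_t e^{i\phi_t}}; the modulation index is the modulus of its
#' time average, \eqn{MI = |n^{-1} \sum_t a_t e^{i\phi_t}|}.
#'
#' @param phase phase series (radians).
#' @param amplitude envelope series (same length, >= 0).
#' @return raw MI (a.u., >= 0); 1-homogeneous in amplitude, bounded by
#'   `mean(amplitude)`.
#' @export
modulation_index <- function(phase, amplitude) {
  if (length(phase) != length(amplitude))
    stop("phase and amplitude must have equal length")
  Mod(mean(amplitude * exp(1i * phase)))
}

#' Surrogate modulation indices by circular envelope shift
#'
#' Each surrogate is the MI of the amplitude envelope circularly shifted by
#' a random offset uniform in [0.1 n, 0.9 n] against the unshifted phase.
#' The shift preserves the envelope's spectrum and autocorrelation while
#' destroying its phase alignment, giving the null MI distribution.
#' The `"fft"` method evaluates all shifts at once through the circular
#' cross-correlation theorem and is exactly equal to the `"direct"`
#' per-shift computation.
#'
#' @param phase,amplitude equal-length series (valid regions).
#' @param n_surrogates number of surrogates (default 50, >= 2).
#' @param seed optional integer seed for the offsets.
#' @param method `"fft"` (default) or `"direct"`.
#' @return numeric vector of `n_surrogates` MI values, with the drawn
#'   offsets attached as attribute `"offsets"`.
#' @export
surrogate_mi <- function(phase, amplitude, n_surrogates = 50, seed = NULL,
                         method = c("fft", "direct")) {
  method <- match.arg(method)
  n <- length(phase)
  if (length(amplitude) != n) stop("length mismatch")
  if (n_surrogates < 2) stop("need at least 2 surrogates")
  if (!is.null(seed)) set.seed(seed)
  lo <- ceiling(0.1 * n)
  hi <- floor(0.9 * n)
  offs <- sample(lo:hi, n_surrogates, replace = TRUE)
  if (method == "direct") {
    e <- exp(1i * phase)
    mis <- vapply(offs, function(k) {
      a <- amplitude[c((k + 1L):n, 1L:k)]
      Mod(mean(a * e))
    }, numeric(1))
  } else {
    cc <- .circular_mi_profile(phase, amplitude)
    mis <- cc[offs + 1L]
  }
  attr(mis, "offsets") <- offs
  mis
}

# |(1/n) sum_t a[(t+m) mod n] e^{i phi_t}| for every m = 0..n-1, via FFT:
# the DFT of c[m] = sum_t e_t a_{t+m} is fft(a)[j] * fft(e)[-j].
.circular_mi_profile <- function(phase, amplitude) {
  n <- length(phase)
  e <- exp(1i * phase)
  A <- stats::fft(amplitude)
  E <- stats::fft(e)
  Erev <- E[c(1L, n:2L)]
  Mod(stats::fft(A * Erev, inverse = TRUE)) / as.numeric(n)^2
}

#' Phase/amplitude band grid for comodulograms
#'
#' Default grid: theta 4-8 Hz in four 1 Hz bins; gamma from 30 Hz in
#' contiguous 4 Hz bins, 27 bins reaching 138 Hz (a 4 Hz binning of the
#' 30-140 Hz gamma range has a 2 Hz remainder; edges are configurable).
#'
#' @param phase_edges increasing vector of phase-band edges, Hz.
#' @param amplitude_edges increasing vector of amplitude-band edges, Hz.
#' @return object of class `band_grid` with matrices `phase_bands` and
#'   `amplitude_bands` (one row per band: low, high).
#' @export
band_grid <- function(phase_edges = 4:8,
                      amplitude_edges = seq(30, 138, by = 4)) {
  mk <- function(edges, what) {
    if (length(edges) < 2 || any(diff(edges) <= 0))
      stop(what, " edges must be strictly increasing")
    cbind(low = edges[-length(edges)], high = edges[-1])
  }
  structure(list(phase_bands = mk(phase_edges, "phase"),
                 amplitude_bands = mk(amplitude_edges, "amplitude")),
            class = "band_grid")
}

#' Theta-gamma comodulogram with surrogate-based significance
#'
#' For every (phase band, amplitude band) cell: the raw Canolty MI, its
#' surrogate z-score `z = (MI - mean(surr)) / sd(surr)`, and a Bonferroni-
#' corrected significance flag. All bands are filtered once; every cell
#' shares the same valid window (the largest filter's edge dropped from
#' both ends, trimmed to an FFT-friendly length).
#'
#' With 50 surrogates the corrected tail (alpha / #cells) cannot be
#' resolved empirically, so the surrogate distribution is approximated
#' parametrically to obtain the threshold: `correction = "gamma"` (default)
#' moment-matches a gamma distribution to the surrogates, which respects
#' the right skew of a modulus statistic and keeps the family-wise error
#' controlled; `"normal"` uses the Gaussian quantile. In both cases a cell
#' is significant iff its z exceeds the cell's corrected threshold
#' (`z_crit`), stored in the result.
#'
#' @param rec an [lfp_recording()] at the analysis rate (preprocess first).
#' @param grid a [band_grid()].
#' @param n_surrogates surrogates per cell (default 50).
#' @param alpha family-wise significance level (default 0.05).
#' @param seed optional integer seed for the surrogate offsets.
#' @param correction `"gamma"` or `"normal"` surrogate tail model.
#' @param min_duration minimum analysis window in seconds (default 120).
#' @param cycles filter order in cycles of each band's low edge.
#' @return object of class `comodulogram`: matrices `raw_mi`, `z_mi`,
#'   `z_crit`, `significant` (phase bands x amplitude bands), surrogate
#'   moments, and the analysis metadata.
#' @export
comodulogram <- function(rec, grid = band_grid(), n_surrogates = 50,
                         alpha = 0.05, seed = NULL,
                         correction = c("gamma", "normal"),
                         min_duration = 120, cycles = 3) {
  stopifnot(inherits(rec, "lfp_recording"), inherits(grid, "band_grid"))
  correction <- match.arg(correction)
  fs <- rec$sampling_rate
  if (length(rec$samples) / fs < min_duration)
    stop("recording shorter than the minimum analysis window (",
         min_duration, " s)")
  pb <- grid$phase_bands
  ab <- grid$amplitude_bands
  if (max(ab) >= fs / 2 || max(pb) >= fs / 2)
    stop("grid extends beyond Nyquist")

  # phase filters are transition-matched to the bin width (a 1 Hz theta
  # bin must reject its neighbours, or every bin phase-locks to the same
  # carrier); amplitude filters follow the cycles-of-low-edge rule, whose
  # wide skirts are what lets a fast band pass the modulation sidebands
  phase_taps <- vapply(seq_len(nrow(pb)), function(i)
    .odd_taps(3.3 * fs / (pb[i, "high"] - pb[i, "low"])), integer(1))
  amp_taps <- vapply(seq_len(nrow(ab)), function(j)
    .odd_taps(cycles * fs / ab[j, "low"]), integer(1))
  edge <- max(phase_taps, amp_taps)
  n <- length(rec$samples)
  n_valid <- .prev_nice_length(n - 2L * edge)
  if (n_valid < 1000) stop("recording too short for the requested grid")
  sel <- (edge + 1L):(edge + n_valid)

  phases <- lapply(seq_len(nrow(pb)), function(i)
    band_phase(rec, pb[i, ], taps = phase_taps[i])[sel])
  amps <- lapply(seq_len(nrow(ab)), function(j)
    band_amplitude(rec, ab[j, ], taps = amp_taps[j])[sel])

  np <- nrow(pb); na <- nrow(ab)
  M <- np * na
  raw <- mu <- sdev <- matrix(NA_real_, np, na)
  if (!is.null(seed)) set.seed(seed)
  # precompute FFT pieces once per band
  Afft <- lapply(amps, stats::fft)
  Erev <- lapply(phases, function(ph) {
    E <- stats::fft(exp(1i * ph))
    E[c(1L, n_valid:2L)]
  })
  lo <- ceiling(0.1 * n_valid); hi <- floor(0.9 * n_valid)
  for (i in seq_len(np)) {
    e <- exp(1i * phases[[i]])
    for (j in seq_len(na)) {
      raw[i, j] <- Mod(mean(amps[[j]] * e))
      offs <- sample(lo:hi, n_surrogates, replace = TRUE)
      prof <- Mod(stats::fft(Afft[[j]] * Erev[[i]],
                             inverse = TRUE)) / as.numeric(n_valid)^2
      surr <- prof[offs + 1L]
      mu[i, j] <- mean(surr)
      sdev[i, j] <- stats::sd(surr)
    }
  }
  z <- (raw - mu) / sdev
  alpha_c <- alpha / M
  if (correction == "normal") {
    zc <- matrix(stats::qnorm(1 - alpha_c), np, na)
  } else {
    shape <- (mu / sdev)^2
    rate <- mu / sdev^2
    q <- stats::qgamma(1 - alpha_c, shape = shape, rate = rate)
    zc <- (q - mu) / sdev
  }
  invalid <- !is.finite(sdev) | sdev == 0
  sig <- !invalid & z > zc
  z[invalid] <- NA_real_
  dimnames(raw) <- dimnames(z) <- dimnames(zc) <- dimnames(sig) <-
    list(paste0(pb[, 1], "-", pb[, 2]), paste0(ab[, 1], "-", ab[, 2]))
  structure(list(grid = grid, raw_mi = raw, z_mi = z, z_crit = zc,
                 significant = sig, surrogate_mean = mu, surrogate_sd = sdev,
                 n_surrogates = n_surrogates, alpha = alpha,
                 correction = paste0("bonferroni-", correction),
                 n_valid = n_valid, sampling_rate = fs,
                 channel_id = rec$channel_id, animal_id = rec$animal_id,
                 genotype = rec$genotype),
            class = "comodulogram")
}

#' @export
print.comodulogram <- function(x, ...) {
  cat(sprintf("Comodulogram: %d x %d cells, %d surrogates, %s\n",
              nrow(x$raw_mi), ncol(x$raw_mi), x$n_surrogates, x$correction))
  cat(sprintf("  max z = %.2f, %d significant cell(s) at alpha = %g\n",
              max(x$z_mi, na.rm = TRUE), sum(x$significant, na.rm = TRUE),
              x$alpha))
  invisible(x)
}

#' Grid cell where the comodulogram peaks
#'
#' The peak is taken over the raw MI map by default — the quantity the
#' comodulogram displays — because raw MI weights each cell by the actual
#' band amplitude and therefore localizes a coupled carrier. The surrogate
#' z-score is invariant to amplitude scaling, so every cell whose filter
#' passes any part of a modulated complex shares the same z and a z-peak
#' does not localize; z is the significance statistic, not the map.
#'
#' @param com a [comodulogram()].
#' @param statistic `"raw"` (default) or `"z"`.
#' @return list with `phase_band`, `amplitude_band` (Hz), `raw_mi`, `z`,
#'   `significant`.
#' @export
comodulogram_peak <- function(com, statistic = c("raw", "z")) {
  statistic <- match.arg(statistic)
  m <- if (statistic == "raw") com$raw_mi else com$z_mi
  ij <- which(m == max(m, na.rm = TRUE), arr.ind = TRUE)[1, ]
  list(phase_band = unname(com$grid$phase_bands[ij[1], ]),
       amplitude_band = unname(com$grid$amplitude_bands[ij[2], ]),
       raw_mi = com$raw_mi[ij[1], ij[2]],
       z = com$z_mi[ij[1], ij[2]],
       significant = com$significant[ij[1], ij[2]])
}

#' Cohort summary of electrode-level modulation
#'
#' Collapses each electrode's comodulogram to a scalar (default: mean of
#' the surrogate z-scores over all grid cells) and reports mean +/- SEM per
#' group, mirroring population bar plots of average MI across all
#' electrodes of all animals in a cohort.
#'
#' @param comods list of [comodulogram()] objects.
#' @param groups group label per comodulogram (defaults to each
#'   comodulogram's `genotype`).
#' @param statistic `"mean_z"` (default), `"max_z"`, `"mean_raw"`, or
#'   `"mean_sig_z"` (mean over significant cells, 0 when none).
#' @return data.frame with `group`, `n_electrodes`, `mean`, `sem`, and the
#'   per-electrode values as attribute `"electrode_values"`.
#' @export
cohort_mi_summary <- function(comods, groups = NULL,
                              statistic = c("mean_z", "max_z", "mean_raw",
                                            "mean_sig_z")) {
  statistic <- match.arg(statistic)
  if (is.null(groups))
    groups <- vapply(comods, function(cm) cm$genotype, character(1))
  if (!length(comods)) stop("no comodulograms supplied")
  if (anyNA(groups)) stop("every comodulogram needs a group label")
  val <- vapply(comods, function(cm) {
    switch(statistic,
           mean_z = mean(cm$z_mi, na.rm = TRUE),
           max_z = max(cm$z_mi, na.rm = TRUE),
           mean_raw = mean(cm$raw_mi),
           mean_sig_z = {
             s <- cm$z_mi[which(cm$significant)]
             if (length(s)) mean(s) else 0
           })
  }, numeric(1))
  out <- do.call(rbind, lapply(unique(groups), function(g) {
    v <- val[groups == g]
    data.frame(group = g, n_electrodes = length(v), mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                     else NA_real_,
               stringsAsFactors = FALSE)
  }))
  attr(out, "electrode_values") <- split(val, groups)
  attr(out, "statistic") <- statistic
  out
}
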