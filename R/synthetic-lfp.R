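#' Configuration for a synthetic phase-amplitude-coupled LFP
#'
#' Generative model:
#' \deqn{x(t) = A_\theta \cos\phi_\theta(t) +
#'   A_\gamma (1 + m \cos(\phi_\theta(t) - \phi_c)) \cos(2\pi f_\gamma t)
#'   + pink + white}
#' with \eqn{\phi_\theta(t) = 2\pi f_\theta t}: a theta carrier whose phase
#' modulates the gamma envelope with depth \eqn{m \in [0,1]}. The raw
#' Canolty MI of the clean coupled component is analytically
#' \eqn{A_\gamma m / 2}.
#'
#' @param sampling_rate Hz (default 20000).
#' @param duration seconds (default 120, the continuous analysis window).
#' @param theta_freq slow (phase) frequency, Hz; 4-8 Hz emulates theta.
#' @param gamma_freq fast (amplitude) frequency, Hz; 30-140 Hz emulates
#'   gamma; must be below Nyquist.
#' @param theta_amp,gamma_amp carrier amplitudes (a.u.).
#' @param coupling_depth modulation depth m in [0, 1].
#' @param coupling_phase preferred theta phase of gamma amplitude, radians.
#' @param noise_white_sd white-noise SD (a.u.).
#' @param noise_pink_sd pink-noise SD (a.u.); spectrally shaped white noise
#'   with power ~ 1/f^`pink_exponent`, DC bin zeroed.
#' @param pink_exponent spectral exponent of the pink noise (default 1).
#' @param freq_jitter_sd stationary SD (Hz) of an Ornstein-Uhlenbeck
#'   jitter on the theta instantaneous frequency (default 0.3). A strictly
#'   periodic carrier (`freq_jitter_sd = 0`) is shift-invariant, so
#'   circular-shift surrogates cannot destroy its coupling; real theta
#'   phase decoheres over seconds, which this smooth frequency wander
#'   emulates. The coupled gamma envelope follows the same (jittered)
#'   theta phase, so the analytic clean-signal MI is unchanged.
#' @param freq_jitter_tau correlation time of the theta frequency jitter,
#'   seconds (default 1).
#' @param gamma_jitter_sd,gamma_jitter_tau Ornstein-Uhlenbeck jitter of
#'   the gamma instantaneous frequency (defaults 1.5 Hz, 0.3 s). Real
#'   gamma is band-spread rather than a spectral line; a pure sinusoidal
#'   gamma carrier places its modulation sidebands exactly at the edges of
#'   neighbouring comodulogram amplitude bins, making peak localization an
#'   artifact of filter roll-off instead of signal content.
#' @param seed integer seed.
#' @return object of class `pac_signal_config`.
#' @export
pac_signal_config <- function(sampling_rate = 20000, duration = 120,
                              theta_freq = 6, gamma_freq = 80,
                              theta_amp = 1, gamma_amp = 0.5,
                              coupling_depth = 0, coupling_phase = 0,
                              noise_white_sd = 0.2, noise_pink_sd = 0.5,
                              pink_exponent = 1, freq_jitter_sd = 0.3,
                              freq_jitter_tau = 1, gamma_jitter_sd = 1.5,
                              gamma_jitter_tau = 0.3, seed = 1L) {
  if (gamma_freq >= sampling_rate / 2)
    stop("gamma_freq at or above Nyquist")
  if (coupling_depth < 0 || coupling_depth > 1)
    stop("coupling_depth must be in [0, 1]")
  if (theta_freq <= 0 || gamma_freq <= theta_freq)
    stop("need 0 < theta_freq < gamma_freq")
  if (noise_white_sd < 0 || noise_pink_sd < 0) stop("noise SDs must be >= 0")
  if (duration <= 0) stop("duration must be positive")
  if (freq_jitter_sd < 0 || freq_jitter_tau <= 0 ||
      gamma_jitter_sd < 0 || gamma_jitter_tau <= 0)
    stop("invalid frequency-jitter parameters")
  structure(list(sampling_rate = sampling_rate, duration = duration,
                 theta_freq = theta_freq, gamma_freq = gamma_freq,
                 theta_amp = theta_amp, gamma_amp = gamma_amp,
                 coupling_depth = coupling_depth,
                 coupling_phase = coupling_phase,
                 noise_white_sd = noise_white_sd,
                 noise_pink_sd = noise_pink_sd,
                 pink_exponent = pink_exponent,
                 freq_jitter_sd = freq_jitter_sd,
                 freq_jitter_tau = freq_jitter_tau,
                 gamma_jitter_sd = gamma_jitter_sd,
                 gamma_jitter_tau = gamma_jitter_tau,
                 seed = as.integer(seed)),
            class = "pac_signal_config")
}

#' Pink (1/f^exponent power) noise by spectral shaping
#'
#' White Gaussian noise is shaped in the frequency domain with amplitude
#' profile f^(-exponent/2) (so power ~ 1/f^exponent); the DC bin is zeroed.
#' The result is standardized to the requested SD.
#'
#' @param n samples.
#' @param sd target standard deviation.
#' @param exponent spectral exponent (1 = classic pink).
#' @return numeric vector of length `n`.
#' @export
pink_noise <- function(n, sd = 1, exponent = 1) {
  if (sd == 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- c(0, seq_len(n - 1))
  f <- pmin(k, n - k)            # symmetric frequency index
  shape <- numeric(n)
  shape[f > 0] <- f[f > 0]^(-exponent / 2)
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  sd * (x - mean(x)) / stats::sd(x)
}

#' Generate a synthetic coupled LFP with known ground truth
#'
#' @param cfg a [pac_signal_config()].
#' @param return_components if `TRUE`, the clean theta component, clean
#'   gamma component and true gamma envelope are returned alongside the
#'   noisy signal (memory-heavy at 20 kHz x 120 s; default `FALSE`).
#' @param channel_id,animal_id,genotype metadata labels for the recording.
#' @return list with `recording` (an [lfp_recording()]), `config`, the
#'   analytic expected clean-component MI `expected_mi` (= gamma_amp *
#'   coupling_depth / 2), and optionally `components`.
#' @export
generate_pac_signal <- function(cfg, return_components = FALSE,
                                channel_id = NA_character_,
                                animal_id = NA_character_,
                                genotype = NA_character_) {
  stopifnot(inherits(cfg, "pac_signal_config"))
  set.seed(cfg$seed)
  n <- round(cfg$duration * cfg$sampling_rate)
  dt <- 1 / cfg$sampling_rate
  t <- (seq_len(n) - 1L) * dt
  # Ornstein-Uhlenbeck wander of an instantaneous frequency: smooth
  # (bounded) frequency, phase decoheres over ~tau seconds
  ou_phase <- function(f0, sd, tau) {
    phi <- 2 * pi * f0 * t
    if (sd > 0) {
      rho <- exp(-dt / tau)
      innov <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
      fj <- as.numeric(stats::filter(innov, rho, method = "recursive"))
      phi <- phi + 2 * pi * cumsum(fj) * dt
    }
    phi
  }
  phi <- ou_phase(cfg$theta_freq, cfg$freq_jitter_sd, cfg$freq_jitter_tau)
  theta <- cfg$theta_amp * cos(phi)
  env <- cfg$gamma_amp *
    (1 + cfg$coupling_depth * cos(phi - cfg$coupling_phase))
  phi_g <- ou_phase(cfg$gamma_freq, cfg$gamma_jitter_sd,
                    cfg$gamma_jitter_tau)
  gamma <- env * cos(phi_g)
  x <- theta + gamma
  if (cfg$noise_pink_sd > 0)
    x <- x + pink_noise(n, cfg$noise_pink_sd, cfg$pink_exponent)
  if (cfg$noise_white_sd > 0)
    x <- x + stats::rnorm(n, 0, cfg$noise_white_sd)
  out <- list(recording = lfp_recording(x, cfg$sampling_rate, channel_id,
                                        animal_id, genotype),
              config = cfg,
              expected_mi = cfg$gamma_amp * cfg$coupling_depth / 2)
  if (return_components)
    out$components <- list(theta = theta, gamma = gamma, envelope = env,
                           theta_phase = phi %% (2 * pi))
  out
}
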