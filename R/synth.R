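# Synthetic-data generators: calibration signals of known fractal dimension
# (fractional Brownian motion, Weierstrass graphs) and a paced-breathing
# cohort with respiratory sinus arrhythmia whose gain peaks at a per-subject
# resonance frequency, so every pipeline stage is testable without recordings.

#' Fractional Brownian motion
#'
#' Exact circulant-embedding (Davies-Harte) synthesis of fractional Gaussian
#' noise with Hurst exponent H, cumulatively summed into fBm. The graph of
#' fBm has fractal dimension 2 - H.
#'
#' @param n Number of samples (>= 256).
#' @param H Hurst exponent in (0, 1).
#' @param seed Integer seed (private RNG stream).
#' @return Numeric vector of length `n`.
#' @export
gen_fbm <- function(n, H, seed = NULL) {
  if (H <= 0 || H >= 1) stop("H must lie strictly in (0, 1)")
  n <- as.integer(n)
  if (n < 256L) stop("gen_fbm needs n >= 256")
  M <- 2^ceiling(log2(2L * n))
  g <- function(k) 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  circ <- c(g(0:(M / 2)), g((M / 2 - 1):1))
  lam <- pmax(Re(stats::fft(circ)), 0)   # tiny negatives from roundoff clipped
  fgn <- .with_seed(seed, {
    u <- stats::rnorm(M); v <- stats::rnorm(M)
    half <- 2:(M / 2)
    z <- complex(length.out = M)
    z[1L] <- u[1L]
    z[M / 2 + 1L] <- u[M / 2 + 1L]
    z[half] <- (u[half] + 1i * v[half]) / sqrt(2)
    z[M + 2L - half] <- Conj(z[half])
    Re(stats::fft(sqrt(lam) * z))[seq_len(n)] / sqrt(M)
  })
  cumsum(fgn)
}

#' Weierstrass function graph of known fractal dimension
#'
#' `W(t) = sum_k gamma^((D-2) k) cos(2 pi gamma^k t + phi_k)` on t in [0, 1),
#' whose graph has box-counting dimension D. Phases are drawn from `seed`
#' (deterministic for a fixed seed).
#'
#' @param n Number of samples.
#' @param D Target dimension in (1, 2).
#' @param gamma Frequency ratio > 1 (default 1.5).
#' @param K Number of terms (>= 20, default 40).
#' @param seed Integer seed for the phases.
#' @return Numeric vector of length `n`.
#' @export
gen_weierstrass <- function(n, D, gamma = 1.5, K = 40L, seed = 1L) {
  if (D <= 1 || D >= 2) stop("D must lie strictly in (1, 2)")
  if (gamma <= 1) stop("gamma must exceed 1")
  if (K < 20L) stop("K must be >= 20")
  t <- (seq_len(n) - 1) / n
  phi <- .with_seed(seed, stats::runif(K + 1L, 0, 2 * pi))
  w <- numeric(n)
  for (k in 0:K)
    w <- w + gamma^((D - 2) * k) * cos(2 * pi * gamma^k * t + phi[k + 1L])
  w
}

#' Cohort specification for the synthetic paced-breathing study
#'
#' Defines the study conditions: number of subjects, the trial set (Baseline,
#' Self-paced, and external pacing at 7, 6.5, 6, 5.5 and 5 BrPM, each
#' 5 min 15 s), the per-subject resonance frequency f0 (drawn uniformly from
#' the paced-rate grid when not supplied), the resonance quality Q of the
#' respiratory-sinus-arrhythmia transfer function, its low-frequency gain G,
#' the mean RR interval, and the 1/f RR noise level.
#'
#' @param n_subjects Number of subjects (default 44).
#' @param f0 Optional vector of per-subject resonance frequencies (Hz),
#'   each in \[0.06, 0.14\].
#' @param Q Resonance quality factor (default 3).
#' @param G RSA gain in ms (default 35; at resonance the tachogram
#'   oscillation amplitude is about G * Q).
#' @param rr0 Mean RR interval in ms, in \[600, 1200\] (default 900).
#' @param noise_sd 1/f RR noise standard deviation in ms (default 15).
#' @param duration_s Trial length in seconds (default 315, i.e. 5 min 15 s).
#' @param seed Master seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 44L, f0 = NULL, Q = 3, G = 35,
                        rr0 = 900, noise_sd = 15, duration_s = 315,
                        seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (!is.null(f0)) {
    if (length(f0) != n_subjects) stop("f0 must have one entry per subject")
    if (any(f0 < 0.06 | f0 > 0.14)) stop("f0 must lie in [0.06, 0.14] Hz")
  }
  if (rr0 < 600 || rr0 > 1200) stop("mean RR must lie in [600, 1200] ms")
  if (is.null(f0))
    f0 <- .with_seed(seed,
      sample(as.numeric(.PACED_TRIALS) / 60, n_subjects, replace = TRUE))
  structure(list(n_subjects = n_subjects, trials = .TRIAL_LEVELS[1:7],
                 f0 = f0, Q = Q, G = G, rr0 = rr0, noise_sd = noise_sd,
                 duration_s = duration_s, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Breathing pacer waveform
#'
#' One cycle is a rising half-cosine over `in_fraction` of the period
#' followed by a falling half-cosine over the remainder — continuous, with no
#' plateau. At 6 BrPM and the standard 40/60 inhalation/exhalation ratio this
#' is a 10 s cycle with 4 s in and 6 s out.
#'
#' @param rate Breathing rate in BrPM (> 0).
#' @param in_fraction Inhalation fraction of the cycle, in (0, 1)
#'   (default 0.4).
#' @param duration_s Waveform duration in seconds.
#' @param fs Sampling rate (default 32 Hz).
#' @return A [uniform_signal()] in arbitrary units in \[-1, 1\].
#' @export
gen_pacer <- function(rate, in_fraction = 0.4, duration_s = 315, fs = 32) {
  if (rate <= 0) stop("rate must be positive")
  if (in_fraction <= 0 || in_fraction >= 1) stop("in_fraction must lie in (0, 1)")
  T <- 60 / rate
  t <- seq(0, duration_s, by = 1 / fs)
  tc <- t %% T
  tin <- in_fraction * T
  v <- ifelse(tc < tin,
              -cos(pi * tc / tin),                       # trough -> peak
              cos(pi * (tc - tin) / (T - tin)))          # peak -> trough
  uniform_signal(v, fs = fs)
}

# RSA amplitude at breathing frequency fb: second-order resonance transfer
.rsa_gain <- function(fb, f0, Q, G) {
  G / sqrt((1 - (fb / f0)^2)^2 + (fb / (Q * f0))^2)
}

#' Generate one synthetic trial: RR intervals plus paired respiration
#'
#' Breathing frequency: the paced rate (with small cycle jitter), near-6 BrPM
#' for self-paced, or 12-16 BrPM for baseline. The instantaneous RR signal is
#' `RR(t) = RR0 + A(f_b) sin(2 pi f_b t + phi) + 1/f noise`, with the RSA
#' amplitude `A(f_b) = G / sqrt((1 - (f_b/f0)^2)^2 + (f_b/(Q f0))^2)` peaking
#' near the subject's resonance frequency f0. Beat times follow the
#' integrate-and-fire rule `t_\{n+1\} = t_n + RR(t_n)/1000`.
#'
#' @param spec A [cohort_spec()].
#' @param subject Subject index (1-based).
#' @param rate Trial label: `"Baseline"`, `"Self"`, or a paced rate
#'   (`"5"` ... `"7"` / numeric BrPM).
#' @return List with `rri` (RR [event_series()], ms), `rsp` (respiration
#'   [uniform_signal()] at 32 Hz), `f_b` (Hz) and `A` (RSA amplitude, ms).
#' @export
gen_rri_trial <- function(spec, subject, rate) {
  stopifnot(inherits(spec, "cohort_spec"))
  lbl <- as.character(rate)
  trial_idx <- match(lbl, .TRIAL_LEVELS)
  if (is.na(trial_idx)) stop("unknown trial label: ", lbl)
  seed <- spec$seed + 7919L * as.integer(subject) + 101L * trial_idx
  .with_seed(seed, {
    fb <- if (lbl == "Baseline") stats::runif(1, 12, 16) / 60
          else if (lbl == "Self") stats::rnorm(1, 6, 0.3) / 60
          else as.numeric(lbl) / 60 * (1 + stats::rnorm(1, 0, 0.005))
    f0 <- spec$f0[subject]
    A <- .rsa_gain(fb, f0, spec$Q, spec$G)
    phi <- stats::runif(1, 0, 2 * pi)
    dur <- spec$duration_s
    # 1/f RR noise on a 4 Hz support grid, linearly interpolated at beat times
    ng <- seq(0, dur, by = 0.25)
    noise <- if (spec$noise_sd > 0) {
      pn <- .colored_noise(length(ng), "pink")
      pn * spec$noise_sd / stats::sd(pn)
    } else numeric(length(ng))
    rr_at <- function(t)
      spec$rr0 + A * sin(2 * pi * fb * t + phi) +
        stats::approx(ng, noise, xout = t, rule = 2)$y
    tn <- 0; beats <- numeric(0)
    repeat {
      rr <- max(300, rr_at(tn))        # physiological floor
      tn <- tn + rr / 1000
      if (tn > dur) break
      beats <- c(beats, rr)
    }
    rsp <- gen_pacer(fb * 60, in_fraction = 0.4, duration_s = dur, fs = 32)
    list(rri = event_series(beats, kind = "RRi"), rsp = rsp, f_b = fb, A = A)
  })
}

#' Synthetic electrodermal activity
#'
#' Tonic level decaying exponentially toward baseline (initial slope
#' `-trend_rate` uS/s), sparse phasic responses (Poisson arrivals,
#' bi-exponential kernels with 0.75 s rise and 3 s decay), and white
#' measurement noise, sampled at 32 Hz. Sitting quietly this drifts
#' downwards, giving a negative robust slope.
#'
#' @param duration_s Duration in seconds.
#' @param trend_rate Initial tonic decay rate in uS/s (default 0.002).
#' @param scr_rate Phasic event rate per minute (default 2).
#' @param seed Integer seed.
#' @param noise_sd White noise sd in uS (default 0.01).
#' @param baseline Tonic asymptote in uS (default 2).
#' @return A [uniform_signal()] at 32 Hz.
#' @export
gen_eda <- function(duration_s, trend_rate = 0.002, scr_rate = 2, seed = NULL,
                    noise_sd = 0.01, baseline = 2) {
  if (duration_s <= 0) stop("duration must be positive")
  fs <- 32
  t <- seq(0, duration_s, by = 1 / fs)
  tau <- duration_s / 3
  tonic <- baseline + trend_rate * tau * exp(-t / tau)
  .with_seed(seed, {
    phasic <- numeric(length(t))
    n_scr <- stats::rpois(1, scr_rate * duration_s / 60)
    if (n_scr > 0) {
      onsets <- stats::runif(n_scr, 0, duration_s)
      amps <- stats::rlnorm(n_scr, log(0.2), 0.4)
      for (i in seq_len(n_scr)) {
        dt <- t - onsets[i]
        k <- dt > 0
        phasic[k] <- phasic[k] + amps[i] * (exp(-dt[k] / 3) - exp(-dt[k] / 0.75))
      }
    }
    noise <- if (noise_sd > 0) stats::rnorm(length(t), 0, noise_sd) else 0
    uniform_signal(tonic + phasic + noise, fs = fs)
  })
}

#' Generate the full synthetic cohort
#'
#' Runs [gen_rri_trial()] for every subject and trial of the specification.
#'
#' @param spec A [cohort_spec()].
#' @return List of class `cohort` with `spec` and `subjects`, each subject a
#'   named list of trials (`rri`, `rsp`, `f_b`, `A`).
#' @export
gen_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- lapply(seq_len(spec$n_subjects), function(s) {
    tr <- lapply(spec$trials, function(lbl) gen_rri_trial(spec, s, lbl))
    names(tr) <- spec$trials
    tr
  })
  structure(list(spec = spec, subjects = subjects), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects x %d trials (%.0f s each), f0 range [%.3f, %.3f] Hz\n",
              x$spec$n_subjects, length(x$spec$trials), x$spec$duration_s,
              min(x$spec$f0), max(x$spec$f0)))
  invisible(x)
}
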