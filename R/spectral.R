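# Frequency-domain HRV: Welch / Burg / Lomb-Scargle spectra of the resampled
# tachogram, band metrics, and the resonance-breathing-assessment scorecard
# with automatic resonance-breathing-rate (RBR) selection.

.LF_BAND <- c(0.04, 0.15)   # Hz
.HF_BAND <- c(0.15, 0.40)   # Hz

.spectral_summary <- function(freqs, psd, method, fs, enbw) {
  structure(list(freqs = freqs, psd = pmax(psd, 0), method = method,
                 fs = fs, enbw = enbw),
            class = "spectral_summary")
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf("<spectral_summary:%s> %d bins, 0..%.3g Hz, df = %.4g Hz\n",
              x$method, length(x$freqs), max(x$freqs), x$freqs[2L] - x$freqs[1L]))
  invisible(x)
}

#' Power spectral density of a uniform signal
#'
#' `welch`: averaged modified periodograms with a Hann taper, 50% overlap and
#' zero-padding of each segment to at least four times its length (so peak
#' location and height are not limited by spectral scalloping).
#' `burg`: autoregressive spectrum from the Burg reflection-coefficient
#' recursion at a fixed order. Both return a one-sided density in
#' (signal units)^2 per Hz, so for an ms tachogram the units are ms^2/Hz and
#' the integral over frequency recovers the signal variance (Parseval).
#'
#' @param x A [uniform_signal()], ideally detrended.
#' @param method `"welch"` or `"burg"`.
#' @param segment_s Welch segment length in seconds (default 150).
#' @param overlap Welch segment overlap fraction (default 0.5).
#' @param order Burg AR order (default 16).
#' @param nfreq Number of frequency bins for the Burg spectrum (default 1024).
#' @return A `spectral_summary` with `freqs` (Hz), `psd`, and `enbw`, the
#'   equivalent noise bandwidth (Hz) used to convert peak density to power.
#' @export
psd_estimate <- function(x, method = c("welch", "burg"), segment_s = 150,
                         overlap = 0.5, order = 16L, nfreq = 1024L) {
  method <- match.arg(method)
  stopifnot(inherits(x, "uniform_signal"))
  v <- x$values; fs <- x$fs; n <- length(v)
  if (method == "welch") {
    L <- min(n, max(8L, round(segment_s * fs)))
    step <- max(1L, floor(L * (1 - overlap)))
    starts <- seq.int(1L, n - L + 1L, by = step)
    w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1L)) / (L - 1L)))   # Hann
    nfft <- 2^ceiling(log2(4L * L))
    acc <- numeric(nfft %/% 2L + 1L)
    for (s in starts) {
      seg <- v[s:(s + L - 1L)]
      y <- c((seg - mean(seg)) * w, numeric(nfft - L))
      Y <- stats::fft(y)[seq_len(nfft %/% 2L + 1L)]
      acc <- acc + 2 * Mod(Y)^2 / (fs * sum(w^2))
    }
    psd <- acc / length(starts)
    freqs <- (seq_along(psd) - 1L) * fs / nfft
    .spectral_summary(freqs, psd, "welch", fs, enbw = fs * sum(w^2) / sum(w)^2)
  } else {
    if (order >= n) stop("Burg order must be below the series length")
    fit <- stats::ar.burg(v - mean(v), order.max = order, aic = FALSE,
                          demean = FALSE)
    freqs <- seq(0, fs / 2, length.out = nfreq)
    ek <- exp(-2i * pi * outer(freqs / fs, seq_len(order)))
    denom <- Mod(1 - as.vector(ek %*% fit$ar))^2
    psd <- 2 * fit$var.pred / fs / denom
    .spectral_summary(freqs, psd, "burg", fs, enbw = freqs[2L] - freqs[1L])
  }
}

#' Lomb-Scargle periodogram of an unevenly sampled series
#'
#' Classic phase-shifted (tau) Lomb-Scargle power, computed without
#' resampling, evaluated from 1/T up to the mean Nyquist frequency with
#' 4-fold oversampling and rescaled to a one-sided density in units^2/Hz.
#'
#' @param t Strictly increasing sample times (s).
#' @param x Values at `t`.
#' @return A `spectral_summary`.
#' @export
lomb_psd <- function(t, x) {
  t <- as.numeric(t); x <- as.numeric(x)
  if (length(t) < 20L) stop("lomb_psd needs at least 20 samples")
  if (any(diff(t) <= 0)) stop("times must be strictly increasing (no duplicates)")
  n <- length(t)
  Tspan <- t[n] - t[1L]
  dt <- Tspan / (n - 1L)
  fmax <- 1 / (2 * dt)
  df <- 1 / (4 * Tspan)
  freqs <- seq(df, fmax, by = df)
  xc <- x - mean(x)
  vx <- stats::var(x)
  if (vx == 0) return(.spectral_summary(freqs, numeric(length(freqs)),
                                        "lomb", 1 / dt, enbw = 1 / Tspan))
  P <- vapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    0.5 * (sum(xc * ct)^2 / sum(ct^2) + sum(xc * st)^2 / sum(st^2))
  }, numeric(1L))
  # unnormalized Scargle power -> one-sided density; on an even grid this
  # matches the classic periodogram scaling 2*|X|^2*dt/n. The resolution
  # bandwidth is 1/T (the grid is 4-fold oversampled).
  .spectral_summary(freqs, 2 * P * dt, "lomb", 1 / dt, enbw = 1 / Tspan)
}

#' Band power, peak frequency, peak power and normalized units
#'
#' Power is the trapezoidal integral of the density over the band; peak
#' frequency is the argmax of the density within the band; peak power is the
#' density at the peak times the spectrum's equivalent resolution bandwidth
#' (giving ms^2 for an ms tachogram); normalized units express the band power
#' as a percentage of LF + HF power.
#'
#' @param S A `spectral_summary`.
#' @param band `c(f_lo, f_hi)` in Hz.
#' @param lf,hf LF and HF band edges used for the normalized units
#'   (defaults 0.04-0.15 and 0.15-0.40 Hz).
#' @return List with `power`, `peak_freq`, `peak_power`, `nu`.
#' @export
band_metrics <- function(S, band, lf = .LF_BAND, hf = .HF_BAND) {
  stopifnot(inherits(S, "spectral_summary"))
  if (band[1L] < min(S$freqs) - 1e-12 || band[2L] > max(S$freqs) + 1e-12)
    stop("band outside the resolved frequency range")
  integ <- function(b) {
    i <- which(S$freqs >= b[1L] & S$freqs <= b[2L])
    if (length(i) < 2L) return(0)
    sum(diff(S$freqs[i]) * (S$psd[i][-1L] + S$psd[i][-length(i)]) / 2)
  }
  i <- which(S$freqs >= band[1L] & S$freqs <= band[2L])
  pk <- i[which.max(S$psd[i])]
  tot <- integ(lf) + integ(hf)
  list(power = integ(band),
       peak_freq = S$freqs[pk],
       peak_power = S$psd[pk] * S$enbw,
       nu = if (tot > 0) 100 * integ(band) / tot else NA_real_)
}

#' Mean within-cycle heart-rate excursion (HRMaxMin)
#'
#' Converts RR intervals to instantaneous heart rate (60000/RRi, bpm), takes
#' max(HR) - min(HR) within each breathing cycle, and returns the mean over
#' cycles containing at least two beats.
#'
#' @param rri An RR-interval [event_series()] (ms).
#' @param cycle_bounds Breathing-cycle boundary times (s), e.g. respiration
#'   peak times; must delimit >= 3 full cycles.
#' @return HRMaxMin in bpm.
#' @export
hr_max_min <- function(rri, cycle_bounds) {
  stopifnot(inherits(rri, "event_series"), rri$kind == "RRi")
  cb <- sort(as.numeric(cycle_bounds))
  if (length(cb) < 4L) stop("need at least 3 full breathing cycles")
  hr <- 60000 / rri$intervals
  excursions <- vapply(seq_len(length(cb) - 1L), function(k) {
    in_cycle <- rri$times >= cb[k] & rri$times < cb[k + 1L]
    if (sum(in_cycle) < 2L) return(NA_real_)
    diff(range(hr[in_cycle]))
  }, numeric(1L))
  mean(excursions, na.rm = TRUE)
}

#' Phase of heart rate relative to respiration at the breathing frequency
#'
#' Cross-spectral phase at the Fourier bin nearest `f_b`, mapped to
#' (-180, 180] degrees, positive when heart rate lags respiration. Invariant
#' to amplitude scaling of either input.
#'
#' @param hr Heart-rate (or tachogram) [uniform_signal()].
#' @param rsp Respiration [uniform_signal()] at the same sampling rate.
#' @param f_b Breathing frequency (Hz); must be resolvable from the record.
#' @return Phase in degrees.
#' @export
resp_hr_phase <- function(hr, rsp, f_b) {
  stopifnot(inherits(hr, "uniform_signal"), inherits(rsp, "uniform_signal"))
  if (abs(hr$fs - rsp$fs) > 1e-9) stop("hr and rsp must share a sampling rate")
  n <- min(length(hr$values), length(rsp$values))
  if (n / hr$fs < 5 / f_b) stop("record must cover at least 5 breathing cycles")
  a <- hr$values[seq_len(n)] - mean(hr$values[seq_len(n)])
  b <- rsp$values[seq_len(n)] - mean(rsp$values[seq_len(n)])
  bin <- round(f_b * n / hr$fs) + 1L
  if (bin < 2L || bin > n %/% 2L) stop("breathing frequency unresolved")
  ph <- Arg(stats::fft(b)[bin] * Conj(stats::fft(a)[bin])) * 180 / pi
  if (ph <= -180) ph <- ph + 360
  ph
}

.PACED_TRIALS <- c("5", "5.5", "6", "6.5", "7")

#' Resonance-breathing-assessment scorecard
#'
#' Computes, per trial, the six-quantity assessment: LF absolute band power
#' (LFBP, ms^2), peak LF power (PLFP, ms^2), normalized LF power (nu),
#' HRMaxMin (bpm) and the HR-respiration phase (degrees); comfort ratings, if
#' supplied, are carried through. The tachogram is resampled at `fs_resample`
#' and linearly detrended before spectral estimation.
#'
#' @param trials Named list (names = trial labels, e.g. `"5"`, `"6.5"`,
#'   `"Baseline"`), each element a list with `rri` (an RR [event_series()])
#'   and optionally `rsp` (a respiration [uniform_signal()]) and `comfort`.
#' @param fs_resample Tachogram resampling rate, Hz (default 4).
#' @param method Spectral method: `"lomb"` (default) computes the
#'   Lomb-Scargle periodogram directly on the beat-ordered intervals, which
#'   needs no resampling and so has no interpolation attenuation at the
#'   breathing frequency; `"welch"` and `"burg"` work on the resampled,
#'   detrended tachogram.
#' @param f_b Optional named breathing frequencies (Hz) per trial; defaults to
#'   rate/60 for the paced trials.
#' @return Data frame of class `rba_scorecard`, one row per trial.
#' @export
rba_scorecard <- function(trials, fs_resample = 4,
                          method = c("lomb", "welch", "burg"), f_b = NULL) {
  method <- match.arg(method)
  rows <- lapply(names(trials), function(lbl) {
    tr <- trials[[lbl]]
    tach <- detrend(resample_uniform(tr$rri, fs_resample), "linear")
    S <- if (method == "lomb")
      lomb_psd(tr$rri$times, tr$rri$intervals - mean(tr$rri$intervals))
    else psd_estimate(tach, method)
    lf <- band_metrics(S, .LF_BAND)
    fb <- if (!is.null(f_b) && lbl %in% names(f_b)) f_b[[lbl]]
          else if (lbl %in% .PACED_TRIALS) as.numeric(lbl) / 60 else NA_real_
    hmm <- ph <- NA_real_
    if (!is.null(tr$rsp)) {
      cyc <- try(extract_breath_intervals(tr$rsp), silent = TRUE)
      if (!inherits(cyc, "try-error") && length(cyc$peak_times) >= 4L) {
        hmm <- hr_max_min(tr$rri, cyc$peak_times)
        if (is.na(fb)) fb <- 1 / mean(cyc$PP$intervals)
        rsp_ds <- uniform_signal(
          stats::approx(signal_times(tr$rsp), tr$rsp$values,
                        xout = signal_times(tach))$y,
          fs = fs_resample, t0 = tach$t0)
        ph <- try(resp_hr_phase(uniform_signal(60000 / tach$values, fs_resample,
                                               tach$t0),
                                rsp_ds, fb), silent = TRUE)
        if (inherits(ph, "try-error")) ph <- NA_real_
      }
    }
    data.frame(trial = lbl, LFBP = lf$power, PLFP = lf$peak_power,
               LF_nu = lf$nu, HRMaxMin = hmm, phase = ph,
               comfort = if (is.null(tr$comfort)) NA_real_ else tr$comfort,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rba_scorecard", "data.frame")
  out
}

#' Select the resonance breathing rate from a scorecard
#'
#' Returns the trial with the highest LF spectral peak power (PLFP) among the
#' externally paced trials (5, 5.5, 6, 6.5, 7 BrPM); `include_self = TRUE`
#' also admits the self-paced trial (some individuals peak higher during slow
#' self-paced breathing). Exact ties break to the slower rate.
#'
#' @param scorecard An [rba_scorecard()] (or data frame with `trial`, `PLFP`).
#' @param include_self Admit the `"Self"` trial (default FALSE).
#' @return The selected trial label.
#' @export
select_rbr <- function(scorecard, include_self = FALSE) {
  df <- as.data.frame(scorecard)
  if (!nrow(df)) stop("empty scorecard")
  eligible <- .PACED_TRIALS
  if (include_self) eligible <- c(eligible, "Self")
  df <- df[df$trial %in% eligible, , drop = FALSE]
  if (!nrow(df) || anyNA(df$PLFP)) stop("PLFP must be present for all paced trials")
  best <- df$PLFP == max(df$PLFP)
  cand <- df$trial[best]
  rate <- suppressWarnings(as.numeric(cand))
  rate[is.na(rate)] <- Inf   # "Self" never wins a tie against a paced rate
  cand[which.min(rate)]
}
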