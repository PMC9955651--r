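# Data-modification toolbox: detrending, deduplication, tachogram resampling,
# segmentation, finegrid interpolation, coloured noise, amplitude transforms,
# stationarity testing and breath-interval extraction.

.values <- function(x) if (inherits(x, "uniform_signal")) x$values else as.numeric(x)

.rewrap <- function(x, values) {
  if (inherits(x, "uniform_signal")) uniform_signal(values, fs = x$fs, t0 = x$t0)
  else values
}

# evaluate expr under a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Remove a least-squares trend
#'
#' Subtracts the least-squares constant or straight-line fit, leaving a
#' zero-mean residual. Idempotent (an orthogonal projection).
#'
#' @param x A [uniform_signal()] or numeric vector.
#' @param method `"linear"` (default) or `"constant"` (mean removal).
#' @return Same type as `x`, detrended.
#' @export
detrend <- function(x, method = c("linear", "constant")) {
  method <- match.arg(method)
  v <- .values(x)
  if (length(v) < 2L) stop("detrend needs at least 2 samples")
  r <- if (method == "constant") v - mean(v) else stats::lsfit(seq_along(v), v)$residuals
  .rewrap(x, unname(r))
}

#' Collapse runs of consecutive equal values
#'
#' Used on up-sampled EDA/respiration streams where hardware repetition
#' produces staircase duplicates.
#'
#' @param x Numeric vector.
#' @return `x` with each run of consecutive equal values reduced to one.
#' @export
deduplicate <- function(x) {
  x <- as.numeric(x)
  if (length(x) <= 1L) return(x)
  x[c(TRUE, x[-1L] != x[-length(x)])]
}

#' Resample an interval series onto a uniform grid (tachogram)
#'
#' The interval value is plotted at the time its event ends and interpolated
#' with shape-preserving (monotone) piecewise cubic interpolation, so the
#' output never overshoots the range of the input intervals. Typical rates
#' for RR-interval data are 4 or 10 Hz.
#'
#' @param x An [event_series()].
#' @param fs Target sampling rate (Hz).
#' @return A [uniform_signal()] in the units of `x$intervals`, starting at the
#'   first event time.
#' @export
resample_uniform <- function(x, fs) {
  stopifnot(inherits(x, "event_series"))
  if (length(x$intervals) < 4L) stop("resample_uniform needs at least 4 events")
  if (fs <= 0) stop("fs must be positive")
  t <- x$times
  grid <- seq(t[1L], t[length(t)], by = 1 / fs)
  vals <- pracma::pchip(t, x$intervals, grid)
  uniform_signal(vals, fs = fs, t0 = t[1L])
}

#' Segmentation plan
#'
#' Two layouts are supported: `"nested"` prefixes of 1..k minutes all sharing
#' the recording start (for data-length analyses), and `"equal_fifths"`, five
#' contiguous non-overlapping length-balanced segments (for within-trial
#' change).
#'
#' @param mode `"nested"` or `"equal_fifths"`.
#' @param minutes For nested mode, ascending prefix durations in minutes.
#' @return A `segmentation_plan` object.
#' @export
segmentation_plan <- function(mode = c("nested", "equal_fifths"), minutes = NULL) {
  mode <- match.arg(mode)
  if (mode == "nested") {
    if (is.null(minutes) || !length(minutes) || is.unsorted(minutes, strictly = TRUE))
      stop("nested plan needs strictly ascending durations in minutes")
  }
  structure(list(mode = mode, minutes = minutes), class = "segmentation_plan")
}

#' Segment a recording
#'
#' Half-open convention: a segment covering `[start, end)` keeps samples or
#' events whose time is strictly before `end`.
#'
#' @param x A [uniform_signal()] or [event_series()].
#' @param plan A [segmentation_plan()].
#' @return List of segments of the same type as `x`.
#' @export
segment_recording <- function(x, plan) {
  stopifnot(inherits(plan, "segmentation_plan"))
  if (inherits(x, "uniform_signal")) {
    n <- length(x$values)
    if (plan$mode == "nested") {
      lens <- round(plan$minutes * 60 * x$fs)
      if (any(lens > n)) stop("recording shorter than requested duration")
      lapply(lens, function(L) uniform_signal(x$values[seq_len(L)], x$fs, x$t0))
    } else {
      cuts <- floor(n * (0:5) / 5)
      lapply(seq_len(5L), function(k) {
        idx <- (cuts[k] + 1L):cuts[k + 1L]
        uniform_signal(x$values[idx], x$fs, x$t0 + cuts[k] / x$fs)
      })
    }
  } else if (inherits(x, "event_series")) {
    rel <- x$times - x$t0
    span <- rel[length(rel)]
    if (plan$mode == "nested") {
      bounds <- plan$minutes * 60
      if (max(bounds) > span + 1e-9 && max(bounds) - span > max(x$intervals) *
          (if (x$units == "ms") 1e-3 else 1))
        stop("recording shorter than requested duration")
      lapply(bounds, function(b)
        event_series(x$intervals[rel < b], kind = x$kind, t0 = x$t0))
    } else {
      bounds <- span * (1:5) / 5
      lo <- c(0, bounds[-5L])
      lapply(seq_len(5L), function(k) {
        keep <- rel >= lo[k] - 1e-12 & rel < bounds[k]
        if (k == 5L) keep <- rel >= lo[k] - 1e-12  # last segment closes the span
        event_series(x$intervals[keep], kind = x$kind, t0 = x$t0 + lo[k])
      })
    }
  } else stop("segment_recording expects a uniform_signal or event_series")
}

#' Finegrid interpolation of short series
#'
#' Inserts `n_points` new values between every adjacent pair, either on the
#' connecting line (`"linear"`) or copying the nearer endpoint (`"nearest"`,
#' midpoint ties go to the left endpoint). Output length is
#' `N + (N - 1) * n_points`.
#'
#' @param x Numeric vector, length >= 2.
#' @param method `"linear"` or `"nearest"`.
#' @param n_points Number of inserted points per gap, 1..3.
#' @return Numeric vector.
#' @export
finegrid_interpolate <- function(x, method = c("linear", "nearest"), n_points = 1L) {
  method <- match.arg(method)
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least 2 points")
  if (!n_points %in% 1:3) stop("n_points must be 1, 2 or 3")
  n <- length(x)
  frac <- seq_len(n_points) / (n_points + 1)
  out <- numeric((n - 1L) * (n_points + 1L) + 1L)
  for (i in seq_len(n - 1L)) {
    base <- (i - 1L) * (n_points + 1L) + 1L
    out[base] <- x[i]
    ins <- if (method == "linear") x[i] + frac * (x[i + 1L] - x[i])
           else ifelse(frac <= 0.5, x[i], x[i + 1L])
    out[base + seq_len(n_points)] <- ins
  }
  out[length(out)] <- x[n]
  out
}

# coloured noise by spectral shaping: amplitude ~ f^(beta/2), beta per colour
.colored_noise <- function(n, colour = c("white", "pink", "brown", "blue")) {
  colour <- match.arg(colour)
  beta <- switch(colour, white = 0, pink = -1, brown = -2, blue = 1)
  w <- stats::rnorm(n)
  if (beta == 0) return(w)
  W <- stats::fft(w)
  f <- seq_len(n) - 1
  f <- pmin(f, n - f)              # two-sided frequency index, symmetric
  shape <- c(0, (f[-1L])^(beta / 2))
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x - mean(x)
}

#' Add coloured noise at a target signal-to-noise ratio
#'
#' Noise is synthesized by spectral shaping (power spectral density
#' proportional to f^beta with beta = 0, -1, -2, +1 for white, pink, brown and
#' blue) and scaled so that `10*log10(var(signal)/var(noise)) = snr_db`.
#' `snr_db = Inf` is the no-noise sentinel.
#'
#' @param x A [uniform_signal()] or numeric vector with positive variance.
#' @param colour `"white"`, `"pink"`, `"brown"` or `"blue"`.
#' @param snr_db Target SNR in dB.
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @return Same type as `x`.
#' @export
add_noise <- function(x, colour = c("white", "pink", "brown", "blue"),
                      snr_db, seed = NULL) {
  colour <- match.arg(colour)
  v <- .values(x)
  if (is.infinite(snr_db) && snr_db > 0) return(x)
  vx <- stats::var(v)
  if (!is.finite(vx) || vx <= 0) stop("zero-variance input with finite snr_db")
  noise <- .with_seed(seed, .colored_noise(length(v), colour))
  target <- vx / 10^(snr_db / 10)
  noise <- noise * sqrt(target / stats::var(noise))
  .rewrap(x, v + noise)
}

#' Amplitude transforms: normalisation and binarisation
#'
#' Three normalisations (z-score, min-max to \[0,1\], robust
#' median/MAD) and three binarisations: `binarize_a` thresholds at the mean
#' (1 where above); `binarize_b` is the sign of successive differences
#' (length N-1, values -1/0/+1); `binarize_c` marks successive differences
#' whose magnitude exceeds the standard deviation of all differences.
#'
#' @param x Numeric vector.
#' @param method One of `"zscore"`, `"minmax"`, `"robust"`, `"binarize_a"`,
#'   `"binarize_b"`, `"binarize_c"`.
#' @return Numeric vector (length N-1 for the difference-based binarisations).
#' @export
transform_amplitude <- function(x, method = c("zscore", "minmax", "robust",
                                              "binarize_a", "binarize_b",
                                              "binarize_c")) {
  method <- match.arg(method)
  x <- as.numeric(x)
  switch(method,
    zscore = {
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0) stop("constant input: z-score undefined")
      (x - mean(x)) / s
    },
    minmax = {
      r <- range(x)
      if (diff(r) == 0) stop("constant input: min-max undefined")
      (x - r[1L]) / diff(r)
    },
    robust = {
      s <- stats::mad(x)  # 1.4826 * MAD, consistent for the normal
      if (!is.finite(s) || s == 0) stop("zero spread: robust scaling undefined")
      (x - stats::median(x)) / s
    },
    binarize_a = as.numeric(x > mean(x)),
    binarize_b = sign(diff(x)),
    binarize_c = {
      d <- diff(x)
      as.numeric(abs(d) > stats::sd(d))
    })
}

#' Reverse-arrangement test for (weak) stationarity
#'
#' Counts reverse arrangements `A = #\{(i,j): i < j, x_i > x_j\}` and compares
#' the normal deviate `z = (A - N(N-1)/4) / sqrt(N(2N+5)(N-1)/72)` against the
#' two-sided normal quantile at `alpha`. A trend in either direction inflates
#' `|z|`; the verdict is invariant under strictly monotone transforms of the
#' values.
#'
#' @param x Numeric vector, length >= 10.
#' @param alpha Two-sided significance level (default 0.05).
#' @return List with `A`, `z`, `p`, `nonstationary`, `n`.
#' @export
reverse_arrangement_test <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10L) stop("reverse_arrangement_test needs N >= 10")
  A <- sum(vapply(seq_len(n - 1L),
                  function(i) sum(x[(i + 1L):n] < x[i]), numeric(1L)))
  mu <- n * (n - 1) / 4
  sg <- sqrt(n * (2 * n + 5) * (n - 1) / 72)
  z <- (A - mu) / sg
  p <- 2 * stats::pnorm(-abs(z))
  list(A = A, z = z, p = p, nonstationary = abs(z) > stats::qnorm(1 - alpha / 2),
       n = n)
}

# centered moving average, edges padded with the raw values
.smooth_ma <- function(v, w) {
  if (w <= 1L) return(v)
  sm <- stats::filter(v, rep(1 / w, w), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- v[is.na(sm)]
  sm
}

#' Extract breath intervals from a respiration waveform
#'
#' Peaks (end-inhalation) and troughs (end-exhalation) are located on a 1-s
#' moving-average smoothed copy of the waveform with a 2-s minimum extremum
#' separation and a prominence floor, then converted into three interval
#' streams: inbreath `IN(n)` from trough n to peak n+1, outbreath `OUT(n)`
#' from peak n to trough n, and peak-to-peak `PP(n)` from peak n to peak n+1,
#' plus the exhalation/inhalation ratio series `OUT(n)/IN(n+1)`.
#'
#' @param rsp A respiration [uniform_signal()] covering at least 3 cycles.
#' @param min_prominence Minimum extremum prominence as a fraction of the
#'   waveform range (default 0.2).
#' @return List with event series `IN`, `OUT`, `PP` (all in seconds), the
#'   `ratio` vector, and `peak_times`/`trough_times`.
#' @export
extract_breath_intervals <- function(rsp, min_prominence = 0.2) {
  stopifnot(inherits(rsp, "uniform_signal"))
  v <- .smooth_ma(rsp$values, max(1L, round(rsp$fs)))
  mind <- max(1L, round(2 * rsp$fs))
  floor_h <- min_prominence * diff(range(v))
  half <- max(1L, round(rsp$fs / 2))
  raw <- rsp$values
  locs <- function(y, refine) {
    pk <- pracma::findpeaks(y, minpeakdistance = mind,
                            minpeakheight = min(y) + floor_h, zero = "+")
    if (is.null(pk)) return(integer(0))
    idx <- sort(pk[, 2L])
    # smoothing shifts the extrema of asymmetric cycles; relocate on the raw
    # waveform within half a smoothing window
    vapply(idx, function(i) {
      win <- max(1L, i - half):min(length(raw), i + half)
      win[refine(raw[win])]
    }, integer(1L))
  }
  ip <- locs(v, which.max)
  it <- locs(-v, which.min)
  if (length(ip) < 3L || length(it) < 2L) stop("no detectable breathing cycles")
  tt <- signal_times(rsp)
  pt <- tt[ip]; trt <- tt[it]
  # trough following each peak
  nxt <- vapply(pt, function(p) { j <- which(trt > p); if (length(j)) trt[j[1L]] else NA_real_ },
                numeric(1L))
  np <- length(pt)
  OUT <- nxt[-np] - pt[-np]                # peak n -> trough n
  IN <- pt[-1L] - nxt[-np]                 # trough n -> peak n+1
  PP <- diff(pt)                           # peak n -> peak n+1
  ok <- is.finite(OUT) & is.finite(IN) & OUT > 0 & IN > 0
  OUT <- OUT[ok]; IN <- IN[ok]; PP <- PP[ok]
  if (length(PP) < 2L) stop("no detectable breathing cycles")
  nr <- length(OUT) - 1L
  ratio <- if (nr >= 1L) OUT[seq_len(nr)] / IN[seq_len(nr) + 1L] else numeric(0)
  list(IN = event_series(IN, kind = "IN"),
       OUT = event_series(OUT, kind = "OUT"),
       PP = event_series(PP, kind = "PP"),
       ratio = ratio, peak_times = pt, trough_times = trt)
}
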