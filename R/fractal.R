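# Fractal-dimension estimators for waveform graphs: Higuchi, Katz,
# Castiglioni, Petrosian, Sevcik, box-counting, normalized length density
# (Kalauzi) and the Maragos morphological multiscale FD. All operate on plain
# numeric sequences; interval series can be analysed non-resampled as
# unit-spaced sequences, or resampled first with resample_uniform().

#' FD estimate container
#'
#' @param method Estimator name.
#' @param value Estimated fractal dimension (1..2 for graph estimators;
#'   `NA` with `diagnostics$undefined = TRUE` for degenerate input).
#' @param params Named list of the parameters used.
#' @param fit Named list of slope-fit diagnostics (`r_squared`, `points`).
#' @param diagnostics Extra named diagnostics.
#' @return An object of class `fd_estimate`.
#' @export
fd_estimate <- function(method, value, params = list(), fit = list(),
                        diagnostics = list()) {
  structure(list(method = method, value = value, params = params,
                 fit = fit, diagnostics = diagnostics),
            class = "fd_estimate")
}

#' @export
print.fd_estimate <- function(x, ...) {
  pv <- if (length(x$params))
    paste0(" (", paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "), ")")
  else ""
  cat(sprintf("<fd_estimate> %s%s: FD = %s", x$method, pv, format(x$value, digits = 5)))
  if (length(x$fit) && !is.null(x$fit$r_squared))
    cat(sprintf("  [fit R^2 = %.4f over %d points]", x$fit$r_squared, x$fit$points))
  cat("\n")
  invisible(x)
}

# least-squares line y ~ x returning slope and R^2
.ls_slope <- function(lx, ly) {
  fit <- stats::lsfit(lx, ly)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ly - mean(ly))^2)
  list(slope = unname(fit$coefficients[2L]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       points = length(lx))
}

#' Higuchi fractal dimension
#'
#' For each delay k = 1..kmax the mean normalized curve length L(k) is
#' computed over the k phase-shifted subsampled curves; the FD is the negative
#' slope of the least-squares line of ln L(k) on ln k (all k are used in the
#' fit). Expected values: ~1 for a finely sampled smooth curve, 2 - H for
#' fractional Brownian motion, ~2 for uncorrelated noise.
#'
#' @param x Numeric sequence, length >= 10 * kmax.
#' @param kmax Maximum delay (>= 2); the literature sweeps 2..15 for
#'   RR-interval data.
#' @return An [fd_estimate()] with `L(k)` in `diagnostics`.
#' @export
fd_higuchi <- function(x, kmax = 8L) {
  x <- as.numeric(x)
  n <- length(x)
  if (kmax < 2L) stop("kmax must be >= 2")
  if (n < 10L * kmax) stop("fd_higuchi needs length >= 10 * kmax")
  L <- vapply(seq_len(kmax), function(k) {
    Lm <- vapply(seq_len(k), function(m) {
      idx <- seq.int(m, n, by = k)
      if (length(idx) < 2L) return(NA_real_)
      sum(abs(diff(x[idx]))) * (n - 1) / ((length(idx) - 1L) * k) / k
    }, numeric(1L))
    mean(Lm, na.rm = TRUE)
  }, numeric(1L))
  if (any(L <= 0))
    return(fd_estimate("higuchi", NA_real_, list(kmax = kmax),
                       diagnostics = list(undefined = TRUE, reason = "degenerate input")))
  fit <- .ls_slope(log(seq_len(kmax)), log(L))
  fd_estimate("higuchi", -fit$slope, list(kmax = kmax),
              fit = fit[c("r_squared", "points")], diagnostics = list(L = L))
}

#' Katz fractal dimension
#'
#' The waveform is a planar curve with unit abscissa steps; with total path
#' length L, maximum distance d from the first point and n = N - 1 steps,
#' FD = ln(n) / (ln(n) + ln(d/L)).
#'
#' @param x Numeric sequence, length >= 3.
#' @return An [fd_estimate()].
#' @export
fd_katz <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) stop("fd_katz needs length >= 3")
  dy <- diff(x)
  L <- sum(sqrt(1 + dy^2))
  d <- max(sqrt((seq_len(n) - 1)^2 + (x - x[1L])^2)[-1L])
  if (d == 0) stop("all points coincide: Katz FD undefined")
  steps <- n - 1
  fd_estimate("katz", log(steps) / (log(steps) + log(d / L)),
              diagnostics = list(L = L, d = d))
}

#' Castiglioni's calibration-independent Katz variant
#'
#' Katz's formula evaluated on amplitudes alone: `L = sum(|successive
#' differences|)`, `d = max |x_i - x_1|`, `n = N - 1` steps, and
#' `FD = ln(n) / (ln(n) + ln(d/L))`. Because d and L share units the ratio is
#' dimensionless, so the estimate does not depend on the amplitude or time
#' calibration of the recording (the flaw of the planar-embedding Katz form).
#' Note the index is monotone in roughness but not confined to \[1, 2\]: on
#' uncorrelated noise, where the total variation L vastly exceeds the
#' excursion d, it saturates above 2.
#'
#' @param x Numeric sequence, length >= 3, non-constant.
#' @return An [fd_estimate()].
#' @export
fd_castiglioni <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L) stop("fd_castiglioni needs length >= 3")
  L <- sum(abs(diff(x)))
  if (L == 0) stop("constant input: FD undefined")
  d <- max(abs(x - x[1L])[-1L])
  if (d == 0) stop("degenerate excursion: FD undefined")
  steps <- length(x) - 1L
  fd_estimate("castiglioni", log(steps) / (log(steps) + log(d / L)),
              diagnostics = list(L = L, d = d))
}

#' Petrosian fractal dimension (three binarisation variants)
#'
#' The series is binarized with [transform_amplitude()] variant a, b or c; with
#' NDelta the number of changes in the binary sequence and N the series
#' length, FD = log10(N) / (log10(N) + log10(N / (N + 0.4 * NDelta))).
#'
#' @param x Numeric sequence, length >= 3.
#' @param variant `"a"` (mean threshold), `"b"` (sign of successive
#'   differences) or `"c"` (large successive differences).
#' @return An [fd_estimate()] with `NDelta` in `diagnostics`.
#' @export
fd_petrosian <- function(x, variant = c("a", "b", "c")) {
  variant <- match.arg(variant)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) stop("fd_petrosian needs length >= 3")
  b <- transform_amplitude(x, paste0("binarize_", variant))
  nd <- sum(b[-1L] != b[-length(b)])
  fd_estimate("petrosian",
              log10(n) / (log10(n) + log10(n / (n + 0.4 * nd))),
              params = list(variant = variant),
              diagnostics = list(NDelta = nd))
}

#' Sevcik fractal dimension
#'
#' The curve is mapped into the unit square (abscissa 0..1 over N-1 steps,
#' ordinate min-max normalized); with L the normalized curve length,
#' FD = 1 + ln(L) / ln(2(N - 1)).
#'
#' @param x Numeric sequence, length >= 3, non-constant.
#' @return An [fd_estimate()].
#' @export
fd_sevcik <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) stop("fd_sevcik needs length >= 3")
  r <- range(x)
  if (diff(r) == 0) stop("constant input: Sevcik FD undefined")
  y <- (x - r[1L]) / diff(r)
  L <- sum(sqrt((1 / (n - 1))^2 + diff(y)^2))
  fd_estimate("sevcik", 1 + log(L) / log(2 * (n - 1)))
}

# boxes occupied by the graph on a k-by-k grid over the unit square: per
# abscissa column, every box between the column's min and max, where the
# column's span also includes the last sample of the previous column so the
# count respects the continuity of the curve across column boundaries
.box_count <- function(ty, k) {
  col <- pmin(floor(ty$t * k), k - 1)
  ybox <- pmin(floor(ty$y * k), k - 1)
  lo <- tapply(ybox, col, min)
  hi <- tapply(ybox, col, max)
  last <- tapply(ybox, col, function(b) b[length(b)])
  nc <- length(lo)
  if (nc > 1L) {
    prev <- last[-nc]
    lo[-1L] <- pmin(lo[-1L], prev)
    hi[-1L] <- pmax(hi[-1L], prev)
  }
  sum(hi - lo + 1)
}

#' Box-counting fractal dimension
#'
#' The graph is embedded in the unit square and occupied boxes N(eps) are
#' counted over a dyadic grid; the FD is the least-squares slope of
#' log N(eps) on log(1/eps). The `moisy` variant fits over all dyadic scales
#' with between 4 and N/4 boxes per side; the `mvdl` variant restricts the fit
#' to the middle half of those scales.
#'
#' @param x Numeric sequence, length >= 64 (enough for >= 4 dyadic scales).
#' @param variant `"moisy"` or `"mvdl"`.
#' @return An [fd_estimate()] with the per-scale counts in `diagnostics`.
#' @export
fd_boxcount <- function(x, variant = c("moisy", "mvdl")) {
  variant <- match.arg(variant)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 64L) stop("fd_boxcount needs length >= 64")
  r <- range(x)
  if (diff(r) == 0) stop("constant input: box-count FD undefined")
  ty <- list(t = (seq_len(n) - 1) / (n - 1), y = (x - r[1L]) / diff(r))
  ks <- 2^(2:floor(log2(n / 4)))
  if (length(ks) < 4L) stop("too few points for >= 4 dyadic scales")
  if (variant == "mvdl") {
    m <- length(ks)
    ks <- ks[max(1L, floor(m / 4) + 1L):ceiling(3 * m / 4)]
  }
  counts <- vapply(ks, function(k) .box_count(ty, as.integer(k)), numeric(1L))
  fit <- .ls_slope(log(ks), log(counts))
  fd_estimate("boxcount", fit$slope, params = list(variant = variant),
              fit = fit[c("r_squared", "points")],
              diagnostics = list(boxes_per_side = ks, counts = counts))
}

# ---- normalized length density (Kalauzi) -----------------------------------

.nld_of <- function(v) {
  r <- range(v)
  if (diff(r) == 0) return(0)
  mean(abs(diff((v - r[1L]) / diff(r))))
}

.nld_cache <- new.env(parent = emptyenv())

#' Calibrate the NLD-to-FD mapping on Weierstrass graphs
#'
#' The mapping from mean normalized length density (NLD) to fractal dimension
#' depends on the analysed length, so it is fitted here on synthetic
#' Weierstrass graphs of known dimension (D = 1.1..1.9) sampled at exactly
#' `n` points, with deterministic phases. Both maps are anchored at
#' NLD = 0 -> FD = 1: linear `FD = 1 + a * NLD` (fitted over, and valid for,
#' the low-dimension range FD <= 1.5 — it overestimates beyond), and
#' power-law `FD = 1 + a * NLD^b` (fitted over the whole range).
#' Results are cached per `n`.
#'
#' @param n Window/series length the calibration is fitted for.
#' @return List with `linear` (coefficient `a`) and `power` (`a`, `b`),
#'   plus the fitted `(nld, D)` design points.
#' @export
nld_calibration <- function(n) {
  key <- as.character(as.integer(n))
  if (!is.null(.nld_cache[[key]])) return(.nld_cache[[key]])
  Ds <- seq(1.1, 1.9, by = 0.1)
  pts <- do.call(rbind, lapply(Ds, function(D) {
    nlds <- vapply(1:3, function(s) {
      w <- gen_weierstrass(n, D = D, seed = 1000L + s)
      .nld_of(w)
    }, numeric(1L))
    cbind(nld = nlds, D = D)
  }))
  # per-dimension mean NLD; both maps anchored at NLD = 0 -> FD = 1
  x <- tapply(pts[, "nld"], pts[, "D"], mean)
  y <- Ds - 1
  # linear map fitted on the low-dimension half only (its validity range:
  # the NLD-dimension relation is close to linear there, then bends)
  low <- y <= 0.5 + 1e-9
  a_lin <- sum(x[low] * y[low]) / sum(x[low]^2)
  # power law fitted by direct least squares in dimension space (a grid over
  # the exponent with the closed-form prefactor), not in log space, so the
  # mid-range is not sacrificed to the extremes
  bs <- seq(0.2, 1.5, by = 0.005)
  sse <- vapply(bs, function(b) {
    xb <- x^b
    a <- sum(xb * y) / sum(xb^2)
    sum((y - a * xb)^2)
  }, numeric(1L))
  b <- bs[which.min(sse)]
  a_pow <- sum(x^b * y) / sum(x^(2 * b))
  cal <- list(linear = list(a = a_lin),
              power = list(a = a_pow, b = b),
              design = data.frame(nld = as.numeric(x), D = Ds),
              n = as.integer(n))
  .nld_cache[[key]] <- cal
  cal
}

#' Fractal dimension from normalized length density
#'
#' The series (or each window) is min-max amplitude-normalized; NLD is the
#' mean absolute successive difference; NLD is mapped to an FD through a
#' Weierstrass-fitted calibration ([nld_calibration()]), linear (`L`) or
#' power-law (`P`). The `w` variants compute the FD per non-overlapping
#' window and report the mean (the `_m` summaries); the `i` variants use the
#' whole series at once.
#'
#' @param x Numeric sequence, length >= 32.
#' @param variant `"wL"`, `"wP"`, `"iL"` or `"iP"`.
#' @param window Window length in samples for the `w` variants (default 128).
#' @return An [fd_estimate()].
#' @export
fd_nld <- function(x, variant = c("wL", "wP", "iL", "iP"), window = 128L) {
  variant <- match.arg(variant)
  x <- as.numeric(x)
  if (length(x) < 32L) stop("fd_nld needs length >= 32")
  if (diff(range(x)) == 0) stop("constant input: NLD FD undefined")
  windowed <- substr(variant, 1L, 1L) == "w"
  law <- substr(variant, 2L, 2L)
  map <- function(nld, cal) {
    if (nld <= 0) return(1)
    if (law == "L") 1 + cal$linear$a * nld
    else 1 + cal$power$a * nld^cal$power$b
  }
  if (windowed) {
    w <- min(as.integer(window), length(x))
    cal <- nld_calibration(w)
    starts <- seq.int(1L, length(x) - w + 1L, by = w)
    fds <- vapply(starts, function(s) map(.nld_of(x[s:(s + w - 1L)]), cal),
                  numeric(1L))
    fd_estimate("nld", mean(fds), params = list(variant = variant, window = w),
                diagnostics = list(per_window = fds))
  } else {
    cal <- nld_calibration(length(x))
    nld <- .nld_of(x)
    fd_estimate("nld", map(nld, cal),
                params = list(variant = variant),
                diagnostics = list(nld = nld))
  }
}

# flat-structuring-element dilation/erosion by iterated 3-sample max/min
.morph_covers <- function(x, smax) {
  n <- length(x)
  dil <- x; ero <- x
  A <- numeric(smax)
  for (s in seq_len(smax)) {
    dil <- pmax(dil, c(dil[-1L], dil[n]), c(dil[1L], dil[-n]))
    ero <- pmin(ero, c(ero[-1L], ero[n]), c(ero[1L], ero[-n]))
    A[s] <- sum(dil - ero)
  }
  A
}

#' Maragos morphological multiscale fractal dimension
#'
#' Morphological cover areas A(s) are obtained by dilating and eroding the
#' graph with a flat structuring element of half-width s samples; the local
#' fractal dimension over a sliding window of log-scales is the slope of
#' ln(A(s)/s^2) on ln(1/s). The multiscale profile is returned per scale
#' window and reduced to a single `mFD_M` summary (mean by default).
#'
#' @param x Numeric sequence, length >= 10 * max(scales).
#' @param scales Integer scales (half-widths, samples); at least 3.
#'   The default is approximately log-spaced, the usual choice for power-law
#'   slope fits (equal leverage per octave).
#' @param window Number of consecutive scales per local fit (default 5).
#' @param summary `"mean"`, `"median"` or `"max"` reduction of the profile.
#' @return An [fd_estimate()] whose value is the `mFD_M` summary, with the
#'   full `profile` and `A` in `diagnostics`.
#' @export
fd_maragos <- function(x, scales = c(3, 4, 6, 8, 11, 16, 23, 32, 45),
                       window = 5L,
                       summary = c("mean", "median", "max")) {
  summary <- match.arg(summary)
  x <- as.numeric(x)
  scales <- sort(unique(as.integer(scales)))
  if (length(scales) < 3L) stop("need at least 3 scales")
  if (length(x) < 10L * max(scales)) stop("fd_maragos needs length >= 10 * max(scales)")
  A <- .morph_covers(x, max(scales))[scales]
  if (any(A <= 0))
    return(fd_estimate("maragos", NA_real_, list(scales = scales),
                       diagnostics = list(undefined = TRUE)))
  ly <- log(A / scales^2)
  lx <- log(1 / scales)
  window <- min(as.integer(window), length(scales))
  nwin <- length(scales) - window + 1L
  profile <- vapply(seq_len(nwin), function(i) {
    idx <- i:(i + window - 1L)
    .ls_slope(lx[idx], ly[idx])$slope
  }, numeric(1L))
  val <- switch(summary, mean = mean(profile), median = stats::median(profile),
                max = max(profile))
  fd_estimate("maragos", val,
              params = list(scales = scales, window = window, summary = summary),
              diagnostics = list(profile = profile, A = A))
}
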