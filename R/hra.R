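# Lagged Poincaré descriptors and heart-rate-asymmetry indices.
#
# Convention used throughout: "up" = above the line of identity (LI) =
# decelerations (RR lengthening, x[i+1] > x[i]); "down" = below the LI =
# accelerations. Some literature writes these as "a"/"d" with the opposite
# pairing; the naming here follows the SDNNup/SD1up usage.

# intervals from event_series / numeric; resampled waveforms trigger a warning
# because beat-ordered asymmetry on an interpolated grid is conceptually dubious
.beat_values <- function(x) {
  if (inherits(x, "event_series")) return(x$intervals)
  if (inherits(x, "uniform_signal")) {
    warning("asymmetry/Poincaré indices on a resampled waveform; ",
            "beat order is interpolated, interpret with care")
    return(x$values)
  }
  as.numeric(x)
}

#' Lagged Poincaré summary
#'
#' Points P_i = (x_i, x_\{i+m\}). SD1 and SD2 are the sample standard
#' deviations (denominator n-1) of the transverse and longitudinal
#' coordinates (x_\{i+m\} -/+ x_i)/sqrt(2); SDNN is defined through the
#' identity SDNN^2 = (SD1^2 + SD2^2)/2; r is the Pearson correlation of the
#' two coordinates.
#'
#' @param x An [event_series()] (RR intervals, ms) or numeric vector.
#' @param m Lag, 1..7.
#' @return List of class `poincare_summary`: `m`, `SD1`, `SD2`, `SDNN`,
#'   `ratio` (SD2/SD1), `r`, `n_points`.
#' @export
lagged_poincare <- function(x, m = 1L) {
  v <- .beat_values(x)
  m <- as.integer(m)
  if (m < 1L || m > 7L) stop("lag m must be in 1..7")
  if (length(v) <= m + 2L) stop("series too short for lag ", m)
  a <- v[seq_len(length(v) - m)]
  b <- v[seq_len(length(v) - m) + m]
  sd1 <- stats::sd((b - a) / sqrt(2))
  sd2 <- stats::sd((b + a) / sqrt(2))
  r <- if (sd1 == 0 && sd2 == 0) NA_real_ else suppressWarnings(stats::cor(a, b))
  structure(list(m = m, SD1 = sd1, SD2 = sd2,
                 SDNN = sqrt((sd1^2 + sd2^2) / 2),
                 ratio = if (sd1 > 0) sd2 / sd1 else NA_real_,
                 r = r, n_points = length(a)),
            class = "poincare_summary")
}

#' @export
print.poincare_summary <- function(x, ...) {
  cat(sprintf("<poincare m=%d> SD1 = %.3f, SD2 = %.3f, SDNN = %.3f, r = %.3f (%d points)\n",
              x$m, x$SD1, x$SD2, x$SDNN, x$r, x$n_points))
  invisible(x)
}

#' Asymmetry decomposition of the lag-1 Poincaré plot
#'
#' Splits short- and long-term Poincaré variance into deceleration ("up",
#' above-LI) and acceleration ("down", below-LI) parts using second moments
#' about zero for SD1 and about the mean for SD2, with on-LI points excluded
#' from the SD1 split (their transverse distance is zero) and given half
#' weight to each side in the SD2 split. These conventions make the
#' conservation identities exact:
#' `SD1up^2 + SD1down^2 = SD1o^2`, `SD2up^2 + SD2down^2 = SD2o^2`,
#' `SDNNup^2 + SDNNdown^2 = SDNNo^2`, `C1a + C1d = 1`, `C2a + C2d = 1`,
#' where the `o` quantities are the corresponding whole-plot moments.
#'
#' @param x An [event_series()] or numeric vector of >= 3 intervals.
#' @return List of class `asymmetry_summary` with fields `d` (signed
#'   transverse distances, units/sqrt(2)), counts `n_up`, `n_down`, `n_on`,
#'   `SD1up`, `SD1down`, `SD2up`, `SD2down`, `SDNNup`, `SDNNdown`, `SD1o`,
#'   `SD2o`, `SDNNo`, and contributions `C1a`, `C1d`, `C2a`, `C2d`.
#' @export
asymmetry_decomposition <- function(x) {
  v <- .beat_values(x)
  if (length(v) < 3L) stop("need at least 3 intervals")
  a <- v[-length(v)]; b <- v[-1L]
  d <- (b - a) / sqrt(2)                 # transverse (signed) distance to LI
  e <- (b + a) / sqrt(2)                 # longitudinal coordinate
  up <- d > 0; down <- d < 0; on <- d == 0
  n <- length(d)
  if (all(on)) stop("all points on the line of identity: asymmetry undefined")
  sd1u2 <- sum(d[up]^2) / n
  sd1d2 <- sum(d[down]^2) / n
  sd1o2 <- sum(d^2) / n
  ec <- e - mean(e)
  sd2u2 <- (sum(ec[up]^2) + 0.5 * sum(ec[on]^2)) / n
  sd2d2 <- (sum(ec[down]^2) + 0.5 * sum(ec[on]^2)) / n
  sd2o2 <- sum(ec^2) / n
  structure(list(
    d = d, n_up = sum(up), n_down = sum(down), n_on = sum(on),
    SD1up = sqrt(sd1u2), SD1down = sqrt(sd1d2), SD1o = sqrt(sd1o2),
    SD2up = sqrt(sd2u2), SD2down = sqrt(sd2d2), SD2o = sqrt(sd2o2),
    SDNNup = sqrt((sd1u2 + sd2u2) / 2), SDNNdown = sqrt((sd1d2 + sd2d2) / 2),
    SDNNo = sqrt((sd1o2 + sd2o2) / 2),
    C1a = sd1u2 / sd1o2, C1d = sd1d2 / sd1o2,
    C2a = if (sd2o2 > 0) sd2u2 / sd2o2 else NA_real_,
    C2d = if (sd2o2 > 0) sd2d2 / sd2o2 else NA_real_),
    class = "asymmetry_summary")
}

#' @export
print.asymmetry_summary <- function(x, ...) {
  cat(sprintf(paste0("<asymmetry> up/down/on = %d/%d/%d\n",
                     "  SD1 up/down = %.3f/%.3f  SD2 up/down = %.3f/%.3f\n",
                     "  SDNN up/down = %.3f/%.3f  C1a = %.3f  C2a = %.3f\n"),
              x$n_up, x$n_down, x$n_on, x$SD1up, x$SD1down, x$SD2up, x$SD2down,
              x$SDNNup, x$SDNNdown, x$C1a, x$C2a))
  invisible(x)
}

#' Classical asymmetry indices: Ehlers, Guzik, Porta
#'
#' With successive differences Delta_i = x_\{i+1\} - x_i and transverse
#' distances d_i = Delta_i / sqrt(2):
#' Ehlers' index `EI = sum(Delta^3) / sum(Delta^2)^(3/2)` (a signed skewness
#' of interval changes); Guzik's index `GI` = 100 x (squared distance above
#' the LI) / (squared distance of all off-LI points); Porta's index `PI` =
#' 100 x (count below the LI) / (off-LI count). GI = PI = 50 for a
#' time-reversible series.
#'
#' @param x An [event_series()] or numeric vector of >= 3 intervals.
#' @return List with `EI`, `GI`, `PI`.
#' @export
classical_indices <- function(x) {
  v <- .beat_values(x)
  if (length(v) < 3L) stop("need at least 3 intervals")
  dl <- diff(v)
  if (all(dl == 0)) stop("all points on the line of identity")
  off <- dl != 0
  list(EI = sum(dl^3) / sum(dl^2)^1.5,
       GI = 100 * sum(dl[dl > 0]^2) / sum(dl[off]^2),
       PI = 100 * sum(dl < 0) / sum(off))
}

#' Slope and Area asymmetry indices
#'
#' Each Poincaré point (x_i, x_\{i+1\}) has an angular deviation theta_i from
#' the line of identity (the 45-degree line through the origin). The slope
#' index SI is 100 x (sum of |theta| above the LI) / (sum over all off-LI
#' points); the area index AI replaces |theta| with the circular-sector area
#' `A_i = r_i^2 |theta_i| / 2`, r_i the distance from the origin. Both are 50
#' for mirror-symmetric plots.
#'
#' @param x An [event_series()] or numeric vector of >= 4 intervals.
#' @return List with `SI`, `AI`.
#' @export
karmakar_indices <- function(x) {
  v <- .beat_values(x)
  if (length(v) < 4L) stop("need at least 4 intervals")
  a <- v[-length(v)]; b <- v[-1L]
  theta <- atan2(b, a) - pi / 4
  off <- theta != 0
  if (!any(off)) stop("all points on the line of identity")
  r2 <- a^2 + b^2
  A <- r2 * abs(theta) / 2
  list(SI = 100 * sum(abs(theta)[theta > 0]) / sum(abs(theta)[off]),
       AI = 100 * sum(A[theta > 0]) / sum(A[off]))
}

#' Asymmetric spread index
#'
#' ASI = 100 x sigma_up / (sigma_up + sigma_down), where sigma_up and
#' sigma_down are the root-mean-square transverse distances |d_i| of the
#' above- and below-LI point sets. 50 for mirror-symmetric plots; strictly
#' increasing in the spread of decelerations.
#'
#' @param x An [event_series()] or numeric vector of >= 4 intervals with
#'   off-LI points on both sides.
#' @return ASI in percent.
#' @export
asymmetric_spread_index <- function(x) {
  v <- .beat_values(x)
  if (length(v) < 4L) stop("need at least 4 intervals")
  d <- diff(v) / sqrt(2)
  up <- d[d > 0]; down <- d[d < 0]
  if (!length(up) || !length(down)) stop("one side of the identity line is empty")
  s_up <- sqrt(mean(up^2)); s_down <- sqrt(mean(down^2))
  100 * s_up / (s_up + s_down)
}

#' Complex correlation measure
#'
#' Temporal structure of the lag-m Poincaré plot: the mean absolute area of
#' the triangles through consecutive plot points, normalized by the plot's
#' characteristic area pi * SD1 * SD2. Zero when all plot points are
#' collinear; translation invariant.
#'
#' @param x An [event_series()] or numeric vector, length >= m + 4.
#' @param m Lag, 1..7.
#' @return CCM (unitless), or `NA` when SD1 * SD2 = 0.
#' @export
ccm <- function(x, m = 1L) {
  v <- .beat_values(x)
  m <- as.integer(m)
  if (length(v) < m + 4L) stop("series too short for lag ", m)
  ps <- lagged_poincare(v, m)
  if (!is.finite(ps$SD1 * ps$SD2) || ps$SD1 * ps$SD2 == 0) return(NA_real_)
  a <- v[seq_len(length(v) - m)]
  b <- v[seq_len(length(v) - m) + m]
  np <- length(a)
  i <- seq_len(np - 2L)
  # shoelace area of triangle (P_i, P_i+1, P_i+2)
  areas <- abs((a[i + 1L] - a[i]) * (b[i + 2L] - b[i]) -
               (a[i + 2L] - a[i]) * (b[i + 1L] - b[i])) / 2
  sum(areas) / (pi * ps$SD1 * ps$SD2 * (np - 2L))
}
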