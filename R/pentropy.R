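# Ordinal-pattern machinery and the permutation-entropy measure family:
# plain/normalized PE, amplitude-aware and edge PE, the composite index CPEI,
# the Jensen-Shannon statistical complexity, and multiscale variants.

# lexicographic rank (1-based) of permutation perm of 1..m, via the factorial
# number system
.perm_rank <- function(perm) {
  m <- length(perm)
  rank <- 0L
  fact <- cumprod(c(1, seq_len(m)))   # fact[k+1] = k!
  for (i in seq_len(m - 1L)) {
    smaller <- sum(perm[(i + 1L):m] < perm[i])
    rank <- rank + smaller * fact[m - i + 1L]   # fact[k+1] = k!
  }
  rank + 1L
}

#' Ordinal-pattern distribution
#'
#' Maps every delay window `(x_j, x_\{j+tau\}, ..., x_\{j+(m-1)tau\})` to the
#' permutation sorting its values ascending and counts patterns over all
#' `N - (m-1)tau` windows. Ties are broken by original position
#' (`"rank_by_order"`, the default) or diverted to a pooled tie slot
#' (`"tie_patterns"`, used by [cpei()]); for the latter, values closer than
#' `tie_threshold` count as tied.
#'
#' @param x Numeric sequence.
#' @param m Pattern order, 2..7.
#' @param tau Delay (lag), >= 1.
#' @param tie_policy `"rank_by_order"` or `"tie_patterns"`.
#' @param tie_threshold Tie tolerance for `"tie_patterns"` (default 0:
#'   exact ties only).
#' @return Object of class `ordinal_distribution`: `counts` (length m!,
#'   lexicographic pattern order, plus a final `"tie"` slot under
#'   `"tie_patterns"`), `m`, `tau`, `n_windows`, `tie_policy`.
#' @export
ordinal_patterns <- function(x, m = 3L, tau = 1L,
                             tie_policy = c("rank_by_order", "tie_patterns"),
                             tie_threshold = 0) {
  tie_policy <- match.arg(tie_policy)
  x <- as.numeric(x)
  m <- as.integer(m); tau <- as.integer(tau)
  if (m < 2L || m > 7L) stop("order m must be in 2..7")
  if (tau < 1L) stop("tau must be >= 1")
  span <- (m - 1L) * tau
  nw <- length(x) - span
  if (nw < 1L) stop("series too short: need length >= (m-1)*tau + 1")
  nm <- factorial(m)
  nslots <- nm + (tie_policy == "tie_patterns")
  counts <- integer(nslots)
  for (j in seq_len(nw)) {
    w <- x[j + tau * (0:(m - 1L))]
    if (tie_policy == "tie_patterns" &&
        min(diff(sort(w))) <= tie_threshold) {
      counts[nslots] <- counts[nslots] + 1L
    } else {
      idx <- .perm_rank(order(w))
      counts[idx] <- counts[idx] + 1L
    }
  }
  structure(list(counts = counts, m = m, tau = tau, n_windows = nw,
                 tie_policy = tie_policy, tie_threshold = tie_threshold),
            class = "ordinal_distribution")
}

#' @export
print.ordinal_distribution <- function(x, ...) {
  cat(sprintf("<ordinal_distribution> m = %d, tau = %d, %d windows over %d slots (%s)\n",
              x$m, x$tau, x$n_windows, length(x$counts), x$tie_policy))
  invisible(x)
}

.probs <- function(p) {
  if (inherits(p, "ordinal_distribution")) {
    if (p$n_windows < 1L) stop("empty ordinal distribution")
    list(pr = p$counts / p$n_windows, nstates = factorial(p$m))
  } else {
    pr <- as.numeric(p)
    if (!length(pr) || any(pr < 0)) stop("invalid probability vector")
    list(pr = pr / sum(pr), nstates = length(pr))
  }
}

.shannon <- function(pr) { pr <- pr[pr > 0]; -sum(pr * log(pr)) }

#' Entropy functionals over an ordinal distribution
#'
#' Shannon `H = -sum p ln p` (normalized by ln m!); Renyi
#' `ln(sum p^alpha)/(1-alpha)` (normalized by ln m!); Tsallis
#' `(1 - sum p^q)/(q-1)` (normalized by its maximum
#' `(1-(m!)^(1-q))/(q-1)`); min-entropy `-ln(max p)/ln(m!)`.
#'
#' @param p An [ordinal_patterns()] result, or a probability vector (then the
#'   number of states is its length).
#' @param family `"shannon"`, `"renyi"`, `"tsallis"` or `"min"`.
#' @param alpha Renyi order (!= 1), default 2.
#' @param q Tsallis order (!= 1), default 2.
#' @param normalize Normalize to \[0, 1\] (default TRUE).
#' @return Entropy value.
#' @export
entropy_functional <- function(p, family = c("shannon", "renyi", "tsallis", "min"),
                               alpha = 2, q = 2, normalize = TRUE) {
  family <- match.arg(family)
  pp <- .probs(p)
  pr <- pp$pr; ns <- pp$nstates
  val <- switch(family,
    shannon = .shannon(pr),
    renyi = {
      if (alpha == 1) stop("alpha must differ from 1 (use shannon)")
      log(sum(pr[pr > 0]^alpha)) / (1 - alpha)
    },
    tsallis = {
      if (q == 1) stop("q must differ from 1 (use shannon)")
      (1 - sum(pr[pr > 0]^q)) / (q - 1)
    },
    min = -log(max(pr)))
  if (!normalize) return(val)
  denom <- switch(family,
    tsallis = (1 - ns^(1 - q)) / (q - 1),
    log(ns))
  val / denom
}

#' Normalized permutation entropy
#'
#' Convenience wrapper: Shannon entropy of [ordinal_patterns()] normalized by
#' ln(m!). 0 for a monotone series, ~1 for i.i.d. noise.
#'
#' @inheritParams ordinal_patterns
#' @return Normalized PE in \[0, 1\].
#' @export
permutation_entropy <- function(x, m = 3L, tau = 1L) {
  entropy_functional(ordinal_patterns(x, m, tau), "shannon")
}

# generic weighted ordinal Shannon entropy, normalized by ln(m!)
.weighted_pe <- function(x, m, tau, weight_fn) {
  x <- as.numeric(x)
  m <- as.integer(m); tau <- as.integer(tau)
  span <- (m - 1L) * tau
  nw <- length(x) - span
  if (nw < 1L) stop("series too short")
  nm <- factorial(m)
  wsum <- numeric(nm)
  for (j in seq_len(nw)) {
    w <- x[j + tau * (0:(m - 1L))]
    idx <- .perm_rank(order(w))
    wsum[idx] <- wsum[idx] + weight_fn(w)
  }
  tot <- sum(wsum)
  if (tot <= 0) stop("zero total pattern weight")
  .shannon(wsum / tot) / log(nm)
}

#' Amplitude-aware permutation entropy
#'
#' Pattern probabilities are weighted per window by
#' `A * mean(|values|) + (1 - A) * mean(|successive differences|)`, computed
#' on the z-scored series so both terms share a scale, then fed through the
#' normalized Shannon formula. Reduces to plain PE when all windows carry
#' equal weight.
#'
#' @inheritParams ordinal_patterns
#' @param A Mixing weight in \[0, 1\] between mean absolute amplitude and mean
#'   absolute increment (default 0.5).
#' @return Normalized AAPE in \[0, 1\].
#' @export
aape <- function(x, m = 3L, tau = 1L, A = 0.5) {
  if (A < 0 || A > 1) stop("A must be in [0, 1]")
  x <- as.numeric(x)
  if (stats::sd(x) == 0) stop("constant input")
  z <- (x - mean(x)) / stats::sd(x)
  .weighted_pe(z, m, tau, function(w)
    A * mean(abs(w)) + (1 - A) * mean(abs(diff(w))))
}

#' Edge permutation entropy
#'
#' Pattern probabilities weighted by the window's total edge magnitude (sum of
#' absolute successive differences); equals plain PE when all windows have
#' equal edge weight; up-weights patterns carrying large excursions.
#'
#' @inheritParams ordinal_patterns
#' @return Normalized EPE in \[0, 1\].
#' @export
edge_pe <- function(x, m = 3L, tau = 1L) {
  x <- as.numeric(x)
  if (all(diff(x) == 0)) stop("constant series: all edges zero")
  .weighted_pe(x, m, tau, function(w) sum(abs(diff(w))))
}

#' Composite permutation entropy index
#'
#' Order-3 ordinal distributions at lags 1 and 2 with near-equal neighbours
#' (difference <= `tie_threshold`) diverted to a pooled tie pattern; the two
#' count vectors are pooled by summation and the Shannon entropy of the
#' pooled distribution is normalized by ln(3!).
#'
#' @param x Numeric sequence, length >= 50.
#' @param tie_threshold Tie tolerance in signal units (default 0).
#' @return CPEI, ~0 for a ramp, ~1 for i.i.d. noise.
#' @export
cpei <- function(x, tie_threshold = 0) {
  x <- as.numeric(x)
  if (length(x) < 50L) stop("cpei needs length >= 50")
  d1 <- ordinal_patterns(x, 3L, 1L, "tie_patterns", tie_threshold)
  d2 <- ordinal_patterns(x, 3L, 2L, "tie_patterns", tie_threshold)
  counts <- d1$counts + d2$counts
  .shannon(counts / sum(counts)) / log(factorial(3))
}

#' Jensen-Shannon statistical complexity of an ordinal distribution
#'
#' `C = Q_J * H_S`: H_S is the normalized Shannon permutation entropy and Q_J
#' the Jensen-Shannon divergence between the pattern distribution and the
#' uniform distribution over the m! patterns, divided by its maximum (attained
#' by a point mass). Zero both for the uniform and for a single-pattern
#' distribution.
#'
#' @param p An [ordinal_patterns()] result or probability vector.
#' @return Complexity C >= 0.
#' @export
pjsc <- function(p) {
  pp <- .probs(p)
  pr <- pp$pr; ns <- pp$nstates
  if (length(pr) > ns) {            # fold any tie slot back: complexity is
    pr <- pr[seq_len(ns)]           # defined over the m! patterns
    if (sum(pr) == 0) return(0)
    pr <- pr / sum(pr)
  }
  u <- rep(1 / ns, ns)
  jsd <- function(a, b) .shannon((a + b) / 2) - .shannon(a) / 2 - .shannon(b) / 2
  delta <- c(1, rep(0, ns - 1L))
  q_j <- jsd(pr, u) / jsd(delta, u)
  h_s <- .shannon(pr) / log(ns)
  q_j * h_s
}

#' Coarse-grain a series
#'
#' Non-overlapping means of `s` consecutive samples (multiscale-entropy
#' graining); output length `floor(N/s)`.
#'
#' @param x Numeric sequence, length >= 2s.
#' @param s Integer scale >= 1.
#' @return Numeric vector of block means.
#' @export
coarse_grain <- function(x, s) {
  x <- as.numeric(x)
  s <- as.integer(s)
  if (s < 1L) stop("scale must be >= 1")
  if (length(x) < 2L * s) stop("series too short for scale ", s)
  nb <- length(x) %/% s
  colMeans(matrix(x[seq_len(nb * s)], nrow = s))
}

#' Multiscale permutation entropy
#'
#' `mPE`: normalized PE of the coarse-grained series at each scale. `ImPE`
#' (improved/refined): at each scale the ordinal distributions over all `s`
#' coarse-graining offsets are averaged before taking one entropy. `mPM_E`:
#' the min-entropy functional applied to the coarse-grained series.
#'
#' @inheritParams ordinal_patterns
#' @param scales Integer scales (default 1:5).
#' @param variant `"mPE"`, `"ImPE"` or `"mPM_E"`.
#' @return Named numeric vector, one value per scale.
#' @export
multiscale_pe <- function(x, m = 3L, tau = 1L, scales = 1:5,
                          variant = c("mPE", "ImPE", "mPM_E")) {
  variant <- match.arg(variant)
  x <- as.numeric(x)
  scales <- as.integer(scales)
  need <- 2L * max(scales) * ((m - 1L) * tau + 1L)
  if (length(x) < need) stop("series too short for scale ", max(scales))
  out <- vapply(scales, function(s) {
    if (variant == "ImPE") {
      prs <- lapply(0:(s - 1L), function(o) {
        cg <- coarse_grain(x[(o + 1L):length(x)], s)
        d <- ordinal_patterns(cg, m, tau)
        d$counts / d$n_windows
      })
      pbar <- Reduce(`+`, prs) / length(prs)
      .shannon(pbar) / log(factorial(m))
    } else {
      cg <- coarse_grain(x, s)
      d <- ordinal_patterns(cg, m, tau)
      if (variant == "mPE") entropy_functional(d, "shannon")
      else entropy_functional(d, "min")
    }
  }, numeric(1L))
  names(out) <- as.character(scales)
  out
}
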