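# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths (naive loops, string-keyed tables).

# all permutations of 1..m in lexicographic order, built recursively
all_perms <- function(m) {
  if (m == 1L) return(matrix(1L, 1L, 1L))
  out <- NULL
  for (first in seq_len(m)) {
    rest <- all_perms(m - 1L)
    rest_vals <- setdiff(seq_len(m), first)
    out <- rbind(out, cbind(first, matrix(rest_vals[rest], nrow(rest))))
  }
  unname(out)
}

# naive ordinal-pattern counter keyed by the pattern string
naive_ordinal_counts <- function(x, m, tau) {
  perms <- all_perms(m)
  keys <- apply(perms, 1L, paste, collapse = "-")
  counts <- stats::setNames(integer(length(keys)), keys)
  nw <- length(x) - (m - 1L) * tau
  for (j in seq_len(nw)) {
    w <- x[j + tau * (0:(m - 1L))]
    k <- paste(order(w), collapse = "-")
    counts[k] <- counts[k] + 1L
  }
  unname(counts)
}

# naive Higuchi curve lengths, direct triple loop
naive_higuchi_L <- function(x, kmax) {
  n <- length(x)
  L <- numeric(kmax)
  for (k in seq_len(kmax)) {
    Lm <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      s <- 0
      for (i in 2:length(idx)) s <- s + abs(x[idx[i]] - x[idx[i - 1L]])
      Lm[m] <- s * (n - 1) / ((length(idx) - 1L) * k) / k
    }
    L[k] <- mean(Lm)
  }
  L
}

# brute-force box occupancy on a k x k grid: per box, scan every sample and
# the column-boundary carry-over explicitly
naive_box_count <- function(x, k) {
  n <- length(x)
  tt <- (seq_len(n) - 1) / (n - 1)
  yy <- (x - min(x)) / diff(range(x))
  col <- pmin(floor(tt * k), k - 1)
  ybox <- pmin(floor(yy * k), k - 1)
  occupied <- 0L
  for (cx in 0:(k - 1)) {
    in_col <- which(col == cx)
    if (!length(in_col)) next
    span <- ybox[in_col]
    prev <- in_col[1L] - 1L           # last sample of the previous column
    if (prev >= 1L) span <- c(span, ybox[prev])
    for (cy in 0:(k - 1))
      if (cy >= min(span) && cy <= max(span)) occupied <- occupied + 1L
  }
  occupied
}

# log-log periodogram slope over a mid-band, for noise-colour checks
psd_slope <- function(x, lo = 0.01, hi = 0.2) {
  sp <- stats::spec.pgram(x, plot = FALSE, taper = 0, detrend = TRUE)
  mid <- sp$freq > lo & sp$freq < hi
  unname(stats::lsfit(log(sp$freq[mid]), log(sp$spec[mid]))$coefficients[2L])
}

# deterministic little RR series around 1000 ms for property loops
random_rri <- function(n, seed) {
  set.seed(seed)
  1000 + stats::rnorm(n, 0, 25)
}
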