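# Nonparametric repeated-measures pipeline: Friedman + Kendall's W, Conover
# all-pairs post-hoc, consistency ICC, Mann-Whitney effect sizes, direction
# counts, robust descriptors, divide-by-maximum standardisation with
# top-slicing, parameter-tuning strategies and Spearman correlation.

.block_matrix <- function(data) {
  m <- as.matrix(data)
  if (!is.numeric(m)) stop("data must be numeric")
  if (anyNA(m)) stop("missing cells are not supported")
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need >= 2 blocks and >= 2 treatments")
  m
}

#' Friedman test with Kendall's W effect size
#'
#' One-way repeated-measures analysis of variance by ranks: within-block
#' midranks, tie-corrected chi-square statistic on k-1 degrees of freedom,
#' and Kendall's coefficient of concordance `W = chi2 / (N (k-1))`
#' (0.1 small, 0.3 medium, > 0.5 strong).
#'
#' @param data Blocks x treatments numeric matrix/data frame (no missing
#'   cells), e.g. participants x trials.
#' @return List of class `friedman_result`: `chi2`, `df`, `p`, `kendall_w`,
#'   `n_blocks`, `k`.
#' @export
friedman_kendall <- function(data) {
  m <- .block_matrix(data)
  ft <- stats::friedman.test(m)
  n <- nrow(m); k <- ncol(m)
  if (is.nan(ft$statistic)) {          # every block fully tied: no evidence
    ft$statistic[] <- 0
    ft$p.value <- 1
  }
  structure(list(chi2 = unname(ft$statistic), df = unname(ft$parameter),
                 p = ft$p.value,
                 kendall_w = unname(ft$statistic) / (n * (k - 1)),
                 n_blocks = n, k = k),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("<friedman> chi2(%d) = %.3f, p = %.3g, Kendall's W = %.3f (N = %d, k = %d)\n",
              x$df, x$chi2, x$p, x$kendall_w, x$n_blocks, x$k))
  invisible(x)
}

#' Conover all-pairs post-hoc test after Friedman
#'
#' For within-block midrank sums R_j, the pairwise statistic is
#' `S = |R_i - R_j| / sqrt(2 N (A1 - B1) / ((N-1)(k-1)))` with
#' `A1 = sum of all squared ranks` and `B1 = (1/N) sum_j R_j^2`, referred to a
#' t distribution on (N-1)(k-1) degrees of freedom (Conover 1999). Perfectly
#' concordant rankings make the denominator zero and S infinite, as in the
#' underlying theory. p-values are Bonferroni-adjusted over the reported
#' pairs; `standardized_S` divides each S by the maximum over the reported
#' set, so the best pair scores 1.
#'
#' @param data Blocks x treatments matrix (k >= 3).
#' @param pairs Optional 2-column character matrix of treatment pairs;
#'   default all pairs.
#' @return Data frame of class `posthoc_result` with columns `pair_a`,
#'   `pair_b`, `S`, `p_adj`, `standardized_S`.
#' @export
conover_posthoc <- function(data, pairs = NULL) {
  m <- .block_matrix(data)
  n <- nrow(m); k <- ncol(m)
  if (k < 3L) stop("Conover post-hoc needs k >= 3 treatments")
  labels <- colnames(m)
  if (is.null(labels)) labels <- as.character(seq_len(k))
  r <- t(apply(m, 1L, rank))
  R <- colSums(r)
  A1 <- sum(r^2)
  B1 <- sum(R^2) / n
  se <- sqrt(2 * n * (A1 - B1) / ((n - 1) * (k - 1)))
  if (is.null(pairs)) {
    cmb <- utils::combn(labels, 2L)
    pairs <- cbind(cmb[1L, ], cmb[2L, ])
  }
  S <- vapply(seq_len(nrow(pairs)), function(i) {
    d <- abs(R[match(pairs[i, 1L], labels)] - R[match(pairs[i, 2L], labels)])
    if (se == 0) { if (d == 0) 0 else Inf } else d / se
  }, numeric(1L))
  df <- (n - 1) * (k - 1)
  p <- pmin(1, 2 * stats::pt(-abs(S), df) * nrow(pairs))   # Bonferroni
  smax <- max(S)
  out <- data.frame(pair_a = pairs[, 1L], pair_b = pairs[, 2L], S = S,
                    p_adj = p,
                    standardized_S = if (is.finite(smax) && smax > 0) S / smax
                                     else as.numeric(S == max(S)),
                    stringsAsFactors = FALSE)
  class(out) <- c("posthoc_result", "data.frame")
  out
}

#' Consistency intraclass correlation, ICC(3,1)
#'
#' Two-way mixed model, single measures, consistency form:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE)` from the two-way ANOVA
#' decomposition (rows = targets, columns = raters/durations). Adding a
#' constant to one column does not change it.
#'
#' @param data Targets x raters numeric matrix (>= 2 rows, >= 2 columns).
#' @return ICC value.
#' @export
icc_consistency <- function(data) {
  m <- .block_matrix(data)
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  ssr <- k * sum((rowMeans(m) - gm)^2)
  ssc <- n * sum((colMeans(m) - gm)^2)
  sst <- sum((m - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr + (k - 1) * mse == 0) stop("degenerate data: no variance")
  (msr - mse) / (msr + (k - 1) * mse)
}

#' Mann-Whitney U with tie-corrected Z and effect size
#'
#' Midrank U statistic for the first sample; Z from the normal approximation
#' with tie correction and no continuity correction; effect size
#' `ES = |Z| / sqrt(n_a + n_b)`.
#'
#' @param a,b Numeric samples.
#' @return List with `U`, `Z`, `ES`, `n`.
#' @export
mannwhitney_es <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  na <- length(a); nb <- length(b); n <- na + nb
  rk <- rank(c(a, b))
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  Z <- if (sigma2 > 0) (U - na * nb / 2) / sqrt(sigma2) else 0
  list(U = U, Z = Z, ES = abs(Z) / sqrt(n), n = n)
}

#' Paired direction counts between two conditions
#'
#' Counts per-participant increases/decreases/no-changes between two paired
#' conditions. The change is called consistent when the proportion of
#' increases exceeds 0.795 or falls below 0.205 — for 44 participants, 35 or
#' more increases, or 9 or fewer (binomial p < 1e-3).
#'
#' @param before,after Paired per-participant values.
#' @param upper,lower Consistency cut points on the proportion of increases
#'   (defaults 0.795 and 0.205).
#' @return List with `ups`, `downs`, `zeros`, `proportion`, `consistent`,
#'   `degenerate` (all differences zero).
#' @export
direction_counts <- function(before, after, upper = 0.795, lower = 0.205) {
  before <- as.numeric(before); after <- as.numeric(after)
  if (length(before) != length(after)) stop("paired samples must have equal length")
  d <- after - before
  n <- length(d)
  ups <- sum(d > 0); downs <- sum(d < 0); zeros <- sum(d == 0)
  prop <- ups / n
  list(ups = ups, downs = downs, zeros = zeros, proportion = prop,
       consistent = (prop > upper || prop < lower) && zeros < n,
       degenerate = zeros == n)
}

#' Robust coefficient of variation and robust slope
#'
#' `RoCV = 1.4826 MAD(x) / |median(x)|`; `RoSlope` is the Theil-Sen median of
#' pairwise slopes of `x` against its sample index. For series longer than
#' 2000 samples the exact O(n^2) Theil-Sen estimate is computed on an evenly
#' thinned subsequence of 2000 points.
#'
#' @param x Numeric sample, n >= 3.
#' @return List with `RoCV`, `RoSlope`.
#' @export
robust_descriptors <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L) stop("need n >= 3")
  med <- stats::median(x)
  if (med == 0) stop("zero median: RoCV undefined")
  n <- length(x)
  idx <- if (n > 2000L) round(seq(1L, n, length.out = 2000L)) else seq_len(n)
  xi <- x[idx]
  slopes <- outer(xi, xi, `-`) / outer(idx, idx, `-`)
  list(RoCV = stats::mad(x) / abs(med),
       RoSlope = stats::median(slopes[lower.tri(slopes)]))
}

#' Divide-by-maximum standardisation with top-slicing
#'
#' Standardizes a set of per-measure statistics by the maximum over the set
#' and retains those reaching `threshold` (default 0.8). The maximum always
#' standardizes to 1 and is always retained.
#'
#' @param values Named (or unnamed) nonnegative statistics, at least one
#'   positive.
#' @param threshold Retention cut on the standardized value (default 0.8).
#' @return List with `standardized` and `retained` (names or indices).
#' @export
standardize_topslice <- function(values, threshold = 0.8) {
  v <- as.numeric(values)
  if (all(!is.finite(v) | v <= 0)) stop("need at least one positive value")
  std <- v / max(v, na.rm = TRUE)
  names(std) <- names(values)
  keep <- which(std >= threshold)
  list(standardized = std,
       retained = if (!is.null(names(values))) names(values)[keep] else keep)
}

#' Parameter tuning over a swept grid
#'
#' Four group strategies for choosing an estimator parameter from a swept
#' grid, given per-participant measure values at two trials (e.g. Baseline
#' vs RBR):
#' s2 — greatest robust CV of the pooled values; s3 — greatest absolute
#' difference of group medians; s4 — greatest absolute median of paired
#' differences; s5 — most per-participant maximal-difference wins. The
#' consensus is the modal selection; an unresolved mode falls back to the
#' strategy whose increase/decrease ratio (at its selected parameter) is
#' farthest from 1.0, and reports `"ambiguous"` if that still does not
#' discriminate.
#'
#' @param trial_a,trial_b Participants x parameters numeric matrices with
#'   identical column names (the parameter grid).
#' @return List of class `tuning_report`: `selected` (named per strategy),
#'   `ratios`, `consensus`.
#' @export
tune_parameter <- function(trial_a, trial_b) {
  a <- as.matrix(trial_a); b <- as.matrix(trial_b)
  if (!is.numeric(a) || !is.numeric(b) || anyNA(a) || anyNA(b))
    stop("grids must be complete numeric matrices")
  if (!identical(dim(a), dim(b))) stop("grids must have identical dimensions")
  if (ncol(a) < 2L) stop("grid must have at least 2 parameters")
  grid <- colnames(a)
  if (is.null(grid)) grid <- as.character(seq_len(ncol(a)))
  rocv <- function(v) { m <- stats::median(v); if (m == 0) 0 else stats::mad(v) / abs(m) }
  s2 <- grid[which.max(vapply(seq_along(grid),
          function(j) rocv(c(a[, j], b[, j])), numeric(1L)))]
  s3 <- grid[which.max(abs(apply(a, 2L, stats::median) -
                           apply(b, 2L, stats::median)))]
  d <- a - b
  s4 <- grid[which.max(abs(apply(d, 2L, stats::median)))]
  wins <- table(factor(grid[apply(abs(d), 1L, which.max)], levels = grid))
  s5 <- grid[which.max(wins)]
  selected <- c(s2 = s2, s3 = s3, s4 = s4, s5 = s5)
  ratios <- vapply(selected, function(p) {
    dj <- a[, match(p, grid)] - b[, match(p, grid)]
    ups <- sum(dj > 0); downs <- sum(dj < 0)
    if (downs == 0) Inf else ups / downs
  }, numeric(1L))
  tab <- sort(table(selected), decreasing = TRUE)
  consensus <- if (length(tab) == 1L || tab[1L] > tab[2L]) names(tab)[1L]
  else {
    dist1 <- abs(log(ratios))                 # symmetric distance from ratio 1
    best <- which(dist1 == max(dist1))
    cand <- unique(selected[best])
    if (length(cand) == 1L) cand else "ambiguous"
  }
  structure(list(selected = selected, ratios = ratios, consensus = consensus),
            class = "tuning_report")
}

#' @export
print.tuning_report <- function(x, ...) {
  cat("<tuning_report>\n")
  for (s in names(x$selected))
    cat(sprintf("  %s -> %s (up/down ratio %.3g)\n", s, x$selected[[s]],
                x$ratios[[s]]))
  cat("  consensus:", x$consensus, "\n")
  invisible(x)
}

#' Spearman rank correlation (midranks)
#'
#' @param a,b Equal-length samples, n >= 3, non-constant.
#' @return rho.
#' @export
spearman_rho <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 3L) stop("need equal lengths >= 3")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("constant input")
  stats::cor(rank(a), rank(b))
}
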