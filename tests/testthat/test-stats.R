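test_that("Friedman + Kendall's W on hand-ranked and degenerate tables", {
  ident <- matrix(c(1, 2, 3, 1.5, 2.5, 3.5, 0.9, 2.1, 3.3), 3, 3, byrow = TRUE)
  f <- friedman_kendall(ident)           # rank sums 3, 6, 9
  expect_equal(f$chi2, 6, tolerance = 1e-12)
  expect_equal(f$kendall_w, 1, tolerance = 1e-12)
  expect_lt(abs(f$p - 0.0498), 1e-4)
  expect_equal(f$df, 2)

  z <- friedman_kendall(matrix(5, 4, 3))
  expect_equal(z$chi2, 0); expect_equal(z$kendall_w, 0)

  # invariance under within-block monotone transforms
  set.seed(26)
  m <- matrix(rnorm(44 * 7), 44, 7)
  expect_equal(friedman_kendall(exp(m))$chi2, friedman_kendall(m)$chi2,
               tolerance = 1e-12)
  expect_error(friedman_kendall(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("Friedman type-I error is calibrated under an exchangeable null", {
  set.seed(27)
  rej <- mean(replicate(2000, friedman_kendall(matrix(rnorm(44 * 7), 44, 7))$p < 0.05))
  expect_lt(abs(rej - 0.05), 0.02)
})

test_that("Conover post-hoc matches a from-scratch hand computation", {
  m <- matrix(c(1, 2, 3, 1.5, 2.5, 3.5, 0.9, 2.6, 2.1), 3, 3, byrow = TRUE)
  cp <- conover_posthoc(m)
  # hand: ranks rows (1,2,3),(1,2,3),(1,3,2); R = (3,7,8); A1 = 42
  R <- c(3, 7, 8); A1 <- 42; B1 <- sum(R^2) / 3
  se <- sqrt(2 * 3 * (A1 - B1) / (2 * 2))
  expect_equal(cp$S, abs(c(R[1] - R[2], R[1] - R[3], R[2] - R[3])) / se,
               tolerance = 1e-12)
  expect_equal(max(cp$standardized_S), 1)
  expect_equal(cp$p_adj,
               pmin(1, 2 * 3 * pt(-cp$S, df = 4)), tolerance = 1e-12)

  ident <- matrix(c(1, 2, 3, 1.5, 2.5, 3.5, 0.9, 2.1, 3.3), 3, 3, byrow = TRUE)
  ci <- conover_posthoc(ident)           # fully concordant: extreme pair maximal
  expect_true(all(ci$standardized_S <= 1))
  expect_equal(ci$standardized_S[ci$pair_a == "1" & ci$pair_b == "3"], 1)
  expect_error(conover_posthoc(matrix(1:4, 2, 2)), "k >= 3")
})

test_that("consistency ICC: duplicates, offsets, independent noise", {
  expect_equal(icc_consistency(cbind(1:10, 1:10)), 1)
  expect_equal(icc_consistency(cbind(1:10, (1:10) + 7)), 1)  # offset-blind
  x <- 1:10
  expect_equal(icc_consistency(cbind(x, x + rnorm(10, 0, 1e-8))), 1,
               tolerance = 1e-6)
  set.seed(28)
  noise <- cbind(rnorm(100), rnorm(100))
  expect_lt(abs(icc_consistency(noise)), 0.15)
})

test_that("Mann-Whitney effect size follows the normal approximation", {
  r <- mannwhitney_es(1:3, 4:6)
  expect_equal(r$U, 0)
  expect_equal(r$Z, (0 - 4.5) / sqrt(5.25), tolerance = 1e-6)
  expect_equal(r$ES, 1.964 / sqrt(6), tolerance = 1e-3)
  same <- mannwhitney_es(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$Z, 0); expect_equal(same$ES, 0)
  set.seed(29)
  a <- rnorm(30); b <- rnorm(25, 0.5)
  expect_equal(mannwhitney_es(exp(a), exp(b))$ES, mannwhitney_es(a, b)$ES,
               tolerance = 1e-12)
})

test_that("direction counts apply the 0.795/0.205 consistency rule", {
  up35 <- direction_counts(rep(0, 44), c(rep(1, 35), rep(-1, 9)))
  expect_equal(up35$proportion, 35 / 44, tolerance = 1e-12)
  expect_true(up35$consistent)                     # 0.7955 > 0.795
  up34 <- direction_counts(rep(0, 44), c(rep(1, 34), rep(-1, 10)))
  expect_false(up34$consistent)                    # 0.7727
  down9 <- direction_counts(rep(0, 44), c(rep(1, 9), rep(-1, 35)))
  expect_true(down9$consistent)                    # 9/44 = 0.2045 < 0.205
  zero <- direction_counts(1:5, 1:5)
  expect_true(zero$degenerate); expect_false(zero$consistent)
  expect_error(direction_counts(1:3, 1:4), "equal length")
})

test_that("robust descriptors: constants, exact slopes, monotone EDA", {
  expect_equal(robust_descriptors(c(7, 7, 7.0001))$RoSlope, 0, tolerance = 1e-3)
  lin <- robust_descriptors(seq(100, 2, by = -2))
  expect_equal(lin$RoSlope, -2, tolerance = 1e-12)
  expect_equal(robust_descriptors(rep(c(10, 12), 10))$RoCV,
               mad(rep(c(10, 12), 10)) / 11, tolerance = 1e-12)
  eda <- gen_eda(300, scr_rate = 0, seed = 30, noise_sd = 0)
  expect_lt(robust_descriptors(eda$values)$RoSlope, 0)
  expect_error(robust_descriptors(c(-1, 0, 1)), "median")
})

test_that("top-slice standardisation divides by the maximum", {
  st <- standardize_topslice(c(a = 5, b = 10, c = 15, d = 20))
  expect_equal(unname(st$standardized), c(0.25, 0.5, 0.75, 1))
  expect_equal(st$retained, "d")
  # printed-table arithmetic: 12.829 / 15.841 and 15.151 / 15.841
  s2 <- standardize_topslice(c(x = 12.829, y = 15.151, z = 15.841))
  expect_lt(abs(s2$standardized[["x"]] - 0.809), 0.001)
  expect_lt(abs(s2$standardized[["y"]] - 0.956), 0.001)
  expect_true("z" %in% s2$retained)                # max always retained
  expect_error(standardize_topslice(c(0, -2)), "positive")
})

test_that("parameter tuning strategies and the sign-ratio arbiter", {
  set.seed(31)
  a <- matrix(rnorm(40, 10), 10, 4, dimnames = list(NULL, paste0("k", 1:4)))
  b <- a; b[, 3] <- b[, 3] + 2                     # k3 dominates every criterion
  tr <- tune_parameter(a, b)
  expect_true(all(tr$selected == "k3"))
  expect_equal(tr$consensus, "k3")

  one <- matrix(c(1, 5, 2), 1, 3, dimnames = list(NULL, c("p1", "p2", "p3")))
  two <- matrix(c(0, 1, 0), 1, 3, dimnames = list(NULL, c("p1", "p2", "p3")))
  t1 <- tune_parameter(one, two)                   # single participant:
  expect_equal(unname(t1$selected["s4"]), unname(t1$selected["s3"]))
  # constructed disagreement: q1 wins the per-participant-maxima and pooled-RoCV
  # strategies (big balanced swings), q2 wins both median strategies (small
  # unidirectional shift); the 2-2 mode is resolved by the up/down ratio,
  # which is 2/2 = 1 at q1 and 4/0 at q2 -> farthest from 1 -> q2
  a2 <- matrix(c(10, 10.5, 10, 10.5, 10, 10.5, 10, 10.5), 4, 2, byrow = TRUE,
               dimnames = list(NULL, c("q1", "q2")))
  b2 <- matrix(c(7, 10, 13, 10, 7, 10, 13, 10), 4, 2, byrow = TRUE,
               dimnames = list(NULL, c("q1", "q2")))
  t2 <- tune_parameter(a2, b2)
  expect_equal(unname(t2$selected["s5"]), "q1")
  expect_equal(unname(t2$selected["s3"]), "q2")
  expect_equal(unname(t2$selected["s4"]), "q2")
  expect_equal(t2$consensus, "q2")
  expect_error(tune_parameter(a2[, 1, drop = FALSE], b2[, 1, drop = FALSE]),
               "2 parameters")
})

test_that("Spearman rho uses midranks", {
  expect_equal(spearman_rho(1:5, c(10, 20, 30, 40, 50)), 1)
  expect_equal(spearman_rho(1:5, 5:1), -1)
  a <- c(1, 2, 2, 3, 4)                            # tie -> midranks (1, 2.5, 2.5, 4, 5)
  b <- c(2, 1, 4, 3, 5)
  expect_equal(spearman_rho(a, b),
               cor(c(1, 2.5, 2.5, 4, 5), c(2, 1, 4, 3, 5)), tolerance = 1e-12)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})
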