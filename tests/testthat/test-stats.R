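test_that("summary statistics match a sorted-array quantile oracle", {
  s <- summarizeVGF(c(0.1, 0.2, 0.3))
  expect_equal(s$median, 0.2)
  expect_equal(c(s$min, s$max), c(0.1, 0.3))

  s2 <- summarizeVGF(rep(0.25, 8))
  expect_equal(s2$q75 - s2$q25, 0)

  set.seed(41)
  x <- rbeta(106, 2, 6)
  s3 <- summarizeVGF(x)
  # independent oracle: linear-interpolation quantile from the sorted array
  xs <- sort(x); n <- length(xs)
  qo <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, n)] - xs[lo])
  }
  expect_equal(s3$median, qo(0.5), tolerance = 1e-12)
  expect_equal(s3$q25, qo(0.25), tolerance = 1e-12)
  expect_equal(s3$q75, qo(0.75), tolerance = 1e-12)
})

test_that("normality testing: skew rejects, null mostly passes, degenerate fails", {
  set.seed(42)
  skewed <- exp(rnorm(100))
  expect_lt(normalityTest(skewed)$p, 0.05)

  # at the nominal 5% level the pass rate over seeds is itself binomial;
  # bound it by the 99% binomial quantile rather than the point value
  rejects <- vapply(1:200, function(s) {
    set.seed(s)
    normalityTest(rnorm(100))$p <= 0.05
  }, logical(1))
  expect_lte(sum(rejects), qbinom(0.995, 200, 0.05))
  expect_gte(sum(rejects), qbinom(0.005, 200, 0.05))

  expect_error(normalityTest(rep(1, 10)), "constant")
  expect_error(normalityTest(rnorm(2)), "3 <= n")
})

test_that("omnibus test selection follows the any-non-normal rule", {
  expect_identical(selectTest(c(0.3, 0.4, 0.5, 0.6)), "RM_ANOVA")
  expect_identical(selectTest(c(0.01, 0.4, 0.5, 0.6)), "FRIEDMAN")
  expect_identical(selectTest(c(0.01, 0.02), alpha = 0), "RM_ANOVA")
})

test_that("Friedman: identical columns, hand-computed 3x3, reference agreement", {
  ident <- matrix(0.2, 5, 4)
  ft <- friedmanTest(ident)
  expect_equal(ft$statistic, 0)
  expect_equal(ft$p, 1)

  m <- rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  ft2 <- friedmanTest(m)
  expect_equal(ft2$statistic, 6)
  expect_equal(ft2$p, pchisq(6, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(ft2$p, 0.0498, tolerance = 1e-3)

  # cross-check against the reference implementation on tie-free data
  set.seed(43)
  m2 <- matrix(rnorm(40), 10, 4)
  ref <- stats::friedman.test(m2)
  ours <- friedmanTest(m2)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
})

test_that("Friedman p agrees with a within-row permutation null", {
  # effect chosen to put p near the 0.05 decision region, where the
  # chi-squared approximation has to be accurate
  set.seed(44)
  m <- matrix(rnorm(40, sd = 1), 10, 4)
  m[, 2] <- m[, 2] + 0.8
  obs <- friedmanTest(m)$statistic
  B <- 10000L
  perm <- vapply(seq_len(B), function(b) {
    mp <- t(apply(m, 1, sample))
    friedmanTest(mp)$statistic
  }, numeric(1))
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(friedmanTest(m)$p - p_perm), 0.01)
})

test_that("Friedman is invariant under strictly monotone within-row maps", {
  set.seed(45)
  m <- matrix(runif(24, 0.05, 0.5), 6, 4)
  f0 <- friedmanTest(m)
  expect_equal(friedmanTest(exp(m))$statistic, f0$statistic)
  expect_equal(friedmanTest(m^3)$statistic, f0$statistic)
})

test_that("repeated-measures ANOVA matches the blocked aov oracle", {
  set.seed(46)
  m <- matrix(rnorm(12, mean = 0.2, sd = 0.03), 4, 3)
  m[, 2] <- m[, 2] + 0.1
  colnames(m) <- c("A", "B", "C")
  ours <- rmAnova(m)
  df <- data.frame(v = as.numeric(m),
                   subj = factor(rep(seq_len(4), 3)),
                   meth = factor(rep(colnames(m), each = 4)))
  fit <- summary(stats::aov(v ~ meth + Error(subj), data = df))
  tab <- fit[["Error: Within"]][[1]]
  expect_equal(ours$F, tab["meth", "F value"], tolerance = 1e-10)
  expect_equal(ours$p, tab["meth", "Pr(>F)"], tolerance = 1e-10)

  # blocking invariance: per-subject constants leave F unchanged
  m2 <- m + matrix(rnorm(4), 4, 3)[, c(1, 1, 1)] * 0 +
    rep(rnorm(4, sd = 0.5), 3)
  expect_equal(rmAnova(m2)$F, ours$F, tolerance = 1e-8)

  # identical columns: zero error variance reported as undefined
  ident <- matrix(rep(rnorm(4), 3), 4, 3)
  expect_true(is.nan(rmAnova(ident)$F) || rmAnova(ident)$F == 0)
})

test_that("Dunn's control comparisons: identities and hand-computed z", {
  ident <- matrix(0.3, 6, 3, dimnames = list(NULL, c("FDK", "B", "C")))
  d <- dunnVsControl(ident, "FDK")
  expect_true(all(d$p_adjusted == 1))
  expect_true(all(d$display == ">0.999"))

  # 5x2: z from the mean-rank formula by hand
  m <- cbind(FDK = c(1, 2, 3, 4, 5), X = c(2, 3, 4, 5, 6))
  d2 <- dunnVsControl(m, "FDK")
  # every row ranks FDK=1, X=2: mean ranks 1 and 2
  z_hand <- (2 - 1) / sqrt(2 * 3 / (6 * 5))
  expect_equal(d2$z, z_hand, tolerance = 1e-12)

  # adjusted never below unadjusted
  set.seed(47)
  m3 <- matrix(runif(40), 10, 4,
               dimnames = list(NULL, c("FDK", "a", "b", "c")))
  d3 <- dunnVsControl(m3, "FDK")
  expect_true(all(d3$p_adjusted >= d3$p_unadjusted - 1e-15))
  expect_error(dunnVsControl(m3, "missing"), "control")
})

test_that("Friedman holds its nominal type-I rate on null cohorts", {
  # matched null: every method is the control plus independent tiny jitter
  set.seed(48)
  rejections <- vapply(1:200, function(r) {
    base <- runif(20, 0.05, 0.5)
    m <- sapply(1:4, function(j) base + rnorm(20, sd = 1e-3))
    friedmanTest(m)$p < 0.05
  }, logical(1))
  rate <- mean(rejections)
  # binomial 99% bounds around 0.05 with n = 200
  bounds <- qbinom(c(0.005, 0.995), 200, 0.05) / 200
  expect_gte(rate, bounds[1])
  expect_lte(rate, bounds[2])
})

test_that("the full comparison pipeline records its decision trail", {
  set.seed(49)
  base <- exp(rnorm(12, log(0.2), 0.5))     # non-normal marginals
  base <- pmin(base, 0.9)
  m <- cbind(FDK = base, FRIST = base + rnorm(12, sd = 0.004),
             SPLIT_MEAN = base + rnorm(12, sd = 0.004))
  m <- pmin(pmax(m, 0), 1)
  rep_ <- compareMethods(m)
  expect_identical(rep_@omnibus$test, "FRIEDMAN")
  expect_true(any(grepl("Friedman", rep_@decision_trail)))
  expect_identical(nrow(rep_@posthoc), 2L)

  # duplicate-control design: omnibus p = 1
  dup <- cbind(FDK = base, FDK2 = base)
  colnames(dup) <- c("FDK", "FDK2")
  rep2 <- compareMethods(dup)
  expect_equal(rep2@omnibus$p, 1)

  # normal-looking matched data takes the RM-ANOVA path
  set.seed(50)
  nm <- cbind(FDK = rnorm(15, 0.2, 0.02), FRIST = rnorm(15, 0.2, 0.02))
  nm <- pmin(pmax(nm, 0), 1)
  rep3 <- compareMethods(nm)
  expect_identical(rep3@omnibus$test, "RM_ANOVA")
  expect_identical(nrow(rep3@posthoc), 0L)
})

test_that("comparison reports round-trip through JSON", {
  set.seed(51)
  base <- runif(10, 0.1, 0.4)
  m <- cbind(FDK = base, FRIST = base + rnorm(10, sd = 0.01),
             SPLIT_MEAN = base + rnorm(10, sd = 0.01))
  m <- pmin(pmax(m, 0), 1)
  rep_ <- compareMethods(m)
  f <- tempfile(fileext = ".json")
  writeReport(rep_, f)
  back <- readReport(f)
  expect_equal(back@vgf_matrix, rep_@vgf_matrix, tolerance = 1e-12)
  expect_equal(back@omnibus$p, rep_@omnibus$p, tolerance = 1e-12)
  expect_identical(back@control, rep_@control)
  expect_equal(back@posthoc$p_adjusted, rep_@posthoc$p_adjusted,
               tolerance = 1e-12)
  expect_identical(back@decision_trail, rep_@decision_trail)
})
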