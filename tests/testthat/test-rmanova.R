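# Repeated-measures ANOVA machinery against definitional oracles.

test_that("F, Mauchly W and epsilon match brute-force definitions on random matrices", {
  set.seed(101)
  for (case in seq_len(120)) {
    n <- sample(5:8, 1)
    m <- sample(3:5, 1)
    Y <- matrix(rnorm(n * m), n, m) +
      outer(rnorm(n), rep(1, m)) + outer(rep(1, n), rnorm(m))
    res <- rm_anova(Y, gg = "never")
    expect_lt(abs(res$F - bf_rm_anova_F(Y)), 1e-10)
    if (n > m - 1) {
      expect_lt(abs(res$mauchly_W - bf_mauchly_W(Y)), 1e-10)
    }
    expect_lt(abs(res$epsilon_gg - bf_box_epsilon(Y)), 1e-10)
    expect_gte(res$epsilon_gg, 1 / (m - 1))
    expect_lte(res$epsilon_gg, 1)
    expect_true(res$mauchly_W > 0 && res$mauchly_W <= 1)
  }
})

test_that("Mauchly statistic and p agree with the base-R multivariate test", {
  set.seed(7)
  for (m in 3:4) {
    Y <- matrix(rnorm(12 * m), 12, m) %*%
      (diag(m) + 0.4 * matrix(1, m, m))
    ours <- mauchly_test(Y)
    fit <- lm(Y ~ 1)
    idata <- data.frame(cond = factor(seq_len(m)))
    ref <- stats::mauchly.test(fit, X = ~1, idata = idata, M = ~cond)
    expect_equal(ours$W, unname(ref$statistic), tolerance = 1e-10)
    # p agrees to the accuracy of the shared chi-square expansion (the
    # second-order term coefficients differ in the last digit)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-3)
  }
})

test_that("degenerate and two-level cases behave as defined", {
  Y <- matrix(rnorm(8), 8, 1)[, c(1, 1, 1)]  # identical columns
  res <- suppressWarnings(rm_anova(Y))
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)

  Y2 <- matrix(rnorm(16), 8, 2)
  res2 <- rm_anova(Y2)
  expect_equal(res2$epsilon_gg, 1)
  expect_equal(res2$mauchly_W, 1)

  # Mauchly undefined when n <= m - 1
  Y3 <- matrix(rnorm(3 * 5), 3, 5)
  expect_error(mauchly_test(Y3), "undefined")

  # location invariance of W
  Y4 <- matrix(rnorm(40), 10, 4)
  expect_equal(mauchly_test(Y4)$W, mauchly_test(Y4 + 100)$W,
               tolerance = 1e-9)

  # zero error variance with a real condition effect
  Y5 <- outer(rnorm(6), rep(1, 3)) + outer(rep(1, 6), c(0, 1, 2))
  expect_warning(res5 <- rm_anova(Y5), "Inf")
  expect_equal(res5$F, Inf)
})

test_that("epsilon approaches its lower bound when one contrast dominates", {
  set.seed(3)
  n <- 40
  z <- rnorm(n, sd = 10)
  Y <- cbind(z, -z, rnorm(n, sd = 1e-3), rnorm(n, sd = 1e-3))
  eps <- gg_epsilon(Y)
  expect_lt(eps, 1 / 3 + 0.01)
  expect_gte(eps, 1 / 3)
  # exact sphericity: independent equal-variance contrasts give eps near 1
  Ys <- matrix(rnorm(4000 * 3), 4000, 3)
  expect_gt(gg_epsilon(Ys), 0.98)
})

test_that("Tukey p-values match direct integration of the studentized range", {
  set.seed(55)
  for (case in 1:6) {
    n <- sample(6:9, 1)
    m <- sample(3:4, 1)
    Y <- matrix(rnorm(n * m), n, m) + outer(rep(1, n), rnorm(m, sd = 0.8))
    res <- rm_anova(Y, gg = "never")
    ph <- tukey_posthoc(Y, res)
    for (i in seq_len(nrow(ph))) {
      expect_lt(abs(ph$p_adjusted[i] -
                      bf_srange_sf(ph$q[i], m, res$df2_uncorrected)), 1e-6)
    }
  }
})

test_that("Tukey handles equal columns and is monotone in the mean difference", {
  set.seed(9)
  base <- rnorm(10)
  Y <- cbind(base, base, base + 1.5)
  colnames(Y) <- c("A", "B", "C")
  res <- suppressWarnings(rm_anova(Y, gg = "never"))
  ph <- suppressWarnings(tukey_posthoc(Y, res))
  ab <- ph[ph$design_A == "A" & ph$design_B == "B", ]
  expect_equal(ab$q, 0)
  expect_equal(ab$p_adjusted, 1)
  # p decreases as |mean difference| grows at fixed error term
  ord <- order(abs(ph$mean_diff))
  expect_true(all(diff(ph$p_adjusted[ord]) <= 1e-12))
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  p <- runif(20)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p - 1e-15))
  expect_true(all(adj <= 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("design similarity is a correlation matrix with expected extremes", {
  set.seed(12)
  x <- rnorm(10)
  Y <- cbind(a = x, b = -x, c = rnorm(10))
  r <- design_similarity(Y)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  expect_equal(r, t(r))
  expect_equal(r["a", "b"], -1)
  Yz <- cbind(a = x, b = rep(1, 10), c = rnorm(10))
  expect_warning(rz <- design_similarity(Yz), "zero-variance")
  expect_true(is.na(rz["a", "b"]))
  expect_equal(rz["b", "b"], 1)
})

test_that("compare_designs assembles all parts coherently", {
  set.seed(77)
  Y <- matrix(rnorm(9 * 4), 9, 4)
  colnames(Y) <- paste0("D", 1:4)
  cmp <- compare_designs(Y)
  expect_s3_class(cmp, "design_comparison")
  expect_equal(nrow(cmp$posthoc), choose(4, 2))
  expect_true(all(cmp$fdr_adjusted_p >= cmp$posthoc$p_adjusted - 1e-15))
  expect_equal(dim(cmp$similarity), c(4, 4))
})
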