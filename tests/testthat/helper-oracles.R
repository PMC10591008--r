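# Independent oracles used across the suite. Each recomputes a quantity
# from its definition by a route different from the package implementation.

# Within-subjects F from explicit sums of squares (loops, no matrix
# centring shortcut).
bf_rm_anova_F <- function(Y) {
  n <- nrow(Y)
  m <- ncol(Y)
  g <- mean(Y)
  ss_cond <- 0
  for (j in seq_len(m)) ss_cond <- ss_cond + n * (mean(Y[, j]) - g)^2
  ss_err <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      ss_err <- ss_err +
        (Y[i, j] - mean(Y[i, ]) - mean(Y[, j]) + g)^2
    }
  }
  (ss_cond / (m - 1)) / (ss_err / ((n - 1) * (m - 1)))
}

# Mauchly W from the determinant/trace definition on a different
# orthonormal contrast basis (W is invariant to the basis choice).
bf_mauchly_W <- function(Y) {
  m <- ncol(Y)
  M <- cbind(rep(1, m), matrix(sin(seq_len(m * (m - 1))), m))
  Q <- qr.Q(qr(M))[, -1, drop = FALSE]
  A <- t(Q) %*% cov(Y) %*% Q
  det(A) / (sum(diag(A)) / (m - 1))^(m - 1)
}

# Greenhouse-Geisser epsilon via Box's closed form on the raw covariance
# matrix (no contrast projection, no eigendecomposition).
bf_box_epsilon <- function(Y) {
  S <- cov(Y)
  m <- ncol(S)
  sbar <- mean(S)
  dbar <- mean(diag(S))
  rbar <- rowMeans(S)
  (m * (dbar - sbar))^2 /
    ((m - 1) * (sum(S^2) - 2 * m * sum(rbar^2) + m^2 * sbar^2))
}

# Studentized-range survival function by direct numerical integration of
# its definitional double integral (independent of stats::ptukey).
bf_srange_sf <- function(q, k, df) {
  inner <- function(s) {
    vapply(s, function(si) {
      g <- function(z) dnorm(z) * (pnorm(z) - pnorm(z - q * si))^(k - 1)
      k * integrate(g, -8, 8, rel.tol = 1e-10)$value
    }, numeric(1))
  }
  fS <- function(s) {
    2 * (df / 2)^(df / 2) / gamma(df / 2) * s^(df - 1) * exp(-df * s^2 / 2)
  }
  1 - integrate(function(s) fS(s) * inner(s), 0, 6,
                rel.tol = 1e-9, subdivisions = 400L)$value
}

# Exact two-sided Wilcoxon signed-rank p by exhaustive enumeration of all
# 2^n sign assignments over the observed absolute-rank configuration.
bf_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.numeric(signs %*% r)
  p_le <- mean(vs <= v_obs + 1e-9)
  p_ge <- mean(vs >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Draw a compound-symmetric repeated-measures sample: m condition means
# with spread f (Cohen's f relative to unit within-condition SD) and
# inter-condition correlation rho.
draw_cs_sample <- function(n, m, f, rho) {
  v <- seq_len(m) - (m + 1) / 2
  mu <- if (f > 0) f * v / sqrt(mean(v^2)) else rep(0, m)
  subj <- rnorm(n, 0, sqrt(rho))
  eps <- matrix(rnorm(n * m, 0, sqrt(1 - rho)), n, m)
  sweep(subj + eps, 2, mu, "+")
}

# Monte-Carlo rejection rate of the uncorrected within-subjects F test.
mc_power <- function(n, m, f, rho, alpha = 0.05, reps = 5000) {
  rej <- 0L
  for (r in seq_len(reps)) {
    Y <- draw_cs_sample(n, m, f, rho)
    res <- rm_anova(Y, gg = "never")
    if (res$p < alpha) rej <- rej + 1L
  }
  rej / reps
}

# Vectorized Monte-Carlo rejection rate of the uncorrected within-subjects
# F test: recomputes every replicate's F from its definitional sums of
# squares with array arithmetic (a route independent of rm_anova).
mc_power_batch <- function(n, m, f, rho, alpha = 0.05, reps = 5000) {
  v <- seq_len(m) - (m + 1) / 2
  mu <- if (f > 0) f * v / sqrt(mean(v^2)) else rep(0, m)
  subj <- array(rep(rnorm(n * reps, 0, sqrt(rho)), times = m),
                c(n, reps, m))
  subj <- aperm(subj, c(1, 3, 2))
  Y <- array(rnorm(n * m * reps, 0, sqrt(1 - rho)), c(n, m, reps)) + subj
  Y <- Y + array(rep(mu, each = n), c(n, m, reps))
  cm <- colMeans(Y)                        # m x reps condition means
  sm <- apply(Y, c(1, 3), mean)            # n x reps subject means
  g <- colMeans(cm)                        # reps grand means
  ss_cond <- n * colSums((cm - rep(g, each = m))^2)
  res <- Y -
    aperm(array(sm, c(n, reps, m)), c(1, 3, 2)) -
    array(rep(cm, each = n), c(n, m, reps)) +
    array(rep(g, each = n * m), c(n, m, reps))
  ss_err <- colSums(matrix(res^2, n * m, reps))
  Fs <- (ss_cond / (m - 1)) / (ss_err / ((n - 1) * (m - 1)))
  ps <- pf(Fs, m - 1, (n - 1) * (m - 1), lower.tail = FALSE)
  mean(ps < alpha)
}

# Simulation config for tests: small grids, counts scaled with n.
test_config <- function(n = 10, ...) {
  simulation_config(n_participants = n, bundles = "CC3", measures = "MD",
                    ...)
}
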