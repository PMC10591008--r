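# Repeated-measures comparison of designs.
#
# Given the aligned participants x designs matrix of estimated slopes for
# one (bundle, measure), designs are compared with a one-way within-subjects
# ANOVA. Sphericity (equal variances of all pairwise condition differences)
# is tested with Mauchly's W; when violated, degrees of freedom are
# multiplied by the Greenhouse-Geisser epsilon. Specific pairs are probed
# with Tukey's studentized-range test on the within-subjects error term, and
# p-values across a sweep can be adjusted with the Benjamini-Hochberg FDR.

# Orthonormal contrast basis orthogonal to the unit vector (m x (m-1)).
contrast_basis <- function(m) {
  C <- stats::contr.helmert(m)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

# Sample covariance of the data projected onto the contrast space.
contrast_cov <- function(mat) {
  C <- contrast_basis(ncol(mat))
  stats::cov(mat %*% C)
}

check_matrix <- function(mat, min_rows = 3, min_cols = 2) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop_config("input must be a numeric participants x designs matrix")
  }
  if (anyNA(mat)) {
    stop_config("matrix has missing cells; align complete cases upstream")
  }
  if (nrow(mat) < min_rows || ncol(mat) < min_cols) {
    stop_config("need >= %d rows and >= %d columns", min_rows, min_cols)
  }
  invisible(mat)
}

#' One-way within-subjects (repeated-measures) ANOVA
#'
#' Decomposes the participants x conditions matrix into condition, subject
#' and error sums of squares; `F = MS_cond / MS_error` with `m - 1` and
#' `(n - 1)(m - 1)` degrees of freedom. With three or more conditions,
#' sphericity is tested with [mauchly_test()]; if its p-value falls below
#' `mauchly_alpha` (or `gg = "always"`), both degrees of freedom are
#' multiplied by the Greenhouse-Geisser epsilon before the p-value is
#' computed.
#'
#' @param mat numeric matrix, participants in rows, designs/conditions in
#'   columns (complete cases).
#' @param mauchly_alpha significance level of the sphericity test gating
#'   the correction.
#' @param gg `"auto"` applies the Greenhouse-Geisser correction only when
#'   Mauchly's test rejects; `"always"` and `"never"` override.
#' @return object of class `design_comparison` with F, df1, df2, p,
#'   mauchly_W, mauchly_p, epsilon_gg, epsilon_applied, ms_error and the
#'   uncorrected error df (`df2_uncorrected`).
#' @export
rm_anova <- function(mat, mauchly_alpha = 0.05,
                     gg = c("auto", "always", "never")) {
  gg <- match.arg(gg)
  check_matrix(mat)
  n <- nrow(mat)
  m <- ncol(mat)
  grand <- mean(mat)
  cond_means <- colMeans(mat)
  subj_means <- rowMeans(mat)
  ss_cond <- n * sum((cond_means - grand)^2)
  resid <- mat - outer(subj_means, rep(1, m)) -
    outer(rep(1, n), cond_means) + grand
  ss_error <- sum(resid^2)
  df1 <- m - 1
  df2 <- (n - 1) * (m - 1)

  # A degenerate contrast covariance (e.g. identical columns) makes the
  # sphericity question moot; treat it as spherical.
  eps <- if (m > 2) {
    tryCatch(gg_epsilon(mat), error = function(e) 1)
  } else 1
  mau <- if (m > 2 && n > m - 1) {
    tryCatch(mauchly_test(mat), error = function(e) list(W = 1, p = 1))
  } else {
    list(W = 1, p = 1)
  }
  apply_eps <- switch(gg,
                      auto = isTRUE(mau$p < mauchly_alpha),
                      always = m > 2,
                      never = FALSE)

  ss_subj <- m * sum((subj_means - grand)^2)
  scale <- ss_cond + ss_error + ss_subj
  if (ss_error <= 1e-12 * max(scale, 1e-300)) {
    if (ss_cond <= 1e-12 * max(scale, 1e-300)) {
      F_stat <- 0
      p <- 1
    } else {
      warning("zero within-subjects error variance; F reported as Inf",
              call. = FALSE)
      F_stat <- Inf
      p <- 0
    }
  } else {
    F_stat <- (ss_cond / df1) / (ss_error / df2)
    adf1 <- if (apply_eps) df1 * eps else df1
    adf2 <- if (apply_eps) df2 * eps else df2
    p <- pf(F_stat, adf1, adf2, lower.tail = FALSE)
  }

  structure(list(
    F = F_stat,
    df1 = if (apply_eps) df1 * eps else df1,
    df2 = if (apply_eps) df2 * eps else df2,
    df2_uncorrected = df2,
    p = p,
    ss_cond = ss_cond, ss_error = ss_error,
    ms_error = ss_error / df2,
    mauchly_W = mau$W, mauchly_p = mau$p,
    epsilon_gg = eps, epsilon_applied = apply_eps,
    n = n, m = m,
    design_names = colnames(mat)
  ), class = "design_comparison")
}

#' Mauchly's test of sphericity
#'
#' For the sample covariance `S` of the data projected on an orthonormal
#' contrast basis `C`, the statistic is
#' `W = det(C'SC) / (trace(C'SC) / (m - 1))^(m - 1)`, compared to a
#' chi-square with `m(m - 1)/2 - 1` degrees of freedom after the standard
#' small-sample scaling of `-(n - 1) log W`.
#'
#' @inheritParams rm_anova
#' @return list with elements `W` and `p`.
#' @export
mauchly_test <- function(mat) {
  check_matrix(mat, min_cols = 2)
  n <- nrow(mat)
  m <- ncol(mat)
  if (m == 2) {
    return(list(W = 1, p = 1))
  }
  if (n <= m - 1) {
    stop_config(paste("Mauchly's test is undefined for n <= m - 1;",
                      "apply the epsilon correction unconditionally"))
  }
  A <- contrast_cov(mat)
  pdim <- m - 1
  tr <- sum(diag(A))
  if (tr <= 0) stop_config("degenerate contrast covariance (zero trace)")
  W <- det(A) / (tr / pdim)^pdim
  W <- min(max(W, 0), 1)
  if (W == 0) return(list(W = W, p = 0))
  dfc <- pdim * (pdim + 1) / 2 - 1
  nd <- n - 1
  # Box's chi-square expansion to second order (the first-order factor d
  # alone already gives 3-digit accuracy at these sample sizes).
  d <- 1 - (2 * pdim^2 + pdim + 2) / (6 * pdim * nd)
  chi2 <- -nd * d * log(W)
  w2 <- (pdim + 2) * (pdim - 1) * (pdim - 2) *
    (2 * pdim^3 + 6 * pdim^2 + 3 * pdim + 2) / (288 * (nd * pdim * d)^2)
  pr1 <- pchisq(chi2, dfc, lower.tail = FALSE)
  pr2 <- pchisq(chi2, dfc + 4, lower.tail = FALSE)
  p <- min(max(pr1 + w2 * (pr2 - pr1), 0), 1)
  list(W = W, p = p)
}

#' Greenhouse-Geisser epsilon
#'
#' `epsilon = (sum lambda)^2 / ((m - 1) sum lambda^2)` over the eigenvalues
#' of the contrast-space sample covariance, clipped to
#' `[1/(m - 1), 1]`. Equals 1 under exact sphericity and approaches the
#' lower bound when one contrast dominates.
#'
#' @inheritParams rm_anova
#' @return scalar epsilon.
#' @export
gg_epsilon <- function(mat) {
  check_matrix(mat, min_cols = 2)
  m <- ncol(mat)
  if (m == 2) return(1)
  A <- contrast_cov(mat)
  lambda <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  if (sum(lambda) <= 0) {
    stop_config("degenerate contrast covariance (all eigenvalues zero)")
  }
  eps <- sum(lambda)^2 / ((m - 1) * sum(lambda^2))
  min(max(eps, 1 / (m - 1)), 1)
}

#' Tukey studentized-range post-hoc test between designs
#'
#' For every pair of columns, `q = |mean_A - mean_B| / sqrt(MS_error / n)`
#' with the within-subjects error mean square from [rm_anova()]; p-values
#' come from the studentized range distribution with `m` groups and the
#' uncorrected error degrees of freedom.
#'
#' @param mat the matrix passed to [rm_anova()].
#' @param anova the corresponding [rm_anova()] result.
#' @param alpha flagging threshold for `significant`.
#' @return data.frame (design_A, design_B, mean_diff, q, p_adjusted,
#'   significant).
#' @export
tukey_posthoc <- function(mat, anova, alpha = 0.05) {
  stopifnot(inherits(anova, "design_comparison"))
  check_matrix(mat)
  n <- nrow(mat)
  m <- ncol(mat)
  nms <- colnames(mat)
  if (is.null(nms)) nms <- paste0("C", seq_len(m))
  ms_error <- anova$ms_error
  df_err <- anova$df2_uncorrected
  se <- sqrt(ms_error / n)
  if (ms_error <= 1e-300) {
    warning("zero error variance in Tukey test; q = Inf for unequal means",
            call. = FALSE)
  }
  pairs <- utils::combn(m, 2)
  out <- data.frame(
    design_A = nms[pairs[1, ]],
    design_B = nms[pairs[2, ]],
    mean_diff = colMeans(mat)[pairs[1, ]] - colMeans(mat)[pairs[2, ]],
    stringsAsFactors = FALSE
  )
  out$q <- ifelse(se > 0, abs(out$mean_diff) / se,
                  ifelse(abs(out$mean_diff) > 0, Inf, 0))
  out$p_adjusted <- ifelse(is.infinite(out$q), 0,
                           ptukey(out$q, m, df_err, lower.tail = FALSE))
  out$p_adjusted[out$q == 0] <- 1
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Thin, validating wrapper around the standard step-up adjustment:
#' order-preserving, each adjusted value in `[0, 1]` and at least the raw
#' p-value.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_config("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Pairwise Pearson similarity between designs
#'
#' Pearson correlation across participants for every pair of design
#' columns; symmetric with unit diagonal. Zero-variance columns yield NA
#' for their pairs, with a warning.
#'
#' @param mat participants x designs matrix of change estimates.
#' @return designs x designs correlation matrix.
#' @export
design_similarity <- function(mat) {
  check_matrix(mat)
  sds <- apply(mat, 2, sd)
  degenerate <- sds == 0
  if (any(degenerate)) {
    warning(sprintf("zero-variance column(s): %s; correlations set to NA",
                    paste(colnames(mat)[degenerate], collapse = ", ")),
            call. = FALSE)
  }
  r <- suppressWarnings(cor(mat))
  r[degenerate, ] <- NA_real_
  r[, degenerate] <- NA_real_
  diag(r) <- 1
  r
}

#' Mean similarity of each tested design to the reference
#'
#' @param sim similarity matrix from [design_similarity()], or a list of
#'   such matrices (e.g. one per bundle-measure cell) to average.
#' @param reference reference design name.
#' @return named vector: mean Pearson r of each non-reference design with
#'   the reference (averaged over matrices when a list is given).
#' @export
similarity_to_reference <- function(sim, reference = "D_R") {
  if (is.list(sim)) {
    cols <- lapply(sim, similarity_to_reference, reference = reference)
    return(Reduce(`+`, cols) / length(cols))
  }
  if (!reference %in% rownames(sim)) {
    stop_config("reference design '%s' not in similarity matrix", reference)
  }
  r <- sim[reference, setdiff(colnames(sim), reference)]
  r
}

#' Compare designs for one (bundle, measure) cell
#'
#' Runs [rm_anova()], [tukey_posthoc()] (with BH-FDR over the pairwise
#' p-values) and [design_similarity()] on an aligned change matrix.
#'
#' @inheritParams rm_anova
#' @param alpha significance level for the post-hoc flags.
#' @return the `design_comparison` object extended with `posthoc`,
#'   `fdr_adjusted_p` and `similarity`.
#' @export
compare_designs <- function(mat, mauchly_alpha = 0.05,
                            gg = c("auto", "always", "never"),
                            alpha = 0.05) {
  res <- rm_anova(mat, mauchly_alpha = mauchly_alpha, gg = gg)
  res$posthoc <- tukey_posthoc(mat, res, alpha = alpha)
  res$fdr_adjusted_p <- bh_fdr(res$posthoc$p_adjusted)
  res$similarity <- design_similarity(mat)
  res
}

#' @export
print.design_comparison <- function(x, ...) {
  cat(sprintf("<design_comparison> F(%.3g, %.3g) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$F, x$p))
  cat(sprintf("  Mauchly W = %.4g (p = %.4g); GG epsilon = %.4g%s\n",
              x$mauchly_W, x$mauchly_p, x$epsilon_gg,
              if (x$epsilon_applied) " [applied]" else ""))
  invisible(x)
}
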