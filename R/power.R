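# Power and sample size for one-group within-subjects ANOVA.
#
# Power for detecting a time effect across m repeated measurements at
# effect size f (Cohen's f = sigma_means / sigma, with sigma the
# within-condition SD) uses the noncentral F distribution with
#   lambda = f^2 * n * m * epsilon / (1 - rho)
#   df1 = (m - 1) * epsilon,  df2 = (n - 1) * (m - 1) * epsilon
# where rho is the mean correlation between repeated measurements and
# epsilon an optional nonsphericity correction. This is the "within
# factors" convention of mainstream power software; it is validated against
# Monte-Carlo rejection rates in the test suite.

#' Power-analysis configuration
#'
#' @param f Cohen's effect size (>= 0); 0.2 is the conventional "small"
#'   setting for a time effect.
#' @param alpha significance level.
#' @param target_power required power for [solve_sample_size()].
#' @param m number of repeated measurements (design size).
#' @param rho repeated-measures correlation, in `(-1/(m-1), 1)`.
#' @param epsilon nonsphericity correction in `[1/(m-1), 1]`; 1 assumes
#'   sphericity.
#' @return validated list of class `power_config`.
#' @export
power_config <- function(f = 0.2, alpha = 0.05, target_power = 0.8,
                         m = 5, rho = 0.5, epsilon = 1) {
  if (!is.numeric(f) || length(f) != 1 || !is.finite(f) || f < 0) {
    stop_config("'f' must be a single non-negative number")
  }
  if (!is_prob(alpha) || !is_prob(target_power)) {
    stop_config("'alpha' and 'target_power' must lie in (0, 1)")
  }
  if (!is_count(m) || m < 2) stop_config("'m' must be an integer >= 2")
  if (!is.numeric(rho) || rho <= -1 / (m - 1) || rho >= 1) {
    stop_config("'rho' must lie in (-1/(m-1), 1)")
  }
  if (!is.numeric(epsilon) || epsilon < 1 / (m - 1) || epsilon > 1) {
    stop_config("'epsilon' must lie in [1/(m-1), 1]")
  }
  structure(list(f = f, alpha = alpha, target_power = target_power,
                 m = as.integer(m), k = 1L, rho = rho, epsilon = epsilon),
            class = "power_config")
}

#' Estimate the repeated-measures correlation of a design
#'
#' Reshapes the dataset cell to a participants x sessions matrix for the
#' design's sessions, computes all pairwise Pearson correlations between
#' session columns, averages them on the Fisher-z scale and transforms
#' back. Arithmetic averaging is available for comparison with software
#' that pools raw correlations.
#'
#' @param dataset a `longitudinal_dataset`.
#' @param bundle,measure cell to use.
#' @param design a `design_spec`; defaults to all sessions present.
#' @param average `"fisher"` (default) or `"arithmetic"`.
#' @return scalar correlation in (-1, 1).
#' @export
estimate_rho <- function(dataset, bundle, measure, design = NULL,
                         average = c("fisher", "arithmetic")) {
  average <- match.arg(average)
  rec <- dataset$records
  rec <- rec[rec$bundle == bundle & rec$measure == measure, , drop = FALSE]
  if (nrow(rec) == 0) {
    stop_config("no records for bundle '%s', measure '%s'", bundle, measure)
  }
  sessions <- if (is.null(design)) sort(unique(rec$session_index))
              else design$session_indices
  rec <- rec[rec$session_index %in% sessions, , drop = FALSE]
  wide <- stats::reshape(
    rec[, c("participant_id", "session_index", "value")],
    idvar = "participant_id", timevar = "session_index",
    direction = "wide")
  wide <- wide[complete.cases(wide), , drop = FALSE]
  if (nrow(wide) < 4) stop_config("need >= 4 participants with complete data")
  Y <- as.matrix(wide[, -1, drop = FALSE])
  if (ncol(Y) < 2) stop_config("design must retain >= 2 sessions")
  sds <- apply(Y, 2, sd)
  pairs <- utils::combn(ncol(Y), 2)
  rs <- numeric(0)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    if (sds[a] == 0 || sds[b] == 0) {
      warning(sprintf("zero-variance session column; skipping pair (%d, %d)",
                      a, b), call. = FALSE)
      next
    }
    rs <- c(rs, cor(Y[, a], Y[, b]))
  }
  if (length(rs) == 0) stop_config("all session pairs degenerate")
  cap <- 1 - 1e-12
  rs <- pmin(pmax(rs, -cap), cap)
  if (average == "fisher") tanh(mean(atanh(rs))) else mean(rs)
}

#' Achieved power of the within-subjects F test
#'
#' @param n number of participants.
#' @param config a [power_config()].
#' @return probability of rejecting at level `alpha` when the effect size
#'   is `f`; equals `alpha` exactly at `f = 0`.
#' @export
power_rm_anova <- function(n, config) {
  stopifnot(inherits(config, "power_config"))
  if (!is_count(n) || n <= config$k) {
    stop_config("'n' must be an integer > %d", config$k)
  }
  m <- config$m
  eps <- config$epsilon
  lambda <- config$f^2 * n * m * eps / (1 - config$rho)
  df1 <- (m - 1) * eps
  df2 <- (n - config$k) * (m - 1) * eps
  fcrit <- qf(1 - config$alpha, df1, df2)
  pf(fcrit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Minimal sample size reaching the target power
#'
#' Exploits monotonicity of power in `n`: doubles an upper bracket until
#' the target is reached, then bisects down to the smallest integer `n`
#' with `power(n) >= target_power` (and `power(n - 1) < target_power`).
#'
#' @param config a [power_config()].
#' @param n_max give up beyond this sample size.
#' @return list of class `power_result`: n_required, achieved_power,
#'   lambda, df1, df2.
#' @export
solve_sample_size <- function(config, n_max = 1e6) {
  stopifnot(inherits(config, "power_config"))
  lo <- config$k + 1L
  if (power_rm_anova(lo, config) >= config$target_power) {
    n <- lo
  } else {
    hi <- lo
    repeat {
      hi <- min(hi * 2L, as.integer(n_max))
      if (power_rm_anova(hi, config) >= config$target_power) break
      if (hi >= n_max) {
        stop_config("target power %.2f unreachable below n = %g",
                    config$target_power, n_max)
      }
    }
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (power_rm_anova(mid, config) >= config$target_power) hi <- mid
      else lo <- mid
    }
    n <- hi
  }
  m <- config$m
  eps <- config$epsilon
  structure(list(
    n_required = n,
    achieved_power = power_rm_anova(n, config),
    lambda = config$f^2 * n * m * eps / (1 - config$rho),
    df1 = (m - 1) * eps,
    df2 = (n - config$k) * (m - 1) * eps
  ), class = "power_result")
}

#' Sample-size sweep over bundles, measures and designs
#'
#' For each (bundle, measure, design) cell: estimate the repeated-measures
#' correlation from the design's sessions with [estimate_rho()], set
#' `m` to the design size, and solve for the minimal sample size at the
#' configured effect size, alpha and power.
#'
#' @param dataset a `longitudinal_dataset`.
#' @param designs list of `design_spec`.
#' @param bundles,measures cells to sweep; default all present.
#' @param f,alpha,target_power,epsilon forwarded to [power_config()].
#' @return data.frame (bundle, measure, design_name, m, rho, n_required);
#'   cells whose correlation cannot be estimated carry NA.
#' @export
sample_size_sweep <- function(dataset, designs, bundles = NULL,
                              measures = NULL, f = 0.2, alpha = 0.05,
                              target_power = 0.8, epsilon = 1) {
  if (is.null(bundles)) bundles <- unique(dataset$records$bundle)
  if (is.null(measures)) measures <- unique(dataset$records$measure)
  rows <- list()
  for (d in designs) {
    m <- length(d$session_indices)
    for (b in bundles) {
      for (msr in measures) {
        rho <- tryCatch(estimate_rho(dataset, b, msr, design = d),
                        error = function(e) NA_real_)
        n_req <- NA_integer_
        if (is.finite(rho)) {
          rho_adm <- min(max(rho, -1 / (m - 1) + 1e-9), 1 - 1e-9)
          cfg <- power_config(f = f, alpha = alpha,
                              target_power = target_power, m = m,
                              rho = rho_adm, epsilon = epsilon)
          n_req <- solve_sample_size(cfg)$n_required
        }
        rows[[paste(b, msr, d$name)]] <- data.frame(
          bundle = b, measure = msr, design_name = d$name, m = m,
          rho = rho, n_required = n_req, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("<power_result> n = %d (power %.3f, lambda %.3g, F df %.3g/%.3g)\n",
              x$n_required, x$achieved_power, x$lambda, x$df1, x$df2))
  invisible(x)
}
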