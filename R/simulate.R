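# Synthetic longitudinal tractometry-style data generator.
#
# The simulator reproduces the statistical structure the downstream analysis
# assumes: per-participant linear trajectories for every (bundle, measure),
# acquisitions on a nominal multi-week schedule with day-level jitter, and
# clinical change scores whose rank correlation with the true MRI slopes is
# controllable through a Gaussian copula.

#' Simulation configuration
#'
#' Build and validate the parameter set for [simulate_dataset()]. Defaults
#' describe a monthly-MRI cohort: 20 participants scanned at baseline and at
#' four follow-ups spaced 4 nominal weeks apart (plus or minus up to one week
#' of scheduling jitter), with tract-averaged diffusion and myelin measures
#' for five white-matter bundles.
#'
#' The observation model for participant \eqn{i} at week \eqn{w} is
#' \deqn{y_{i}(w) = \mu + \beta w + x_i'\gamma + a_i + b_i w + \epsilon,}
#' with \eqn{(a_i, b_i)} bivariate normal (standard deviations
#' `intercept_sd`, `slope_sd`, correlation `intercept_slope_corr`), residuals
#' \eqn{\epsilon \sim N(0, \sigma^2)} independent across sessions, and
#' covariate effects \eqn{\gamma} zero unless set. Random effects are drawn
#' independently for each (bundle, measure) pair.
#'
#' @param n_participants number of participants.
#' @param session_weeks strictly increasing nominal week offsets, first 0.
#' @param jitter_days half-width (days) of the uniform acquisition-day jitter
#'   applied to follow-up sessions; baseline stays at week 0.
#' @param bundles,measures character vectors of bundle and measure names.
#' @param baseline_mean population mean at baseline; scalar or named by
#'   measure.
#' @param fixed_slope population mean slope, in measure units per week;
#'   scalar or named by measure.
#' @param slope_sd between-participant SD of the random slope (units/week).
#' @param intercept_sd between-participant SD of the random intercept.
#' @param intercept_slope_corr correlation of random intercept and slope.
#' @param noise_sd residual SD; a scalar, a vector named by measure, or a
#'   data.frame with columns bundle, measure, noise_sd.
#' @param covariate_params list with age_mean, age_sd, n_male, n_female,
#'   disease_duration_mean, disease_duration_sd.
#' @param covariate_betas named list of fixed covariate effects on the
#'   measure value (age, sex_male, disease_duration); all default 0.
#' @param clinical_scores data.frame with columns score, delta_mean,
#'   delta_sd giving the marginal moments of each clinical change score.
#' @param clinical_target_spearman desired population Spearman correlation
#'   between true slopes of the anchor (bundle, measure) and each clinical
#'   change score; scalar or named by score.
#' @param clinical_anchor length-2 character vector (bundle, measure) whose
#'   true slopes drive the clinical coupling; defaults to the first of each.
#' @param missing_rate per-session probability that a participant-session is
#'   dropped (baseline always kept); scalar or one value per session.
#' @param n_dropout number of participants who leave after baseline (their
#'   follow-up sessions are removed), emulating study attrition.
#' @param seed integer seed; identical config and seed give bit-identical
#'   datasets.
#'
#' @return An object of class `simulation_config` (a validated list).
#' @seealso [simulate_dataset()], [simulate_clinical()]
#' @export
#' @examples
#' cfg <- simulation_config(n_participants = 6, bundles = "CC3",
#'                          measures = "MD", seed = 1)
#' ds <- simulate_dataset(cfg)
#' head(ds$records)
simulation_config <- function(n_participants = 20,
                              session_weeks = c(0, 4, 8, 12, 16),
                              jitter_days = 7,
                              bundles = c("CC3", "CST", "CG", "SLF2", "OR"),
                              measures = c("MD", "RD", "FW", "AFDtotal",
                                           "ICvf", "ISOvf", "MTR",
                                           "ihMTdR1sat"),
                              baseline_mean = 1,
                              fixed_slope = -0.005,
                              slope_sd = 0.01,
                              intercept_sd = 0.1,
                              intercept_slope_corr = -0.2,
                              noise_sd = 0.05,
                              covariate_params = list(
                                age_mean = 36, age_sd = 4.7,
                                n_male = 4, n_female = 16,
                                disease_duration_mean = 7,
                                disease_duration_sd = 5.9),
                              covariate_betas = list(
                                age = 0, sex_male = 0, disease_duration = 0),
                              clinical_scores = default_clinical_scores(),
                              clinical_target_spearman = 0.3,
                              clinical_anchor = NULL,
                              missing_rate = 0,
                              n_dropout = 0,
                              seed = 1L) {
  if (!is_count(n_participants) || n_participants < 1) {
    stop_config("'n_participants' must be a positive integer")
  }
  session_weeks <- as.numeric(session_weeks)
  if (length(session_weeks) < 2 || any(diff(session_weeks) <= 0)) {
    stop_config("'session_weeks' must be strictly increasing")
  }
  if (session_weeks[1] != 0) {
    stop_config("'session_weeks' must start at 0 (baseline)")
  }
  for (nm in c("jitter_days", "slope_sd", "intercept_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      stop_config("'%s' must be a single non-negative number", nm)
    }
  }
  if (abs(intercept_slope_corr) > 1) {
    stop_config("'intercept_slope_corr' must lie in [-1, 1]")
  }
  bundles <- as.character(bundles)
  measures <- as.character(measures)
  if (anyDuplicated(bundles) || anyDuplicated(measures)) {
    stop_config("bundle and measure names must be unique")
  }
  noise_tab <- resolve_noise(noise_sd, bundles, measures)
  if (any(noise_tab$noise_sd < 0)) stop_config("'noise_sd' must be >= 0")
  stopifnot(is.data.frame(clinical_scores),
            all(c("score", "delta_mean", "delta_sd") %in%
                  names(clinical_scores)))
  tgt <- resolve_by_key(clinical_target_spearman,
                        as.character(clinical_scores$score),
                        "clinical_target_spearman")
  if (any(abs(tgt) > 1)) {
    stop_config("'clinical_target_spearman' must lie in [-1, 1]")
  }
  if (is.null(clinical_anchor)) {
    clinical_anchor <- c(bundle = bundles[1], measure = measures[1])
  } else {
    clinical_anchor <- setNames(as.character(clinical_anchor),
                                c("bundle", "measure"))
  }
  if (!clinical_anchor[["bundle"]] %in% bundles ||
      !clinical_anchor[["measure"]] %in% measures) {
    stop_config("'clinical_anchor' must name a simulated bundle and measure")
  }
  covariate_params <- utils::modifyList(
    list(age_mean = 36, age_sd = 4.7, n_male = 4, n_female = 16,
         disease_duration_mean = 7, disease_duration_sd = 5.9),
    covariate_params)
  # Keep the configured male:female ratio when n_participants differs from
  # the sum of the configured counts.
  tot <- covariate_params$n_male + covariate_params$n_female
  if (tot != n_participants) {
    nm <- round(n_participants * covariate_params$n_male / tot)
    covariate_params$n_male <- nm
    covariate_params$n_female <- n_participants - nm
  }
  missing_rate <- rep_len(as.numeric(missing_rate), length(session_weeks))
  if (any(missing_rate < 0 | missing_rate >= 1)) {
    stop_config("'missing_rate' values must lie in [0, 1)")
  }
  if (!is_count(n_dropout) || n_dropout >= n_participants) {
    stop_config("'n_dropout' must be a count below 'n_participants'")
  }
  cfg <- list(
    n_participants = as.integer(n_participants),
    session_weeks = session_weeks,
    jitter_days = jitter_days,
    bundles = bundles,
    measures = measures,
    baseline_mean = resolve_by_key(baseline_mean, measures, "baseline_mean"),
    fixed_slope = resolve_by_key(fixed_slope, measures, "fixed_slope"),
    slope_sd = slope_sd,
    intercept_sd = intercept_sd,
    intercept_slope_corr = intercept_slope_corr,
    noise_sd = noise_tab,
    covariate_params = covariate_params,
    covariate_betas = utils::modifyList(
      list(age = 0, sex_male = 0, disease_duration = 0), covariate_betas),
    clinical_scores = clinical_scores,
    clinical_target_spearman = tgt,
    clinical_anchor = clinical_anchor,
    missing_rate = missing_rate,
    n_dropout = as.integer(n_dropout),
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  cfg
}

#' Default clinical change-score marginals
#'
#' Marginal mean and SD of the follow-up-minus-baseline change for the four
#' clinical scores carried through the analysis: EDSS (disability), SDMT
#' (processing speed), 9HPT (dexterity, seconds) and T25FW (walking speed,
#' seconds).
#'
#' @return data.frame with columns score, delta_mean, delta_sd.
#' @export
default_clinical_scores <- function() {
  data.frame(
    score = c("EDSS", "SDMT", "9HPT", "T25FW"),
    delta_mean = c(0, 4.4, -0.9, -0.12),
    delta_sd = c(0.25, 13.8, 3.5, 1.0),
    stringsAsFactors = FALSE
  )
}

resolve_noise <- function(noise_sd, bundles, measures) {
  grid <- expand.grid(bundle = bundles, measure = measures,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (is.data.frame(noise_sd)) {
    stopifnot(all(c("bundle", "measure", "noise_sd") %in% names(noise_sd)))
    out <- merge(grid, noise_sd, by = c("bundle", "measure"), all.x = TRUE)
    if (anyNA(out$noise_sd)) {
      stop_config("'noise_sd' data.frame must cover every (bundle, measure)")
    }
    return(out)
  }
  by_measure <- resolve_by_key(noise_sd, measures, "noise_sd")
  grid$noise_sd <- by_measure[grid$measure]
  grid
}

#' Simulate a longitudinal dataset
#'
#' Draws a complete long-format dataset: per-participant linear trajectories
#' for every (bundle, measure) with correlated random intercepts and slopes,
#' jittered acquisition weeks, demographic covariates, clinical change
#' scores rank-coupled to the true slopes of the anchor measure, and the
#' ground-truth slope table.
#'
#' @param config a [simulation_config()].
#' @return An object of class `longitudinal_dataset`: a list with elements
#'   `records` (participant_id, session_index, acquisition_week, bundle,
#'   measure, value), `covariates` (participant_id, age, sex,
#'   disease_duration), `clinical` (participant_id, score_name,
#'   baseline_value, followup_value), `truth` (participant_id, bundle,
#'   measure, true_slope) and `session_weeks` (the nominal schedule).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  n <- cfg$n_participants
  ids <- sprintf("P%03d", seq_len(n))
  weeks <- cfg$session_weeks
  m <- length(weeks)

  # Acquisition calendar: follow-ups jittered uniformly in days, baseline
  # pinned to week 0. A 4-week grid with <=1 week jitter cannot reorder.
  jit_w <- cfg$jitter_days / 7
  acq <- matrix(rep(weeks, each = n), nrow = n)
  if (jit_w > 0 && m > 1) {
    acq[, -1] <- acq[, -1] + matrix(runif(n * (m - 1), -jit_w, jit_w),
                                    nrow = n)
  }

  # Covariates: fixed male/female counts, Gaussian age and disease duration.
  cp <- cfg$covariate_params
  sex <- sample(rep(c("M", "F"), c(cp$n_male, cp$n_female)))
  if (length(sex) != n) {
    stop_config("covariate_params male + female counts must equal %d", n)
  }
  covariates <- data.frame(
    participant_id = ids,
    age = rnorm(n, cp$age_mean, cp$age_sd),
    sex = sex,
    disease_duration = pmax(0, rnorm(n, cp$disease_duration_mean,
                                     cp$disease_duration_sd)),
    stringsAsFactors = FALSE
  )
  cb <- cfg$covariate_betas
  cov_shift <- cb$age * covariates$age +
    cb$sex_male * (covariates$sex == "M") +
    cb$disease_duration * covariates$disease_duration

  grid <- cfg$noise_sd  # one row per (bundle, measure) with its sigma
  rec_list <- vector("list", nrow(grid))
  truth_list <- vector("list", nrow(grid))
  r <- cfg$intercept_slope_corr
  for (g in seq_len(nrow(grid))) {
    bnd <- grid$bundle[g]
    msr <- grid$measure[g]
    sigma <- grid$noise_sd[g]
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    a_i <- cfg$intercept_sd * z1
    b_i <- cfg$slope_sd * (r * z1 + sqrt(1 - r^2) * z2)
    eps <- matrix(rnorm(n * m, 0, sigma), nrow = n)
    mu <- cfg$baseline_mean[[msr]]
    beta <- cfg$fixed_slope[[msr]]
    vals <- mu + cov_shift + a_i + outer(a_i * 0 + beta + b_i, rep(1, m)) * acq
    vals <- vals + eps
    rec_list[[g]] <- data.frame(
      participant_id = rep(ids, m),
      session_index = rep(seq_len(m) - 1L, each = n),
      acquisition_week = as.vector(acq),
      bundle = bnd, measure = msr,
      value = as.vector(vals),
      stringsAsFactors = FALSE
    )
    truth_list[[g]] <- data.frame(
      participant_id = ids, bundle = bnd, measure = msr,
      true_slope = beta + b_i, stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, rec_list)
  truth <- do.call(rbind, truth_list)

  # Missingness: per-session Bernoulli drops plus whole-participant dropout.
  keep <- matrix(TRUE, n, m)
  if (any(cfg$missing_rate > 0)) {
    for (j in seq_len(m)[-1]) {
      keep[, j] <- runif(n) >= cfg$missing_rate[j]
    }
  }
  if (cfg$n_dropout > 0) {
    dropped <- sample(ids, cfg$n_dropout)
    keep[match(dropped, ids), -1] <- FALSE
  }
  if (!all(keep)) {
    kd <- data.frame(participant_id = rep(ids, m),
                     session_index = rep(seq_len(m) - 1L, each = n),
                     keep = as.vector(keep))
    records <- merge(records, kd, by = c("participant_id", "session_index"))
    records <- records[records$keep, setdiff(names(records), "keep")]
  }
  records <- records[order(records$participant_id, records$session_index,
                           records$bundle, records$measure), ]
  rownames(records) <- NULL

  ds <- structure(
    list(records = records, covariates = covariates, clinical = NULL,
         truth = truth, session_weeks = weeks),
    class = "longitudinal_dataset"
  )
  ds$clinical <- simulate_clinical_impl(ds, cfg)
  ds
}

#' Simulate clinical change scores coupled to true slopes
#'
#' Generates baseline and follow-up clinical scores whose change
#' (follow-up minus baseline) has a controllable population Spearman
#' correlation with the true MRI slopes of the anchor (bundle, measure).
#' Coupling acts on the latent rank scale through a Gaussian copula: the
#' latent Pearson correlation is \eqn{2 \sin(\pi \rho_s / 6)} so that the
#' implied Spearman correlation equals the target \eqn{\rho_s}; marginals
#' are Gaussian with the configured change mean and SD.
#'
#' @param truth data.frame with participant_id and true_slope for the
#'   anchor (bundle, measure), e.g. a subset of `dataset$truth`.
#' @param config a [simulation_config()].
#' @return data.frame (participant_id, score_name, baseline_value,
#'   followup_value).
#' @export
simulate_clinical <- function(truth, config) {
  stopifnot(inherits(config, "simulation_config"))
  ds <- list(truth = truth)
  with_seed(derive_seed(config$seed, "clinical"),
            simulate_clinical_impl(ds, config, anchored = FALSE))
}

simulate_clinical_impl <- function(ds, cfg, anchored = TRUE) {
  truth <- ds$truth
  if (anchored) {
    truth <- truth[truth$bundle == cfg$clinical_anchor[["bundle"]] &
                     truth$measure == cfg$clinical_anchor[["measure"]], ]
  }
  if (nrow(truth) == 0 || anyDuplicated(truth$participant_id)) {
    stop_config("clinical coupling needs exactly one anchor slope per participant")
  }
  n <- nrow(truth)
  # Normal scores of the slope ranks: the copula's first latent coordinate.
  z_slope <- qnorm((rank(truth$true_slope, ties.method = "average") - 0.5) / n)
  scores <- cfg$clinical_scores
  out <- vector("list", nrow(scores))
  for (k in seq_len(nrow(scores))) {
    sc <- as.character(scores$score[k])
    rho_s <- cfg$clinical_target_spearman[[sc]]
    r_lat <- 2 * sin(pi * rho_s / 6)
    z <- r_lat * z_slope + sqrt(max(0, 1 - r_lat^2)) * rnorm(n)
    delta <- scores$delta_mean[k] + scores$delta_sd[k] * z
    base <- rnorm(n, mean = baseline_score_mean(sc), sd = baseline_score_sd(sc))
    out[[k]] <- data.frame(
      participant_id = truth$participant_id,
      score_name = sc,
      baseline_value = base,
      followup_value = base + delta,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Baseline score levels are cosmetic (only the change enters the analysis);
# values echo typical clinic-visit magnitudes.
baseline_score_mean <- function(score) {
  switch(score, EDSS = 2, SDMT = 57.1, `9HPT` = 23.5, T25FW = 6.2, 50)
}

baseline_score_sd <- function(score) {
  switch(score, EDSS = 1, SDMT = 11.4, `9HPT` = 9.8, T25FW = 2.5, 10)
}

#' @export
print.longitudinal_dataset <- function(x, ...) {
  ns <- length(unique(x$records$session_index))
  cat("<longitudinal_dataset>\n")
  cat(sprintf("  %d participants, %d sessions, %d bundles x %d measures\n",
              length(unique(x$records$participant_id)), ns,
              length(unique(x$records$bundle)),
              length(unique(x$records$measure))))
  cat(sprintf("  %d records; truth table %s\n", nrow(x$records),
              if (is.null(x$truth)) "absent" else "present"))
  invisible(x)
}
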