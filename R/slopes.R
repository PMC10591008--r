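# Participant-specific change estimation via linear mixed models.
#
# For one (bundle, measure) the model is
#   value ~ 1 + time (+ covariates) + (1 + time | participant)
# fitted by REML: time as fixed effect, correlated random intercept and
# slope per participant. A participant's change over time is the fixed time
# coefficient plus the participant's predicted random slope (the conditional
# mode, i.e. BLUP). Random-slope fits on three timepoints are fragile, so a
# documented fallback ladder is used: correlated random effects ->
# independent random effects -> random intercept with per-participant OLS
# slope deviations. Residual-free data short-circuits to exact
# per-participant OLS.

#' Fit a mixed model and extract per-participant slopes
#'
#' @param dataset a `longitudinal_dataset` (typically already restricted to
#'   a design via [subsample()]).
#' @param bundle,measure the (bundle, measure) cell to fit.
#' @param covariates character vector of participant-level fixed effects to
#'   adjust for, among `"age"`, `"sex"`, `"disease_duration"`; empty for an
#'   unadjusted fit.
#' @param design_name label stored with the resulting slopes.
#' @param time_scale `"acquisition"` uses the real (jittered) acquisition
#'   week as the time covariate; `"nominal"` uses the scheduled week of the
#'   session index.
#' @return list with `entries` (participant_id, bundle, measure,
#'   design_name, slope) and `meta` (method used, fixed effects, variance
#'   components, convergence flag).
#' @export
fit_lmm <- function(dataset, bundle, measure, covariates = character(),
                    design_name = "D_R",
                    time_scale = c("acquisition", "nominal")) {
  stopifnot(inherits(dataset, "longitudinal_dataset"))
  time_scale <- match.arg(time_scale)
  rec <- dataset$records
  rec <- rec[rec$bundle == bundle & rec$measure == measure, , drop = FALSE]
  if (nrow(rec) == 0) {
    stop_config("no records for bundle '%s', measure '%s'", bundle, measure)
  }
  if (length(unique(rec$participant_id)) < 3) {
    stop_config("mixed-model fit needs >= 3 participants")
  }
  df <- data.frame(
    participant_id = rec$participant_id,
    time = if (time_scale == "acquisition") rec$acquisition_week
           else dataset$session_weeks[rec$session_index + 1L],
    value = rec$value,
    stringsAsFactors = FALSE
  )
  nsess <- tapply(df$time, df$participant_id, length)
  if (any(nsess < 2)) {
    drop <- names(nsess)[nsess < 2]
    warning(sprintf("dropping %d participant(s) with < 2 sessions",
                    length(drop)), call. = FALSE)
    df <- df[!df$participant_id %in% drop, ]
  }
  if (length(covariates) > 0) {
    unknown <- setdiff(covariates, names(dataset$covariates))
    if (length(unknown) > 0) {
      stop_config("unknown covariate(s): %s", paste(unknown, collapse = ", "))
    }
    df <- merge(df, dataset$covariates[, c("participant_id", covariates),
                                       drop = FALSE],
                by = "participant_id")
    if ("sex" %in% covariates) df$sex <- factor(df$sex)
  }

  # Residual-free data: per-participant OLS is exact and the mixed model is
  # degenerate, so short-circuit.
  ols <- per_participant_ols(df)
  if (ols$max_resid < 1e-9 * max(1, max(abs(df$value)))) {
    entries <- data.frame(participant_id = names(ols$slopes),
                          bundle = bundle, measure = measure,
                          design_name = design_name,
                          slope = unname(ols$slopes),
                          stringsAsFactors = FALSE)
    meta <- list(bundle = bundle, measure = measure,
                 design_name = design_name, method = "ols_exact",
                 converged = TRUE,
                 fixed = c(time = unname(mean(ols$slopes))),
                 varcomp = c(residual = 0))
    return(list(entries = entries, meta = meta))
  }

  fixed_rhs <- paste(c("time", covariates), collapse = " + ")
  ladders <- list(
    correlated = paste0("value ~ ", fixed_rhs, " + (1 + time | participant_id)"),
    independent = paste0("value ~ ", fixed_rhs, " + (1 + time || participant_id)")
  )
  fit <- NULL
  method <- NA_character_
  for (nm in names(ladders)) {
    cand <- try_lmer(ladders[[nm]], df)
    if (!is.null(cand) && !lme4::isSingular(cand, tol = 1e-5)) {
      fit <- cand
      method <- nm
      break
    }
    if (is.null(fit) && !is.null(cand)) {
      fit <- cand  # keep a singular fit in case every rung is singular
      method <- paste0(nm, "_singular")
    }
  }

  if (!is.null(fit) && !grepl("singular", method)) {
    fe <- lme4::fixef(fit)
    re <- lme4::ranef(fit)$participant_id
    slopes <- fe[["time"]] + re[rownames(re), "time"]
    names(slopes) <- rownames(re)
    vc <- as.data.frame(lme4::VarCorr(fit))
    meta <- list(bundle = bundle, measure = measure,
                 design_name = design_name, method = method,
                 converged = length(fit@optinfo$conv$lme4$messages) == 0,
                 fixed = fe,
                 varcomp = setNames(vc$vcov,
                                    paste(vc$grp, vc$var1, vc$var2,
                                          sep = ".")))
  } else {
    # Random-intercept model plus centred per-participant OLS slope
    # deviations around the fixed slope.
    ri <- try_lmer(paste0("value ~ ", fixed_rhs, " + (1 | participant_id)"),
                   df)
    beta <- if (!is.null(ri)) lme4::fixef(ri)[["time"]]
            else unname(mean(ols$slopes))
    slopes <- beta + (ols$slopes - mean(ols$slopes))
    method <- "intercept_plus_ols"
    meta <- list(bundle = bundle, measure = measure,
                 design_name = design_name, method = method,
                 converged = !is.null(ri),
                 fixed = c(time = beta), varcomp = NULL)
  }
  ord <- order(names(slopes))
  entries <- data.frame(participant_id = names(slopes)[ord],
                        bundle = bundle, measure = measure,
                        design_name = design_name,
                        slope = unname(slopes)[ord],
                        stringsAsFactors = FALSE)
  if (any(!is.finite(entries$slope))) {
    stop_config("non-finite slope in fit for (%s, %s, %s)",
                bundle, measure, design_name)
  }
  list(entries = entries, meta = meta)
}

try_lmer <- function(formula_str, df) {
  tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(stats::as.formula(formula_str), data = df, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))
    )),
    error = function(e) NULL
  )
}

per_participant_ols <- function(df) {
  ids <- sort(unique(df$participant_id))
  slopes <- numeric(length(ids))
  max_resid <- 0
  for (i in seq_along(ids)) {
    d <- df[df$participant_id == ids[i], ]
    f <- lm(value ~ time, data = d)
    slopes[i] <- coef(f)[["time"]]
    max_resid <- max(max_resid, max(abs(stats::residuals(f))))
  }
  list(slopes = setNames(slopes, ids), max_resid = max_resid)
}

#' Fit slopes for every (bundle, measure, design) combination
#'
#' Subsamples the dataset to each design and runs [fit_lmm()] per
#' (bundle, measure), collecting all per-participant slopes into one tidy
#' table.
#'
#' @param dataset a `longitudinal_dataset`.
#' @param designs list of `design_spec` objects.
#' @param bundles,measures cells to fit; default all present.
#' @inheritParams fit_lmm
#' @return object of class `slope_table`: list with `entries` (one row per
#'   participant x bundle x measure x design) and `fit_meta` (list keyed by
#'   "bundle|measure|design").
#' @export
fit_slopes <- function(dataset, designs, bundles = NULL, measures = NULL,
                       covariates = character(),
                       time_scale = c("acquisition", "nominal")) {
  time_scale <- match.arg(time_scale)
  if (is.null(bundles)) bundles <- unique(dataset$records$bundle)
  if (is.null(measures)) measures <- unique(dataset$records$measure)
  entries <- list()
  meta <- list()
  for (d in designs) {
    sub <- subsample(dataset, d)
    for (b in bundles) {
      for (msr in measures) {
        fit <- fit_lmm(sub, b, msr, covariates = covariates,
                       design_name = d$name, time_scale = time_scale)
        key <- paste(b, msr, d$name, sep = "|")
        entries[[key]] <- fit$entries
        meta[[key]] <- fit$meta
      }
    }
  }
  structure(list(entries = do.call(rbind, c(entries, make.row.names = FALSE)),
                 fit_meta = meta),
            class = "slope_table")
}

#' Align participant change estimates across designs
#'
#' For one (bundle, measure), returns the participants x designs matrix of
#' estimated slopes, restricted to participants present in every requested
#' design, with rows sorted by participant id.
#'
#' @param slopes a `slope_table` (or its `entries` data.frame).
#' @param designs character vector of design names (column order).
#' @param bundle,measure cell to extract.
#' @return numeric matrix, rownames participant ids, colnames design names.
#' @export
extract_change_vectors <- function(slopes, designs, bundle, measure) {
  entries <- if (inherits(slopes, "slope_table")) slopes$entries else slopes
  sub <- entries[entries$bundle == bundle & entries$measure == measure &
                   entries$design_name %in% designs, , drop = FALSE]
  present <- unique(sub$design_name)
  absent <- setdiff(designs, present)
  if (length(absent) > 0) {
    stop_config("no slopes for design(s): %s", paste(absent, collapse = ", "))
  }
  tabs <- split(sub, sub$design_name)
  common <- Reduce(intersect, lapply(tabs, function(t) t$participant_id))
  n_drop <- length(unique(sub$participant_id)) - length(common)
  if (n_drop > 0) {
    message(sprintf("extract_change_vectors: excluded %d participant(s) missing from some design", n_drop))
  }
  common <- sort(common)
  if (length(common) == 0) stop_config("no participant present in all designs")
  mat <- sapply(designs, function(dn) {
    t <- tabs[[dn]]
    t$slope[match(common, t$participant_id)]
  })
  mat <- matrix(mat, nrow = length(common),
                dimnames = list(common, designs))
  mat
}

#' Write slope-table entries as tidy CSV
#' @param slopes a `slope_table`.
#' @param path CSV file path.
#' @export
write_slopes <- function(slopes, path) {
  stopifnot(inherits(slopes, "slope_table"))
  write.csv(slopes$entries, path, row.names = FALSE)
  invisible(path)
}
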