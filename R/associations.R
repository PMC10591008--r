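# MRI-clinical association analysis and the preservation ledger.
#
# Clinical change is the follow-up minus baseline score from the study's
# first and last clinical visits, regardless of which MRI sessions a design
# retains. Associations between per-participant MRI slopes and clinical
# change use Spearman correlation at an uncorrected p < 0.01. Each tested
# design's associations are then classified against the reference design:
# preserved (significant in both, same sign), inverse (significant in both,
# opposite sign), lost (reference only) or new (tested only).

#' Clinical change scores
#'
#' @param clinical data.frame (participant_id, score_name, baseline_value,
#'   followup_value).
#' @return data.frame (participant_id, score_name, delta) with
#'   `delta = followup - baseline`; records with a missing value are
#'   skipped with a message.
#' @export
clinical_change <- function(clinical) {
  if (is.null(clinical) || nrow(clinical) == 0) {
    warning("empty clinical table", call. = FALSE)
    return(data.frame(participant_id = character(),
                      score_name = character(), delta = numeric()))
  }
  ok <- is.finite(clinical$baseline_value) &
    is.finite(clinical$followup_value)
  if (any(!ok)) {
    message(sprintf("clinical_change: skipped %d record(s) with missing values",
                    sum(!ok)))
  }
  cl <- clinical[ok, , drop = FALSE]
  data.frame(participant_id = cl$participant_id,
             score_name = cl$score_name,
             delta = cl$followup_value - cl$baseline_value,
             stringsAsFactors = FALSE)
}

#' Wilcoxon signed-rank test for paired change
#'
#' Zeros are dropped (the classical zero-handling); the statistic `V` is
#' the sum of the ranks of positive differences over the average ranks of
#' the absolute differences. The two-sided p-value is exact — computed from
#' the full distribution of `V` over all sign assignments, which remains
#' valid under ties — for up to 15 nonzero differences, and uses the
#' normal approximation with tie correction and continuity correction
#' beyond that.
#'
#' @param deltas numeric vector of paired differences.
#' @return list with `statistic` (V), `p`, `n` (nonzero differences) and
#'   `method` ("exact" or "normal").
#' @export
wilcoxon_paired <- function(deltas) {
  d <- deltas[is.finite(deltas)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop_config("all paired differences are zero")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 15) {
    # Distribution of V by dynamic programming over 2*ranks (integers even
    # under average-rank ties).
    ir <- as.integer(round(2 * r))
    total <- sum(ir)
    dist <- numeric(total + 1)  # index s+1 = P(2V = s) * 2^n
    dist[1] <- 1
    for (w in ir) {
      shifted <- c(numeric(w), dist[seq_len(total + 1 - w)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    s_obs <- as.integer(round(2 * v))
    p_le <- sum(dist[seq_len(s_obs + 1)])
    p_ge <- sum(dist[(s_obs + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal"
  }
  list(statistic = v, p = p, n = n, method = method)
}

#' Spearman rank correlation with small-sample exact p-value
#'
#' Rank correlation with average ranks for ties. The two-sided p-value is
#' exact by full permutation enumeration for `n <= 9` without ties, and
#' uses the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` otherwise.
#'
#' @param x,y paired numeric vectors, `n >= 5`.
#' @return list with `rho`, `p`, `n`, `method`.
#' @export
spearman_assoc <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop_config("Spearman association needs >= 5 pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input; Spearman correlation undefined", call. = FALSE)
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  has_ties <- anyDuplicated(rx) > 0 || anyDuplicated(ry) > 0
  if (n <= 9 && !has_ties) {
    rhos <- perm_spearman_null(n)
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    denom <- 1 - rho^2
    if (denom <= 0) {
      p <- 0
    } else {
      tval <- rho * sqrt((n - 2) / denom)
      p <- 2 * pt(-abs(tval), n - 2)
    }
    method <- "t"
  }
  list(rho = rho, p = p, n = n, method = method)
}

# Null distribution of the Spearman coefficient for untied samples of size
# n: correlation of 1..n with every permutation. Cached per n.
perm_null_cache <- new.env(parent = emptyenv())

perm_spearman_null <- function(n) {
  key <- as.character(n)
  if (!is.null(perm_null_cache[[key]])) return(perm_null_cache[[key]])
  perms <- all_permutations(n)
  base <- seq_len(n)
  num <- perms %*% base - n * (n + 1)^2 / 4
  den <- sum((base - mean(base))^2)
  rhos <- as.numeric(num) / den
  perm_null_cache[[key]] <- rhos
  rhos
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                 sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[row + seq_len(nrow(sub)), ] <- blk
    row <- row + nrow(sub)
  }
  out
}

#' Slope-clinical associations per design
#'
#' For every (bundle, measure, design, score) cell, joins the design's
#' per-participant slopes with the clinical change scores and computes the
#' Spearman association.
#'
#' @param slopes a `slope_table` (see [fit_slopes()]) or its entries.
#' @param clinical clinical table (participant_id, score_name,
#'   baseline_value, followup_value) or precomputed changes from
#'   [clinical_change()].
#' @param alpha significance threshold (uncorrected), default 0.01.
#' @return data.frame (bundle, measure, design_name, score, rho, p, n,
#'   significant).
#' @export
associate_designs <- function(slopes, clinical, alpha = 0.01) {
  entries <- if (inherits(slopes, "slope_table")) slopes$entries else slopes
  deltas <- if ("delta" %in% names(clinical)) clinical
            else clinical_change(clinical)
  cells <- unique(entries[, c("bundle", "measure", "design_name")])
  scores <- unique(deltas$score_name)
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    sl <- entries[entries$bundle == cell$bundle &
                    entries$measure == cell$measure &
                    entries$design_name == cell$design_name, ]
    for (sc in scores) {
      dl <- deltas[deltas$score_name == sc, ]
      j <- match(sl$participant_id, dl$participant_id)
      ok <- !is.na(j)
      res <- spearman_assoc(sl$slope[ok], dl$delta[j[ok]])
      rows[[length(rows) + 1L]] <- data.frame(
        bundle = cell$bundle, measure = cell$measure,
        design_name = cell$design_name, score = sc,
        rho = res$rho, p = res$p, n = res$n,
        significant = isTRUE(res$p < alpha),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Build the association-preservation ledger
#'
#' Classifies each tested design's associations against the reference
#' design's. For each (bundle, measure, score) cell significant in the
#' reference, a tested design either preserves it (significant, same
#' sign), inverts it (significant, opposite sign) or loses it (not
#' significant); these three statuses partition the reference-significant
#' set. Cells significant only in a tested design are "new".
#'
#' @param assoc association table from [associate_designs()], covering the
#'   reference and all tested designs on the same (bundle, measure, score)
#'   grid.
#' @param reference reference design name.
#' @param require_sign when TRUE (default) "preserved" requires the same
#'   correlation sign; when FALSE any significant pair counts as preserved
#'   and "inverse" is empty.
#' @return object of class `association_ledger`: list with `records` (the
#'   input plus a `status` column), `frequencies` (per design: preserved /
#'   inverse / lost / new counts and preserved percentage of the reference
#'   total), `by_bundle` and `by_measure` preserved-percentage breakdowns,
#'   and `reference_total`.
#' @export
build_ledger <- function(assoc, reference = "D_R", require_sign = TRUE) {
  if (!reference %in% assoc$design_name) {
    stop_config("reference design '%s' absent from association table",
                reference)
  }
  keyof <- function(d) paste(d$bundle, d$measure, d$score, sep = "|")
  ref <- assoc[assoc$design_name == reference, ]
  ref_keys <- keyof(ref)
  if (anyDuplicated(ref_keys)) stop_config("duplicate reference cells")
  tested_names <- setdiff(unique(assoc$design_name), reference)
  assoc$status <- "none"
  assoc$status[assoc$design_name == reference & assoc$significant] <-
    "reference"
  reference_total <- sum(ref$significant, na.rm = TRUE)

  freq_rows <- list()
  for (dn in tested_names) {
    tst <- assoc[assoc$design_name == dn, ]
    tkeys <- keyof(tst)
    if (!setequal(tkeys, ref_keys) || anyDuplicated(tkeys)) {
      stop_config("design '%s' is not on the reference association grid", dn)
    }
    j <- match(tkeys, ref_keys)
    ref_sig <- ref$significant[j]
    ref_rho <- ref$rho[j]
    same_sign <- !require_sign | (sign(tst$rho) == sign(ref_rho))
    status <- rep("none", nrow(tst))
    status[ref_sig & tst$significant & same_sign] <- "preserved"
    status[ref_sig & tst$significant & !same_sign] <- "inverse"
    status[ref_sig & !tst$significant] <- "lost"
    status[!ref_sig & tst$significant] <- "new"
    assoc$status[assoc$design_name == dn] <- status
    pct <- function(k) if (reference_total > 0) 100 * k / reference_total
                       else 0
    freq_rows[[dn]] <- data.frame(
      design_name = dn,
      preserved = sum(status == "preserved"),
      inverse = sum(status == "inverse"),
      lost = sum(status == "lost"),
      new = sum(status == "new"),
      preserved_pct = pct(sum(status == "preserved")),
      inverse_pct = pct(sum(status == "inverse")),
      stringsAsFactors = FALSE)
  }
  frequencies <- do.call(rbind, c(freq_rows, make.row.names = FALSE))

  breakdown <- function(by) {
    tst <- assoc[assoc$design_name != reference, ]
    agg <- aggregate(list(preserved = tst$status == "preserved"),
                     by = list(group = tst[[by]],
                               design_name = tst$design_name),
                     FUN = sum)
    agg$preserved_pct <- if (reference_total > 0) {
      100 * agg$preserved / reference_total
    } else 0
    names(agg)[1] <- by
    agg
  }

  structure(list(records = assoc,
                 frequencies = frequencies,
                 by_bundle = breakdown("bundle"),
                 by_measure = breakdown("measure"),
                 reference_total = reference_total,
                 reference = reference),
            class = "association_ledger")
}

#' @export
print.association_ledger <- function(x, ...) {
  cat(sprintf("<association_ledger> %d reference association(s)\n",
              x$reference_total))
  if (!is.null(x$frequencies)) print(x$frequencies)
  invisible(x)
}

#' Write ledger tables as CSV
#' @param ledger an `association_ledger`.
#' @param dir output directory.
#' @export
write_ledger <- function(ledger, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(ledger$records, file.path(dir, "associations.csv"),
            row.names = FALSE)
  if (!is.null(ledger$frequencies)) {
    write.csv(ledger$frequencies, file.path(dir, "frequencies.csv"),
              row.names = FALSE)
    write.csv(ledger$by_bundle, file.path(dir, "frequencies_by_bundle.csv"),
              row.names = FALSE)
    write.csv(ledger$by_measure, file.path(dir, "frequencies_by_measure.csv"),
              row.names = FALSE)
  }
  invisible(dir)
}
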