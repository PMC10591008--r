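# Clinical change, exact small-sample tests and the association ledger.

test_that("clinical change is follow-up minus baseline with skips logged", {
  cl <- data.frame(participant_id = c("P1", "P2", "P3"),
                   score_name = "9HPT",
                   baseline_value = c(23.5, 20, NA),
                   followup_value = c(22.7, 20, 25))
  expect_message(ch <- clinical_change(cl), "skipped 1")
  expect_equal(nrow(ch), 2)
  expect_equal(ch$delta, c(-0.8, 0))
  expect_warning(empty <- clinical_change(cl[0, ]), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("Wilcoxon exact p matches the textbook all-positive case", {
  res <- wilcoxon_paired(c(0.3, 1.1, 0.4, 2.2, 0.9))
  expect_equal(res$statistic, 15)
  expect_equal(res$p, 2 / 2^5)
  expect_equal(res$method, "exact")
})

test_that("Wilcoxon exact p matches exhaustive sign enumeration", {
  set.seed(66)
  for (case in 1:5) {
    d <- round(rnorm(8, 0.3, 1), 2)
    d <- d[d != 0]
    res <- wilcoxon_paired(d)
    expect_equal(res$p, bf_wilcoxon_p(d), tolerance = 1e-12)
  }
  # with ties in |d| the enumeration stays valid
  d_tied <- c(1, -1, 2, 2, -3, 4, 4, -5)
  expect_equal(wilcoxon_paired(d_tied)$p, bf_wilcoxon_p(d_tied),
               tolerance = 1e-12)
  # agreement with the base implementation on a tie-free sample
  d2 <- c(0.7, -1.3, 2.9, 0.4, -0.2, 1.8, 3.3, -2.1)
  expect_equal(wilcoxon_paired(d2)$p,
               wilcox.test(d2, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("Wilcoxon edge cases: zeros dropped, symmetry, degenerate input", {
  expect_error(wilcoxon_paired(c(0, 0, 0)), "zero")
  # antisymmetric sample: statistic at the distribution midpoint
  d <- c(1.5, -1.5, 0.8, -0.8, 2.2, -2.2)
  res <- wilcoxon_paired(d)
  expect_equal(res$statistic, 6 * 7 / 4)
  # zeros are dropped before ranking
  expect_equal(wilcoxon_paired(c(0, 1, 2, 3))$n, 3)
  # large-sample route reports its method
  set.seed(1)
  expect_equal(wilcoxon_paired(rnorm(30, 0.4))$method, "normal")
})

test_that("Spearman coefficient hits the monotone extremes", {
  x <- c(3, 8, 1, 9, 5)
  res <- spearman_assoc(x, exp(x))
  expect_equal(res$rho, 1)
  res2 <- spearman_assoc(x, -x)
  expect_equal(res2$rho, -1)
  expect_warning(res3 <- spearman_assoc(x, rep(1, 5)), "constant")
  expect_true(is.na(res3$rho))
  expect_error(spearman_assoc(1:3, 3:1), ">= 5")
})

test_that("Spearman exact p matches the full permutation distribution", {
  set.seed(30)
  for (case in 1:4) {
    x <- sample(100, 7)
    y <- sample(100, 7)
    res <- spearman_assoc(x, y)
    expect_equal(res$method, "exact")
    ref <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(res$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(res$p, ref$p.value, tolerance = 1e-9)
  }
  # ties fall back to the t approximation
  xt <- c(1, 1, 2, 3, 4, 5, 6)
  yt <- c(2, 1, 4, 3, 6, 5, 7)
  expect_equal(spearman_assoc(xt, yt)$method, "t")
})

assoc_cache <- new.env(parent = emptyenv())

make_assoc_fixture <- function(seed = 123, coupling = 0.8) {
  key <- paste(seed, coupling)
  if (!is.null(assoc_cache[[key]])) return(assoc_cache[[key]])
  assoc_cache[[key]] <- make_assoc_fixture_impl(seed, coupling)
  assoc_cache[[key]]
}

make_assoc_fixture_impl <- function(seed = 123, coupling = 0.8) {
  cfg <- simulation_config(
    n_participants = 14, bundles = c("CC3", "CST"),
    measures = c("MD", "FW"), clinical_target_spearman = coupling,
    seed = seed)
  ds <- simulate_dataset(cfg)
  designs <- enumerate_designs(5, 3)
  st <- fit_slopes(ds, designs)
  associate_designs(st, ds$clinical)
}

test_that("self-comparison preserves every reference association", {
  assoc <- make_assoc_fixture()
  # duplicate the reference under a tested-design name
  clone <- assoc[assoc$design_name == "D_R", ]
  clone$design_name <- "D_clone"
  led <- build_ledger(rbind(assoc[assoc$design_name == "D_R", ], clone))
  row <- led$frequencies[led$frequencies$design_name == "D_clone", ]
  expect_equal(row$preserved, led$reference_total)
  expect_equal(row$preserved_pct, 100)
  expect_equal(row$new, 0)
  expect_equal(row$inverse + row$lost, 0)
})

test_that("a sign-flipped design turns every preserved cell inverse", {
  assoc <- make_assoc_fixture()
  ref <- assoc[assoc$design_name == "D_R", ]
  flip <- ref
  flip$design_name <- "D_flip"
  flip$rho <- -flip$rho
  led <- build_ledger(rbind(ref, flip))
  row <- led$frequencies[led$frequencies$design_name == "D_flip", ]
  expect_equal(row$inverse, led$reference_total)
  expect_equal(row$preserved, 0)
  # significance-only mode counts them as preserved instead
  led2 <- build_ledger(rbind(ref, flip), require_sign = FALSE)
  row2 <- led2$frequencies[led2$frequencies$design_name == "D_flip", ]
  expect_equal(row2$preserved, led2$reference_total)
  expect_equal(row2$inverse, 0)
})

test_that("preserved, inverse and lost partition the reference set", {
  assoc <- make_assoc_fixture(seed = 9, coupling = 0.7)
  led <- build_ledger(assoc)
  expect_gt(led$reference_total, 0)
  for (i in seq_len(nrow(led$frequencies))) {
    row <- led$frequencies[i, ]
    expect_equal(row$preserved + row$inverse + row$lost,
                 led$reference_total)
  }
  # frequencies invariant to grid ordering
  shuffled <- assoc[sample(nrow(assoc)), ]
  led2 <- build_ledger(shuffled)
  f1 <- led$frequencies[order(led$frequencies$design_name), ]
  f2 <- led2$frequencies[order(led2$frequencies$design_name), ]
  rownames(f1) <- rownames(f2) <- NULL
  expect_equal(f1, f2)
})

test_that("grid mismatches and absent references are rejected", {
  assoc <- make_assoc_fixture()
  expect_error(build_ledger(assoc, reference = "D_999"), "reference")
  broken <- assoc[-(which(assoc$design_name == "D_012")[1]), ]
  expect_error(build_ledger(broken), "grid")
})

test_that("ledger breakdowns by bundle and measure sum to the design totals", {
  assoc <- make_assoc_fixture(seed = 4, coupling = 0.9)
  led <- build_ledger(assoc)
  for (dn in unique(led$by_bundle$design_name)) {
    expect_equal(sum(led$by_bundle$preserved[led$by_bundle$design_name == dn]),
                 led$frequencies$preserved[led$frequencies$design_name == dn])
    expect_equal(sum(led$by_measure$preserved[led$by_measure$design_name == dn]),
                 led$frequencies$preserved[led$frequencies$design_name == dn])
  }
  expect_true(all(led$frequencies$preserved_pct >= 0 &
                    led$frequencies$preserved_pct <= 100))
})
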