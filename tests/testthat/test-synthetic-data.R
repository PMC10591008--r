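# Synthetic longitudinal data generator.

test_that("default configuration yields the expected cohort structure", {
  cfg <- simulation_config(seed = 11)
  ds <- simulate_dataset(cfg)
  rec <- ds$records
  # 20 participants x 5 sessions = 100 participant-sessions
  ps <- unique(rec[, c("participant_id", "session_index")])
  expect_equal(nrow(ps), 100)
  expect_equal(length(unique(rec$bundle)), 5)
  expect_equal(length(unique(rec$measure)), 8)
  expect_equal(nrow(rec), 100 * 5 * 8)
  # demographics: 4 male / 16 female, age drawn around 36
  expect_equal(sum(ds$covariates$sex == "M"), 4)
  expect_equal(sum(ds$covariates$sex == "F"), 16)
  expect_lt(abs(mean(ds$covariates$age) - 36), 3 * 4.7 / sqrt(20))
  # baseline pinned at week 0, follow-ups within +/- 1 week of nominal
  expect_true(all(rec$acquisition_week[rec$session_index == 0] == 0))
  for (s in 1:4) {
    w <- rec$acquisition_week[rec$session_index == s]
    expect_true(all(abs(w - 4 * s) <= 1 + 1e-12))
  }
  # acquisition weeks strictly increasing within participant
  one <- rec[rec$bundle == "CC3" & rec$measure == "MD", ]
  one <- one[order(one$participant_id, one$session_index), ]
  gaps <- unlist(tapply(one$acquisition_week, one$participant_id, diff))
  expect_true(all(gaps > 0))
})

test_that("identical config and seed give bit-identical datasets", {
  cfg <- test_config(8, seed = 7)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$records, d2$records)
  expect_identical(d1$covariates, d2$covariates)
  expect_identical(d1$clinical, d2$clinical)
  expect_identical(d1$truth, d2$truth)
  d3 <- simulate_dataset(test_config(8, seed = 8))
  expect_false(identical(d1$records$value, d3$records$value))
})

test_that("noise-free datasets are exactly linear per participant", {
  cfg <- test_config(6, jitter_days = 0, noise_sd = 0, slope_sd = 0,
                     intercept_sd = 0, seed = 2)
  ds <- simulate_dataset(cfg)
  beta <- cfg$fixed_slope[["MD"]]
  mu <- cfg$baseline_mean[["MD"]]
  pred <- mu + beta * ds$records$acquisition_week
  expect_lt(max(abs(ds$records$value - pred)), 1e-9)
})

test_that("random-effect and residual moments are recovered at large n", {
  cfg <- test_config(2000, slope_sd = 0.01, noise_sd = 0.05, seed = 31)
  ds <- simulate_dataset(cfg)
  expect_lt(abs(var(ds$truth$true_slope) / 0.01^2 - 1), 0.05)
  # pooled per-participant OLS residual variance, df-corrected
  rec <- ds$records
  sse <- 0
  for (sp in split(rec, rec$participant_id)) {
    f <- lm(value ~ acquisition_week, data = sp)
    sse <- sse + sum(residuals(f)^2)
  }
  res_var <- sse / (2000 * (5 - 2))
  expect_lt(abs(res_var / 0.05^2 - 1), 0.05)
})

test_that("configuration errors are caught before any simulation", {
  expect_error(simulation_config(session_weeks = c(0, 8, 4)),
               "strictly increasing")
  expect_error(simulation_config(session_weeks = c(4, 8, 12)),
               "start at 0")
  expect_error(simulation_config(slope_sd = -1), "non-negative")
  expect_error(simulation_config(clinical_target_spearman = 1.5),
               "\\[-1, 1\\]")
  expect_error(simulation_config(missing_rate = 1.2), "missing_rate")
})

test_that("perfect rank coupling makes clinical change monotone in truth", {
  cfg <- test_config(12, clinical_target_spearman = 1, seed = 5)
  ds <- simulate_dataset(cfg)
  truth <- ds$truth[ds$truth$bundle == "CC3" & ds$truth$measure == "MD", ]
  ch <- clinical_change(ds$clinical)
  for (sc in unique(ch$score_name)) {
    d <- ch[ch$score_name == sc, ]
    j <- match(truth$participant_id, d$participant_id)
    expect_equal(cor(truth$true_slope, d$delta[j], method = "spearman"), 1)
  }
})

test_that("copula coupling hits the target Spearman correlation at large n", {
  cfg <- test_config(2000, clinical_target_spearman = 0.6, seed = 13)
  ds <- simulate_dataset(cfg)
  truth <- ds$truth
  ch <- clinical_change(ds$clinical)
  d <- ch[ch$score_name == "SDMT", ]
  j <- match(truth$participant_id, d$participant_id)
  rho <- cor(truth$true_slope, d$delta[j], method = "spearman")
  # compare on the Fisher-z scale, 3 standard errors
  expect_lt(abs(atanh(rho) - atanh(0.6)), 3 / sqrt(2000 - 3))
  # marginal moments: SDMT change mean 4.4 (SD 13.8)
  expect_lt(abs(mean(d$delta) - 4.4), 3 * 13.8 / sqrt(2000))
})

test_that("dropout and per-session missingness thin follow-ups only", {
  cfg <- test_config(20, n_dropout = 1, seed = 3)
  ds <- simulate_dataset(cfg)
  n_by_session <- table(ds$records$session_index)
  expect_equal(unname(n_by_session[["0"]]), 20)
  expect_true(all(n_by_session[c("1", "2", "3", "4")] == 19))

  cfg2 <- test_config(200, missing_rate = c(0, 0.3, 0.3, 0.3, 0.3),
                      seed = 9)
  ds2 <- simulate_dataset(cfg2)
  tab <- table(ds2$records$session_index)
  expect_equal(unname(tab[["0"]]), 200)
  expect_true(all(tab[c("1", "2", "3", "4")] < 200))
})

test_that("datasets survive a CSV round trip", {
  cfg <- test_config(6, seed = 21)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$records, ds$records, tolerance = 1e-12)
  expect_equal(back$clinical, ds$clinical, tolerance = 1e-12)
  expect_equal(back$truth, ds$truth, tolerance = 1e-12)
  expect_equal(back$session_weeks, ds$session_weeks)
})

test_that("schema violations are reported by column", {
  cfg <- test_config(5, seed = 1)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  rec <- read.csv(file.path(dir, "records.csv"))
  rec$participant_id <- NULL
  write.csv(rec, file.path(dir, "records.csv"), row.names = FALSE)
  expect_error(read_dataset(dir), "participant_id")
})

test_that("an empty records table reads back with a warning", {
  dir <- withr::local_tempdir()
  empty <- data.frame(participant_id = character(),
                      session_index = integer(),
                      acquisition_week = numeric(), bundle = character(),
                      measure = character(), value = numeric())
  write.csv(empty, file.path(dir, "records.csv"), row.names = FALSE)
  expect_warning(ds <- read_dataset(dir), "empty")
  expect_equal(nrow(ds$records), 0)
})
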