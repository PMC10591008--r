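# End-to-end orchestration: simulate -> subsample -> fit -> compare ->
# power -> associate, with seeded substreams per stage, CSV/JSON outputs
# and a manifest recording the configuration hash.

#' Run configuration
#'
#' Bundles the simulation settings, the design menu and the analysis
#' thresholds of a full study run.
#'
#' @param simulation a [simulation_config()].
#' @param designs list of `design_spec`, or `"auto"` to enumerate all
#'   baseline-anchored designs of size `k` plus the reference.
#' @param k tested-design size when `designs = "auto"`.
#' @param anova_alpha,assoc_alpha,mauchly_alpha analysis thresholds.
#' @param covariates participant-level fixed effects for the slope model.
#' @param power a [power_config()] holding f, alpha and target power.
#' @param output_dir where [run_study()] writes results.
#' @param seed root seed; stage streams are derived from it.
#' @param replicates reserved for Monte-Carlo summaries (>= 1).
#' @return validated list of class `run_config`.
#' @export
run_config <- function(simulation = simulation_config(),
                       designs = "auto", k = 3,
                       anova_alpha = 0.05, assoc_alpha = 0.01,
                       mauchly_alpha = 0.05,
                       covariates = character(),
                       power = power_config(),
                       output_dir = tempfile("longdesign_run_"),
                       seed = 1L, replicates = 1L) {
  for (nm in c("anova_alpha", "assoc_alpha", "mauchly_alpha")) {
    if (!is_prob(get(nm))) stop_config("'%s' must lie in (0, 1)", nm)
  }
  if (!is_count(replicates) || replicates < 1) {
    stop_config("'replicates' must be a positive integer")
  }
  stopifnot(inherits(simulation, "simulation_config"),
            inherits(power, "power_config"))
  if (identical(designs, "auto")) {
    designs <- enumerate_designs(length(simulation$session_weeks), k,
                                 session_weeks = simulation$session_weeks)
  }
  stopifnot(all(vapply(designs, inherits, TRUE, "design_spec")))
  structure(list(simulation = simulation, designs = designs,
                 anova_alpha = anova_alpha, assoc_alpha = assoc_alpha,
                 mauchly_alpha = mauchly_alpha, covariates = covariates,
                 power = power, output_dir = output_dir,
                 seed = as.integer(seed),
                 replicates = as.integer(replicates)),
            class = "run_config")
}

#' Run the full design-evaluation study
#'
#' Executes every stage on one simulated dataset and writes all results
#' under `config$output_dir`:
#' \itemize{
#'   \item `dataset/` — the simulated long-format tables;
#'   \item `slopes.csv` — per-participant slopes per (bundle, measure,
#'     design);
#'   \item `comparisons.csv` — RM-ANOVA per (bundle, measure) across
#'     designs, with Mauchly, epsilon and FDR-adjusted Tukey columns;
#'   \item `similarity.csv` — per-cell design-vs-reference Pearson r;
#'   \item `sample_sizes.csv` — the correlation-adjusted sample-size
#'     sweep;
#'   \item `associations/` — association ledger tables;
#'   \item `manifest.json` — seed, configuration hash, thresholds, design
#'     menu and stage record counts.
#' }
#'
#' @param config a [run_config()].
#' @return invisibly, a list with all in-memory stage results.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  sim_cfg <- config$simulation
  sim_cfg$seed <- derive_seed(config$seed, "simulate")
  dataset <- simulate_dataset(sim_cfg)
  write_dataset(dataset, file.path(out, "dataset"))

  designs <- lapply(config$designs, classify_design,
                    session_weeks = dataset$session_weeks)
  write_designs(designs, file.path(out, "designs.json"))

  slopes <- fit_slopes(dataset, designs, covariates = config$covariates)
  write_slopes(slopes, file.path(out, "slopes.csv"))

  design_names <- vapply(designs, function(d) d$name, "")
  ref <- design_names[1]
  cells <- unique(slopes$entries[, c("bundle", "measure")])
  comp_rows <- list()
  sim_rows <- list()
  sim_mats <- list()
  for (i in seq_len(nrow(cells))) {
    b <- cells$bundle[i]; msr <- cells$measure[i]
    mat <- extract_change_vectors(slopes, design_names, b, msr)
    cmp <- compare_designs(mat, mauchly_alpha = config$mauchly_alpha,
                           alpha = config$anova_alpha)
    comp_rows[[i]] <- data.frame(
      bundle = b, measure = msr, F = cmp$F, df1 = cmp$df1, df2 = cmp$df2,
      p = cmp$p, mauchly_W = cmp$mauchly_W, mauchly_p = cmp$mauchly_p,
      epsilon_gg = cmp$epsilon_gg, epsilon_applied = cmp$epsilon_applied,
      stringsAsFactors = FALSE)
    sim_mats[[paste(b, msr, sep = "|")]] <- cmp$similarity
    sr <- similarity_to_reference(cmp$similarity, reference = ref)
    sim_rows[[i]] <- data.frame(bundle = b, measure = msr,
                                design_name = names(sr), r = unname(sr),
                                stringsAsFactors = FALSE)
  }
  comparisons <- do.call(rbind, c(comp_rows, make.row.names = FALSE))
  comparisons$p_fdr <- bh_fdr(comparisons$p)
  write.csv(comparisons, file.path(out, "comparisons.csv"),
            row.names = FALSE)
  similarity <- do.call(rbind, c(sim_rows, make.row.names = FALSE))
  write.csv(similarity, file.path(out, "similarity.csv"), row.names = FALSE)

  sizes <- sample_size_sweep(dataset, designs,
                             f = config$power$f,
                             alpha = config$power$alpha,
                             target_power = config$power$target_power,
                             epsilon = config$power$epsilon)
  write.csv(sizes, file.path(out, "sample_sizes.csv"), row.names = FALSE)

  assoc <- associate_designs(slopes, dataset$clinical,
                             alpha = config$assoc_alpha)
  ledger <- build_ledger(assoc, reference = ref)
  write_ledger(ledger, file.path(out, "associations"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("longdesign")),
    seed = config$seed,
    config_hash = config_hash(config),
    designs = design_names,
    thresholds = list(anova_alpha = config$anova_alpha,
                      assoc_alpha = config$assoc_alpha,
                      mauchly_alpha = config$mauchly_alpha,
                      power_f = config$power$f,
                      power_alpha = config$power$alpha,
                      target_power = config$power$target_power),
    counts = list(records = nrow(dataset$records),
                  slopes = nrow(slopes$entries),
                  comparisons = nrow(comparisons),
                  associations = nrow(assoc),
                  reference_associations = ledger$reference_total)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(dataset = dataset, designs = designs, slopes = slopes,
                 comparisons = comparisons, similarity = similarity,
                 similarity_matrices = sim_mats, sample_sizes = sizes,
                 ledger = ledger, manifest = manifest,
                 output_dir = out))
}

# Stable hash of the run configuration (FNV-style over its serialized
# form), so reruns can be matched to their settings.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- NULL  # the hash identifies the settings, not the sink
  txt <- paste(utils::capture.output(utils::str(cfg, digits.d = 12)),
               collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) h <- ((h * 16777619) + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Summarize a completed run
#'
#' Reads the result files of a [run_study()] output directory and returns
#' the headline tables: mean design-to-reference similarity, the
#' bundle x design sample-size matrix, and preserved-association
#' frequencies.
#'
#' @param dir a [run_study()] output directory.
#' @return list with `similarity_summary` (mean r per design),
#'   `sample_size_matrix` (bundle x design, averaged over measures) and
#'   `preserved_frequencies`.
#' @export
report <- function(dir) {
  need <- c("similarity.csv", "sample_sizes.csv",
            file.path("associations", "frequencies.csv"))
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0) {
    stop_config("incomplete run: missing %s", paste(missing, collapse = ", "))
  }
  similarity <- read.csv(file.path(dir, "similarity.csv"))
  sim_summary <- aggregate(r ~ design_name, similarity, mean)
  sizes <- read.csv(file.path(dir, "sample_sizes.csv"))
  nmat <- tapply(sizes$n_required,
                 list(sizes$bundle, sizes$design_name),
                 function(x) mean(x, na.rm = TRUE))
  freqs <- read.csv(file.path(dir, "associations", "frequencies.csv"))
  list(similarity_summary = sim_summary,
       sample_size_matrix = nmat,
       preserved_frequencies = freqs)
}
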