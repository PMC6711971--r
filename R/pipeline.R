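CONFIG_DEFAULTS <- list(
  seed = 1,
  arms = c("B1HB2", "H1BH2"),
  n_bhb = 16,
  n_hbh = 19,
  p_missing_visit = 0.1,
  p_replicate_visit = 0.15,
  n_features_long = 300,
  n_features_small = 100,
  n_controls = 20,
  truth_fractions_long = c(acute_up = 0.05, acute_down = 0.05,
                           recovery_up = 0.03, recovery_down = 0.03,
                           continuous_up = 0.02, continuous_down = 0.02,
                           reversal_up_down = 0.02, reversal_down_up = 0.02),
  truth_fractions_small = c(condition_up = 0.05, condition_down = 0.10),
  delta_long = 30,
  delta_small = 10,
  subject_intercept_sd = 5,
  residual_sd = 5,
  covariates = c("batch", "bmi", "age"),
  B = 1000,
  resampling_mode = "per_feature",
  alpha = 0.05,
  slope_threshold_long = 10,
  slope_threshold_small = 5,
  expressed_median = 25,
  high_small_median = 50,
  min_input_reads = 50000,
  near_window = 1000,
  ibd_B = 50,
  planted_repeat = "(TTTC)n",
  planted_repeat_delta = 25,
  motility_genes = c("GENE001", "GENE002", "GENE003")
)

#' Analysis configuration
#'
#' All thresholds and sizes of a pipeline run, with the study defaults:
#' long-RNA slope threshold 10 RPKM, small-RNA 5 RPM, expressed-median 25
#' RPKM, highly-expressed small-RNA median 50 RPM, minimum 50,000 input
#' reads, near-exon window 1,000 bp. Unknown keys are rejected before any
#' computation.
#'
#' @param ... Overrides of the defaults (see `crossbackr:::CONFIG_DEFAULTS`
#'   for the full key list).
#' @return A named list of class `crossback_config`.
#' @export
crossback_config <- function(...) {
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(CONFIG_DEFAULTS))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(CONFIG_DEFAULTS, overrides)
  assert_count(cfg$seed, "seed")
  assert_probability(cfg$alpha, "alpha")
  stopifnot(all(cfg$arms %in% ARMS))
  structure(cfg, class = "crossback_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [crossback_config()] keys.
#' @return A `crossback_config`.
#' @export
read_crossback_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("truth_fractions_long", "truth_fractions_small")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(crossback_config, raw)
}

#' Run the full synthetic-study pipeline
#'
#' Simulates a crossover study (design, annotation, long- and small-RNA
#' matrices, external control cohort), then runs every analysis stage:
#' per-arm transition models with empirical P-values, pattern
#' classification, repeat enrichment, condition-pooled small-RNA models,
#' the case-vs-control consensus, and the summary report. Each stage's
#' tables are written as TSV under `out_dir` (prefixed with the stage
#' name) along with a manifest; a failing stage aborts with its name and
#' leaves its partial outputs with a `.partial` suffix. Identical config
#' and seed give byte-identical outputs.
#'
#' @param config A [crossback_config()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly; the written tables are the interface.
#' @export
run_crossback_pipeline <- function(config = crossback_config(), out_dir) {
  stopifnot(inherits(config, "crossback_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed_for <- function(stage) derive_seed(config$seed, stage)
  env <- new.env(parent = emptyenv())

  run_stage(out_dir, "simulate", function() {
    design <- simulate_crossover_design(
      n_bhb = config$n_bhb, n_hbh = config$n_hbh,
      p_missing_visit = config$p_missing_visit,
      p_replicate_visit = config$p_replicate_visit,
      seed = seed_for("design")
    )
    ann <- simulate_re_annotation(config$n_features_long,
                                  near_window = config$near_window,
                                  seed = seed_for("annotation"))
    noise <- noise_spec(config$subject_intercept_sd, config$residual_sd)
    # repeat-linked features: low baseline, induced only under high DBP
    planted_ids <- ann$annotation$re_id[
      stringr::str_detect(ann$annotation$repeat_names,
                          stringr::fixed(config$planted_repeat))]
    baselines <- withr::with_seed(
      seed_for("baselines"),
      rgamma(config$n_features_long, shape = 4, rate = 0.1)
    )
    baselines[match(planted_ids, sprintf("re_%05d", seq_len(config$n_features_long)))] <- 12
    long <- simulate_long_matrix(
      design, n_features = config$n_features_long,
      truth_fractions = config$truth_fractions_long, noise = noise,
      delta = config$delta_long, baseline_means = baselines,
      condition_delta = setNames(rep(config$planted_repeat_delta,
                                     length(planted_ids)), planted_ids),
      seed = seed_for("long_matrix")
    )
    small <- simulate_small_matrix(
      design, n_features = config$n_features_small,
      truth_fractions = config$truth_fractions_small, noise = noise,
      delta = config$delta_small, seed = seed_for("small_matrix")
    )
    ctrl <- simulate_control_matrix(
      n_controls = config$n_controls, truth = long$truth,
      noise = noise, seed = seed_for("controls")
    )
    env$design <- design; env$ann <- ann; env$long <- long
    env$small <- small; env$ctrl <- ctrl
    write_expression_matrix(long$matrix, file.path(out_dir, "long_matrix.tsv"))
    write_expression_matrix(small$matrix, file.path(out_dir, "small_matrix.tsv"))
    write_bed_annotation(ann$annotation, file.path(out_dir, "annotation.bed"))
    list(sample_sheet = design, sample_sheet_small = small$design,
         truth_long = long$truth, truth_small = small$truth,
         control_sheet = ctrl$design)
  })

  specs <- function(threshold) {
    model_spec(covariates = config$covariates, B = config$B,
               resampling_mode = config$resampling_mode, alpha = config$alpha,
               slope_threshold = threshold, seed = config$seed)
  }

  run_stage(out_dir, "diff_long", function() {
    fits <- list()
    for (arm in config$arms) {
      for (tr in c("T1", "T2")) {
        fits[[paste(arm, tr, sep = "_")]] <-
          fit_transition_lmem(env$long$matrix, env$design, arm = arm,
                              transition = tr,
                              spec = specs(config$slope_threshold_long))
      }
    }
    env$fits_long <- fits
    setNames(lapply(fits, tidy), paste0("diff_long_", names(fits)))
  })

  run_stage(out_dir, "patterns", function() {
    out <- list()
    env$patterns <- list()
    for (arm in config$arms) {
      calls <- pattern_calls(env$fits_long[[paste0(arm, "_T1")]],
                             env$fits_long[[paste0(arm, "_T2")]])
      env$patterns[[arm]] <- calls
      out[[paste0("patterns_", arm)]] <- calls
      out[[paste0("patterns_summary_", arm)]] <-
        summarize_patterns(calls, env$ann$annotation)
    }
    out
  })

  run_stage(out_dir, "repeats", function() {
    enr <- enrichment_by_visit(env$long$matrix, env$design,
                               env$ann$annotation,
                               threshold = config$expressed_median)
    counts <- bind_rows(lapply(config$arms, function(arm) {
      differential_repeat_counts(env$patterns[[arm]], env$ann$annotation) |>
        mutate(arm = arm)
    }))
    list(repeat_enrichment = enr, repeat_differential_counts = counts)
  })

  run_stage(out_dir, "diff_small", function() {
    sheet <- filter_small_libraries(env$small$design, config$min_input_reads)
    out <- list(small_highly_expressed = highly_expressed_small(
      env$small$matrix[, sheet$sample_id, drop = FALSE],
      threshold = config$high_small_median))
    for (arm in config$arms) {
      fit <- fit_condition_lmem(env$small$matrix, sheet, arm = arm,
                                spec = specs(config$slope_threshold_small))
      out[[paste0("diff_small_", arm)]] <- tidy(fit)
    }
    out
  })

  run_stage(out_dir, "ibd", function() {
    per_visit <- list()
    for (v in VISITS) {
      sheet <- env$design |>
        filter(.data$arm == "B1HB2", .data$visit == v, .data$qc_pass)
      per_visit[[v]] <- ibd_linear_model(
        env$ctrl$matrix, env$ctrl$design,
        env$long$matrix[, sheet$sample_id, drop = FALSE], sheet,
        covariates = intersect(config$covariates, names(env$ctrl$design)),
        B = config$ibd_B, seed = seed_for(paste0("ibd_", v)),
        alpha = config$alpha, slope_threshold = config$slope_threshold_long
      )
    }
    consensus <- consensus_two_of_three(per_visit$baseline,
                                        per_visit$crossover,
                                        per_visit$crossback)
    env$ibd_consensus <- consensus
    list(ibd_baseline = per_visit$baseline, ibd_crossover = per_visit$crossover,
         ibd_crossback = per_visit$crossback, ibd_consensus = consensus)
  })

  run_stage(out_dir, "report", function() {
    ann_dir <- env$ann$annotation |>
      select(feature_id = "re_id", "re_class", "gene_symbols")
    motility <- bind_rows(lapply(config$arms, function(arm) {
      env$patterns[[arm]] |>
        mutate(direction = if_else(.data$call_t1 != "ns", .data$call_t1, .data$call_t2)) |>
        left_join(ann_dir, by = "feature_id") |>
        motility_overlap(config$motility_genes) |>
        mutate(arm = arm)
    }))
    list(report_motility_overlap = motility)
  })

  pipeline_report(out_dir)
  manifest_cfg <- unclass(config)
  manifest_cfg$arms <- as.list(manifest_cfg$arms)
  write_results(list(), out_dir, config = manifest_cfg, seed = config$seed)
  invisible(out_dir)
}

# Run one stage: tables are first written with a .partial suffix and only
# renamed once the whole stage has succeeded, so an aborted run leaves its
# incomplete stage clearly marked.
run_stage <- function(out_dir, stage, fn) {
  tables <- tryCatch(fn(), error = function(e) {
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
  })
  partial <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv.partial"))
    readr::write_tsv(as_tibble(tables[[nm]]), p, progress = FALSE)
    partial <- c(partial, p)
  }
  for (p in partial) file.rename(p, sub("\\.partial$", "", p))
  rlang::inform(sprintf("[%s] wrote %d table(s): %s", stage, length(tables),
                        paste(names(tables), collapse = ", ")))
  invisible(names(tables))
}

#' Summary report of a completed run
#'
#' Reassembles the run's headline tables from the stage TSVs: per-arm,
#' per-transition up/down counts; pattern-by-RE-class tables; the repeat
#' enrichment sweep; and the case-vs-control consensus count. Regenerating
#' the report is idempotent.
#'
#' @param run_dir Directory produced by [run_crossback_pipeline()].
#' @return A list of tibbles (also written as `report_*.tsv`).
#' @export
pipeline_report <- function(run_dir) {
  need <- function(name) {
    p <- file.path(run_dir, paste0(name, ".tsv"))
    if (!file.exists(p)) abort(sprintf("missing stage output: %s", p))
    readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
  }
  diff_files <- list.files(run_dir, pattern = "^diff_long_.*\\.tsv$")
  if (!length(diff_files)) abort("missing stage output: diff_long_*.tsv")
  diff_counts <- bind_rows(lapply(diff_files, function(f) {
    d <- readr::read_tsv(file.path(run_dir, f), show_col_types = FALSE,
                         progress = FALSE)
    parts <- stringr::str_match(f, "^diff_long_(.*)_(T[12])\\.tsv$")
    tibble(arm = parts[2], transition = parts[3],
           n_up = sum(d$call == "up"), n_down = sum(d$call == "down"),
           n_ns = sum(d$call == "ns"))
  }))
  consensus <- need("ibd_consensus")
  report <- list(
    report_diff_counts = diff_counts,
    report_ibd_consensus_counts = consensus |>
      filter(.data$consensus != "none") |>
      count(.data$consensus)
  )
  for (nm in names(report)) {
    readr::write_tsv(report[[nm]], file.path(run_dir, paste0(nm, ".tsv")),
                     progress = FALSE)
  }
  report
}
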