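#' Simulate a crossover/crossback study design
#'
#' Generates a sample sheet emulating a two-arm crossover exposure study:
#' each subject is sampled at baseline, crossover, and crossback, with the
#' exposure condition (high-DBP vs background) determined by arm and visit.
#' Visits can be missing, and a visit can contribute replicate libraries,
#' mirroring the incomplete visit sets and repeat collections of real
#' cohorts.
#'
#' Subject-level covariates (age, BMI, smoking, months on the high-DBP drug
#' before enrolment) and sample-level library covariates (sequencing batch,
#' seasonal warmth at collection, amplification efficiency, duplication
#' rate, alignment rate) are drawn from documented distributions; their only
#' role is to act as adjustable confounders for the mixed models downstream.
#'
#' @param n_bhb Number of subjects in the B1HB2 arm (background first).
#' @param n_hbh Number of subjects in the H1BH2 arm (high-DBP first).
#' @param p_missing_visit Probability that a visit is missing. Either a
#'   single value or a named vector over
#'   `c("baseline", "crossover", "crossback")`.
#' @param p_replicate_visit Probability that a present visit contributes a
#'   second (replicate) library.
#' @param n_batches Number of sequencing batches.
#' @param seed Integer seed; identical seeds give identical sheets.
#' @return A tibble with one row per sample: `sample_id`, `subject_id`,
#'   `arm`, `visit`, `condition`, `replicate`, the covariates, and
#'   `qc_pass`.
#' @examples
#' design <- simulate_crossover_design(p_missing_visit = 0, seed = 1)
#' nrow(design) # 35 subjects x 3 visits
#' @export
simulate_crossover_design <- function(n_bhb = 16, n_hbh = 19,
                                      p_missing_visit = 0.1,
                                      p_replicate_visit = 0.15,
                                      n_batches = 3, seed = 1) {
  assert_count(n_bhb, "n_bhb")
  assert_count(n_hbh, "n_hbh")
  if (n_bhb + n_hbh == 0) abort("at least one subject is required across the two arms")
  if (length(p_missing_visit) == 1 && is.null(names(p_missing_visit))) {
    p_missing_visit <- setNames(rep(p_missing_visit, 3), VISITS)
  }
  if (!all(VISITS %in% names(p_missing_visit))) {
    abort("`p_missing_visit` must be a scalar or named over baseline/crossover/crossback")
  }
  assert_probability(p_missing_visit, "p_missing_visit")
  assert_probability(p_replicate_visit, "p_replicate_visit")
  assert_count(seed, "seed")

  withr::local_seed(seed)

  subjects <- tibble(
    subject_id = sprintf("S%03d", seq_len(n_bhb + n_hbh)),
    arm = rep(ARMS, c(n_bhb, n_hbh)),
    age = round(rnorm_trunc(n_bhb + n_hbh, 35, 8, lower = 18), 1),
    bmi = round(rnorm(n_bhb + n_hbh, 27, 4), 1),
    smoking = rbinom(n_bhb + n_hbh, 1, 0.2)
  )
  # Time already spent on the high-DBP drug before the study: zero for the
  # background-first arm, several months to years for the high-DBP-first arm.
  subjects$months_on_dbp_prior <- ifelse(
    subjects$arm == "H1BH2", round(runif(nrow(subjects), 3, 60)), 0
  )

  grid <- tidyr::crossing(subjects, visit = VISITS) |>
    mutate(visit = factor(.data$visit, levels = VISITS)) |>
    arrange(.data$subject_id, .data$visit) |>
    mutate(visit = as.character(.data$visit))

  keep <- runif(nrow(grid)) >= p_missing_visit[grid$visit]
  grid <- grid[keep, , drop = FALSE]
  reps <- 1L + rbinom(nrow(grid), 1, p_replicate_visit)
  grid <- grid[rep(seq_len(nrow(grid)), reps), , drop = FALSE]
  grid <- grid |>
    group_by(.data$subject_id, .data$visit) |>
    mutate(replicate = dplyr::row_number()) |>
    ungroup()

  n <- nrow(grid)
  grid |>
    mutate(
      condition = arm_visit_condition(.data$arm, .data$visit),
      sample_id = sprintf("%s_%s_r%d", .data$subject_id,
                          c(baseline = "V1", crossover = "V2", crossback = "V3")[.data$visit],
                          .data$replicate),
      batch = sprintf("batch%d", sample.int(n_batches, n, replace = TRUE)),
      season_warm = rbinom(n, 1, 0.5),
      amplification_efficiency = round(rbeta(n, 20, 5), 4),
      duplication_rate = round(rbeta(n, 2, 8), 4),
      alignment_rate = round(rbeta(n, 30, 3), 4),
      qc_pass = TRUE
    ) |>
    select(
      "sample_id", "subject_id", "arm", "visit", "condition", "replicate",
      "batch", "months_on_dbp_prior", "bmi", "season_warm", "smoking", "age",
      "amplification_efficiency", "duplication_rate", "alignment_rate",
      "qc_pass"
    )
}
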