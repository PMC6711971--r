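#' Noise model for simulated expression
#'
#' Variance components and covariate coefficients used by the expression
#' simulators. Expression noise is Gaussian on the RPKM/RPM scale with
#' zero-clipping, matching the scale on which the differential models
#' operate (the estimand is a slope in expression units, not a count-model
#' log fold change).
#'
#' @param subject_intercept_sd SD of the per-subject random intercept, in
#'   expression units.
#' @param residual_sd Residual SD per sample, in expression units.
#' @param covariate_effects Named numeric vector of covariate coefficients
#'   added to every feature, e.g. `c(bmi = 0.5, batch2 = 3)`. Categorical
#'   batch levels are referenced as `batch2`, `batch3`, ...; all other names
#'   must match numeric sample-sheet columns. Empty by default.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(subject_intercept_sd = 5, residual_sd = 5,
                       covariate_effects = c()) {
  if (subject_intercept_sd < 0 || residual_sd < 0) {
    abort("noise standard deviations must be >= 0")
  }
  if (length(covariate_effects) && is.null(names(covariate_effects))) {
    abort("`covariate_effects` must be a named numeric vector")
  }
  structure(
    list(
      subject_intercept_sd = subject_intercept_sd,
      residual_sd = residual_sd,
      covariate_effects = covariate_effects
    ),
    class = "noise_spec"
  )
}

# Per-sample covariate contribution implied by `covariate_effects`.
covariate_shift <- function(design, effects) {
  shift <- numeric(nrow(design))
  for (nm in names(effects)) {
    if (grepl("^batch", nm) && !nm %in% names(design)) {
      shift <- shift + effects[[nm]] * (design$batch == nm)
    } else {
      if (!nm %in% names(design)) {
        abort(sprintf("covariate effect '%s' matches no sample-sheet column", nm))
      }
      shift <- shift + effects[[nm]] * as.numeric(design[[nm]])
    }
  }
  shift
}

# Cumulative planted visit offsets per response class: the offset at
# crossover is delta_t1 and the offset at crossback is delta_t1 + delta_t2,
# so delta_t1/delta_t2 are exactly the two transition effects.
class_deltas <- function(response_class, delta) {
  d <- list(
    acute_up         = c(+delta, 0),
    acute_down       = c(-delta, 0),
    recovery_up      = c(0, +delta),
    recovery_down    = c(0, -delta),
    continuous_up    = c(+delta, +delta),
    continuous_down  = c(-delta, -delta),
    reversal_up_down = c(+delta, -delta),
    reversal_down_up = c(-delta, +delta),
    none             = c(0, 0)
  )
  d[[response_class]]
}

assign_truth_classes <- function(n_features, truth_fractions) {
  if (length(truth_fractions)) {
    bad <- setdiff(names(truth_fractions), setdiff(RESPONSE_CLASSES, "none"))
    if (length(bad)) abort(sprintf("unknown response class in truth_fractions: %s", bad[1]))
    if (sum(truth_fractions) > 1 + 1e-9) abort("truth_fractions must sum to <= 1")
  }
  counts <- floor(truth_fractions * n_features)
  classes <- rep("none", n_features)
  i <- 1L
  for (nm in names(counts)) {
    k <- counts[[nm]]
    if (k > 0) {
      classes[i:(i + k - 1L)] <- nm
      i <- i + k
    }
  }
  classes
}

#' Simulate a long-RNA (RPKM) expression matrix with planted truth
#'
#' Builds a feature-by-sample RPKM matrix over a simulated design. Each
#' value is `baseline_mean + subject intercept + covariate effects +
#' planted visit offset + Gaussian residual`, clipped at zero. Planted
#' effects follow the eight acute/recovery/continuous/reversal response
#' classes: `delta_t1` acts at the baseline-to-crossover transition and
#' `delta_t2` at the crossover-to-crossback transition. Replicate libraries
#' of the same visit share the subject intercept and planted effect and
#' differ only in the residual draw.
#'
#' @param design Sample sheet from [simulate_crossover_design()].
#' @param n_features Number of features (REs).
#' @param truth_fractions Named fractions of features per non-null response
#'   class; the remainder are null. E.g. `c(acute_up = 0.05)`.
#' @param noise A [noise_spec()].
#' @param delta Magnitude (expression units) of planted per-transition
#'   effects.
#' @param baseline_means Optional numeric vector of per-feature baseline
#'   means (recycled names = feature ids); drawn from Gamma(4, rate 0.1)
#'   when omitted.
#' @param condition_delta Optional named numeric vector (names = feature
#'   ids) added whenever a sample's condition is `high_dbp`, on top of any
#'   class-based offsets. Used to plant condition-linked (e.g.
#'   repeat-group) expression.
#' @param seed Integer seed.
#' @return A list with `matrix` (features x samples, `unit` attribute
#'   `"RPKM"`, `clip_fraction` attribute), and `truth`, a tibble with one
#'   row per feature (`feature_id`, `response_class`, `delta_t1`,
#'   `delta_t2`, `baseline_mean`).
#' @examples
#' d <- simulate_crossover_design(4, 4, p_missing_visit = 0, seed = 1)
#' sim <- simulate_long_matrix(d, n_features = 10,
#'                             truth_fractions = c(acute_up = 0.2), seed = 2)
#' dim(sim$matrix)
#' @export
simulate_long_matrix <- function(design, n_features = 500,
                                 truth_fractions = c(), noise = noise_spec(),
                                 delta = 30, baseline_means = NULL,
                                 condition_delta = NULL, seed = 1) {
  simulate_expression(design, n_features, truth_fractions, noise, delta,
                      baseline_means, condition_delta, seed,
                      unit = "RPKM", effect_on = "visit")
}

#' Simulate a small-RNA (RPM) expression matrix with planted truth
#'
#' As [simulate_long_matrix()], but effects are planted on the exposure
#' *condition* (high-DBP vs background) rather than on visit transitions,
#' matching the condition-pooled model used for small RNAs, and the design
#' gains an `input_reads` column (log-normal) so the 50,000-read library
#' filter can be exercised. Truth classes are `condition_up`,
#' `condition_down`, or `none`; `delta_t1` records the planted
#' high-vs-background difference.
#'
#' @inheritParams simulate_long_matrix
#' @param truth_fractions Named fractions over
#'   `c("condition_up", "condition_down")`.
#' @param mean_input_reads Median of the log-normal input-read
#'   distribution.
#' @param sdlog_input_reads Log-scale SD of input reads.
#' @return A list with `matrix` (`unit` `"RPM"`), `truth`, and `design`
#'   (the input design plus `input_reads`).
#' @export
simulate_small_matrix <- function(design, n_features = 200,
                                  truth_fractions = c(), noise = noise_spec(),
                                  delta = 10, baseline_means = NULL,
                                  mean_input_reads = 150000,
                                  sdlog_input_reads = 0.7, seed = 1) {
  if (length(truth_fractions)) {
    bad <- setdiff(names(truth_fractions), c("condition_up", "condition_down"))
    if (length(bad)) abort("small-RNA truth classes are condition_up/condition_down")
  }
  # reuse the visit machinery: a condition effect is planted via the
  # continuous classes and then applied to the condition indicator instead
  frac <- truth_fractions
  if (length(frac)) names(frac) <- sub("^condition", "continuous", names(frac))
  sim <- simulate_expression(design, n_features, frac, noise, delta,
                             baseline_means, NULL, seed,
                             unit = "RPM", effect_on = "condition")
  sim$truth$response_class <- sub("continuous", "condition", sim$truth$response_class)
  sim$truth$delta_t2 <- 0
  withr::local_seed(derive_seed(seed, "input_reads"))
  design$input_reads <- round(rlnorm(nrow(design), log(mean_input_reads),
                                     sdlog_input_reads))
  sim$design <- design
  sim
}

simulate_expression <- function(design, n_features, truth_fractions, noise,
                                delta, baseline_means, condition_delta, seed,
                                unit, effect_on) {
  assert_count(n_features, "n_features", min = 1)
  stopifnot(inherits(noise, "noise_spec"))
  withr::local_seed(seed)

  feature_ids <- sprintf("re_%05d", seq_len(n_features))
  classes <- assign_truth_classes(n_features, truth_fractions)
  if (is.null(baseline_means)) {
    baseline_means <- rgamma(n_features, shape = 4, rate = 0.1)
  } else {
    stopifnot(length(baseline_means) == n_features)
  }

  subjects <- unique(design$subject_id)
  intercepts <- setNames(rnorm(length(subjects), 0, noise$subject_intercept_sd),
                         subjects)
  cov_shift <- covariate_shift(design, noise$covariate_effects)

  truth <- tibble(
    feature_id = feature_ids,
    response_class = classes,
    delta_t1 = map_dbl(classes, ~ class_deltas(.x, delta)[1]),
    delta_t2 = map_dbl(classes, ~ class_deltas(.x, delta)[2]),
    baseline_mean = baseline_means
  )

  # cumulative offset per feature x visit (or condition)
  visit_idx <- match(design$visit, VISITS)
  offsets <- cbind(0, truth$delta_t1, truth$delta_t1 + truth$delta_t2)
  n <- nrow(design)
  base <- matrix(truth$baseline_mean, n_features, n)
  samp <- matrix(rep(intercepts[design$subject_id] + cov_shift, each = n_features),
                 n_features, n)
  if (effect_on == "visit") {
    planted <- offsets[, visit_idx, drop = FALSE]
  } else {
    planted <- outer(truth$delta_t1, as.numeric(design$condition == "high_dbp"))
  }
  eps <- matrix(rnorm(n_features * n, 0, noise$residual_sd), n_features, n)
  mat <- base + samp + planted + eps
  dimnames(mat) <- list(feature_ids, design$sample_id)
  if (!is.null(condition_delta)) {
    idx <- match(names(condition_delta), feature_ids)
    if (anyNA(idx)) abort("condition_delta names must be feature ids")
    mat[idx, ] <- mat[idx, ] +
      outer(unname(condition_delta), as.numeric(design$condition == "high_dbp"))
  }
  clipped <- mat < 0
  mat[clipped] <- 0
  attr(mat, "unit") <- unit
  attr(mat, "clip_fraction") <- mean(clipped)
  list(matrix = mat, truth = truth)
}

#' Simulate an external control cohort matrix
#'
#' Generates a single-visit control cohort (one sample per subject) on the
#' same features as a simulated study matrix, for the case-vs-control
#' linear-model comparison. `control_delta` plants features expressed more
#' highly in controls (positive) or in cases (negative).
#'
#' @param n_controls Number of control subjects.
#' @param truth Truth tibble from [simulate_long_matrix()] (supplies
#'   feature ids and baseline means).
#' @param control_delta Named numeric vector (feature ids) of
#'   control-minus-case offsets, in RPKM.
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @return A list with `matrix` and `design` (control sample sheet with the
#'   numeric covariates used downstream).
#' @export
simulate_control_matrix <- function(n_controls = 52, truth, control_delta = c(),
                                    noise = noise_spec(), seed = 1) {
  assert_count(n_controls, "n_controls", min = 1)
  withr::local_seed(seed)
  design <- tibble(
    sample_id = sprintf("C%03d_V1_r1", seq_len(n_controls)),
    subject_id = sprintf("C%03d", seq_len(n_controls)),
    group = "control",
    batch = sprintf("batch%d", sample.int(3, n_controls, replace = TRUE)),
    bmi = round(rnorm(n_controls, 27, 4), 1),
    age = round(rnorm_trunc(n_controls, 35, 8, lower = 18), 1),
    qc_pass = TRUE
  )
  n_features <- nrow(truth)
  shift <- numeric(n_features)
  if (length(control_delta)) {
    idx <- match(names(control_delta), truth$feature_id)
    if (anyNA(idx)) abort("control_delta names must be feature ids")
    shift[idx] <- control_delta
  }
  mat <- matrix(truth$baseline_mean + shift, n_features, n_controls,
                dimnames = list(truth$feature_id, design$sample_id)) +
    matrix(rep(rnorm(n_controls, 0, noise$subject_intercept_sd), each = n_features),
           n_features, n_controls) +
    matrix(rnorm(n_features * n_controls, 0, noise$residual_sd),
           n_features, n_controls)
  mat[mat < 0] <- 0
  attr(mat, "unit") <- "RPKM"
  list(matrix = mat, design = design)
}
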