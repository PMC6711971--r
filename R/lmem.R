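#' Model specification for per-feature differential testing
#'
#' Bundles the covariate set, resampling policy, and significance
#' thresholds used by [fit_transition_lmem()] and [fit_condition_lmem()].
#'
#' @param covariates Character vector of sample-sheet columns used as fixed
#'   covariates (categorical columns are expanded to dummies).
#' @param B Number of within-subject label permutations for the empirical
#'   P-value (at least 19, i.e. a minimum attainable P of 0.05).
#' @param resampling_mode `"per_feature"` (each feature's P uses its own
#'   permutations) or `"pooled_null"` (null slopes pooled across all
#'   features of the run, the economical choice when very many features are
#'   tested).
#' @param alpha Significance level for the empirical P.
#' @param slope_threshold Minimum absolute slope (strict), in matrix units:
#'   10 RPKM for long RNAs, 5 RPM for small RNAs.
#' @param seed Master seed; per-feature permutation streams are derived by
#'   hashing the feature id so results are independent of iteration order.
#' @param perm_refit `"gls"` recomputes the generalized-least-squares slope
#'   under permuted labels with variance components held at the observed
#'   REML fit (fast); `"full"` refits the mixed model per permutation.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(covariates = character(0), B = 1000,
                       resampling_mode = c("per_feature", "pooled_null"),
                       alpha = 0.05, slope_threshold = 10, seed = 1,
                       perm_refit = c("gls", "full")) {
  assert_count(B, "B", min = 19)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  if (slope_threshold < 0) abort("`slope_threshold` must be >= 0")
  structure(
    list(covariates = covariates, B = as.integer(B),
         resampling_mode = match.arg(resampling_mode), alpha = alpha,
         slope_threshold = slope_threshold, seed = as.integer(seed),
         perm_refit = match.arg(perm_refit)),
    class = "model_spec"
  )
}

#' Permutation empirical P-value (add-one estimator)
#'
#' `p = (1 + #\{|null| >= |observed|\}) / (B + 1)`. The add-one form never
#' returns zero: the smallest attainable P with `B` permutations is
#' `1 / (B + 1)`.
#'
#' @param observed Observed slope (scalar).
#' @param null_slopes Numeric vector of null slopes from label resampling.
#' @return Empirical P in `[1/(B+1), 1]`.
#' @examples
#' empirical_pvalue(5, rnorm(999)) # beats all 999 nulls -> 1/1000
#' @export
empirical_pvalue <- function(observed, null_slopes) {
  (1 + sum(abs(null_slopes) >= abs(observed))) / (length(null_slopes) + 1)
}

#' Significance call from slope and P-value
#'
#' `up` if `slope > +threshold` and `p < alpha`; `down` if
#' `slope < -threshold` and `p < alpha`; otherwise `ns`. Both inequalities
#' are strict ("exceeded 10 RPKM", "less than 0.05").
#'
#' @param slope Numeric vector of slopes.
#' @param p Numeric vector of P-values.
#' @param spec A [model_spec()] (supplies `slope_threshold` and `alpha`).
#' @return Character vector of `"up"`/`"down"`/`"ns"`.
#' @export
call_significance <- function(slope, p, spec = model_spec()) {
  dplyr::case_when(
    slope > spec$slope_threshold & p < spec$alpha ~ "up",
    slope < -spec$slope_threshold & p < spec$alpha ~ "down",
    .default = "ns"
  )
}

#' Transition differential test: per-feature linear mixed-effects models
#'
#' For one study arm and one visit transition (`T1` = baseline to
#' crossover, `T2` = crossover to crossback), fits per feature
#' `expression ~ visit_indicator + covariates + (1 | subject)` and reports
#' the visit-indicator slope (later visit minus earlier, in matrix units)
#' with a permutation empirical P-value. The null distribution permutes
#' visit labels within each subject — preserving per-subject sample counts
#' and subject-level dependence — and refits per [model_spec()]'s
#' `perm_refit`. When fewer distinct within-subject permutations exist
#' than `B`, the test is exact over all of them (with a warning).
#'
#' Features whose mixed-model fit fails are refit by ordinary least
#' squares with subject effects absorbed (flagged `ols_fallback`);
#' all-constant features get slope 0 and P 1.
#'
#' @param mat Expression matrix (features x samples), RPKM.
#' @param samples Sample sheet covering the matrix columns.
#' @param arm `"B1HB2"` or `"H1BH2"`.
#' @param transition `"T1"` or `"T2"`.
#' @param spec A [model_spec()].
#' @return A `transition_fit` object; see [tidy.transition_fit()].
#' @export
fit_transition_lmem <- function(mat, samples, arm = ARMS,
                                transition = c("T1", "T2"),
                                spec = model_spec()) {
  arm <- match.arg(arm)
  transition <- match.arg(transition)
  visits <- if (transition == "T1") VISITS[1:2] else VISITS[2:3]
  samples <- samples |>
    filter(.data$qc_pass, .data$arm == !!arm, .data$visit %in% visits)
  if (nrow(samples) == 0) abort("no samples for this arm/transition")
  both <- samples |>
    distinct(.data$subject_id, .data$visit) |>
    count(.data$subject_id) |>
    filter(.data$n == 2)
  if (nrow(both) < 4) {
    abort(sprintf("need >= 4 subjects with both %s and %s visits, found %d",
                  visits[1], visits[2], nrow(both)))
  }
  indicator <- as.numeric(samples$visit == visits[2])
  fit <- fit_indicator_lmem(mat, samples, indicator, spec,
                            stage = paste("long", arm, transition, sep = "_"))
  new_transition_fit(fit, comparison = transition, arm = arm, spec = spec,
                     unit = attr(mat, "unit") %||% "RPKM",
                     label = sprintf("%s -> %s", visits[1], visits[2]))
}

#' Condition differential test for small RNAs
#'
#' Pools all visits of one arm and contrasts exposure conditions
#' (high-DBP = 1 vs background = 0), treating a condition's samples as
#' replicates: `expression ~ condition + covariates + (1 | subject)`. The
#' permutation null permutes condition labels within subject. Intended for
#' RPM matrices pre-filtered with [filter_small_libraries()]; use
#' `model_spec(slope_threshold = 5)` for the small-RNA calling threshold.
#'
#' @inheritParams fit_transition_lmem
#' @param spec A [model_spec()]; default threshold 5 RPM.
#' @return A `transition_fit` object with comparison `"condition"`.
#' @export
fit_condition_lmem <- function(mat, samples, arm = ARMS,
                               spec = model_spec(slope_threshold = 5)) {
  arm <- match.arg(arm)
  samples <- samples |> filter(.data$qc_pass, .data$arm == !!arm)
  if (nrow(samples) == 0) abort("no samples for this arm")
  if (length(unique(samples$condition)) < 2) {
    abort(sprintf("arm %s has a single exposure condition; no contrast possible", arm))
  }
  indicator <- as.numeric(samples$condition == "high_dbp")
  fit <- fit_indicator_lmem(mat, samples, indicator, spec,
                            stage = paste("small", arm, sep = "_"))
  new_transition_fit(fit, comparison = "condition", arm = arm, spec = spec,
                     unit = attr(mat, "unit") %||% "RPM",
                     label = "high_dbp vs background")
}

new_transition_fit <- function(fit, comparison, arm, spec, unit, label) {
  fit$results$call <- call_significance(fit$results$slope,
                                        fit$results$empirical_p, spec)
  structure(
    list(results = fit$results, comparison = comparison, arm = arm,
         spec = spec, unit = unit, label = label,
         n_samples = fit$n_samples, n_subjects = fit$n_subjects),
    class = "transition_fit"
  )
}

## ---- engine ---------------------------------------------------------------

# Per-feature mixed-model slope + within-subject permutation null.
fit_indicator_lmem <- function(mat, samples, indicator, spec, stage) {
  mat <- mat[, samples$sample_id, drop = FALSE]
  n <- ncol(mat)
  subject <- factor(samples$subject_id)

  covar_df <- build_covariates(samples, spec$covariates)
  df <- data.frame(covar_df, .subject = subject, .ind = indicator)

  # distinct within-subject permutations of the (binary) indicator
  rows_by_subject <- split(seq_len(n), subject)
  log_nperm <- sum(map_dbl(rows_by_subject, function(r) {
    lchoose(length(r), sum(indicator[r]))
  }))
  exact <- is.finite(log_nperm) && log_nperm <= log(spec$B + 1)
  if (exact) {
    perms <- enumerate_indicator_perms(rows_by_subject, indicator)
    # drop the identity arrangement; the add-one estimator restores it
    keep <- !apply(perms == indicator, 2, all)
    # an all-identical set means the indicator is not permutable at all
    perms <- perms[, keep | !any(keep), drop = FALSE]
    if (ncol(perms) < spec$B) {
      warn(sprintf(
        "only %d distinct within-subject permutations exist; using all of them (exact test) instead of B = %d",
        ncol(perms) + 1L, spec$B))
    }
  }

  feature_ids <- rownames(mat)
  n_feat <- length(feature_ids)
  slope <- numeric(n_feat)
  method <- character(n_feat)
  null_list <- vector("list", n_feat)

  fixed_rhs <- paste(c("1", ".ind", names(covar_df)), collapse = " + ")
  lmer_formula <- stats::as.formula(paste0(".y ~ ", fixed_rhs, " + (1 | .subject)"))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")

  for (f in seq_len(n_feat)) {
    y <- mat[f, ]
    if (length(unique(y)) == 1L) {
      slope[f] <- 0
      method[f] <- "constant"
      null_list[[f]] <- numeric(0)
      next
    }
    df$.y <- y
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(lmer_formula, data = df, REML = TRUE, control = ctrl)
      )),
      error = function(e) NULL
    )
    if (!is.null(fit) && !is.na(lme4::fixef(fit)[".ind"])) {
      slope[f] <- unname(lme4::fixef(fit)[".ind"])
      vc <- as.data.frame(lme4::VarCorr(fit))
      sigma_b2 <- vc$vcov[vc$grp == ".subject"]
      sigma_e2 <- vc$vcov[vc$grp == "Residual"]
      method[f] <- "lmem"
    } else {
      # OLS fallback with subject effects absorbed (subject-mean centering)
      sigma_b2 <- NA
      sigma_e2 <- NA
      method[f] <- "ols_fallback"
    }

    if (exact) {
      perm_ind <- perms
    } else {
      withr::local_seed(derive_seed(spec$seed, paste(stage, feature_ids[f])))
      perm_ind <- draw_indicator_perms(rows_by_subject, indicator, spec$B)
    }

    if (spec$perm_refit == "full" && method[f] == "lmem") {
      null_list[[f]] <- apply(perm_ind, 2, function(ind_b) {
        df$.ind <- ind_b
        fb <- tryCatch(
          suppressMessages(suppressWarnings(
            lme4::lmer(lmer_formula, data = df, REML = TRUE, control = ctrl))),
          error = function(e) NULL
        )
        if (is.null(fb)) NA_real_ else unname(lme4::fixef(fb)[".ind"])
      })
      df$.ind <- indicator
    } else {
      null_list[[f]] <- gls_null_slopes(y, indicator, perm_ind, covar_df,
                                        subject, sigma_b2, sigma_e2,
                                        absorb_subject = method[f] == "ols_fallback")
      if (method[f] == "ols_fallback") {
        slope[f] <- gls_slope(y, indicator, covar_df, subject,
                              NA, NA, absorb_subject = TRUE)
      }
    }
    null_list[[f]] <- null_list[[f]][!is.na(null_list[[f]])]
  }

  p <- numeric(n_feat)
  if (spec$resampling_mode == "pooled_null") {
    pool <- abs(unlist(null_list))
    for (f in seq_len(n_feat)) {
      p[f] <- if (method[f] == "constant") 1 else empirical_pvalue(slope[f], pool)
    }
  } else {
    for (f in seq_len(n_feat)) {
      p[f] <- if (method[f] == "constant") 1 else empirical_pvalue(slope[f], null_list[[f]])
    }
  }

  list(
    results = tibble(
      feature_id = feature_ids, slope = slope, empirical_p = p,
      method = method,
      n_perm = map_int(null_list, length)
    ),
    n_samples = n,
    n_subjects = nlevels(subject)
  )
}

# Covariate columns as a plain data frame (factors for character columns).
build_covariates <- function(samples, covariates) {
  missing <- setdiff(covariates, names(samples))
  if (length(missing)) {
    abort(sprintf("covariate(s) not in sample sheet: %s",
                  paste(missing, collapse = ", ")))
  }
  out <- lapply(samples[covariates], function(x) {
    if (is.character(x) || is.logical(x)) factor(x) else as.numeric(x)
  })
  # constant covariates carry no information and break the model matrix
  out <- out[vapply(out, function(x) length(unique(x)) > 1, logical(1))]
  df <- as.data.frame(matrix(nrow = nrow(samples), ncol = 0))
  for (nm in names(out)) df[[nm]] <- out[[nm]]
  df
}

# All distinct within-subject arrangements of a binary indicator.
enumerate_indicator_perms <- function(rows_by_subject, indicator) {
  per_subject <- lapply(rows_by_subject, function(r) {
    k <- sum(indicator[r])
    pos <- utils::combn(length(r), k)
    # each column: an indicator sub-vector for this subject's rows
    apply(pos, 2, function(p) {
      v <- numeric(length(r))
      v[p] <- 1
      v
    }, simplify = FALSE)
  })
  counts <- map_int(per_subject, length)
  total <- prod(counts)
  out <- matrix(0, length(indicator), total)
  idx <- rep(1L, length(per_subject))
  for (col in seq_len(total)) {
    for (s in seq_along(per_subject)) {
      out[rows_by_subject[[s]], col] <- per_subject[[s]][[idx[s]]]
    }
    # mixed-radix increment
    for (s in seq_along(idx)) {
      idx[s] <- idx[s] + 1L
      if (idx[s] <= counts[s]) break
      idx[s] <- 1L
    }
  }
  out
}

# B random within-subject arrangements (columns).
draw_indicator_perms <- function(rows_by_subject, indicator, B) {
  n <- length(indicator)
  out <- matrix(rep(indicator, B), n, B)
  for (r in rows_by_subject) {
    if (length(r) > 1 && length(unique(indicator[r])) > 1) {
      for (b in seq_len(B)) out[r, b] <- indicator[r][sample.int(length(r))]
    }
  }
  out
}

# GLS machinery: V = sigma_e^2 I + sigma_b^2 Z Z' from the observed REML
# fit; permuted-label slopes are GLS solutions with V fixed. With
# absorb_subject = TRUE (OLS fallback) V = I and subject dummies join the
# nuisance block.
gls_null_slopes <- function(y, indicator, perm_ind, covar_df, subject,
                            sigma_b2, sigma_e2, absorb_subject = FALSE) {
  w <- gls_whitener(y, covar_df, subject, sigma_b2, sigma_e2, absorb_subject)
  apply(perm_ind, 2, function(ind_b) {
    xr <- qr.resid(w$qrZ, w$whiten(ind_b))
    den <- sum(xr^2)
    if (den < 1e-10) return(NA_real_)
    sum(xr * w$yr) / den
  })
}

gls_slope <- function(y, indicator, covar_df, subject, sigma_b2, sigma_e2,
                      absorb_subject = FALSE) {
  w <- gls_whitener(y, covar_df, subject, sigma_b2, sigma_e2, absorb_subject)
  xr <- qr.resid(w$qrZ, w$whiten(indicator))
  den <- sum(xr^2)
  if (den < 1e-10) return(0)
  sum(xr * w$yr) / den
}

gls_whitener <- function(y, covar_df, subject, sigma_b2, sigma_e2,
                         absorb_subject) {
  n <- length(y)
  Zcols <- if (ncol(covar_df) > 0) {
    stats::model.matrix(~ ., data = covar_df)
  } else {
    matrix(1, n, 1)
  }
  if (absorb_subject) {
    Zcols <- cbind(Zcols, stats::model.matrix(~ 0 + subject))
    whiten <- identity
  } else {
    sigma_e2 <- max(sigma_e2, 1e-8)
    Zsub <- stats::model.matrix(~ 0 + subject)
    V <- diag(sigma_e2, n) + sigma_b2 * tcrossprod(Zsub)
    L <- chol(V)
    whiten <- function(v) backsolve(L, v, transpose = TRUE)
  }
  Zw <- vapply(seq_len(ncol(Zcols)), function(j) whiten(Zcols[, j]),
               numeric(n))
  qrZ <- qr(Zw)
  yr <- qr.resid(qrZ, whiten(y))
  list(whiten = whiten, qrZ = qrZ, yr = yr)
}
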