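#' Case-vs-control linear model with visit-replicate resampling
#'
#' Compares one study visit of the case (IBD) arm against an external
#' control cohort. Case subjects may contribute replicate libraries at the
#' visit; each of `B` resamples draws one library per case subject
#' uniformly at random and fits, per feature, ordinary least squares
#' `expression ~ group + covariates`, with group coded so a *positive*
#' slope means higher expression in controls. Per feature the median slope
#' and median P across resamples are reported; median P-values are then
#' Benjamini-Hochberg adjusted across features. A feature is called when
#' `bh_p < alpha` and `|slope|` strictly exceeds `slope_threshold`.
#'
#' With no replicate libraries all resamples are identical and the result
#' collapses to a single OLS fit.
#'
#' @param control_matrix,control_samples Control cohort matrix (one sample
#'   per subject) and its sample sheet.
#' @param ibd_matrix,ibd_samples Case matrix restricted to one visit, and
#'   its sample sheet (possibly replicate rows per subject).
#' @param covariates Covariate columns present in both sample sheets.
#' @param B Number of resamples.
#' @param seed Integer seed.
#' @param alpha BH-adjusted significance level.
#' @param slope_threshold Minimum absolute slope, RPKM (strict).
#' @return Tibble: `feature_id`, `slope`, `p`, `bh_p`, `call`
#'   (`"up"` = control-enriched, `"down"` = case-enriched, `"ns"`).
#' @export
ibd_linear_model <- function(control_matrix, control_samples,
                             ibd_matrix, ibd_samples,
                             covariates = character(0), B = 100, seed = 1,
                             alpha = 0.05, slope_threshold = 10) {
  assert_count(B, "B", min = 1)
  features <- intersect(rownames(control_matrix), rownames(ibd_matrix))
  if (!length(features)) abort("control and case matrices share no features")
  control_matrix <- control_matrix[features, , drop = FALSE]
  ibd_matrix <- ibd_matrix[features, , drop = FALSE]

  subj <- split(seq_len(nrow(ibd_samples)), ibd_samples$subject_id)
  empty <- names(subj)[lengths(subj) == 0]
  if (length(empty)) {
    warn(sprintf("case subject(s) with no sample at this visit dropped: %s",
                 paste(empty, collapse = ", ")))
    subj <- subj[lengths(subj) > 0]
  }
  if (!length(subj)) abort("no case samples at this visit")
  if (all(lengths(subj) == 1L)) B <- 1L # resampling collapses

  withr::local_seed(seed)
  n_feat <- length(features)
  slopes <- matrix(NA_real_, n_feat, B)
  pvals <- matrix(NA_real_, n_feat, B)
  for (b in seq_len(B)) {
    pick <- map_int(subj, function(r) if (length(r) == 1) r else sample(r, 1))
    sam <- bind_rows(
      control_samples |> mutate(.group = 1),
      ibd_samples[pick, , drop = FALSE] |> mutate(.group = 0)
    )
    Y <- t(cbind(control_matrix, ibd_matrix[, pick, drop = FALSE]))
    covar_df <- build_covariates(sam, covariates)
    X <- stats::model.matrix(~ ., data = cbind(sam[".group"], covar_df))
    qrX <- qr(X)
    coefs <- qr.coef(qrX, Y)
    res <- qr.resid(qrX, Y)
    df_res <- nrow(X) - qrX$rank
    sigma2 <- colSums(res^2) / df_res
    g <- which(colnames(X) == ".group")
    xtxinv_g <- solve(crossprod(X))[g, g]
    se <- sqrt(sigma2 * xtxinv_g)
    tstat <- coefs[".group", ] / se
    slopes[, b] <- coefs[".group", ]
    pvals[, b] <- 2 * pt(abs(tstat), df_res, lower.tail = FALSE)
  }
  med_slope <- apply(slopes, 1, median)
  med_p <- apply(pvals, 1, median)
  bh <- bh_adjust(med_p)
  tibble(
    feature_id = features,
    slope = med_slope,
    p = med_p,
    bh_p = bh,
    call = dplyr::case_when(
      med_slope > slope_threshold & bh < alpha ~ "up",
      med_slope < -slope_threshold & bh < alpha ~ "down",
      .default = "ns"
    )
  )
}

#' Two-of-three consensus across visit comparisons
#'
#' A feature is retained when it is significant with the *same* direction
#' in at least two of the three per-visit case-vs-control comparisons
#' (baseline, crossover, crossback). A triple with two consistent calls
#' plus one opposite call is retained on the majority direction but
#' flagged as conflicting.
#'
#' @param results_b1,results_h,results_b2 Per-visit result tibbles from
#'   [ibd_linear_model()] (columns `feature_id`, `call`).
#' @return Tibble: `feature_id`, `call_B1`, `call_H`, `call_B2`,
#'   `consensus` (`"up"`/`"down"`/`"none"`), `conflict` (logical).
#' @export
consensus_two_of_three <- function(results_b1, results_h, results_b2) {
  joined <- results_b1 |>
    select("feature_id", call_B1 = "call") |>
    inner_join(select(results_h, "feature_id", call_H = "call"), by = "feature_id") |>
    inner_join(select(results_b2, "feature_id", call_B2 = "call"), by = "feature_id")
  calls <- as.matrix(joined[, c("call_B1", "call_H", "call_B2")])
  n_up <- rowSums(calls == "up")
  n_down <- rowSums(calls == "down")
  joined |>
    mutate(
      consensus = dplyr::case_when(n_up >= 2 ~ "up",
                                   n_down >= 2 ~ "down",
                                   .default = "none"),
      conflict = (n_up >= 2 & n_down > 0) | (n_down >= 2 & n_up > 0)
    )
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotone
#' enforcement; adjusted values are never smaller than the raw P and are
#' capped at 1. Missing or out-of-range P-values are an error rather than
#' silently propagated.
#'
#' @param p Numeric vector of P-values in `[0, 1]`.
#' @return Adjusted P-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort("`p` must be numeric in [0, 1] with no missing values")
  }
  p.adjust(p, method = "BH")
}
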