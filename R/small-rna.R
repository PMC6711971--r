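#' Filter small-RNA libraries by input reads
#'
#' Retains libraries with at least `min_reads` input reads (default
#' 50,000, read as a minimum: exactly 50,000 is kept). Sperm yields very
#' little small RNA, so shallow libraries are unreliable and are dropped
#' before condition modeling.
#'
#' @param samples Sample sheet with an `input_reads` column.
#' @param min_reads Minimum input reads.
#' @return The retained sample rows.
#' @export
filter_small_libraries <- function(samples, min_reads = 50000) {
  if (!"input_reads" %in% names(samples)) {
    abort("`samples` lacks the input_reads column required for library filtering")
  }
  if (anyNA(samples$input_reads)) abort("input_reads contains missing values")
  filter(samples, .data$input_reads >= min_reads)
}

#' Highly expressed small RNAs
#'
#' Features whose median RPM across *all* samples strictly exceeds the
#' threshold (default 50; a median of exactly 50 is excluded).
#'
#' @param mat RPM matrix (features x samples).
#' @param threshold Median-RPM cutoff (strict).
#' @param families Optional named character vector mapping feature ids to
#'   small-RNA families (piRNA, miRNA, tRF, ...).
#' @return Tibble with `feature_id`, `median_rpm`, and (when `families`
#'   is given) `family`; the `family_counts` attribute then summarises
#'   features per family.
#' @export
highly_expressed_small <- function(mat, threshold = 50, families = NULL) {
  med <- apply(mat, 1, median)
  keep <- med > threshold
  out <- tibble(feature_id = rownames(mat)[keep], median_rpm = unname(med[keep]))
  if (!is.null(families)) {
    out$family <- unname(families[out$feature_id])
    attr(out, "family_counts") <- out |> count(.data$family, name = "n_features")
  }
  out
}
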