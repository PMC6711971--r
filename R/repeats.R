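#' Features passing a median-expression threshold
#'
#' Features whose median expression across the given samples is at least
#' `threshold` (inclusive: a median of exactly 25 RPKM counts as
#' expressed).
#'
#' @param mat Expression matrix.
#' @param sample_ids Samples (columns) defining the visit.
#' @param threshold Median expression cutoff, default 25 RPKM.
#' @return Character vector of expressed feature ids.
#' @export
expressed_filter <- function(mat, sample_ids, threshold = 25) {
  if (length(sample_ids) == 0) abort("empty sample set for expressed_filter")
  missing <- setdiff(sample_ids, colnames(mat))
  if (length(missing)) abort(sprintf("sample(s) not in matrix: %s", missing[1]))
  med <- apply(mat[, sample_ids, drop = FALSE], 1, median)
  rownames(mat)[med >= threshold]
}

#' Repeat enrichment delta-ratio
#'
#' `delta_ratio = R_expressed / A_expressed - R / A`: the change in a
#' repeat's share of the repeat-associated RE population when an
#' expression threshold is applied. `R` counts the REs overlapping the
#' repeat of interest, `A` the REs overlapping *any* repeat; the
#' `_expressed` counts are those passing the threshold. Positive values
#' mean the repeat is over-represented among expressed REs (enrichment),
#' negative under-represented (depletion).
#'
#' @param R,A,R_expressed,A_expressed Nonnegative counts with `R <= A`,
#'   `R_expressed <= min(R, A_expressed)`; `A > 0` and `A_expressed > 0`.
#' @return The delta-ratio, in `(-1, 1)`.
#' @examples
#' delta_ratio(10, 100, 5, 20) # 0.15
#' @export
delta_ratio <- function(R, A, R_expressed, A_expressed) {
  if (A <= 0) abort("`A` must be positive")
  if (A_expressed <= 0) {
    abort("no expressed repeat-associated REs at this visit: delta-ratio undefined")
  }
  if (R > A || R_expressed > R || R_expressed > A_expressed) {
    abort("inconsistent counts: need R <= A and R_expressed <= min(R, A_expressed)")
  }
  R_expressed / A_expressed - R / A
}

#' Hypergeometric test for repeat enrichment or depletion
#'
#' Draws `A_expressed` REs without replacement from a population of `A`
#' repeat-associated REs of which `R` belong to the repeat of interest,
#' and asks whether observing `R_expressed` of them is extreme: one-sided
#' in the direction of the delta-ratio's sign, `P(X >= R_expressed)` for
#' enrichment and `P(X <= R_expressed)` for depletion. A zero delta-ratio
#' (`direction = "none"`) returns 1 by convention.
#'
#' @inheritParams delta_ratio
#' @param direction `"enriched"`, `"depleted"`, or `"none"`.
#' @return One-sided hypergeometric P-value.
#' @export
hypergeom_test <- function(R, A, R_expressed, A_expressed,
                           direction = c("enriched", "depleted", "none")) {
  direction <- match.arg(direction)
  if (direction == "none") return(1)
  if (direction == "enriched") {
    phyper(R_expressed - 1, R, A - R, A_expressed, lower.tail = FALSE)
  } else {
    phyper(R_expressed, R, A - R, A_expressed, lower.tail = TRUE)
  }
}

#' Per-visit repeat enrichment sweep
#'
#' For every arm-by-visit cell (optionally stratified by RE class),
#' computes each repeat's delta-ratio and hypergeometric P over the
#' universe of repeat-associated REs, with BH adjustment within each
#' sweep. Repeats with `R = 0` in a universe are skipped. REs overlapping
#' several repeats count once per repeat.
#'
#' @param mat RPKM matrix.
#' @param samples Sample sheet (uses `qc_pass` rows only).
#' @param annotation Annotation tibble with `re_id`, `re_class`,
#'   `repeat_names` (comma-separated).
#' @param threshold Median-RPKM expression threshold (inclusive).
#' @param stratify_class Also stratify the universe by RE class?
#' @return Tibble: `arm`, `visit`, `condition` (plus `re_class` when
#'   stratified), `repeat_name`, `R`, `A`, `R_expressed`, `A_expressed`,
#'   `delta_ratio`, `direction`, `p_hyper`, `bh_p`.
#' @export
enrichment_by_visit <- function(mat, samples, annotation, threshold = 25,
                                stratify_class = FALSE) {
  samples <- filter(samples, .data$qc_pass)
  rep_map <- annotation |>
    filter(.data$repeat_names != "") |>
    mutate(repeat_name = strsplit(.data$repeat_names, ",", fixed = TRUE)) |>
    tidyr::unnest("repeat_name") |>
    select(feature_id = "re_id", "re_class", "repeat_name")
  if (nrow(rep_map) == 0) abort("annotation has no repeat-associated REs")

  cells <- distinct(samples, .data$arm, .data$visit, .data$condition)
  out <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    ids <- samples |>
      filter(.data$arm == cell$arm, .data$visit == cell$visit) |>
      pull("sample_id")
    expressed <- expressed_filter(mat, ids, threshold)
    strata <- if (stratify_class) split(rep_map, rep_map$re_class) else list(all = rep_map)
    for (stratum_name in names(strata)) {
      universe <- strata[[stratum_name]]
      A <- dplyr::n_distinct(universe$feature_id)
      A_expressed <- dplyr::n_distinct(intersect(universe$feature_id, expressed))
      if (A_expressed == 0) next
      per_repeat <- universe |>
        group_by(.data$repeat_name) |>
        summarise(R = dplyr::n_distinct(.data$feature_id),
                  R_expressed = dplyr::n_distinct(intersect(.data$feature_id, expressed)),
                  .groups = "drop") |>
        filter(.data$R > 0) |>
        mutate(
          A = A, A_expressed = A_expressed,
          delta_ratio = .data$R_expressed / A_expressed - .data$R / A,
          direction = dplyr::case_when(.data$delta_ratio > 0 ~ "enriched",
                                       .data$delta_ratio < 0 ~ "depleted",
                                       .default = "none"),
          arm = cell$arm, visit = cell$visit, condition = cell$condition
        )
      per_repeat$p_hyper <- mapply(hypergeom_test, per_repeat$R, A,
                                   per_repeat$R_expressed, A_expressed,
                                   per_repeat$direction)
      if (stratify_class) per_repeat$re_class <- stratum_name
      out[[length(out) + 1]] <- per_repeat
    }
  }
  bind_rows(out) |>
    group_by(.data$arm, .data$visit,
             dplyr::across(dplyr::any_of("re_class"))) |>
    mutate(bh_p = bh_adjust(.data$p_hyper)) |>
    ungroup() |>
    select(dplyr::any_of(c("arm", "visit", "condition", "re_class")),
           "repeat_name", "R", "A", "R_expressed", "A_expressed",
           "delta_ratio", "direction", "p_hyper", "bh_p")
}

#' Differential REs per repeat and response class
#'
#' Counts, for each repeat name, how many differential REs (non-`none`
#' response class) overlap it, split by response class. An RE overlapping
#' two repeats is counted once under each.
#'
#' @param calls Tibble from [pattern_calls()].
#' @param annotation Annotation with `re_id` and `repeat_names`.
#' @return Tibble: `repeat_name`, `response_class`, `n`.
#' @export
differential_repeat_counts <- function(calls, annotation) {
  rep_map <- annotation |>
    filter(.data$repeat_names != "") |>
    mutate(repeat_name = strsplit(.data$repeat_names, ",", fixed = TRUE)) |>
    tidyr::unnest("repeat_name") |>
    select(feature_id = "re_id", "repeat_name")
  calls |>
    filter(.data$response_class != "none") |>
    inner_join(rep_map, by = "feature_id", relationship = "many-to-many") |>
    count(.data$repeat_name, .data$response_class)
}
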