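## The eight expression patterns: every combination of up/down/ns across
## the two transitions except (ns, ns), which is "none".

PATTERN_MAP <- c(
  "up.ns"     = "acute_up",
  "down.ns"   = "acute_down",
  "ns.up"     = "recovery_up",
  "ns.down"   = "recovery_down",
  "up.up"     = "continuous_up",
  "down.down" = "continuous_down",
  "up.down"   = "reversal_up_down",
  "down.up"   = "reversal_down_up",
  "ns.ns"     = "none"
)

#' Classify the two transition calls into an expression pattern
#'
#' Maps each (T1 call, T2 call) pair to one of eight response classes, or
#' `none` for (ns, ns): *acute* patterns change at baseline-to-crossover
#' only; *recovery* patterns change at crossover-to-crossback only;
#' *continuous* patterns change in the same direction at both transitions;
#' *reversal* patterns change in opposite directions (an acute response
#' followed by an opposite recovery). The mapping is a bijection on the
#' eight non-null combinations.
#'
#' @param call_t1,call_t2 Character vectors of `"up"`/`"down"`/`"ns"`.
#' @return Character vector of response classes.
#' @examples
#' classify_pattern("up", "ns")   # acute_up
#' classify_pattern("ns", "down") # recovery_down
#' @export
classify_pattern <- function(call_t1, call_t2) {
  if (any(!call_t1 %in% CALLS) || any(!call_t2 %in% CALLS)) {
    bad <- setdiff(c(call_t1, call_t2), CALLS)
    abort(sprintf("unknown call token '%s' (expected up/down/ns)", bad[1]))
  }
  unname(PATTERN_MAP[paste(call_t1, call_t2, sep = ".")])
}

#' Pattern calls from two fitted transitions
#'
#' Joins the per-feature calls of the T1 and T2 [fit_transition_lmem()]
#' fits and classifies each feature's pattern.
#'
#' @param fit_t1,fit_t2 `transition_fit` objects for the two transitions
#'   of one arm.
#' @return Tibble: `feature_id`, `call_t1`, `call_t2`, `slope_t1`,
#'   `slope_t2`, `response_class`.
#' @export
pattern_calls <- function(fit_t1, fit_t2) {
  stopifnot(inherits(fit_t1, "transition_fit"), inherits(fit_t2, "transition_fit"))
  fit_t1$results |>
    select("feature_id", slope_t1 = "slope", call_t1 = "call") |>
    inner_join(
      select(fit_t2$results, "feature_id", slope_t2 = "slope", call_t2 = "call"),
      by = "feature_id"
    ) |>
    mutate(response_class = classify_pattern(.data$call_t1, .data$call_t2))
}

#' Summarize patterns by RE class
#'
#' Cross-tabulates response classes against RE annotation classes, with
#' arm-level totals and the fraction of differential features altered in
#' both transitions (`#(non-ns in both) / #(non-ns in any)`). Features
#' missing from the annotation are tallied under `unannotated`.
#'
#' @param calls Tibble from [pattern_calls()] (needs `feature_id`,
#'   `call_t1`, `call_t2`, `response_class`).
#' @param annotation Annotation tibble with `re_id` and `re_class`.
#' @return Tibble of counts (`response_class` x `re_class`, plus a `total`
#'   column), with attributes `fraction_both_transitions` and
#'   `n_differential`.
#' @export
summarize_patterns <- function(calls, annotation = NULL) {
  if (!is.null(annotation)) {
    calls <- calls |>
      left_join(select(annotation, feature_id = "re_id", "re_class"),
                by = "feature_id") |>
      mutate(re_class = if_else(is.na(.data$re_class), "unannotated", .data$re_class))
  } else {
    calls$re_class <- "unannotated"
  }
  tab <- calls |>
    count(.data$response_class, .data$re_class) |>
    tidyr::pivot_wider(names_from = "re_class", values_from = "n", values_fill = 0L)
  tab <- tidyr::complete(
    tab, response_class = RESPONSE_CLASSES,
    fill = as.list(setNames(rep(0L, ncol(tab) - 1), names(tab)[-1]))
  ) |>
    mutate(response_class = factor(.data$response_class, levels = RESPONSE_CLASSES)) |>
    arrange(.data$response_class) |>
    mutate(response_class = as.character(.data$response_class))
  tab$total <- rowSums(tab[, -1, drop = FALSE])
  any_sig <- calls$call_t1 != "ns" | calls$call_t2 != "ns"
  both_sig <- calls$call_t1 != "ns" & calls$call_t2 != "ns"
  attr(tab, "n_differential") <- sum(any_sig)
  attr(tab, "fraction_both_transitions") <-
    if (sum(any_sig) == 0) NA_real_ else sum(both_sig) / sum(any_sig)
  tab
}
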