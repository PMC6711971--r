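#' Tidy a transition fit
#'
#' One row per feature: slope (matrix units), permutation empirical P,
#' significance call, fitting method (`lmem`, `ols_fallback`, or
#' `constant`), and the number of permutations used.
#'
#' @param x A `transition_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy transition_fit
#' @export
tidy.transition_fit <- function(x, ...) {
  x$results
}

#' One-line summary of a transition fit
#'
#' @param x A `transition_fit`.
#' @param ... Unused.
#' @return A one-row tibble of run-level counts and thresholds.
#' @method glance transition_fit
#' @export
glance.transition_fit <- function(x, ...) {
  tibble(
    arm = x$arm,
    comparison = x$comparison,
    label = x$label,
    unit = x$unit,
    n_features = nrow(x$results),
    n_samples = x$n_samples,
    n_subjects = x$n_subjects,
    n_up = sum(x$results$call == "up"),
    n_down = sum(x$results$call == "down"),
    n_ns = sum(x$results$call == "ns"),
    n_fallback = sum(x$results$method == "ols_fallback"),
    B = x$spec$B,
    alpha = x$spec$alpha,
    slope_threshold = x$spec$slope_threshold
  )
}

#' @export
print.transition_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<transition_fit> %s arm, %s (%s)\n", g$arm, g$comparison, g$label))
  cat(sprintf("  %d features over %d samples / %d subjects\n",
              g$n_features, g$n_samples, g$n_subjects))
  cat(sprintf("  up %d | down %d | ns %d  (|slope| > %g %s, empirical P < %g, B = %d)\n",
              g$n_up, g$n_down, g$n_ns, g$slope_threshold, g$unit, g$alpha, g$B))
  invisible(x)
}
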