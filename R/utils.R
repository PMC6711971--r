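## Shared vocabulary and small helpers.

ARMS <- c("B1HB2", "H1BH2")
VISITS <- c("baseline", "crossover", "crossback")
CONDITIONS <- c("background", "high_dbp")
CALLS <- c("up", "down", "ns")
RE_CLASSES <- c("exonic", "near_exon", "intronic", "orphan")
RESPONSE_CLASSES <- c(
  "acute_up", "acute_down", "recovery_up", "recovery_down",
  "continuous_up", "continuous_down", "reversal_up_down", "reversal_down_up",
  "none"
)

#' Exposure condition implied by arm and visit
#'
#' In the B1HB2 arm subjects start on the background-DBP drug, cross over to
#' the high-DBP drug, and cross back; the H1BH2 arm is the mirror image.
#' The condition of every sample is therefore a deterministic function of
#' its arm and visit.
#'
#' @param arm Character vector of `"B1HB2"` / `"H1BH2"`.
#' @param visit Character vector of `"baseline"` / `"crossover"` /
#'   `"crossback"`, recycled against `arm`.
#' @return Character vector of `"background"` / `"high_dbp"`.
#' @examples
#' arm_visit_condition("B1HB2", c("baseline", "crossover", "crossback"))
#' @export
arm_visit_condition <- function(arm, visit) {
  stopifnot(all(arm %in% ARMS), all(visit %in% VISITS))
  high_at_crossover <- arm == "B1HB2"
  crossover <- visit == "crossover"
  if_else(high_at_crossover == crossover, "high_dbp", "background")
}

# Deterministic 31-bit polynomial string hash, used to derive per-feature
# RNG streams so results do not depend on feature iteration order. The
# multiply is split in two so every intermediate stays inside 2^53.
hash_string31 <- function(x) {
  vapply(x, function(s) {
    h <- 216613626
    for (b in utf8ToInt(s)) {
      h <- bitwXor(h, b)
      h <- (h * 403) %% 2147483647
      h <- (h * 41621) %% 2147483647
    }
    as.integer(h %% 2147483647L)
  }, integer(1), USE.NAMES = FALSE)
}

# Combine a master seed with a (feature_id, stage) label into one 31-bit seed.
derive_seed <- function(master_seed, label) {
  as.integer((as.numeric(master_seed) + hash_string31(label)) %% 2147483647)
}

assert_probability <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(x)
}

# Truncated normal via rejection; fine for the mild truncations used here.
rnorm_trunc <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lower)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}
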