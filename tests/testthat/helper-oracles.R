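# Independent oracles used across tests. These deliberately re-derive
# results by brute force, enumeration, or hand rules, and never call the
# implementation paths they check.

# Quadratic-scan interval classifier: same rule as classify_re but written
# as a direct per-pair loop over 0-based half-open intervals.
brute_classify <- function(re_start, re_end, re_chrom,
                           exons, genes, near_window) {
  overlaps <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1
  gap <- function(s1, e1, s2, e2) {
    if (overlaps(s1, e1, s2, e2)) 0 else max(s2 - e1, s1 - e2)
  }
  hit_exon <- FALSE
  near <- FALSE
  for (j in seq_len(nrow(exons))) {
    if (exons$chrom[j] != re_chrom) next
    if (overlaps(re_start, re_end, exons$start[j], exons$end[j])) hit_exon <- TRUE
    g <- gap(re_start, re_end, exons$start[j], exons$end[j])
    if (g > 0 && g <= near_window) near <- TRUE
  }
  if (hit_exon) return("exonic")
  if (near) return("near_exon")
  for (j in seq_len(nrow(genes))) {
    if (genes$chrom[j] != re_chrom) next
    if (overlaps(re_start, re_end, genes$start[j], genes$end[j])) return("intronic")
  }
  "orphan"
}

# Step-up BH written from the definition: sort, adjust, cumulative min from
# the largest P down, restore order.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# Hypergeometric tail by explicit enumeration over all draw outcomes.
brute_hyper <- function(R, A, R_expressed, A_expressed, direction) {
  k <- max(0, A_expressed - (A - R)):min(R, A_expressed)
  prob <- choose(R, k) * choose(A - R, A_expressed - k) / choose(A, A_expressed)
  if (direction == "enriched") sum(prob[k >= R_expressed]) else sum(prob[k <= R_expressed])
}

# Hand rule for the two-of-three consensus: majority direction among
# non-ns calls wins when it appears at least twice.
brute_consensus <- function(c1, c2, c3) {
  calls <- c(c1, c2, c3)
  n_up <- sum(calls == "up")
  n_down <- sum(calls == "down")
  if (n_up >= 2) "up" else if (n_down >= 2) "down" else "none"
}

# Small balanced two-arm design without missingness, for fast model tests.
tiny_design <- function(n_per_arm = 8, seed = 1, p_rep = 0) {
  simulate_crossover_design(n_bhb = n_per_arm, n_hbh = n_per_arm,
                            p_missing_visit = 0, p_replicate_visit = p_rep,
                            seed = seed)
}

# Planted repeat-enrichment fixture: one repeat induced only under the
# high-DBP condition, against constitutive and silent repeat-associated REs.
repeat_fixture <- function(seed = 63) {
  d <- simulate_crossover_design(8, 8, p_missing_visit = 0,
                                 p_replicate_visit = 0, seed = seed)
  n <- 120
  ids <- sprintf("re_%05d", 1:n)
  planted <- ids[1:30]          # the repeat of interest, induced by exposure
  always <- ids[31:75]          # other repeats, constitutively expressed
  never <- ids[76:120]          # other repeats, never expressed
  baselines <- c(rep(12, 30), rep(40, 45), rep(5, 45))
  sim <- simulate_long_matrix(
    d, n_features = n, noise = noise_spec(1, 2), baseline_means = baselines,
    condition_delta = setNames(rep(25, 30), planted), seed = seed + 1
  )
  ann <- tibble::tibble(
    re_id = ids, chrom = "chr1", start = seq(0, by = 200, length.out = n),
    end = seq(100, by = 200, length.out = n), strand = ".",
    re_class = "orphan",
    repeat_names = c(rep("(TTTC)n", 30), rep("OtherRep", 90))
  )
  list(design = d, sim = sim, ann = ann, planted = planted)
}
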