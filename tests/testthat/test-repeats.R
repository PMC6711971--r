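test_that("the expressed filter uses an inclusive 25-RPKM median", {
  m <- rbind(high = c(30, 30, 30), zero = c(0, 0, 0), edge = c(25, 25, 25),
             low = c(24, 26, 24))
  colnames(m) <- c("s1", "s2", "s3")
  expect_setequal(expressed_filter(m, colnames(m)), c("high", "edge"))
  expect_error(expressed_filter(m, character(0)), "empty sample set")
  expect_error(expressed_filter(m, "nope"), "not in matrix")
})

test_that("raising the threshold can only shrink the expressed set", {
  withr::local_seed(61)
  m <- matrix(rgamma(300, 3, 0.1), 50, 6,
              dimnames = list(sprintf("f%02d", 1:50), paste0("s", 1:6)))
  sets <- lapply(c(10, 25, 40, 80), function(th) expressed_filter(m, colnames(m), th))
  for (i in 2:4) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("the delta-ratio equals its printed arithmetic", {
  expect_equal(delta_ratio(10, 100, 5, 20), 0.15)
  expect_equal(delta_ratio(50, 100, 50, 100), 0) # no threshold applied
  expect_equal(delta_ratio(50, 100, 0, 30), -0.5)
  expect_error(delta_ratio(10, 100, 5, 0), "undefined")
  expect_error(delta_ratio(110, 100, 5, 20), "inconsistent")
})

test_that("hypergeometric P matches exhaustive enumeration, including hand cases", {
  expect_equal(hypergeom_test(5, 10, 4, 4, "enriched"), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_test(5, 10, 0, 4, "depleted"), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_test(5, 10, 5, 10, "enriched"), 1) # draw everything
  expect_equal(hypergeom_test(5, 10, 2, 4, "none"), 1)
  withr::local_seed(62)
  for (i in 1:200) {
    A <- sample(2:25, 1)
    R <- sample(0:A, 1)
    A_exp <- sample(1:A, 1)
    k_min <- max(0, A_exp - (A - R))
    R_exp <- sample(k_min:min(R, A_exp), 1)
    for (dir in c("enriched", "depleted")) {
      expect_equal(hypergeom_test(R, A, R_exp, A_exp, dir),
                   brute_hyper(R, A, R_exp, A_exp, dir), tolerance = 1e-12)
    }
  }
})

test_that("a repeat induced only under high DBP is enriched at high-DBP visits only", {
  fx <- repeat_fixture()
  enr <- enrichment_by_visit(fx$sim$matrix, fx$design, fx$ann, threshold = 25)
  planted <- enr[enr$repeat_name == "(TTTC)n", ]
  high <- planted[planted$condition == "high_dbp", ]
  naive <- planted[planted$arm == "B1HB2" & planted$visit == "baseline", ]
  expect_equal(nrow(high), 3) # B1HB2 crossover, H1BH2 baseline + crossback
  expect_true(all(high$delta_ratio > 0))
  expect_true(all(high$direction == "enriched"))
  expect_true(all(high$bh_p < 0.05))
  expect_false(naive$direction == "enriched" & naive$bh_p < 0.05)
})

test_that("uniform expression yields near-zero delta-ratios and no significant repeats", {
  d <- simulate_crossover_design(6, 6, p_missing_visit = 0,
                                 p_replicate_visit = 0, seed = 64)
  n <- 60
  sim <- simulate_long_matrix(d, n_features = n, noise = noise_spec(1, 2),
                              baseline_means = rep(40, n), seed = 65)
  ann <- tibble::tibble(
    re_id = sprintf("re_%05d", 1:n), chrom = "chr1",
    start = seq(0, by = 200, length.out = n),
    end = seq(100, by = 200, length.out = n), strand = ".", re_class = "orphan",
    repeat_names = rep(c("A-rich", "GA-rich", "MER54"), each = n / 3)
  )
  enr <- enrichment_by_visit(sim$matrix, d, ann, threshold = 25)
  expect_true(all(abs(enr$delta_ratio) < 0.05))
  expect_false(any(enr$bh_p < 0.05))
})

test_that("stratified sweeps emit one row per repeat and RE class", {
  fx <- repeat_fixture(seed = 66)
  fx$ann$re_class <- rep(c("orphan", "intronic"), 60)
  enr <- enrichment_by_visit(fx$sim$matrix, fx$design, fx$ann, threshold = 25,
                             stratify_class = TRUE)
  expect_true("re_class" %in% names(enr))
  expect_setequal(unique(enr$re_class), c("orphan", "intronic"))
})

test_that("differential RE counts per repeat double-count multi-repeat REs", {
  calls <- tibble::tibble(
    feature_id = c("re1", "re2", "re3"),
    response_class = c("acute_down", "acute_down", "none")
  )
  ann <- tibble::tibble(
    re_id = c("re1", "re2", "re3"),
    repeat_names = c("(AATGGAATGG)n", "(AATGGAATGG)n,GA-rich", "GA-rich")
  )
  out <- differential_repeat_counts(calls, ann)
  expect_equal(out$n[out$repeat_name == "(AATGGAATGG)n"], 2)
  expect_equal(out$n[out$repeat_name == "GA-rich"], 1) # re3 is not differential
  none <- differential_repeat_counts(
    tibble::tibble(feature_id = "re1", response_class = "none"), ann)
  expect_equal(nrow(none), 0)
})
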