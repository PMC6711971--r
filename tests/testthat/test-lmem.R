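test_that("model_spec enforces its invariants", {
  expect_error(model_spec(B = 10), ">= 19")
  expect_error(model_spec(alpha = 0), "alpha")
  expect_error(model_spec(alpha = 1), "alpha")
  expect_s3_class(model_spec(B = 19), "model_spec")
})

test_that("empirical P follows the add-one counting formula", {
  expect_equal(empirical_pvalue(10, seq_len(999) / 1000), 1 / 1000)
  expect_equal(empirical_pvalue(1, c(2, 3, 0.5, 0.1)), 3 / 5)
  expect_equal(empirical_pvalue(0, numeric(19)), 1) # ties count as extreme
  expect_gte(empirical_pvalue(100, rnorm(50)), 1 / 51)
})

test_that("significance calls use strict thresholds on slope and P", {
  long <- model_spec(slope_threshold = 10, B = 19)
  expect_equal(call_significance(15, 0.01, long), "up")
  expect_equal(call_significance(9.9, 0.001, long), "ns")
  expect_equal(call_significance(10, 0.001, long), "ns") # exactly 10 not "exceeded"
  expect_equal(call_significance(15, 0.05, long), "ns") # exactly alpha not "less than"
  small <- model_spec(slope_threshold = 5, B = 19)
  expect_equal(call_significance(-6, 0.04, small), "down")
})

test_that("a noiseless planted effect is recovered to machine precision", {
  d <- tiny_design(6, seed = 1)
  sim <- simulate_long_matrix(d, n_features = 1,
                              truth_fractions = c(acute_up = 1),
                              noise = noise_spec(0, 0), delta = 30, seed = 2)
  fit <- fit_transition_lmem(sim$matrix, d, arm = "B1HB2", transition = "T1",
                             spec = model_spec(B = 19, seed = 3))
  expect_equal(tidy(fit)$slope, 30, tolerance = 1e-6)
})

test_that("null features give slopes centred at zero", {
  d <- simulate_crossover_design(20, 0, p_missing_visit = 0,
                                 p_replicate_visit = 0, seed = 4)
  sim <- simulate_long_matrix(d, n_features = 100, noise = noise_spec(5, 5),
                              seed = 5)
  fit <- fit_transition_lmem(sim$matrix, d, arm = "B1HB2", transition = "T1",
                             spec = model_spec(B = 19, seed = 6))
  expect_lt(abs(mean(tidy(fit)$slope)), 0.5)
})

test_that("adjusting for a planted batch confounder removes its bias", {
  d <- simulate_crossover_design(20, 0, p_missing_visit = 0,
                                 p_replicate_visit = 0, seed = 7)
  # half the subjects change batch exactly at the crossover visit
  confounded <- d$subject_id %in% unique(d$subject_id)[1:10]
  d$batch <- ifelse(confounded & d$visit == "crossover", "batch2", "batch1")
  sim <- simulate_long_matrix(
    d, n_features = 30, noise = noise_spec(0, 1, covariate_effects = c(batch2 = 15)),
    seed = 8
  )
  adj <- fit_transition_lmem(sim$matrix, d, arm = "B1HB2", transition = "T1",
                             spec = model_spec(covariates = "batch", B = 19, seed = 9))
  raw <- fit_transition_lmem(sim$matrix, d, arm = "B1HB2", transition = "T1",
                             spec = model_spec(B = 19, seed = 9))
  expect_lt(abs(mean(tidy(adj)$slope)), 1)
  # without adjustment, half the subjects carry the +15 batch shift
  expect_equal(mean(tidy(raw)$slope), 7.5, tolerance = 1.5)
})

test_that("with few subjects the permutation test becomes exact, with a warning", {
  d <- simulate_crossover_design(4, 0, p_missing_visit = 0,
                                 p_replicate_visit = 0, seed = 10)
  sim <- simulate_long_matrix(d, n_features = 3, noise = noise_spec(2, 2),
                              seed = 11)
  expect_warning(
    fit <- fit_transition_lmem(sim$matrix, d, arm = "B1HB2", transition = "T1",
                               spec = model_spec(B = 100, seed = 12)),
    "distinct within-subject permutations"
  )
  r <- tidy(fit)
  expect_true(all(r$n_perm == 2^4 - 1)) # all arrangements minus the identity
  expect_true(all(r$empirical_p >= 1 / 16 & r$empirical_p <= 1))
})

test_that("within-subject permutations preserve per-subject label counts", {
  ind <- c(0, 1, 0, 0, 1, 1, 0, 1)
  rows <- list(s1 = 1:3, s2 = 4:6, s3 = 7:8)
  perms <- withr::with_seed(13, crossbackr:::draw_indicator_perms(rows, ind, 50))
  for (b in seq_len(ncol(perms))) {
    for (r in rows) expect_equal(sum(perms[r, b]), sum(ind[r]))
  }
})

test_that("constant features are reported as ns with P = 1", {
  d <- tiny_design(5, seed = 1)
  m <- matrix(7, 2, nrow(d), dimnames = list(c("f1", "f2"), d$sample_id))
  m[2, ] <- rnorm(nrow(d), 50, 5)
  fit <- fit_transition_lmem(m, d, arm = "B1HB2", transition = "T1",
                             spec = model_spec(B = 19, seed = 2))
  r <- tidy(fit)
  expect_equal(r$method[1], "constant")
  expect_equal(r$slope[1], 0)
  expect_equal(r$empirical_p[1], 1)
  expect_equal(r$call[1], "ns")
})

test_that("condition-pooled small-RNA model recovers a planted condition effect", {
  d <- simulate_crossover_design(10, 10, p_missing_visit = 0,
                                 p_replicate_visit = 0, seed = 14)
  sim <- simulate_small_matrix(d, n_features = 20,
                               truth_fractions = c(condition_up = 0.25),
                               noise = noise_spec(2, 1), delta = 10, seed = 15)
  keep <- filter_small_libraries(sim$design, min_reads = 0)
  fit <- fit_condition_lmem(sim$matrix, keep, arm = "H1BH2",
                            spec = model_spec(slope_threshold = 5, B = 99, seed = 16))
  r <- tidy(fit)
  planted <- sim$truth$feature_id[sim$truth$response_class == "condition_up"]
  expect_equal(mean(r$slope[r$feature_id %in% planted]), 10, tolerance = 1)
  expect_true(all(r$call[r$feature_id %in% planted] == "up"))
})

test_that("an arm observed under a single condition cannot be contrasted", {
  d <- simulate_crossover_design(6, 0, p_missing_visit = 0,
                                 p_replicate_visit = 0, seed = 17)
  d <- d[d$visit == "baseline", ]
  sim <- simulate_small_matrix(d, n_features = 3, seed = 18)
  expect_error(fit_condition_lmem(sim$matrix, d, arm = "B1HB2"),
               "single exposure condition")
})

test_that("pooled-null mode shares one null distribution across features", {
  d <- tiny_design(8, seed = 19)
  sim <- simulate_long_matrix(d, n_features = 10, noise = noise_spec(3, 3),
                              seed = 20)
  per <- fit_transition_lmem(sim$matrix, d, arm = "B1HB2", transition = "T1",
                             spec = model_spec(B = 39, seed = 21))
  pooled <- fit_transition_lmem(sim$matrix, d, arm = "B1HB2", transition = "T1",
                                spec = model_spec(B = 39, seed = 21,
                                                  resampling_mode = "pooled_null"))
  expect_equal(tidy(per)$slope, tidy(pooled)$slope)
  # pooled p-values are computed against 10 x 39 null slopes
  expect_true(all(tidy(pooled)$empirical_p >= 1 / (10 * 39 + 1)))
  expect_false(identical(tidy(per)$empirical_p, tidy(pooled)$empirical_p))
})

test_that("full mixed-model refits and GLS refits give consistent conclusions", {
  d <- tiny_design(10, seed = 22)
  sim <- simulate_long_matrix(d, n_features = 4,
                              truth_fractions = c(acute_up = 0.25),
                              noise = noise_spec(3, 3), delta = 30, seed = 23)
  gls <- fit_transition_lmem(sim$matrix, d, arm = "B1HB2", transition = "T1",
                             spec = model_spec(B = 49, seed = 24))
  full <- fit_transition_lmem(sim$matrix, d, arm = "B1HB2", transition = "T1",
                              spec = model_spec(B = 49, seed = 24,
                                                perm_refit = "full"))
  expect_equal(tidy(gls)$slope, tidy(full)$slope, tolerance = 1e-6)
  expect_equal(tidy(gls)$call[1], "up")
  expect_equal(tidy(full)$call[1], "up")
})
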