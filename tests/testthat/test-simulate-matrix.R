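test_that("noiseless planted acute effect shifts crossover values by exactly delta", {
  d <- tiny_design(6, seed = 1)
  sim <- simulate_long_matrix(d, n_features = 2,
                              truth_fractions = c(acute_up = 0.5),
                              noise = noise_spec(0, 0), delta = 30, seed = 2)
  m <- sim$matrix
  base_ids <- d$sample_id[d$visit == "baseline"]
  cross_ids <- d$sample_id[d$visit == "crossover"]
  # feature 1 planted, feature 2 null; subjects ordered identically
  expect_equal(unname(m["re_00001", cross_ids] - m["re_00001", base_ids]),
               rep(30, length(base_ids)))
  expect_equal(unname(m["re_00002", cross_ids] - m["re_00002", base_ids]),
               rep(0, length(base_ids)))
})

test_that("null features show no systematic visit difference", {
  d <- tiny_design(10, seed = 3)
  sim <- simulate_long_matrix(d, n_features = 500, noise = noise_spec(0, 5),
                              seed = 4)
  m <- sim$matrix
  diffs <- rowMeans(m[, d$sample_id[d$visit == "crossover"]]) -
    rowMeans(m[, d$sample_id[d$visit == "baseline"]])
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))
})

test_that("continuous_up features have strictly increasing visit means in both arms", {
  d <- simulate_crossover_design(20, 20, p_missing_visit = 0,
                                 p_replicate_visit = 0, seed = 5)
  sim <- simulate_long_matrix(d, n_features = 20,
                              truth_fractions = c(continuous_up = 1),
                              noise = noise_spec(0, 1), delta = 20, seed = 6)
  for (arm in c("B1HB2", "H1BH2")) {
    means <- vapply(c("baseline", "crossover", "crossback"), function(v) {
      mean(sim$matrix[, d$sample_id[d$arm == arm & d$visit == v]])
    }, numeric(1))
    expect_true(all(diff(means) > 0))
  }
})

test_that("truth bookkeeping: one record per feature, null deltas zero", {
  d <- tiny_design(4, seed = 1)
  sim <- simulate_long_matrix(d, n_features = 50,
                              truth_fractions = c(acute_up = 0.1, recovery_down = 0.1),
                              seed = 7)
  expect_equal(sort(sim$truth$feature_id), sort(rownames(sim$matrix)))
  expect_false(anyDuplicated(sim$truth$feature_id) > 0)
  nulls <- sim$truth[sim$truth$response_class == "none", ]
  expect_true(all(nulls$delta_t1 == 0 & nulls$delta_t2 == 0))
  acute <- sim$truth[sim$truth$response_class == "acute_up", ]
  expect_true(all(acute$delta_t1 > 0 & acute$delta_t2 == 0))
})

test_that("matrices are clipped at zero and rarely clipped at defaults", {
  d <- tiny_design(8, seed = 2)
  sim <- simulate_long_matrix(d, n_features = 300, seed = 8)
  expect_gte(min(sim$matrix), 0)
  expect_lt(attr(sim$matrix, "clip_fraction"), 0.05)
})

test_that("negative noise SDs are rejected", {
  expect_error(noise_spec(-1, 5), ">= 0")
  expect_error(noise_spec(5, -1), ">= 0")
})

test_that("small-RNA condition effect is planted on high-DBP samples", {
  d <- simulate_crossover_design(10, 10, p_missing_visit = 0,
                                 p_replicate_visit = 0, seed = 9)
  sim <- simulate_small_matrix(d, n_features = 50,
                               truth_fractions = c(condition_up = 0.5),
                               noise = noise_spec(0, 1), delta = 10, seed = 10)
  planted <- sim$truth$feature_id[sim$truth$response_class == "condition_up"]
  high <- sim$design$sample_id[sim$design$condition == "high_dbp"]
  bg <- sim$design$sample_id[sim$design$condition == "background"]
  gap <- rowMeans(sim$matrix[planted, high]) - rowMeans(sim$matrix[planted, bg])
  expect_equal(mean(gap), 10, tolerance = 0.1)
  expect_equal(attr(sim$matrix, "unit"), "RPM")
})

test_that("simulated input reads straddle the 50,000-read library threshold", {
  d <- simulate_crossover_design(15, 15, seed = 11)
  sim <- simulate_small_matrix(d, n_features = 10, mean_input_reads = 60000,
                               sdlog_input_reads = 0.8, seed = 12)
  expect_true(any(sim$design$input_reads < 50000))
  expect_true(any(sim$design$input_reads >= 50000))
})

test_that("control cohort matrix carries planted control-enrichment", {
  d <- tiny_design(4, seed = 1)
  sim <- simulate_long_matrix(d, n_features = 20, noise = noise_spec(0, 1),
                              seed = 13)
  ctrl <- simulate_control_matrix(30, sim$truth,
                                  control_delta = c(re_00001 = 20),
                                  noise = noise_spec(0, 1), seed = 14)
  expect_equal(ncol(ctrl$matrix), 30)
  expect_equal(mean(ctrl$matrix["re_00001", ]) - sim$truth$baseline_mean[1], 20,
               tolerance = 1)
  expect_equal(mean(ctrl$matrix["re_00002", ]) - sim$truth$baseline_mean[2], 0,
               tolerance = 1)
})
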