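validation_fixture <- function(n = 120, seed = 5, noise_sd = 0.3) {
  tab <- natural_descriptor_table()
  rec <- generate_sequences(n, L = 8L, alphabet = tab$NT, seed = seed)
  rec <- generate_potencies(
    rec, tab,
    beta = c(nt1_BCUT_SMR_3 = 0.8, nt2_BCUT_SLOGP_0 = -0.7),
    noise_sd = noise_sd, seed = seed + 1L
  )
  enc <- encode_dataset(rec, tab)
  cl <- art2a_cluster(enc, vigilance = 0.2, seed = seed)
  list(enc = enc, cl = cl)
}

test_that("a single split gives degenerate aggregates", {
  fx <- validation_fixture()
  sp <- generate_splits(fx$enc, fx$cl, 1, 12, seed = 2)
  st <- multi_split_evaluation(fx$enc, sp, n_components = 3)
  agg <- st$aggregate
  expect_true(all(agg$sd == 0))
  expect_true(all(agg$mean == agg$min & agg$mean == agg$max))
})

test_that("aggregates are consistent with a naive second pass", {
  fx <- validation_fixture()
  sp <- generate_splits(fx$enc, fx$cl, 6, 12, seed = 3)
  st <- multi_split_evaluation(fx$enc, sp, n_components = 3)
  for (s in c("train", "test")) {
    per <- st$per_split[st$per_split$set == s, ]
    agg <- st$aggregate[st$aggregate$set == s &
                        st$aggregate$statistic == "r", ]
    expect_equal(agg$mean, mean(per$r))
    expect_equal(agg$sd, sd(per$r))
    expect_equal(agg$max, max(per$r))
    expect_equal(agg$min, min(per$r))
    expect_true(agg$min <= agg$mean && agg$mean <= agg$max)
  }
  expect_error(
    multi_split_evaluation(fx$enc, list(list(train_idx = 1:5, test_idx = 4:8)),
                           n_components = 2),
    class = "sibcut_error_input")
})

test_that("component scans report every grid entry and nested training fit", {
  fx <- validation_fixture()
  sp <- design_split(fx$enc, fx$cl, 12, seed = 4)
  one <- pc_scan(fx$enc, sp, component_grid = list("all"))
  expect_equal(nrow(one), 2L)            # train + test rows
  scan <- pc_scan(fx$enc, sp, component_grid = as.list(1:6))
  tr <- scan[scan$set == "train", ]
  expect_true(all(diff(tr$r) >= -1e-10))
})

test_that("the test correlation peaks near the planted dimensionality", {
  bench <- synthetic_benchmark("small", seed = 31)
  cl <- art2a_cluster(bench$encoded, vigilance = 0.8, seed = 31)
  sps <- generate_splits(bench$encoded, cl, 3, 9, seed = 31)
  r_at <- function(nc) {
    mean(vapply(sps, function(sp) {
      scan <- pc_scan(bench$encoded, sp, component_grid = list(nc))
      scan$r[scan$set == "test"]
    }, numeric(1)))
  }
  # four planted directions: large gain up to 4 components, only plateau
  # or decline beyond
  expect_gte(r_at(4) - r_at(1), 0.15)
  expect_gte(r_at(4), r_at(14) - 0.1)
})

test_that("training-size scans skip infeasible fractions and fill tests", {
  fx <- validation_fixture()
  empty <- training_size_scan(fx$enc, numeric(0))
  expect_equal(nrow(empty), 0L)
  expect_warning(
    res <- training_size_scan(fx$enc, c(0.005, 0.5), clustering = fx$cl,
                              seed = 6),
    "skipped")
  expect_true(all(res$fraction == 0.5))
  expect_equal(unique(res$n_train + res$n_test), nrow(fx$enc))
})

test_that("larger training fractions do not hurt held-out correlation", {
  fx <- validation_fixture(n = 150, seed = 8)
  res <- training_size_scan(fx$enc, c(0.1, 0.8), clustering = fx$cl,
                            seed = 7)
  te <- res[res$set == "test", ]
  expect_gt(te$r[te$fraction == 0.8], te$r[te$fraction == 0.1] - 0.05)
})

test_that("y-scrambling preserves the potency multiset and kills signal", {
  fx <- validation_fixture(n = 150, seed = 9, noise_sd = 0.2)
  scr <- y_scramble_test(fx$enc, fx$cl, n_splits = 3, test_size = 15,
                         n_components = 3, seed = 10)
  expect_equal(sort(fx$enc$potency[scr$permutation]), sort(fx$enc$potency))
  red <- scr$reduction
  expect_equal(red$percent_reduction,
               100 * (1 - red$scrambled_mean_r / red$original_mean_r),
               tolerance = 1e-12)
  te <- red[red$set == "test", ]
  expect_lt(abs(te$scrambled_mean_r), 0.35)
  expect_gt(te$original_mean_r, 0.6)
})

test_that("relative importance concentrates on planted positions", {
  fx <- validation_fixture(n = 150, seed = 12, noise_sd = 0.2)
  sp <- generate_splits(fx$enc, fx$cl, 5, 15, seed = 13)
  st <- multi_split_evaluation(fx$enc, sp, n_components = 4,
                               keep_models = TRUE)
  imp <- relative_importance(st$models)
  expect_equal(sum(imp$per_column$importance), 1, tolerance = 1e-9)
  expect_equal(sum(imp$per_position$importance), 1, tolerance = 1e-9)
  expect_equal(sum(imp$per_bcut$importance), 1, tolerance = 1e-9)
  top2 <- imp$per_position$position[order(-imp$per_position$importance)][1:2]
  expect_setequal(top2, c(1L, 2L))
})

test_that("a single relevant coefficient dominates the importance report", {
  X <- matrix(rnorm(300), 50, 6)
  colnames(X) <- paste0("nt", rep(1:2, each = 3), "_BCUT_PEOE_", rep(0:2, 2))
  y <- X[, "nt2_BCUT_PEOE_1"]
  fit <- fit_pls(X, y = y, n_components = 1)
  imp <- relative_importance(list(fit), L = 2L)
  best <- imp$per_column$term[which.max(imp$per_column$importance)]
  expect_equal(best, "nt2_BCUT_PEOE_1")
  expect_equal(which.max(imp$per_position$importance), 2L)
})
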