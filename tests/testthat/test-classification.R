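test_that("confusion-count metrics match hand evaluation", {
  m <- metrics_from_counts(50, 30, 10, 10)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$recall, 5 / 6)
  expect_equal(m$jaccard, 2 / 3)
  expect_equal(m$P, 60); expect_equal(m$N, 40)
  # perfect classifier
  mp <- metrics_from_counts(60, 40, 0, 0)
  expect_equal(mp$accuracy, 1); expect_equal(mp$recall, 1)
  expect_equal(mp$jaccard, 1)
})

test_that("jaccard never exceeds accuracy over small count grids", {
  grid <- expand.grid(tp = 0:4, tn = 0:4, fp = 0:4, fn = 0:4)
  grid <- grid[rowSums(grid) > 0, ]
  for (i in seq_len(nrow(grid))) {
    m <- metrics_from_counts(grid$tp[i], grid$tn[i], grid$fp[i], grid$fn[i])
    expect_lte(m$jaccard, m$accuracy + 1e-12)
  }
})

test_that("MFCC features are a 72-vector with the documented statistics", {
  set.seed(31)
  sig <- sm_signal(rnorm(8000), 4000)
  f <- mfcc_features(sig)
  expect_length(f, 72L)
  expect_true(all(is.finite(f)))
  expect_equal(names(f)[1:6],
               paste0("mfcc01_", c("mean", "sd", "min", "max",
                                   "mean_absdiff", "sd_absdiff")))
  expect_error(mfcc_features(sm_signal(rnorm(10), 4000)), "too short")
})

test_that("trajectory statistics match hand computations", {
  expect_equal(trajectory_stats(rep(3, 10)), c(3, 0, 3, 3, 0, 0))
  # (0,1,0,1): successive absolute differences are (1,1,1)
  expect_equal(trajectory_stats(c(0, 1, 0, 1)),
               c(0.5, sd(c(0, 1, 0, 1)), 0, 1, 1, 0))
})

test_that("grouped splits never let a group straddle the sides", {
  tab <- make_table()
  for (seed in 1:10) {
    sp <- grouped_split(tab, seed = seed)
    tr_groups <- unique(tab$group[sp$train])
    te_groups <- unique(tab$group[sp$test])
    expect_length(intersect(tr_groups, te_groups), 0L)
    expect_setequal(c(sp$train, sp$test), seq_len(nrow(tab)))
    # both classes appear on both sides
    expect_setequal(unique(tab$class[sp$train]), c("a", "b"))
    expect_setequal(unique(tab$class[sp$test]), c("a", "b"))
  }
  single <- tab[tab$group %in% c("a_g1", "b_g1", "b_g2"), ]
  class(single) <- class(tab)
  expect_error(grouped_split(single), "single group")
})

test_that("class weights are inversely proportional to frequency", {
  y <- factor(rep(c("a", "b", "c"), times = c(10, 20, 70)))
  w <- spectromesh:::class_weights(y)
  expect_equal(as.numeric(w["a"] / w["b"]), 2, tolerance = 1e-12)
  expect_equal(as.numeric(w["a"] / w["c"]), 7, tolerance = 1e-12)
  expect_true(all(is.finite(w)))
})

test_that("combining feature tables gives the full 88-wide design", {
  spec <- speech_like_spec(n_per_class = 3, groups_per_class = 3, seed = 5)
  corpus <- generate_signals(spec)
  dtab <- distortion_feature_table(
    corpus$signals, corpus$labels, grid_N = 16,
    cfg = flatten_config(max_iters = 20))
  mtab <- mfcc_feature_table(corpus$signals, corpus$labels)
  expect_length(feature_names(dtab), 16L)
  expect_length(feature_names(mtab), 72L)
  joined <- combine_features(dtab, mtab)
  expect_length(feature_names(joined), 88L)
  # k = width is the identity selection
  sel <- combine_and_select(dtab, mtab, k = 88, seed = 1)
  expect_setequal(feature_names(sel), feature_names(joined))
  sel45 <- combine_and_select(dtab, mtab, k = 45, seed = 1)
  expect_length(feature_names(sel45), 45L)
  expect_error(combine_and_select(dtab, mtab, k = 100), "k must be")
})

test_that("a label-copy feature dominates the importance ranking", {
  tab <- make_table(p = 6, sep = 0, seed = 2)
  X <- feature_matrix(tab)
  X[, 4] <- as.numeric(factor(tab$class))  # perfect predictor
  X[, 6] <- 0                              # constant feature
  colnames(X)[4] <- "label_copy"; colnames(X)[6] <- "constant"
  tab2 <- feature_table(tab[, c("id", "group", "class")], X)
  rk <- rank_features(tab2, method = "rf_importance", seed = 3)
  expect_equal(rk$feature[1], "label_copy")
  expect_equal(rk$score[rk$feature == "constant"], 0, tolerance = 1e-12)
  expect_equal(tail(rk$feature, 1), "constant")
  # deterministic under a fixed seed
  rk2 <- rank_features(tab2, method = "rf_importance", seed = 3)
  expect_identical(rk, rk2)
  expect_error(rank_features(tab2, method = "magic"))
})

test_that("shap ranking finds the label-copy feature too", {
  tab <- make_table(n_per_class = 20, p = 4, sep = 0, seed = 4)
  X <- feature_matrix(tab)
  X[, 2] <- as.numeric(factor(tab$class)) + rnorm(nrow(X), sd = 0.01)
  colnames(X)[2] <- "label_copy"
  tab2 <- feature_table(tab[, c("id", "group", "class")], X)
  rk <- rank_features(tab2, method = "shap", seed = 5,
                      shap_samples = 5, shap_instances = 15)
  expect_equal(rk$feature[1], "label_copy")
  rk2 <- rank_features(tab2, method = "shap", seed = 5,
                       shap_samples = 5, shap_instances = 15)
  expect_identical(rk, rk2)
})

test_that("separable classes are classified perfectly on held-out groups", {
  tab <- make_table(sep = 4)
  rep_rf <- evaluate_model(tab, model = "rf", n_draws = 3, seed = 7)
  expect_equal(rep_rf$metrics$accuracy, 1)
  expect_equal(rep_rf$metrics$auroc, 1)
  expect_true(all(rep_rf$manifest$side %in% c("train", "test")))
  # determinism of the whole evaluation under a fixed seed
  rep2 <- evaluate_model(tab, model = "rf", n_draws = 3, seed = 7)
  expect_identical(rep_rf$metrics, rep2$metrics)
})

test_that("every classifier in the suite runs on a 3-class problem", {
  tab <- make_table(n_per_class = 24, n_groups = 6, sep = 5,
                    classes = c("a", "b", "c"), seed = 8)
  for (m in c("lr", "svm", "rf", "knn", "ab", "xgb")) {
    rep <- evaluate_model(tab, model = m, n_draws = 4, seed = 9)
    expect_true(rep$metrics$accuracy > 0.5,
                label = sprintf("%s accuracy > chance", m))
    expect_true(is.finite(rep$metrics$auroc))
    expect_equal(nrow(rep$per_class), 3L)
    # per-class one-vs-rest counts are consistent: P = TP + FN
    expect_equal(rep$per_class$P, rep$per_class$TP + rep$per_class$FN)
  }
  expect_error(evaluate_model(tab, model = "nope"), "unknown model")
})

test_that("feature-table validation catches malformed inputs", {
  labels <- data.frame(id = c("a", "b"), group = c("g1", "g2"),
                       class = c("x", "y"))
  X <- matrix(1:4, 2, dimnames = list(NULL, c("f1", "f2")))
  expect_s3_class(feature_table(labels, X), "sm_feature_table")
  X_na <- X; X_na[1] <- NA
  expect_error(feature_table(labels, X_na), "missing")
  expect_error(feature_table(labels, matrix(1:4, 2)), "feature names")
  bad <- labels; bad$group <- c("", "g2")
  expect_error(feature_table(bad, X), "group")
})
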