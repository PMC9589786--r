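#' Classification metrics from confusion counts
#'
#' Accuracy `(TP + TN) / (TP + TN + FP + FN)`, recall `TP / (TP + FN)` and
#' the Jaccard-style score `(TP + TN) / (2 (P + N) - (TP + TN))`, where `P =
#' TP + FN` and `N = TN + FP`. The Jaccard score never exceeds the accuracy
#' and both reach 1 exactly for a perfect classifier.
#'
#' @param tp,tn,fp,fn non-negative confusion counts.
#' @return Named list with `accuracy`, `recall`, `jaccard`, plus the counts
#'   and `P`, `N`.
#' @examples
#' metrics_from_counts(50, 30, 10, 10)  # accuracy 0.8, recall 5/6, jaccard 2/3
#' @export
metrics_from_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  P <- tp + fn; N <- tn + fp
  list(accuracy = (tp + tn) / (tp + tn + fp + fn),
       recall = if (P > 0) tp / P else NA_real_,
       jaccard = (tp + tn) / (2 * (P + N) - (tp + tn)),
       TP = tp, TN = tn, FP = fp, FN = fn, P = P, N = N)
}

#' Grouped train/test split
#'
#' Splits recordings 80/20 (by default) at the group (subject) level,
#' stratified by class: within every class, whole groups are assigned to
#' the test side, so no subject ever straddles the split. Every class must
#' contribute at least two groups.
#'
#' @param tab an `sm_feature_table` (or any data.frame with `group` and
#'   `class` columns).
#' @param test_fraction fraction of groups per class held out; default 0.2.
#' @param seed integer seed.
#' @return List with `train` and `test` row indices and a `manifest`
#'   data.frame (group, class, side).
#' @export
grouped_split <- function(tab, test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  gc <- unique(tab[, c("group", "class")])
  if (anyDuplicated(gc$group)) {
    stop("a group appears under more than one class; grouped ",
         "class-stratified splitting is ambiguous")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  test_groups <- character(0)
  for (cl in unique(gc$class)) {
    g <- gc$group[gc$class == cl]
    if (length(g) < 2L) {
      stop(sprintf("class '%s' has a single group; grouped split impossible",
                   cl))
    }
    n_test <- max(1L, round(test_fraction * length(g)))
    n_test <- min(n_test, length(g) - 1L)
    test_groups <- c(test_groups, sample(g, n_test))
  }
  test <- which(tab$group %in% test_groups)
  train <- setdiff(seq_len(nrow(tab)), test)
  manifest <- data.frame(group = gc$group, class = gc$class,
                         side = ifelse(gc$group %in% test_groups,
                                       "test", "train"))
  list(train = train, test = test, manifest = manifest)
}

# fold ids at the group level, stratified by class
grouped_folds <- function(groups, classes, k) {
  gc <- unique(data.frame(group = groups, class = classes))
  fold_of <- integer(0)
  for (cl in unique(gc$class)) {
    g <- sample(gc$group[gc$class == cl])
    f <- rep(seq_len(k), length.out = length(g))
    fold_of[g] <- f
  }
  fold_of[groups]
}

# inverse-frequency class weights, normalized to mean 1
class_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * as.numeric(tab))
  names(w) <- names(tab)
  w
}

# ---- classifier wrappers: fit(X, y, w, params) / predict -> prob matrix ----

prob_matrix <- function(p, levels) {
  if (is.null(dim(p))) p <- cbind(1 - p, p)  # binary vector -> 2 columns
  p <- as.matrix(p)
  if (is.null(colnames(p))) colnames(p) <- levels
  p <- p[, levels, drop = FALSE]
  p / pmax(rowSums(p), 1e-12)
}

sm_fit <- function(model, X, y, params, seed) {
  y <- droplevels(factor(y))
  cw <- class_weights(y)
  w <- as.numeric(cw[as.character(y)])
  set.seed(seed)
  fit <- switch(model,
    lr = {
      df <- data.frame(.y = y, X, check.names = FALSE)
      utils::capture.output(
        m <- nnet::multinom(.y ~ ., data = df, weights = w,
                            decay = params$decay, maxit = 200,
                            MaxNWts = 5000, trace = FALSE))
      m
    },
    svm = e1071::svm(X, y, cost = params$cost, gamma = params$gamma,
                     class.weights = cw, probability = TRUE),
    rf = randomForest::randomForest(X, y, ntree = params$ntree,
                                    mtry = min(params$mtry, ncol(X)),
                                    classwt = cw),
    knn = {
      mu <- colMeans(X); sdv <- pmax(apply(X, 2L, stats::sd), 1e-12)
      list(X = scale(X, mu, sdv), y = y, k = params$k, mu = mu, sdv = sdv)
    },
    ab = fit_adaboost(X, y, w, n_rounds = params$n_rounds,
                      maxdepth = params$maxdepth),
    xgb = {
      num_y <- as.integer(y) - 1L
      nc <- nlevels(y)
      obj <- if (nc == 2L) "binary:logistic" else "multi:softprob"
      pars <- list(objective = obj, eta = params$eta,
                   max_depth = params$max_depth, nthread = 1L)
      if (nc > 2L) pars$num_class <- nc
      dtr <- xgboost::xgb.DMatrix(X, label = num_y, weight = w)
      xgboost::xgb.train(params = pars, data = dtr,
                         nrounds = params$nrounds, verbose = 0)
    },
    stop(sprintf("unknown model '%s'", model)))
  structure(list(model = model, fit = fit, levels = levels(y)),
            class = "sm_classifier")
}

sm_predict <- function(obj, X) {
  lv <- obj$levels
  p <- switch(obj$model,
    lr = {
      pr <- stats::predict(obj$fit, newdata = as.data.frame(X), type = "probs")
      if (is.null(dim(pr))) {
        pr <- cbind(1 - pr, pr); colnames(pr) <- lv
      }
      pr
    },
    svm = attr(stats::predict(obj$fit, X, probability = TRUE),
               "probabilities"),
    rf = stats::predict(obj$fit, X, type = "prob"),
    knn = predict_knn(obj$fit, X),
    ab = predict_adaboost(obj$fit, X),
    xgb = {
      pr <- stats::predict(obj$fit, xgboost::xgb.DMatrix(X))
      m <- if (length(lv) == 2L) {
        cbind(1 - pr, pr)
      } else if (is.matrix(pr)) {
        pr
      } else {
        matrix(pr, ncol = length(lv), byrow = TRUE)
      }
      colnames(m) <- lv
      m
    })
  prob_matrix(p, lv)
}

predict_knn <- function(fit, X) {
  Xs <- scale(X, fit$mu, fit$sdv)
  lv <- levels(fit$y)
  d2 <- outer(rowSums(Xs^2), rowSums(fit$X^2), `+`) -
    2 * Xs %*% t(fit$X)
  t(apply(d2, 1L, function(row) {
    nb <- fit$y[order(row)[seq_len(fit$k)]]
    as.numeric(table(nb)[lv]) / fit$k
  })) -> p
  p[is.na(p)] <- 0
  colnames(p) <- lv
  p
}

# SAMME AdaBoost over shallow rpart trees (stumps by default)
fit_adaboost <- function(X, y, w, n_rounds = 40L, maxdepth = 1L) {
  lv <- levels(y)
  K <- length(lv)
  n <- length(y)
  w <- w / sum(w)
  stumps <- list(); alphas <- numeric(0)
  df <- data.frame(.y = y, X, check.names = FALSE)
  for (r in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w * n,
                        control = rpart::rpart.control(
                          maxdepth = maxdepth, cp = 0, minsplit = 2,
                          xval = 0))
    pred <- stats::predict(fit, df, type = "class")
    err <- sum(w * (pred != y))
    if (err >= 1 - 1 / K) break
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(K - 1)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    stumps[[r]] <- fit; alphas[r] <- alpha
    if (err < 1e-10) break
  }
  list(stumps = stumps, alphas = alphas, levels = lv)
}

predict_adaboost <- function(fit, X) {
  lv <- fit$levels
  scores <- matrix(0, nrow(X), length(lv), dimnames = list(NULL, lv))
  df <- as.data.frame(X)
  for (r in seq_along(fit$stumps)) {
    if (is.null(fit$stumps[[r]])) next
    pred <- stats::predict(fit$stumps[[r]], df, type = "class")
    scores[cbind(seq_len(nrow(X)), as.integer(pred))] <-
      scores[cbind(seq_len(nrow(X)), as.integer(pred))] + fit$alphas[r]
  }
  sw <- rowSums(scores)
  sw[sw == 0] <- 1
  scores / sw
}

# random hyper-parameter draws per model
draw_params <- function(model, n) {
  lapply(seq_len(n), function(i) switch(model,
    lr = list(decay = 10^stats::runif(1, -4, 0)),
    svm = list(cost = 10^stats::runif(1, -1, 2),
               gamma = 10^stats::runif(1, -3, 0)),
    rf = list(ntree = sample(c(100L, 200L, 300L, 500L), 1L),
              mtry = sample(2:10, 1L)),
    knn = list(k = sample(1:15, 1L)),
    ab = list(n_rounds = sample(c(20L, 40L, 80L), 1L),
              maxdepth = sample(1:2, 1L)),
    xgb = list(nrounds = sample(c(30L, 60L, 120L), 1L),
               eta = 10^stats::runif(1, -1.5, -0.3),
               max_depth = sample(2:6, 1L))))
}

macro_auroc <- function(y, prob) {
  lv <- colnames(prob)
  if (length(lv) == 2L) {
    return(as.numeric(pROC::auc(pROC::roc(
      response = y == lv[2L], predictor = prob[, 2L],
      levels = c(FALSE, TRUE), direction = "<", quiet = TRUE))))
  }
  aucs <- vapply(lv, function(cl) {
    if (length(unique(y == cl)) < 2L) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(
      response = y == cl, predictor = prob[, cl],
      levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)))
  }, numeric(1L))
  mean(aucs, na.rm = TRUE)
}

# macro-averaged one-vs-rest metrics plus overall accuracy
summary_metrics <- function(y, pred, prob) {
  lv <- levels(y)
  per_class <- lapply(lv, function(cl) {
    m <- metrics_from_counts(tp = sum(pred == cl & y == cl),
                             tn = sum(pred != cl & y != cl),
                             fp = sum(pred == cl & y != cl),
                             fn = sum(pred != cl & y == cl))
    c(list(class = cl), m)
  })
  pc <- do.call(rbind, lapply(per_class, as.data.frame))
  list(accuracy = mean(pred == y),
       recall = mean(pc$recall, na.rm = TRUE),
       jaccard = mean(pc$jaccard),
       auroc = macro_auroc(y, prob),
       per_class = pc)
}

#' Train and evaluate a classifier under the grouped protocol
#'
#' Splits the corpus 80/20 at the group (subject) level stratified by
#' class, tunes the chosen classifier by randomized hyper-parameter search
#' under fivefold grouped cross-validation on the training side (objective:
#' accuracy for multiclass tasks, AUROC for binary ones), applies
#' inverse-frequency class weights, refits the best configuration on the
#' full training side, and reports accuracy, macro recall, macro Jaccard
#' and AUROC on the held-out test side. Optionally performs random-forest
#' feature selection to `select_k` features inside the training side, so no
#' test information leaks into the selection. All randomness is seeded.
#'
#' @param tab an `sm_feature_table` with at least 2 classes and 2 groups
#'   per class.
#' @param model one of `"lr"`, `"svm"`, `"rf"`, `"knn"`, `"ab"`, `"xgb"`.
#' @param test_fraction held-out fraction of groups per class; default 0.2.
#' @param cv_folds cross-validation folds; default 5.
#' @param n_draws random hyper-parameter draws; default 8.
#' @param select_k optional number of features to keep by training-side
#'   random-forest ranking before fitting.
#' @param split optional precomputed [grouped_split()] result, so several
#'   models can share one split.
#' @param seed integer seed.
#' @return An `sm_eval_report`: test-side `metrics` (accuracy, recall,
#'   jaccard, auroc), `per_class` one-vs-rest counts and metrics,
#'   `confusion` matrix, `best_params`, `cv_results`, the split `manifest`,
#'   `selected_features` (if any) and `seed`.
#' @export
evaluate_model <- function(tab, model = "rf", test_fraction = 0.2,
                           cv_folds = 5L, n_draws = 8L, select_k = NULL,
                           split = NULL, seed = 1L) {
  stopifnot(inherits(tab, "sm_feature_table"))
  y_all <- factor(tab$class)
  if (nlevels(y_all) < 2L) stop("need at least 2 classes")
  if (is.null(split)) split <- grouped_split(tab, test_fraction, seed)

  train_tab <- tab[split$train, ]
  test_tab <- tab[split$test, ]
  selected <- NULL
  if (!is.null(select_k)) {
    rk <- rank_features(train_tab, method = "rf_importance", seed = seed)
    selected <- rk$feature[seq_len(min(select_k,
                                       length(feature_names(tab))))]
  }
  pick <- function(tt) {
    X <- feature_matrix(tt)
    if (!is.null(selected)) X <- X[, selected, drop = FALSE]
    X
  }
  Xtr <- pick(train_tab); ytr <- droplevels(factor(train_tab$class))
  Xte <- pick(test_tab); yte <- factor(test_tab$class, levels = levels(ytr))

  binary <- nlevels(ytr) == 2L
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  grid <- draw_params(model, n_draws)
  folds <- grouped_folds(train_tab$group, train_tab$class, cv_folds)

  cv_score <- function(params) {
    sc <- vapply(seq_len(cv_folds), function(f) {
      tr <- folds != f; va <- folds == f
      if (!any(va) || length(unique(ytr[tr])) < 2L) return(NA_real_)
      fit <- sm_fit(model, Xtr[tr, , drop = FALSE], ytr[tr], params, seed)
      prob <- sm_predict(fit, Xtr[va, , drop = FALSE])
      pred <- factor(colnames(prob)[max.col(prob)], levels = levels(ytr))
      yv <- factor(ytr[va], levels = levels(ytr))
      if (binary) macro_auroc(yv, prob) else mean(pred == yv)
    }, numeric(1L))
    mean(sc, na.rm = TRUE)
  }
  scores <- vapply(grid, cv_score, numeric(1L))
  best <- if (all(!is.finite(scores))) {
    warning("cross-validation produced no finite scores ",
            "(corpus too small?); using the first hyper-parameter draw")
    grid[[1L]]
  } else {
    grid[[which.max(scores)]]
  }

  fit <- sm_fit(model, Xtr, ytr, best, seed)
  prob <- sm_predict(fit, Xte)
  pred <- factor(colnames(prob)[max.col(prob)], levels = levels(ytr))
  sm <- summary_metrics(yte, pred, prob)

  structure(list(
    model = model,
    metrics = sm[c("accuracy", "recall", "jaccard", "auroc")],
    per_class = sm$per_class,
    confusion = table(truth = yte, predicted = pred),
    best_params = best,
    cv_results = data.frame(draw = seq_along(scores), score = scores),
    manifest = split$manifest,
    selected_features = selected,
    seed = seed), class = "sm_eval_report")
}

#' @export
print.sm_eval_report <- function(x, ...) {
  cat(sprintf("<sm_eval_report: model %s>\n", x$model))
  m <- x$metrics
  cat(sprintf("  accuracy %.3f | recall %.3f | jaccard %.3f | auroc %.3f\n",
              m$accuracy, m$recall, m$jaccard, m$auroc))
  cat(sprintf("  test groups: %s\n",
              paste(x$manifest$group[x$manifest$side == "test"],
                    collapse = ", ")))
  invisible(x)
}

#' Rank features by importance
#'
#' Orders the features of a table by importance, either by random-forest
#' mean decrease in accuracy (`"rf_importance"`, the default) or by
#' Monte-Carlo Shapley values (`"shap"`): sampled-permutation marginal
#' contributions of each feature to the fitted random forest's class
#' probabilities, averaged over instances (Shapley sampling approximation).
#' Both are deterministic under a fixed seed. Constant features receive
#' zero importance and rank last.
#'
#' @param tab an `sm_feature_table`.
#' @param method `"rf_importance"` or `"shap"`.
#' @param seed integer seed.
#' @param ntree random-forest size; default 300.
#' @param shap_samples permutation samples per instance for `"shap"`;
#'   default 15.
#' @param shap_instances maximum instances scored for `"shap"`; default 40.
#' @return data.frame with columns `feature`, `score`, ordered by
#'   decreasing score.
#' @export
rank_features <- function(tab, method = c("rf_importance", "shap"),
                          seed = 1L, ntree = 300L, shap_samples = 15L,
                          shap_instances = 40L) {
  method <- match.arg(method)
  X <- feature_matrix(tab)
  y <- droplevels(factor(tab$class))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rf <- randomForest::randomForest(X, y, ntree = ntree, importance = TRUE)
  score <- if (method == "rf_importance") {
    imp <- randomForest::importance(rf, type = 1L, scale = FALSE)[, 1L]
    pmax(imp, 0)
  } else {
    shap_scores(rf, X, shap_samples, shap_instances)
  }
  out <- data.frame(feature = colnames(X), score = as.numeric(score))
  # among zero-importance ties, constant features sort last
  is_const <- apply(X, 2L, function(v) stats::sd(v) == 0)
  out <- out[order(-out$score, is_const, out$feature), ]
  rownames(out) <- NULL
  out
}

# Monte-Carlo Shapley values: mean |marginal contribution| of each feature
# to the predicted probability of the instance's own class
shap_scores <- function(rf, X, n_samples, n_instances) {
  n <- nrow(X); p <- ncol(X)
  inst <- sample(n, min(n_instances, n))
  phi <- matrix(0, length(inst), p)
  pred_own <- function(M, own) {
    pr <- stats::predict(rf, M, type = "prob")
    pr[cbind(seq_len(nrow(M)), own)]
  }
  for (ii in seq_along(inst)) {
    i <- inst[ii]
    own <- which.max(stats::predict(rf, X[i, , drop = FALSE],
                                    type = "prob")[1L, ])
    acc <- numeric(p)
    for (s in seq_len(n_samples)) {
      perm <- sample(p)
      bg <- X[sample(n, 1L), ]
      z <- bg
      prev <- pred_own(matrix(z, 1L, p, dimnames = list(NULL, colnames(X))),
                       own)
      for (j in perm) {
        z[j] <- X[i, j]
        cur <- pred_own(matrix(z, 1L, p, dimnames = list(NULL, colnames(X))),
                        own)
        acc[j] <- acc[j] + (cur - prev)
        prev <- cur
      }
    }
    phi[ii, ] <- acc / n_samples
  }
  colMeans(abs(phi))
}

#' Top-ranked features report
#'
#' @param ranking data.frame from [rank_features()].
#' @param n how many top features to keep; default 10.
#' @return The top rows with a `rank` column.
#' @export
top_features <- function(ranking, n = 10L) {
  out <- utils::head(ranking, n)
  cbind(rank = seq_len(nrow(out)), out)
}

#' Export an evaluation report as JSON and CSV
#'
#' Writes `metrics` and provenance as `<path>.json` and the confusion table
#' as `<path>_confusion.csv`.
#'
#' @param report an `sm_eval_report`.
#' @param path base path (no extension).
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(
    list(model = report$model, metrics = report$metrics,
         best_params = report$best_params, seed = report$seed,
         test_groups = report$manifest$group[report$manifest$side == "test"]),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(report$confusion),
                   paste0(path, "_confusion.csv"), row.names = FALSE)
  invisible(path)
}
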