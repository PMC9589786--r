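#' Construct a feature table
#'
#' A feature table is a data.frame with one row per recording: the columns
#' `id`, `group` (subject label driving grouped splitting) and `class`,
#' followed by numeric feature columns. All values must be finite and every
#' row must carry a group label.
#'
#' @param labels data.frame with columns `id`, `group`, `class`.
#' @param X numeric matrix of features, one row per recording; column names
#'   become feature names.
#' @return A data.frame of class `sm_feature_table`.
#' @export
feature_table <- function(labels, X) {
  stopifnot(is.data.frame(labels),
            all(c("id", "group", "class") %in% names(labels)))
  X <- as.matrix(X)
  if (nrow(X) != nrow(labels)) stop("labels and X row counts differ")
  if (is.null(colnames(X)) || any(!nzchar(colnames(X)))) {
    stop("X must have feature names")
  }
  if (!all(is.finite(X))) stop("feature table contains missing values")
  if (any(!nzchar(labels$group))) stop("every row needs a group label")
  tab <- cbind(labels[, c("id", "group", "class")], as.data.frame(X))
  class(tab) <- c("sm_feature_table", "data.frame")
  tab
}

#' Feature columns of a feature table
#'
#' @param tab an `sm_feature_table`.
#' @return Character vector of feature column names
#'   (`feature_matrix()`: the numeric matrix itself).
#' @export
feature_names <- function(tab) {
  setdiff(names(tab), c("id", "group", "class"))
}

#' @rdname feature_names
#' @export
feature_matrix <- function(tab) {
  as.matrix(tab[, feature_names(tab), drop = FALSE])
}

#' Distortion-signature features for a corpus
#'
#' Runs the geometric pipeline (surface, mesh, flattening, 16-feature
#' signature, see [signal_signature()]) over a list of signals.
#'
#' @param signals list of [sm_signal] objects.
#' @param labels data.frame with `id`, `group`, `class` (one row per
#'   signal, matched by `id`).
#' @param ... passed to [signal_signature()] (e.g. `grid_N`, `kind`, `cfg`).
#' @return An `sm_feature_table` with 16 feature columns.
#' @export
distortion_feature_table <- function(signals, labels, ...) {
  feats <- t(vapply(signals, function(s) signal_signature(s, ...),
                    numeric(16L)))
  rownames(feats) <- vapply(signals, function(s) s$id, "")
  feature_table(labels[match(rownames(feats), labels$id), ], feats)
}

#' MFCC baseline features for a corpus
#'
#' @param signals list of [sm_signal] objects.
#' @param labels data.frame with `id`, `group`, `class`.
#' @param n_mfcc number of cepstral coefficients (default 12, i.e. 72
#'   features).
#' @param ... passed to [mfcc_features()].
#' @return An `sm_feature_table` with `6 * n_mfcc` feature columns.
#' @export
mfcc_feature_table <- function(signals, labels, n_mfcc = 12L, ...) {
  feats <- t(vapply(signals, function(s) mfcc_features(s, n_mfcc = n_mfcc, ...),
                    numeric(6L * n_mfcc)))
  rownames(feats) <- vapply(signals, function(s) s$id, "")
  feature_table(labels[match(rownames(feats), labels$id), ], feats)
}

#' Join two feature tables on recording id
#'
#' @param a,b `sm_feature_table`s over the same recordings.
#' @return An `sm_feature_table` with the union of feature columns.
#' @export
combine_features <- function(a, b) {
  if (!setequal(a$id, b$id)) stop("feature tables cover different ids")
  if (length(intersect(feature_names(a), feature_names(b)))) {
    stop("duplicate feature names across tables")
  }
  b <- b[match(a$id, b$id), ]
  feature_table(a[, c("id", "group", "class")],
                cbind(feature_matrix(a), feature_matrix(b)))
}

#' Combine distortion and MFCC features, then select the top k
#'
#' Joins the two tables (16 + 72 = 88 features for the defaults), ranks the
#' features by random-forest importance fitted on the training rows only,
#' and keeps the `k` most important. Fitting the ranking on training rows
#' avoids leaking test information into the selection.
#'
#' @param distortion,mfcc `sm_feature_table`s sharing ids.
#' @param k number of features to keep; default 45. `k` equal to the joined
#'   width is the identity selection.
#' @param seed integer seed for the random forest.
#' @param train_ids ids of the training rows the ranking may see; defaults
#'   to all rows (only appropriate before any train/test split exists).
#' @return The selected `sm_feature_table`, with attributes `ranking` (full
#'   importance ordering) and `selected_features`.
#' @export
combine_and_select <- function(distortion, mfcc, k = 45L, seed = 1L,
                               train_ids = NULL) {
  joined <- combine_features(distortion, mfcc)
  k <- as.integer(k)
  p <- length(feature_names(joined))
  if (k < 1L || k > p) stop(sprintf("k must be in 1..%d", p))
  if (is.null(train_ids)) train_ids <- joined$id
  train <- joined[joined$id %in% train_ids, ]
  rk <- rank_features(train, method = "rf_importance", seed = seed)
  keep <- rk$feature[seq_len(k)]
  out <- feature_table(joined[, c("id", "group", "class")],
                       feature_matrix(joined)[, keep, drop = FALSE])
  attr(out, "ranking") <- rk
  attr(out, "selected_features") <- keep
  out
}

#' Write / read a feature table as CSV
#'
#' @param tab an `sm_feature_table`.
#' @param path file path.
#' @export
write_feature_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  feature_table(df[, c("id", "group", "class")],
                as.matrix(df[, setdiff(names(df), c("id", "group", "class")),
                             drop = FALSE]))
}
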