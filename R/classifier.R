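# Two-stage complaint filter: pluggable text feature extractor feeding a
# gradient-boosted binary classifier, with the fivefold cross-validation
# protocol (fixed test sets reused across both stages) and whole-corpus
# inference.
#
# The feature-extractor contract is: deterministic function text -> fixed-
# dimension numeric vector. The default is a hashed word n-gram
# vectorizer, which keeps the whole pipeline desk-scale and seed-free; an
# encoder producing CLS-style sentence vectors can be plugged in through
# the same contract.

#' Hashed word n-gram feature extractor
#'
#' Lowercases, tokenizes on non-alphanumerics (keeping `_TOKEN` and
#' `:emoji_name:` markers intact), forms word unigrams and bigrams, and
#' hashes each into a fixed number of buckets (count features).
#' Deterministic: identical text always yields the identical vector.
#'
#' @param hash_dim Number of hash buckets (feature dimension).
#' @param ngram Integer vector of n-gram orders (subset of 1:3).
#' @return A `feature_extractor` object.
#' @export
ngram_extractor <- function(hash_dim = 1024L, ngram = 1:2) {
  hash_dim <- as.integer(hash_dim)
  stopifnot(hash_dim >= 2L, all(ngram %in% 1:3))
  structure(list(hash_dim = hash_dim, ngram = as.integer(ngram),
                 tag = sprintf("ngram-hash-%d-n%s", hash_dim,
                               paste(ngram, collapse = ""))),
            class = "feature_extractor")
}

tokenize_for_features <- function(text) {
  stringi::stri_extract_all_regex(tolower(text), "[a-z0-9_]+|:[a-z0-9_]+:")
}

#' Extract a feature matrix from normalized texts
#'
#' @param texts Character vector of (normalized) texts, all nonempty.
#' @param extractor A `feature_extractor` (default [ngram_extractor()]).
#' @param ids Optional item ids used as row names.
#' @return A sparse `dgCMatrix` (items x dimensions) with attribute
#'   `extractor_tag`.
#' @export
extract_features <- function(texts, extractor = ngram_extractor(), ids = NULL) {
  stopifnot(inherits(extractor, "feature_extractor"))
  n <- length(texts)
  if (n == 0L) {
    out <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(0L, extractor$hash_dim))
    attr(out, "extractor_tag") <- extractor$tag
    return(out)
  }
  if (anyNA(texts)) stop("texts must be nonempty", call. = FALSE)
  toks <- tokenize_for_features(texts)
  grams_of <- function(tk) {
    tk <- tk[!is.na(tk)]
    out <- character(0)
    if (1L %in% extractor$ngram) out <- c(out, tk)
    if (2L %in% extractor$ngram && length(tk) >= 2L) {
      out <- c(out, paste(tk[-length(tk)], tk[-1L], sep = "_"))
    }
    if (3L %in% extractor$ngram && length(tk) >= 3L) {
      out <- c(out, paste(tk[seq_len(length(tk) - 2L)],
                          tk[seq(2L, length(tk) - 1L)],
                          tk[seq(3L, length(tk))], sep = "_"))
    }
    out
  }
  grams <- lapply(toks, grams_of)
  lens <- lengths(grams)
  flat <- unlist(grams, use.names = FALSE)
  if (length(flat) == 0L) {
    out <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, extractor$hash_dim))
  } else {
    uniq <- unique(flat)
    bucket <- hash_string(uniq, extractor$hash_dim)
    j <- bucket[match(flat, uniq)]
    i <- rep.int(seq_len(n), lens)
    out <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                                dims = c(n, extractor$hash_dim))
  }
  if (!is.null(ids)) rownames(out) <- ids
  attr(out, "extractor_tag") <- extractor$tag
  out
}

#' Deterministic (optionally stratified) k-fold assignment
#'
#' Produces a partition of the items into k folds whose sizes differ by at
#' most one; with stratification, each fold's class counts are within one
#' item of proportionality. The same assignment object is meant to be
#' reused for every training stage so test sets stay fixed.
#'
#' @param ids Character vector of unique item ids.
#' @param k Number of folds (default 5).
#' @param seed Integer seed (assignment is a pure function of ids, k,
#'   seed, and strata).
#' @param stratify_by Optional label vector aligned with `ids`.
#' @return A `fold_assignment`: list with `k`, `fold_of` (named integer
#'   vector), `seed`.
#' @export
make_folds <- function(ids, k = 5L, seed = 1L, stratify_by = NULL) {
  k <- as.integer(k)
  n <- length(ids)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("k exceeds the number of items", call. = FALSE)
  if (anyDuplicated(ids)) stop("ids must be unique", call. = FALSE)
  fold_of <- integer(n)
  withr::with_seed(as.integer(seed), {
    strata <- if (is.null(stratify_by)) rep(1L, n) else as.integer(factor(stratify_by))
    # Deal items to folds in one continuous round-robin, class by class,
    # so per-class counts and overall fold sizes both stay within one.
    cursor <- 0L
    for (s in unique(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- ((cursor + seq_along(idx) - 1L) %% k) + 1L
      cursor <- (cursor + length(idx)) %% k
    }
  })
  names(fold_of) <- ids
  structure(list(k = k, fold_of = fold_of, seed = as.integer(seed)),
            class = "fold_assignment")
}

default_model_params <- function() {
  list(nrounds = 50L, max_depth = 6L, learning_rate = 0.3, nthread = 1L,
       seed = 42L)
}

fit_xgb <- function(X, y01, params) {
  dm <- xgboost::xgb.DMatrix(X, label = y01, nthread = params$nthread)
  xgboost::xgb.train(
    params = xgboost::xgb.params(objective = "binary:logistic",
                                 max_depth = params$max_depth,
                                 learning_rate = params$learning_rate,
                                 nthread = params$nthread,
                                 seed = params$seed),
    data = dm, nrounds = params$nrounds, verbose = 0)
}

#' Fit the gradient-boosted complaint classifier on all labeled items
#'
#' @param features Feature matrix (items x d).
#' @param labels Character vector in `{complaint, other}` aligned with the
#'   feature rows.
#' @param model_params Named list overriding the defaults
#'   (`nrounds`, `max_depth`, `learning_rate`, `nthread`, `seed`).
#' @return A `complaint_model`: the fitted booster plus feature metadata.
#' @export
fit_classifier <- function(features, labels, model_params = list()) {
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("training data contains a single class", call. = FALSE)
  }
  params <- utils::modifyList(default_model_params(), model_params)
  booster <- fit_xgb(features, as.numeric(labels == "complaint"), params)
  structure(list(booster = booster, dim = ncol(features),
                 extractor_tag = attr(features, "extractor_tag"),
                 params = params),
            class = "complaint_model")
}

#' Cross-validated training with pooled held-out predictions
#'
#' For each fold, trains on the remaining k - 1 folds and predicts the
#' held-out fold; the pooled predictions cover every item exactly once and
#' are the basis of the reported confusion matrix and metrics.
#'
#' @param features Feature matrix (items x d) with ids as row names, or
#'   pass `ids`.
#' @param labels True labels aligned with rows.
#' @param folds A [make_folds()] assignment over the same ids.
#' @param model_params See [fit_classifier()].
#' @param ids Item ids (defaults to the feature row names).
#' @return A list: `models` (per-fold `complaint_model`s), `predictions`
#'   (tibble `id`, `true`, `predicted`, `fold`), `folds` (the assignment
#'   used, unchanged).
#' @export
crossval_train <- function(features, labels, folds, model_params = list(),
                           ids = rownames(features)) {
  stopifnot(inherits(folds, "fold_assignment"))
  if (is.null(ids)) stop("item ids required (row names or `ids`)", call. = FALSE)
  if (!setequal(ids, names(folds$fold_of)) || nrow(features) != length(ids)) {
    stop("fold assignment does not match the feature ids", call. = FALSE)
  }
  fold_of <- folds$fold_of[ids]
  models <- vector("list", folds$k)
  pred <- character(length(ids))
  for (f in seq_len(folds$k)) {
    test <- which(fold_of == f)
    train <- which(fold_of != f)
    if (length(unique(labels[train])) < 2L) {
      stop(sprintf("fold %d: training split contains a single class", f),
           call. = FALSE)
    }
    models[[f]] <- fit_classifier(features[train, , drop = FALSE],
                                  labels[train], model_params)
    p <- predict_corpus(models[[f]], features[test, , drop = FALSE],
                        ids = ids[test])
    pred[test] <- p$predicted
  }
  list(models = models,
       predictions = tibble::tibble(id = ids, true = labels,
                                    predicted = pred,
                                    fold = unname(fold_of)),
       folds = folds)
}

#' Predict complaint/other labels for a feature matrix
#'
#' @param model A `complaint_model` from [fit_classifier()].
#' @param features Feature matrix with the training dimension.
#' @param ids Item ids (defaults to row names).
#' @return A prediction tibble `id`, `predicted`.
#' @export
predict_corpus <- function(model, features, ids = rownames(features)) {
  stopifnot(inherits(model, "complaint_model"))
  if (ncol(features) != model$dim) {
    stop(sprintf("feature dimension %d does not match the model's %d",
                 ncol(features), model$dim), call. = FALSE)
  }
  if (nrow(features) == 0L) {
    return(tibble::tibble(id = character(), predicted = character()))
  }
  if (is.null(ids)) ids <- as.character(seq_len(nrow(features)))
  prob <- predict(model$booster,
                  xgboost::xgb.DMatrix(features, nthread = model$params$nthread))
  tibble::tibble(id = ids,
                 predicted = ifelse(prob > 0.5, "complaint", "other"))
}

#' Keep only tweets predicted as complaints
#'
#' @param tweets Corpus tibble.
#' @param predictions Prediction tibble covering every tweet id.
#' @return The complaint subset, with attribute `"counts"` holding
#'   `n_input` and `n_complaint`.
#' @export
filter_complaints <- function(tweets, predictions) {
  idx <- match(tweets$id, predictions$id)
  if (anyNA(idx)) {
    stop("no prediction for tweet id: ", tweets$id[which(is.na(idx))[1L]],
         call. = FALSE)
  }
  keep <- predictions$predicted[idx] == "complaint"
  out <- tweets[keep, , drop = FALSE]
  attr(out, "counts") <- list(n_input = nrow(tweets), n_complaint = nrow(out))
  out
}
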