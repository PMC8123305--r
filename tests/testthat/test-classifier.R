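test_that("the hashed n-gram extractor is deterministic with fixed shape", {
  ex <- ngram_extractor(hash_dim = 256)
  X <- extract_features(c("my back pain is bad", "my back pain is bad",
                          "buy this mattress now"), ex)
  expect_equal(dim(X), c(3L, 256L))
  expect_equal(X[1, ], X[2, ])
  expect_false(all(X[1, ] == X[3, ]))
  expect_equal(attr(X, "extractor_tag"), ex$tag)
  X2 <- extract_features(c("my back pain is bad"), ex)
  expect_equal(as.numeric(X[1, ]), as.numeric(X2[1, ]))
  expect_equal(nrow(extract_features(character(0), ex)), 0L)
})

test_that("generated complaint and other texts are separable in feature space", {
  s <- generate_corpus(small_sim(seed = 12, days = 6, rate = 15,
                                 duplicate_rate = 0, nonenglish_rate = 0))
  idx <- seq_len(min(2000, nrow(s$tweets)))
  texts <- normalize_text(s$tweets$text[idx])$norm_text
  lab <- s$truth$label[idx]
  X <- extract_features(texts, ngram_extractor(512))
  Xn <- X / sqrt(Matrix::rowSums(X^2))
  cen_c <- Matrix::colMeans(Xn[lab == "complaint", ])
  cen_o <- Matrix::colMeans(Xn[lab == "other", ])
  sim_within <- mean(c(as.numeric(Xn[lab == "complaint", ] %*% cen_c),
                       as.numeric(Xn[lab == "other", ] %*% cen_o)))
  sim_between <- mean(c(as.numeric(Xn[lab == "complaint", ] %*% cen_o),
                        as.numeric(Xn[lab == "other", ] %*% cen_c)))
  expect_gt(sim_within, sim_between)
})

test_that("fold assignment partitions items with balanced, stratified sizes", {
  ids <- sprintf("t%04d", 1:5000)
  f <- make_folds(ids, k = 5, seed = 3)
  expect_equal(sort(unique(unname(f$fold_of))), 1:5)
  expect_equal(as.integer(table(f$fold_of)), rep(1000L, 5))
  expect_identical(make_folds(ids, k = 5, seed = 3), f)
  expect_false(identical(make_folds(ids, k = 5, seed = 4)$fold_of, f$fold_of))

  lab <- rep(c("complaint", "other"), c(2977, 2023))
  fs <- make_folds(ids, k = 5, seed = 3, stratify_by = lab)
  per_fold <- table(fs$fold_of, lab)
  expect_true(all(per_fold[, "complaint"] %in% c(595L, 596L)))
  expect_true(all(abs(diff(range(table(fs$fold_of)))) <= 1))

  expect_error(make_folds(ids[1:3], k = 5), "exceeds")
})

test_that("fold partition properties hold for arbitrary n and k", {
  withr::with_seed(77, {
    for (rep in 1:10) {
      n <- sample(10:200, 1)
      k <- sample(2:min(10, n), 1)
      ids <- sprintf("x%d", seq_len(n))
      f <- make_folds(ids, k = k, seed = rep)
      sizes <- tabulate(f$fold_of, k)
      expect_equal(sum(sizes), n)
      expect_lte(diff(range(sizes)), 1L)
    }
  })
})

test_that("cross-validation pools one prediction per item and separates blobs", {
  withr::with_seed(5, {
    n <- 2000; d <- 20
    lab <- rep(c("complaint", "other"), each = n / 2)
    X <- matrix(rnorm(n * d), n, d)
    X[lab == "complaint", 1:5] <- X[lab == "complaint", 1:5] + 5
  })
  X <- methods::as(X, "CsparseMatrix")
  rownames(X) <- sprintf("b%04d", 1:n)
  attr(X, "extractor_tag") <- "test"
  folds <- make_folds(rownames(X), k = 5, seed = 1, stratify_by = lab)
  cv <- crossval_train(X, lab, folds, model_params = list(nrounds = 20))
  expect_setequal(cv$predictions$id, rownames(X))
  expect_false(any(duplicated(cv$predictions$id)))
  expect_gte(mean(cv$predictions$true == cv$predictions$predicted), 0.99)
  # the same assignment object is reused across stages, untouched
  expect_identical(cv$folds, folds)
})

test_that("label-shuffled data scores at the majority-class rate", {
  accs <- vapply(1:5, function(seed) {
    withr::with_seed(seed, {
      n <- 600; d <- 10
      X <- matrix(rnorm(n * d), n, d)
      lab <- sample(rep(c("complaint", "other"), c(360, 240)))
    })
    X <- methods::as(X, "CsparseMatrix")
    rownames(X) <- sprintf("r%03d", 1:n)
    folds <- make_folds(rownames(X), k = 5, seed = seed, stratify_by = lab)
    # a shallow booster: under the permutation null the model should fall
    # back to (near-)majority prediction rather than memorized noise
    cv <- crossval_train(X, lab, folds,
                         model_params = list(nrounds = 10, max_depth = 2))
    mean(cv$predictions$true == cv$predictions$predicted)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.6), 0.05)
})

test_that("prediction is deterministic, shape-checked, and overfits separable data", {
  withr::with_seed(9, {
    n <- 400; d <- 15
    lab <- rep(c("complaint", "other"), each = n / 2)
    X <- matrix(rnorm(n * d), n, d)
    X[lab == "complaint", 1] <- X[lab == "complaint", 1] + 6
  })
  X <- methods::as(X, "CsparseMatrix")
  rownames(X) <- sprintf("p%03d", 1:n)
  model <- fit_classifier(X, lab, list(nrounds = 20))
  p1 <- predict_corpus(model, X)
  p2 <- predict_corpus(model, X)
  expect_identical(p1, p2)
  expect_gte(mean(p1$predicted == lab), 0.99)
  expect_equal(nrow(predict_corpus(model, X[0, , drop = FALSE])), 0L)
  expect_error(predict_corpus(model, X[, 1:5]), "dimension")
  expect_error(fit_classifier(X, rep("complaint", n)), "single class")
})

test_that("single-class training folds raise an error naming the fold", {
  X <- methods::as(diag(10), "CsparseMatrix")
  rownames(X) <- sprintf("s%02d", 1:10)
  lab <- rep(c("complaint", "other"), each = 5)
  # folds built so some training split sees one class only
  f <- make_folds(rownames(X), k = 2, seed = 1)
  f$fold_of[] <- rep(1:2, each = 5)  # fold 2 train = all complaint
  expect_error(crossval_train(X, lab, f), "fold \\d")
})

test_that("complaint filtering keeps exactly the predicted-complaint subset", {
  tw <- make_tiny_corpus(5)
  preds <- tibble::tibble(id = tw$id,
                          predicted = c("complaint", "other", "complaint",
                                        "other", "complaint"))
  out <- filter_complaints(tw, preds)
  expect_equal(out$id, tw$id[c(1, 3, 5)])
  expect_equal(attr(out, "counts"), list(n_input = 5L, n_complaint = 3L))

  all_other <- tibble::tibble(id = tw$id, predicted = "other")
  expect_equal(nrow(filter_complaints(tw, all_other)), 0L)
  all_comp <- tibble::tibble(id = tw$id, predicted = "complaint")
  expect_equal(filter_complaints(tw, all_comp)$id, tw$id)
  expect_error(filter_complaints(tw, preds[1:3, ]), "no prediction")
})
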