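# penalised logistic training, ROC AUC, cross-validation, reporting

test_that("a separable 1-D problem gets a positive weight and single-class input errors", {
  X <- matrix(c(rep(0, 50), rep(5, 50)), ncol = 1, dimnames = list(NULL, "f"))
  y <- c(rep(0, 50), rep(1, 50))
  m <- train_cadd(X, y, l2 = 0.1)
  expect_gt(m$weights[["f"]], 0)
  expect_error(train_cadd(X, rep(1, 100)), "single class")
  expect_error(train_cadd(X, y, l2 = -1), "l2")
})

test_that("the trainer agrees with an independent ridge-logistic implementation", {
  skip_if_not_installed("glmnet")
  fm <- toy_feature_matrix(n = 3000)
  m <- train_cadd(fm, l2 = 0.1)
  g <- glmnet::glmnet(fm$X, fm$y, family = "binomial", alpha = 0,
                      lambda = 1 / (nrow(fm$X) * 0.1), standardize = FALSE,
                      thresh = 1e-12)
  co <- as.numeric(stats::coef(g))
  expect_equal(unname(m$weights), co[-1], tolerance = 1e-5)
  expect_equal(m$intercept, co[1], tolerance = 1e-5)
})

test_that("planted coefficients are recovered in rank order", {
  beta <- c(2, -1, 0.5, 0)
  fm <- toy_feature_matrix(n = 20000, beta = beta, seed = 17)
  m <- train_cadd(fm, l2 = 0.1, max_iter = 100)
  w <- m$weights
  expect_true(m$converged)
  ord <- order(-abs(w))
  expect_equal(ord, order(-abs(beta)))          # |w1| > |w2| > |w3| > |w4|
  expect_gt(w[1], 0); expect_lt(w[2], 0); expect_gt(w[3], 0)
  expect_equal(unname(which.min(abs(w))), 4L)   # planted zero smallest
  expect_equal(top_features(m, 1)$feature, "x1")
})

test_that("a stronger penalty never increases the weight norm", {
  fm <- toy_feature_matrix(n = 2000)
  norms <- vapply(c(1, 0.5, 0.25, 0.125, 0.0625), function(l2)
    sqrt(sum(train_cadd(fm, l2 = l2)$weights^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-10))
})

test_that("training with permuted columns yields identically permuted weights", {
  fm <- toy_feature_matrix(n = 1000)
  m1 <- train_cadd(fm$X, fm$y, l2 = 0.1)
  perm <- c(3, 1, 2)
  m2 <- train_cadd(fm$X[, perm], fm$y, l2 = 0.1)
  expect_equal(unname(m2$weights), unname(m1$weights[perm]), tolerance = 1e-9)
})

test_that("roc_auc equals the brute-force all-pairs statistic on tied data", {
  withr::with_seed(5, {
    for (rep in 1:25) {
      n <- sample(10:200, 1)
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) y <- c(0, 1, y[-(1:2)])
      s <- sample(round(rnorm(n), 1))  # rounding forces ties
      expect_equal(roc_auc(y, s), auc_brute(y, s))
    }
  })
  expect_equal(roc_auc(c(0, 0, 1, 1), c(1, 2, 3, 4)), 1)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(1, 2, 3, 4)), 0)
  expect_equal(roc_auc(c(0, 1), c(2, 2)), 0.5)
  expect_true(is.na(roc_auc(c(1, 1), c(1, 2))))
})

test_that("label inversion and monotone transforms act on AUC as expected", {
  withr::with_seed(8, {
    y <- rbinom(300, 1, 0.4)
    s <- rnorm(300) + y
    a <- roc_auc(y, s)
    expect_equal(roc_auc(1 - y, s), 1 - a)
    expect_equal(roc_auc(y, exp(s)), a)
    expect_equal(roc_auc(y, 10 * s - 3), a)
    expect_equal(roc_auc(y, rank(s, ties.method = "min")), a)
  })
})

test_that("cross-validation is seed-reproducible, stratified, and averages its folds", {
  fm <- toy_feature_matrix(n = 1500, beta = c(1, -0.5, 0.2))
  cv1 <- cross_validate(fm, k = 5, seed = 4)
  cv2 <- cross_validate(fm, k = 5, seed = 4)
  expect_identical(cv1$fold_auc, cv2$fold_auc)
  expect_equal(cv1$mean_auc, mean(cv1$fold_auc))
  for (f in 1:5) expect_true(all(table(fm$y[cv1$folds == f]) > 0))
  cv3 <- cross_validate(fm, k = 5, seed = 5)
  expect_false(identical(cv1$folds, cv3$folds))
  tiny <- toy_feature_matrix(n = 8)
  expect_error(cross_validate(tiny, k = 6, seed = 1), "stratify")
})

test_that("cross-validated AUC approaches the generative oracle", {
  beta <- c(1, -0.8)
  fm <- toy_feature_matrix(n = 20000, beta = beta, seed = 23)
  # oracle: AUC of the true linear score under the logistic generative model,
  # estimated on a large independent Monte-Carlo draw
  oracle <- withr::with_seed(99, {
    Xo <- matrix(rnorm(4e5 * 2), ncol = 2)
    eta <- drop(Xo %*% beta)
    yo <- rbinom(nrow(Xo), 1, plogis(eta))
    roc_auc(yo, eta)
  })
  cv <- cross_validate(fm, k = 5, seed = 1)
  expect_lt(abs(cv$mean_auc - oracle), 0.03)
})

test_that("label permutation drives cross-validated AUC to chance", {
  fm <- toy_feature_matrix(n = 10000, beta = c(1, -0.5, 0.3), seed = 29)
  fm$y <- withr::with_seed(30, sample(fm$y))
  cv <- cross_validate(fm, k = 5, seed = 2)
  expect_gt(cv$mean_auc, 0.45)
  expect_lt(cv$mean_auc, 0.55)
})

test_that("subset AUC restricts out-of-fold predictions and reports undefined subsets", {
  fm <- toy_feature_matrix(n = 2000, beta = c(1.2, -0.6))
  cv <- cross_validate(fm, k = 4, seed = 3)
  all_in <- subset_auc(cv, list(everything = rep(TRUE, 2000)))
  expect_equal(all_in$auc, roc_auc(fm$y, cv$oof))
  # an uninformative subset by construction: scores shuffled within it
  half <- seq_len(1000)
  cvs <- cv
  cvs$oof[half] <- withr::with_seed(7, sample(cvs$oof[half]))
  res <- subset_auc(cvs, list(shuffled = seq_len(2000) %in% half))
  expect_lt(abs(res$auc - 0.5), 0.06)
  # single-class subset: undefined with counts
  one_class <- which(fm$y == 1)[1:50]
  res2 <- subset_auc(cv, list(pos_only = one_class))
  expect_true(is.na(res2$auc))
  expect_equal(res2$n_pos, 50)
  expect_equal(res2$n_neg, 0)
  # factor-label interface
  lab <- ifelse(seq_len(2000) <= 1000, "first", "second")
  res3 <- subset_auc(cv, lab)
  expect_setequal(res3$subset, c("first", "second"))
})

test_that("top_features ranks by |weight| with deterministic column-order ties", {
  m <- structure(list(weights = c(a = 0.5, b = -0.5, c = 2, d = 0.1),
                      intercept = 0, column_names = letters[1:4]),
                 class = "cadd_model")
  tf <- top_features(m, 10)
  expect_equal(tf$feature, c("c", "a", "b", "d"))
  expect_equal(nrow(top_features(m, 2)), 2)
})

test_that("raw scores are the linear predictor and respect the column contract", {
  m <- structure(list(weights = c(f = 2), intercept = -1, column_names = "f"),
                 class = "cadd_model")
  expect_equal(raw_score(m, matrix(3, dimnames = list(NULL, "f"))), 5)
  z <- structure(list(weights = c(f = 0), intercept = 0, column_names = "f"),
                 class = "cadd_model")
  expect_equal(raw_score(z, matrix(rnorm(5), ncol = 1,
                                   dimnames = list(NULL, "f"))), rep(0, 5))
  expect_error(raw_score(m, matrix(1, dimnames = list(NULL, "g"))),
               "do not match")
  # monotone: raising a positive-weight feature never lowers the score
  xs <- matrix(seq(-3, 3, by = 0.5), ncol = 1, dimnames = list(NULL, "f"))
  expect_true(all(diff(raw_score(m, xs)) >= 0))
})

test_that("models round-trip through their JSON artifact", {
  fm <- toy_feature_matrix(n = 500)
  m <- train_cadd(fm, l2 = 0.1)
  m$imputation_stats <- list(x1 = 1.25)
  m$specs <- list(feature_spec("x1", kind = "numeric",
                               imputation = "mean_from_simulated"),
                  feature_spec("x2", kind = "numeric", imputation = "fixed",
                               value = 0),
                  feature_spec("x3", kind = "numeric"))
  p <- withr::local_tempfile()
  write_model(m, p)
  back <- read_model(p)
  expect_equal(back$weights, m$weights)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$imputation_stats, m$imputation_stats)
  expect_equal(back$specs[[1]]$imputation, "mean_from_simulated")
  expect_equal(raw_score(back, fm$X[1:5, ]), raw_score(m, fm$X[1:5, ]))
})
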