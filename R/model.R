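#' Train the L2-penalised logistic classifier
#'
#' Fits logistic regression separating simulated (class 1) from derived
#' (class 0) variants by minimising the penalised log-loss
#' `sum_i log(1 + exp(-y_i eta_i)) + ||w||^2 / (2 l2)`, where `l2` is the
#' inverse-regularisation constant (smaller = stronger penalty; the
#' intercept is not penalised). The solver is damped Newton (iteratively
#' reweighted least squares) from a zero start, with step halving; it is
#' fully deterministic for fixed input.
#'
#' @param x a `feature_matrix` from [encode_and_impute()], or a numeric
#'   matrix (then `y` is required).
#' @param y binary labels when `x` is a plain matrix.
#' @param l2 inverse regularisation strength, > 0.
#' @param max_iter maximum Newton iterations.
#' @param standardize centre/scale columns before fitting (the penalty then
#'   applies on the standardised scale); reported weights are mapped back to
#'   the raw scale.
#' @param tol convergence threshold on the max absolute gradient per sample.
#' @return a `cadd_model`: named `weights`, `intercept`, hyperparameters,
#'   `converged` flag and `n_iter`.
#' @export
train_cadd <- function(x, y = NULL, l2 = 0.1, max_iter = 100L,
                       standardize = FALSE, tol = 1e-8) {
  if (inherits(x, "feature_matrix")) {
    y <- x$y
    x <- x$X
  }
  if (is.null(y)) stop2("labels are required to train")
  y <- as.numeric(y)
  if (!is.numeric(l2) || length(l2) != 1L || l2 < 0)
    stop2("l2 must be a single non-negative number")
  if (l2 == 0) stop2("l2 = 0 (infinite penalty) is not a usable setting")
  if (length(unique(y)) < 2L)
    stop2("training data contains a single class")
  if (any(!is.finite(x))) stop2("training matrix contains non-finite values")
  n <- nrow(x); m <- ncol(x)
  cn <- colnames(x) %||% paste0("x", seq_len(m))
  center <- rep(0, m); scale <- rep(1, m)
  if (standardize) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
    x <- sweep(sweep(x, 2, center), 2, scale, "/")
  }
  lambda <- 1 / l2
  theta <- rep(0, m + 1L)  # intercept first
  Xa <- cbind(1, x)
  pen <- c(0, rep(lambda, m))
  obj <- function(th) {
    eta <- drop(Xa %*% th)
    # numerically stable log(1 + exp(-y*eta)) with y in {0,1}
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) + sum(pen * th^2) / 2
  }
  converged <- FALSE
  it <- 0L
  J <- obj(theta)
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(Xa %*% theta)
    p <- 1 / (1 + exp(-eta))
    g <- drop(crossprod(Xa, p - y)) + pen * theta
    if (max(abs(g)) < tol * max(1, n)) {
      converged <- TRUE
      break
    }
    wgt <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(Xa * wgt, Xa)
    diag(H) <- diag(H) + pen
    step <- drop(solve(H, g))
    alpha <- 1
    repeat {
      th_new <- theta - alpha * step
      J_new <- obj(th_new)
      if (J_new <= J + 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    if (abs(J - J_new) < 1e-12 * max(1, abs(J))) {
      theta <- th_new
      J <- J_new
      converged <- TRUE
      break
    }
    theta <- th_new
    J <- J_new
  }
  b <- unname(theta[1L]); w <- unname(theta[-1L])
  if (standardize) {
    w_raw <- w / scale
    b <- b - sum(w * center / scale)
    w <- w_raw
  }
  structure(list(weights = stats::setNames(w, cn), intercept = b,
                 l2 = l2, max_iter = as.integer(max_iter),
                 standardize = standardize, converged = converged,
                 n_iter = it, column_names = cn),
            class = "cadd_model")
}

#' @export
print.cadd_model <- function(x, ...) {
  cat(sprintf("cadd_model: %d features, l2 = %g, %s after %d iteration(s)\n",
              length(x$weights), x$l2,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Linear classifier score
#'
#' Returns `w'x + b` for encoded rows; higher means more like the simulated
#' (proxy-deleterious) class. A linear predictor rather than a probability:
#' the two are rank-equivalent, and only ranks matter downstream.
#'
#' @param model a `cadd_model`.
#' @param x encoded numeric matrix or `feature_matrix` whose columns match
#'   the model.
#' @return numeric vector of raw scores.
#' @export
raw_score <- function(model, x) {
  if (inherits(x, "feature_matrix")) x <- x$X
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  if (!identical(colnames(x), model$column_names)) {
    if (is.null(colnames(x)) && ncol(x) == length(model$weights)) {
      # accept unnamed matrices of the right width
    } else if (!is.null(colnames(x)) && setequal(colnames(x), model$column_names)) {
      x <- x[, model$column_names, drop = FALSE]
    } else {
      stop2("matrix columns do not match the model's %d features",
            length(model$weights))
    }
  }
  drop(x %*% model$weights) + model$intercept
}

#' ROC AUC (Mann-Whitney statistic)
#'
#' Probability that a random class-1 score exceeds a random class-0 score,
#' counting ties as one half; computed from midranks, so ties are exact.
#' Undefined (NA) when either class is absent.
#'
#' @param labels binary labels (0/1, logical, or `"derived"`/`"simulated"`).
#' @param scores numeric scores, higher = more class-1-like.
#' @return AUC in \[0, 1\], or `NA` if a class is missing.
#' @export
roc_auc <- function(labels, scores) {
  if (is.character(labels)) labels <- as.integer(labels == "simulated")
  labels <- as.integer(as.logical(as.numeric(labels)))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}

#' Stratified k-fold cross-validation
#'
#' Splits rows into `k` class-stratified folds (assignment reproducible from
#' `seed`), trains on k-1 folds, and records the ROC AUC on each held-out
#' fold together with the out-of-fold scores.
#'
#' @param fm a `feature_matrix` with labels.
#' @param k number of folds, >= 2.
#' @param seed integer seed controlling fold assignment.
#' @param l2,max_iter,standardize passed to [train_cadd()].
#' @return a `cv_report`: `k`, `fold_auc`, `mean_auc`, `seed`, plus the
#'   per-row fold ids (`folds`) and out-of-fold scores (`oof`) and labels.
#' @export
cross_validate <- function(fm, k = 5L, seed = 1L, l2 = 0.1, max_iter = 100L,
                           standardize = FALSE) {
  if (k < 2L) stop2("k must be >= 2")
  y <- fm$y
  if (is.null(y)) stop2("feature matrix carries no labels")
  n <- length(y)
  if (min(sum(y == 1L), sum(y == 0L)) < k)
    stop2("a class has fewer than k = %d members; cannot stratify", k)
  folds <- integer(n)
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  oof <- numeric(n)
  fold_auc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    model <- train_cadd(fm$X[tr, , drop = FALSE], y[tr], l2 = l2,
                        max_iter = max_iter, standardize = standardize)
    sc <- raw_score(model, fm$X[!tr, , drop = FALSE])
    oof[!tr] <- sc
    fold_auc[f] <- roc_auc(y[!tr], sc)
  }
  structure(list(k = as.integer(k), fold_auc = fold_auc,
                 mean_auc = mean(fold_auc), seed = as.integer(seed),
                 folds = folds, oof = oof, labels = y),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d folds, mean AUC %.4f (folds: %s)\n",
              x$k, x$mean_auc, paste(sprintf("%.4f", x$fold_auc), collapse = ", ")))
  invisible(x)
}

#' Out-of-fold AUC over variant subsets
#'
#' Restricts the cross-validated out-of-fold scores to each subset and
#' reports its AUC; subsets lacking one of the classes are reported as
#' undefined (`NA`) with their counts.
#'
#' @param cv a `cv_report` from [cross_validate()].
#' @param subsets a named list of logical/index vectors over the rows, or a
#'   factor/character vector of per-row subset labels.
#' @return data frame `subset, n, n_pos, n_neg, auc`.
#' @export
subset_auc <- function(cv, subsets) {
  n <- length(cv$labels)
  if (!is.list(subsets)) {
    lab <- as.character(subsets)
    if (length(lab) != n) stop2("subset labels and variants differ in length")
    subsets <- lapply(stats::setNames(nm = sort(unique(lab[!is.na(lab)]))),
                      function(lv) !is.na(lab) & lab == lv)
  }
  rows <- lapply(names(subsets), function(nm) {
    sel <- subsets[[nm]]
    if (!is.logical(sel)) sel <- seq_len(n) %in% sel
    y <- cv$labels[sel]
    data.frame(subset = nm, n = sum(sel),
               n_pos = sum(y == 1L), n_neg = sum(y == 0L),
               auc = roc_auc(y, cv$oof[sel]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Largest-weight features
#'
#' Ranks features by absolute weight (descending); exact ties keep column
#' order, so the ranking is deterministic.
#'
#' @param model a `cadd_model`.
#' @param k number of features to return.
#' @return data frame `feature, weight` with `min(k, m)` rows.
#' @export
top_features <- function(model, k = 10L) {
  w <- model$weights
  o <- order(-abs(w), seq_along(w))
  o <- o[seq_len(min(k, length(w)))]
  data.frame(feature = names(w)[o], weight = unname(w[o]),
             stringsAsFactors = FALSE)
}

#' Serialise a trained model (with its encoding context) as JSON
#'
#' The artifact stores the weights and intercept, hyperparameters, the
#' column layout, the imputation statistics frozen at training time, and
#' (when attached) the feature specs, so scoring can re-encode new variants
#' identically.
#'
#' @param model a `cadd_model`; may carry `$imputation_stats` and `$specs`.
#' @param path output path.
#' @return `write_model` returns `path` invisibly; `read_model` the model.
#' @export
write_model <- function(model, path) {
  obj <- list(format_version = 1L,
              weights = as.list(model$weights), intercept = model$intercept,
              l2 = model$l2, max_iter = model$max_iter,
              standardize = model$standardize, converged = model$converged,
              n_iter = model$n_iter, column_names = model$column_names,
              imputation_stats = model$imputation_stats %||% list(),
              # file paths are environment-specific and not needed to score
              # (tracks are loaded from the run configuration), so the model
              # artifact stays reproducible across working directories
              specs = lapply(model$specs %||% list(), function(s) {
                s <- s[!vapply(s, is.null, logical(1))]
                s[setdiff(names(s), c("path", "format", "field"))]
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  specs <- lapply(obj$specs, function(s) {
    feature_spec(name = s$name, source = s$source, kind = s$kind,
                 imputation = s$imputation, value = s$value,
                 levels = if (!is.null(s$levels)) unlist(s$levels),
                 path = s$path, format = s$format, field = s$field)
  })
  structure(list(weights = stats::setNames(as.numeric(unlist(obj$weights)),
                                           names(obj$weights)),
                 intercept = as.numeric(obj$intercept), l2 = obj$l2,
                 max_iter = as.integer(obj$max_iter),
                 standardize = isTRUE(obj$standardize),
                 converged = isTRUE(obj$converged),
                 n_iter = as.integer(obj$n_iter),
                 column_names = as.character(unlist(obj$column_names)),
                 imputation_stats = lapply(obj$imputation_stats, as.numeric),
                 specs = specs),
            class = "cadd_model")
}
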