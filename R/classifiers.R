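# Per-feature nine-class (healthy + 8 cancer types) classifiers with
# cross-validated model selection by macro one-vs-rest AUC.
#
# The candidate pool is a tractable stand-in for an AutoML search:
# ridge- and lasso-regularized multinomial logistic regression (glmnet,
# with a small internal lambda grid evaluated inside the CV loop) and
# linear discriminant analysis. Each candidate's score is its best
# mean CV AUC over its grid; ties break by candidate order.

cls_candidates <- function() {
  list(
    glmnet_ridge = list(alpha = 0, lambda = c(1, 0.1, 0.01, 0.001)),
    glmnet_lasso = list(alpha = 1, lambda = c(0.1, 0.03, 0.01, 0.003)),
    lda          = list()
  )
}

# glmnet needs >= 2 predictors; pad degenerate matrices with a zero column
pad_features <- function(x) {
  if (ncol(x) >= 2) return(x)
  cbind(x, `.pad` = 0)
}

#' Macro one-vs-rest multiclass AUC
#'
#' Mean of binary one-vs-rest AUCs over the classes present in `labels`
#' (classes absent from the evaluation set are skipped).
#'
#' @param proba Samples x classes probability matrix (named columns).
#' @param labels Character labels.
#' @return Macro-averaged AUC in \[0, 1\].
#' @export
macro_ovr_auc <- function(proba, labels) {
  present <- intersect(colnames(proba), unique(labels))
  aucs <- vapply(present, function(cl) {
    auc_binary(proba[, cl], labels == cl)
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

fit_candidate <- function(alg, x, y, classes, lambda = NULL) {
  if (alg %in% c("glmnet_ridge", "glmnet_lasso")) {
    spec <- cls_candidates()[[alg]]
    lam <- lambda %||% spec$lambda
    # glmnet's coordinate descent needs a decreasing path for warm starts;
    # a lone small lambda can fail to converge, so prepend one
    if (length(lam) == 1L) {
      lam <- exp(seq(log(lam * 100), log(lam), length.out = 8))
    }
    withCallingHandlers(
      glmnet::glmnet(pad_features(x), factor(y, levels = classes),
                     family = "multinomial", alpha = spec$alpha,
                     lambda = lam, standardize = FALSE),
      warning = function(w) {
        # small per-class counts are routine at desk scale
        if (grepl("fewer than 8", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  } else if (alg == "lda") {
    MASS::lda(x, grouping = factor(y, levels = classes))
  } else {
    stop("unknown candidate algorithm: ", alg)
  }
}

# predict class probabilities; for glmnet with a lambda path, returns a
# list of matrices (one per lambda), otherwise a single matrix
predict_candidate <- function(alg, fit, x, classes) {
  if (alg %in% c("glmnet_ridge", "glmnet_lasso")) {
    pr <- predict(fit, pad_features(x), type = "response")
    out <- lapply(seq_len(dim(pr)[3]), function(k) {
      m <- pr[, , k, drop = TRUE]
      if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(m)))
      m[, classes, drop = FALSE]
    })
    names(out) <- dimnames(pr)[[3]]
    out
  } else {
    post <- predict(fit, x)$posterior
    miss <- setdiff(classes, colnames(post))
    if (length(miss)) {
      post <- cbind(post, matrix(0, nrow(post), length(miss),
                                 dimnames = list(NULL, miss)))
    }
    post[, classes, drop = FALSE]
  }
}

stratified_folds <- function(labels, folds) {
  fold_id <- integer(length(labels))
  for (cl in unique(labels)) {
    ix <- which(labels == cl)
    fold_id[ix] <- sample(rep_len(seq_len(folds), length(ix)))
  }
  fold_id
}

#' Cross-validated model selection for a feature's nine-class classifier
#'
#' Runs stratified k-fold cross-validation over the candidate algorithms,
#' scores each by mean macro one-vs-rest AUC on the held-out folds, picks
#' the best (ties broken by candidate order), and refits the winner on all
#' training data. Out-of-fold probabilities of the winning candidate are
#' kept in the bundle for leakage-free downstream ensembling.
#'
#' @param features Training matrix (samples x features, named columns,
#'   rownames = sample ids).
#' @param labels Character labels (`"healthy"` or a cancer type), aligned
#'   with the rows of `features`.
#' @param candidates Candidate algorithm ids (subset of
#'   `names(cls_candidates())`).
#' @param folds Number of CV folds (default 4).
#' @param seed Seed for the fold assignment.
#' @param feature_namespace Label recorded in the bundle
#'   (`"amf"`, `"cnv"`, `"fsr"`, `"fsd"`, ...).
#' @return An `mced_model` bundle: winning `algorithm` and hyperparameters,
#'   refit `fit`, fixed `classes` order, per-candidate `cv_auc`, the
#'   training `scaler`, out-of-fold probabilities `oof_proba`, and
#'   `fold_id`.
#' @export
select_best_model <- function(features, labels,
                              candidates = names(cls_candidates()),
                              folds = 4L, seed = 1L,
                              feature_namespace = "feature") {
  stopifnot(is.matrix(features), nrow(features) == length(labels),
            length(candidates) >= 1)
  bad <- setdiff(unique(labels), class_levels())
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ","))
  classes <- intersect(class_levels(), unique(labels))
  tab <- table(labels)
  small <- names(tab)[tab < folds]
  if (length(small)) {
    stop("class(es) with fewer than ", folds, " samples: ",
         paste(small, collapse = ","))
  }
  unknown <- setdiff(candidates, names(cls_candidates()))
  if (length(unknown)) stop("unknown candidates: ", paste(unknown, collapse = ","))

  with_seed(seed, {
    fold_id <- stratified_folds(labels, folds)
    n <- nrow(features)
    # per candidate: per-grid-point AUC per fold, plus oof probabilities
    cv <- list()
    for (alg in candidates) {
      spec <- cls_candidates()[[alg]]
      grid <- spec$lambda %||% NA_real_
      auc_fold <- matrix(NA_real_, folds, length(grid))
      oof <- lapply(seq_along(grid), function(i) {
        matrix(NA_real_, n, length(classes),
               dimnames = list(rownames(features), classes))
      })
      failed <- FALSE
      for (f in seq_len(folds)) {
        tr <- fold_id != f
        sc <- fit_scaler(features[tr, , drop = FALSE])
        xtr <- apply_scaler(sc, features[tr, , drop = FALSE])
        xte <- apply_scaler(sc, features[!tr, , drop = FALSE])
        fit <- tryCatch(
          fit_candidate(alg, xtr, labels[tr], classes,
                        lambda = spec$lambda),
          error = function(e) NULL)
        if (is.null(fit)) { failed <- TRUE; break }
        pr <- predict_candidate(alg, fit, xte, classes)
        if (!is.list(pr)) pr <- list(pr)
        for (i in seq_along(grid)) {
          pi_ <- pr[[min(i, length(pr))]]
          auc_fold[f, i] <- macro_ovr_auc(pi_, labels[!tr])
          oof[[i]][!tr, ] <- pi_
        }
      }
      if (failed) {
        warning("candidate ", alg, " failed to fit; skipped")
        next
      }
      mean_auc <- colMeans(auc_fold)
      best_i <- which.max(mean_auc)
      cv[[alg]] <- list(auc = mean_auc[best_i],
                        lambda = if (all(is.na(grid))) NULL else grid[best_i],
                        oof = oof[[best_i]])
    }
    if (!length(cv)) stop("all candidate models failed")
    aucs <- vapply(cv, `[[`, numeric(1), "auc")
    winner <- names(cv)[which.max(aucs)]   # which.max keeps first on ties

    scaler <- fit_scaler(features)
    xall <- apply_scaler(scaler, features)
    final_lambda <- cv[[winner]]$lambda
    fit <- fit_candidate(winner, xall, labels, classes, lambda = final_lambda)
    structure(list(
      feature = feature_namespace,
      algorithm = winner,
      lambda = final_lambda,
      fit = fit,
      classes = classes,
      folds = folds,
      seed = seed,
      cv_auc = aucs,
      scaler = scaler,
      oof_proba = cv[[winner]]$oof,
      fold_id = fold_id,
      train_ids = rownames(features)),
      class = "mced_model")
  })
}

#' @export
print.mced_model <- function(x, ...) {
  cat(sprintf("mced %s model: %s (CV macro AUC %.3f), %d classes\n",
              x$feature, x$algorithm, max(x$cv_auc), length(x$classes)))
  invisible(x)
}

#' Predict class probabilities from a fitted model bundle
#'
#' @param bundle An `mced_model` from [select_best_model()].
#' @param features Matrix whose columns match the training feature
#'   namespace.
#' @return Samples x classes probability matrix in the bundle's fixed
#'   class order; rows sum to 1.
#' @export
predict_proba <- function(bundle, features) {
  stopifnot(inherits(bundle, "mced_model"))
  if (is.null(colnames(features)) ||
      !all(bundle$scaler$features %in% colnames(features))) {
    stop("feature columns do not match the training namespace")
  }
  x <- apply_scaler(bundle$scaler, features)
  pr <- predict_candidate(bundle$algorithm, bundle$fit, x, bundle$classes)
  if (is.list(pr)) pr <- pr[[length(pr)]]
  pr <- pr / rowSums(pr)
  rownames(pr) <- rownames(features)
  pr
}

#' Cancer-signal score from nine-class probabilities
#'
#' The cumulative probability of the eight cancer classes, i.e.
#' 1 - P(healthy).
#'
#' @param proba Probability matrix with a `healthy` column.
#' @return Per-sample score in \[0, 1\].
#' @export
feature_csd_score <- function(proba) {
  stopifnot("healthy" %in% colnames(proba))
  cancer_cols <- setdiff(colnames(proba), "healthy")
  rowSums(proba[, cancer_cols, drop = FALSE])
}

#' Conditional tissue-of-origin probabilities
#'
#' Renormalizes the cancer-class probabilities to sum to 1, omitting the
#' healthy class. Rows where every cancer probability is zero fall back to
#' the uniform distribution and are flagged in `attr(, "uniform_rows")`.
#'
#' @param proba Nine-class probability matrix with a `healthy` column.
#' @return Samples x 8 conditional probability matrix.
#' @export
conditional_too_proba <- function(proba) {
  stopifnot("healthy" %in% colnames(proba))
  p <- proba[, setdiff(colnames(proba), "healthy"), drop = FALSE]
  tot <- rowSums(p)
  zero <- tot == 0
  out <- p / tot
  if (any(zero)) out[zero, ] <- 1 / ncol(p)
  attr(out, "uniform_rows") <- which(zero)
  out
}
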