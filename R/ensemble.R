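# The cancer-signature ensemble (CSE): logit-normalized per-feature scores
# plus age and sex aggregated by logistic regression for cancer-signal
# detection (CSD) with a specificity-calibrated threshold, and weighted
# conditional-probability aggregation for tissue-of-origin (TOO) with
# top-1/top-2 calls and the ambiguity ("in between") rule.

#' Clipped logit transform
#'
#' `log(p / (1 - p))` with `p` clipped to `[eps, 1 - eps]` so boundary
#' probabilities stay finite.
#'
#' @param p Probabilities in \[0, 1\].
#' @param eps Clipping constant in (0, 0.5).
#' @return Real-valued logits.
#' @export
logit <- function(p, eps = 1e-6) {
  if (eps <= 0 || eps >= 0.5) stop("eps must lie in (0, 0.5)")
  # tolerate floating-point overshoot from probability renormalization
  if (any(p < -1e-8 | p > 1 + 1e-8, na.rm = TRUE)) {
    stop("p must lie in [0, 1]")
  }
  p <- clip01(p, eps)
  log(p / (1 - p))
}

# smallest observed-score threshold whose strict exceedance fraction among
# healthy training scores is <= 1 - target specificity
calibrate_threshold <- function(healthy_scores, target_spec) {
  cand <- sort(unique(healthy_scores))
  for (t in cand) {
    if (mean(healthy_scores > t) <= 1 - target_spec) return(t)
  }
  max(healthy_scores)
}

#' Fit the CSE cancer-signal-detection meta-model
#'
#' Logistic regression of the binary cancer label on the logit-transformed
#' per-feature CSD scores plus age (years) and sex (0 = female, 1 = male).
#' The decision threshold is the smallest observed ensemble score among the
#' training healthy samples such that the fraction of training healthy
#' samples strictly above it is at most `1 - target_spec`.
#'
#' Feature scores supplied here should be out-of-fold (cross-fitted)
#' predictions of the single-feature models; in-sample scores would
#' miscalibrate the threshold.
#'
#' @param feature_scores Matrix (samples x features, e.g. columns `amf`,
#'   `cnv`, `fsr`, `fsd`) of per-feature CSD scores in \[0, 1\].
#' @param age Numeric ages in years.
#' @param sex `"F"`/`"M"` or 0/1 indicator.
#' @param labels Binary labels: `TRUE`/1 for cancer, `FALSE`/0 for healthy.
#' @param target_spec Target specificity (default 0.95).
#' @param eps Logit clipping constant.
#' @param weights Optional TOO feature weights to store (non-negative,
#'   normalized to sum 1).
#' @param delta TOO ambiguity threshold to store (default 0.07).
#' @param ridge Small L2 penalty on the logistic fit (default 0.01).
#'   Logit-transformed feature scores are often completely separable on
#'   well-powered cohorts, where the unpenalized MLE diverges and the
#'   fitted probabilities collapse to 0/1, making the specificity
#'   threshold meaningless; a light ridge keeps coefficients finite and
#'   the training-score distribution continuous.
#' @return An `mced_cse` model: coefficients, threshold, target
#'   specificity, feature names, eps, TOO weights, delta, and training
#'   provenance ids.
#' @export
fit_cse_csd <- function(feature_scores, age, sex, labels,
                        target_spec = 0.95, eps = 1e-6,
                        weights = NULL, delta = 0.07, ridge = 0.01) {
  stopifnot(is.matrix(feature_scores),
            nrow(feature_scores) == length(labels),
            length(age) == length(labels), length(sex) == length(labels))
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2) stop("both classes must be present for fitting")
  sex01 <- if (is.character(sex) || is.factor(sex)) {
    as.integer(as.character(sex) == "M")
  } else as.integer(sex)
  X <- cbind(apply(feature_scores, 2, logit, eps = eps),
             age = age, sex = sex01)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = exp(seq(log(ridge * 100), log(ridge),
                                         length.out = 8)))
  cf <- as.numeric(coef(fit, s = ridge, exact = FALSE))
  names(cf) <- rownames(coef(fit))
  score <- as.numeric(plogis(cbind(1, X) %*% cf))
  thr <- calibrate_threshold(score[y == 0], target_spec)
  if (mean(score[y == 0] > thr) > 1 - target_spec + 1e-12) {
    stop("internal error: threshold calibration failed")
  }
  if (!is.null(weights)) {
    if (any(weights < 0)) stop("TOO weights must be non-negative")
    weights <- weights / sum(weights)
  }
  structure(list(
    coef = cf,
    feature_names = colnames(feature_scores),
    threshold = thr,
    target_spec = target_spec,
    eps = eps,
    too_weights = weights,
    delta = delta,
    train_ids = rownames(feature_scores),
    train_scores = score,
    train_labels = y),
    class = "mced_cse")
}

#' @export
print.mced_cse <- function(x, ...) {
  cat(sprintf("CSE meta-model over (%s) + age + sex; threshold %.4f (target spec %.2f)\n",
              paste(x$feature_names, collapse = ", "),
              x$threshold, x$target_spec))
  invisible(x)
}

#' Recalibrate the decision threshold on held-out healthy scores
#'
#' Replaces the model's threshold with the smallest observed score among
#' the supplied healthy ensemble scores whose strict exceedance fraction is
#' at most `1 - target_spec`. Used with a calibration subset of training
#' healthy samples that no fitting stage has touched, so the calibration
#' scores follow the same distribution as test-sample scores.
#'
#' @param model An `mced_cse`.
#' @param healthy_scores Ensemble scores of held-out healthy samples.
#' @param ids Optional sample ids recorded as calibration provenance.
#' @return The model with an updated threshold.
#' @export
recalibrate_threshold <- function(model, healthy_scores, ids = NULL) {
  stopifnot(inherits(model, "mced_cse"), length(healthy_scores) >= 1)
  model$threshold <- calibrate_threshold(healthy_scores, model$target_spec)
  model$calibration_ids <- ids
  model
}

#' Predict the ensemble CSD score and binary cancer call
#'
#' @param model An `mced_cse` from [fit_cse_csd()].
#' @param feature_scores Matrix of per-feature CSD scores (same columns as
#'   at fit time; no imputation — missing values are an error).
#' @param age,sex As in [fit_cse_csd()].
#' @return Data frame with `score` (logistic probability) and `call`
#'   (`score > threshold`, strict).
#' @export
predict_csd <- function(model, feature_scores, age, sex) {
  stopifnot(inherits(model, "mced_cse"))
  if (!identical(colnames(feature_scores), model$feature_names)) {
    if (is.null(colnames(feature_scores)) ||
        !all(model$feature_names %in% colnames(feature_scores))) {
      stop("missing feature score column(s)")
    }
    feature_scores <- feature_scores[, model$feature_names, drop = FALSE]
  }
  if (anyNA(feature_scores) || anyNA(age) || anyNA(sex)) {
    stop("missing feature score / covariate; no imputation is performed")
  }
  sex01 <- if (is.character(sex) || is.factor(sex)) {
    as.integer(as.character(sex) == "M")
  } else as.integer(sex)
  lg <- logit(feature_scores, eps = model$eps)
  dim(lg) <- dim(feature_scores)   # logit preserves values, restore shape
  X <- cbind(1, lg, age, sex01)
  eta <- as.numeric(X %*% model$coef)
  score <- plogis(eta)
  data.frame(sample_id = rownames(feature_scores) %||%
               seq_along(score),
             score = score, call = score > model$threshold,
             stringsAsFactors = FALSE)
}

#' Weighted-ensemble tissue-of-origin prediction
#'
#' Aggregates per-feature conditional (healthy-omitted) probabilities as
#' `sum_f w_f p_f(type)`, reports the two highest-probability types, and
#' flags a sample as "in between" when the top-1/top-2 probability gap is
#' strictly below `delta`. Ties break deterministically by class label
#' order.
#'
#' @param weights Named non-negative weights (one per feature), normalized
#'   internally to sum 1.
#' @param conditional_probas Named list of samples x 8 conditional
#'   probability matrices, names matching `names(weights)`.
#' @param delta Ambiguity threshold (default 0.07).
#' @return Data frame with `too_top1`, `too_top2`, `too_p1`, `too_p2`,
#'   `in_between`, plus the aggregated matrix in `attr(, "aggregated")`.
#' @export
predict_too <- function(weights, conditional_probas, delta = 0.07) {
  if (is.null(names(weights)) ||
      !setequal(names(weights), names(conditional_probas))) {
    stop("weights and conditional probability matrices must share names")
  }
  if (any(weights < 0)) stop("weights must be non-negative")
  w <- weights / sum(weights)
  types <- colnames(conditional_probas[[1]])
  agg <- 0
  for (f in names(w)) {
    p <- conditional_probas[[f]]
    if (!identical(colnames(p), types)) {
      p <- p[, types, drop = FALSE]
    }
    agg <- agg + w[[f]] * p
  }
  # stable order: probability descending, label order as tie-break
  top <- t(apply(agg, 1, function(r) order(-r, seq_along(r))[1:2]))
  p1 <- agg[cbind(seq_len(nrow(agg)), top[, 1])]
  p2 <- agg[cbind(seq_len(nrow(agg)), top[, 2])]
  out <- data.frame(sample_id = rownames(agg) %||% seq_len(nrow(agg)),
                    too_top1 = types[top[, 1]], too_top2 = types[top[, 2]],
                    too_p1 = p1, too_p2 = p2,
                    in_between = (p1 - p2) < delta,
                    stringsAsFactors = FALSE)
  attr(out, "aggregated") <- agg
  out
}

#' Normalize per-feature TOO weights from out-of-fold accuracies
#'
#' Weights are proportional to each feature's out-of-fold top-1 TOO
#' accuracy on the training split; a degenerate all-zero vector falls back
#' to uniform weights.
#'
#' @param accuracies Named non-negative accuracies.
#' @return Named weights summing to 1.
#' @export
too_weights_from_accuracy <- function(accuracies) {
  if (any(accuracies < 0)) stop("accuracies must be non-negative")
  if (sum(accuracies) == 0) {
    return(setNames(rep(1 / length(accuracies), length(accuracies)),
                    names(accuracies)))
  }
  accuracies / sum(accuracies)
}

#' Evaluate CSD and TOO predictions against truth
#'
#' Computes overall and per-type/per-stage sensitivity, specificity and
#' ROC AUC for the binary cancer call, TOO top-1/top-2 accuracy over
#' detected-or-not cancer samples (top-2 counts the truth appearing in
#' either of the two highest-probability calls), Wilson 95% confidence
#' intervals per cell, and the same TOO metrics restricted to the
#' unambiguous (not "in between") subset.
#'
#' @param predictions Data frame with `sample_id`, `score`, `call`, and
#'   (optionally) `too_top1`, `too_top2`, `in_between`.
#' @param truth Sample sheet with `sample_id`, `label`, `stage`.
#' @return List with `metrics` (long data frame: metric, group, value, n,
#'   ci_lo, ci_hi) and `auc`.
#' @export
evaluate_predictions <- function(predictions, truth) {
  ix <- match(predictions$sample_id, truth$sample_id)
  if (anyNA(ix)) stop("predictions contain sample ids missing from truth")
  lab <- truth$label[ix]
  stage <- truth$stage[ix]
  is_cancer <- lab != "healthy"

  row_of <- function(metric, group, x, n) {
    ci <- wilson_ci(x, n)
    data.frame(metric = metric, group = group, value = ci[["est"]],
               n = n, ci_lo = ci[["lo"]], ci_hi = ci[["hi"]],
               stringsAsFactors = FALSE)
  }
  rows <- list(
    row_of("sensitivity", "overall", sum(predictions$call & is_cancer),
           sum(is_cancer)),
    row_of("specificity", "overall", sum(!predictions$call & !is_cancer),
           sum(!is_cancer)))
  for (ty in intersect(cancer_types(), unique(lab))) {
    m <- lab == ty
    rows[[length(rows) + 1L]] <-
      row_of("sensitivity", ty, sum(predictions$call & m), sum(m))
  }
  for (st in intersect(c("I", "II", "III", "IV"), unique(stage))) {
    m <- !is.na(stage) & stage == st & is_cancer
    if (any(m)) {
      rows[[length(rows) + 1L]] <-
        row_of("sensitivity", paste0("stage_", st),
               sum(predictions$call & m), sum(m))
    }
  }
  auc <- auc_binary(predictions$score, is_cancer)

  if (!is.null(predictions$too_top1)) {
    cm <- is_cancer
    top1_ok <- predictions$too_top1[cm] == lab[cm]
    top2_ok <- top1_ok | predictions$too_top2[cm] == lab[cm]
    rows[[length(rows) + 1L]] <- row_of("too_top1", "overall",
                                        sum(top1_ok), sum(cm))
    rows[[length(rows) + 1L]] <- row_of("too_top2", "overall",
                                        sum(top2_ok), sum(cm))
    if (!is.null(predictions$in_between)) {
      keep <- cm & !predictions$in_between
      if (any(keep)) {
        t1 <- predictions$too_top1[keep] == lab[keep]
        t2 <- t1 | predictions$too_top2[keep] == lab[keep]
        rows[[length(rows) + 1L]] <- row_of("too_top1", "unambiguous",
                                            sum(t1), sum(keep))
        rows[[length(rows) + 1L]] <- row_of("too_top2", "unambiguous",
                                            sum(t2), sum(keep))
      }
    }
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  list(metrics = metrics, auc = auc)
}
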