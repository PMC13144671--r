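test_that("logit is clipped, antisymmetric, and validates eps", {
  expect_equal(logit(0.5), 0)
  expect_true(is.finite(logit(1)))
  expect_equal(logit(1), log((1 - 1e-6) / 1e-6))
  p <- c(0.1, 0.25, 0.7)
  expect_equal(logit(p), -logit(1 - p))
  expect_error(logit(0.5, eps = 0), "eps")
  expect_error(logit(0.5, eps = 0.6), "eps")
  expect_error(logit(1.5), "\\[0, 1\\]")
})

fit_toy_cse <- function(n_h = 100, n_c = 100, seed = 4, informative = "amf",
                        target_spec = 0.95) {
  set.seed(seed)
  y <- c(rep(0, n_h), rep(1, n_c))
  n <- n_h + n_c
  scores <- sapply(c("amf", "cnv", "fsr", "fsd"), function(f) {
    if (f == informative) plogis(rnorm(n, ifelse(y == 1, 1.5, -1.5), 1))
    else runif(n)
  })
  rownames(scores) <- sprintf("P%03d", 1:n)
  age <- round(runif(n, 50, 80))
  sex <- sample(c("F", "M"), n, TRUE)
  list(scores = scores, age = age, sex = sex, y = y,
       model = fit_cse_csd(scores, age, sex, y, target_spec = target_spec))
}

test_that("threshold calibration bounds the training-healthy exceedance", {
  toy <- fit_toy_cse()
  m <- toy$model
  h_scores <- m$train_scores[m$train_labels == 0]
  expect_lte(mean(h_scores > m$threshold), 0.05)
  # brute force: no smaller observed score satisfies the bound
  cand <- sort(unique(h_scores))
  smaller <- cand[cand < m$threshold]
  expect_true(all(vapply(smaller, function(t) mean(h_scores > t) > 0.05,
                         logical(1))))
  # target_spec = 1 pushes the threshold to at least the healthy maximum
  toy2 <- fit_toy_cse(target_spec = 1)
  m2 <- toy2$model
  expect_gte(m2$threshold, max(m2$train_scores[m2$train_labels == 0]))
  expect_error(fit_cse_csd(toy$scores, toy$age, toy$sex,
                           rep(1, length(toy$y))), "both classes")
})

test_that("predict_csd applies a strict threshold and refuses missing input", {
  toy <- fit_toy_cse()
  m <- toy$model
  pr <- predict_csd(m, toy$scores, toy$age, toy$sex)
  expect_equal(pr$score, unname(m$train_scores), tolerance = 1e-9)
  # a score exactly at the threshold is a negative call
  at <- which.min(abs(pr$score - m$threshold))
  if (pr$score[at] == m$threshold) expect_false(pr$call[at])
  expect_equal(pr$call, pr$score > m$threshold)
  bad <- toy$scores; bad[1, "amf"] <- NA
  expect_error(predict_csd(m, bad, toy$age, toy$sex), "imputation")
  expect_error(predict_csd(m, toy$scores[, 1:3], toy$age, toy$sex),
               "missing feature")
})

test_that("raising a positively weighted feature never lowers the score", {
  toy <- fit_toy_cse()
  m <- toy$model
  pos <- names(which(m$coef[c("amf", "cnv", "fsr", "fsd")] > 0))
  f <- pos[1]
  grid <- seq(0.05, 0.95, by = 0.1)
  base <- toy$scores[1, , drop = FALSE]
  sc <- vapply(grid, function(v) {
    x <- base; x[1, f] <- v
    predict_csd(m, x, toy$age[1], toy$sex[1])$score
  }, numeric(1))
  expect_true(all(diff(sc) >= -1e-12))
})

test_that("a dominant informative feature keeps its edge in the ensemble", {
  toy <- fit_toy_cse(n_h = 150, n_c = 150, seed = 6)
  m <- toy$model
  feat_auc <- auc_binary(toy$scores[, "amf"], toy$y == 1)
  ens_auc <- auc_binary(predict_csd(m, toy$scores, toy$age, toy$sex)$score,
                        toy$y == 1)
  expect_gte(ens_auc, feat_auc - 0.03)
  # and the informative feature carries the largest positive coefficient
  co <- m$coef[c("amf", "cnv", "fsr", "fsd")]
  expect_equal(names(which.max(co)), "amf")
})

test_that("recalibrate_threshold matches the exceedance rule on new scores", {
  toy <- fit_toy_cse()
  set.seed(10)
  cal <- runif(200, 0, 0.6)
  m <- recalibrate_threshold(toy$model, cal)
  expect_lte(mean(cal > m$threshold), 0.05)
  expect_true(m$threshold %in% cal)
})

test_that("predict_too aggregates, ranks, and flags ambiguity per the delta rule", {
  types <- cancer_types()
  p1 <- matrix(0, 2, 8, dimnames = list(c("A", "B"), types))
  p1["A", ] <- c(0.40, 0.36, 0.06, 0.06, 0.04, 0.04, 0.02, 0.02)
  p1["B", ] <- c(0.80, 0.10, 0.02, 0.02, 0.02, 0.02, 0.01, 0.01)
  out <- predict_too(c(only = 1), list(only = p1), delta = 0.07)
  expect_equal(out$too_top1, c(types[1], types[1]))
  expect_equal(out$in_between, c(TRUE, FALSE))   # 0.40 - 0.36 < 0.07
  expect_true(all(out$too_p1 >= out$too_p2))
  # degenerate weights reproduce the single feature's ranking
  p2 <- matrix(runif(8), 1, 8, dimnames = list("C", types))
  p2 <- p2 / sum(p2)
  noise <- matrix(1 / 8, 1, 8, dimnames = list("C", types))
  out2 <- predict_too(c(a = 1, b = 0), list(a = p2, b = noise))
  expect_equal(out2$too_top1, types[order(-p2[1, ])[1]])
  # uniform probabilities tie: top1 - top2 = 0, in between at any delta > 0,
  # ties broken by label order
  out3 <- predict_too(c(a = 1), list(a = noise), delta = 0.01)
  expect_true(out3$in_between)
  expect_equal(out3$too_top1, types[1])
  expect_equal(out3$too_top2, types[2])
  # weighted average: w * p
  out4 <- predict_too(c(a = 0.75, b = 0.25), list(a = p1[1, , drop = FALSE],
                                                  b = noise))
  expect_equal(attr(out4, "aggregated")[1, 1],
               unname(0.75 * p1[1, 1] + 0.25 / 8))
  expect_error(predict_too(c(a = 1), list(b = noise)), "share names")
})

test_that("too_weights_from_accuracy normalizes with a uniform fallback", {
  w <- too_weights_from_accuracy(c(amf = 0.6, cnv = 0.3, fsr = 0.1, fsd = 0))
  expect_equal(sum(w), 1)
  expect_equal(unname(w["amf"]), 0.6)
  w0 <- too_weights_from_accuracy(c(a = 0, b = 0))
  expect_equal(unname(w0), c(0.5, 0.5))
  expect_error(too_weights_from_accuracy(c(a = -1)), "non-negative")
})

test_that("evaluate_predictions reproduces a hand-tallied confusion table", {
  # 3 TP, 1 FN, 18 TN, 2 FP -> sensitivity 75%, specificity 90%
  truth <- data.frame(
    sample_id = sprintf("S%02d", 1:24),
    label = c(rep("lung", 4), rep("healthy", 20)),
    stage = c("I", "II", "III", "IV", rep(NA, 20)))
  pred <- data.frame(
    sample_id = truth$sample_id,
    score = c(0.9, 0.8, 0.7, 0.2, runif(18, 0, 0.3), 0.8, 0.9),
    call = c(TRUE, TRUE, TRUE, FALSE, rep(FALSE, 18), TRUE, TRUE))
  ev <- evaluate_predictions(pred, truth)
  m <- ev$metrics
  expect_equal(m$value[m$metric == "sensitivity" & m$group == "overall"], 0.75)
  expect_equal(m$value[m$metric == "specificity" & m$group == "overall"], 0.90)
  # Wilson CI sanity against the closed form
  ci <- wilson_ci(3, 4)
  expect_equal(m$ci_lo[m$metric == "sensitivity" & m$group == "overall"],
               unname(ci["lo"]))
  # perfect predictions: sensitivity = specificity = top-1 = 100%
  pred2 <- pred
  pred2$call <- truth$label != "healthy"
  pred2$score <- as.numeric(pred2$call)
  pred2$too_top1 <- "lung"; pred2$too_top2 <- "breast"
  pred2$in_between <- FALSE
  ev2 <- evaluate_predictions(pred2, truth)
  m2 <- ev2$metrics
  expect_true(all(m2$value[m2$metric %in% c("sensitivity", "specificity",
                                            "too_top1")] == 1))
  expect_equal(ev2$auc, 1)
  # top-2 accuracy never falls below top-1
  expect_gte(m2$value[m2$metric == "too_top2" & m2$group == "overall"],
             m2$value[m2$metric == "too_top1" & m2$group == "overall"])
  expect_error(evaluate_predictions(transform(pred, sample_id = paste0("X", sample_id)),
                                    truth), "missing from truth")
})
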