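# End-to-end orchestration: QC -> split -> marker building (train only) ->
# featurization -> single-feature training -> ensemble training ->
# prediction -> evaluation, with provenance tracking and a leakage audit.

default_pipeline_params <- function() {
  list(fdr = 0.05, min_cov = 3, min_cpg = 3, pct = 10,
       alpha_pct = 5, beta_pct = 20, k_sigma = 2,
       target_spec = 0.95, delta = 0.07, eps = 1e-6,
       candidates = names(cls_candidates()), folds = 4L,
       split_ratio = 0.6, ensemble_min_age = 50, fallback_k = 50L,
       calibrate = "holdout", cal_frac = 1 / 3,
       seed = 1L)
}

# Fallback AMF feature set when no marker clears the FDR gate (e.g. a null
# cohort): the fallback_k lowest-p regions from the pooled cancer-vs-healthy
# comparison, flagged. Keeps the pipeline total so null cohorts can still be
# scored (and should yield chance-level AUC).
fallback_amf_regions <- function(amf, cancer_ids, healthy_ids, k) {
  wt <- welch_t_regions(amf, cancer_ids, healthy_ids)
  ord <- order(wt$p)
  colnames(amf)[head(ord, k)]
}

fallback_cnv_markers <- function(calls, labels, k) {
  healthy <- labels == "healthy"
  dirsign <- c(gain = 1L, loss = -1L)
  rows <- list()
  for (d in names(dirsign)) {
    hit <- calls == dirsign[[d]]
    hf <- rowMeans(hit[, healthy, drop = FALSE])
    cf <- rowMeans(hit[, !healthy, drop = FALSE])
    rows[[d]] <- data.frame(
      bin_id = rownames(calls), direction = d,
      healthy_freq = hf, max_cancer_freq = cf, score = cf - hf,
      stringsAsFactors = FALSE)
  }
  all_ <- do.call(rbind, rows)
  all_ <- all_[order(-all_$score), ]
  out <- all_[seq_len(min(k, nrow(all_))), names(all_) != "score"]
  rownames(out) <- NULL
  class(out) <- c("mced_cnv_markers", class(out))
  attr(out, "fallback") <- TRUE
  out
}

#' Fit the full multimodal MCED pipeline on a cohort
#'
#' Runs marker discovery, featurization, single-feature classifier
#' training, and ensemble training on the training split of a cohort whose
#' sample sheet already carries `split` assignments. Per-sample features
#' are computed for every sample (feature extraction is sample-local); all
#' fitting — site filtering reference, methylation status, marker
#' selection, CNV reference statistics, scalers, model selection, TOO
#' weights, and threshold calibration — consumes training samples only.
#'
#' @param cohort An `mced_cohort` (simulated or read from disk) whose
#'   sheet has `split` filled for all samples.
#' @param params Named list overriding `default_pipeline_params()`.
#' @return An `mced_fit` object.
#' @export
mced_fit <- function(cohort, params = list()) {
  p <- modifyList(default_pipeline_params(), params)
  sheet <- cohort$sheet
  if (anyNA(sheet$split)) stop("sheet has unassigned split; run stratified_split first")
  plasma_all <- sheet[sheet$material == "plasma", , drop = FALSE]

  # carve a calibration subset out of the ensemble-eligible training
  # healthy samples: no fitting stage touches them, so their ensemble
  # scores follow the same distribution as test scores and the specificity
  # threshold calibrates without in-sample optimism
  tr_all <- plasma_all[plasma_all$split == "train", , drop = FALSE]
  ens_healthy <- tr_all$sample_id[tr_all$label == "healthy" &
                                    tr_all$age >= p$ensemble_min_age]
  cal_ids <- character(0)
  if (identical(p$calibrate, "holdout") && length(ens_healthy) >= 10) {
    cal_ids <- with_seed(p$seed + 11L,
                         sample(ens_healthy,
                                ceiling(length(ens_healthy) * p$cal_frac)))
  }
  sheet_fit <- sheet
  sheet_fit$split[sheet_fit$sample_id %in% cal_ids] <- "calibration"

  plasma <- plasma_all
  tr <- sheet_fit[sheet_fit$material == "plasma" &
                    sheet_fit$split == "train", , drop = FALSE]
  healthy_tr <- tr$sample_id[tr$label == "healthy"]
  cancer_tr <- tr$sample_id[tr$label != "healthy"]
  if (length(healthy_tr) < 2 || length(cancer_tr) < 2) {
    stop("training split must contain healthy and cancer samples")
  }

  ## --- methylome: filter, status, regions, AMF, markers (train only) ---
  filtered <- filter_sites(cohort$cpg, healthy_tr, min_cov = p$min_cov,
                           blacklist = cohort$blacklist)
  status <- classify_cpg_status(filtered, healthy_tr, pct = p$pct)
  regions <- build_regions(status, filtered$sites, min_cpg = p$min_cpg)
  amf <- compute_amf(filtered, regions)
  markers <- build_marker_sets(amf, sheet_fit, fdr = p$fdr)
  marker_regions <- union(markers$csd$region_id, markers$too$region_id)
  amf_fallback <- FALSE
  if (length(marker_regions) < 2) {
    marker_regions <- fallback_amf_regions(amf, cancer_tr, healthy_tr,
                                           p$fallback_k)
    amf_fallback <- TRUE
  }
  amf_feat <- amf[plasma$sample_id, marker_regions, drop = FALSE]

  ## --- copy number: reference, calls, markers, score ---
  cr <- normalize_bins(list(bins = cohort$bins$bins,
                            counts = cohort$bins$counts[, plasma$sample_id,
                                                        drop = FALSE]),
                       healthy_tr)
  calls <- call_alterations(cr, k_sigma = p$k_sigma)
  calls_tr <- calls[, tr$sample_id, drop = FALSE]
  cnv_markers <- select_cnv_markers(calls_tr, tr$label,
                                    alpha_pct = p$alpha_pct,
                                    beta_pct = p$beta_pct)
  cnv_fallback <- FALSE
  if (nrow(cnv_markers) == 0) {
    cnv_markers <- fallback_cnv_markers(calls_tr, tr$label, p$fallback_k)
    cnv_fallback <- TRUE
  }
  cnv_score <- cnv_csd_score(calls, cnv_markers)
  # 0/1 marker-detection features for the CNV TOO classifier
  sgn <- ifelse(cnv_markers$direction == "gain", 1L, -1L)
  cnv_feat <- t(calls[match(cnv_markers$bin_id, rownames(calls)), ,
                      drop = FALSE] == sgn) + 0
  colnames(cnv_feat) <- paste0("cnv:", cnv_markers$bin_id, ":",
                               cnv_markers$direction)

  ## --- fragmentome ---
  fsr <- compute_fsr(cohort$frags)[plasma$sample_id, , drop = FALSE]
  fsd <- compute_fsd(cohort$frags)[plasma$sample_id, , drop = FALSE]

  ## --- single-feature nine-class models (train split only) ---
  train_x <- function(x) x[tr$sample_id, , drop = FALSE]
  bundles <- list(
    amf = select_best_model(train_x(amf_feat), tr$label, p$candidates,
                            folds = p$folds, seed = p$seed,
                            feature_namespace = "amf"),
    cnv = select_best_model(train_x(cnv_feat), tr$label, p$candidates,
                            folds = p$folds, seed = p$seed + 1L,
                            feature_namespace = "cnv"),
    fsr = select_best_model(train_x(fsr), tr$label, p$candidates,
                            folds = p$folds, seed = p$seed + 2L,
                            feature_namespace = "fsr"),
    fsd = select_best_model(train_x(fsd), tr$label, p$candidates,
                            folds = p$folds, seed = p$seed + 3L,
                            feature_namespace = "fsd"))

  ## --- ensemble training on out-of-fold scores ---
  # CSD enters as: AMF/FSR/FSD classifier scores (out-of-fold) and the CNV
  # marker-frequency score. The CNV score is cross-fit as well: markers
  # re-selected per fold on the in-fold samples score the held-out fold,
  # otherwise the winner's-curse on marker healthy frequencies (markers are
  # retained precisely where training healthy calls are rare) deflates
  # training healthy scores relative to test samples and miscalibrates the
  # specificity threshold.
  cnv_oof <- cnv_score[tr$sample_id]
  cnv_folds <- with_seed(p$seed + 7L, stratified_folds(tr$label, p$folds))
  for (f in seq_len(p$folds)) {
    infold <- cnv_folds != f
    sel <- select_cnv_markers(calls_tr[, infold, drop = FALSE],
                              tr$label[infold],
                              alpha_pct = p$alpha_pct, beta_pct = p$beta_pct)
    if (nrow(sel) == 0) {
      sel <- fallback_cnv_markers(calls_tr[, infold, drop = FALSE],
                                  tr$label[infold], p$fallback_k)
    }
    cnv_oof[!infold] <- cnv_csd_score(calls_tr[, !infold, drop = FALSE], sel)
  }
  oof_scores <- cbind(
    amf = feature_csd_score(bundles$amf$oof_proba),
    cnv = cnv_oof,
    fsr = feature_csd_score(bundles$fsr$oof_proba),
    fsd = feature_csd_score(bundles$fsd$oof_proba))
  rownames(oof_scores) <- tr$sample_id

  # TOO weights from out-of-fold top-1 accuracy on training cancer samples
  is_ca <- tr$label != "healthy"
  oof_top1_acc <- vapply(bundles, function(b) {
    cond <- conditional_too_proba(b$oof_proba[is_ca, , drop = FALSE])
    mean(colnames(cond)[max.col(cond, "first")] == tr$label[is_ca])
  }, numeric(1))
  weights <- too_weights_from_accuracy(oof_top1_acc)

  # healthy controls restricted to age >= ensemble_min_age for ensemble
  # training; cancer samples all enter
  ens_keep <- is_ca | tr$age >= p$ensemble_min_age
  cse <- fit_cse_csd(oof_scores[ens_keep, , drop = FALSE],
                     tr$age[ens_keep], tr$sex[ens_keep],
                     is_ca[ens_keep],
                     target_spec = p$target_spec, eps = p$eps,
                     weights = weights, delta = p$delta)

  features <- list(amf = amf_feat, cnv_score = cnv_score,
                   cnv_feat = cnv_feat, fsr = fsr, fsd = fsd)

  # threshold recalibration on the untouched calibration healthy subset,
  # scored through the same path test samples will take
  if (length(cal_ids)) {
    cal_scores <- cbind(
      amf = feature_csd_score(
        predict_proba(bundles$amf, amf_feat[cal_ids, , drop = FALSE])),
      cnv = cnv_score[cal_ids],
      fsr = feature_csd_score(
        predict_proba(bundles$fsr, fsr[cal_ids, , drop = FALSE])),
      fsd = feature_csd_score(
        predict_proba(bundles$fsd, fsd[cal_ids, , drop = FALSE])))
    rownames(cal_scores) <- cal_ids
    meta_cal <- plasma_all[match(cal_ids, plasma_all$sample_id), , drop = FALSE]
    cal_ens <- predict_csd(cse, cal_scores, meta_cal$age, meta_cal$sex)$score
    cse <- recalibrate_threshold(cse, cal_ens, cal_ids)
  }

  provenance <- list(
    site_filter = healthy_tr,
    status_reference = healthy_tr,
    methyl_markers = sheet_fit$sample_id[sheet_fit$split == "train"],
    cnv_reference = healthy_tr,
    cnv_markers = tr$sample_id,
    model_training = tr$sample_id,
    ensemble_training = c(tr$sample_id[ens_keep], cal_ids))

  structure(list(sheet = sheet, params = p,
                 regions = regions, markers = markers,
                 marker_regions = marker_regions,
                 amf_fallback = amf_fallback,
                 cnv_markers = cnv_markers, cnv_fallback = cnv_fallback,
                 copyratio = cr, calls = calls,
                 bundles = bundles, cse = cse, too_weights = weights,
                 oof_top1_acc = oof_top1_acc,
                 features = features,
                 provenance = provenance),
            class = "mced_fit")
}

#' @export
print.mced_fit <- function(x, ...) {
  cat("mced pipeline fit:", length(x$marker_regions), "AMF marker regions,",
      nrow(x$cnv_markers), "CNV markers; threshold",
      signif(x$cse$threshold, 4), "\n")
  invisible(x)
}

#' Predict cancer-signal detection and tissue of origin for samples
#'
#' @param fit An `mced_fit`.
#' @param ids Sample ids to score (default: the test-split plasma
#'   samples).
#' @return Data frame of prediction records: per-feature CSD scores,
#'   ensemble score and call, TOO top-1/top-2 with probabilities, and the
#'   `in_between` ambiguity flag.
#' @export
mced_predict <- function(fit, ids = NULL) {
  sheet <- fit$sheet
  plasma <- sheet[sheet$material == "plasma", , drop = FALSE]
  if (is.null(ids)) ids <- plasma$sample_id[plasma$split == "test"]
  stopifnot(all(ids %in% plasma$sample_id))
  meta <- plasma[match(ids, plasma$sample_id), , drop = FALSE]

  proba <- list(
    amf = predict_proba(fit$bundles$amf, fit$features$amf[ids, , drop = FALSE]),
    cnv = predict_proba(fit$bundles$cnv, fit$features$cnv_feat[ids, , drop = FALSE]),
    fsr = predict_proba(fit$bundles$fsr, fit$features$fsr[ids, , drop = FALSE]),
    fsd = predict_proba(fit$bundles$fsd, fit$features$fsd[ids, , drop = FALSE]))
  scores <- cbind(amf = feature_csd_score(proba$amf),
                  cnv = fit$features$cnv_score[ids],
                  fsr = feature_csd_score(proba$fsr),
                  fsd = feature_csd_score(proba$fsd))
  rownames(scores) <- ids
  csd <- predict_csd(fit$cse, scores, meta$age, meta$sex)
  cond <- lapply(proba, conditional_too_proba)
  too <- predict_too(fit$too_weights, cond, delta = fit$cse$delta)
  out <- data.frame(sample_id = ids,
                    amf_score = scores[, "amf"], cnv_score = scores[, "cnv"],
                    fsr_score = scores[, "fsr"], fsd_score = scores[, "fsd"],
                    score = csd$score, call = csd$call,
                    too_top1 = too$too_top1, too_top2 = too$too_top2,
                    too_p1 = too$too_p1, too_p2 = too$too_p2,
                    in_between = too$in_between,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Audit a fitted pipeline for train/test information leakage
#'
#' Asserts that no test-split sample id appears in the provenance of any
#' fitted artifact (site filter, status reference, marker selection, CNV
#' reference, model training, ensemble training/calibration).
#'
#' @param fit An `mced_fit`.
#' @return `TRUE` invisibly on success; stops with the offending artifact
#'   otherwise.
#' @export
audit_leakage <- function(fit) {
  test_ids <- fit$sheet$sample_id[fit$sheet$split == "test"]
  for (nm in names(fit$provenance)) {
    bad <- intersect(fit$provenance[[nm]], test_ids)
    if (length(bad)) {
      stop("leakage: test sample(s) in artifact '", nm, "': ",
           paste(head(bad, 5), collapse = ","))
    }
  }
  # model bundles record their own training ids
  for (nm in names(fit$bundles)) {
    bad <- intersect(fit$bundles[[nm]]$train_ids, test_ids)
    if (length(bad)) stop("leakage: test sample(s) in model '", nm, "'")
  }
  bad <- intersect(fit$cse$train_ids, test_ids)
  if (length(bad)) stop("leakage: test sample(s) in ensemble")
  invisible(TRUE)
}

# plausible sequencing QC metrics for simulated samples; a small fraction
# fail the mapping-rate gate to exercise it
simulate_qc_metrics <- function(sample_ids, seed, fail_rate = 0.02) {
  with_seed(seed, {
    n <- length(sample_ids)
    fail <- runif(n) < fail_rate
    data.frame(
      sample_id = sample_ids,
      mapping_rate = ifelse(fail, runif(n, 0.70, 0.80), runif(n, 0.85, 0.99)),
      duplication_rate = runif(n, 0.05, 0.20),
      conversion_efficiency = runif(n, 0.992, 0.999),
      stringsAsFactors = FALSE)
  })
}

#' Run the full synthetic pipeline end to end
#'
#' Simulate -> QC gate -> stratified split -> fit (markers, features,
#' models, ensemble) -> predict on the test split -> evaluate, optionally
#' writing all artifacts and a manifest to `out_dir`.
#'
#' @param sim An `mced_sim_config` (or `NULL` for defaults).
#' @param params Pipeline parameter overrides (see
#'   `default_pipeline_params()`).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param seed Overrides both the simulation and pipeline seeds.
#' @return List with `cohort`, `qc`, `fit`, `predictions`, `evaluation`,
#'   and (when written) `paths`.
#' @export
run_pipeline <- function(sim = NULL, params = list(), out_dir = NULL,
                         seed = NULL) {
  sim <- sim %||% sim_config()
  if (!is.null(seed)) {
    sim$seed <- as.integer(seed)
    params$seed <- as.integer(seed)
  }
  p <- modifyList(default_pipeline_params(), params)

  cohort <- simulate_cohort(sim)
  qc <- qc_gate(simulate_qc_metrics(cohort$sheet$sample_id,
                                    seed = sim$seed + 1000L))
  keep <- qc$sample_id[qc$pass]
  cohort$sheet <- cohort$sheet[cohort$sheet$sample_id %in% keep, , drop = FALSE]
  cohort$sheet <- stratified_split(cohort$sheet, ratio = p$split_ratio,
                                   seed = p$seed)
  fit <- mced_fit(cohort, p)
  audit_leakage(fit)
  predictions <- mced_predict(fit)
  evaluation <- evaluate_predictions(predictions, fit$sheet)

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "inputs"))
    data.table::fwrite(qc, file.path(out_dir, "qc_metrics.tsv"), sep = "\t")
    data.table::fwrite(fit$sheet, file.path(out_dir, "sample_sheet.tsv"),
                       sep = "\t")
    mk <- rbind(
      cbind(fit$markers$csd[c("region_id", "comparison", "target",
                              "direction", "p_value", "q_value")],
            role = "csd"),
      cbind(fit$markers$too[c("region_id", "comparison", "target",
                              "direction", "p_value", "q_value")],
            role = "too"))
    data.table::fwrite(mk, file.path(out_dir, "methyl_markers.tsv"),
                       sep = "\t")
    data.table::fwrite(
      fit$cnv_markers[c("bin_id", "direction", "healthy_freq",
                        "max_cancer_freq")],
      file.path(out_dir, "cnv_markers.tsv"), sep = "\t")
    data.table::fwrite(predictions, file.path(out_dir, "predictions.tsv"),
                       sep = "\t")
    data.table::fwrite(evaluation$metrics, file.path(out_dir, "metrics.tsv"),
                       sep = "\t")
    jsonlite::write_json(list(auc = evaluation$auc),
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    write_cse_json(fit$cse, file.path(out_dir, "cse_model.json"))
    inputs <- list.files(file.path(out_dir, "inputs"), full.names = TRUE)
    manifest <- list(
      seed = sim$seed,
      package_version = as.character(utils::packageVersion("mced")),
      r_version = R.version.string,
      input_md5 = as.list(tools::md5sum(inputs)),
      stages = c("simulate", "qc", "split", "markers", "featurize",
                 "train", "ensemble", "predict", "evaluate"),
      outputs = list.files(out_dir, recursive = TRUE))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    paths <- out_dir
  }
  list(cohort = cohort, qc = qc, fit = fit, predictions = predictions,
       evaluation = evaluation, paths = paths)
}
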