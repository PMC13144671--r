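# Bin-level copy-ratio computation, 2-sigma alteration calling, CNV marker
# selection under the healthy-exclusion and alpha/beta prevalence rules, and
# the marker-frequency CNV CSD score.

#' Depth-normalize bin counts against a healthy median reference
#'
#' Each sample's counts are scaled to equal total depth, divided by the
#' per-bin median of the (training) healthy reference samples, and
#' log2-transformed. Bins with zero healthy median are dropped and
#' recorded. Per-bin mean and standard deviation of the healthy reference
#' log2 ratios are retained for alteration calling.
#'
#' @param counts List with `bins` (data frame, `bin_id` first) and `counts`
#'   (bins x samples non-negative matrix), as produced by
#'   [simulate_cohort()], or a bare matrix with rownames as bin ids.
#' @param healthy_ids Healthy reference sample ids (training split only, at
#'   least 3).
#' @return An `mced_copyratio` list: `bins`, `log2` (bins x samples),
#'   `healthy_mean`, `healthy_sd`, `reference_ids`, `dropped_bins`.
#' @export
normalize_bins <- function(counts, healthy_ids) {
  if (is.matrix(counts)) {
    counts <- list(bins = data.frame(bin_id = rownames(counts) %||%
                                       sprintf("bin%04d", seq_len(nrow(counts))),
                                     stringsAsFactors = FALSE),
                   counts = counts)
  }
  m <- counts$counts
  if (any(m < 0)) stop("bin counts must be non-negative")
  if (length(healthy_ids) < 3) stop("need at least 3 healthy reference samples")
  if (!all(healthy_ids %in% colnames(m))) {
    stop("healthy_ids not all present in bin count table")
  }
  tot <- colSums(m)
  if (any(tot == 0)) {
    stop("all-zero sample(s): ", paste(colnames(m)[tot == 0], collapse = ","))
  }
  depth_norm <- sweep(m, 2, tot / mean(tot), "/")
  ref_med <- apply(depth_norm[, healthy_ids, drop = FALSE], 1, median)
  keep <- ref_med > 0
  dropped <- counts$bins$bin_id[!keep]
  ratio <- depth_norm[keep, , drop = FALSE] / ref_med[keep]
  # half-count pseudo floor keeps log2 finite at isolated zero bins
  ratio[ratio == 0] <- 0.5 / mean(tot)
  lr <- log2(ratio)
  rownames(lr) <- counts$bins$bin_id[keep]
  h <- lr[, healthy_ids, drop = FALSE]
  n_ref <- ncol(h)
  raw_var <- apply(h, 1, var)
  # moderated per-bin variance: with few reference samples the raw per-bin
  # sigma is noisy, and downstream marker selection couples to that noise
  # (bins with underestimated sigma over-call in every cohort); shrink
  # toward the median bin variance with prior df equal to the reference n
  d0 <- n_ref
  s0_sq <- median(raw_var)
  mod_var <- (d0 * s0_sq + (n_ref - 1) * raw_var) / (d0 + n_ref - 1)
  structure(list(bins = counts$bins[keep, , drop = FALSE],
                 log2 = lr,
                 healthy_mean = rowMeans(h),
                 healthy_sd = sqrt(mod_var),
                 healthy_sd_raw = sqrt(raw_var),
                 prior_df = d0, prior_var = s0_sq,
                 reference_ids = healthy_ids,
                 dropped_bins = dropped),
            class = "mced_copyratio")
}

#' Call copy-number alterations at k sigma
#'
#' A gain is called when a bin's log2 ratio strictly exceeds the healthy
#' mean + `k_sigma` * healthy sd; a loss when it falls strictly below the
#' mean - `k_sigma` * sd. Zero-sd bins call on strict inequality against
#' the mean alone. Reference panel members are scored against leave-one-out
#' statistics (their own value removed from the mean and variance), so
#' their call rates are exchangeable with samples outside the panel rather
#' than optimistically deflated by self-normalization.
#'
#' @param ratios An `mced_copyratio` object.
#' @param k_sigma Sigma multiplier (default 2).
#' @return Integer matrix bins x samples with values -1 (loss), 0, +1
#'   (gain).
#' @export
call_alterations <- function(ratios, k_sigma = 2) {
  stopifnot(inherits(ratios, "mced_copyratio"))
  up <- ratios$healthy_mean + k_sigma * ratios$healthy_sd
  dn <- ratios$healthy_mean - k_sigma * ratios$healthy_sd
  calls <- (ratios$log2 > up) - (ratios$log2 < dn)

  ref <- intersect(ratios$reference_ids, colnames(ratios$log2))
  n <- length(ref)
  if (n >= 4) {
    x <- ratios$log2[, ref, drop = FALSE]
    mu <- ratios$healthy_mean
    ss <- (n - 1) * ratios$healthy_sd_raw^2
    mu_loo <- (n * mu - x) / (n - 1)
    ss_loo <- pmax(ss - (x - mu)^2 * n / (n - 1), 0)
    raw_var_loo <- ss_loo / (n - 2)
    mod_var_loo <- (ratios$prior_df * ratios$prior_var +
                      (n - 2) * raw_var_loo) / (ratios$prior_df + n - 2)
    sd_loo <- sqrt(mod_var_loo)
    calls[, ref] <- (x > mu_loo + k_sigma * sd_loo) -
      (x < mu_loo - k_sigma * sd_loo)
  }
  storage.mode(calls) <- "integer"
  calls
}

#' Select CNV markers under the healthy-exclusion and alpha/beta rules
#'
#' Bins altered (either direction) in more than `alpha_pct`% of healthy
#' samples are excluded globally (this guards against recurrent
#' nonmalignant alterations such as clonal hematopoiesis). Among the
#' remaining bins, a (bin, direction) pair is retained as a marker when its
#' healthy frequency is strictly below `alpha_pct`% and its frequency in at
#' least one cancer type strictly exceeds `beta_pct`%. Setting
#' `exclude_healthy = FALSE` disables both healthy-frequency conditions
#' (the pre-exclusion comparator).
#'
#' @param calls Integer call matrix from [call_alterations()] (training
#'   split only).
#' @param labels Sample labels aligned with `colnames(calls)` (`"healthy"`
#'   or a cancer type).
#' @param alpha_pct Healthy prevalence bound in percent (default 5).
#' @param beta_pct Cancer prevalence bound in percent (default 20).
#' @param directions Marker directions considered (default gain and loss).
#' @param exclude_healthy Apply the healthy-frequency conditions (default
#'   `TRUE`).
#' @return An `mced_cnv_markers` data frame (`bin_id`, `direction`,
#'   `healthy_freq`, `max_cancer_freq`, one `freq_<type>` column per
#'   cancer type) with the configuration in attributes.
#' @export
select_cnv_markers <- function(calls, labels, alpha_pct = 5, beta_pct = 20,
                               directions = c("gain", "loss"),
                               exclude_healthy = TRUE) {
  if (alpha_pct <= 0 || alpha_pct >= 100 || beta_pct <= 0 || beta_pct > 100) {
    stop("alpha_pct must lie in (0, 100) and beta_pct in (0, 100]")
  }
  stopifnot(length(labels) == ncol(calls))
  healthy <- labels == "healthy"
  if (!any(healthy)) stop("no healthy samples in calls")
  types <- intersect(cancer_types(), unique(labels))
  dirsign <- c(gain = 1L, loss = -1L)[directions]

  any_alt_h <- rowMeans(calls[, healthy, drop = FALSE] != 0L)
  excluded <- exclude_healthy & (any_alt_h > alpha_pct / 100)

  rows <- list()
  for (d in names(dirsign)) {
    hit <- calls == dirsign[[d]]
    hf <- rowMeans(hit[, healthy, drop = FALSE])
    cf <- vapply(types, function(ty) {
      rowMeans(hit[, labels == ty, drop = FALSE])
    }, numeric(nrow(calls)))
    if (is.null(dim(cf))) cf <- matrix(cf, nrow = nrow(calls))
    colnames(cf) <- types
    maxcf <- apply(cf, 1, max)
    ok <- !excluded & maxcf > beta_pct / 100
    if (exclude_healthy) ok <- ok & hf < alpha_pct / 100
    if (any(ok)) {
      df <- data.frame(bin_id = rownames(calls)[ok], direction = d,
                       healthy_freq = hf[ok], max_cancer_freq = maxcf[ok],
                       stringsAsFactors = FALSE)
      cfr <- as.data.frame(cf[ok, , drop = FALSE])
      names(cfr) <- paste0("freq_", types)
      rows[[d]] <- cbind(df, cfr)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(bin_id = character(), direction = character(),
               healthy_freq = numeric(), max_cancer_freq = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  # post-exclusion invariant: no retained marker bin is altered in more
  # than alpha% of healthy controls
  if (exclude_healthy && nrow(out) > 0 &&
      any(any_alt_h[match(out$bin_id, rownames(calls))] > alpha_pct / 100)) {
    stop("internal error: excluded bin leaked into the marker set")
  }
  attr(out, "alpha_pct") <- alpha_pct
  attr(out, "beta_pct") <- beta_pct
  attr(out, "exclude_healthy") <- exclude_healthy
  attr(out, "excluded_bins") <- rownames(calls)[excluded]
  class(out) <- c("mced_cnv_markers", class(out))
  out
}

#' Marker-frequency CNV cancer-signal score
#'
#' The fraction of selected (bin, direction) markers detected in each
#' sample's alteration calls; lies in \[0, 1\].
#'
#' @param calls Integer call matrix (bins x samples) from
#'   [call_alterations()].
#' @param markers An `mced_cnv_markers` data frame (non-empty).
#' @return Named numeric vector of per-sample scores.
#' @export
cnv_csd_score <- function(calls, markers) {
  if (nrow(markers) == 0) stop("empty CNV marker set")
  ix <- match(markers$bin_id, rownames(calls))
  if (anyNA(ix)) stop("marker bins missing from call matrix")
  sgn <- ifelse(markers$direction == "gain", 1L, -1L)
  hit <- calls[ix, , drop = FALSE] == sgn
  colSums(hit) / nrow(markers)
}
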