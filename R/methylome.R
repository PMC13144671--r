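# CpG filtering, methylation-status classification, region construction,
# AMF quantification, and DMR/marker selection with concordance refinement.

#' Construct a CpG count table
#'
#' Houses per-sample cytosine (`C`) and thymine (`T`) counts at CpG sites;
#' the per-site methylation level is beta = C / (C + T) wherever coverage is
#' positive.
#'
#' @param sites Data frame with columns `chrom` and `pos0` (0-based).
#' @param C,T Integer matrices, sites x samples, with identical column names.
#' @return An object of class `mced_cpg`.
#' @export
new_cpg_counts <- function(sites, C, T) {
  stopifnot(is.data.frame(sites), all(c("chrom", "pos0") %in% names(sites)),
            nrow(C) == nrow(sites), all(dim(C) == dim(T)),
            identical(colnames(C), colnames(T)))
  if (any(C < 0) || any(T < 0)) stop("counts must be non-negative")
  if (anyDuplicated(sites[c("chrom", "pos0")])) {
    stop("sites must be unique by (chrom, pos0)")
  }
  structure(list(sites = sites, C = C, T = T), class = "mced_cpg")
}

#' @export
print.mced_cpg <- function(x, ...) {
  cat("CpG count table:", nrow(x$sites), "sites x", ncol(x$C), "samples\n")
  invisible(x)
}

#' Per-site, per-sample methylation levels
#'
#' @param table An `mced_cpg` table.
#' @return Sites x samples matrix of C / (C + T), `NA` at zero coverage.
#' @export
beta_values <- function(table) {
  cov <- table$C + table$T
  b <- table$C / cov
  b[cov == 0] <- NA_real_
  b
}

site_in_intervals <- function(chrom, pos0, intervals) {
  # intervals: 0-based half-open (chrom, start, end)
  hit <- logical(length(pos0))
  if (is.null(intervals) || nrow(intervals) == 0) return(hit)
  if (any(intervals$start >= intervals$end)) {
    stop("blacklist format error: interval with start >= end")
  }
  for (k in seq_len(nrow(intervals))) {
    hit <- hit | (chrom == intervals$chrom[k] &
                    pos0 >= intervals$start[k] & pos0 < intervals$end[k])
  }
  hit
}

#' Filter CpG sites on healthy coverage, blacklist, and sex chromosomes
#'
#' Sites are retained when their healthy-sample coverage reaches `min_cov`
#' (by default the mean across healthy samples; `aggregate = "all"` requires
#' every healthy sample to reach it), they fall outside the blacklist
#' intervals, and they are not on a sex chromosome.
#'
#' @param table An `mced_cpg` table.
#' @param healthy_ids Healthy sample ids (columns of `table`).
#' @param min_cov Minimum healthy coverage (default 3).
#' @param blacklist Data frame (`chrom`, `start`, `end`), 0-based half-open,
#'   or `NULL`.
#' @param sex_chroms Chromosome labels to drop (default chrX/chrY).
#' @param aggregate `"mean"` (default) or `"all"`.
#' @return Filtered `mced_cpg` table; the index of retained sites relative
#'   to the input is stored in `attr(, "kept")`.
#' @export
filter_sites <- function(table, healthy_ids, min_cov = 3,
                         blacklist = NULL,
                         sex_chroms = c("chrX", "chrY", "X", "Y"),
                         aggregate = c("mean", "all")) {
  aggregate <- match.arg(aggregate)
  if (length(healthy_ids) == 0) stop("healthy_ids must be non-empty")
  if (!all(healthy_ids %in% colnames(table$C))) {
    stop("healthy_ids not all present in table")
  }
  cov_h <- table$C[, healthy_ids, drop = FALSE] +
    table$T[, healthy_ids, drop = FALSE]
  ok_cov <- if (aggregate == "mean") {
    rowMeans(cov_h) >= min_cov
  } else {
    apply(cov_h >= min_cov, 1, all)
  }
  ok_bl <- !site_in_intervals(table$sites$chrom, table$sites$pos0, blacklist)
  ok_sex <- !(table$sites$chrom %in% sex_chroms)
  keep <- which(ok_cov & ok_bl & ok_sex)
  out <- new_cpg_counts(table$sites[keep, , drop = FALSE],
                        table$C[keep, , drop = FALSE],
                        table$T[keep, , drop = FALSE])
  attr(out, "kept") <- keep
  out
}

#' Classify CpG methylation status from healthy samples
#'
#' A site is `unmethylated` when its mean healthy beta lies strictly below
#' the `pct` percentile of site means AND below `beta_cut`; `methylated`
#' when strictly above the `100 - pct` percentile AND above `beta_cut`;
#' otherwise `neutral`. Strict inequalities mean that in a degenerate table
#' where all site means tie, every site is neutral.
#'
#' @param table An `mced_cpg` table.
#' @param healthy_ids Healthy sample ids.
#' @param pct Percentile defining the extremes (default 10, must be in
#'   (0, 50)).
#' @param beta_cut Absolute beta cut (default 0.5).
#' @return Character vector (`"methylated"`, `"unmethylated"`, `"neutral"`)
#'   with the per-site mean healthy beta in `attr(, "mean_beta")`.
#' @export
classify_cpg_status <- function(table, healthy_ids, pct = 10,
                                beta_cut = 0.5) {
  if (pct <= 0 || pct >= 50) stop("pct must lie in (0, 50)")
  if (length(healthy_ids) < 1) stop("need at least one healthy sample")
  b <- beta_values(table)[, healthy_ids, drop = FALSE]
  mb <- rowMeans(b, na.rm = TRUE)
  mb[is.nan(mb)] <- NA_real_
  q_lo <- quantile(mb, pct / 100, na.rm = TRUE, names = FALSE)
  q_hi <- quantile(mb, 1 - pct / 100, na.rm = TRUE, names = FALSE)
  status <- rep("neutral", nrow(table$sites))
  status[!is.na(mb) & mb < q_lo & mb < beta_cut] <- "unmethylated"
  status[!is.na(mb) & mb > q_hi & mb > beta_cut] <- "methylated"
  attr(status, "mean_beta") <- mb
  status
}

#' Group contiguous same-status CpG sites into regions
#'
#' Maximal runs of identical non-neutral status become regions; runs are
#' split at chromosome boundaries and runs shorter than `min_cpg` are
#' dropped. Output regions are disjoint and sorted in input site order.
#'
#' @param status Status vector aligned with `sites`.
#' @param sites Data frame (`chrom`, `pos0`) sorted by chromosome then
#'   position.
#' @param min_cpg Minimum sites per region (default 3).
#' @return Data frame with `region_id`, `chrom`, `start`, `end` (0-based
#'   half-open over member site positions), `status`, `n_cpg`, and a list
#'   column `site_idx` of member site indices.
#' @export
build_regions <- function(status, sites, min_cpg = 3) {
  stopifnot(length(status) == nrow(sites))
  by_chrom <- split(sites$pos0, sites$chrom)
  if (any(vapply(by_chrom, is.unsorted, logical(1)))) {
    stop("sites must be sorted by (chrom, pos0)")
  }
  key <- paste(sites$chrom, status)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_status <- status[starts]
  keep <- run_status != "neutral" & r$lengths >= min_cpg
  if (!any(keep)) {
    out <- data.frame(region_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      status = character(), n_cpg = integer(),
                      stringsAsFactors = FALSE)
    out$site_idx <- list()
    return(out)
  }
  starts <- starts[keep]; ends <- ends[keep]
  out <- data.frame(
    region_id = sprintf("R%05d", seq_along(starts)),
    chrom = sites$chrom[starts],
    start = sites$pos0[starts],
    end = sites$pos0[ends] + 1L,
    status = run_status[keep],
    n_cpg = ends - starts + 1L,
    stringsAsFactors = FALSE)
  out$site_idx <- Map(`:`, starts, ends)
  out
}

#' Average methylation fraction per sample and region
#'
#' For region i with member CpG sites R_i, AMF_i is the unweighted mean of
#' per-site methylated fractions C_j / (C_j + T_j) over the member sites
#' covered in that sample; a region with no covered member site is `NA`.
#'
#' @param table An `mced_cpg` table.
#' @param regions Region data frame from [build_regions()].
#' @return Samples x regions numeric matrix (rownames = sample ids,
#'   colnames = region ids), values in \[0, 1\] or `NA`.
#' @export
compute_amf <- function(table, regions) {
  if (nrow(regions) == 0) {
    return(matrix(numeric(), nrow = ncol(table$C), ncol = 0,
                  dimnames = list(colnames(table$C), NULL)))
  }
  if (any(vapply(regions$site_idx, length, integer(1)) == 0)) {
    stop("region with zero member sites")
  }
  b <- beta_values(table)
  idx <- unlist(regions$site_idx, use.names = FALSE)
  if (any(idx < 1 | idx > nrow(b))) stop("region references invalid site index")
  grp <- rep(seq_len(nrow(regions)),
             vapply(regions$site_idx, length, integer(1)))
  bsub <- b[idx, , drop = FALSE]
  covered <- !is.na(bsub)
  bsub[!covered] <- 0
  sums <- rowsum(bsub, grp)
  ns <- rowsum(covered + 0, grp)
  amf <- sums / ns
  amf[ns == 0] <- NA_real_
  amf <- t(amf)
  colnames(amf) <- regions$region_id
  rownames(amf) <- colnames(table$C)
  amf
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return q-values (adjusted p-values), capped at 1, preserving input
#'   order; `NA` inputs stay `NA` and do not count toward the family size.
#' @export
bh_fdr <- function(p_values) {
  p <- p_values
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  m <- sum(ok)
  q <- rep(NA_real_, length(p))
  if (m == 0) return(q)
  pv <- p[ok]
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  # step-up: running minimum of p * m / rank from the largest p downwards
  q[ok] <- pmin(1, cummin(pv[o] * m / (m - seq_along(pv) + 1L)))[ro]
  q
}

# Vectorized Welch two-sample t-test across matrix columns (regions).
# Returns per-region p-values and group means; regions with fewer than
# min_n defined values in either group get NA (skipped, recorded upstream).
welch_t_regions <- function(amf, ids_a, ids_b, min_n = 2L) {
  xa <- amf[ids_a, , drop = FALSE]
  xb <- amf[ids_b, , drop = FALSE]
  na_ <- colSums(!is.na(xa)); nb_ <- colSums(!is.na(xb))
  ma <- colMeans(xa, na.rm = TRUE); mb <- colMeans(xb, na.rm = TRUE)
  va <- apply(xa, 2, var, na.rm = TRUE)
  vb <- apply(xb, 2, var, na.rm = TRUE)
  se2 <- va / na_ + vb / nb_
  t_ <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na_)^2 / (na_ - 1) + (vb / nb_)^2 / (nb_ - 1))
  p <- 2 * pt(abs(t_), df, lower.tail = FALSE)
  # degenerate variance: identical groups -> p = 1, separated constants -> 0
  zero_se <- !is.na(se2) & se2 == 0
  p[zero_se] <- ifelse(ma[zero_se] == mb[zero_se], 1, 0)
  p[na_ < min_n | nb_ < min_n] <- NA_real_
  list(p = p, mean_a = ma, mean_b = mb, n_a = na_, n_b = nb_)
}

#' Select differentially methylated regions between two groups
#'
#' Per-region Welch two-sample t-tests on AMF values, Benjamini-Hochberg
#' adjustment across the tested regions, and retention at `q < fdr`.
#' Direction is `hyper` when group A's mean exceeds group B's.
#'
#' @param amf Samples x regions AMF matrix.
#' @param group_a,group_b Disjoint sample-id vectors (rownames of `amf`).
#' @param fdr FDR threshold (default 0.05).
#' @param comparison Label recorded in the output (one of the assay's
#'   comparison settings).
#' @param target Target cancer type (or `"csd"`/`"too"` role) recorded in
#'   the output.
#' @return `mced_markers` data frame (`region_id`, `comparison`, `target`,
#'   `direction`, `p_value`, `q_value`); regions skipped for insufficient
#'   defined values are listed in `attr(, "skipped")` and the number tested
#'   in `attr(, "n_tested")`.
#' @export
select_dmrs <- function(amf, group_a, group_b, fdr = 0.05,
                        comparison = "cfdna-cancer-vs-healthy",
                        target = NA_character_) {
  if (length(intersect(group_a, group_b)) > 0) stop("groups must be disjoint")
  if (!all(c(group_a, group_b) %in% rownames(amf))) {
    stop("group sample ids missing from AMF matrix")
  }
  wt <- welch_t_regions(amf, group_a, group_b)
  tested <- !is.na(wt$p)
  q <- rep(NA_real_, length(wt$p))
  q[tested] <- bh_fdr(wt$p[tested])
  sel <- which(tested & q < fdr)
  out <- data.frame(
    region_id = colnames(amf)[sel],
    comparison = rep(comparison, length(sel)),
    target = rep(target, length(sel)),
    direction = ifelse(wt$mean_a[sel] > wt$mean_b[sel], "hyper", "hypo"),
    p_value = wt$p[sel],
    q_value = q[sel],
    stringsAsFactors = FALSE)
  attr(out, "n_tested") <- sum(tested)
  attr(out, "skipped") <- colnames(amf)[!tested]
  class(out) <- c("mced_markers", class(out))
  out
}

#' Concordance filter between tissue- and cfDNA-derived markers
#'
#' Retains cfDNA markers whose region appears in the tissue-derived set for
#' the same target with the same methylation-change direction.
#'
#' @param tissue_markers,cfdna_markers Marker data frames from
#'   [select_dmrs()].
#' @return Filtered cfDNA marker data frame (possibly empty), with the
#'   tissue comparison label recorded in `tissue_comparison`.
#' @export
concordance_filter <- function(tissue_markers, cfdna_markers) {
  key_t <- paste(tissue_markers$region_id, tissue_markers$target,
                 tissue_markers$direction)
  key_c <- paste(cfdna_markers$region_id, cfdna_markers$target,
                 cfdna_markers$direction)
  out <- cfdna_markers[key_c %in% key_t, , drop = FALSE]
  out$tissue_comparison <- if (nrow(out)) tissue_markers$comparison[1] else character(0)
  rownames(out) <- NULL
  out
}

#' Build CSD and TOO methylation marker sets from a training cohort
#'
#' For each cancer type: cfDNA markers come from comparing that type's
#' plasma samples with healthy plasma; where matched tumor/adjacent tissue
#' exists, tissue markers (tumor vs adjacent) gate the cfDNA markers through
#' the concordance filter; types without tissue use their cfDNA markers
#' directly (flagged `concordant = NA`). TOO markers come from the
#' one-vs-other-cancers comparison. The CSD set is the union over types of
#' the (concordance-refined) cfDNA-vs-healthy markers.
#'
#' @param amf Samples x regions AMF matrix over plasma + tissue samples.
#' @param sheet Sample sheet (needs `sample_id`, `label`, `split`,
#'   `material`).
#' @param fdr FDR threshold (default 0.05).
#' @return List with `csd` and `too` marker data frames and `per_type`
#'   detail.
#' @export
build_marker_sets <- function(amf, sheet, fdr = 0.05) {
  tr <- sheet[sheet$split == "train", , drop = FALSE]
  plasma <- tr[tr$material == "plasma", , drop = FALSE]
  healthy <- plasma$sample_id[plasma$label == "healthy"]
  csd_list <- list(); too_list <- list(); detail <- list()
  for (ty in cancer_types()) {
    ids_ty <- plasma$sample_id[plasma$label == ty]
    if (length(ids_ty) < 2) next
    cf <- select_dmrs(amf, ids_ty, healthy, fdr = fdr,
                      comparison = "cfdna-cancer-vs-healthy", target = ty)
    tum <- tr$sample_id[tr$material == "tumor" & tr$label == ty]
    adj <- tr$sample_id[tr$material == "adjacent" & tr$label == ty]
    if (length(tum) >= 2 && length(adj) >= 2) {
      tis <- select_dmrs(amf, tum, adj, fdr = fdr,
                         comparison = "tumor-vs-adjacent", target = ty)
      kept <- concordance_filter(tis, cf)
      kept$concordant <- rep(TRUE, nrow(kept))
    } else {
      tis <- NULL
      kept <- cf
      kept$tissue_comparison <- rep(NA_character_, nrow(kept))
      kept$concordant <- rep(NA, nrow(kept))
    }
    others <- plasma$sample_id[!plasma$label %in% c(ty, "healthy")]
    ovr <- select_dmrs(amf, ids_ty, others, fdr = fdr,
                       comparison = "cancer-vs-other-cancers", target = ty)
    csd_list[[ty]] <- kept
    too_list[[ty]] <- ovr
    detail[[ty]] <- list(cfdna = cf, tissue = tis, final = kept, too = ovr)
  }
  list(csd = do.call(rbind, csd_list),
       too = do.call(rbind, too_list),
       per_type = detail)
}
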