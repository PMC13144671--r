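# File formats (TSV/BED/JSON/YAML), the sequencing-QC gate, and the
# stratified train/test split. Coordinates are 0-based half-open
# everywhere; BED files are native.

#' Sequencing quality-control gate
#'
#' A sample passes when its mapping rate strictly exceeds 0.80, its
#' duplication rate is strictly below 0.25, and its methylation conversion
#' efficiency strictly exceeds 0.99 (all three inequalities strict, so a
#' sample exactly at a threshold fails).
#'
#' @param metrics Data frame with `sample_id`, `mapping_rate`,
#'   `duplication_rate`, `conversion_efficiency`, all in \[0, 1\].
#' @param mapping_min,duplication_max,conversion_min Gate thresholds.
#' @return The metrics data frame with logical `pass` and character
#'   `fail_reason` columns.
#' @export
qc_gate <- function(metrics, mapping_min = 0.80, duplication_max = 0.25,
                    conversion_min = 0.99) {
  need <- c("sample_id", "mapping_rate", "duplication_rate",
            "conversion_efficiency")
  miss <- setdiff(need, names(metrics))
  if (length(miss)) stop("missing QC column(s): ", paste(miss, collapse = ","))
  for (f in need[-1]) {
    bad <- which(is.na(metrics[[f]]))
    if (length(bad)) {
      stop("missing QC metric ", f, " for sample ",
           metrics$sample_id[bad[1]])
    }
    if (any(metrics[[f]] < 0 | metrics[[f]] > 1)) {
      stop("QC metric ", f, " outside [0, 1]")
    }
  }
  reasons <- character(nrow(metrics))
  fail_map <- metrics$mapping_rate <= mapping_min
  fail_dup <- metrics$duplication_rate >= duplication_max
  fail_conv <- metrics$conversion_efficiency <= conversion_min
  reasons <- vapply(seq_len(nrow(metrics)), function(i) {
    paste(c(if (fail_map[i]) "mapping_rate",
            if (fail_dup[i]) "duplication_rate",
            if (fail_conv[i]) "conversion_efficiency"), collapse = ";")
  }, character(1))
  metrics$pass <- !(fail_map | fail_dup | fail_conv)
  metrics$fail_reason <- reasons
  metrics
}

#' Stratified train/test split
#'
#' Assigns each (label, stage, sex) stratum to train/test at the given
#' ratio. The train count per stratum is `round(ratio * n)`; strata of
#' size 1 go to train. Deterministic given the seed.
#'
#' @param sheet Sample sheet data frame.
#' @param ratio Train fraction in (0, 1), default 0.6.
#' @param strata Stratification columns (default label, stage, sex).
#' @param seed Integer seed.
#' @return The sheet with its `split` column filled (`"train"`/`"test"`);
#'   rows whose split was already set (e.g. tissue samples) are left as is.
#' @export
stratified_split <- function(sheet, ratio = 0.6,
                             strata = c("label", "stage", "sex"),
                             seed = 1L) {
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie in (0, 1)")
  stopifnot(all(strata %in% names(sheet)))
  todo <- which(is.na(sheet$split))
  key <- do.call(paste, c(lapply(strata, function(s) {
    v <- sheet[[s]][todo]
    ifelse(is.na(v), "<NA>", as.character(v))
  }), sep = "|"))
  split <- character(length(todo))
  with_seed(seed, {
    for (k in unique(key)) {
      ix <- which(key == k)
      n <- length(ix)
      if (n == 1L) { split[ix] <- "train"; next }
      n_train <- max(1L, round(ratio * n))
      tr <- sample(ix, n_train)
      split[tr] <- "train"
      split[setdiff(ix, tr)] <- "test"
    }
  })
  sheet$split[todo] <- split
  sheet
}

# --- TSV / BED / JSON round trips -------------------------------------------

#' Write a simulated cohort to a directory of plain-text files
#'
#' Emits `sample_sheet.tsv`, `cpg_counts.tsv` (wide: chrom, pos0, then
#' `<id>.C` / `<id>.T` per sample), `bin_counts.tsv`, `fragment_hist.tsv`
#' (long), `blacklist.bed`, and `ground_truth.json`.
#'
#' @param cohort An `mced_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(cohort$sheet, file.path(dir, "sample_sheet.tsv"),
                     sep = "\t")
  ids <- colnames(cohort$cpg$C)
  wide <- data.table::data.table(chrom = cohort$cpg$sites$chrom,
                                 pos0 = cohort$cpg$sites$pos0)
  for (id in ids) {
    wide[[paste0(id, ".C")]] <- cohort$cpg$C[, id]
    wide[[paste0(id, ".T")]] <- cohort$cpg$T[, id]
  }
  data.table::fwrite(wide, file.path(dir, "cpg_counts.tsv"), sep = "\t")
  bc <- data.table::data.table(cohort$bins$bins,
                               as.data.frame(cohort$bins$counts))
  data.table::fwrite(bc, file.path(dir, "bin_counts.tsv"), sep = "\t")
  data.table::fwrite(cohort$frags, file.path(dir, "fragment_hist.tsv"),
                     sep = "\t")
  data.table::fwrite(cohort$blacklist, file.path(dir, "blacklist.bed"),
                     sep = "\t", col.names = FALSE)
  jsonlite::write_json(cohort$truth[c("cnv_segments", "chip_bins",
                                      "chip_carriers", "low_cov_sites")],
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory path.
#' @return An `mced_cohort`-like list (without the full ground truth).
#' @export
read_cohort <- function(dir) {
  sheet <- as.data.frame(data.table::fread(
    file.path(dir, "sample_sheet.tsv"),
    colClasses = list(character = c("stage", "split"))))
  sheet$stage[sheet$stage == ""] <- NA_character_
  sheet$split[sheet$split == ""] <- NA_character_
  wide <- data.table::fread(file.path(dir, "cpg_counts.tsv"))
  ids <- unique(sub("\\.(C|T)$", "",
                    grep("\\.(C|T)$", names(wide), value = TRUE)))
  C <- as.matrix(wide[, paste0(ids, ".C"), with = FALSE])
  Tm <- as.matrix(wide[, paste0(ids, ".T"), with = FALSE])
  colnames(C) <- colnames(Tm) <- ids
  cpg <- new_cpg_counts(data.frame(chrom = wide$chrom, pos0 = wide$pos0,
                                   stringsAsFactors = FALSE), C, Tm)
  bc <- data.table::fread(file.path(dir, "bin_counts.tsv"))
  meta_cols <- c("bin_id", "chrom", "start", "end")
  counts <- as.matrix(bc[, setdiff(names(bc), meta_cols), with = FALSE])
  rownames(counts) <- bc$bin_id
  bins <- list(bins = as.data.frame(bc[, meta_cols, with = FALSE]),
               counts = counts)
  frags <- data.table::fread(file.path(dir, "fragment_hist.tsv"))
  bl_path <- file.path(dir, "blacklist.bed")
  blacklist <- if (file.size(bl_path) > 0) {
    as.data.frame(data.table::fread(bl_path,
                                    col.names = c("chrom", "start", "end")))
  } else {
    data.frame(chrom = character(), start = integer(), end = integer())
  }
  structure(list(sheet = sheet, cpg = cpg, bins = bins, frags = frags,
                 blacklist = blacklist, truth = NULL, config = NULL),
            class = "mced_cohort")
}

#' Read pipeline configuration from a YAML file
#'
#' @param path YAML file; keys override [sim_config()] defaults under
#'   `simulate:` and pipeline parameters under `pipeline:`.
#' @return List with `simulate` (an `mced_sim_config`) and `pipeline`
#'   parameter list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  sim <- do.call(sim_config, raw$simulate %||% list())
  list(simulate = sim, pipeline = raw$pipeline %||% list())
}

#' Serialize a fitted CSE model to JSON
#'
#' @param model An `mced_cse`.
#' @param path Output path.
#' @export
write_cse_json <- function(model, path) {
  jsonlite::write_json(list(
    coef = as.list(model$coef),
    feature_names = model$feature_names,
    threshold = model$threshold,
    target_spec = model$target_spec,
    eps = model$eps,
    too_weights = as.list(model$too_weights %||% list()),
    delta = model$delta,
    class_order = class_levels(),
    version = as.character(utils::packageVersion("mced"))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
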