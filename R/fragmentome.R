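# Fragment-length feature extraction: per-window short/long fragment size
# ratio (FSR) and global 5-bp fragment size distribution (FSD), with
# training-anchored standardization.

#' Classify a cfDNA fragment length as short, long, or neither
#'
#' Short fragments are strictly between 80 and 150 bp; long fragments
#' strictly between 150 and 220 bp. The boundary lengths 80, 150 and 220
#' belong to neither class (the size-interval definitions are strict on
#' both ends).
#'
#' @param length Positive integer fragment length(s) in bp.
#' @return Character vector in `{"short", "long", "neither"}`.
#' @export
classify_fragment <- function(length) {
  if (any(is.na(length)) || any(length <= 0)) {
    stop("fragment lengths must be positive")
  }
  out <- rep("neither", base::length(length))
  out[length > 80 & length < 150] <- "short"
  out[length > 150 & length < 220] <- "long"
  out
}

#' Per-window short/long fragment size ratio
#'
#' @param histograms Data frame / data.table with columns `sample_id`,
#'   `window_id`, `length`, `count`.
#' @return Samples x windows matrix of short/long count ratios, column
#'   names `fsr:<window_id>`; windows with zero long fragments are `NA`
#'   (their (sample, window) pairs are recorded in `attr(, "missing")`).
#' @export
compute_fsr <- function(histograms) {
  h <- data.table::as.data.table(histograms)
  stopifnot(all(c("sample_id", "window_id", "length", "count") %in% names(h)))
  h <- h[count > 0]
  h[, class := classify_fragment(length)]
  agg <- h[class != "neither",
           .(n = sum(count)), by = .(sample_id, window_id, class)]
  wide <- data.table::dcast(agg, sample_id + window_id ~ class,
                            value.var = "n", fill = 0)
  if (!"short" %in% names(wide)) wide[, short := 0]
  if (!"long" %in% names(wide)) wide[, long := 0]
  wide[, fsr := ifelse(long > 0, short / long, NA_real_)]
  m <- data.table::dcast(wide, sample_id ~ window_id, value.var = "fsr")
  ids <- m$sample_id
  m[, sample_id := NULL]
  out <- as.matrix(m)
  rownames(out) <- ids
  colnames(out) <- paste0("fsr:", colnames(out))
  miss <- which(is.na(out), arr.ind = TRUE)
  attr(out, "missing") <- data.frame(
    sample_id = rownames(out)[miss[, 1]],
    window = colnames(out)[miss[, 2]], stringsAsFactors = FALSE)
  out
}

#' Fragment size distribution in 5-bp bins
#'
#' Pools each sample's fragments across windows and bins lengths into
#' `width`-bp intervals over \[`lo`, `hi`): with the defaults, 28 bins
#' \[80,85), ..., \[215,220). Proportions are relative to the total
#' in-range count and sum to 1 per sample.
#'
#' @param histograms Data frame with `sample_id`, `length`, `count`
#'   (window column ignored; the FSD is genome-wide).
#' @param lo,hi Range in bp (default 80-220, half-open).
#' @param width Bin width in bp (default 5).
#' @return Samples x bins matrix of proportions, column names
#'   `fsd:<bin_start>`.
#' @export
compute_fsd <- function(histograms, lo = 80, hi = 220, width = 5) {
  stopifnot((hi - lo) %% width == 0)
  h <- data.table::as.data.table(histograms)
  h <- h[length >= lo & length < hi & count > 0]
  starts <- seq(lo, hi - width, by = width)
  all_ids <- unique(data.table::as.data.table(histograms)$sample_id)
  if (nrow(h) == 0 || !all(all_ids %in% h$sample_id)) {
    bad <- setdiff(all_ids, h$sample_id)
    stop("zero in-range fragments for sample(s): ",
         paste(bad, collapse = ","))
  }
  h[, bin := lo + width * ((length - lo) %/% width)]
  agg <- h[, .(n = sum(count)), by = .(sample_id, bin)]
  m <- matrix(0, nrow = length(all_ids), ncol = length(starts),
              dimnames = list(all_ids, paste0("fsd:", starts)))
  m[cbind(match(agg$sample_id, all_ids), match(agg$bin, starts))] <- agg$n
  m / rowSums(m)
}

#' Fit a standard scaler on training features
#'
#' @param train Numeric matrix (train samples x features).
#' @return An `mced_scaler` with per-feature train mean and sd.
#' @export
fit_scaler <- function(train) {
  if (is.null(dim(train)) || nrow(train) == 0) stop("empty training matrix")
  structure(list(mean = colMeans(train, na.rm = TRUE),
                 sd = apply(train, 2, sd, na.rm = TRUE),
                 features = colnames(train)),
            class = "mced_scaler")
}

#' Apply a fitted standard scaler
#'
#' Maps x to (x - train_mean) / train_sd per feature; features with zero
#' (or undefined) training sd map to 0, as do missing values (a missing
#' standardized feature equals the training mean).
#'
#' @param scaler An `mced_scaler` from [fit_scaler()].
#' @param x Matrix with the same feature columns as the training matrix.
#' @return Standardized matrix.
#' @export
apply_scaler <- function(scaler, x) {
  if (!inherits(scaler, "mced_scaler")) {
    stop("standardization applied before fitting: not an mced_scaler")
  }
  if (!identical(colnames(x), scaler$features)) {
    if (is.null(colnames(x)) || !all(scaler$features %in% colnames(x))) {
      stop("feature columns do not match the fitted scaler")
    }
    x <- x[, scaler$features, drop = FALSE]
  }
  s <- scaler$sd
  degenerate <- is.na(s) | s == 0
  s[degenerate] <- 1
  z <- sweep(sweep(x, 2, scaler$mean, "-"), 2, s, "/")
  z[, degenerate] <- 0
  z[is.na(z)] <- 0
  z
}

#' Standardize features against a training matrix
#'
#' Convenience wrapper: fits the scaler on `train` and applies it to
#' `apply_to` (default: the training matrix itself).
#'
#' @param train Training feature matrix.
#' @param apply_to Matrix to standardize (defaults to `train`).
#' @return Standardized matrix with the scaler in `attr(, "scaler")`.
#' @export
standardize <- function(train, apply_to = train) {
  sc <- fit_scaler(train)
  out <- apply_scaler(sc, apply_to)
  attr(out, "scaler") <- sc
  out
}

#' Read fragment lengths from a coordinate-sorted BAM file
#'
#' Optional ingestion path: extracts absolute template lengths of properly
#' paired, primary alignments and returns a histogram table compatible with
#' [compute_fsr()]/[compute_fsd()]. Requires the Rsamtools package.
#'
#' @param bam Path to a BAM file.
#' @param windows Optional data frame (`window_id`, `chrom`, `start`,
#'   `end`); when `NULL` all fragments go into a single pooled window.
#' @return Data frame with `sample_id`, `window_id`, `length`, `count`.
#' @export
fragment_histogram_from_bam <- function(bam, windows = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("Rsamtools is required for BAM ingestion")
  }
  sample_id <- sub("\\.bam$", "", basename(bam))
  flag <- Rsamtools::scanBamFlag(isProperPair = TRUE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isFirstMateRead = TRUE)
  read_one <- function(which_param, wid) {
    p <- Rsamtools::ScanBamParam(flag = flag, what = c("isize"),
                                 which = which_param)
    res <- Rsamtools::scanBam(bam, param = p)
    len <- abs(unlist(lapply(res, `[[`, "isize"), use.names = FALSE))
    len <- len[!is.na(len) & len > 0]
    if (!length(len)) return(NULL)
    tab <- table(len)
    data.frame(sample_id = sample_id, window_id = wid,
               length = as.integer(names(tab)), count = as.integer(tab),
               stringsAsFactors = FALSE)
  }
  if (is.null(windows)) {
    p <- Rsamtools::ScanBamParam(flag = flag, what = c("isize"))
    res <- Rsamtools::scanBam(bam, param = p)[[1]]
    len <- abs(res$isize)
    len <- len[!is.na(len) & len > 0]
    tab <- table(len)
    return(data.frame(sample_id = sample_id, window_id = "pooled",
                      length = as.integer(names(tab)),
                      count = as.integer(tab), stringsAsFactors = FALSE))
  }
  out <- lapply(seq_len(nrow(windows)), function(i) {
    gr <- GenomicRanges::GRanges(windows$chrom[i],
                                 IRanges::IRanges(windows$start[i] + 1,
                                                  windows$end[i]))
    read_one(gr, windows$window_id[i])
  })
  do.call(rbind, out)
}
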