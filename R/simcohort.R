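# Synthetic multimodal cfDNA cohort simulator.
#
# The generator emulates the statistical structure the assay assumes: plasma
# methylation is a (1 - TF) * beta_healthy + TF * beta_tumor mixture observed
# through beta-binomial counts, copy-number bins shift multiplicatively with
# TF at planted segments, and fragment lengths follow a two-component
# (healthy/tumor-mode) mixture with tumor weight TF. TF is drawn per stage.

#' Default age/sex model (per-label age mean, sd, male fraction)
#'
#' Defaults follow the demographic structure typical of multi-cancer
#' screening cohorts: breast/ovarian female-only and diagnosed in the early
#' 50s, prostate male-only in the early 70s, gastrointestinal and lung
#' cancers around 60-66 with male predominance, healthy controls split into
#' a young (<50) and an old (>=50) arm because model training downstream is
#' restricted to healthy individuals aged 50+.
#'
#' @return Named list keyed by label; `healthy` has `young`/`old` components.
#' @export
default_age_sex_model <- function() {
  list(
    healthy    = list(young = c(mean = 41.6, sd = 6.9),
                      old   = c(mean = 59.2, sd = 6.8),
                      young_frac = 0.4, male_frac = 0.30),
    breast     = list(age = c(mean = 53.0, sd = 11.8), male_frac = 0),
    colorectal = list(age = c(mean = 62.0, sd = 9.4),  male_frac = 0.63),
    gastric    = list(age = c(mean = 59.7, sd = 12.7), male_frac = 0.56),
    liver      = list(age = c(mean = 60.5, sd = 11.4), male_frac = 0.74),
    lung       = list(age = c(mean = 65.9, sd = 11.3), male_frac = 0.69),
    ovarian    = list(age = c(mean = 54.3, sd = 13.8), male_frac = 0),
    pancreatic = list(age = c(mean = 63.9, sd = 10.4), male_frac = 0.59),
    prostate   = list(age = c(mean = 69.9, sd = 7.5),  male_frac = 1)
  )
}

#' Configuration for the synthetic cohort simulator
#'
#' Defaults describe a desk-scale cohort: 50 healthy individuals plus five
#' patients per cancer type per stage (I-IV) across eight cancer types,
#' 20,000 CpG sites in 8-site blocks, 500 copy-number bins, and 100 FSR
#' windows. Tumor fraction (TF) distributions per stage are centred at
#' 3/5/8/12% (stage I-IV), matching the observation that most early-stage
#' plasma samples carry low (<5%) tumor fractions while advanced stages
#' shed more ctDNA.
#'
#' @param n_healthy Number of healthy plasma samples.
#' @param n_per_cancer_per_stage Patients per cancer type per stage.
#' @param n_cpg_sites Number of simulated CpG sites.
#' @param n_cnv_bins Number of copy-number bins.
#' @param n_fsr_windows Number of fragmentation windows.
#' @param coverage_mean Mean sequencing coverage per CpG site.
#' @param tf_by_stage Named list `I`..`IV`, each `c(mean, sd)` of the
#'   truncated-normal tumor-fraction distribution.
#' @param dmr_effect Absolute beta shift between tumor and healthy
#'   methylomes at planted DMR sites. Default 0.6 (well-separated
#'   differentially methylated regions typically move from ~0.1 to ~0.7+).
#' @param cnv_segment_effect Log2 copy-ratio shift of a planted segment at
#'   TF = 1. Default 0.8 (between a one-copy gain, log2 1.5 = 0.58, and a
#'   two-copy gain, log2 2 = 1).
#' @param frag_healthy_mode,frag_tumor_mode Fragment-length modes (bp) for
#'   healthy- and tumor-derived cfDNA. Defaults 166/145 (mono-nucleosomal
#'   convention; tumor fragments run shorter).
#' @param frag_sd Fragment-length standard deviation (bp) of each component.
#' @param frag_per_window Expected fragment count per (sample, window).
#' @param chip_rate Fraction of individuals (healthy and cancer alike)
#'   carrying clonal-hematopoiesis-like recurrent gains at designated bins.
#' @param chip_log2 Log2 shift of CHIP-like gains (clone-level, not
#'   TF-scaled).
#' @param bb_concentration Beta-binomial concentration for methylation
#'   counts (biological + technical dispersion; larger = less noise).
#' @param n_dmr_blocks_per_type Planted DMR blocks per cancer type.
#' @param hyper_frac Fraction of planted DMR blocks that are
#'   hypermethylated in tumor (the rest are hypomethylated).
#' @param block_size CpG sites per homogeneous methylation block.
#' @param n_cnv_segments_per_type Planted CNV segments per cancer type.
#' @param cnv_segment_bins Bins per planted CNV segment.
#' @param n_chip_bins Number of designated CHIP-prone bins.
#' @param reads_per_bin Mean read count per copy-number bin.
#' @param cnv_nb_size Negative-binomial size for bin counts (overdispersion
#'   beyond Poisson; larger = closer to Poisson).
#' @param low_cov_frac Fraction of CpG sites with ~5% of nominal coverage
#'   (low-mappability stand-ins; exercised by the coverage filter).
#' @param blacklist_frac Fraction of methylation blocks emitted as
#'   blacklist intervals.
#' @param n_tissue_pairs Matched tumor/adjacent-normal tissue pairs per
#'   tissue-profiled cancer type.
#' @param tissue_types Cancer types with matched tissue profiling.
#' @param age_sex_model See [default_age_sex_model()].
#' @param seed Integer seed; identical configs reproduce identical cohorts.
#' @return A validated `mced_sim_config` list.
#' @export
sim_config <- function(n_healthy = 50L,
                       n_per_cancer_per_stage = 5L,
                       n_cpg_sites = 20000L,
                       n_cnv_bins = 500L,
                       n_fsr_windows = 100L,
                       coverage_mean = 30,
                       tf_by_stage = list(I   = c(0.03, 0.02),
                                          II  = c(0.05, 0.03),
                                          III = c(0.08, 0.04),
                                          IV  = c(0.12, 0.06)),
                       dmr_effect = 0.6,
                       cnv_segment_effect = 0.8,
                       frag_healthy_mode = 166,
                       frag_tumor_mode = 145,
                       frag_sd = 10,
                       frag_per_window = 2000,
                       chip_rate = 0.1,
                       chip_log2 = 0.15,
                       bb_concentration = 50,
                       n_dmr_blocks_per_type = 15L,
                       hyper_frac = 0.6,
                       block_size = 8L,
                       n_cnv_segments_per_type = 3L,
                       cnv_segment_bins = 10L,
                       n_chip_bins = 5L,
                       reads_per_bin = 2000,
                       cnv_nb_size = 2000,
                       low_cov_frac = 0.02,
                       blacklist_frac = 0.005,
                       n_tissue_pairs = 5L,
                       tissue_types = c("colorectal", "liver", "lung"),
                       age_sex_model = default_age_sex_model(),
                       seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_healthy", "n_per_cancer_per_stage", "n_cpg_sites",
              "n_cnv_bins", "n_fsr_windows", "block_size",
              "n_dmr_blocks_per_type", "n_cnv_segments_per_type",
              "cnv_segment_bins")
  for (nm in counts) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop("configuration error: ", nm, " must be a positive count")
    }
  }
  if (coverage_mean <= 0 || frag_per_window <= 0 || reads_per_bin <= 0) {
    stop("configuration error: rates must be positive")
  }
  if (chip_rate < 0 || chip_rate > 1) {
    stop("configuration error: chip_rate must lie in [0, 1]")
  }
  stages <- c("I", "II", "III", "IV")
  if (!all(stages %in% names(tf_by_stage))) {
    stop("tf_by_stage must name stages I, II, III, IV")
  }
  tf_means <- vapply(tf_by_stage[stages], `[`, numeric(1), 1)
  if (any(diff(tf_means) < 0)) {
    stop("configuration error: stage TF means must be non-decreasing I -> IV")
  }
  if (any(!tissue_types %in% cancer_types())) {
    stop("unknown tissue_types")
  }
  need_bins <- (8L * n_cnv_segments_per_type + 1L) * cnv_segment_bins
  if (need_bins > n_cnv_bins) {
    stop("configuration error: n_cnv_bins too small for planted segments (need ",
         need_bins, ")")
  }
  n_blocks <- n_cpg_sites %/% block_size
  if (8L * n_dmr_blocks_per_type * 3L > n_blocks) {
    stop("configuration error: n_cpg_sites too small for planted DMR blocks")
  }
  structure(cfg, class = "mced_sim_config")
}

#' Draw a tumor fraction for a cancer stage
#'
#' Draws from the stage's configured normal distribution, truncated to
#' \[0, 1\] (values outside the unit interval are clamped, not resampled).
#' Uses the current RNG stream; seed via `set.seed()` or the config seed in
#' [simulate_cohort()].
#'
#' @param stage One of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param config An `mced_sim_config`.
#' @param n Number of draws.
#' @return Numeric vector of tumor fractions in \[0, 1\].
#' @export
draw_tumor_fraction <- function(stage, config, n = 1L) {
  if (length(stage) != 1L || !stage %in% c("I", "II", "III", "IV")) {
    stop("unknown stage: ", paste(stage, collapse = ","))
  }
  ms <- config$tf_by_stage[[stage]]
  pmin(pmax(rnorm(n, ms[1], ms[2]), 0), 1)
}

# --- internal design helpers -------------------------------------------------

# Lay out CpG sites on 22 pseudo-chromosomes in homogeneous blocks, plant
# type-specific DMR blocks at the extremes of the baseline beta distribution
# (so they survive the decile-based status classification downstream), and
# reserve blacklist / low-coverage decoys.
design_methylome <- function(cfg) {
  n_sites <- as.integer(cfg$n_cpg_sites)
  bs <- as.integer(cfg$block_size)
  n_blocks <- n_sites %/% bs
  n_sites <- n_blocks * bs            # trim remainder sites
  block_of <- rep(seq_len(n_blocks), each = bs)

  chroms <- paste0("chr", 1:22)
  chrom_block <- sort(rep_len(seq_along(chroms), n_blocks))
  chrom <- chroms[chrom_block[block_of]]
  pos0 <- integer(n_sites)
  for (ch in unique(chrom)) {
    ix <- which(chrom == ch)
    pos0[ix] <- seq(1000L, by = 150L, length.out = length(ix))
  }

  state <- sample(c("low", "mid", "high"), n_blocks, replace = TRUE,
                  prob = c(0.20, 0.55, 0.25))

  # choose planted DMR blocks: pairwise non-adjacent, spread over types
  types <- cancer_types()
  n_per <- as.integer(cfg$n_dmr_blocks_per_type)
  n_hyper <- round(cfg$hyper_frac * n_per)
  need <- 8L * n_per
  cand <- sample.int(n_blocks)
  taken <- logical(n_blocks)
  picked <- integer(0)
  for (b in cand) {
    if (length(picked) >= need) break
    nb <- c(b - 1L, b, b + 1L)
    nb <- nb[nb >= 1L & nb <= n_blocks]
    if (any(taken[nb])) next
    # keep planted blocks inside one chromosome neighbourhood
    taken[b] <- TRUE
    picked <- c(picked, b)
  }
  if (length(picked) < need) stop("could not place DMR blocks; increase n_cpg_sites")
  dmr_blocks <- matrix(picked[seq_len(need)], nrow = n_per)
  colnames(dmr_blocks) <- types

  is_dmr <- logical(n_blocks)
  dmr_dir <- character(n_blocks)      # "" / "hyper" / "hypo"
  dmr_type <- character(n_blocks)
  for (ty in types) {
    bl <- dmr_blocks[, ty]
    hyper <- bl[seq_len(n_hyper)]
    hypo <- bl[-seq_len(n_hyper)]
    is_dmr[bl] <- TRUE
    dmr_type[bl] <- ty
    dmr_dir[hyper] <- "hyper"
    dmr_dir[hypo] <- "hypo"
  }
  # neighbours of planted blocks forced to mid so planted runs do not merge
  nbrs <- unique(c(which(is_dmr) - 1L, which(is_dmr) + 1L))
  nbrs <- setdiff(nbrs[nbrs >= 1L & nbrs <= n_blocks], which(is_dmr))
  state[nbrs] <- "mid"

  beta0_block <- numeric(n_blocks)
  beta0_block[state == "low"] <- runif(sum(state == "low"), 0.05, 0.12)
  beta0_block[state == "mid"] <- runif(sum(state == "mid"), 0.30, 0.70)
  beta0_block[state == "high"] <- runif(sum(state == "high"), 0.88, 0.95)
  # planted blocks sit strictly inside the decile extremes
  beta0_block[dmr_dir == "hyper"] <- runif(sum(dmr_dir == "hyper"), 0.030, 0.045)
  beta0_block[dmr_dir == "hypo"] <- runif(sum(dmr_dir == "hypo"), 0.955, 0.970)

  beta_h <- pmin(pmax(beta0_block[block_of] + rnorm(n_sites, 0, 0.005),
                      0.02), 0.98)

  beta_t <- matrix(beta_h, nrow = n_sites, ncol = 8,
                   dimnames = list(NULL, types))
  for (ty in types) {
    hy <- which(block_of %in% dmr_blocks[dmr_dir[dmr_blocks[, ty]] == "hyper", ty])
    ho <- which(block_of %in% dmr_blocks[dmr_dir[dmr_blocks[, ty]] == "hypo", ty])
    beta_t[hy, ty] <- pmin(beta_t[hy, ty] + cfg$dmr_effect, 0.98)
    beta_t[ho, ty] <- pmax(beta_t[ho, ty] - cfg$dmr_effect, 0.02)
  }

  # coverage structure: per-site multiplicative factor; a small fraction of
  # sites are low-mappability decoys at ~5% of nominal coverage
  cov_factor <- exp(rnorm(n_sites, 0, 0.15))
  low_cov <- sample.int(n_sites, round(cfg$low_cov_frac * n_sites))
  low_cov <- setdiff(low_cov, which(is_dmr[block_of]))
  cov_factor[low_cov] <- cov_factor[low_cov] * 0.05

  # blacklist decoy intervals over non-planted blocks
  bl_blocks <- sample(setdiff(which(!is_dmr), nbrs),
                      max(0L, round(cfg$blacklist_frac * n_blocks)))
  blacklist <- do.call(rbind, lapply(bl_blocks, function(b) {
    ix <- which(block_of == b)
    data.frame(chrom = chrom[ix[1]], start = pos0[ix[1]],
               end = pos0[ix[length(ix)]] + 2L)
  }))
  if (is.null(blacklist)) {
    blacklist <- data.frame(chrom = character(), start = integer(),
                            end = integer())
  }

  list(sites = data.frame(chrom = chrom, pos0 = pos0,
                          stringsAsFactors = FALSE),
       block_of = block_of, n_blocks = n_blocks,
       beta_healthy = beta_h, beta_tumor = beta_t,
       cov_factor = cov_factor,
       dmr_blocks = dmr_blocks, dmr_dir = dmr_dir, dmr_type = dmr_type,
       low_cov_sites = sort(low_cov), blacklist = blacklist)
}

# Plant disjoint CNV segments (per type: gains and one loss) and designated
# CHIP-prone bins.
design_cnv <- function(cfg) {
  n_bins <- as.integer(cfg$n_cnv_bins)
  seg_len <- as.integer(cfg$cnv_segment_bins)
  n_seg <- as.integer(cfg$n_cnv_segments_per_type)
  types <- cancer_types()

  n_slots <- n_bins %/% seg_len
  slots <- sample.int(n_slots, 8L * n_seg + 1L)   # +1 slot reserved for CHIP
  seg_tbl <- NULL
  k <- 0L
  for (ty in types) {
    for (s in seq_len(n_seg)) {
      k <- k + 1L
      first <- (slots[k] - 1L) * seg_len + 1L
      dir <- if (s == n_seg && n_seg > 1L) "loss" else "gain"
      seg_tbl <- rbind(seg_tbl, data.frame(
        type = ty, segment = s, direction = dir,
        bin_from = first, bin_to = first + seg_len - 1L))
    }
  }
  chip_first <- (slots[8L * n_seg + 1L] - 1L) * seg_len + 1L
  chip_bins <- chip_first:(chip_first + min(seg_len, cfg$n_chip_bins) - 1L)

  chroms <- paste0("chr", 1:22)
  bin_chrom <- chroms[sort(rep_len(seq_along(chroms), n_bins))]
  start <- unlist(lapply(rle(bin_chrom)$lengths,
                         function(l) seq(0L, by = 1000000L, length.out = l)))
  bins <- data.frame(bin_id = sprintf("bin%04d", seq_len(n_bins)),
                     chrom = bin_chrom, start = start,
                     end = start + 1000000L, stringsAsFactors = FALSE)
  weight <- exp(rnorm(n_bins, 0, 0.2))
  list(bins = bins, weight = weight, segments = seg_tbl,
       chip_bins = chip_bins)
}

# --- cohort simulation -------------------------------------------------------

#' Simulate a seeded synthetic multimodal cfDNA cohort
#'
#' Generates a sample sheet (healthy + eight cancer types across stages
#' I-IV, plus matched tumor/adjacent tissue pairs for the tissue-profiled
#' types), CpG cytosine/thymine count tables, copy-number bin counts,
#' per-window fragment-length histograms, a blacklist, and the ground truth
#' needed for parameter-recovery tests. Identical configs (including the
#' seed) reproduce identical cohorts.
#'
#' @param config An `mced_sim_config` from [sim_config()].
#' @return An `mced_cohort` list with elements `sheet`, `cpg`, `bins`,
#'   `frags`, `blacklist`, `truth`, and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "mced_sim_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  types <- cancer_types()
  stages <- c("I", "II", "III", "IV")
  asm <- cfg$age_sex_model

  # ---- sample sheet ----
  n_h <- as.integer(cfg$n_healthy)
  nps <- as.integer(cfg$n_per_cancer_per_stage)
  lab <- c(rep("healthy", n_h),
           rep(types, each = nps * 4L))
  stg <- c(rep(NA_character_, n_h),
           rep(rep(stages, each = nps), times = 8L))
  n_plasma <- length(lab)
  tf <- numeric(n_plasma)
  for (i in which(lab != "healthy")) {
    tf[i] <- draw_tumor_fraction(stg[i], cfg, 1L)
  }
  age <- numeric(n_plasma); sex <- character(n_plasma)
  young <- runif(n_h) < asm$healthy$young_frac
  age[seq_len(n_h)] <- ifelse(
    young,
    pmin(pmax(rnorm(n_h, asm$healthy$young["mean"], asm$healthy$young["sd"]), 25), 49),
    pmin(pmax(rnorm(n_h, asm$healthy$old["mean"], asm$healthy$old["sd"]), 50), 90))
  sex[seq_len(n_h)] <- ifelse(runif(n_h) < asm$healthy$male_frac, "M", "F")
  for (i in which(lab != "healthy")) {
    m <- asm[[lab[i]]]
    age[i] <- pmin(pmax(rnorm(1, m$age["mean"], m$age["sd"]), 25), 95)
    sex[i] <- if (runif(1) < m$male_frac) "M" else "F"
  }
  sheet <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n_plasma)),
    label = lab, stage = stg, age = round(age, 1), sex = sex,
    split = NA_character_, material = "plasma", true_tf = tf,
    stringsAsFactors = FALSE)

  # matched tissue pairs (tumor purity in lieu of TF; adjacent normal = 0)
  tissue <- NULL
  for (ty in cfg$tissue_types) {
    for (k in seq_len(cfg$n_tissue_pairs)) {
      m <- asm[[ty]]
      a <- round(pmin(pmax(rnorm(1, m$age["mean"], m$age["sd"]), 25), 95), 1)
      sx <- if (runif(1) < m$male_frac) "M" else "F"
      st <- sample(c("II", "III"), 1)
      tissue <- rbind(tissue,
        data.frame(sample_id = sprintf("T_%s_%02d_tumor", ty, k),
                   label = ty, stage = st, age = a, sex = sx,
                   split = "train", material = "tumor",
                   true_tf = runif(1, 0.5, 0.9), stringsAsFactors = FALSE),
        data.frame(sample_id = sprintf("T_%s_%02d_adj", ty, k),
                   label = ty, stage = st, age = a, sex = sx,
                   split = "train", material = "adjacent",
                   true_tf = 0, stringsAsFactors = FALSE))
    }
  }
  sheet <- rbind(sheet, tissue)
  n_all <- nrow(sheet)

  # ---- methylome ----
  des <- design_methylome(cfg)
  n_sites <- nrow(des$sites)
  type_idx <- match(sheet$label, types)          # NA for healthy
  beta_eff <- matrix(des$beta_healthy, n_sites, n_all)
  for (j in which(!is.na(type_idx) & sheet$true_tf > 0)) {
    t_ <- sheet$true_tf[j]
    beta_eff[, j] <- (1 - t_) * des$beta_healthy +
      t_ * des$beta_tumor[, type_idx[j]]
  }
  lam <- cfg$coverage_mean * des$cov_factor
  cov <- matrix(rpois(n_sites * n_all, rep(lam, n_all)), n_sites, n_all)
  conc <- cfg$bb_concentration
  p_eff <- clip01(beta_eff, 1e-4)
  p_draw <- matrix(rbeta(n_sites * n_all, p_eff * conc, (1 - p_eff) * conc),
                   n_sites, n_all)
  C <- matrix(rbinom(n_sites * n_all, cov, p_draw), n_sites, n_all)
  Tmat <- cov - C
  colnames(C) <- colnames(Tmat) <- sheet$sample_id
  cpg <- new_cpg_counts(des$sites, C, Tmat)

  # ---- copy number ----
  cdes <- design_cnv(cfg)
  n_bins <- nrow(cdes$bins)
  mult <- matrix(1, n_bins, n_all)
  for (j in which(!is.na(type_idx) & sheet$true_tf > 0)) {
    segs <- cdes$segments[cdes$segments$type == sheet$label[j], , drop = FALSE]
    for (r in seq_len(nrow(segs))) {
      ix <- segs$bin_from[r]:segs$bin_to[r]
      sh <- cfg$cnv_segment_effect * sheet$true_tf[j]
      mult[ix, j] <- mult[ix, j] * 2^(if (segs$direction[r] == "gain") sh else -sh)
    }
  }
  chip_carrier <- runif(n_all) < cfg$chip_rate
  mult[cdes$chip_bins, chip_carrier] <-
    mult[cdes$chip_bins, chip_carrier] * 2^cfg$chip_log2
  depth_factor <- exp(rnorm(n_all, 0, 0.1))
  mu <- (cfg$reads_per_bin * cdes$weight / mean(cdes$weight)) %o% depth_factor * mult
  counts <- matrix(rnbinom(n_bins * n_all, mu = mu, size = cfg$cnv_nb_size),
                   n_bins, n_all)
  storage.mode(counts) <- "integer"
  colnames(counts) <- sheet$sample_id
  bins <- list(bins = cdes$bins, counts = counts)

  # ---- fragmentome ----
  support <- 50:400
  dh <- stats::dnorm(support, cfg$frag_healthy_mode, cfg$frag_sd)
  dt_ <- stats::dnorm(support, cfg$frag_tumor_mode, cfg$frag_sd)
  nw <- as.integer(cfg$n_fsr_windows)
  frag_list <- vector("list", n_all)
  for (j in seq_len(n_all)) {
    t_ <- if (is.na(type_idx[j])) 0 else sheet$true_tf[j]
    p <- (1 - t_) * dh + t_ * dt_
    p <- p / sum(p)
    # Poissonized multinomial: independent Poisson cells share the
    # marginal distribution of per-window multinomial counts
    lam <- cfg$frag_per_window * p
    m <- matrix(rpois(length(support) * nw, rep(lam, nw)),
                length(support), nw)
    nz <- which(m > 0, arr.ind = TRUE)
    frag_list[[j]] <- data.table::data.table(
      sample_id = sheet$sample_id[j],
      window_id = sprintf("w%03d", nz[, 2]),
      length = support[nz[, 1]],
      count = m[nz])
  }
  frags <- data.table::rbindlist(frag_list)

  truth <- list(
    sheet = sheet[, c("sample_id", "label", "stage", "true_tf", "material")],
    dmr_blocks = des$dmr_blocks,
    dmr_dir = des$dmr_dir,
    dmr_sites = lapply(setNames(types, types), function(ty) {
      bl <- des$dmr_blocks[, ty]
      list(hyper = which(des$block_of %in% bl[des$dmr_dir[bl] == "hyper"]),
           hypo  = which(des$block_of %in% bl[des$dmr_dir[bl] == "hypo"]))
    }),
    block_of = des$block_of,
    cnv_segments = cdes$segments,
    chip_bins = cdes$chip_bins,
    chip_carriers = sheet$sample_id[chip_carrier],
    low_cov_sites = des$low_cov_sites,
    beta_healthy = des$beta_healthy)

  structure(list(sheet = sheet, cpg = cpg, bins = bins, frags = frags,
                 blacklist = des$blacklist, truth = truth, config = cfg),
            class = "mced_cohort")
}

#' @export
print.mced_cohort <- function(x, ...) {
  cat("mced synthetic cohort:", nrow(x$sheet), "samples (",
      sum(x$sheet$material == "plasma"), "plasma ),",
      nrow(x$cpg$sites), "CpG sites,", nrow(x$bins$bins), "CNV bins,",
      length(unique(x$frags$window_id)), "fragment windows\n")
  invisible(x)
}
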