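# Shared fixtures: tiny hand-built tables and a small cached cohort.

# CpG table with explicit counts; samples H1..H3 healthy, C1..C2 cancer-like
tiny_cpg <- function() {
  sites <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2", "chrX"),
    pos0 = c(100L, 250L, 400L, 100L, 300L, 50L))
  C <- matrix(c(5, 3, 2, 8, 0, 4,
                4, 4, 2, 7, 1, 4,
                5, 2, 3, 9, 0, 4,
                9, 8, 4, 1, 0, 4,
                8, 9, 4, 0, 1, 4), nrow = 6,
              dimnames = list(NULL, c("H1", "H2", "H3", "C1", "C2")))
  T <- matrix(c(0, 1, 2, 1, 9, 4,
                1, 0, 2, 2, 8, 4,
                0, 2, 1, 0, 9, 4,
                1, 1, 4, 9, 9, 4,
                1, 0, 4, 9, 8, 4), nrow = 6,
              dimnames = list(NULL, c("H1", "H2", "H3", "C1", "C2")))
  new_cpg_counts(sites, C, T)
}

# small simulated cohort, cached per test session
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_cpg_sites = 3200, n_cnv_bins = 300,
                        n_fsr_windows = 10, n_healthy = 24,
                        n_per_cancer_per_stage = 2, n_tissue_pairs = 2,
                        n_dmr_blocks_per_type = 8, seed = 42)
      co <- simulate_cohort(cfg)
      co$sheet <- stratified_split(co$sheet, seed = 42)
      cache <<- co
    }
    cache
  }
})

# brute-force AMF oracle: per-sample mean of per-site C/(C+T) over covered
# member sites, computed with explicit loops
amf_oracle <- function(table, regions) {
  out <- matrix(NA_real_, ncol(table$C), nrow(regions),
                dimnames = list(colnames(table$C), regions$region_id))
  for (j in seq_len(ncol(table$C))) {
    for (r in seq_len(nrow(regions))) {
      vals <- c()
      for (i in regions$site_idx[[r]]) {
        cov <- table$C[i, j] + table$T[i, j]
        if (cov > 0) vals <- c(vals, table$C[i, j] / cov)
      }
      if (length(vals)) out[j, r] <- sum(vals) / length(vals)
    }
  }
  out
}

# independent BH step-up oracle, straight from the definition: find the
# largest k with p_(k) <= k q / m; here returns adjusted values by the
# equivalent running-minimum construction evaluated naively
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    # adjusted p for rank i = min over j >= i of p_(j) * m / j, capped at 1
    cand <- vapply(i:m, function(j) p[o[j]] * m / j, numeric(1))
    q[o[i]] <- min(1, min(cand))
  }
  q
}
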