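test_that("filter_sites applies coverage, blacklist and sex-chromosome rules", {
  tab <- tiny_cpg()
  healthy <- c("H1", "H2", "H3")
  # chr2:300 has healthy coverage (9,9,10) -> kept; chrX always removed
  out <- filter_sites(tab, healthy, min_cov = 3)
  expect_false("chrX" %in% out$sites$chrom)
  # site with healthy coverages (2,2,2) under min_cov 3 is removed
  tab2 <- tab
  tab2$C[1, healthy] <- 1L; tab2$T[1, healthy] <- 1L
  out2 <- filter_sites(tab2, healthy, min_cov = 3)
  expect_false(any(out2$sites$chrom == "chr1" & out2$sites$pos0 == 100))
  # empty blacklist + ample coverage: only the sex chromosome goes
  expect_equal(nrow(filter_sites(tab, healthy, min_cov = 0)$sites), 5)
  # blacklist interval removes exactly the covered site (0-based half-open)
  bl <- data.frame(chrom = "chr1", start = 200, end = 251)
  out3 <- filter_sites(tab, healthy, min_cov = 0, blacklist = bl)
  expect_false(any(out3$sites$pos0 == 250 & out3$sites$chrom == "chr1"))
  expect_true(any(out3$sites$pos0 == 400))
  # malformed blacklist and empty healthy set error
  expect_error(filter_sites(tab, healthy, blacklist =
    data.frame(chrom = "chr1", start = 5, end = 5)), "format error")
  expect_error(filter_sites(tab, character(0)), "non-empty")
  # per-sample aggregation is stricter than the mean
  tab3 <- tab
  tab3$C[2, "H1"] <- 0L; tab3$T[2, "H1"] <- 2L  # coverage 2 in one sample
  expect_true(250 %in% filter_sites(tab3, healthy, min_cov = 3)$sites$pos0)
  expect_false(250 %in% filter_sites(tab3, healthy, min_cov = 3,
                                     aggregate = "all")$sites$pos0)
})

test_that("classify_cpg_status combines decile and absolute-beta rules", {
  # 20 sites: mean beta ramp 0.02..0.97; decile extremes are classified
  n <- 20
  mb <- seq(0.02, 0.97, length.out = n)
  C <- matrix(round(mb * 100), n, 2)
  T <- matrix(100 - round(mb * 100), n, 2)
  colnames(C) <- colnames(T) <- c("H1", "H2")
  tab <- new_cpg_counts(data.frame(chrom = "chr1",
                                   pos0 = seq(100, by = 100, length.out = n)),
                        C, T)
  st <- classify_cpg_status(tab, c("H1", "H2"), pct = 10)
  expect_equal(st[1], "unmethylated")
  expect_equal(st[n], "methylated")
  expect_true(all(st[5:15] == "neutral"))
  # degenerate high-beta site in the top decile but below 0.5 stays neutral
  mb2 <- c(rep(0.05, 18), 0.46, 0.48)
  C2 <- matrix(round(mb2 * 100), n, 2)
  T2 <- matrix(100 - round(mb2 * 100), n, 2)
  colnames(C2) <- colnames(T2) <- c("H1", "H2")
  tab2 <- new_cpg_counts(tab$sites, C2, T2)
  st2 <- classify_cpg_status(tab2, c("H1", "H2"), pct = 10)
  expect_equal(st2[20], "neutral")   # beta > 0.5 fails
  # all-identical means: strict percentile inequality -> all neutral
  C3 <- matrix(50L, n, 2); T3 <- matrix(50L, n, 2)
  colnames(C3) <- colnames(T3) <- c("H1", "H2")
  st3 <- classify_cpg_status(new_cpg_counts(tab$sites, C3, T3), c("H1", "H2"))
  expect_true(all(st3 == "neutral"))
  expect_error(classify_cpg_status(tab, "H1", pct = 60), "pct")
})

test_that("build_regions is a run-length partition with min-size and chrom splits", {
  sites <- data.frame(chrom = rep("chr1", 7),
                      pos0 = seq(100, by = 50, length.out = 7))
  st <- c("methylated", "methylated", "methylated",
          "unmethylated", "unmethylated", "neutral", "methylated")
  regs <- build_regions(st, sites, min_cpg = 2)
  expect_equal(nrow(regs), 2)
  expect_equal(regs$status, c("methylated", "unmethylated"))
  expect_equal(regs$site_idx[[1]], 1:3)
  expect_equal(regs$site_idx[[2]], 4:5)
  # trailing singleton dropped by min_cpg
  expect_false(any(vapply(regs$site_idx, function(x) 7 %in% x, logical(1))))
  # all neutral -> empty
  expect_equal(nrow(build_regions(rep("neutral", 7), sites, 2)), 0)
  # a run crossing a chromosome boundary splits in two
  sites2 <- data.frame(chrom = c("chr1", "chr1", "chr2", "chr2"),
                       pos0 = c(10, 20, 10, 20))
  regs2 <- build_regions(rep("methylated", 4), sites2, min_cpg = 2)
  expect_equal(regs2$chrom, c("chr1", "chr2"))
  # unsorted input errors
  sites3 <- data.frame(chrom = "chr1", pos0 = c(30, 10, 20))
  expect_error(build_regions(rep("methylated", 3), sites3, 1), "sorted")
})

test_that("compute_amf matches the hand-evaluated formula and handles coverage gaps", {
  sites <- data.frame(chrom = "chr1", pos0 = c(10, 20, 30))
  C <- matrix(c(5, 3, 2), 3, 1, dimnames = list(NULL, "S1"))
  T <- matrix(c(0, 1, 2), 3, 1, dimnames = list(NULL, "S1"))
  tab <- new_cpg_counts(sites, C, T)
  regs <- build_regions(rep("methylated", 3), sites, min_cpg = 3)
  expect_equal(unname(compute_amf(tab, regs)["S1", ]), 0.75)  # (1+0.75+0.5)/3
  # fully methylated region hits the upper bound exactly
  tabU <- new_cpg_counts(sites, C, matrix(0L, 3, 1, dimnames = list(NULL, "S1")))
  expect_equal(unname(compute_amf(tabU, regs)["S1", ]), 1)
  # uncovered member site is dropped from the mean
  C2 <- C; T2 <- T; C2[2, 1] <- 0L; T2[2, 1] <- 0L
  tab2 <- new_cpg_counts(sites, C2, T2)
  expect_equal(unname(compute_amf(tab2, regs)["S1", ]), (1 + 0.5) / 2)
  # region with no covered site -> NA
  C3 <- matrix(0L, 3, 1, dimnames = list(NULL, "S1"))
  tab3 <- new_cpg_counts(sites, C3, C3)
  expect_true(is.na(compute_amf(tab3, regs)["S1", 1]))
})

test_that("compute_amf equals the brute-force oracle on fuzzed tables", {
  set.seed(71)
  for (rep in 1:25) {
    n <- sample(6:15, 1)
    ns <- sample(2:4, 1)
    sites <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                        pos0 = seq_len(n) * 10L)
    sites <- sites[order(sites$chrom, sites$pos0), ]
    C <- matrix(rpois(n * ns, 3), n, ns)
    T <- matrix(rpois(n * ns, 3), n, ns)
    colnames(C) <- colnames(T) <- paste0("S", seq_len(ns))
    tab <- new_cpg_counts(sites, C, T)
    st <- sample(c("methylated", "unmethylated", "neutral"), n, TRUE)
    regs <- build_regions(st, sites, min_cpg = 1)
    if (nrow(regs) == 0) next
    expect_equal(compute_amf(tab, regs), amf_oracle(tab, regs),
                 tolerance = 1e-12)
  }
})

test_that("bh_fdr reproduces the hand-derived examples", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  # q-values are monotone in p rank
  set.seed(8)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("select_dmrs matches a direct Welch t computation and labels direction", {
  amf <- rbind(matrix(c(0.9, 0.9, 0.9), 3, 1), matrix(c(0.1, 0.11, 0.09), 3, 1))
  amf <- cbind(amf, 0.5 + c(0.01, -0.01, 0.02, 0, 0.01, -0.02))
  rownames(amf) <- paste0("S", 1:6)
  colnames(amf) <- c("R1", "R2")
  mk <- select_dmrs(amf, paste0("S", 1:3), paste0("S", 4:6), fdr = 0.05,
                    target = "toy")
  expect_equal(mk$region_id, "R1")
  expect_equal(mk$direction, "hyper")
  # cross-check p and q against stats::t.test (Welch) on the same data
  t1 <- t.test(amf[1:3, 1], amf[4:6, 1])$p.value
  t2 <- t.test(amf[1:3, 2], amf[4:6, 2])$p.value
  expect_equal(mk$p_value, t1, tolerance = 1e-9)
  expect_equal(mk$q_value, bh_fdr(c(t1, t2))[1], tolerance = 1e-9)
  expect_gte(mk$q_value, mk$p_value)
  # identical values in both groups -> p = 1, never selected
  amf2 <- matrix(0.4, 6, 1, dimnames = list(paste0("S", 1:6), "R1"))
  expect_equal(nrow(select_dmrs(amf2, paste0("S", 1:3), paste0("S", 4:6))), 0)
  expect_error(select_dmrs(amf, c("S1", "S2"), c("S2", "S3")), "disjoint")
})

test_that("select_dmrs controls the false-selection rate on null matrices", {
  set.seed(31)
  hits <- replicate(8, {
    amf <- matrix(rnorm(40 * 400, 0.5, 0.05), 40, 400,
                  dimnames = list(paste0("S", 1:40), paste0("R", 1:400)))
    nrow(select_dmrs(amf, paste0("S", 1:20), paste0("S", 21:40), fdr = 0.05))
  })
  expect_lt(mean(hits) / 400, 0.05 * 2)
})

test_that("concordance_filter keeps direction-consistent markers only", {
  tis <- data.frame(region_id = c("R1", "R2", "R3"), comparison = "tumor-vs-adjacent",
                    target = "colorectal", direction = c("hyper", "hyper", "hypo"),
                    p_value = 1e-5, q_value = 1e-4)
  cf <- data.frame(region_id = c("R1", "R2", "R4"), comparison = "cfdna-cancer-vs-healthy",
                   target = "colorectal", direction = c("hyper", "hypo", "hyper"),
                   p_value = 1e-4, q_value = 1e-3)
  out <- concordance_filter(tis, cf)
  expect_equal(out$region_id, "R1")       # R2 flips direction, R4 absent in tissue
  # empty intersection is allowed
  out2 <- concordance_filter(tis[0, ], cf)
  expect_equal(nrow(out2), 0)
})

test_that("welch skip rule: regions with < 2 defined values are recorded, not fatal", {
  amf <- matrix(c(0.1, NA, NA, 0.5, 0.6, 0.7,
                  0.1, 0.2, 0.15, 0.5, 0.6, 0.7), 6, 2,
                dimnames = list(paste0("S", 1:6), c("R1", "R2")))
  mk <- select_dmrs(amf, paste0("S", 1:3), paste0("S", 4:6))
  expect_true("R1" %in% attr(mk, "skipped"))
  expect_equal(attr(mk, "n_tested"), 1)
})
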