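# helper: counts list with named bins
make_counts <- function(m) {
  list(bins = data.frame(bin_id = sprintf("b%02d", seq_len(nrow(m))),
                         stringsAsFactors = FALSE),
       counts = m)
}

test_that("normalize_bins matches the brute-force normalize-divide-log oracle", {
  set.seed(5)
  m <- matrix(rpois(8 * 6, 100), 8, 6,
              dimnames = list(NULL, paste0("S", 1:6)))
  healthy <- paste0("S", 1:4)
  cr <- normalize_bins(make_counts(m), healthy)
  # oracle: explicit loops
  tot <- colSums(m)
  dn <- m
  for (j in 1:6) dn[, j] <- m[, j] / (tot[j] / mean(tot))
  med <- apply(dn[, 1:4], 1, median)
  expect_equal(unname(cr$log2), unname(log2(dn / med)), tolerance = 1e-12)
  # a sample matching the healthy reference profile (at twice the depth)
  # has log2 ratio exactly 0 everywhere after depth normalization
  w <- matrix(rep(c(50L, 80L, 120L, 60L, 90L, 110L, 70L, 100L), 4), 8, 4,
              dimnames = list(NULL, paste0("S", 1:4)))
  mw <- cbind(w, Sx = 2L * w[, 1])
  crw <- normalize_bins(make_counts(mw), paste0("S", 1:4))
  expect_true(all(abs(crw$log2[, "Sx"]) < 1e-12))
  # one bin doubled: log2 ratio rises by exactly 1 minus the sample's own
  # depth-renormalization shift (the doubling inflates its total depth)
  m3 <- m
  m3[1, 5] <- m3[1, 5] * 2L
  cr3 <- normalize_bins(make_counts(m3), healthy)
  delta <- cr3$log2[1, "S5"] - cr$log2[1, "S5"]
  expect_equal(unname(delta), 1 - log2(sum(m3[, 5]) / sum(m[, 5])),
               tolerance = 1e-12)
  expect_error(normalize_bins(make_counts(m), paste0("S", 1:2)), "at least 3")
  m0 <- m; m0[, 1] <- 0L
  expect_error(normalize_bins(make_counts(m0), healthy), "all-zero")
})

test_that("zero-median bins are dropped and recorded", {
  m <- matrix(rpois(5 * 4, 50), 5, 4, dimnames = list(NULL, paste0("S", 1:4)))
  m[3, 1:3] <- 0L
  cr <- normalize_bins(make_counts(m), paste0("S", 1:3))
  expect_equal(cr$dropped_bins, "b03")
  expect_equal(nrow(cr$log2), 4)
})

test_that("call_alterations applies strict k-sigma rules", {
  # hand-built copy-ratio object: 2 bins, non-reference samples only
  lr <- matrix(c(0.2, 0.31, 0.1, -0.11, 0.0, 0.05), 2, 3,
               dimnames = list(c("b1", "b2"), paste0("S", 1:3)))
  cr <- structure(list(
    log2 = lr, healthy_mean = c(0.0, 0.01), healthy_sd = c(0.1, 0.05),
    healthy_sd_raw = c(0.1, 0.05), prior_df = 10, prior_var = 0.01^2,
    reference_ids = character(0), bins = NULL, dropped_bins = character(0)),
    class = "mced_copyratio")
  calls <- call_alterations(cr, k_sigma = 2)
  expect_equal(unname(calls["b1", ]), c(0L, 0L, 0L))  # 0.2 == mean + 2*0.1: strict
  expect_equal(unname(calls["b2", ]), c(1L, -1L, 0L)) # 0.31 > 0.11; -0.11 < -0.09
  # sigma = 0 bin calls on strict inequality against the mean
  cr$healthy_sd <- c(0, 0)
  calls0 <- call_alterations(cr, 2)
  expect_equal(unname(calls0["b1", ]), c(1L, 1L, 0L))   # 0.0 is not > mean 0
  expect_equal(unname(calls0["b2", ]), c(1L, -1L, 1L))  # strict vs mean 0.01
})

test_that("null healthy gain-call rate tracks the Gaussian 2-sigma tail", {
  set.seed(17)
  rates <- replicate(3, {
    m <- matrix(rnbinom(400 * 40, mu = 1000, size = 800), 400, 40,
                dimnames = list(NULL, paste0("S", 1:40)))
    cr <- normalize_bins(make_counts(m), paste0("S", 1:20))
    calls <- call_alterations(cr, 2)
    mean(calls[, 21:40] == 1L)
  })
  expect_gt(mean(rates), 0.012)
  expect_lt(mean(rates), 0.035)   # ~pnorm(-2) = 2.3%
})

test_that("select_cnv_markers enforces the alpha/beta prevalence rules", {
  # 30 samples: 20 healthy + 10 colorectal; craft calls per the examples
  calls <- matrix(0L, 3, 30,
                  dimnames = list(c("b1", "b2", "b3"), paste0("S", 1:30)))
  labels <- c(rep("healthy", 20), rep("colorectal", 10))
  calls["b1", 1:3] <- 1L                      # gained in 3/20 healthy (15%)
  calls["b1", 21:30] <- 1L
  calls["b2", 21:26] <- 1L                    # 0/20 healthy, 6/10 colorectal
  mk10 <- select_cnv_markers(calls, labels, alpha_pct = 10, beta_pct = 20)
  expect_false("b1" %in% mk10$bin_id)         # excluded: healthy 15% > 10%
  mk <- select_cnv_markers(calls, labels, alpha_pct = 5, beta_pct = 20)
  expect_true(all(c("b2") %in% mk$bin_id))
  expect_false("b1" %in% mk$bin_id)
  expect_equal(mk$direction[mk$bin_id == "b2"], "gain")
  # beta = 100 is an impossible prevalence: empty marker set
  expect_equal(nrow(select_cnv_markers(calls, labels, 5, 100)), 0)
  expect_error(select_cnv_markers(calls, labels, 0, 20), "alpha_pct")
  # post-exclusion invariant holds on every run
  expect_true(all(mk$healthy_freq < 0.05))
})

test_that("cnv_csd_score is the detected-marker fraction", {
  calls <- matrix(0L, 4, 2, dimnames = list(paste0("b", 1:4), c("S1", "S2")))
  calls[1, 1] <- 1L; calls[2, 1] <- -1L; calls[3, 1] <- 1L
  markers <- data.frame(bin_id = paste0("b", 1:4),
                        direction = c("gain", "loss", "loss", "gain"),
                        stringsAsFactors = FALSE)
  sc <- cnv_csd_score(calls, markers)
  expect_equal(unname(sc["S1"]), 0.5)   # b1 gain + b2 loss detected, b3 wrong dir
  expect_equal(unname(sc["S2"]), 0)
  calls[, 2] <- c(1L, -1L, -1L, 1L)
  expect_equal(unname(cnv_csd_score(calls, markers)["S2"]), 1)
  expect_error(cnv_csd_score(calls, markers[0, ]), "empty")
})

test_that("mean CNV score is non-decreasing in TF on simulated cohorts", {
  co <- small_cohort()
  sheet <- co$sheet
  plasma <- sheet[sheet$material == "plasma", ]
  healthy <- plasma$sample_id[plasma$label == "healthy"]
  cr <- normalize_bins(list(bins = co$bins$bins,
                            counts = co$bins$counts[, plasma$sample_id]),
                       healthy)
  calls <- call_alterations(cr)
  mk <- select_cnv_markers(calls, plasma$label)
  sc <- cnv_csd_score(calls, mk)
  cancer <- plasma$label != "healthy"
  grp <- cut(plasma$true_tf[cancer], c(-1, 0.05, 0.1, 2))
  mm <- tapply(sc[plasma$sample_id[cancer]], grp, mean)
  expect_true(all(diff(mm[!is.na(mm)]) >= 0))
})
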