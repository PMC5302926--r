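test_that("the bundled array yields a 0.15 ng limit for both target genes", {
  arr <- reference_dilution_array()
  for (gene in c("GFRA1", "P16")) {
    lim <- estimate_detection_limit(arr, gene)
    expect_s3_class(lim, "detection_limit")
    expect_equal(lim$limit_ng, 0.15)
    expect_equal(lim$n_conditions_at_limit, 4L)
  }
})

test_that("an all-FULL array returns the smallest amount present", {
  m <- data.frame(net_meth_ng = c(2, 1, 0.5, 0.25), gene = "G",
                  detection = "FULL", stringsAsFactors = FALSE)
  expect_equal(estimate_detection_limit(m, "G")$limit_ng, 0.25)
})

test_that("dropout at the largest amount raises a no-reliable-limit error", {
  m <- data.frame(net_meth_ng = c(2, 1), gene = "G",
                  detection = c("PARTIAL", "FULL"), stringsAsFactors = FALSE)
  expect_error(estimate_detection_limit(m, "G"),
               class = "methylgate_no_limit_error")
})

test_that("estimator equals the brute-force oracle on random arrays", {
  set.seed(42)
  for (i in 1:200) {
    arr <- random_array(sample(2:12, 1))
    oracle <- oracle_detection_limit(arr$net_meth_ng, arr$detection)
    if (is.na(oracle)) {
      expect_error(estimate_detection_limit(arr, "G"),
                   class = "methylgate_no_limit_error")
    } else {
      expect_equal(estimate_detection_limit(arr, "G")$limit_ng, oracle)
    }
  }
})

test_that("estimator is order-invariant and stable to adding FULL above it", {
  set.seed(7)
  arr <- random_array(10)
  # making the largest amount FULL guarantees a reliable limit exists
  arr$detection[which.max(arr$net_meth_ng)] <- "FULL"
  lim <- estimate_detection_limit(arr, "G")$limit_ng
  perm <- arr[sample(nrow(arr)), ]
  expect_equal(estimate_detection_limit(perm, "G")$limit_ng, lim)
  extra <- rbind(arr, data.frame(net_meth_ng = max(arr$net_meth_ng) * 2,
                                 gene = "G", detection = "FULL"))
  expect_equal(estimate_detection_limit(extra, "G")$limit_ng, lim)
})

test_that("degrading a FULL condition never decreases the limit", {
  set.seed(11)
  for (i in 1:50) {
    arr <- random_array(8)
    base <- tryCatch(estimate_detection_limit(arr, "G")$limit_ng,
                     error = function(e) Inf)
    full_idx <- which(arr$detection == "FULL")
    if (!length(full_idx)) next
    arr$detection[sample(full_idx, 1)] <- "PARTIAL"
    worse <- tryCatch(estimate_detection_limit(arr, "G")$limit_ng,
                      error = function(e) Inf)
    expect_gte(worse, base)
  }
})

test_that("derive_policy reproduces the reference gating rule", {
  pol <- reference_policy()
  expect_equal(round(pol$min_tait_ng, 1), 9.4)
  expect_equal(pol$min_tait_ng, 0.15 / 0.016)
  expect_equal(pol$ct_threshold, 29.3)
  expect_equal(pol$total_requirement_ng, 38)
  expect_equal(pol$n_reactions, 4L)
})

test_that("derive_policy handles degenerate and hand-computed cases", {
  # cutoff 1: a pure methylated sample needs exactly the detection limit
  expect_equal(derive_policy(0.15, 1, 1)$min_tait_ng, 0.15)
  p <- derive_policy(0.2, 0.01, 2)
  expect_equal(p$min_tait_ng, 20)
  expect_equal(p$total_requirement_ng, 40)
  expect_true(is.na(p$ct_threshold))
})

test_that("min TAIT scales as 1/cutoff and total requirement grows with reactions", {
  cutoffs <- c(0.004, 0.016, 0.05, 0.5)
  taits <- vapply(cutoffs, function(cf) derive_policy(0.15, cf, 1)$min_tait_ng,
                  numeric(1))
  expect_equal(taits, 0.15 / cutoffs)
  totals <- vapply(1:6, function(n) derive_policy(0.15, 0.016, n)$total_requirement_ng,
                   numeric(1))
  expect_true(all(diff(totals) >= 0))
})

test_that("Ct threshold interpolates on log2(amount) away from standard points", {
  sp <- data.frame(total_ng = c(16, 8, 4), mean_ref_ct = c(28, 29.25, 30.5))
  # 11.3 ng is >5% from all points: interpolate between 8 and 16 on log2
  pol <- derive_policy(0.1808, 0.016, 1, sp)   # min TAIT 11.3
  expect_equal(pol$ct_threshold,
               round(28 + (29.25 - 28) * (log2(16) - log2(11.3)) / 1, 1))
  # nearest-point rule takes over within 5%
  pol2 <- derive_policy(0.1296, 0.016, 1, sp)  # min TAIT 8.1
  expect_equal(pol2$ct_threshold, 29.2)        # uses the 8 ng point, 29.25
})

test_that("non-monotone standard points warn but still interpolate", {
  sp <- data.frame(total_ng = c(16, 8, 4), mean_ref_ct = c(28, 27.5, 30.5))
  expect_warning(pol <- derive_policy(0.1808, 0.016, 1, sp), "monotone")
  expect_false(is.na(pol$ct_threshold))
})

test_that("policies survive a write/read round trip", {
  pol <- reference_policy()
  path <- tempfile(fileext = ".policy")
  write_policy(pol, path)
  pol2 <- read_policy(path)
  expect_equal(pol2$min_tait_ng, pol$min_tait_ng)
  expect_equal(pol2$ct_threshold, pol$ct_threshold)
  expect_equal(pol2$total_requirement_ng, pol$total_requirement_ng)
  expect_equal(pol2$n_reactions, pol$n_reactions)
})
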