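pol <- reference_policy()

test_that("gate_sample applies the boundary-inclusive Ct rule", {
  expect_equal(gate_sample(list(mean_ct = 29.3, detection = "FULL"), pol),
               "INFORMATIVE")
  expect_equal(gate_sample(list(mean_ct = 32.9, detection = "FULL"), pol),
               "NON_INFORMATIVE")
  expect_equal(gate_sample(list(mean_ct = NA_real_, detection = "NONE"), pol),
               "NO_REFERENCE")
})

test_that("lowering the threshold never makes a sample more informative", {
  set.seed(3)
  cts <- runif(50, 25, 35)
  thresholds <- sort(runif(10, 26, 34), decreasing = TRUE)
  prev <- rep(TRUE, 50)
  for (th in thresholds) {
    inf <- gate_sample(list(mean_ct = cts, detection = "FULL"),
                       derive_policy(0.15, 0.016, 4,
                                     data.frame(total_ng = 1,
                                                mean_ref_ct = th))) ==
      "INFORMATIVE"
    expect_true(all(inf <= prev))   # monotone gate
    prev <- inf
  }
})

test_that("call_methylation requires full-replicate detection", {
  expect_equal(call_methylation(list(detection = "FULL")), "POSITIVE")
  expect_equal(call_methylation(list(detection = "PARTIAL")), "NEGATIVE")
  expect_equal(call_methylation(list(detection = "NONE")), "NEGATIVE")
  expect_equal(call_methylation("PARTIAL", partial = "indeterminate"),
               "INDETERMINATE")
})

test_that("pmr matches the delta-delta-Ct identities", {
  expect_equal(pmr(33, 28, 33, 28), 100)
  expect_equal(pmr(34, 28, 33, 28), 50)     # one extra cycle halves the PMR
  expect_equal(pmr(33, 28, 33, 28, efficiency = 1.74), 100)
  expect_equal(pmr(34, 28, 33, 28, efficiency = 1.74), 100 / 1.74)
  expect_warning(pmr(32, 28, 33, 28), "above 100")
  expect_error(pmr(NA, 28, 33, 28), "determined")
})

test_that("pmr decreases monotonically along the carrier-dilution axis", {
  arr <- reference_dilution_array()
  undiluted <- arr[arr$te_dilution == 1, ]
  g <- undiluted[undiluted$gene == "GFRA1", ]
  ref <- undiluted[undiluted$gene == "COL2A1", ]
  ord <- order(-g$meth_dilution)
  vals <- pmr(g$mean_ct[ord], ref$mean_ct[ord],
              g$mean_ct[ord][1], ref$mean_ct[ord][1])
  expect_true(all(diff(vals) < 0))
})

make_plate <- function(ids, ref_cts, target_det) {
  # target_det: per sample, "FULL"/"PARTIAL"/"NONE"
  do.call(rbind, lapply(seq_along(ids), function(i) {
    t_ct <- switch(target_det[i],
                   FULL = c(35, 35.2, 35.4),
                   PARTIAL = c(36, NA, 37),
                   NONE = c(NA_real_, NA, NA))
    data.frame(sample_id = ids[i],
               gene = rep(c("COL2A1", "GFRA1"), each = 3),
               role = rep(c("REFERENCE", "TARGET"), each = 3),
               replicate = rep(1:3, 2),
               ct = c(rep(ref_cts[i], 3), t_ct),
               stringsAsFactors = FALSE)
  }))
}

test_that("score_cohort gates and calls deterministically and idempotently", {
  plate <- make_plate(c("A", "B", "C"), c(28.0, 31.0, 29.3),
                      c("FULL", "PARTIAL", "FULL"))
  res <- score_cohort(plate, pol)
  expect_equal(res$informative,
               c("INFORMATIVE", "NON_INFORMATIVE", "INFORMATIVE"))
  expect_equal(res$call, c("POSITIVE", "NEGATIVE", "POSITIVE"))
  expect_equal(score_cohort(plate, pol), res)
})

test_that("external MSP/DHPLC calls are gated by the same reference rule", {
  plate <- make_plate(c("A", "B"), c(28.0, 31.0), c("NONE", "NONE"))
  ext <- data.frame(sample_id = c("A", "B"), gene = "P16",
                    call = c("POSITIVE", "NEGATIVE"),
                    stringsAsFactors = FALSE)
  res <- score_cohort(plate, pol, assay_kind = "MSP", external_calls = ext)
  expect_equal(res$assay_kind, c("MSP", "MSP"))
  expect_equal(res$informative, c("INFORMATIVE", "NON_INFORMATIVE"))
  expect_equal(res$call, c("POSITIVE", "NEGATIVE"))
})

test_that("reanalyze demands full coverage of non-informative samples", {
  plate <- make_plate(c("A", "B", "C"), c(28, 31, 32),
                      c("FULL", "NONE", "NONE"))
  res <- score_cohort(plate, pol)
  reassay <- make_plate("B", 28.5, "FULL")
  expect_error(reanalyze(res, reassay, pol), "missing.*C")
})

test_that("reanalyze applies pass-2 rules and flags persistent failures", {
  plate <- make_plate(c("A", "B", "C"), c(28, 31, 32),
                      c("FULL", "NONE", "NONE"))
  res <- score_cohort(plate, pol)
  # B becomes informative and positive; C is still above the threshold
  reassay <- make_plate(c("B", "C"), c(28.5, 30.5), c("FULL", "FULL"))
  ra <- reanalyze(res, reassay, pol)
  expect_equal(unique(ra$results$pass_index), 2L)
  expect_equal(ra$still_non_informative, "C")
  expect_equal(ra$summary$rate_before, 0)      # both were negative in pass 1
  expect_equal(ra$summary$rate_after, 100)     # B (informative) now positive
  expect_equal(ra$summary$n_reanalyzed, 2L)
})

test_that("reanalyze of an empty non-informative set is the identity", {
  plate <- make_plate("A", 28, "FULL")
  res <- score_cohort(plate, pol)
  ra <- reanalyze(res, plate, pol)
  expect_equal(nrow(ra$results), 0L)
  expect_equal(nrow(ra$summary), 0L)
  expect_length(ra$still_non_informative, 0L)
})
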