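clean_ntc <- classified_counts(15646, 1, 0, 0, well_id = "NTC")
thr <- decision_thresholds()

test_that("NTC quality control applies the per-channel false-positive ceiling", {
  expect_true(ntc_qc(classified_counts(15000, 0, 0, 0), thr)$pass)
  expect_true(ntc_qc(classified_counts(15000, 3, 4, 0), thr)$pass)
  fail <- ntc_qc(classified_counts(15000, 5, 0, 0), thr)
  expect_false(fail$pass)
  expect_equal(fail$fail_channels, "ch1")
})

test_that("threshold container rejects inconsistent limits", {
  expect_error(decision_thresholds(ntc_max_false_pos = 6, min_fetal_pos = 5),
               "below min_fetal_pos")
  expect_error(decision_thresholds(min_msp = -1), "non-negative")
})

test_that("calls over the full fetus-specific count range match the rule-table oracle", {
  ctx <- maternal_context("KEL_rs8176058", "KEL2/KEL2")
  for (fsp in 0:12) {
    sample <- classified_counts(14000, fsp, 760, 0,
                                well_id = paste0("fsp", fsp))
    res <- call_fetal_genotype(sample, clean_ntc, ctx, thr)
    oracle <- oracle_call_rules(fsp)
    if (oracle$verdict == "positive") {
      expect_equal(res$fetal_genotype_call, "KEL1/KEL2", label = fsp)
      expect_false(is.null(res$fetal_fraction))
      expect_gte(res$fsp, thr$min_fetal_pos)
    } else {
      expect_equal(res$fetal_genotype_call, "KEL2/KEL2", label = fsp)
      expect_null(res$fetal_fraction)
    }
    if (oracle$repeat_zone) {
      expect_equal(res$status, "REPEAT_RECOMMENDED", label = fsp)
      expect_true("repeat_zone" %in% res$qc_flags)
    } else {
      expect_equal(res$status, "CONCLUSIVE", label = fsp)
    }
  }
})

test_that("a failing NTC voids the run with no genotype call", {
  ctx <- maternal_context("RHD_ex7", "RHD-/RHD-")
  bad_ntc <- classified_counts(15646, 6, 0, 0, well_id = "NTC")
  sample <- classified_counts(15349, 47, 1540, 0, well_id = "S1")
  res <- call_fetal_genotype(sample, bad_ntc, ctx, thr)
  expect_equal(res$status, "QC_FAIL")
  expect_true(is.na(res$fetal_genotype_call))
  expect_null(res$fetal_fraction)
  expect_true(any(grepl("ntc_fail", res$qc_flags)))
})

test_that("RHD wells call presence/absence against the total-DNA control", {
  ctx <- maternal_context("RHD_ex7", "RHD-/RHD-")
  pos <- call_fetal_genotype(
    classified_counts(15349, 47, 1540, 0, well_id = "rhd_pos"),
    clean_ntc, ctx, thr)
  expect_equal(pos$fetal_genotype_call, "RHD/RHD-")
  expect_equal(pos$status, "CONCLUSIVE")
  expect_equal(pos$fsp, 47L)
  expect_equal(pos$msp, 1540L)
  expect_false(is.null(pos$fetal_fraction))

  neg <- call_fetal_genotype(
    classified_counts(15698, 0, 1457, 0, well_id = "rhd_neg"),
    clean_ntc, ctx, thr)
  expect_equal(neg$fetal_genotype_call, "RHD-/RHD-")
  expect_equal(neg$status, "CONCLUSIVE")
  expect_null(neg$fetal_fraction)
})

test_that("inadequate maternal signal or saturation yields INCONCLUSIVE, never a call", {
  ctx <- maternal_context("RHCE_rs676785", "cc")
  low <- call_fetal_genotype(classified_counts(14000, 150, 0, 0),
                             clean_ntc, ctx, thr)
  expect_equal(low$status, "INCONCLUSIVE")
  expect_true("low_msp" %in% low$qc_flags)
  expect_true(is.na(low$fetal_genotype_call))

  sat <- call_fetal_genotype(classified_counts(14000, 14000, 20, 20),
                             clean_ntc, ctx, thr)
  expect_equal(sat$status, "INCONCLUSIVE")
  expect_true("saturation" %in% sat$qc_flags)
})

test_that("counts in a user-configured gap between the limits refuse to call", {
  gap_thr <- decision_thresholds(ntc_max_false_pos = 2, min_fetal_pos = 8,
                                 repeat_halfwidth = 0)
  ctx <- maternal_context("RHCE_rs676785", "cc")
  res <- call_fetal_genotype(classified_counts(14000, 700, 5, 0),
                             clean_ntc, ctx, gap_thr)
  expect_equal(res$status, "INCONCLUSIVE")
  expect_true("undefined_zone" %in% res$qc_flags)
  expect_true(is.na(res$fetal_genotype_call))
})

test_that("increasing the fetus-specific count never flips a positive call negative", {
  ctx <- maternal_context("RHCE_rs609320", "ee")
  calls <- vapply(0:40, function(fsp) {
    res <- call_fetal_genotype(classified_counts(14000, 1450, fsp, 0),
                               clean_ntc, ctx, thr)
    !is.null(res$fetal_fraction)
  }, logical(1))
  # once positive, stays positive
  expect_true(all(diff(calls) >= 0))
})

test_that("the caller demands a valid homozygous maternal context", {
  expect_error(
    call_fetal_genotype(classified_counts(14000, 700, 10, 0), clean_ntc,
                        list(), thr),
    "maternal_context")
})
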