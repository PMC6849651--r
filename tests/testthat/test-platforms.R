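test_that("qRT-PCR calls apply the unevaluable rule before the ERG rule", {
  expect_equal(qpcr_call(46, 30), "negative")   # Ct_ERG >= 45
  expect_equal(qpcr_call(33, 39), NA_character_)  # Ct_GAPDH >= 38
  expect_equal(qpcr_call(33, 30), "positive")
  expect_equal(qpcr_call(NA, 30), "negative")   # undetectable ERG
  expect_equal(qpcr_call(33, NA), NA_character_)  # undetectable GAPDH
  expect_equal(qpcr_call(c(46, 33), c(30, 39)),
               c("negative", NA))
  expect_error(qpcr_call(-1, 30), "positive or NA")
})

test_that("fold difference is 2 to the delta Ct", {
  expect_equal(qpcr_fold(30, 30), 1)
  expect_equal(qpcr_fold(30, 33), 8)
  expect_equal(qpcr_fold(33, 30), 0.125)
})

test_that("score_qpcr annotates calls, delta Ct and fold", {
  qp <- tibble::tibble(patient = c("P1", "P2", "P3"),
                       ct_erg = c(30, 46, 33),
                       ct_gapdh = c(33, 30, 39))
  out <- score_qpcr(qp)
  expect_equal(out$call, c("positive", "negative", NA))
  expect_equal(out$fold[1], 8)
  expect_true(is.na(out$fold[3]))
})

test_that("any-negative combination predicts recurrence from any platform", {
  calls <- tibble::tibble(
    patient = sprintf("P%d", 1:4),
    nanostring = c("negative", "positive", NA, NA),
    qpcr = c("positive", "positive", "negative", NA))
  out <- combine_calls(calls)
  expect_equal(out$call, c("positive", "negative", "positive", NA))
  strict <- combine_calls(calls, rule = "all_negative")
  expect_equal(strict$call, c("negative", "negative", "positive", NA))
  maj <- combine_calls(calls, rule = "majority")
  expect_equal(maj$call, c("negative", "negative", "positive", NA))
  expect_error(combine_calls(calls[, 1:2]), ">= 2 platforms")
})

test_that("combined sensitivity dominates members, specificity is dominated", {
  co <- default_cohort()
  qp <- score_qpcr(co$qpcr)
  ihc <- co$ihc
  # ERG-negative status predicts recurrence on each platform
  plat <- tibble::tibble(
    patient = co$erg_state$patient,
    qpcr = qp$call[match(co$erg_state$patient, qp$patient)],
    ihc = ihc$call[match(co$erg_state$patient, ihc$patient)])
  comb <- combine_calls(plat)  # already a BCR prediction (positive = BCR)
  to_bcr <- function(v) ifelse(is.na(v), NA,
                               ifelse(v == "negative", "positive", "negative"))
  oc <- co$erg_state$outcome
  both <- !is.na(plat$qpcr) & !is.na(plat$ihc)
  cs_c <- confusion_summary(comb$call[both], oc[both])
  for (member in c("qpcr", "ihc")) {
    cs_m <- confusion_summary(to_bcr(plat[[member]])[both], oc[both])
    expect_gte(cs_c$sensitivity, cs_m$sensitivity)
    expect_lte(cs_c$specificity, cs_m$specificity)
  }
})

test_that("platform concordance reports pairwise and overall agreement", {
  calls <- tibble::tibble(
    patient = sprintf("P%d", 1:3),
    a = c("positive", "negative", "positive"),
    b = c("positive", "negative", "positive"),
    c = c("positive", "negative", "positive"))
  pc <- platform_concordance(calls)
  expect_true(all(pc$pairwise$agreement_pct == 100))
  expect_equal(pc$overall_pct, 100L)

  calls8 <- tibble::tibble(
    patient = sprintf("P%d", 1:8),
    a = rep("positive", 8),
    b = c(rep("positive", 5), rep("negative", 3)))
  pc8 <- platform_concordance(calls8)
  expect_equal(pc8$pairwise$agreement_pct, 63L)  # 5/8 rounded
  expect_error(platform_concordance(calls[, c("patient", "a")]),
               ">= 2 platforms")
})
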