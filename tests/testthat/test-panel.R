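test_that("cutoff selection maximizes sensitivity under the specificity floor", {
  values <- c(5, 8, 30, 25, 40, 50)
  outcome <- rep(c("BCR", "nonBCR"), each = 3)
  rule <- select_cutoff(values, outcome, min_specificity = 0.7)
  expect_gt(rule$cutoff, 8)
  expect_lte(rule$cutoff, 25)
  expect_equal(rule$sensitivity, 2 / 3)
  expect_equal(rule$specificity, 1)
  expect_true(rule$met_floor)
  # oracle: exhaustive sweep over all midpoints
  sv <- sort(unique(values))
  mids <- (sv[-1] + sv[-length(sv)]) / 2
  best <- max(vapply(mids, function(ct) {
    sens <- mean(values[outcome == "BCR"] < ct)
    spec <- mean(values[outcome == "nonBCR"] >= ct)
    if (spec >= 0.7) sens else -1
  }, numeric(1)))
  expect_equal(rule$sensitivity, best)
})

test_that("perfect separation yields sensitivity and specificity 1", {
  rule <- select_cutoff(c(2, 4, 30, 40), rep(c("BCR", "nonBCR"), each = 2))
  expect_equal(c(rule$sensitivity, rule$specificity), c(1, 1))
  expect_error(select_cutoff(c(1, 2), c("BCR", "BCR")), "both outcome classes")
})

test_that("an unreachable floor returns the most specific cutoff with a warning", {
  values <- c(10, 20, 30, 5, 15, 25)  # heavily overlapping
  outcome <- rep(c("BCR", "nonBCR"), each = 3)
  expect_warning(rule <- select_cutoff(values, outcome, min_specificity = 1.1),
                 "most specific")
  expect_false(rule$met_floor)
})

test_that("binarization uses strict less-than semantics at the cutoff", {
  rule <- tibble::tibble(cutoff = 20, direction = "down_in_BCR")
  expect_equal(binarize_counts(c(19, 20, 21, NA), rule),
               c("positive", "negative", "negative", NA))
  up <- tibble::tibble(cutoff = 20, direction = "up_in_BCR")
  expect_equal(binarize_counts(c(19, 20, 21), up),
               c("negative", "negative", "positive"))
  expect_error(binarize_counts(1, tibble::tibble(cutoff = -1, direction = "down_in_BCR")),
               "positive number")
})

test_that("confusion arithmetic matches the published worked examples", {
  # 15 of 21 recurrence patients called positive -> sensitivity 71%
  calls_bcr <- rep(c("positive", "negative"), c(15, 6))
  # 20 of 35 evaluable non-recurrence called negative, 7 unevaluable -> 57%
  calls_non <- rep(c("negative", "positive", NA), c(20, 15, 7))
  cs <- confusion_summary(c(calls_bcr, calls_non),
                          rep(c("BCR", "nonBCR"), c(21, 42)))
  expect_equal(cs$sensitivity_pct, 71L)
  expect_equal(cs$specificity_pct, 57L)
  expect_equal(cs$n_evaluable, 56)
  perfect <- confusion_summary(c("positive", "negative"), c("BCR", "nonBCR"))
  expect_equal(c(perfect$sensitivity_pct, perfect$specificity_pct), c(100L, 100L))
  none <- confusion_summary(c(NA, "negative"), c("BCR", "nonBCR"))
  expect_true(is.na(none$sensitivity))
})

test_that("confusion is invariant to patient order", {
  calls <- c("positive", "negative", NA, "positive")
  outcome <- c("BCR", "nonBCR", "BCR", "nonBCR")
  perm <- withr::with_seed(2, sample(4))
  expect_equal(confusion_summary(calls[perm], outcome[perm]),
               confusion_summary(calls, outcome))
})

test_that("greedy panel accepts only sensitivity gains within tolerance", {
  calls <- tibble::tibble(
    patient = sprintf("P%d", 1:6),
    A = c("positive", "positive", "negative", "negative", "negative", "negative"),
    B = c("negative", "negative", "positive", "negative", "negative", "negative"),
    C = c("positive", "positive", "negative", "negative", "negative", "negative"),
    D = c("negative", "negative", "negative", "positive", "negative", "negative"))
  outcome <- tibble::tibble(patient = sprintf("P%d", 1:6),
                            outcome = rep(c("BCR", "nonBCR"), each = 3))
  panel <- build_panel(calls, outcome, tolerance = 0)
  # B adds patient P3 with no false positives -> accepted
  expect_true("B" %in% panel$members)
  # C duplicates the current calls -> rejected (no sensitivity gain)
  expect_equal(panel$audit$action[panel$audit$probe == "C"], "reject")
  # D flags a non-BCR patient at tolerance 0 -> rejected
  expect_equal(panel$audit$action[panel$audit$probe == "D"], "reject")
  expect_equal(panel$confusion$sensitivity, 1)
  expect_equal(panel$confusion$specificity, 1)
  expect_error(build_panel(calls[, 1, drop = FALSE], outcome), "empty candidate")
})

test_that("panel sensitivity never falls and specificity never rises", {
  co <- default_cohort()
  norm <- default_normalized()
  tum <- co$samples[co$samples$tissue == "tumor", ]
  m <- as.matrix(norm[, -1]); rownames(m) <- norm$probe
  cands <- c("Pan.ERG", "ERG8", "GGT1", "HDAC1", "KLK2", "MYO6", "BICD1")
  calls <- purrr::map(cands, function(pr) {
    rule <- select_cutoff(m[pr, tum$sample], tum$outcome, probe = pr)
    binarize_counts(m[pr, tum$sample], rule)
  })
  calls <- dplyr::bind_cols(tibble::tibble(patient = tum$patient),
                            tibble::as_tibble(stats::setNames(calls, cands)))
  outcome <- tibble::tibble(patient = tum$patient, outcome = tum$outcome)
  panel <- build_panel(calls, outcome, tolerance = 0.05)
  acc <- panel$audit[panel$audit$action == "accept", ]
  expect_false(is.unsorted(acc$sensitivity_after))
  expect_false(is.unsorted(rev(acc$specificity_after)))
  # replaying the audit's accepted order reproduces the identical panel
  replay <- build_panel(calls, outcome, candidates = panel$members,
                        tolerance = 0.05)
  expect_identical(replay$members, panel$members)
  expect_equal(replay$confusion, panel$confusion)
})

test_that("concordance counts jointly evaluable agreement", {
  expect_equal(as.integer(call_concordance(c("positive", "negative"),
                                           c("positive", "negative"))), 100L)
  cc <- call_concordance(c("positive", "positive", "negative"),
                         c("positive", "negative", "negative"))
  expect_equal(as.integer(cc), 67L)
  expect_equal(attr(cc, "n"), 3L)
  expect_error(call_concordance(c(NA, NA), c("positive", "negative")),
               "no jointly evaluable")
})
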