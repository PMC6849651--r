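make_paired_sheet <- function(n) {
  tibble::tibble(
    sample = c(sprintf("P%d_T", 1:n), sprintf("P%d_N", 1:n)),
    patient = rep(sprintf("P%d", 1:n), 2),
    tissue = rep(c("tumor", "normal"), each = n),
    outcome = rep(rep(c("BCR", "nonBCR"), length.out = n), 2),
    lane = sprintf("L%d", 1:(2 * n)))
}

test_that("tumor/normal ratios behave on exact inputs", {
  sheet <- make_paired_sheet(3)
  m <- matrix(10, 2, 6, dimnames = list(c("A", "B"), sheet$sample))
  r <- compute_ratios(toy_counts(m), sheet, pseudocount = 0)
  expect_true(all(r$log2_ratio == 0))
  m[, 1:3] <- 20  # tumor = 2 x normal
  r2 <- compute_ratios(toy_counts(m), sheet, pseudocount = 0)
  expect_true(all(r2$log2_ratio == 1))
  m["A", "P1_N"] <- 0
  expect_warning(r3 <- compute_ratios(toy_counts(m), sheet, pseudocount = 0),
                 "non-finite")
  expect_false(any(r3$patient == "P1" & r3$probe == "A"))
})

test_that("unpaired patients are excluded with a warning", {
  sheet <- make_paired_sheet(3)[-4, ]  # drop P1 normal
  m <- matrix(5, 1, 5, dimnames = list("A", sheet$sample))
  expect_warning(r <- compute_ratios(toy_counts(m), sheet), "P1")
  expect_setequal(unique(r$patient), c("P2", "P3"))
})

test_that("identical groups give d = 0 and p = 1", {
  res <- sam_test(c(2, 2, 2), c(2, 2, 2), n_permutations = 100, seed = 1)
  expect_equal(res$d, 0)
  expect_equal(res$p_value, 1)
  expect_error(sam_test(1, c(1, 2)), ">= 2 observations")
})

test_that("3 vs 3 permutation p equals exhaustive enumeration", {
  cases <- list(
    list(x = c(1.2, 3.4, 2.2), y = c(5.0, 6.1, 4.9)),
    list(x = c(0.0, 0.1, -0.2), y = c(0.05, -0.1, 0.2)),
    list(x = c(10, 11, 12), y = c(10, 11, 12)))
  for (cs in cases) {
    got <- sam_test(cs$x, cs$y, n_permutations = 10000, seed = 1)
    expect_true(got$exhaustive)
    expect_equal(got$p_value, enumerate_sam_p(cs$x, cs$y), tolerance = 1e-12)
  }
})

test_that("d and p are invariant to shifts, scalings and label swaps", {
  x <- c(1.1, 2.3, 0.8, 1.9); y <- c(3.2, 2.8, 4.1, 3.3)
  base <- sam_test(x, y, n_permutations = 500, seed = 3)
  shift <- sam_test(x + 7, y + 7, n_permutations = 500, seed = 3)
  expect_equal(shift$d, base$d, tolerance = 1e-12)
  expect_equal(shift$p_value, base$p_value)
  scale <- sam_test(3 * x, 3 * y, n_permutations = 500, seed = 3)
  expect_equal(scale$d, base$d, tolerance = 1e-12)  # s0 = 0: fully scale-free
  expect_equal(scale$p_value, base$p_value)
  swap <- sam_test(y, x, n_permutations = 500, seed = 3)
  expect_equal(swap$d, -base$d, tolerance = 1e-12)
  expect_equal(swap$p_value, base$p_value)
})

test_that("run_differential covers exactly the endogenous probes", {
  co <- default_cohort()
  de <- default_diffexp()
  endo <- co$probes$probe[co$probes$class == "endogenous"]
  expect_setequal(de$probe, endo)
  expect_true(all(de$p_value > 0 & de$p_value <= 1))
  expect_true(all((de$delta > 0) == (de$direction == "up_in_BCR")))
})

test_that("simulated ERG loss is recovered as down in BCR", {
  de <- default_diffexp()
  erg <- de[de$probe %in% c("Pan.ERG", "ERG8", "ERG1.ERG2.ERG3",
                            "T2.ERG.exon4.fusion"), ]
  expect_true(all(erg$direction == "down_in_BCR"))
  # ERG probes carry more evidence than a typical null probe
  expect_lt(min(erg$p_value), median(de$p_value))
})

test_that("ratio mode needs paired samples and wilcoxon mode runs", {
  co <- default_cohort()
  norm <- default_normalized()
  tumor_only_sheet <- co$samples[co$samples$tissue == "tumor", ]
  expect_error(
    suppressWarnings(run_differential(norm, co$probes, tumor_only_sheet,
                                      mode = "tumor_vs_normal")),
    "pair")
  dw <- run_differential(norm, co$probes, co$samples, mode = "tumor_only",
                         test = "wilcoxon")
  expect_true(all(is.na(dw$d)))
  expect_true(all(dw$p_value > 0 & dw$p_value <= 1))
  erg_w <- dw[dw$probe %in% c("Pan.ERG", "ERG8", "ERG1.ERG2.ERG3",
                              "T2.ERG.exon4.fusion"), ]
  expect_true(all(erg_w$direction == "down_in_BCR"))
  expect_lt(min(erg_w$p_value), median(dw$p_value))
})

test_that("permutation p-values are reproducible under a fixed seed", {
  co <- default_cohort()
  norm <- default_normalized()
  a <- run_differential(norm, co$probes, co$samples, n_permutations = 300, seed = 11)
  b <- run_differential(norm, co$probes, co$samples, n_permutations = 300, seed = 11)
  expect_identical(a$p_value, b$p_value)
})
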