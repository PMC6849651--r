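test_that("default cohort has the study's dimensions and pairing", {
  co <- default_cohort()
  expect_equal(nrow(co$counts), 151)
  expect_equal(ncol(co$counts), 127)  # probe column + 126 samples
  pat <- dplyr::distinct(co$samples, patient, outcome)
  expect_equal(sum(pat$outcome == "BCR"), 21)
  expect_equal(sum(pat$outcome == "nonBCR"), 42)
  # every patient has exactly one tumor and one normal sample
  tab <- table(co$samples$patient, co$samples$tissue)
  expect_true(all(tab == 1))
  m <- as.matrix(co$counts[, -1])
  expect_true(all(m >= 0) && all(m == floor(m)))
  # truth covers every endogenous probe
  endo <- co$probes$probe[co$probes$class == "endogenous"]
  expect_setequal(co$truth$probe, endo)
  expect_equal(dplyr::count(co$probes, class)$n[order(dplyr::count(co$probes, class)$class)],
               c(126, 11, 8, 6))
})

test_that("a fixed seed reproduces the cohort bitwise", {
  a <- simulate_cohort(sim_params(seed = 7))
  b <- simulate_cohort(sim_params(seed = 7))
  expect_identical(a$counts, b$counts)
  expect_identical(a$qpcr, b$qpcr)
  expect_identical(a$ihc, b$ihc)
  c2 <- simulate_cohort(sim_params(seed = 8))
  expect_false(identical(a$counts, c2$counts))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulate_cohort(sim_params(seed = 5)))
  expect_identical(runif(1), before)
})

test_that("all four ERG probes follow the shared latent state", {
  co <- default_cohort()
  m <- as.matrix(co$counts[, -1])
  rownames(m) <- co$counts$probe
  tum <- co$samples$sample[co$samples$tissue == "tumor"]
  state <- co$erg_state$erg_positive[
    match(sub("_T$", "", tum), co$erg_state$patient)]
  for (pr in c("Pan.ERG", "ERG8", "ERG1.ERG2.ERG3", "T2.ERG.exon4.fusion")) {
    hi <- m[pr, tum][state]
    lo <- m[pr, tum][!state]
    expect_gt(min(hi), max(lo))  # bimodal separation in tumor counts
  }
})

test_that("qRT-PCR cycles encode the latent state and the unevaluable rule", {
  co <- default_cohort()
  expect_true(all(co$qpcr$ct_erg[!is.na(co$qpcr$ct_erg)] > 0))
  # patients scored low-ERG by the generator sit at or beyond cycle 45
  low <- co$qpcr$ct_erg >= 45
  expect_true(any(low) && any(!low))
  expect_true(all(co$ihc$call %in% c("positive", "negative")))
})

test_that("invalid parameters fail with the field named", {
  expect_error(sim_params(erg_pos_frac_bcr = 1.5), "erg_pos_frac_bcr")
  expect_error(sim_params(dispersion = -1), "dispersion")
  expect_error(sim_params(neg_mu = 0), "neg_mu")
  expect_error(sim_params(n_bcr = -1), "n_bcr")
  expect_error(simulate_cohort(sim_params(effect_log2fc = c(NOPE = 1))),
               "effect_log2fc")
})

test_that("cohort fixtures round-trip through CSV", {
  co <- simulate_cohort(sim_params(seed = 3))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(as.data.frame(back$counts), as.data.frame(co$counts))
  expect_equal(as.data.frame(back$samples), as.data.frame(co$samples))
  expect_equal(back$qpcr$ct_erg, co$qpcr$ct_erg, tolerance = 1e-12)
  # truth file covers exactly the endogenous probes
  endo <- sum(co$probes$class == "endogenous")
  expect_equal(nrow(back$truth), endo)
  # writing twice is byte-identical (seeded provenance header included)
  dir2 <- withr::local_tempdir()
  write_cohort(co, dir2)
  expect_identical(readLines(file.path(dir, "counts.csv")),
                   readLines(file.path(dir2, "counts.csv")))
})

test_that("an empty cohort cannot be written", {
  co <- simulate_cohort(sim_params(seed = 1))
  co$counts <- co$counts[, 1, drop = FALSE]
  expect_error(write_cohort(co, withr::local_tempdir()), "empty cohort")
})
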