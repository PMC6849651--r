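# Lane-level QC and the three normalization steps: positive-control scaling,
# background subtraction (mean of negative controls + 2 SD), housekeeping
# scaling. Every sample occupies one cartridge lane, so factors are per
# sample column. Normalized matrices are defined up to one run-level
# constant fixed by the reference convention (arithmetic mean of per-lane
# geometric means by default); all downstream statistics are invariant to
# that constant.

probes_of_class <- function(probes, cls) probes$probe[probes$class == cls]

#' Lane quality control: spike linearity and sensitivity
#'
#' For each lane, fits log2(count + 1) of the positive controls against
#' log2(spike concentration in fM) by least squares and reports the R
#' squared, plus a detection flag for the 0.5 fM spike (count above that
#' lane's background threshold, mean of negative controls + 2 SD). A lane
#' passes when R squared exceeds 0.95 and the 0.5 fM spike is detected.
#'
#' @param counts Raw wide count tibble.
#' @param probes Probe annotation.
#' @param sheet Optional sample sheet used to attach lane ids.
#' @param r2_min Linearity threshold (default 0.95).
#' @return A tibble of class `bcr_lane_qc`: one row per sample with
#'   `r_squared`, `detected_05fM`, `background_threshold`, `pass`, `reason`.
#' @export
lane_qc <- function(counts, probes, sheet = NULL, r2_min = 0.95) {
  m <- counts_to_matrix(counts)
  pos <- intersect(probes_of_class(probes, "positive"), rownames(m))
  neg <- intersect(probes_of_class(probes, "negative"), rownames(m))
  if (length(pos) == 0L)
    abort("lane_qc: no positive-control probes", class = "bcrpanel_validation_error")
  conc <- probes$spike_fM[match(pos, probes$probe)]
  if (length(unique(conc)) < 3L)
    abort("lane_qc: need >= 3 positive controls with distinct concentrations",
          class = "bcrpanel_validation_error")
  if (length(neg) < 2L)
    abort("lane_qc: need >= 2 negative-control probes",
          class = "bcrpanel_validation_error")
  sens_probe <- if (any(conc == 0.5)) pos[which(conc == 0.5)[1]] else pos[which.min(conc)]
  lx <- log2(conc)
  out <- purrr::map_dfr(colnames(m), function(s) {
    y <- log2(m[pos, s] + 1)
    thr <- mean(m[neg, s]) + 2 * sd(m[neg, s])
    if (sd(y) == 0) {
      tibble::tibble(sample = s, r_squared = NA_real_,
                     detected_05fM = m[sens_probe, s] > thr,
                     background_threshold = thr, pass = FALSE,
                     reason = "zero spike variance")
    } else {
      r2 <- stats::cor(lx, y)^2
      det <- m[sens_probe, s] > thr
      pass <- r2 > r2_min && det
      reason <- if (pass) NA_character_
                else if (r2 <= r2_min) sprintf("R squared %.4f <= %.2f", r2, r2_min)
                else "0.5 fM spike not detected above background"
      tibble::tibble(sample = s, r_squared = r2, detected_05fM = det,
                     background_threshold = thr, pass = pass, reason = reason)
    }
  })
  if (!is.null(sheet))
    out <- dplyr::left_join(out, dplyr::select(sheet, "sample", "lane"), by = "sample")
  class(out) <- c("bcr_lane_qc", class(out))
  out
}

per_lane_factors <- function(m, ids, reference, what) {
  g <- apply(m[ids, , drop = FALSE], 2, geo_mean)
  ref <- switch(reference, arithmetic = mean(g), geometric = geo_mean(g),
                abort(sprintf("%s: unknown reference '%s'", what, reference)))
  ref / g
}

#' Positive-control scaling factors
#'
#' Per-lane factor = (reference across lanes) / (per-lane geometric mean of
#' positive-control counts); multiplying each lane by its factor equalizes
#' positive-control geometric means, correcting assay-efficiency differences.
#'
#' @param counts Wide count tibble.
#' @param probes Probe annotation.
#' @param reference `"arithmetic"` (default: arithmetic mean of per-lane
#'   geometric means) or `"geometric"`; the choice moves all lanes by one
#'   global constant only.
#' @return Named numeric vector of per-lane factors.
#' @export
positive_factors <- function(counts, probes, reference = "arithmetic") {
  m <- counts_to_matrix(counts)
  pos <- intersect(probes_of_class(probes, "positive"), rownames(m))
  if (length(pos) == 0L)
    abort("positive_factors: no positive-control probes",
          class = "bcrpanel_validation_error")
  if (any(m[pos, ] == 0))
    abort("positive_factors: zero positive-control count (log of zero)",
          class = "bcrpanel_validation_error")
  per_lane_factors(m, pos, reference, "positive_factors")
}

#' Housekeeping scaling factors
#'
#' Per-lane factor equalizing the geometric mean of the housekeeping genes
#' across lanes, to account for sample-input variation. Housekeeping values
#' of zero (possible after background subtraction) take a pseudocount before
#' the geometric mean; this is reported, not an error.
#'
#' @inheritParams positive_factors
#' @param pseudocount Added to housekeeping values when any is zero.
#' @return Named numeric vector of per-lane factors.
#' @export
housekeeping_factors <- function(counts, probes, reference = "arithmetic",
                                 pseudocount = 0.5) {
  m <- counts_to_matrix(counts)
  hk <- intersect(probes_of_class(probes, "housekeeping"), rownames(m))
  if (length(hk) == 0L)
    abort("housekeeping_factors: no housekeeping probes",
          class = "bcrpanel_validation_error")
  if (any(m[hk, ] == 0))
    inform(sprintf(
      "housekeeping_factors: zero housekeeping value(s); using pseudocount %g",
      pseudocount))
  g <- apply(m[hk, , drop = FALSE], 2, geo_mean, pseudocount = pseudocount)
  ref <- switch(reference, arithmetic = mean(g), geometric = geo_mean(g),
                abort("housekeeping_factors: unknown reference"))
  ref / g
}

#' Background subtraction from negative controls
#'
#' Per lane, the background threshold is the mean of the negative-control
#' counts plus two standard deviations (sample SD, n - 1 denominator).
#' In `"subtract"` mode (default) the threshold is subtracted from every
#' value and results are clamped at zero, so sub-threshold signals become
#' exactly 0; in `"zero"` mode sub-threshold values are zeroed and the rest
#' left untouched.
#'
#' @inheritParams positive_factors
#' @param mode `"subtract"` or `"zero"`.
#' @return A wide count tibble, stage `"background_subtracted"`, carrying the
#'   per-lane thresholds in attribute `"background_threshold"`.
#' @export
background_subtract <- function(counts, probes, mode = c("subtract", "zero")) {
  mode <- match.arg(mode)
  m <- counts_to_matrix(counts)
  neg <- intersect(probes_of_class(probes, "negative"), rownames(m))
  if (length(neg) < 2L)
    abort("background_subtract: need >= 2 negative controls (SD undefined)",
          class = "bcrpanel_validation_error")
  thr <- apply(m[neg, , drop = FALSE], 2, function(v) mean(v) + 2 * sd(v))
  out <- if (mode == "subtract") {
    pmax(sweep(m, 2, thr, `-`), 0)
  } else {
    below <- sweep(m, 2, thr, `<`)
    m * !below
  }
  res <- matrix_to_counts(out, stage = "background_subtracted")
  attr(res, "background_threshold") <- thr
  res
}

#' Full count normalization pipeline
#'
#' Applies, in order: positive-control scaling, background subtraction,
#' housekeeping scaling. After normalization the per-lane housekeeping
#' geometric means are equal across lanes (to floating-point precision).
#'
#' @inheritParams positive_factors
#' @param sheet Optional sample sheet (unused by the arithmetic, kept for a
#'   uniform stage interface).
#' @param background_mode Passed to [background_subtract()].
#' @param pseudocount Passed to [housekeeping_factors()].
#' @return A wide count tibble, stage `"normalized"`, with attribute
#'   `"factors"`: a tibble of per-sample positive factor, background
#'   threshold and housekeeping factor.
#' @export
normalize_counts <- function(counts, probes, sheet = NULL,
                             background_mode = c("subtract", "zero"),
                             reference = "arithmetic", pseudocount = 0.5) {
  background_mode <- match.arg(background_mode)
  validate_count_matrix(counts, stage = count_stage(counts) %||% "raw")
  pf <- positive_factors(counts, probes, reference = reference)
  m <- counts_to_matrix(counts)
  m <- sweep(m, 2, pf, `*`)
  bs <- background_subtract(matrix_to_counts(m, "raw"), probes,
                            mode = background_mode)
  thr <- attr(bs, "background_threshold")
  hf <- housekeeping_factors(bs, probes, reference = reference,
                             pseudocount = pseudocount)
  out <- sweep(counts_to_matrix(bs), 2, hf, `*`)
  res <- matrix_to_counts(out, stage = "normalized")
  attr(res, "factors") <- tibble::tibble(
    sample = colnames(out), positive_factor = unname(pf),
    background_threshold = unname(thr), housekeeping_factor = unname(hf))
  res
}
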