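# Storey-Tibshirani false discovery rates: pi0 estimation with spline
# smoothing over a lambda grid, step-up q-values, expected false positives
# (q x rank), and the rounded-inclusive significance filter.

#' Estimate the null proportion pi0 (Storey-Tibshirani)
#'
#' Computes `pi0(lambda) = #\{p > lambda\} / (m * (1 - lambda))` over a grid
#' of lambda values, smooths with a natural cubic spline (3 df) and takes
#' the smoothed value at the largest lambda, clamped into (0, 1]. With fewer
#' than 20 p-values the tail counts are too unstable and pi0 falls back to 1
#' (reported via a message).
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param lambda Grid of lambda values (default 0.05 to 0.95 by 0.05).
#' @return A list of class `pi0_estimate`: `pi0`, `pi0_smooth` (unclamped),
#'   `lambda`, `pi0_lambda`, `m`, `fallback`.
#' @export
estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  if (length(p) == 0L) abort("estimate_pi0: empty p-value vector",
                             class = "bcrpanel_validation_error")
  if (anyNA(p) || any(p < 0 | p > 1))
    abort("estimate_pi0: p-values must lie in [0, 1]",
          class = "bcrpanel_validation_error")
  m <- length(p)
  if (m < 20L) {
    inform(sprintf("estimate_pi0: only %d p-values; falling back to pi0 = 1", m))
    out <- list(pi0 = 1, pi0_smooth = 1, lambda = lambda,
                pi0_lambda = rep(NA_real_, length(lambda)), m = m,
                fallback = TRUE)
    class(out) <- "pi0_estimate"
    return(out)
  }
  pi0_lambda <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)), numeric(1))
  fit <- smooth.spline(lambda, pi0_lambda, df = 3)
  pi0_smooth <- predict(fit, x = max(lambda))$y
  pi0 <- min(max(pi0_smooth, .Machine$double.eps), 1)
  out <- list(pi0 = pi0, pi0_smooth = pi0_smooth, lambda = lambda,
              pi0_lambda = pi0_lambda, m = m, fallback = FALSE)
  class(out) <- "pi0_estimate"
  out
}

#' @export
print.pi0_estimate <- function(x, ...) {
  cat(sprintf("<pi0_estimate> pi0 = %.4f (smoothed %.4f over %d p-values%s)\n",
              x$pi0, x$pi0_smooth, x$m,
              if (x$fallback) ", small-m fallback" else ""))
  invisible(x)
}

#' Storey q-values from p-values
#'
#' On p-values sorted ascending, `q_(i) = min_(j >= i) pi0 * m * p_(j) / j`,
#' capped at 1; tied p-values share the smaller q, ranks are made
#' deterministic by a stable sort on the probe id, and the output is
#' returned in the original order.
#'
#' @param p Vector of p-values.
#' @param pi0 Null proportion in (0, 1]; default estimates it via
#'   [estimate_pi0()].
#' @param id Optional ids used for deterministic tie-breaking (default the
#'   input order).
#' @return A tibble: `id`, `p_value`, `rank` (ascending p, 1-based),
#'   `q_value`, `expected_fp` (exact product `q * rank`).
#' @export
compute_qvalues <- function(p, pi0 = NULL, id = NULL) {
  if (length(p) == 0L) abort("compute_qvalues: empty input",
                             class = "bcrpanel_validation_error")
  if (anyNA(p) || any(p < 0 | p > 1))
    abort("compute_qvalues: p-values must lie in [0, 1]",
          class = "bcrpanel_validation_error")
  if (is.null(id)) id <- sprintf("item_%04d", seq_along(p))
  if (length(id) != length(p) || anyDuplicated(id))
    abort("compute_qvalues: `id` must be unique and match `p` in length",
          class = "bcrpanel_validation_error")
  if (is.null(pi0)) pi0 <- estimate_pi0(p)$pi0
  if (length(pi0) != 1L || is.na(pi0) || pi0 <= 0 || pi0 > 1)
    abort("compute_qvalues: pi0 must lie in (0, 1]",
          class = "bcrpanel_validation_error")
  m <- length(p)
  ord <- order(p, id)
  ps <- p[ord]
  q_sorted <- pmin(rev(cummin(rev(pi0 * m * ps / seq_len(m)))), 1)
  rank_sorted <- seq_len(m)
  out <- tibble::tibble(
    id = id[ord], p_value = ps, rank = rank_sorted,
    q_value = q_sorted, expected_fp = q_sorted * rank_sorted)
  out[match(id, out$id), , drop = FALSE]
}

#' Expected false positives among the top-ranked probes
#'
#' The product of a probe's q-value and its rank, rounded (default 3
#' decimals) for reporting: the expected number of false positives incurred
#' by calling everything up to that rank significant. Rounding is
#' decimal-faithful, so products of printed decimals behave as on paper
#' (q = 0.04225 at rank 10 gives 0.422).
#'
#' @param q q-value(s) in \[0, 1\].
#' @param rank Rank(s), 1-based.
#' @param digits Decimals for reporting (default 3).
#' @return Numeric vector of expected false positives.
#' @examples
#' expected_fp(0.00287, 1)   # 0.003
#' expected_fp(0.04225, 10)  # 0.422
#' @export
expected_fp <- function(q, rank, digits = 3) {
  if (any(q < 0 | q > 1, na.rm = TRUE))
    abort("expected_fp: q must lie in [0, 1]", class = "bcrpanel_validation_error")
  if (any(rank < 1, na.rm = TRUE))
    abort("expected_fp: rank must be >= 1", class = "bcrpanel_validation_error")
  round_dec(q * rank, digits)
}

#' Significance filter with rounded-inclusive cutoff
#'
#' A probe passes when its q-value, rounded to `digits` decimals, is at most
#' the cutoff. The rounding makes the boundary inclusive the way the
#' published table is: a probe with q = 0.07502 counts as significant at
#' cutoff 0.075. Probes are additionally collapsed to genes (all
#' ERG-targeting probe sets report the single gene ERG).
#'
#' @param fdr A tibble with columns `probe`, `q_value` and (optionally)
#'   `gene`; typically from [compute_fdr()].
#' @param q_cutoff Significance cutoff in (0, 1).
#' @param digits Decimals used for the rounded comparison (default 3).
#' @return A list of class `bcr_significant`: `table` (passing rows),
#'   `probes`, `genes`, `q_cutoff`.
#' @export
filter_significant <- function(fdr, q_cutoff, digits = 3) {
  if (!is.numeric(q_cutoff) || length(q_cutoff) != 1L ||
      q_cutoff <= 0 || q_cutoff >= 1)
    abort("filter_significant: q_cutoff must lie in (0, 1)",
          class = "bcrpanel_validation_error")
  if (!all(c("probe", "q_value") %in% names(fdr)))
    abort("filter_significant: `fdr` needs columns probe, q_value")
  pass <- round_dec(fdr$q_value, digits) <= q_cutoff
  tab <- fdr[pass, , drop = FALSE]
  genes <- if ("gene" %in% names(tab)) unique(tab$gene) else unique(tab$probe)
  out <- list(table = tab, probes = tab$probe, genes = genes,
              q_cutoff = q_cutoff)
  class(out) <- "bcr_significant"
  out
}

#' @export
print.bcr_significant <- function(x, ...) {
  cat(sprintf("<bcr_significant> %d probe set(s), %d gene(s) at q <= %.3f\n",
              length(x$probes), length(x$genes), x$q_cutoff))
  if (length(x$genes)) cat("  genes:", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' Full FDR table from a differential-expression result
#'
#' Estimates pi0 from the p-values, computes q-values and expected false
#' positives, and returns a ranked table shaped like the published one
#' (probe, p, q, expected FP, direction).
#'
#' @param diffexp A `bcr_diffexp` tibble from [run_differential()].
#' @param lambda Lambda grid for [estimate_pi0()].
#' @param pi0 Optional fixed pi0 overriding the estimate.
#' @return A tibble of class `bcr_fdr`, sorted by rank, with attribute
#'   `"pi0"` (the `pi0_estimate`).
#' @export
compute_fdr <- function(diffexp, lambda = seq(0.05, 0.95, by = 0.05),
                        pi0 = NULL) {
  need <- c("probe", "p_value")
  if (!all(need %in% names(diffexp)))
    abort("compute_fdr: input needs columns probe, p_value")
  est <- if (is.null(pi0)) estimate_pi0(diffexp$p_value, lambda = lambda)
         else structure(list(pi0 = pi0, fallback = FALSE), class = "pi0_estimate")
  qt <- compute_qvalues(diffexp$p_value, pi0 = est$pi0, id = diffexp$probe)
  out <- tibble::tibble(
    probe = qt$id,
    gene = if ("gene" %in% names(diffexp))
      diffexp$gene[match(qt$id, diffexp$probe)] else qt$id,
    mode = if ("mode" %in% names(diffexp))
      diffexp$mode[match(qt$id, diffexp$probe)] else NA_character_,
    p_value = qt$p_value, rank = qt$rank, q_value = qt$q_value,
    expected_fp = qt$expected_fp,
    direction = if ("direction" %in% names(diffexp))
      diffexp$direction[match(qt$id, diffexp$probe)] else NA_character_)
  out <- dplyr::arrange(out, .data$rank)
  attr(out, "pi0") <- est
  class(out) <- c("bcr_fdr", class(out))
  out
}
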