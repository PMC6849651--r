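# Per-probe two-group differential expression, BCR vs non-BCR, in the style
# of the Significance Analysis of Microarrays: a moderated d-statistic with
# an exchangeability constant s0, and two-sided permutation p-values over
# outcome-label permutations (full enumeration when feasible).

#' Per-patient tumor/normal log2 ratios
#'
#' @param counts Normalized wide count tibble.
#' @param sheet Sample sheet pairing tumor and normal samples by patient.
#' @param pseudocount Added to both tissues before the ratio; with
#'   `pseudocount = 0`, patient/probe pairs with a zero normal value are
#'   excluded with a warning.
#' @return A tibble of class `bcr_ratio`: `patient`, `probe`, `log2_ratio`.
#' @export
compute_ratios <- function(counts, sheet, pseudocount = 1) {
  m <- counts_to_matrix(counts)
  sheet <- sheet[sheet$sample %in% colnames(m), , drop = FALSE]
  wide <- tidyr::pivot_wider(
    dplyr::select(sheet, "patient", "tissue", "sample"),
    names_from = "tissue", values_from = "sample")
  if (!all(c("tumor", "normal") %in% names(wide)))
    wide[setdiff(c("tumor", "normal"), names(wide))] <- NA_character_
  unpaired <- wide$patient[is.na(wide$tumor) | is.na(wide$normal)]
  if (length(unpaired)) {
    warn(sprintf("compute_ratios: excluding unpaired patient(s): %s",
                 paste(unpaired, collapse = ", ")))
    wide <- wide[!wide$patient %in% unpaired, , drop = FALSE]
  }
  if (nrow(wide) == 0L)
    abort("compute_ratios: no tumor/normal pairs", class = "bcrpanel_validation_error")
  tum <- m[, wide$tumor, drop = FALSE] + pseudocount
  nor <- m[, wide$normal, drop = FALSE] + pseudocount
  ratio <- log2(tum / nor)
  colnames(ratio) <- wide$patient
  out <- tidyr::pivot_longer(
    tibble::as_tibble(ratio, rownames = "probe"),
    -"probe", names_to = "patient", values_to = "log2_ratio")
  bad <- !is.finite(out$log2_ratio)
  if (any(bad)) {
    warn(sprintf(
      "compute_ratios: %d non-finite ratio(s) (zero counts with pseudocount 0); excluded",
      sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  out <- dplyr::select(out, "patient", "probe", "log2_ratio")
  class(out) <- c("bcr_ratio", class(out))
  out
}

sam_d <- function(x, y, s0 = 0) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  s <- sqrt(sp2 * (1 / n1 + 1 / n2))
  list(d = (mean(x) - mean(y)) / (s + s0), s = s)
}

# Group-1 membership indicator matrix (n x B) over label permutations.
# Exhaustive when the number of distinct assignments fits the budget.
permutation_sets <- function(n, n1, n_permutations, seed) {
  n_all <- choose(n, n1)
  if (n_all <= n_permutations) {
    idx <- combn(n, n1)
    g <- matrix(0, n, ncol(idx))
    g[cbind(as.vector(idx), rep(seq_len(ncol(idx)), each = n1))] <- 1
    list(g = g, exhaustive = TRUE)
  } else {
    g <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(i) {
        v <- numeric(n); v[sample.int(n, n1)] <- 1; v
      }, numeric(n))
    })
    list(g = g, exhaustive = FALSE)
  }
}

# Vectorized d-statistics for a probe-by-sample value matrix under a set of
# group-1 indicator columns.
d_matrix <- function(X, G, s0) {
  n1 <- colSums(G)[1]; n <- nrow(G); n2 <- n - n1
  M1 <- (X %*% G) / n1
  M2 <- (X %*% (1 - G)) / n2
  S1 <- (X^2 %*% G)
  S2 <- (X^2 %*% (1 - G))
  ss_within <- pmax((S1 - n1 * M1^2) + (S2 - n2 * M2^2), 0)
  s <- sqrt(ss_within / (n - 2) * (1 / n1 + 1 / n2))
  diff <- M1 - M2
  d <- diff / (s + s0)
  d[diff == 0 & (s + s0) == 0] <- 0  # constant data: no evidence either way
  d
}

perm_pvalues <- function(X, labels1, n_permutations, seed, s0) {
  n <- ncol(X)
  n1 <- sum(labels1)
  perms <- permutation_sets(n, n1, n_permutations, seed)
  obs <- d_matrix(X, matrix(as.numeric(labels1), ncol = 1), s0)[, 1]
  D <- abs(d_matrix(X, perms$g, s0))
  tol <- 1e-12
  hits <- rowSums(D >= abs(obs) * (1 - tol) - tol)
  p <- if (perms$exhaustive) hits / ncol(perms$g) else (1 + hits) / (1 + ncol(perms$g))
  list(d = obs, p = pmin(p, 1), exhaustive = perms$exhaustive)
}

#' SAM-style two-group permutation test for a single probe
#'
#' The statistic is `d = (mean(x) - mean(y)) / (s + s0)` with `s` the pooled
#' standard error and `s0` an exchangeability constant (0 for a single
#' probe; [run_differential()] sets it from a quantile of all probes' pooled
#' SEs). The two-sided p-value is estimated over outcome-label permutations,
#' with the add-one correction `(1 + hits) / (1 + B)` for sampled
#' permutations and exact enumeration whenever the number of distinct label
#' assignments is within the permutation budget.
#'
#' @param x,y Numeric vectors of values per group (each length >= 2).
#' @param n_permutations Permutation budget (default 10000).
#' @param seed Seed for sampled permutations.
#' @param s0 Exchangeability constant added to the denominator.
#' @return A one-row tibble: `d`, `p_value`, `exhaustive`.
#' @examples
#' sam_test(c(1, 2, 3), c(4, 5, 7), n_permutations = 1000, seed = 1)
#' @export
sam_test <- function(x, y, n_permutations = 10000, seed = 1L, s0 = 0) {
  if (length(x) < 2L || length(y) < 2L)
    abort("sam_test: each group needs >= 2 observations",
          class = "bcrpanel_validation_error")
  X <- matrix(c(x, y), nrow = 1)
  labels1 <- c(rep(TRUE, length(x)), rep(FALSE, length(y)))
  res <- perm_pvalues(X, labels1, n_permutations, seed, s0)
  tibble::tibble(d = res$d, p_value = res$p, exhaustive = res$exhaustive)
}

#' Differential expression over all endogenous probes
#'
#' Two analysis modes mirror the study: `tumor_only` compares
#' `log2(normalized count + 1)` in tumor samples between BCR and non-BCR
#' patients; `tumor_vs_normal` compares the per-patient paired tumor/normal
#' log2 ratio between the groups. Control and housekeeping probes are
#' excluded. For the SAM-style test, `s0` is set to a quantile (default the
#' median) of all probes' pooled standard errors; a Wilcoxon rank-sum
#' alternative is available.
#'
#' @param counts Normalized wide count tibble.
#' @param probes Probe annotation.
#' @param sheet Sample sheet.
#' @param mode `"tumor_only"` or `"tumor_vs_normal"`.
#' @param test `"sam"` (permutation d-statistic) or `"wilcoxon"`.
#' @param n_permutations,seed Permutation budget and seed.
#' @param s0_quantile Quantile of pooled SEs used as `s0`.
#' @param pseudocount Pseudocount for the log2 transforms.
#' @return A tibble of class `bcr_diffexp`: one row per endogenous probe with
#'   `probe`, `gene`, `mode`, `mean_bcr`, `mean_nonbcr`, `delta` (log2 scale),
#'   `d`, `p_value`, `direction` (`down_in_BCR` / `up_in_BCR`).
#' @export
run_differential <- function(counts, probes, sheet,
                             mode = c("tumor_only", "tumor_vs_normal"),
                             test = c("sam", "wilcoxon"),
                             n_permutations = 10000, seed = 1L,
                             s0_quantile = 0.5, pseudocount = 1) {
  mode <- match.arg(mode)
  test <- match.arg(test)
  endo <- probes$probe[probes$class == "endogenous"]

  if (mode == "tumor_only") {
    tum <- sheet[sheet$tissue == "tumor", , drop = FALSE]
    m <- counts_to_matrix(counts)
    keep <- intersect(endo, rownames(m))
    X <- log2(m[keep, tum$sample, drop = FALSE] + pseudocount)
    labels1 <- tum$outcome == "BCR"
  } else {
    ratios <- compute_ratios(counts, sheet, pseudocount = pseudocount)
    wide <- tidyr::pivot_wider(ratios, names_from = "patient",
                               values_from = "log2_ratio")
    keep <- intersect(endo, wide$probe)
    X <- counts_to_matrix(dplyr::rename(wide, probe = "probe"))[keep, , drop = FALSE]
    pat <- dplyr::distinct(sheet, .data$patient, .data$outcome)
    labels1 <- pat$outcome[match(colnames(X), pat$patient)] == "BCR"
  }
  if (sum(labels1) < 2L || sum(!labels1) < 2L)
    abort("run_differential: each outcome group needs >= 2 observations",
          class = "bcrpanel_validation_error")

  if (test == "sam") {
    s_all <- d_matrix_s(X, labels1)
    s0 <- unname(quantile(s_all, s0_quantile))
    res <- perm_pvalues(X, labels1, n_permutations, seed, s0)
    d <- res$d; p <- res$p
  } else {
    s0 <- NA_real_
    d <- rep(NA_real_, nrow(X))
    p <- apply(X, 1, function(v)
      suppressWarnings(wilcox.test(v[labels1], v[!labels1])$p.value))
  }
  mean_bcr <- unname(rowMeans(X[, labels1, drop = FALSE]))
  mean_nonbcr <- unname(rowMeans(X[, !labels1, drop = FALSE]))
  delta <- mean_bcr - mean_nonbcr
  out <- tibble::tibble(
    probe = rownames(X),
    gene = probes$gene[match(rownames(X), probes$probe)],
    mode = mode,
    mean_bcr = mean_bcr, mean_nonbcr = mean_nonbcr, delta = delta,
    d = unname(d), p_value = unname(pmin(pmax(p, .Machine$double.xmin), 1)),
    direction = ifelse(delta > 0, "up_in_BCR", "down_in_BCR")
  )
  attr(out, "s0") <- s0
  attr(out, "test") <- test
  class(out) <- c("bcr_diffexp", class(out))
  out
}

# Pooled standard errors per probe for the observed labels (used for s0).
d_matrix_s <- function(X, labels1) {
  n1 <- sum(labels1); n2 <- sum(!labels1)
  G <- matrix(as.numeric(labels1), ncol = 1)
  M1 <- (X %*% G) / n1; M2 <- (X %*% (1 - G)) / n2
  ss <- pmax((X^2 %*% G - n1 * M1^2) + (X^2 %*% (1 - G) - n2 * M2^2), 0)
  sqrt(ss / (n1 + n2 - 2) * (1 / n1 + 1 / n2))[, 1]
}
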