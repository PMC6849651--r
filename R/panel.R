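# Cutoff-based binarization of transcript counts and greedy OR-rule panel
# construction: a probe's continuous tumor count becomes a positive/negative
# BCR prediction via a per-probe cutoff chosen to prioritize specificity, and
# probes are added to the panel only when sensitivity rises without giving up
# more specificity than the tolerance allows.

#' Choose a per-probe cutoff that prioritizes specificity
#'
#' Candidate cutoffs are the midpoints between consecutive distinct observed
#' values. Among candidates whose specificity meets the floor, the one
#' maximizing sensitivity is chosen (ties: higher specificity, then smaller
#' cutoff). If no candidate reaches the floor, the cutoff maximizing
#' specificity is returned and flagged. For `direction = "down_in_BCR"`
#' (e.g. ERG, where loss of expression predicts recurrence) a value strictly
#' below the cutoff is a marker-positive (BCR-predicting) call.
#'
#' @param values Tumor transcript counts, one per patient (NA allowed).
#' @param outcome Outcome labels, `"BCR"` / `"nonBCR"`, aligned with
#'   `values`.
#' @param direction Whether low (`"down_in_BCR"`) or high (`"up_in_BCR"`)
#'   counts predict recurrence, usually taken from [run_differential()].
#' @param min_specificity Specificity floor (default 0.70).
#' @param probe Optional probe id carried into the rule.
#' @return A one-row tibble (class `bcr_probe_rule`): `probe`, `cutoff`,
#'   `direction`, `sensitivity`, `specificity`, `met_floor`.
#' @export
select_cutoff <- function(values, outcome, direction = "down_in_BCR",
                          min_specificity = 0.70, probe = NA_character_) {
  keep <- !is.na(values) & !is.na(outcome)
  v <- values[keep]; o <- outcome[keep]
  if (length(unique(o)) < 2L)
    abort("select_cutoff: both outcome classes must be present",
          class = "bcrpanel_validation_error")
  sv <- sort(unique(v))
  if (length(sv) < 2L)
    abort("select_cutoff: need at least two distinct values",
          class = "bcrpanel_validation_error")
  cand <- (sv[-1] + sv[-length(sv)]) / 2
  perf <- purrr::map_dfr(cand, function(ct) {
    calls <- binarize_values(v, ct, direction)
    cs <- confusion_summary(calls, o)
    tibble::tibble(cutoff = ct, sensitivity = cs$sensitivity,
                   specificity = cs$specificity)
  })
  ok <- perf$specificity >= min_specificity - 1e-12
  pick_from <- if (any(ok)) perf[ok, ] else perf
  pick <- if (any(ok)) {
    dplyr::arrange(pick_from, dplyr::desc(.data$sensitivity),
                   dplyr::desc(.data$specificity), .data$cutoff)[1, ]
  } else {
    dplyr::arrange(pick_from, dplyr::desc(.data$specificity),
                   dplyr::desc(.data$sensitivity), .data$cutoff)[1, ]
  }
  if (!any(ok))
    warn(sprintf(
      "select_cutoff%s: no cutoff reaches specificity %.2f; returning the most specific",
      if (is.na(probe)) "" else sprintf(" (%s)", probe), min_specificity))
  out <- tibble::tibble(probe = probe, cutoff = pick$cutoff,
                        direction = direction,
                        sensitivity = pick$sensitivity,
                        specificity = pick$specificity,
                        met_floor = any(ok))
  class(out) <- c("bcr_probe_rule", class(out))
  out
}

binarize_values <- function(values, cutoff, direction) {
  pos <- if (direction == "down_in_BCR") values < cutoff else values > cutoff
  ifelse(is.na(values), NA_character_, ifelse(pos, "positive", "negative"))
}

#' Binarize transcript counts under a probe rule
#'
#' Strict-inequality semantics: with `direction = "down_in_BCR"`, a count
#' strictly below the cutoff is `"positive"` (predicts BCR) and a count equal
#' to the cutoff is `"negative"` — matching the published "< 20 transcript
#' counts is ERG negative" convention. NA counts give NA calls.
#'
#' @param values Numeric counts.
#' @param rule A `bcr_probe_rule` row from [select_cutoff()], or a list with
#'   `cutoff` and `direction`.
#' @return Character vector of `"positive"` / `"negative"` / NA calls.
#' @examples
#' rule <- tibble::tibble(cutoff = 20, direction = "down_in_BCR")
#' binarize_counts(c(19, 20, NA), rule)
#' @export
binarize_counts <- function(values, rule) {
  if (is.null(rule$cutoff) || is.null(rule$direction))
    abort("binarize_counts: rule needs `cutoff` and `direction`")
  if (!is.finite(rule$cutoff[1]) || rule$cutoff[1] <= 0)
    abort("binarize_counts: cutoff must be a positive number",
          class = "bcrpanel_validation_error")
  binarize_values(values, rule$cutoff[1], rule$direction[1])
}

#' Confusion summary of binary BCR predictions
#'
#' Sensitivity is TP / (TP + FN) over evaluable BCR patients, specificity
#' TN / (TN + FP) over evaluable non-BCR patients; NA calls are excluded
#' from the evaluable set. Percentages are reported rounded to whole
#' percent, as in the publication (15/21 gives 71%).
#'
#' @param calls `"positive"` / `"negative"` / NA BCR predictions.
#' @param outcome `"BCR"` / `"nonBCR"` labels aligned with `calls`.
#' @return A one-row tibble (class `bcr_confusion`): `tp`, `fp`, `tn`, `fn`,
#'   `n_evaluable`, `sensitivity`, `specificity`, `sensitivity_pct`,
#'   `specificity_pct`.
#' @export
confusion_summary <- function(calls, outcome) {
  if (length(calls) != length(outcome))
    abort("confusion_summary: calls and outcome must align")
  keep <- !is.na(calls)
  calls <- calls[keep]; outcome <- outcome[keep]
  tp <- sum(calls == "positive" & outcome == "BCR")
  fn <- sum(calls == "negative" & outcome == "BCR")
  fp <- sum(calls == "positive" & outcome == "nonBCR")
  tn <- sum(calls == "negative" & outcome == "nonBCR")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  out <- tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn, n_evaluable = length(calls),
    sensitivity = sens, specificity = spec,
    sensitivity_pct = if (is.na(sens)) NA_integer_ else pct(sens),
    specificity_pct = if (is.na(spec)) NA_integer_ else pct(spec))
  class(out) <- c("bcr_confusion", class(out))
  out
}

panel_or_calls <- function(call_matrix, members) {
  sub <- call_matrix[, members, drop = FALSE]
  any_pos <- apply(sub == "positive", 1, any, na.rm = TRUE)
  all_na <- apply(is.na(sub), 1, all)
  ifelse(all_na, NA_character_, ifelse(any_pos, "positive", "negative"))
}

#' Greedy OR-rule panel construction
#'
#' Candidates are visited in order (by convention ascending tumor-only
#' p-value). The panel starts with the first candidate; each further
#' candidate is tentatively added under the OR combination rule (a patient
#' is panel-positive when any member calls positive; NA member calls count
#' as negative, and a patient is evaluable when at least one member call is
#' not NA) and accepted only if panel sensitivity strictly increases while
#' panel specificity drops by at most `tolerance`. Every decision is
#' recorded in an audit trail.
#'
#' @param calls A wide tibble: column `patient` plus one call column
#'   (`"positive"` / `"negative"` / NA) per candidate probe.
#' @param outcome Tibble with columns `patient` and `outcome`, or a vector
#'   aligned with `calls$patient`.
#' @param candidates Candidate probe order (default: the call columns in
#'   order).
#' @param tolerance Maximum allowed drop in specificity per accepted member
#'   (default 0).
#' @return A list of class `bcr_panel`: `members`, `audit` (tibble of every
#'   decision), `confusion`, `calls` (tibble `patient`, `call`), `tolerance`.
#' @export
build_panel <- function(calls, outcome, candidates = NULL, tolerance = 0) {
  if (!is.data.frame(calls) || !"patient" %in% names(calls))
    abort("build_panel: `calls` needs a `patient` column")
  if (is.data.frame(outcome)) {
    oc <- outcome$outcome[match(calls$patient, outcome$patient)]
  } else oc <- outcome
  cm <- as.matrix(calls[, setdiff(names(calls), "patient"), drop = FALSE])
  rownames(cm) <- calls$patient
  if (is.null(candidates)) candidates <- colnames(cm)
  if (length(candidates) == 0L)
    abort("build_panel: empty candidate set", class = "bcrpanel_validation_error")
  missing <- setdiff(candidates, colnames(cm))
  if (length(missing))
    abort(sprintf("build_panel: candidate(s) without call column: %s",
                  paste(missing, collapse = ", ")))

  members <- candidates[1]
  cur <- confusion_summary(panel_or_calls(cm, members), oc)
  audit <- tibble::tibble(
    probe = candidates[1], action = "accept",
    sensitivity_before = NA_real_, specificity_before = NA_real_,
    sensitivity_after = cur$sensitivity, specificity_after = cur$specificity,
    reason = "first candidate")
  for (cand in candidates[-1]) {
    trial <- confusion_summary(panel_or_calls(cm, c(members, cand)), oc)
    gain <- trial$sensitivity > cur$sensitivity + 1e-12
    hold <- trial$specificity >= cur$specificity - tolerance - 1e-12
    accept <- isTRUE(gain) && isTRUE(hold)
    audit <- dplyr::bind_rows(audit, tibble::tibble(
      probe = cand, action = if (accept) "accept" else "reject",
      sensitivity_before = cur$sensitivity,
      specificity_before = cur$specificity,
      sensitivity_after = trial$sensitivity,
      specificity_after = trial$specificity,
      reason = if (accept) "sensitivity gain within specificity tolerance"
               else if (!gain) "no sensitivity gain"
               else sprintf("specificity drop exceeds tolerance %g", tolerance)))
    if (accept) { members <- c(members, cand); cur <- trial }
  }
  acc <- audit[audit$action == "accept", , drop = FALSE]
  stopifnot(!is.unsorted(acc$sensitivity_after, na.rm = TRUE))
  # OR-rule law: with fully evaluable calls, specificity cannot rise as
  # members are added (NA-call expansion of the evaluable set is exempt).
  if (!anyNA(cm))
    stopifnot(!is.unsorted(rev(acc$specificity_after), na.rm = TRUE))
  final_calls <- tibble::tibble(patient = rownames(cm),
                                call = panel_or_calls(cm, members))
  out <- list(members = members, audit = audit, confusion = cur,
              calls = final_calls, tolerance = tolerance)
  class(out) <- "bcr_panel"
  out
}

#' @export
print.bcr_panel <- function(x, ...) {
  cat(sprintf("<bcr_panel> %d member(s): %s\n", length(x$members),
              paste(x$members, collapse = ", ")))
  cat(sprintf("  sensitivity %d%%, specificity %d%% (n = %d evaluable)\n",
              x$confusion$sensitivity_pct, x$confusion$specificity_pct,
              x$confusion$n_evaluable))
  invisible(x)
}

#' Percent agreement between two call vectors
#'
#' Agreement is computed over patients evaluable (non-NA) in both vectors
#' and reported rounded to whole percent.
#'
#' @param a,b Call vectors (`"positive"` / `"negative"` / NA), aligned.
#' @return Percent agreement (integer), with attribute `"n"` (the number of
#'   jointly evaluable cases).
#' @examples
#' call_concordance(c("positive", "positive", "negative"),
#'                  c("positive", "negative", "negative"))  # 67
#' @export
call_concordance <- function(a, b) {
  if (length(a) != length(b))
    abort("call_concordance: vectors must align")
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep))
    abort("call_concordance: no jointly evaluable cases",
          class = "bcrpanel_validation_error")
  structure(pct(mean(a[keep] == b[keep])), n = sum(keep))
}
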