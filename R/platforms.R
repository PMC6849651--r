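# qRT-PCR delta-Ct ERG scoring, IHC call ingestion, and combination of
# per-patient ERG status across measurement platforms.

#' ERG call from qRT-PCR threshold cycles
#'
#' The unevaluable rule is applied first: a case with GAPDH threshold cycle
#' of 38 or greater, or undetectable GAPDH (NA), is unevaluable (NA call).
#' Otherwise a case with ERG threshold cycle of 45 or greater (or
#' undetectable ERG) is ERG negative; everything else is ERG positive.
#'
#' @param ct_erg,ct_gapdh Threshold cycles (NA = undetectable). Vectorized.
#' @return Character vector: `"positive"`, `"negative"`, or NA.
#' @examples
#' qpcr_call(c(46, 33, 33), c(30, 39, 30))  # negative, NA, positive
#' @export
qpcr_call <- function(ct_erg, ct_gapdh) {
  if (length(ct_erg) != length(ct_gapdh))
    abort("qpcr_call: ct_erg and ct_gapdh must align")
  bad <- (!is.na(ct_erg) & ct_erg <= 0) | (!is.na(ct_gapdh) & ct_gapdh <= 0)
  if (any(bad))
    abort("qpcr_call: threshold cycles must be positive or NA (undetectable)",
          class = "bcrpanel_validation_error")
  out <- ifelse(is.na(ct_erg) | ct_erg >= 45, "negative", "positive")
  out[is.na(ct_gapdh) | ct_gapdh >= 38] <- NA_character_
  out
}

#' Fold difference from delta Ct
#'
#' `delta Ct = Ct_GAPDH - Ct_ERG`; the fold difference relative to the GAPDH
#' control is `2^(delta Ct)`.
#'
#' @param ct_erg,ct_gapdh Evaluable threshold cycles.
#' @return Numeric fold difference.
#' @examples
#' qpcr_fold(30, 33)  # 8
#' @export
qpcr_fold <- function(ct_erg, ct_gapdh) 2^(ct_gapdh - ct_erg)

#' Score a qRT-PCR table
#'
#' @param qpcr Tibble with columns `patient`, `ct_erg`, `ct_gapdh`.
#' @return The input with `delta_ct`, `fold` and `call` columns added
#'   (`delta_ct` and `fold` are NA for unevaluable cases).
#' @export
score_qpcr <- function(qpcr) {
  need <- c("patient", "ct_erg", "ct_gapdh")
  if (!all(need %in% names(qpcr)))
    abort(sprintf("score_qpcr: input needs columns %s", paste(need, collapse = ", ")))
  call <- qpcr_call(qpcr$ct_erg, qpcr$ct_gapdh)
  delta <- ifelse(is.na(call), NA_real_, qpcr$ct_gapdh - qpcr$ct_erg)
  dplyr::mutate(qpcr, delta_ct = delta, fold = 2^delta, call = call)
}

#' Combine per-platform ERG calls into a BCR prediction
#'
#' Default rule (`any_negative`): predict BCR when any evaluable platform
#' reports ERG negative; NA platforms are ignored and a patient is NA only
#' when every platform is NA. Alternatives: `all_negative` (every evaluable
#' platform negative) and `majority` (negative on more than half of the
#' evaluable platforms).
#'
#' @param calls Wide tibble: column `patient` plus one ERG-status column per
#'   platform (`"positive"` / `"negative"` / NA).
#' @param rule Combination rule.
#' @return Tibble `patient`, `call` where `"positive"` predicts BCR.
#' @export
combine_calls <- function(calls, rule = c("any_negative", "all_negative",
                                          "majority")) {
  rule <- match.arg(rule)
  if (!is.data.frame(calls) || !"patient" %in% names(calls))
    abort("combine_calls: `calls` needs a `patient` column")
  plat <- setdiff(names(calls), "patient")
  if (length(plat) < 2L)
    abort("combine_calls: need >= 2 platforms", class = "bcrpanel_validation_error")
  cm <- as.matrix(calls[, plat, drop = FALSE])
  neg <- cm == "negative"
  n_eval <- rowSums(!is.na(cm))
  n_neg <- rowSums(neg, na.rm = TRUE)
  hit <- switch(rule,
    any_negative = n_neg >= 1,
    all_negative = n_neg == n_eval & n_eval > 0,
    majority = n_neg > n_eval / 2)
  tibble::tibble(
    patient = calls$patient,
    call = ifelse(n_eval == 0, NA_character_,
                  ifelse(hit, "positive", "negative")))
}

#' Pairwise and overall concordance of platform ERG calls
#'
#' Pairwise agreement uses [call_concordance()] (patients evaluable on both
#' platforms); overall agreement is the fraction of patients evaluable on
#' every selected platform whose status is identical on all of them.
#'
#' @param calls Wide tibble: `patient` plus one column per platform.
#' @param platforms Platform subset (default all call columns).
#' @return A list of class `bcr_concordance`: `pairwise` (tibble
#'   `platform_a`, `platform_b`, `agreement_pct`, `n`), `overall_pct`,
#'   `n_overall`.
#' @export
platform_concordance <- function(calls, platforms = NULL) {
  if (!is.data.frame(calls) || !"patient" %in% names(calls))
    abort("platform_concordance: `calls` needs a `patient` column")
  plat <- platforms %||% setdiff(names(calls), "patient")
  if (length(plat) < 2L)
    abort("platform_concordance: need >= 2 platforms",
          class = "bcrpanel_validation_error")
  missing <- setdiff(plat, names(calls))
  if (length(missing))
    abort(sprintf("platform_concordance: unknown platform(s): %s",
                  paste(missing, collapse = ", ")))
  pairs <- utils::combn(plat, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    cc <- call_concordance(calls[[pr[1]]], calls[[pr[2]]])
    tibble::tibble(platform_a = pr[1], platform_b = pr[2],
                   agreement_pct = as.integer(cc), n = attr(cc, "n"))
  })
  cm <- as.matrix(calls[, plat, drop = FALSE])
  full <- rowSums(is.na(cm)) == 0
  if (!any(full))
    abort("platform_concordance: no cases evaluable on all platforms",
          class = "bcrpanel_validation_error")
  same <- apply(cm[full, , drop = FALSE], 1,
                function(r) length(unique(r)) == 1L)
  out <- list(pairwise = pairwise, overall_pct = pct(mean(same)),
              n_overall = sum(full))
  class(out) <- "bcr_concordance"
  out
}

#' @export
print.bcr_concordance <- function(x, ...) {
  cat(sprintf("<bcr_concordance> overall %d%% over %d fully-evaluable case(s)\n",
              x$overall_pct, x$n_overall))
  print(x$pairwise)
  invisible(x)
}
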