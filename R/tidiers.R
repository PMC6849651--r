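# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidiers
#' @title Tidy and summarize bcrpanel result objects
#' @description `tidy()` returns the per-element table of a result object
#'   (lambda grid for a pi0 estimate, audit trail for a panel, pairwise
#'   table for a concordance object); `glance()` returns a one-row summary.
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pi0_estimate
#' @export
tidy.pi0_estimate <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, pi0_lambda = x$pi0_lambda)
}

#' @rdname tidiers
#' @method glance pi0_estimate
#' @export
glance.pi0_estimate <- function(x, ...) {
  tibble::tibble(pi0 = x$pi0, pi0_smooth = x$pi0_smooth, m = x$m,
                 fallback = x$fallback)
}

#' @rdname tidiers
#' @method tidy bcr_panel
#' @export
tidy.bcr_panel <- function(x, ...) x$audit

#' @rdname tidiers
#' @method glance bcr_panel
#' @export
glance.bcr_panel <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_members = length(x$members),
                   members = paste(x$members, collapse = ",")),
    x$confusion)
}

#' @rdname tidiers
#' @method tidy bcr_concordance
#' @export
tidy.bcr_concordance <- function(x, ...) x$pairwise

#' @rdname tidiers
#' @method glance bcr_concordance
#' @export
glance.bcr_concordance <- function(x, ...) {
  tibble::tibble(overall_pct = x$overall_pct, n_overall = x$n_overall)
}

#' @rdname tidiers
#' @method tidy bcr_significant
#' @export
tidy.bcr_significant <- function(x, ...) x$table

#' @rdname tidiers
#' @method glance bcr_significant
#' @export
glance.bcr_significant <- function(x, ...) {
  tibble::tibble(n_probes = length(x$probes), n_genes = length(x$genes),
                 q_cutoff = x$q_cutoff)
}

#' @rdname tidiers
#' @method glance bcr_run_report
#' @export
glance.bcr_run_report <- function(x, ...) {
  tibble::tibble(
    seed = x$provenance$seed,
    lanes_pass = sum(x$lane_qc$pass),
    lanes_total = nrow(x$lane_qc),
    n_sig_probes_tumor = length(x$significant$tumor_only$probes),
    n_sig_genes_tumor = length(x$significant$tumor_only$genes),
    n_sig_probes_ratio = length(x$significant$tumor_vs_normal$probes),
    panel_size = if (is.null(x$panel)) NA_integer_ else length(x$panel$members),
    panel_sensitivity_pct = if (is.null(x$panel)) NA_integer_
                            else x$panel$confusion$sensitivity_pct,
    panel_specificity_pct = if (is.null(x$panel)) NA_integer_
                            else x$panel$confusion$specificity_pct)
}
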