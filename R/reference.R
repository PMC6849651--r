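#' Published differential-expression reference table
#'
#' The printed per-probe results of the discovery study (both analysis
#' modes, top 15 probe sets each): p-value, q-value, expected false
#' positives and direction. Shipped as a plain CSV and used as the worked
#' input for the expected-false-positive arithmetic and the significance
#' filter.
#'
#' @param analysis `"tumor_only"`, `"tumor_vs_normal"` or `"both"`.
#' @return A tibble with columns `analysis`, `rank`, `probe`, `gene`,
#'   `p_value`, `q_value`, `expected_fp`, `direction`.
#' @examples
#' tab <- reference_table("tumor_only")
#' expected_fp(tab$q_value, tab$rank)
#' @export
reference_table <- function(analysis = c("both", "tumor_only",
                                         "tumor_vs_normal")) {
  analysis <- match.arg(analysis)
  path <- system.file("extdata", "published_probe_table.csv", package = "bcrpanel",
                      mustWork = TRUE)
  tab <- read_csv_quiet(path)
  if (analysis != "both") tab <- tab[tab$analysis == analysis, , drop = FALSE]
  tab
}
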