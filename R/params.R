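# Simulation parameters: the study conditions the synthetic cohorts emulate.

#' Simulation parameters for a synthetic recurrence cohort
#'
#' Defaults mirror the discovery-study design: 21 patients with biochemical
#' recurrence (BCR) and 42 without, each contributing one tumor and one
#' matched benign-epithelium sample, assayed with a 151-probe CodeSet-style
#' layout. ERG is simulated as a latent, fusion-like bimodal state per
#' patient, shared by all four ERG-targeting probe sets; the default
#' positive-state fractions (31/42 in non-BCR, 6/21 in BCR) are the rates
#' implied by the published 74% specificity and 71% sensitivity of the
#' transcript-count ERG call. Seven further genes (`GGT1`, `HDAC1`, `KLK2`,
#' `MYO6`, `PLA2G7`, `BICD1`, `CACNA1D`) carry a modest default down-effect
#' in BCR tumors.
#'
#' @param n_bcr,n_nonbcr Patient counts per outcome group.
#' @param probe_layout Probe annotation tibble (see [default_probe_layout()]).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters for per-probe
#'   baseline mean counts of endogenous probes.
#' @param dispersion Negative-binomial dispersion of probe counts
#'   (`variance = mu + dispersion * mu^2`); values below 1e-8 fall back to
#'   Poisson sampling.
#' @param erg_pos_frac_nonbcr,erg_pos_frac_bcr Fraction of patients per
#'   outcome group carrying the high (fusion-positive) latent ERG state.
#' @param erg_high_mu,erg_low_mu Mean tumor transcript counts of ERG-targeting
#'   probes in the high and low latent state; benign epithelium always draws
#'   from the low state.
#' @param effect_log2fc Named numeric vector of per-probe log2 fold changes
#'   (BCR vs non-BCR, applied in tumor samples); probes not named get 0. A
#'   single unnamed number applies to the seven default signal genes.
#' @param lane_factor_sd SD of per-lane log-scale efficiency factors.
#' @param pos_counts_per_fM Expected counts per fM for positive spike-ins.
#' @param neg_mu Poisson mean of negative-control counts.
#' @param qpcr_flip_prob Probability that the qRT-PCR assay misreads a
#'   patient's latent ERG state (drives its lower observed concordance).
#' @param qpcr_na_frac Probability that a patient's qRT-PCR GAPDH reaction is
#'   unevaluable (threshold cycle at or above 38, or undetectable).
#' @param ihc_flip_prob Probability that the IHC call flips the latent state.
#' @param seed Integer seed; fixed seed implies bitwise-identical cohorts.
#' @return A validated list of class `sim_params`.
#' @seealso [simulate_cohort()], [null_sim_params()]
#' @export
sim_params <- function(n_bcr = 21,
                       n_nonbcr = 42,
                       probe_layout = default_probe_layout(),
                       baseline_meanlog = log(200),
                       baseline_sdlog = 1.2,
                       dispersion = 0.05,
                       erg_pos_frac_nonbcr = 31 / 42,
                       erg_pos_frac_bcr = 6 / 21,
                       erg_high_mu = 250,
                       erg_low_mu = 8,
                       effect_log2fc = -0.3,
                       lane_factor_sd = 0.15,
                       pos_counts_per_fM = 250,
                       neg_mu = 4,
                       qpcr_flip_prob = 0.15,
                       qpcr_na_frac = 0.11,
                       ihc_flip_prob = 0.03,
                       seed = 1L) {
  p <- list(
    n_bcr = n_bcr, n_nonbcr = n_nonbcr, probe_layout = probe_layout,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    dispersion = dispersion,
    erg_pos_frac_nonbcr = erg_pos_frac_nonbcr,
    erg_pos_frac_bcr = erg_pos_frac_bcr,
    erg_high_mu = erg_high_mu, erg_low_mu = erg_low_mu,
    effect_log2fc = effect_log2fc,
    lane_factor_sd = lane_factor_sd,
    pos_counts_per_fM = pos_counts_per_fM, neg_mu = neg_mu,
    qpcr_flip_prob = qpcr_flip_prob, qpcr_na_frac = qpcr_na_frac,
    ihc_flip_prob = ihc_flip_prob, seed = seed
  )
  class(p) <- "sim_params"
  validate_sim_params(p)
}

#' Fully-null simulation parameters
#'
#' Convenience constructor for calibration studies: all per-probe effects are
#' zero and both outcome groups share the same latent ERG-positive fraction,
#' so BCR and non-BCR samples are drawn from identical distributions and
#' downstream p-values are uniform.
#'
#' @param seed Integer seed.
#' @param erg_pos_frac Common ERG-positive fraction for both groups.
#' @param ... Further arguments passed to [sim_params()].
#' @return A `sim_params` object.
#' @export
null_sim_params <- function(seed = 1L, erg_pos_frac = 0.5, ...) {
  sim_params(effect_log2fc = 0,
             erg_pos_frac_nonbcr = erg_pos_frac,
             erg_pos_frac_bcr = erg_pos_frac,
             seed = seed, ...)
}

validate_sim_params <- function(p) {
  bad <- function(field, why) {
    abort(sprintf("invalid simulation parameter `%s`: %s", field, why),
          class = "bcrpanel_validation_error")
  }
  chk_num <- function(field, lo = -Inf, strict = FALSE, len1 = TRUE) {
    x <- p[[field]]
    if (!is.numeric(x) || (len1 && length(x) != 1L) || anyNA(x))
      bad(field, "must be a non-missing number")
    if (strict && any(x <= lo)) bad(field, sprintf("must be > %g", lo))
    if (!strict && any(x < lo)) bad(field, sprintf("must be >= %g", lo))
  }
  chk_num("n_bcr", 0)
  chk_num("n_nonbcr", 0)
  if (p$n_bcr + p$n_nonbcr <= 0) bad("n_bcr", "n_bcr + n_nonbcr must be > 0")
  for (f in c("erg_pos_frac_nonbcr", "erg_pos_frac_bcr",
              "qpcr_flip_prob", "qpcr_na_frac", "ihc_flip_prob")) {
    chk_num(f, 0)
    if (p[[f]] > 1) bad(f, "must lie in [0, 1]")
  }
  chk_num("dispersion", 0)
  chk_num("lane_factor_sd", 0)
  chk_num("baseline_sdlog", 0)
  chk_num("baseline_meanlog")
  for (f in c("erg_high_mu", "erg_low_mu", "pos_counts_per_fM", "neg_mu"))
    chk_num(f, 0, strict = TRUE)
  if (!is.numeric(p$effect_log2fc) || anyNA(p$effect_log2fc))
    bad("effect_log2fc", "must be numeric without NA")
  validate_probe_annotation(p$probe_layout, context = "probe_layout")
  p
}
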