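# Reference probe layout: a 151-probe CodeSet-style annotation with four
# ERG-targeting probe sets, 122 further endogenous probes, 11 housekeeping
# genes, a 6-point positive-control spike ladder and 8 negative controls.

erg_probe_ids <- function() {
  c("Pan.ERG", "ERG8", "ERG1.ERG2.ERG3", "T2.ERG.exon4.fusion")
}

panel_signal_genes <- function() {
  c("GGT1", "HDAC1", "KLK2", "MYO6", "PLA2G7", "BICD1", "CACNA1D")
}

housekeeping_ids <- function() {
  c("ACTB", "B2M", "CLTC", "GAPDH", "GUSB", "HPRT1", "PGK1",
    "RPL13A", "RPL27", "RPS13", "TUBB")
}

other_endogenous_ids <- function() {
  c(
    # progression-associated genes
    "AKT1", "ANXA2", "AR", "AURKA", "CAMK2N1", "CCND1", "CHD1", "C.MYC",
    "COL1A1", "COL3A1", "CXCR4", "EZH2", "FZD4", "HSP27", "JAG1", "KLF4",
    "MAOA", "MUC1", "MYCN", "NCOA2", "OCT4", "PARP1", "PTENP1", "PTEN",
    "SMAD4", "SOX2", "SPINK1", "SPP1", "SPRY1", "SPRY2", "STAG2", "TFF3",
    "TOP2A", "ZEB1",
    # up-regulated in prostate cancer
    "AMACR", "BICD1", "CACNA1D", "CLDN8", "CRISP3", "EPC1", "EPC2", "ETV1",
    "ETV4", "ETV5", "GGT1", "HOXC6", "HPGD", "MYO6", "NPY", "PCA3",
    "PCGEM1", "PLA2G7", "PSGR", "PSGR2", "FOLH1", "SPARC", "TMEFF2",
    "TWIST1",
    # down-regulated in prostate cancer
    "AMD1", "EVA1", "GSTP1", "HOXB13", "KLK2", "KLK3", "LTF", "MSMB",
    "NEFH", "NKX3.1", "ODC1", "ACPP", "PMEPA1", "KLK4", "PSCA", "STAG1",
    "TMPRSS2",
    # cancer gene subset
    "AKT2", "BRAF", "CAV1", "EGFR", "FAS", "GATA1", "HDAC1", "HIF1A",
    "HRAS", "KRAS", "MMP2", "MMP9", "NOTCH1", "NRAS", "NUMA1", "PDGFR",
    "PIK3CA", "RAF1", "STAT1", "STAT3", "TP53", "VEGFA", "VEGFR",
    "VEGFR1", "WNT1",
    # stroma / epithelium markers and ETS family
    "ALCAM", "KRT18", "KRT5", "POSTN", "VIM",
    "ESE3", "ETS1", "ETS2", "FLI1", "SPDEF",
    # fusion-variant probes
    "T2.ERG.exon2.fusion", "ACSL3.ETV1.fusion", "CANT1.ETV4.fusion",
    "DDX5.ETV4.fusion", "HERPUD1.ERG.fusion", "KLK2.ETV4.fusion",
    "NDRG1.ERG.fusion", "SLC45A3.ETV5.fusion", "SLC45A3.ERG.fusion",
    "T1.ETV4.fusion", "AGTRAP.BRAF.fusion", "SLC45A3.BRAF.fusion"
  )
}

#' Reference probe annotation (151 probes)
#'
#' The default CodeSet-style layout used by [simulate_cohort()]: 126
#' endogenous probes (four of which target ERG splice or fusion variants and
#' share one latent fusion state per patient), 11 housekeeping genes, 6
#' positive spike-in controls on a 128 to 0.125 fM ladder, and 8 negative
#' controls.
#'
#' @param spike_concs Positive-control concentration ladder in fM, highest
#'   first; length defines the number of positive-control probes.
#' @return A tibble with columns `probe`, `gene`, `class` (one of
#'   `endogenous`, `housekeeping`, `positive`, `negative`) and `spike_fM`
#'   (`NA` except for positive controls).
#' @examples
#' dplyr::count(default_probe_layout(), class)
#' @export
default_probe_layout <- function(spike_concs = c(128, 32, 8, 2, 0.5, 0.125)) {
  erg <- erg_probe_ids()
  endo <- c(erg, other_endogenous_ids())
  gene <- endo
  gene[endo %in% c(erg, "T2.ERG.exon2.fusion")] <- "ERG"
  hk <- housekeeping_ids()
  pos <- sprintf("POS_%s", LETTERS[seq_along(spike_concs)])
  neg <- sprintf("NEG_%s", LETTERS[1:8])
  tibble::tibble(
    probe = c(endo, hk, pos, neg),
    gene = c(gene, hk, pos, neg),
    class = rep(c("endogenous", "housekeeping", "positive", "negative"),
                times = c(length(endo), length(hk), length(pos), length(neg))),
    spike_fM = c(rep(NA_real_, length(endo) + length(hk)), spike_concs,
                 rep(NA_real_, length(neg)))
  )
}
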