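# Seeded synthetic cohorts with the statistical structure the downstream
# analysis assumes: negative-binomial probe counts around lane-scaled means,
# a shared latent bimodal ERG state, spike-in control ladders, and matched
# qRT-PCR / IHC ERG calls.

#' Simulate a synthetic recurrence cohort
#'
#' Generates a raw probe-by-sample count matrix, a sample sheet, matched
#' qRT-PCR threshold-cycle and IHC call tables, and a truth table of the
#' simulated effects. Lane batching mirrors the assay design in which each
#' BCR patient was hybridized together with two non-BCR patients; every
#' sample occupies one lane of a 12-lane cartridge and receives its own
#' log-normal efficiency factor. Positive-control counts scale linearly with
#' the spike ladder, negative controls are Poisson background, housekeeping
#' probes carry no group effect, and the four ERG-targeting probe sets share
#' one latent fusion-like state per patient.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `bcr_cohort` with elements `counts` (wide tibble,
#'   stage `"raw"`), `probes`, `samples`, `truth` (per endogenous probe),
#'   `erg_state` (per patient), `qpcr`, `ihc` and `params`.
#' @examples
#' cohort <- simulate_cohort(sim_params(seed = 1))
#' dim(cohort$counts)   # 151 probes x (1 + 126 samples)
#' @export
simulate_cohort <- function(params = sim_params()) {
  if (!inherits(params, "sim_params")) params <- do.call(sim_params, params)
  validate_sim_params(params)
  with_seed(params$seed, simulate_cohort_impl(params))
}

simulate_cohort_impl <- function(p) {
  ann <- p$probe_layout
  endo <- ann$probe[ann$class == "endogenous"]
  hk <- ann$probe[ann$class == "housekeeping"]
  pos <- ann$probe[ann$class == "positive"]
  neg <- ann$probe[ann$class == "negative"]
  erg <- intersect(erg_probe_ids(), endo)

  samples <- build_sample_sheet(p$n_bcr, p$n_nonbcr)
  patients <- dplyr::distinct(samples, .data$patient, .data$outcome)

  ## latent fusion-like ERG state, one draw per patient
  frac <- ifelse(patients$outcome == "BCR",
                 p$erg_pos_frac_bcr, p$erg_pos_frac_nonbcr)
  erg_state <- tibble::tibble(
    patient = patients$patient,
    outcome = patients$outcome,
    erg_positive = rbinom(nrow(patients), 1L, frac) == 1L
  )

  ## per-probe true effects (log2 BCR-vs-non-BCR in tumor)
  fc <- p$effect_log2fc
  effects <- setNames(rep(0, length(endo)), endo)
  if (is.null(names(fc)) && length(fc) == 1L) {
    effects[intersect(panel_signal_genes(), endo)] <- fc
  } else {
    unknown <- setdiff(names(fc), endo)
    if (length(unknown))
      abort(sprintf("invalid simulation parameter `effect_log2fc`: unknown probe(s) %s",
                    paste(unknown, collapse = ", ")),
            class = "bcrpanel_validation_error")
    effects[names(fc)] <- fc
  }
  effects[erg] <- 0  # ERG signal enters through the latent state instead
  truth <- tibble::tibble(
    probe = endo,
    effect_log2fc = unname(effects),
    is_erg_probe = endo %in% erg
  )

  ## baseline means: endogenous log-normal, housekeeping ladder over range
  mu_endo <- stats::rlnorm(length(endo), p$baseline_meanlog, p$baseline_sdlog)
  names(mu_endo) <- endo
  mu_hk <- exp(seq(log(50), log(5000), length.out = length(hk)))
  names(mu_hk) <- hk
  erg_rel <- stats::rlnorm(length(erg), 0, 0.25)  # probe-to-probe level spread
  names(erg_rel) <- erg

  n_s <- nrow(samples)
  is_tumor <- samples$tissue == "tumor"
  is_bcr <- samples$outcome == "BCR"
  pat_state <- setNames(erg_state$erg_positive, erg_state$patient)
  samp_state <- pat_state[samples$patient]

  mu <- matrix(0, nrow(ann), n_s, dimnames = list(ann$probe, samples$sample))
  for (pr in endo) {
    base <- mu_endo[[pr]]
    if (pr %in% erg) {
      lvl <- ifelse(is_tumor & samp_state, p$erg_high_mu, p$erg_low_mu)
      mu[pr, ] <- lvl * erg_rel[[pr]]
    } else {
      mu[pr, ] <- base * 2^(effects[[pr]] * (is_tumor & is_bcr))
    }
  }
  mu[hk, ] <- matrix(mu_hk, length(hk), n_s)
  mu[pos, ] <- matrix(ann$spike_fM[match(pos, ann$probe)] * p$pos_counts_per_fM,
                      length(pos), n_s)

  lane_factor <- exp(rnorm(n_s, 0, p$lane_factor_sd))
  mu <- sweep(mu, 2, lane_factor, `*`)

  counts <- mu
  nb_rows <- setdiff(ann$probe, neg)
  nb_mu <- mu[nb_rows, , drop = FALSE]
  counts[nb_rows, ] <- if (p$dispersion < 1e-8) {
    rpois(length(nb_mu), lambda = nb_mu)
  } else {
    rnbinom(length(nb_mu), size = 1 / p$dispersion, mu = nb_mu)
  }
  counts[neg, ] <- rpois(length(neg) * n_s,
                         lambda = rep(lane_factor * p$neg_mu, each = length(neg)))

  ## matched qRT-PCR threshold cycles (tumor RNA) and IHC calls
  n_p <- nrow(erg_state)
  qpcr_state <- xor(erg_state$erg_positive, runif(n_p) < p$qpcr_flip_prob)
  ct_gapdh <- rnorm(n_p, 26, 1)
  na_case <- runif(n_p) < p$qpcr_na_frac
  undetect <- runif(n_p) < 0.5
  ct_gapdh[na_case] <- ifelse(undetect[na_case], NA_real_,
                              runif(sum(na_case), 38, 42))
  ct_erg <- ifelse(qpcr_state,
                   pmin(rnorm(n_p, 30, 1.5), 44.5),
                   runif(n_p, 45, 50))
  qpcr <- tibble::tibble(patient = erg_state$patient,
                         ct_erg = ct_erg, ct_gapdh = ct_gapdh)

  ihc_state <- xor(erg_state$erg_positive, runif(n_p) < p$ihc_flip_prob)
  ihc <- tibble::tibble(patient = erg_state$patient,
                        call = ifelse(ihc_state, "positive", "negative"))

  structure(list(
    counts = matrix_to_counts(counts, stage = "raw"),
    probes = ann,
    samples = samples,
    truth = truth,
    erg_state = erg_state,
    qpcr = qpcr,
    ihc = ihc,
    params = p
  ), class = "bcr_cohort")
}

# One BCR patient batched with two non-BCR patients; six samples per batch,
# two batches per 12-lane cartridge.
build_sample_sheet <- function(n_bcr, n_nonbcr) {
  pat <- tibble::tibble(
    patient = sprintf("P%03d", seq_len(n_bcr + n_nonbcr)),
    outcome = rep(c("BCR", "nonBCR"), times = c(n_bcr, n_nonbcr))
  )
  bcr_ids <- pat$patient[pat$outcome == "BCR"]
  non_ids <- pat$patient[pat$outcome == "nonBCR"]
  order_ids <- character(0)
  i <- j <- 1L
  while (i <= length(bcr_ids) || j <= length(non_ids)) {
    if (i <= length(bcr_ids)) { order_ids <- c(order_ids, bcr_ids[i]); i <- i + 1L }
    take <- min(2L, length(non_ids) - j + 1L)
    if (take > 0L) { order_ids <- c(order_ids, non_ids[j:(j + take - 1L)]); j <- j + take }
  }
  out <- tidyr::expand_grid(patient = order_ids, tissue = c("tumor", "normal"))
  out$sample <- paste0(out$patient, "_", ifelse(out$tissue == "tumor", "T", "N"))
  lane_no <- seq_len(nrow(out))
  out$lane <- sprintf("C%02d_L%02d", (lane_no - 1L) %/% 12L + 1L,
                      (lane_no - 1L) %% 12L + 1L)
  out$outcome <- pat$outcome[match(out$patient, pat$patient)]
  dplyr::select(out, "sample", "patient", "tissue", "outcome", "lane")
}

#' @export
print.bcr_cohort <- function(x, ...) {
  n <- table(dplyr::distinct(x$samples, .data$patient, .data$outcome)$outcome)
  cat(sprintf(
    "<bcr_cohort> %d probes x %d samples (%s BCR / %s non-BCR patients), seed %s\n",
    nrow(x$counts), ncol(x$counts) - 1L,
    n[["BCR"]], n[["nonBCR"]], format(x$params$seed)))
  invisible(x)
}
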