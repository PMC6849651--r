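# Shared fixtures (built in code, memoized per test run) and independent
# oracles used across test files.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

default_cohort <- function() memo("cohort", simulate_cohort(sim_params(seed = 42)))

default_normalized <- function() memo("normalized", {
  co <- default_cohort()
  normalize_counts(co$counts, co$probes)
})

default_diffexp <- function() memo("diffexp", {
  co <- default_cohort()
  run_differential(default_normalized(), co$probes, co$samples,
                   mode = "tumor_only", n_permutations = 2000, seed = 7)
})

# Tiny hand-built count set: 2 positive controls, 2 negatives, 1 housekeeping,
# 2 endogenous probes over `n` lanes, values supplied as a probe x lane matrix.
toy_probes <- function(n_pos = 2) {
  tibble::tibble(
    probe = c(sprintf("POS_%d", seq_len(n_pos)), "NEG_1", "NEG_2", "HK_1",
              "GENE_A", "GENE_B"),
    gene = probe,
    class = c(rep("positive", n_pos), "negative", "negative", "housekeeping",
              "endogenous", "endogenous"),
    spike_fM = c(2^(seq_len(n_pos) + 2), rep(NA_real_, 4 + 1)))
}

toy_counts <- function(m) {
  tibble::as_tibble(m, rownames = "probe")
}

# Independent q-value oracle: direct evaluation of
#   q_i = min over thresholds t in {p_j : p_j >= p_i} of pi0 * m * t / #{p <= t}
brute_force_q <- function(p, pi0 = 1) {
  m <- length(p)
  vapply(p, function(pi) {
    ts <- sort(unique(p[p >= pi - 1e-15]))
    min(1, min(vapply(ts, function(t) pi0 * m * t / sum(p <= t), numeric(1))))
  }, numeric(1))
}

# Independent SAM oracle for one probe: exhaustive enumeration over every
# group-1 assignment, plain loops, no shared code with the implementation.
enumerate_sam_p <- function(x, y, s0 = 0) {
  v <- c(x, y)
  n1 <- length(x)
  dstat <- function(a, b) {
    sp <- sqrt((sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
                 (length(a) + length(b) - 2) * (1 / length(a) + 1 / length(b)))
    (mean(a) - mean(b)) / (sp + s0)
  }
  obs <- abs(dstat(x, y))
  idx <- utils::combn(length(v), n1)
  ds <- apply(idx, 2, function(i) abs(dstat(v[i], v[-i])))
  mean(ds >= obs - 1e-12)
}
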