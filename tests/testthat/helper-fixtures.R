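# Shared fixtures, built in code once per test run, plus the
# independent brute-force oracles used against the implementation.

# small heterogeneous cohort used by several files
fx_cohort <- generate_cohort(cohort_config(
  n_tumour = 10, n_normal = 8, n_genes = 300, n_subtypes = 2,
  subtype_props = c(0.5, 0.5), frac_group_de = 0.1,
  frac_subtype_de = 0.05, frac_private_de = 0.05,
  effect_log2fc_sd = 2, dispersion = 0.1, depth_range = c(0.8, 1.25),
  frac_paired_patients = 0, seed = 42))

fx_panel <- generate_drug_panel(
  drug_panel_config(n_drugs = 12, frac_reversal_drugs = 0.25,
                    frac_no_control = 0, noise_sd = 0.5, seed = 7),
  fx_cohort$truth, rownames(fx_cohort$counts),
  targets = drug_targets_from_cohort(fx_cohort))

# brute-force step-up BH oracle (independent of stats::p.adjust)
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  fdr <- numeric(n)
  for (i in seq_len(n)) {
    cand <- vapply(i:n, function(j) p[o[j]] * n / j, numeric(1))
    fdr[o[i]] <- min(1, min(cand))
  }
  fdr
}

# exhaustive running-sum oracle for the weighted enrichment score:
# walks every position of the ranking, tracking the extrema by hand,
# then applies the contract's tie rule (positive extremum wins a tie,
# to floating-point tolerance)
oracle_es <- function(ranked, set_w) {
  N <- length(ranked)
  W <- sum(set_w)
  nmiss <- N - length(set_w)
  rs <- 0
  hi <- -Inf
  lo <- Inf
  for (i in seq_len(N)) {
    g <- ranked[i]
    rs <- if (g %in% names(set_w)) rs + set_w[[g]] / W
          else rs - 1 / nmiss
    if (rs > hi) hi <- rs
    if (rs < lo) lo <- rs
  }
  if (hi >= -lo - 1e-12) hi else lo
}

# random drug-signature-like ranking scaffold
rand_drug_sig <- function(genes, seed) {
  with_seed(seed, {
    sig <- data.frame(gene = genes,
                      slope = rnorm(length(genes)),
                      moderated_t = rnorm(length(genes)),
                      p = runif(length(genes)),
                      stringsAsFactors = FALSE)
    sig$fdr <- bh_fdr(sig$p)
    class(sig) <- c("rc_drug_signature", "data.frame")
    sig
  })
}
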