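# Aggregation of connectivity results: per-drug negative-enrichment
# frequencies, empirical cumulative P-values against the distribution
# of "empty" (low-DEG) drug signatures, per-decile FDR on the %DEG
# quality covariate, gene directionality against the group signature,
# and replicate sign consistency.

#' Negative-enrichment frequency of one drug
#'
#' Fraction of scored samples flagged negatively enriched; unscorable
#' pairs are excluded from both numerator and denominator.
#'
#' @param results connectivity rows for a single drug (as produced by
#'   [score_connectivity()]).
#' @return frequency in `[0, 1]`, or `NA_real_` (with a warning) when
#'   no sample was scorable.
#' @export
enrichment_frequency <- function(results) {
  sc <- results[results$scored %in% TRUE, , drop = FALSE]
  if (!nrow(sc)) {
    warning("drug has zero scored samples; dropped")
    return(NA_real_)
  }
  mean(sc$negative_enriched)
}

#' Monte-Carlo null threshold on the number of DEG
#'
#' How many genes would pass `fdr < fdr_cutoff` by chance 95% of the
#' time: draws `n_genes` uniform p-values, applies Benjamini-Hochberg,
#' counts genes under the cutoff, and returns the 95th percentile over
#' `n_mc` replicates. Drugs with fewer DEG than this threshold form the
#' empirical null for [cumulative_enrichment_p()].
#'
#' @param n_genes number of genes per signature.
#' @param fdr_cutoff DEG cutoff (default 0.5).
#' @param n_mc Monte-Carlo replicates (default 10000).
#' @param seed integer seed.
#' @return integer threshold (count of genes).
#' @export
null_deg_threshold <- function(n_genes, fdr_cutoff = 0.5, n_mc = 10000,
                               seed = 1) {
  .check(n_genes >= 1, "n_genes must be >= 1")
  with_seed(seed, {
    counts <- vapply(seq_len(n_mc), function(i) {
      ps <- sort(runif(n_genes))
      fdr <- rev(cummin(rev(ps * n_genes / seq_len(n_genes))))
      sum(fdr < fdr_cutoff)
    }, numeric(1))
    as.integer(quantile(counts, 0.95, type = 1, names = FALSE))
  })
}

#' Cumulative enrichment P-value against the low-DEG null drugs
#'
#' `p = (1 + #{null drugs with neg_freq >= drug's neg_freq}) /
#'  (n_null + 1)`.
#'
#' @param neg_freq the drug's negative-enrichment frequency.
#' @param null_freqs frequencies of the null (low-DEG) drugs.
#' @return empirical p-value.
#' @export
cumulative_enrichment_p <- function(neg_freq, null_freqs) {
  null_freqs <- null_freqs[!is.na(null_freqs)]
  if (!length(null_freqs))
    stop("empty null-drug set: supply drugs whose DEG count is below ",
         "null_deg_threshold()", call. = FALSE)
  if (length(null_freqs) < 20)
    warning("fewer than 20 null drugs (", length(null_freqs),
            "); cumulative P is coarse")
  (1 + sum(null_freqs >= neg_freq)) / (length(null_freqs) + 1)
}

#' Per-decile FDR on cumulative enrichment P-values
#'
#' Drugs are ranked by %DEG (ties broken by drug id), split into 10
#' equal-size bins, and Benjamini-Hochberg is applied to `cum_p` within
#' each bin separately, so signature quality cannot confound the
#' correction.
#'
#' @param summaries data.frame with `drug_id`, `pct_deg`, `cum_p`.
#' @return the data.frame with `decile` and `fdr` columns added.
#' @export
decile_fdr <- function(summaries) {
  .check(nrow(summaries) >= 10, "need >= 10 drugs for deciles")
  o <- order(summaries$pct_deg, summaries$drug_id)
  rank <- integer(nrow(summaries)); rank[o] <- seq_len(nrow(summaries))
  summaries$decile <- as.integer(ceiling(rank * 10 / nrow(summaries)))
  summaries$fdr <- NA_real_
  for (d in unique(summaries$decile)) {
    in_d <- summaries$decile == d & !is.na(summaries$cum_p)
    if (any(in_d)) summaries$fdr[in_d] <- bh_fdr(summaries$cum_p[in_d])
  }
  summaries
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Pearson correlation of tie-averaged ranks; the p-value uses
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of
#' freedom (two-sided).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho` and `p`.
#' @export
spearman <- function(x, y) {
  .check(length(x) == length(y) && length(x) >= 3,
         "x and y must have equal length >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant vector: Spearman correlation undefined", call. = FALSE)
  rho <- cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
  n <- length(x)
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tstat), df = n - 2))
}

#' Gene inclusion and directionality across sample signatures
#'
#' For each gene of the group signature thresholded at FDR < 1%:
#' how often it enters the individual sample signatures at
#' `fdr_sample`, and -- among those inclusions -- how often its sign
#' agrees with the group signature. Genes never included, or absent
#' from the thresholded group signature, are reported with `NA`
#' direction.
#'
#' @param sample_sigs list of sample `rc_signature`s.
#' @param group_sig the group `rc_signature`.
#' @param fdr_sample per-sample inclusion cutoff (1% or 50% in the
#'   headline figure).
#' @param fdr_group group-signature cutoff (default 0.01).
#' @return data.frame: gene, in_group, inclusion_freq,
#'   frac_same_direction.
#' @export
gene_directionality <- function(sample_sigs, group_sig,
                                fdr_sample = 0.01, fdr_group = 0.01) {
  genes <- group_sig$gene
  gsel <- group_sig$fdr < fdr_group & group_sig$log2fc != 0
  gsign <- setNames(sign(group_sig$log2fc), group_sig$gene)
  inc <- matrix(FALSE, length(genes), length(sample_sigs))
  same <- matrix(NA, length(genes), length(sample_sigs))
  for (j in seq_along(sample_sigs)) {
    s <- sample_sigs[[j]]
    stopifnot(identical(s$gene, genes))
    in_j <- s$fdr < fdr_sample & s$log2fc != 0
    inc[, j] <- in_j
    same[in_j, j] <- sign(s$log2fc[in_j]) == gsign[genes][in_j]
  }
  freq <- rowMeans(inc)
  frac <- vapply(seq_along(genes), function(i) {
    v <- same[i, inc[i, ]]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
  frac[!gsel] <- NA_real_
  data.frame(gene = genes, in_group = gsel, inclusion_freq = freq,
             frac_same_direction = frac, stringsAsFactors = FALSE)
}

#' Sign consistency of connectivity scores across replicate analyses
#'
#' Pairs of scores for the same (sample or patient, drug) are binned by
#' the first analysis' P-value -- `[0.01, 0.1)`, `[0.001, 0.01)` and
#' `< 0.001` -- and the fraction with matching sign is reported per
#' bin. A zero score counts as a sign mismatch against a non-zero
#' partner.
#'
#' @param pairs data.frame with `score1`, `p1`, `score2`.
#' @return data.frame: interval, n_pairs, same_sign_fraction (NA for
#'   empty bins).
#' @export
directional_consistency <- function(pairs) {
  bins <- list("[0.01,0.1)" = c(0.01, 0.1),
               "[0.001,0.01)" = c(0.001, 0.01),
               "<0.001" = c(0, 0.001))
  same <- sign(pairs$score1) == sign(pairs$score2)
  out <- lapply(names(bins), function(b) {
    lim <- bins[[b]]
    in_b <- pairs$p1 >= lim[1] & pairs$p1 < lim[2]
    data.frame(interval = b, n_pairs = sum(in_b),
               same_sign_fraction = if (any(in_b)) mean(same[in_b])
                                    else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Summarize a connectivity run into per-drug statistics
#'
#' Computes per-drug negative-enrichment frequencies, identifies the
#' empirical-null drugs (DEG count below [null_deg_threshold()]),
#' attaches cumulative enrichment P-values and the per-decile FDR.
#'
#' @param results connectivity data.frame from [score_connectivity()].
#' @param drug_status status table from [drug_signatures()] (supplies
#'   pct_deg per drug).
#' @param n_genes number of genes per drug signature (for the null
#'   threshold).
#' @param deg_fdr_cutoff DEG cutoff (default 0.5).
#' @param n_mc,seed Monte-Carlo budget for the null threshold.
#' @return data.frame: drug_id, pct_deg, n_scored, neg_freq, is_null,
#'   cum_p, decile, fdr.
#' @export
summarize_connectivity <- function(results, drug_status, n_genes,
                                   deg_fdr_cutoff = 0.5, n_mc = 2000,
                                   seed = 1) {
  st <- drug_status[drug_status$status == "OK", , drop = FALSE]
  freq <- vapply(st$drug, function(d)
    enrichment_frequency(results[results$drug_id == d, , drop = FALSE]),
    numeric(1))
  n_scored <- vapply(st$drug, function(d)
    sum(results$drug_id == d & results$scored %in% TRUE), numeric(1))
  thr <- null_deg_threshold(n_genes, deg_fdr_cutoff, n_mc, seed)
  deg_count <- st$pct_deg / 100 * n_genes
  is_null <- deg_count < thr
  out <- data.frame(drug_id = st$drug, pct_deg = st$pct_deg,
                    n_scored = n_scored, neg_freq = freq,
                    is_null = is_null, stringsAsFactors = FALSE)
  out <- out[!is.na(out$neg_freq), , drop = FALSE]
  null_freqs <- out$neg_freq[out$is_null]
  out$cum_p <- vapply(out$neg_freq, function(f)
    cumulative_enrichment_p(f, null_freqs), numeric(1))
  decile_fdr(out)
}
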