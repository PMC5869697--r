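# Connectivity mapping: each tumour-sample query signature (genes
# under 1% FDR, weighted by |log2FC|) is scored against each drug's
# moderated-t ranking with a two-set weighted Kolmogorov-Smirnov
# statistic; significance comes from gene-label permutations. A
# negative connectivity score means the drug's expression changes
# oppose the tumour signature; negative enrichment is a negative score
# with permutation P < 0.05.

#' Build a weighted query signature from a tumour signature
#'
#' Up/down gene sets are the genes with `fdr < fdr_cutoff` split by the
#' sign of their log2 fold change, weighted by `|log2fc|`. An optional
#' gene subset (e.g. the directly measured landmark genes of the drug
#' platform) is applied before thresholding.
#'
#' @param sig an `rc_signature`.
#' @param fdr_cutoff query FDR threshold (default 0.01).
#' @param gene_subset optional character vector; genes outside it are
#'   dropped before thresholding.
#' @return an `rc_query`: list with `up`, `down` (named weight
#'   vectors), `sample_id`, `unscorable` (TRUE when both sets are
#'   empty).
#' @export
build_query <- function(sig, fdr_cutoff = 0.01, gene_subset = NULL) {
  .check(nrow(sig) > 0, "empty signature")
  s <- sig
  if (!is.null(gene_subset)) s <- s[s$gene %in% gene_subset, , drop = FALSE]
  hit <- s$fdr < fdr_cutoff & s$log2fc != 0
  up <- s[hit & s$log2fc > 0, , drop = FALSE]
  dn <- s[hit & s$log2fc < 0, , drop = FALSE]
  structure(list(up = setNames(abs(up$log2fc), up$gene),
                 down = setNames(abs(dn$log2fc), dn$gene),
                 sample_id = attr(sig, "contrast_id"),
                 unscorable = nrow(up) + nrow(dn) == 0),
            class = "rc_query")
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the drug-ranked gene list; a hit at gene `j` adds
#' `w_j / sum(w)`, a miss subtracts `1 / (N - N_hit)`. The score is the
#' running-sum value of maximal absolute magnitude (signed; the
#' positive extremum wins an exact tie). +1 means the whole set sits at
#' the top of the ranking, -1 at the bottom.
#'
#' @param ranked_genes character vector of unique genes ordered by
#'   decreasing drug statistic.
#' @param gene_set named numeric vector of positive weights; names must
#'   all appear in `ranked_genes`.
#' @return enrichment score in `[-1, 1]`.
#' @export
weighted_es <- function(ranked_genes, gene_set) {
  .check(!anyDuplicated(ranked_genes), "ranked list has duplicate genes")
  .check(length(gene_set) > 0, "empty gene set: enrichment undefined")
  .check(all(names(gene_set) %in% ranked_genes),
         "gene_set must be a subset of the ranked list")
  .check(all(gene_set > 0), "weights must be positive")
  N <- length(ranked_genes)
  m <- length(gene_set)
  if (m == N) return(1)
  w <- setNames(rep(0, N), ranked_genes)
  w[names(gene_set)] <- gene_set / sum(gene_set)
  step <- unname(ifelse(w > 0, w, -1 / (N - m)))
  rs <- cumsum(step)
  hi <- max(rs); lo <- min(rs)
  # the positive extremum wins a tie (to fp tolerance)
  if (hi >= -lo - 1e-12) hi else lo
}

# vectorized ES over permutations, from sorted hit positions.
# pos, w: m x B matrices, columns sorted by position; N: universe size.
.es_from_sorted <- function(pos, w, N) {
  m <- nrow(pos); B <- ncol(pos)
  if (m == N) return(rep(1, B))
  cw <- .colcumsum(w)
  W <- rep(cw[m, ], each = m)
  miss <- (pos - seq_len(m)) / (N - m)
  H <- cw / W - miss                       # running sum just after hit j
  L <- rbind(0, cw[-m, , drop = FALSE]) / W - miss   # just before hit j
  maxH <- .colmax(H)
  minL <- pmin(.colmin(L), 0)
  ifelse(maxH >= -minL - 1e-12, maxH, minL)
}

# sort position/weight columns jointly (positions ascending per column)
.sort_pos_w <- function(pos, w) {
  m <- nrow(pos); B <- ncol(pos)
  ord <- order(rep(seq_len(B), each = m), as.vector(pos))
  list(pos = matrix(as.vector(pos)[ord], m, B),
       w = matrix(as.vector(w)[ord], m, B))
}

# permutation ES for random sets of size m with fixed weights
.es_perm <- function(N, weights, n_perm) {
  m <- length(weights)
  if (m == N) return(rep(1, n_perm))
  pos <- vapply(seq_len(n_perm), function(i) sample.int(N, m),
                integer(m))
  s <- .sort_pos_w(matrix(pos, m, n_perm), matrix(weights, m, n_perm))
  .es_from_sorted(s$pos, s$w, N)
}

# permutation scores for a two-set query: the up and down sets are
# redrawn jointly (disjoint, as real queries are) with weights kept.
# Pure-R twin of the compiled kernel; kept as the independent oracle.
.score_perm_r <- function(N, w_up, w_dn, n_perm) {
  mu <- length(w_up); md <- length(w_dn); m <- mu + md
  pos <- vapply(seq_len(n_perm), function(i) sample.int(N, m),
                integer(m))
  pos <- matrix(pos, m, n_perm)
  es_up <- if (mu > 0) {
    s <- .sort_pos_w(pos[seq_len(mu), , drop = FALSE],
                     matrix(w_up, mu, n_perm))
    .es_from_sorted(s$pos, s$w, N)
  } else rep(0, n_perm)
  es_dn <- if (md > 0) {
    s <- .sort_pos_w(pos[mu + seq_len(md), , drop = FALSE],
                     matrix(w_dn, md, n_perm))
    .es_from_sorted(s$pos, s$w, N)
  } else rep(0, n_perm)
  same <- sign(es_up) == sign(es_dn) & es_up != 0 & es_dn != 0
  ifelse(same, 0, (es_up - es_dn) / 2)
}

# drug ranking: genes by decreasing moderated t, ties broken by gene id
.drug_ranking <- function(drug_sig) {
  drug_sig$gene[order(-drug_sig$moderated_t, drug_sig$gene)]
}

# combine two enrichment scores under the classic two-set convention
.combine_es <- function(es_up, es_down) {
  if (sign(es_up) == sign(es_down) && es_up != 0 && es_down != 0) 0
  else (es_up - es_down) / 2
}

#' Connectivity score of a query against a drug signature
#'
#' Query genes absent from the drug platform are dropped; the up and
#' down enrichment scores on the drug's t-ranking are combined as
#' `(es_up - es_down) / 2` when their signs differ (or one is 0) and 0
#' otherwise. Score < 0 means the drug's expression change opposes the
#' tumour signature.
#'
#' @param query an `rc_query`.
#' @param drug_sig an `rc_drug_signature`.
#' @param min_shared minimum number of query genes present on the drug
#'   platform (default 5); below it the pair is unscorable.
#' @return list with `score`, `es_up`, `es_down`, `n_shared_genes`,
#'   `unscorable`.
#' @export
connectivity_score <- function(query, drug_sig, min_shared = 5) {
  ranking <- .drug_ranking(drug_sig)
  up <- query$up[names(query$up) %in% ranking]
  dn <- query$down[names(query$down) %in% ranking]
  n_shared <- length(up) + length(dn)
  if (query$unscorable || n_shared < min_shared)
    return(list(score = NA_real_, es_up = NA_real_, es_down = NA_real_,
                n_shared_genes = n_shared, unscorable = TRUE))
  es_up <- if (length(up)) weighted_es(ranking, up) else 0
  es_dn <- if (length(dn)) weighted_es(ranking, dn) else 0
  list(score = .combine_es(es_up, es_dn), es_up = es_up, es_down = es_dn,
       n_shared_genes = n_shared, unscorable = FALSE)
}

#' Gene-permutation p-value for a connectivity score
#'
#' Each permutation redraws gene sets of the same sizes uniformly from
#' the drug platform's genes (weights kept, genes resampled without
#' replacement) and recomputes the combined score;
#' `p = (1 + #{|score_perm| >= |score|}) / (n_perm + 1)` (two-sided on
#' the absolute score).
#'
#' @param query an `rc_query`.
#' @param drug_sig an `rc_drug_signature`.
#' @param score observed score from [connectivity_score()].
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed for this pair's permutation stream (derive
#'   it from the global seed with [derive_seed()]).
#' @param min_shared as in [connectivity_score()].
#' @return p-value in `(0, 1]`.
#' @export
permutation_p <- function(query, drug_sig, score, n_perm = 1000,
                          seed = 1, min_shared = 5) {
  .check(n_perm >= 1, "n_perm must be >= 1")
  ranking <- .drug_ranking(drug_sig)
  up <- query$up[names(query$up) %in% ranking]
  dn <- query$down[names(query$down) %in% ranking]
  N <- length(ranking)
  with_seed(seed, {
    perm <- .score_perm_cpp(N, unname(up), unname(dn), n_perm)
    (1 + sum(abs(perm) >= abs(score))) / (n_perm + 1)
  })
}

#' Negative-enrichment predicate
#'
#' The operational criterion for therapeutic potential: a negative
#' connectivity score whose permutation P-value is below 0.05.
#'
#' @param score connectivity score(s).
#' @param p permutation p-value(s).
#' @return logical vector.
#' @export
is_negative_enrichment <- function(score, p) score < 0 & p < 0.05

#' Score every (query, drug) pair of a panel
#'
#' @param queries named list of `rc_query` objects (names = sample
#'   ids).
#' @param drug_sigs named list of `rc_drug_signature` objects.
#' @param n_perm permutations per pair. For group/subtype queries the
#'   published convention is `1000 * n_tumour_samples`; pass it here.
#' @param seed global seed; each pair's stream is derived from
#'   `(seed, sample_id, drug_id)`.
#' @param min_shared minimum shared genes per pair.
#' @return data.frame: sample_id, drug_id, score, p, n_shared_genes,
#'   negative_enriched, scored. Unscorable pairs keep a row with
#'   `scored = FALSE` and NA score/p.
#' @export
score_connectivity <- function(queries, drug_sigs, n_perm = 1000,
                               seed = 1, min_shared = 5) {
  rows <- vector("list", length(queries) * length(drug_sigs))
  r <- 0L
  for (qi in seq_along(queries)) {
    q <- queries[[qi]]
    qid <- names(queries)[qi]
    for (di in seq_along(drug_sigs)) {
      did <- names(drug_sigs)[di]
      cs <- connectivity_score(q, drug_sigs[[di]], min_shared)
      r <- r + 1L
      if (cs$unscorable) {
        rows[[r]] <- data.frame(sample_id = qid, drug_id = did,
                                score = NA_real_, p = NA_real_,
                                n_shared_genes = cs$n_shared_genes,
                                negative_enriched = NA, scored = FALSE,
                                stringsAsFactors = FALSE)
        next
      }
      p <- permutation_p(q, drug_sigs[[di]], cs$score, n_perm,
                         seed = derive_seed(seed, qid, did), min_shared)
      rows[[r]] <- data.frame(sample_id = qid, drug_id = did,
                              score = cs$score, p = p,
                              n_shared_genes = cs$n_shared_genes,
                              negative_enriched =
                                is_negative_enrichment(cs$score, p),
                              scored = TRUE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
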