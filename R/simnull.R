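# The simulation study: extract per-gene (mu, size) from the fitted
# group or subtype models, simulate batches of pseudo-tumour samples
# with the observed sequencing-depth distribution, run the full
# per-sample pipeline on each batch (signatures -> connectivity ->
# negative-enrichment counts), and locate the observed individual
# enrichment frequency against the simulated distribution. Simulated
# samples are contrasted against the real normal samples, and the
# normal-side intercept is re-fitted within every per-sample contrast.

#' Extract a fitted NB generator from a two-group fit
#'
#' Takes the tumour-condition fitted means rescaled to unit depth and
#' pairs them with `size = 1 / phi` (a zero dispersion flags the
#' Poisson limit) and the pool of observed tumour depth factors.
#' Genes whose IRLS did not converge fall back to the observed
#' depth-normalized group mean and are flagged.
#'
#' @param fit `rc_nbfit` of a two-group (intercept + case indicator)
#'   model; the case coefficient must be the second column.
#' @param counts the counts the fit was computed on (fallback means).
#' @param case logical vector marking the tumour-condition samples.
#' @param source label, e.g. `"group"` or `"subtype:2"`.
#' @return an `rc_generator`: list with `mu` (per-gene mean at unit
#'   depth), `size`, `poisson` flag, `depth_pool`, `fallback` (logical
#'   per gene), `source`.
#' @export
extract_generator <- function(fit, counts, case, source = "group") {
  stopifnot(inherits(fit, "rc_nbfit"))
  d <- exp(fit$offsets)
  mu <- if (ncol(fit$coefficients) >= 2)
    exp(fit$coefficients[, 1] + fit$coefficients[, 2])
  else exp(fit$coefficients[, 1])
  fb <- !fit$converged
  if (any(fb)) {
    Y <- as.matrix(counts)
    obs <- rowSums(Y[, case, drop = FALSE]) / sum(d[case])
    mu[fb] <- pmax(obs[fb], .MU_EPS)
  }
  phi <- fit$dispersion
  structure(list(mu = mu, size = if (phi == 0) Inf else 1 / phi,
                 poisson = phi == 0, depth_pool = d[case],
                 fallback = fb, source = source),
            class = "rc_generator")
}

#' Simulate a batch of pseudo-tumour samples from fitted generators
#'
#' Depth factors are resampled with replacement from the generator's
#' observed pool; counts are `NB(depth * mu, size)` (Poisson when
#' flagged). A list of generators plus mixture proportions draws each
#' sample's generator first -- the subtype-mixture null.
#'
#' @param gen an `rc_generator`, or a list of them.
#' @param n_samples batch size.
#' @param seed integer seed.
#' @param props mixture proportions when `gen` is a list (defaults to
#'   equal).
#' @return integer gene x sample count matrix (columns `sim01`, ...).
#' @export
simulate_batch <- function(gen, n_samples, seed = 1, props = NULL) {
  .check(n_samples >= 1, "n_samples must be >= 1")
  gens <- if (inherits(gen, "rc_generator")) list(gen) else gen
  if (is.null(props)) props <- rep(1 / length(gens), length(gens))
  .check(length(props) == length(gens), "one proportion per generator")
  G <- length(gens[[1]]$mu)
  with_seed(seed, {
    which_gen <- if (length(gens) == 1) rep(1L, n_samples)
                 else sample.int(length(gens), n_samples, replace = TRUE,
                                 prob = props)
    out <- matrix(0L, G, n_samples)
    depth <- numeric(n_samples)
    for (j in seq_len(n_samples)) {
      g <- gens[[which_gen[j]]]
      depth[j] <- sample(g$depth_pool, 1, replace = TRUE)
      m <- depth[j] * g$mu
      out[, j] <- if (g$poisson) rpois(G, m)
                  else rnbinom(G, mu = m, size = g$size)
    }
    dimnames(out) <- list(names(gens[[1]]$mu),
                          sprintf("sim%03d", seq_len(n_samples)))
    attr(out, "depth") <- depth
    out
  })
}

# per-sample pipeline on one simulated batch: signatures against the
# real normals, queries, connectivity, negative-enrichment counts
.batch_neg_counts <- function(sim_counts, normals, dispersion,
                              drug_sigs, query_fdr, n_perm,
                              min_shared, seed) {
  Y <- cbind(normals, sim_counts)
  meta <- data.frame(sample_id = colnames(Y),
                     tissue = rep(c("normal", "tumour"),
                                  c(ncol(normals), ncol(sim_counts))),
                     subtype = NA_character_, stringsAsFactors = FALSE)
  offs <- log(effective_lib_sizes(Y))
  sigs <- make_signatures(Y, meta, dispersion, kind = "sample",
                          offsets = offs)
  queries <- lapply(sigs, build_query, fdr_cutoff = query_fdr)
  counts <- setNames(integer(length(drug_sigs)), names(drug_sigs))
  for (di in seq_along(drug_sigs)) {
    did <- names(drug_sigs)[di]
    for (qi in seq_along(queries)) {
      q <- queries[[qi]]
      cs <- connectivity_score(q, drug_sigs[[di]], min_shared)
      if (cs$unscorable) next
      p <- permutation_p(q, drug_sigs[[di]], cs$score, n_perm,
                         seed = derive_seed(seed, names(queries)[qi], did),
                         min_shared = min_shared)
      if (is_negative_enrichment(cs$score, p))
        counts[did] <- counts[did] + 1L
    }
  }
  counts
}

#' Simulated null distribution of negative-enrichment counts
#'
#' Simulates `n_batches` batches from the generator(s), runs the full
#' per-sample pipeline on each (per-sample signatures against the real
#' normal samples, query construction, connectivity with permutation
#' P-values), and records per drug the number of negatively enriched
#' simulated samples. Reports the empirical 2.5%/97.5% interval and
#' the fold-ratio of the observed count against each endpoint.
#'
#' @param gen generator or list of generators (+`props`) as in
#'   [simulate_batch()].
#' @param drug_sigs named list of `rc_drug_signature`s.
#' @param observed_counts named vector: observed number of negatively
#'   enriched real tumour samples per drug.
#' @param normals real normal-sample count matrix (comparison group).
#' @param dispersion cohort dispersion.
#' @param n_batches number of simulated batches (>= 2).
#' @param batch_size samples per batch (the size of the original
#'   batch).
#' @param props mixture proportions for a generator list.
#' @param query_fdr query threshold (default 0.01).
#' @param n_perm permutations per (sample, drug) pair.
#' @param min_shared minimum shared genes per pair.
#' @param seed global seed; batch `b` uses the stream
#'   `derive_seed(seed, "batch", b)`.
#' @return an `rc_simnull`: list with `batch_counts` (n_batches x
#'   n_drugs matrix), `interval` (2 x n_drugs, empirical type-1
#'   percentiles, so 2 batches give min/max), `observed`,
#'   `fold_ratios` (observed / endpoints), `n_batches`, `batch_size`,
#'   `source`.
#' @export
null_enrichment_distribution <- function(gen, drug_sigs, observed_counts,
                                         normals, dispersion,
                                         n_batches = 200, batch_size = 50,
                                         props = NULL, query_fdr = 0.01,
                                         n_perm = 200, min_shared = 5,
                                         seed = 1) {
  .check(n_batches >= 2, "n_batches must be >= 2")
  M <- matrix(NA_integer_, n_batches, length(drug_sigs),
              dimnames = list(NULL, names(drug_sigs)))
  failed <- 0L
  for (b in seq_len(n_batches)) {
    bseed <- derive_seed(seed, "batch", b)
    res <- tryCatch({
      sim <- simulate_batch(gen, batch_size, seed = bseed, props = props)
      .batch_neg_counts(sim, normals, dispersion, drug_sigs, query_fdr,
                        n_perm, min_shared, bseed)
    }, error = function(e) {
      warning("batch ", b, " failed and was skipped: ",
              conditionMessage(e))
      NULL
    })
    if (is.null(res)) failed <- failed + 1L else M[b, ] <- res
  }
  if (failed > 0.1 * n_batches)
    stop("more than 10% of simulated batches failed (", failed, "/",
         n_batches, "); aborting", call. = FALSE)
  M <- M[stats::complete.cases(M), , drop = FALSE]
  interval <- apply(M, 2, quantile, probs = c(0.025, 0.975), type = 1)
  obs <- observed_counts[colnames(M)]
  fold <- rbind(lower = obs / pmax(interval[1, ], 1),
                upper = obs / pmax(interval[2, ], 1))
  src <- if (inherits(gen, "rc_generator")) gen$source
         else paste(vapply(gen, `[[`, "", "source"), collapse = "+")
  structure(list(batch_counts = M, interval = interval, observed = obs,
                 fold_ratios = fold, n_batches = nrow(M),
                 batch_size = batch_size, source = src),
            class = "rc_simnull")
}
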