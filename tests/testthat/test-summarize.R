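# Per-drug enrichment frequencies, the Monte-Carlo null-DEG threshold,
# cumulative empirical P-values, per-decile FDR, Spearman correlation,
# gene directionality and replicate sign consistency.

res_row <- function(drug, neg, scored = TRUE)
  data.frame(sample_id = "S", drug_id = drug, score = -0.5, p = 0.01,
             n_shared_genes = 10, negative_enriched = neg,
             scored = scored, stringsAsFactors = FALSE)

test_that("enrichment frequency excludes unscorable pairs from both sides", {
  res <- do.call(rbind, c(lapply(1:10, function(i)
    res_row("d1", i <= 3)), list(make.row.names = FALSE)))
  expect_equal(enrichment_frequency(res), 0.30)
  res2 <- rbind(res, res_row("d1", NA, scored = FALSE))
  expect_equal(enrichment_frequency(res2), 0.30)
  allbad <- res; allbad$scored <- FALSE
  expect_warning(f <- enrichment_frequency(allbad), "zero scored")
  expect_true(is.na(f))
  # brute-force count on shuffled inputs
  for (s in 1:10) {
    sh <- with_seed(s, res2[sample(nrow(res2)), ])
    expect_equal(enrichment_frequency(sh),
                 sum(sh$negative_enriched & sh$scored, na.rm = TRUE) /
                   sum(sh$scored))
  }
})

test_that("null DEG threshold: single-gene enumeration, stability, monotonicity", {
  # one uniform p: BH fdr = p, count = 1{p < 0.5}, 95th pct = 1
  expect_identical(null_deg_threshold(1, n_mc = 2000, seed = 1), 1L)
  t1 <- null_deg_threshold(500, n_mc = 2000, seed = 2)
  t2 <- null_deg_threshold(500, n_mc = 4000, seed = 3)
  expect_lte(abs(t1 - t2), 1)                 # Monte-Carlo convergence
  ladder <- vapply(c(10, 100, 1000), function(G)
    null_deg_threshold(G, n_mc = 1000, seed = 4), integer(1))
  expect_true(all(diff(ladder) >= 0))         # stochastic dominance in G
})

test_that("cumulative enrichment P follows the +1 empirical rule", {
  nulls <- c(rep(0, 50), runif(49, 0, 0.2))
  expect_equal(suppressWarnings(cumulative_enrichment_p(0.5, nulls)),
               1 / 100)
  expect_equal(suppressWarnings(
    cumulative_enrichment_p(0, c(0, runif(10)))), 1)
  for (s in 1:10) {
    nf <- with_seed(s, runif(40))
    x <- with_seed(s + 50, runif(1))
    expect_equal(cumulative_enrichment_p(x, nf),
                 (1 + sum(nf >= x)) / 41)
  }
  expect_error(cumulative_enrichment_p(0.5, numeric(0)), "null-drug set")
  expect_warning(cumulative_enrichment_p(0.5, runif(5)), "fewer than 20")
  # monotone non-increasing in neg_freq for a fixed null set
  nf <- with_seed(9, runif(60))
  ps <- vapply(seq(0, 1, 0.05), cumulative_enrichment_p,
               numeric(1), null_freqs = nf)
  expect_true(all(diff(ps) <= 0))
})

test_that("decile FDR bins by %DEG rank and applies BH within bins", {
  summ <- data.frame(drug_id = sprintf("d%02d", 1:10),
                     pct_deg = 1:10, cum_p = rep(0.01, 10),
                     stringsAsFactors = FALSE)
  out <- decile_fdr(summ)
  expect_identical(out$decile, 1:10)          # one drug per decile
  expect_equal(out$fdr, out$cum_p)            # single-drug BH identity
  # a decile of identical cum_p keeps them unchanged under BH
  summ2 <- data.frame(drug_id = sprintf("d%02d", 1:20),
                      pct_deg = rep(1:10, each = 2),
                      cum_p = rep(0.01, 20), stringsAsFactors = FALSE)
  out2 <- decile_fdr(summ2)
  expect_equal(out2$fdr, rep(0.01, 20))
  # pooled-then-split brute force on random inputs
  summ3 <- data.frame(drug_id = sprintf("d%03d", 1:40),
                      pct_deg = with_seed(5, sample(100, 40, TRUE)),
                      cum_p = with_seed(6, runif(40)),
                      stringsAsFactors = FALSE)
  out3 <- decile_fdr(summ3)
  o <- order(summ3$pct_deg, summ3$drug_id)
  for (d in 1:10) {
    members <- summ3$drug_id[o][(d - 1) * 4 + 1:4]
    idx <- match(members, out3$drug_id)
    expect_identical(sort(unique(out3$decile[idx])), d)
    expect_equal(out3$fdr[idx], oracle_bh(out3$cum_p[idx]))
  }
})

test_that("spearman handles monotone pairs, ties, and constant input", {
  expect_equal(spearman(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman(1:10, -(1:10))$rho, -1)
  x <- c(1, 2, 2, 3, 5, 5, 5, 8)
  y <- c(2, 1, 4, 4, 6, 7, 5, 9)
  s <- spearman(x, y)
  expect_equal(s$rho, cor(rank(x), rank(y)))
  ref <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(s$rho, unname(ref$estimate), tolerance = 1e-10)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
})

test_that("gene directionality counts inclusions and sign agreement", {
  mk <- function(fc, fdr, id) {
    s <- data.frame(gene = c("g1", "g2", "g3"), log2fc = fc,
                    p = fdr / 2, fdr = fdr, stringsAsFactors = FALSE)
    attr(s, "contrast_id") <- id
    class(s) <- c("rc_signature", "data.frame")
    s
  }
  group <- mk(c(2, -1, 0.5), c(0.001, 0.001, 0.5), "group")
  samples <- list(mk(c(1, 1, 1), c(0.001, 0.001, 0.9), "s1"),
                  mk(c(2, -2, 1), c(0.001, 0.9, 0.9), "s2"))
  gd <- gene_directionality(samples, group, fdr_sample = 0.01)
  # g1: in both samples, always same sign as group -> (1, 1)
  expect_equal(gd[gd$gene == "g1", c("inclusion_freq",
                                     "frac_same_direction")],
               data.frame(inclusion_freq = 1, frac_same_direction = 1),
               ignore_attr = TRUE)
  # g2: included once with opposite sign
  expect_equal(gd$inclusion_freq[gd$gene == "g2"], 0.5)
  expect_equal(gd$frac_same_direction[gd$gene == "g2"], 0)
  # g3: never included and outside the thresholded group signature
  expect_equal(gd$inclusion_freq[gd$gene == "g3"], 0)
  expect_true(is.na(gd$frac_same_direction[gd$gene == "g3"]))
  expect_false(gd$in_group[gd$gene == "g3"])
})

test_that("directionality on planted data: opposing private effects dilute agreement", {
  co <- generate_cohort(cohort_config(
    n_tumour = 12, n_normal = 15, n_genes = 500, frac_group_de = 0.1,
    frac_subtype_de = 0, frac_private_de = 0.1, effect_log2fc_sd = 2,
    dispersion = 0.1, seed = 91, frac_paired_patients = 0))
  filt <- filter_low_expressed(co$counts)
  gp <- make_signatures(filt, co$samples, 0.1, "group")$group
  ss <- make_signatures(filt, co$samples, 0.1, "sample")
  gd <- gene_directionality(ss, gp, fdr_sample = 0.5)
  # group-DE genes that also carry an opposing private effect somewhere
  gtr <- co$truth[co$truth$scope == "group", ]
  ptr <- co$truth[startsWith(co$truth$scope, "sample:"), ]
  both <- merge(gtr, ptr, by = "gene")
  opp <- unique(both$gene[sign(both$log2fc.x) != sign(both$log2fc.y)])
  opp <- intersect(opp, gd$gene[gd$in_group])
  frac <- gd$frac_same_direction[match(opp, gd$gene)]
  expect_true(any(frac < 1))
  expect_lt(mean(frac, na.rm = TRUE), 1)
})

test_that("directional consistency bins by P and scores sign matches", {
  pairs <- data.frame(score1 = c(0.5, -0.2, 0.3, -0.4),
                      p1 = c(0.05, 0.005, 0.0005, 0.5),
                      score2 = c(0.5, -0.2, 0.3, -0.4))
  rep1 <- directional_consistency(pairs)
  occ <- rep1$n_pairs > 0
  expect_equal(rep1$same_sign_fraction[occ],
               rep(1, sum(occ)))                    # identical replicates
  expect_identical(rep1$n_pairs, c(1L, 1L, 1L))     # p1 = 0.5 binned nowhere
  # independent random scores agree in sign about half the time
  big <- with_seed(8, data.frame(score1 = rnorm(6000),
                                 p1 = runif(6000, 0, 0.1),
                                 score2 = rnorm(6000)))
  rep2 <- directional_consistency(big)
  expect_true(all(abs(rep2$same_sign_fraction - 0.5) < 0.05))
  # zero scores count as mismatches against non-zero partners
  z <- data.frame(score1 = 0, p1 = 0.05, score2 = 1)
  expect_equal(directional_consistency(z)$same_sign_fraction[1], 0)
})

test_that("replicate re-analysis consistency rises as connectivity P falls", {
  # technical replicates: two count-level re-draws from the same
  # planted sample means (the paper-style analytical replicate), each
  # pushed through the full per-sample pipeline
  co <- generate_cohort(cohort_config(
    n_tumour = 12, n_normal = 15, n_genes = 500, frac_group_de = 0.05,
    frac_subtype_de = 0, frac_private_de = 0.08, effect_log2fc_sd = 2,
    dispersion = 0.1, seed = 351, frac_paired_patients = 0))
  G <- nrow(co$counts)
  meta <- co$samples
  L <- matrix(0, G, nrow(meta),
              dimnames = list(rownames(co$counts), meta$sample_id))
  for (i in which(meta$tissue == "tumour")) {
    fc <- planted_log2fc(co, meta$sample_id[i])
    L[names(fc), i] <- fc
  }
  mu_mat <- co$baseline_mu * 2^L * rep(meta$depth, each = G)
  redraw <- function(seed) with_seed(seed, {
    m <- matrix(rnbinom(length(mu_mat), mu = mu_mat, size = 10), G,
                dimnames = dimnames(L))
    storage.mode(m) <- "integer"
    m
  })
  pan <- generate_drug_panel(
    drug_panel_config(n_drugs = 60, frac_reversal_drugs = 0.5,
                      reversal_strength = 0.35, noise_sd = 1.2,
                      frac_no_control = 0, seed = 352),
    co$truth, rownames(co$counts),
    targets = drug_targets_from_cohort(co))
  ds <- drug_signatures(pan)
  analyse <- function(Y, pseed) {
    off <- log(effective_lib_sizes(Y))
    nrm <- meta$tissue == "normal"
    phi <- estimate_dispersion(Y[, nrm, drop = FALSE],
                               matrix(1, sum(nrm), 1), off[nrm])
    sigs <- make_signatures(Y, meta, phi, "sample", offsets = off)
    score_connectivity(lapply(sigs, build_query), ds$signatures,
                       n_perm = 1000, seed = pseed)
  }
  r1 <- analyse(redraw(1001), 11)
  r2 <- analyse(redraw(1002), 99)
  ok <- r1$scored & r2$scored
  rep_ <- directional_consistency(
    data.frame(score1 = r1$score[ok], p1 = r1$p[ok],
               score2 = r2$score[ok]))
  expect_true(all(rep_$n_pairs > 20))
  expect_true(all(diff(rep_$same_sign_fraction) > 0))
})
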