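# Query construction, the weighted KS running sum (against a
# brute-force oracle), score combination, permutation p-values and
# their symmetry/bound invariants.

test_that("query construction applies the FDR rule and gene subset", {
  sig <- data.frame(gene = c("g1", "g2", "g3"),
                    log2fc = c(2, -1, 3),
                    p = c(0.001, 0.001, 0.2),
                    fdr = c(0.005, 0.005, 0.5),
                    stringsAsFactors = FALSE)
  attr(sig, "contrast_id") <- "S1"
  class(sig) <- c("rc_signature", "data.frame")
  q <- build_query(sig)
  expect_equal(q$up, c(g1 = 2))
  expect_equal(q$down, c(g2 = 1))
  expect_false(q$unscorable)
  q2 <- build_query(sig, gene_subset = c("g2", "g3"))
  expect_length(q2$up, 0)
  expect_equal(q2$down, c(g2 = 1))
  q3 <- build_query(sig, fdr_cutoff = 0.001)
  expect_true(q3$unscorable)
})

test_that("query recovers most of a planted sample program", {
  # baseline depth mimics well-expressed post-filter genes: losing a
  # 4-fold down-effect is only detectable from one observation when
  # the gene is not read-starved
  co <- generate_cohort(cohort_config(
    n_tumour = 2, n_normal = 50, n_genes = 600, frac_group_de = 0,
    frac_subtype_de = 0, frac_private_de = 0.2, effect_log2fc_sd = 2,
    dispersion = 0.1, baseline_meanlog = 5.5, baseline_sdlog = 1,
    seed = 19, frac_paired_patients = 0))
  filt <- filter_low_expressed(co$counts)
  sigs <- make_signatures(filt, co$samples, 0.1, "sample")
  q <- build_query(sigs$T001)
  truth <- names(planted_log2fc(co, "T001"))
  truth <- intersect(truth, rownames(filt))
  recovered <- intersect(c(names(q$up), names(q$down)), truth)
  expect_gte(length(recovered) / length(truth), 0.8)
})

test_that("extreme rankings force the enrichment score to +/-1", {
  ranked <- c("a", "b", "c", "d")
  expect_equal(weighted_es(ranked, c(a = 7)), 1)
  expect_equal(weighted_es(ranked, c(d = 7)), -1)
})

test_that("weighted ES equals the exhaustive running-sum oracle", {
  for (s in 1:300) {
    with_seed(s, {
      N <- sample(3:12, 1)
      ranked <- sprintf("g%02d", sample(50, N))
      m <- sample(seq_len(N - 1), 1)
      set_w <- setNames(runif(m, 0.1, 3), sample(ranked, m))
    })
    expect_equal(weighted_es(ranked, set_w),
                 oracle_es(ranked, set_w), tolerance = 1e-12)
  }
})

test_that("the sorted-position ES used in permutations matches weighted_es", {
  for (s in 1:100) {
    with_seed(s, {
      N <- sample(5:40, 1)
      ranked <- sprintf("g%02d", seq_len(N))
      m <- sample(seq_len(N - 1), 1)
      hits <- sort(sample.int(N, m))
      w <- runif(m, 0.2, 2)
    })
    es_ref <- weighted_es(ranked, setNames(w, ranked[hits]))
    es_fast <- revcon:::.es_from_sorted(matrix(hits, m, 1),
                                        matrix(w, m, 1), N)
    expect_equal(es_fast, es_ref, tolerance = 1e-12)
  }
})

test_that("score combination follows the two-set sign convention", {
  expect_equal(revcon:::.combine_es(1, -1), 1)    # drug mimics tumour
  expect_equal(revcon:::.combine_es(-1, 1), -1)   # perfect reversal
  expect_equal(revcon:::.combine_es(0.5, 0.5), 0) # same sign -> 0
  expect_equal(revcon:::.combine_es(0.5, 0), 0.25)
  expect_equal(revcon:::.combine_es(0, -0.4), 0.2)
})

test_that("negating the drug ranking negates ES and score", {
  dsig <- rand_drug_sig(sprintf("g%03d", 1:60), seed = 21)
  q <- structure(list(up = setNames(runif(8, 0.5, 2),
                                    sample(dsig$gene, 8)),
                      down = setNames(runif(6, 0.5, 2),
                                      sample(setdiff(dsig$gene,
                                                     sprintf("g%03d", 1:8)), 6)),
                      sample_id = "S", unscorable = FALSE),
                 class = "rc_query")
  cs <- connectivity_score(q, dsig)
  neg <- dsig; neg$moderated_t <- -neg$moderated_t
  cs2 <- connectivity_score(q, neg)
  expect_equal(cs2$es_up, -cs$es_up, tolerance = 1e-12)
  expect_equal(cs2$es_down, -cs$es_down, tolerance = 1e-12)
  expect_equal(cs2$score, -cs$score, tolerance = 1e-12)
  expect_lte(abs(cs$score), 1)
})

test_that("pairs sharing too few genes are unscorable", {
  dsig <- rand_drug_sig(sprintf("g%03d", 1:30), seed = 22)
  q <- structure(list(up = c(g001 = 1, g002 = 1, zzz = 1),
                      down = c(yyy = 1), sample_id = "S",
                      unscorable = FALSE), class = "rc_query")
  cs <- connectivity_score(q, dsig, min_shared = 5)
  expect_true(cs$unscorable)
  expect_identical(cs$n_shared_genes, 2L)
})

test_that("permutation p obeys the +1 rule and the zero-score tie", {
  dsig <- rand_drug_sig(sprintf("g%03d", 1:80), seed = 23)
  q <- structure(list(up = setNames(rep(1, 5), sprintf("g%03d", 1:5)),
                      down = setNames(rep(1, 5), sprintf("g%03d", 6:10)),
                      sample_id = "S", unscorable = FALSE),
                 class = "rc_query")
  # |observed| = 1.01 can never be beaten -> p = 1/(n+1)
  p <- permutation_p(q, dsig, score = 1.01, n_perm = 1000, seed = 1)
  expect_equal(p, 1 / 1001)
  # score 0 ties with every permutation -> p = 1
  p0 <- permutation_p(q, dsig, score = 0, n_perm = 200, seed = 1)
  expect_equal(p0, 1)
  # determinism under the same derived seed
  p1 <- permutation_p(q, dsig, score = 0.4, n_perm = 300, seed = 7)
  p2 <- permutation_p(q, dsig, score = 0.4, n_perm = 300, seed = 7)
  expect_identical(p1, p2)
})

test_that("compiled permutation kernel matches the R oracle in distribution", {
  wu <- with_seed(3, runif(12, 0.5, 2))
  wd <- with_seed(4, runif(9, 0.5, 2))
  pc <- with_seed(5, revcon:::.score_perm_cpp(60, wu, wd, 3000))
  pr <- with_seed(6, revcon:::.score_perm_r(60, wu, wd, 3000))
  expect_lte(abs(mean(pc) - mean(pr)), 0.02)
  expect_lte(abs(sd(pc) - sd(pr)), 0.02)
  expect_gt(suppressWarnings(ks.test(pc, pr)$p.value), 0.01)
  expect_true(all(abs(pc) <= 1))
})

test_that("a reversal drug scores negative with small p against its target", {
  hits <- 0L
  for (s in 1:10) {
    co <- generate_cohort(cohort_config(
      n_tumour = 4, n_normal = 15, n_genes = 400, frac_group_de = 0.05,
      frac_subtype_de = 0, frac_private_de = 0.08, effect_log2fc_sd = 2,
      dispersion = 0.1, seed = 100 + s, frac_paired_patients = 0))
    pan <- generate_drug_panel(
      drug_panel_config(n_drugs = 2, frac_reversal_drugs = 0.5,
                        reversal_strength = 1, noise_sd = 0.5,
                        frac_no_control = 0, seed = 200 + s),
      co$truth, rownames(co$counts),
      targets = drug_targets_from_cohort(co))
    tr <- pan$truth[pan$truth$type == "reversal", ][1, ]
    sigs <- make_signatures(co$counts, co$samples, 0.1, "sample")
    q <- build_query(sigs[[tr$target]])
    ds <- drug_signatures(pan)
    cs <- connectivity_score(q, ds$signatures[[tr$drug]])
    p <- permutation_p(q, ds$signatures[[tr$drug]], cs$score, 1000,
                       seed = derive_seed(s, tr$target, tr$drug))
    if (!cs$unscorable && cs$score < 0 && p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
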