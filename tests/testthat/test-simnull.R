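# Generator extraction round-trips, simulated-batch moments, and the
# null-distribution bookkeeping (degenerate percentiles, determinism,
# skip/abort behaviour).

sim_fit <- local({
  co <- generate_cohort(cohort_config(
    n_tumour = 100, n_normal = 30, n_genes = 300, frac_group_de = 0.1,
    frac_subtype_de = 0, frac_private_de = 0, effect_log2fc_sd = 1.5,
    dispersion = 0.1, seed = 61, frac_paired_patients = 0))
  off <- log(effective_lib_sizes(co$counts))
  X <- cbind(1, as.numeric(co$samples$tissue == "tumour"))
  list(co = co,
       fit = fit_nb_glm(co$counts, X, off, dispersion = 0.1))
})

test_that("extracted generator recovers the planted tumour-condition means", {
  co <- sim_fit$co
  gen <- extract_generator(sim_fit$fit, co$counts,
                           co$samples$tissue == "tumour")
  expect_s3_class(gen, "rc_generator")
  expect_false(gen$poisson)
  expect_equal(gen$size, 10)
  expect_length(gen$depth_pool, 100)
  # planted tumour mean at unit depth: mu_g * 2^group_fc; offsets are
  # normalized to a unit geometric mean, so compare up to one global
  # scale factor
  tr <- co$truth[co$truth$scope == "group", ]
  planted <- setNames(rep(0, nrow(co$counts)), rownames(co$counts))
  planted[tr$gene] <- tr$log2fc
  true_mu <- co$baseline_mu * 2^planted
  ratio <- gen$mu / true_mu
  scale <- median(ratio)
  expect_lt(median(abs(ratio / scale - 1)), 0.05)
})

test_that("a zero-dispersion fit flags the generator as Poisson", {
  co <- sim_fit$co
  fit0 <- fit_nb_glm(co$counts[1:50, ], cbind(rep(1, 130)),
                     dispersion = 0)
  gen <- extract_generator(fit0, co$counts[1:50, ],
                           rep(TRUE, 130))
  expect_true(gen$poisson)
  expect_identical(gen$size, Inf)
  # at constant depth a Poisson generator gives variance/mean ~ 1
  genc <- structure(list(mu = setNames(runif(200, 5, 50),
                                       sprintf("g%03d", 1:200)),
                         size = Inf, poisson = TRUE, depth_pool = 1,
                         fallback = FALSE, source = "group"),
                    class = "rc_generator")
  sim <- simulate_batch(genc, 500, seed = 5)
  m <- rowMeans(sim); v <- apply(sim, 1, var)
  expect_lt(abs(median(v / m) - 1), 0.1)
})

test_that("simulated counts match the generator's moments and are deterministic", {
  co <- sim_fit$co
  gen <- extract_generator(sim_fit$fit, co$counts,
                           co$samples$tissue == "tumour")
  sim1 <- simulate_batch(gen, 1000, seed = 9)
  sim2 <- simulate_batch(gen, 1000, seed = 9)
  expect_identical(sim1, sim2)
  m <- rowMeans(sim1)
  expected <- mean(attr(sim1, "depth")) * gen$mu
  se <- sqrt((expected + 0.1 * expected^2) / 1000)  # NB variance / n
  frac_in <- mean(abs(m - expected) <= 3 * se * 2)
  expect_gt(frac_in, 0.9)
})

test_that("subtype mixtures draw generators in the stated proportions", {
  g1 <- structure(list(mu = c(a = 10), size = 10, poisson = FALSE,
                       depth_pool = 1, fallback = FALSE,
                       source = "subtype:1"), class = "rc_generator")
  g2 <- structure(list(mu = c(a = 1000), size = 10, poisson = FALSE,
                       depth_pool = 1, fallback = FALSE,
                       source = "subtype:2"), class = "rc_generator")
  sim <- simulate_batch(list(g1, g2), 400, seed = 3, props = c(0.8, 0.2))
  from_g2 <- sim[1, ] > 300
  expect_lt(abs(mean(from_g2) - 0.2), 0.07)
})

test_that("two batches give a min/max interval and results are reproducible", {
  co <- generate_cohort(cohort_config(
    n_tumour = 6, n_normal = 6, n_genes = 120, frac_group_de = 0.2,
    frac_subtype_de = 0, frac_private_de = 0, effect_log2fc_sd = 2,
    dispersion = 0.1, seed = 71, frac_paired_patients = 0))
  off <- log(effective_lib_sizes(co$counts))
  X <- cbind(1, as.numeric(co$samples$tissue == "tumour"))
  fit <- fit_nb_glm(co$counts, X, off, dispersion = 0.1)
  gen <- extract_generator(fit, co$counts, co$samples$tissue == "tumour")
  pan <- generate_drug_panel(
    drug_panel_config(n_drugs = 2, frac_reversal_drugs = 0.5,
                      reversal_strength = 1, noise_sd = 1,
                      frac_no_control = 0, seed = 72),
    co$truth, rownames(co$counts), targets = list(group = "group"))
  ds <- drug_signatures(pan)
  normals <- co$counts[, co$samples$tissue == "normal"]
  obs <- setNames(c(1, 1), names(ds$signatures))
  nl <- null_enrichment_distribution(gen, ds$signatures, obs, normals,
                                     0.1, n_batches = 2, batch_size = 4,
                                     n_perm = 50, seed = 5)
  expect_equal(unname(nl$interval[1, ]),
                   unname(apply(nl$batch_counts, 2, min)))
  expect_equal(unname(nl$interval[2, ]),
                   unname(apply(nl$batch_counts, 2, max)))
  nl2 <- null_enrichment_distribution(gen, ds$signatures, obs, normals,
                                      0.1, n_batches = 2, batch_size = 4,
                                      n_perm = 50, seed = 5)
  expect_identical(nl$batch_counts, nl2$batch_counts)
  expect_error(
    null_enrichment_distribution(gen, ds$signatures, obs, normals, 0.1,
                                 n_batches = 1, batch_size = 4),
    "n_batches")
})

test_that("subtype-mixture null sits between the group null and the observation", {
  # heterogeneity partly subtype-structured: strong subtype programs
  # plus sample-private programs; the drug reverses subtype 1 and the
  # private programs of a few samples outside it
  co <- generate_cohort(cohort_config(
    n_tumour = 24, n_normal = 8, n_genes = 150, n_subtypes = 4,
    subtype_props = rep(0.25, 4), frac_group_de = 0,
    frac_subtype_de = 0.15, frac_private_de = 0.15,
    effect_log2fc_sd = 2, dispersion = 0.1, baseline_meanlog = 4.5,
    baseline_sdlog = 1, seed = 777, frac_paired_patients = 0))
  Y <- co$counts
  off <- log(effective_lib_sizes(Y))
  nrm <- co$samples$tissue == "normal"
  tum <- !nrm
  phi <- estimate_dispersion(Y[, nrm, drop = FALSE],
                             matrix(1, sum(nrm), 1), off[nrm])
  gen_g <- extract_generator(
    fit_nb_glm(Y, cbind(1, as.numeric(tum)), off, dispersion = phi),
    Y, tum, "group")
  gens <- list(); props <- c()
  for (s in c("1", "2", "3", "4")) {
    sel <- nrm | (tum & co$samples$subtype == s)
    Xs <- cbind(1, as.numeric(co$samples$tissue[sel] == "tumour"))
    f <- fit_nb_glm(Y[, sel], Xs, off[sel], dispersion = phi)
    gens[[s]] <- extract_generator(f, Y[, sel],
                                   co$samples$tissue[sel] == "tumour",
                                   paste0("subtype:", s))
    props <- c(props, mean(co$samples$subtype[tum] == s))
  }
  pan <- generate_drug_panel(
    drug_panel_config(n_drugs = 1, frac_reversal_drugs = 1,
                      reversal_strength = 0.6, noise_sd = 1,
                      frac_no_control = 0, seed = 778),
    co$truth, rownames(Y),
    targets = list(mix = c("subtype:1",
      paste0("sample:", head(co$samples$sample_id[
        tum & co$samples$subtype != "1"], 4)))))
  ds <- drug_signatures(pan)
  normals <- Y[, nrm, drop = FALSE]
  obs <- revcon:::.batch_neg_counts(Y[, tum, drop = FALSE], normals,
                                    phi, ds$signatures, 0.01, 100, 5,
                                    derive_seed(777, "obs"))
  nl_g <- null_enrichment_distribution(
    gen_g, ds$signatures, obs, normals, phi, n_batches = 100,
    batch_size = 24, n_perm = 100, seed = derive_seed(777, "g"))
  nl_s <- null_enrichment_distribution(
    gens, ds$signatures, obs, normals, phi, n_batches = 100,
    batch_size = 24, n_perm = 100, props = props,
    seed = derive_seed(777, "s"))
  mid_g <- mean(nl_g$interval[, 1])
  mid_s <- mean(nl_s$interval[, 1])
  expect_lt(mid_g, mid_s)
  expect_lt(mid_s, obs)
})
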