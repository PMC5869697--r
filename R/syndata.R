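# Synthetic tumour cohorts and drug perturbation panels with known
# ground truth. The generator emulates the statistical structure the
# downstream analysis assumes: NB-distributed counts with group-,
# subtype- and sample-private differential-expression programs, and
# drug experiments with controls, covariates, and a subset of
# "reversal" drugs whose effect vector opposes a tumour program.

#' Configuration for a synthetic tumour cohort
#'
#' Defaults mirror a large renal-carcinoma mRNA-seq cohort: 534 tumour
#' and 72 matched normal samples, 11,333 genes after filtering, four
#' molecular subtypes, and a stage distribution matching the published
#' cohort table. Counts are negative binomial with
#' `variance = mu + dispersion * mu^2`.
#'
#' @param n_tumour,n_normal,n_genes cohort dimensions.
#' @param n_subtypes number of molecular subtypes.
#' @param subtype_props probability vector over subtypes (sums to 1).
#' @param frac_group_de fraction of genes differentially expressed in
#'   all tumours.
#' @param frac_subtype_de fraction of genes DE in each subtype.
#' @param frac_private_de fraction of genes DE privately per tumour
#'   sample (before stage scaling).
#' @param effect_log2fc_sd magnitude of planted log2 fold changes;
#'   signs are +/- with equal probability, the magnitude is fixed so
#'   recovery tolerances are sharp.
#' @param dispersion NB dispersion phi (`size = 1/phi`); 0 gives
#'   Poisson counts.
#' @param depth_range `(min, max)` library-size factors; depths are
#'   drawn log-uniformly over this range.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-gene baseline mean `mu_g`, chosen to mimic the RNA-seq dynamic
#'   range so the CPM filter behaves realistically.
#' @param stage_props probability vector over tumour stages I-IV.
#' @param stage_private_mult multiplier on `frac_private_de` per stage;
#'   the default of 1 for every stage decouples heterogeneity from
#'   stage, set an increasing vector to couple them.
#' @param frac_paired_patients fraction of tumour samples that arrive
#'   as a second sample from an already-sampled patient (shared
#'   subtype/stage/group effects, independent private program).
#' @param seed integer seed; identical configuration gives bit-identical
#'   output.
#' @return a validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_tumour = 534, n_normal = 72, n_genes = 11333,
                          n_subtypes = 4,
                          subtype_props = rep(1 / n_subtypes, n_subtypes),
                          frac_group_de = 0.10, frac_subtype_de = 0.05,
                          frac_private_de = 0.05, effect_log2fc_sd = 1.5,
                          dispersion = 0.15, depth_range = c(0.5, 2),
                          baseline_meanlog = 4, baseline_sdlog = 1.5,
                          stage_props = c(0.505, 0.109, 0.232, 0.154),
                          stage_private_mult = rep(1, 4),
                          frac_paired_patients = 4 / 530, seed = 1) {
  cfg <- list(n_tumour = n_tumour, n_normal = n_normal, n_genes = n_genes,
              n_subtypes = n_subtypes, subtype_props = subtype_props,
              frac_group_de = frac_group_de, frac_subtype_de = frac_subtype_de,
              frac_private_de = frac_private_de,
              effect_log2fc_sd = effect_log2fc_sd, dispersion = dispersion,
              depth_range = depth_range, baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog, stage_props = stage_props,
              stage_private_mult = stage_private_mult,
              frac_paired_patients = frac_paired_patients, seed = seed)
  .check(n_genes >= 1 && (n_tumour + n_normal) >= 1,
         "cohort must have at least one gene and one sample")
  .check(length(subtype_props) == n_subtypes &&
           abs(sum(subtype_props) - 1) < 1e-8,
         "subtype_props must have length n_subtypes and sum to 1")
  fr <- c(frac_group_de, frac_subtype_de, frac_private_de,
          frac_paired_patients)
  .check(all(fr >= 0 & fr <= 1), "all fractions must lie in [0, 1]")
  .check(dispersion >= 0, "dispersion must be >= 0")
  .check(length(depth_range) == 2 && all(depth_range > 0) &&
           depth_range[1] <= depth_range[2],
         "depth_range must be (min, max) with 0 < min <= max")
  .check(abs(sum(stage_props) - 1) < 1e-8, "stage_props must sum to 1")
  structure(cfg, class = "cohort_config")
}

.scope_subtype <- function(k) paste0("subtype:", k)
.scope_sample <- function(id) paste0("sample:", id)

#' Generate a synthetic tumour cohort with planted ground truth
#'
#' Counts are drawn as
#' `counts[g, i] ~ NB(mean = depth_i * mu_g * 2^L(g, i), size = 1/phi)`
#' where `L(g, i)` sums the planted group, subtype, and sample-private
#' log2 fold changes that apply to sample `i`. Normal samples carry no
#' planted effects. Private programs are sampled without replacement
#' within each sample and may overlap between samples.
#'
#' @param config a [cohort_config()].
#' @return an object of class `"rc_cohort"`: a list with `counts`
#'   (integer gene x sample matrix), `gene_lengths` (named bp vector),
#'   `samples` (data.frame: sample_id, patient_id, tissue, subtype,
#'   stage, depth), `truth` (data.frame: gene, scope, log2fc -- one row
#'   per planted effect), `baseline_mu` (the drawn per-gene baseline
#'   means, for recovery tests) and the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cf <- config
  G <- cf$n_genes; nT <- cf$n_tumour; nN <- cf$n_normal
  with_seed(cf$seed, {
    genes <- sprintf("g%05d", seq_len(G))
    mu <- rlnorm(G, cf$baseline_meanlog, cf$baseline_sdlog)
    lens <- pmax(200, round(rlnorm(G, log(1500), 0.7)))
    names(lens) <- genes

    ## patients: a small fraction of tumours are second samples from an
    ## already-sampled patient
    n_paired <- min(round(cf$frac_paired_patients * nT), nT %/% 2)
    n_patients <- nT - n_paired
    pat_of_tumour <- c(seq_len(n_patients),
                       if (n_paired > 0) seq_len(n_paired))
    pat_subtype <- sample.int(cf$n_subtypes, n_patients, replace = TRUE,
                              prob = cf$subtype_props)
    pat_stage <- sample.int(length(cf$stage_props), n_patients,
                            replace = TRUE, prob = cf$stage_props)
    subtype <- pat_subtype[pat_of_tumour]
    stage <- pat_stage[pat_of_tumour]

    t_ids <- sprintf("T%03d", seq_len(nT))
    n_ids <- if (nN > 0) sprintf("N%03d", seq_len(nN)) else character(0)
    ## matched normals come from the first patients
    n_pat <- if (nN > 0) seq_len(nN) %% max(n_patients, 1) + 1 else integer(0)

    samples <- data.frame(
      sample_id = c(t_ids, n_ids),
      patient_id = sprintf("P%03d", c(pat_of_tumour, n_pat)),
      tissue = rep(c("tumour", "normal"), c(nT, nN)),
      subtype = c(as.character(subtype), rep(NA_character_, nN)),
      stage = c(c("I", "II", "III", "IV")[stage], rep(NA_character_, nN)),
      stringsAsFactors = FALSE)

    pm <- function(n) sample(c(-1, 1), n, replace = TRUE) *
      cf$effect_log2fc_sd

    truth <- list()
    n_gde <- round(cf$frac_group_de * G)
    if (n_gde > 0) {
      gsel <- sample(genes, n_gde)
      truth[["group"]] <- data.frame(gene = gsel, scope = "group",
                                     log2fc = pm(n_gde),
                                     stringsAsFactors = FALSE)
    }
    n_sde <- round(cf$frac_subtype_de * G)
    for (k in seq_len(cf$n_subtypes)) {
      if (n_sde > 0) {
        gsel <- sample(genes, n_sde)
        truth[[.scope_subtype(k)]] <- data.frame(
          gene = gsel, scope = .scope_subtype(k), log2fc = pm(n_sde),
          stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(nT)) {
      mult <- cf$stage_private_mult[stage[i]]
      n_pde <- round(cf$frac_private_de * mult * G)
      if (n_pde > 0) {
        gsel <- sample(genes, n_pde)
        truth[[.scope_sample(t_ids[i])]] <- data.frame(
          gene = gsel, scope = .scope_sample(t_ids[i]), log2fc = pm(n_pde),
          stringsAsFactors = FALSE)
      }
    }
    truth <- if (length(truth)) do.call(rbind, c(truth, list(make.row.names = FALSE)))
             else data.frame(gene = character(0), scope = character(0),
                             log2fc = numeric(0))

    ## per-sample total planted log2FC matrix (tumours only)
    L <- matrix(0, G, nT, dimnames = list(genes, t_ids))
    add_scope <- function(scope, cols) {
      tr <- truth[truth$scope == scope, , drop = FALSE]
      if (nrow(tr) && length(cols))
        L[cbind(rep(match(tr$gene, genes), length(cols)),
                rep(cols, each = nrow(tr)))] <<-
          L[cbind(rep(match(tr$gene, genes), length(cols)),
                  rep(cols, each = nrow(tr)))] + rep(tr$log2fc, length(cols))
    }
    add_scope("group", seq_len(nT))
    for (k in seq_len(cf$n_subtypes))
      add_scope(.scope_subtype(k), which(subtype == k))
    for (i in seq_len(nT)) add_scope(.scope_sample(t_ids[i]), i)

    S <- nT + nN
    depth <- exp(runif(S, log(cf$depth_range[1]), log(cf$depth_range[2])))
    samples$depth <- depth

    mu_mat <- cbind(L * log(2), matrix(0, G, nN))
    mu_mat <- exp(mu_mat + log(mu)) * rep(depth, each = G)
    counts <- if (cf$dispersion == 0) {
      matrix(rpois(G * S, mu_mat), G, S)
    } else {
      matrix(rnbinom(G * S, mu = mu_mat, size = 1 / cf$dispersion), G, S)
    }
    dimnames(counts) <- list(genes, samples$sample_id)
    storage.mode(counts) <- "integer"

    structure(list(counts = counts, gene_lengths = lens, samples = samples,
                   truth = truth, baseline_mu = setNames(mu, genes),
                   config = cf),
              class = "rc_cohort")
  })
}

#' Total planted log2 fold change applicable to one tumour sample
#'
#' Sums the group, subtype and sample-private planted effects that act
#' on the given sample; this is the ground-truth signature its
#' tumour-vs-normal contrast should recover.
#'
#' @param cohort an `rc_cohort`.
#' @param sample_id a tumour sample id.
#' @return named numeric vector (only genes with a non-zero planted
#'   effect).
#' @export
planted_log2fc <- function(cohort, sample_id) {
  meta <- cohort$samples
  row <- meta[meta$sample_id == sample_id, , drop = FALSE]
  .check(nrow(row) == 1 && row$tissue == "tumour",
         "sample_id must name one tumour sample")
  scopes <- c("group", .scope_subtype(row$subtype), .scope_sample(sample_id))
  tr <- cohort$truth[cohort$truth$scope %in% scopes, , drop = FALSE]
  if (!nrow(tr)) return(setNames(numeric(0), character(0)))
  fc <- tapply(tr$log2fc, tr$gene, sum)
  fc <- fc[fc != 0]
  setNames(as.numeric(fc), names(fc))
}

#' Configuration for a synthetic drug perturbation panel
#'
#' Each drug is profiled on `n_cell_lines` cell lines at each
#' concentration (0 = vehicle control) and duration, on a log-intensity
#' scale. A fraction of drugs are "reversal" drugs whose per-gene
#' concentration effect is `-reversal_strength` times a chosen planted
#' tumour program; the rest have no effect. A fraction of drugs lack
#' control (concentration 0) columns entirely, mimicking the small
#' percentage of library drugs that cannot be processed.
#'
#' @param n_drugs,n_cell_lines,n_batches panel dimensions.
#' @param concentrations dose levels; must include 0 (controls) --
#'   no-control drugs have their 0 columns removed after the fact.
#' @param durations perturbation durations (hours).
#' @param frac_reversal_drugs fraction of drugs that oppose a tumour
#'   program.
#' @param reversal_strength multiplier `k`: reversal drug effect per
#'   unit concentration is `-k * true_log2fc` of its target program.
#' @param frac_no_control fraction of drugs generated without
#'   concentration-0 columns.
#' @param noise_sd Gaussian measurement noise on the log scale.
#' @param baseline_mean,baseline_sd per-gene platform baseline.
#' @param cell_line_sd,batch_sd,duration_sd SDs of the per-gene
#'   categorical covariate offsets.
#' @param seed integer seed.
#' @return a validated list of class `"drug_panel_config"`.
#' @export
drug_panel_config <- function(n_drugs = 100, n_cell_lines = 3,
                              concentrations = c(0, 0.1, 0.5, 1),
                              durations = c(6, 24), n_batches = 2,
                              frac_reversal_drugs = 0.1,
                              reversal_strength = 1,
                              frac_no_control = 0.02, noise_sd = 0.5,
                              baseline_mean = 6, baseline_sd = 1.5,
                              cell_line_sd = 0.5, batch_sd = 0.3,
                              duration_sd = 0.3, seed = 1) {
  cfg <- list(n_drugs = n_drugs, n_cell_lines = n_cell_lines,
              concentrations = concentrations, durations = durations,
              n_batches = n_batches,
              frac_reversal_drugs = frac_reversal_drugs,
              reversal_strength = reversal_strength,
              frac_no_control = frac_no_control, noise_sd = noise_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              cell_line_sd = cell_line_sd, batch_sd = batch_sd,
              duration_sd = duration_sd, seed = seed)
  .check(n_drugs >= 1, "need at least one drug")
  .check(all(c(frac_reversal_drugs, frac_no_control) >= 0 &
               c(frac_reversal_drugs, frac_no_control) <= 1),
         "fractions must lie in [0, 1]")
  .check(any(concentrations == 0) && all(concentrations >= 0),
         "concentrations must be non-negative and include 0 (controls)")
  .check(noise_sd >= 0, "noise_sd must be >= 0")
  structure(cfg, class = "drug_panel_config")
}

#' Reversal-drug targets spanning every tumour sample of a cohort
#'
#' Convenience builder for [generate_drug_panel()]: one candidate target
#' per tumour sample, whose program is the union of the group effects,
#' the sample's subtype effects, and its private effects -- i.e. the
#' full planted signature its tumour-vs-normal contrast sees.
#'
#' @param cohort an `rc_cohort`.
#' @return a named list of scope-character-vectors.
#' @export
drug_targets_from_cohort <- function(cohort) {
  meta <- cohort$samples
  tum <- meta[meta$tissue == "tumour", , drop = FALSE]
  out <- lapply(seq_len(nrow(tum)), function(i)
    c("group", .scope_subtype(tum$subtype[i]),
      .scope_sample(tum$sample_id[i])))
  names(out) <- tum$sample_id
  out
}

#' Generate a synthetic drug perturbation panel
#'
#' Expression of column `j` for gene `g` is
#' `baseline_g + cellline_offset + batch_offset + duration_offset +
#'  concentration_j * effect_g + N(0, noise_sd)`,
#' with `effect_g = -k * true_log2fc` of the assigned target program
#' for reversal drugs and 0 otherwise.
#'
#' @param config a [drug_panel_config()].
#' @param truth a cohort truth table (data.frame gene/scope/log2fc), as
#'   produced by [generate_cohort()]. Required when
#'   `frac_reversal_drugs > 0`.
#' @param genes character vector of panel gene ids.
#' @param targets optional named list of scope vectors (see
#'   [drug_targets_from_cohort()]); reversal drugs cycle over it. The
#'   default takes each sample-scoped program together with the group
#'   program.
#' @return an object of class `"rc_drug_panel"`: list with `expr`
#'   (gene x experiment matrix, log scale), `meta` (data.frame:
#'   column_id, drug, concentration, cell_line, duration, batch),
#'   `truth` (data.frame: drug, type, target, k, has_control) and the
#'   `config`.
#' @export
generate_drug_panel <- function(config, truth, genes, targets = NULL) {
  stopifnot(inherits(config, "drug_panel_config"))
  cf <- config
  G <- length(genes)
  .check(G >= 1, "need at least one gene")
  n_rev <- round(cf$frac_reversal_drugs * cf$n_drugs)
  if (n_rev > 0) {
    .check(!missing(truth) && !is.null(truth) && nrow(truth) > 0,
           "frac_reversal_drugs > 0 requires a non-empty truth table")
  }
  if (is.null(targets) && n_rev > 0) {
    ssc <- unique(truth$scope[startsWith(truth$scope, "sample:")])
    targets <- if (length(ssc)) {
      out <- lapply(ssc, function(s) c("group", s))
      names(out) <- sub("^sample:", "", ssc)
      out
    } else list(group = "group")
  }

  with_seed(cf$seed, {
    drugs <- sprintf("drug%03d", seq_len(cf$n_drugs))
    rev_drugs <- if (n_rev > 0) sort(sample(drugs, n_rev)) else character(0)
    n_nc <- round(cf$frac_no_control * cf$n_drugs)
    nc_drugs <- if (n_nc > 0) sort(sample(drugs, n_nc)) else character(0)

    baseline <- rnorm(G, cf$baseline_mean, cf$baseline_sd)
    cls <- sprintf("CL%02d", seq_len(cf$n_cell_lines))
    cl_off <- matrix(rnorm(G * cf$n_cell_lines, 0, cf$cell_line_sd), G,
                     dimnames = list(genes, cls))
    bats <- sprintf("B%02d", seq_len(cf$n_batches))
    bat_off <- matrix(rnorm(G * cf$n_batches, 0, cf$batch_sd), G,
                      dimnames = list(genes, bats))
    durs <- sort(unique(cf$durations))
    dur_off <- if (length(durs) > 1)
      matrix(rnorm(G * length(durs), 0, cf$duration_sd), G,
             dimnames = list(genes, as.character(durs)))
    else matrix(0, G, 1, dimnames = list(genes, as.character(durs)))

    grid <- expand.grid(cell_line = cls, concentration = cf$concentrations,
                        duration = durs, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)

    expr_list <- vector("list", cf$n_drugs)
    meta_list <- vector("list", cf$n_drugs)
    truth_list <- vector("list", cf$n_drugs)
    tgt_idx <- 0L
    for (d in seq_len(cf$n_drugs)) {
      dg <- grid
      if (drugs[d] %in% nc_drugs)
        dg <- dg[dg$concentration > 0, , drop = FALSE]
      nc <- nrow(dg)
      ## batches are assigned by balanced randomization: any cyclic
      ## scheme aliases the batch factor with cell line or duration for
      ## some panel shapes, collapsing every design to rank deficiency
      dg$batch <- sample(rep_len(bats, nc))

      effect <- numeric(G)
      target <- NA_character_
      if (drugs[d] %in% rev_drugs) {
        tgt_idx <- tgt_idx %% length(targets) + 1L
        target <- names(targets)[tgt_idx]
        tr <- truth[truth$scope %in% targets[[tgt_idx]], , drop = FALSE]
        tr <- tr[tr$gene %in% genes, , drop = FALSE]
        if (nrow(tr)) {
          fc <- tapply(tr$log2fc, tr$gene, sum)
          effect[match(names(fc), genes)] <- -cf$reversal_strength *
            as.numeric(fc)
        }
      }

      E <- baseline +
        cl_off[, dg$cell_line, drop = FALSE] +
        bat_off[, dg$batch, drop = FALSE] +
        dur_off[, as.character(dg$duration), drop = FALSE] +
        outer(effect, dg$concentration)
      if (cf$noise_sd > 0) E <- E + matrix(rnorm(G * nc, 0, cf$noise_sd), G)
      colnames(E) <- sprintf("%s_e%02d", drugs[d], seq_len(nc))
      rownames(E) <- genes

      expr_list[[d]] <- E
      meta_list[[d]] <- data.frame(
        column_id = colnames(E), drug = drugs[d],
        concentration = dg$concentration, cell_line = dg$cell_line,
        duration = dg$duration, batch = dg$batch,
        stringsAsFactors = FALSE)
      truth_list[[d]] <- data.frame(
        drug = drugs[d],
        type = if (drugs[d] %in% rev_drugs) "reversal" else "null",
        target = target, k = cf$reversal_strength,
        has_control = !(drugs[d] %in% nc_drugs),
        stringsAsFactors = FALSE)
    }
    structure(list(expr = do.call(cbind, expr_list),
                   meta = do.call(rbind, c(meta_list,
                                           list(make.row.names = FALSE))),
                   truth = do.call(rbind, c(truth_list,
                                            list(make.row.names = FALSE))),
                   genes = genes, config = cf),
              class = "rc_drug_panel")
  })
}
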