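# End-to-end orchestration: synthetic data -> preprocessing -> tumour
# signatures -> drug signatures -> connectivity -> summaries
# (-> simulation null). A manifest records parameter hashes and output
# checksums per stage; a stage whose outputs exist under an unchanged
# parameter hash is skipped, so deleting an intermediate re-runs only
# the affected stage and everything downstream of it.

#' Assemble a pipeline run configuration
#'
#' All module parameters in one serializable list; `save_run_config()`
#' / `load_run_config()` round-trip it through YAML.
#'
#' @param outdir run directory.
#' @param seed global seed; every random draw in the run flows from it
#'   through [derive_seed()].
#' @param cohort list of [cohort_config()] overrides.
#' @param drug_panel list of [drug_panel_config()] overrides.
#' @param cpm_cutoff,min_fraction low-expression filter parameters.
#' @param query_fdr tumour-query FDR threshold (default 0.01).
#' @param deg_fdr DEG-quality FDR threshold (default 0.5).
#' @param n_perm permutations per (sample, drug) pair; group/subtype
#'   queries use `n_perm * n_tumour`.
#' @param min_shared minimum shared genes per scored pair.
#' @param kinds signature families to compute.
#' @param group_connectivity also score the group signature against
#'   every drug (at the multiplied permutation budget).
#' @param null_mc Monte-Carlo replicates for the null-DEG threshold.
#' @param simnull optional list (enabled, source, n_batches,
#'   batch_size, n_perm, drugs).
#' @param figures emit SVG figures.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(outdir = "revcon_run", seed = 17, cohort = list(),
                       drug_panel = list(), cpm_cutoff = 0.5,
                       min_fraction = 1 / 6, query_fdr = 0.01,
                       deg_fdr = 0.5, n_perm = 1000, min_shared = 5,
                       kinds = c("group", "subtype", "sample",
                                 "normal_control"),
                       group_connectivity = FALSE, null_mc = 2000,
                       simnull = list(enabled = FALSE), figures = FALSE) {
  structure(list(outdir = outdir, seed = seed, cohort = cohort,
                 drug_panel = drug_panel, cpm_cutoff = cpm_cutoff,
                 min_fraction = min_fraction, query_fdr = query_fdr,
                 deg_fdr = deg_fdr, n_perm = n_perm,
                 min_shared = min_shared, kinds = kinds,
                 group_connectivity = group_connectivity,
                 null_mc = null_mc, simnull = simnull,
                 figures = figures, version = "0.1.0"),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 12)
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(run_config, raw[setdiff(names(raw), "version")])
  cfg
}

.hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

.log_line <- function(logfile, ...) {
  cat(paste0(format(Sys.time(), "%H:%M:%S"), " ", ..., "\n"),
      file = logfile, append = TRUE)
}

#' Run the full pipeline
#'
#' Executes synthetic-data generation, preprocessing, tumour and drug
#' signatures, connectivity scoring and summaries (plus the simulation
#' null when enabled) into `config$outdir`. The run log records seeds
#' and every exclusion (UNPROCESSABLE drugs, UNSCORABLE pairs); the
#' manifest records parameter hashes and output checksums per stage,
#' which is what makes re-runs incremental and byte-reproducible.
#'
#' @param config a [run_config()].
#' @return the run directory, invisibly; side effects on disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(config$outdir, "run.log")
  man_path <- file.path(config$outdir, "manifest.json")
  manifest <- if (file.exists(man_path))
    jsonlite::read_json(man_path) else list(stages = list())
  state <- new.env()

  stage <- function(name, params, outputs, run) {
    h <- .hash_obj(params)
    paths <- file.path(config$outdir, outputs)
    prev <- manifest$stages[[name]]
    fresh <- !is.null(prev) && identical(prev$params_hash, unname(h)) &&
      all(file.exists(paths))
    if (fresh) {
      .log_line(logfile, "stage ", name, ": up to date, skipped")
    } else {
      .log_line(logfile, "stage ", name, ": running")
      run(paths)
      manifest$stages[[name]] <<- list(
        params_hash = unname(h),
        files = as.list(tools::md5sum(paths)))
      jsonlite::write_json(manifest, man_path, auto_unbox = TRUE)
    }
    invisible(paths)
  }

  ## 1. synthetic data ------------------------------------------------
  ccfg <- do.call(cohort_config,
                  modifyList(config$cohort,
                             list(seed = derive_seed(config$seed,
                                                     "cohort"))))
  stage("simulate-data", list(cohort = unclass(ccfg),
                              panel = config$drug_panel),
        c("cohort/counts.tsv", "cohort/truth.tsv",
          "panel/drug_metadata.tsv"), function(paths) {
    cohort <- generate_cohort(ccfg)
    state$cohort <- cohort
    write_cohort(cohort, file.path(config$outdir, "cohort"))
    pcfg <- do.call(drug_panel_config,
                    modifyList(config$drug_panel,
                               list(seed = derive_seed(config$seed,
                                                       "panel"))))
    panel <- generate_drug_panel(pcfg, cohort$truth,
                                 rownames(cohort$counts),
                                 targets = drug_targets_from_cohort(cohort))
    state$panel <- panel
    write_drug_panel(panel, file.path(config$outdir, "panel"))
  })
  if (is.null(state$cohort)) {
    state$cohort <- list(
      counts = read_counts_tsv(file.path(config$outdir, "cohort/counts.tsv")),
      samples = read_samples_tsv(file.path(config$outdir,
                                           "cohort/samples.tsv")))
    pcfg <- do.call(drug_panel_config,
                    modifyList(config$drug_panel,
                               list(seed = derive_seed(config$seed,
                                                       "panel"))))
    ## same seed and same targets as the original generation, so the
    ## reconstructed panel is bit-identical
    state$panel <- generate_drug_panel(
      pcfg,
      read.delim(file.path(config$outdir, "cohort/truth.tsv"),
                 stringsAsFactors = FALSE),
      rownames(state$cohort$counts),
      targets = drug_targets_from_cohort(state$cohort))
  }

  ## 2. preprocess ----------------------------------------------------
  stage("preprocess", list(cpm_cutoff = config$cpm_cutoff,
                           min_fraction = config$min_fraction),
        "filtered_counts.tsv", function(paths) {
    filt <- filter_low_expressed(state$cohort$counts, config$cpm_cutoff,
                                 config$min_fraction)
    .log_line(logfile, "filter: ", nrow(state$cohort$counts), " -> ",
              nrow(filt), " genes")
    .write_tsv(filt, paths[1], "gene")
  })
  counts <- read_counts_tsv(file.path(config$outdir,
                                      "filtered_counts.tsv"))
  meta <- state$cohort$samples

  ## 3. tumour signatures ---------------------------------------------
  sig_files <- paste0("signatures_", config$kinds, ".tsv")
  stage("tumour-signatures", list(kinds = config$kinds),
        c("dispersion.json", sig_files), function(paths) {
    ## dispersion from the normal replicates: tumour heterogeneity must
    ## not inflate the null scale of the per-sample contrasts
    nrm <- meta$tissue == "normal"
    phi <- estimate_dispersion(
      counts[, nrm, drop = FALSE], matrix(1, sum(nrm), 1),
      log(effective_lib_sizes(counts))[nrm])
    .log_line(logfile, "common dispersion: ", signif(phi, 4))
    jsonlite::write_json(list(dispersion = phi), paths[1],
                         auto_unbox = TRUE, digits = NA)
    for (i in seq_along(config$kinds)) {
      sigs <- make_signatures(counts, meta, phi, config$kinds[i])
      write_signatures_tsv(sigs, paths[i + 1])
      state[[paste0("sigs_", config$kinds[i])]] <- sigs
    }
  })
  phi <- jsonlite::read_json(file.path(config$outdir,
                                       "dispersion.json"))$dispersion
  for (k in config$kinds)
    if (is.null(state[[paste0("sigs_", k)]]))
      state[[paste0("sigs_", k)]] <- make_signatures(counts, meta, phi, k)

  ## 4. drug signatures -----------------------------------------------
  stage("drug-signatures", list(deg_fdr = config$deg_fdr),
        c("drug_signatures.tsv", "drug_status.json"), function(paths) {
    ds <- drug_signatures(state$panel, fdr_cutoff = config$deg_fdr)
    state$drugsigs <- ds
    n_un <- sum(ds$status$status == "UNPROCESSABLE")
    .log_line(logfile, "drugs: ", nrow(ds$status), " total, ", n_un,
              " UNPROCESSABLE (",
              signif(100 * n_un / nrow(ds$status), 3), "%)")
    write_signatures_tsv(ds$signatures, paths[1])
    jsonlite::write_json(ds$status, paths[2], auto_unbox = TRUE,
                         digits = NA, na = "null")
  })
  if (is.null(state$drugsigs))
    state$drugsigs <- drug_signatures(state$panel,
                                      fdr_cutoff = config$deg_fdr)

  ## 5. connectivity --------------------------------------------------
  stage("connect", list(query_fdr = config$query_fdr,
                        n_perm = config$n_perm,
                        min_shared = config$min_shared,
                        group = config$group_connectivity),
        "connectivity.tsv", function(paths) {
    queries <- lapply(state$sigs_sample, build_query,
                      fdr_cutoff = config$query_fdr)
    res <- score_connectivity(queries, state$drugsigs$signatures,
                              n_perm = config$n_perm, seed = config$seed,
                              min_shared = config$min_shared)
    .log_line(logfile, "UNSCORABLE pairs: ", sum(!res$scored))
    if (isTRUE(config$group_connectivity) &&
        !is.null(state$sigs_group)) {
      gq <- lapply(state$sigs_group, build_query,
                   fdr_cutoff = config$query_fdr)
      gres <- score_connectivity(
        gq, state$drugsigs$signatures,
        n_perm = config$n_perm * length(queries), seed = config$seed,
        min_shared = config$min_shared)
      res <- rbind(res, gres)
    }
    state$results <- res
    df <- res
    df[c("score", "p")] <- lapply(df[c("score", "p")], signif, 8)
    .write_tsv(df, paths[1])
  })
  if (is.null(state$results))
    state$results <- read.delim(file.path(config$outdir,
                                          "connectivity.tsv"),
                                stringsAsFactors = FALSE)

  ## 6. summarize -----------------------------------------------------
  stage("summarize", list(deg_fdr = config$deg_fdr,
                          null_mc = config$null_mc),
        "drug_summary.tsv", function(paths) {
    res <- state$results
    res <- res[res$sample_id %in%
                 meta$sample_id[meta$tissue == "tumour"], , drop = FALSE]
    summ <- suppressWarnings(summarize_connectivity(
      res, state$drugsigs$status, n_genes = nrow(counts),
      deg_fdr_cutoff = config$deg_fdr, n_mc = config$null_mc,
      seed = derive_seed(config$seed, "nullmc")))
    state$summary <- summ
    sdf <- summ
    num <- vapply(sdf, is.numeric, logical(1))
    sdf[num] <- lapply(sdf[num], signif, 8)
    .write_tsv(sdf, paths[1])
  })
  if (is.null(state$summary))
    state$summary <- read.delim(file.path(config$outdir,
                                          "drug_summary.tsv"),
                                stringsAsFactors = FALSE)

  ## 7. optional simulation null & figures ----------------------------
  if (isTRUE(config$simnull$enabled)) {
    sn <- config$simnull
    stage("simulate-null", sn, "simnull.json", function(paths) {
      X <- cbind(1, as.numeric(meta$tissue == "tumour"))
      fit <- fit_nb_glm(counts, X, log(effective_lib_sizes(counts)),
                        dispersion = phi)
      gen <- extract_generator(fit, counts, meta$tissue == "tumour",
                               source = "group")
      drugs <- sn$drugs %||% head(names(state$drugsigs$signatures), 2)
      dsig <- state$drugsigs$signatures[drugs]
      tum <- state$results$sample_id %in%
        meta$sample_id[meta$tissue == "tumour"]
      obs <- vapply(drugs, function(d) {
        r <- state$results[tum & state$results$drug_id == d, ]
        sum(r$negative_enriched %in% TRUE)
      }, numeric(1))
      nl <- null_enrichment_distribution(
        gen, dsig, obs, counts[, meta$tissue == "normal", drop = FALSE],
        phi, n_batches = sn$n_batches %||% 200,
        batch_size = sn$batch_size %||% sum(meta$tissue == "tumour"),
        query_fdr = config$query_fdr, n_perm = sn$n_perm %||% 200,
        min_shared = config$min_shared,
        seed = derive_seed(config$seed, "simnull"))
      jsonlite::write_json(
        list(source = nl$source, observed = as.list(nl$observed),
             interval = apply(nl$interval, 2, as.list),
             fold_ratios = apply(nl$fold_ratios, 2, as.list),
             n_batches = nl$n_batches, batch_size = nl$batch_size),
        paths[1], auto_unbox = TRUE, digits = NA)
    })
  }
  if (isTRUE(config$figures)) render_figures(state, config)
  invisible(config$outdir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
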