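# The four tumour-signature families: group (all tumours vs all
# normals), subtype (each subtype vs all normals), sample (one tumour
# vs all normals) and normal-control (each normal vs the remaining
# normals). Dispersion is FIXED at the cohort estimate for every
# contrast: a single tumour sample cannot inform its own dispersion,
# and a shared phi keeps the per-sample likelihood-ratio tests
# well-defined.
#
# Per-sample contrasts (intercept + one-sample indicator) are fitted
# through an exact decomposition of the profile likelihood: the free
# indicator coefficient saturates the singleton sample (its MLE mean is
# the observed count), so the full-model likelihood separates into an
# intercept-only fit on the comparison group plus a point term, and the
# reduced model is an intercept-only fit on the pooled samples. The
# decomposition is algebraically identical to the general IRLS route
# (tested) and is what makes scoring thousands of simulated samples
# feasible.

# intercept-only NB fit, vectorized over genes.
# Y: G x n counts, d: n library sizes (exp(offset)).
.nb_int_fit <- function(Y, d, phi) {
  G <- nrow(Y); n <- ncol(Y)
  rs <- rowSums(Y)
  b <- log(pmax(rs, 1e-8) / sum(d))
  if (phi == 0) {                     # Poisson: closed-form intercept MLE
    ll <- rowSums(dpois(Y, pmax(exp(b) %o% d, .MU_EPS), log = TRUE))
    return(list(b = b, ll = ll))
  }
  k <- 1 / phi
  for (it in seq_len(40)) {
    Mu <- exp(b) %o% d
    sc <- rowSums(k * (Y - Mu) / (k + Mu))
    info <- rowSums(k * Mu / (k + Mu))
    step <- sc / pmax(info, 1e-12)
    step <- pmin(pmax(step, -5), 5)
    b <- pmin(pmax(b + step, -.ETA_CLAMP), .ETA_CLAMP)
    if (max(abs(step)) < 1e-12) break
  }
  Mu <- pmax(exp(b) %o% d, .MU_EPS)
  list(b = b, ll = rowSums(dnbinom(Y, size = k, mu = Mu, log = TRUE)))
}

# intercept-only NB fit on (base samples + one extra observation), for
# every extra column at once. Ybase: G x n, yext: G x S, dext: S.
# Returns b and ll as G x S matrices.
.nb_int_fit_plus <- function(Ybase, dbase, yext, dext, phi) {
  G <- nrow(Ybase); n <- ncol(Ybase); S <- ncol(yext)
  tot_y <- rowSums(Ybase) + yext                     # G x S
  tot_d <- sum(dbase) + rep(dext, each = G)
  b <- log(pmax(tot_y, 1e-8)) - log(tot_d)
  dext_m <- rep(dext, each = G)
  if (phi == 0) {
    ll <- matrix(0, G, S)
    eb <- exp(b)
    for (i in seq_len(n))
      ll <- ll + dpois(Ybase[, i], pmax(eb * dbase[i], .MU_EPS),
                       log = TRUE)
    ll <- ll + dpois(yext, pmax(eb * dext_m, .MU_EPS), log = TRUE)
    return(list(b = b, ll = ll))
  }
  k <- 1 / phi
  for (it in seq_len(40)) {
    eb <- exp(b)
    sc <- matrix(0, G, S); info <- matrix(0, G, S)
    for (i in seq_len(n)) {
      Mu <- eb * dbase[i]
      sc <- sc + k * (Ybase[, i] - Mu) / (k + Mu)
      info <- info + k * Mu / (k + Mu)
    }
    Mu <- eb * dext_m
    sc <- sc + k * (yext - Mu) / (k + Mu)
    info <- info + k * Mu / (k + Mu)
    step <- sc / pmax(info, 1e-12)
    step <- pmin(pmax(step, -5), 5)
    b <- pmin(pmax(b + step, -.ETA_CLAMP), .ETA_CLAMP)
    if (max(abs(step)) < 1e-12) break
  }
  eb <- exp(b)
  ll <- matrix(0, G, S)
  for (i in seq_len(n))
    ll <- ll + dnbinom(Ybase[, i], size = k,
                       mu = pmax(eb * dbase[i], .MU_EPS), log = TRUE)
  ll <- ll + dnbinom(yext, size = k, mu = pmax(eb * dext_m, .MU_EPS),
                     log = TRUE)
  list(b = b, ll = ll)
}

# leave-one-out intercept fits: for every held-out column j, an
# intercept-only fit on the remaining columns. Returns b, ll (G x n).
.nb_int_fit_minus <- function(Y, d, phi) {
  G <- nrow(Y); n <- ncol(Y)
  .check(n >= 2, "leave-one-out fit needs >= 2 samples")
  rs <- rowSums(Y)
  tot_y <- rs - Y                                    # G x n
  tot_d <- sum(d) - d
  b <- log(pmax(tot_y, 1e-8)) - matrix(log(tot_d), G, n, byrow = TRUE)
  d_m <- matrix(d, G, n, byrow = TRUE)
  if (phi == 0) {
    eb <- exp(b)
    ll <- matrix(0, G, n)
    for (i in seq_len(n))
      ll <- ll + dpois(Y[, i], pmax(eb * d[i], .MU_EPS), log = TRUE)
    ll <- ll - dpois(Y, pmax(eb * d_m, .MU_EPS), log = TRUE)
    return(list(b = b, ll = ll))
  }
  k <- 1 / phi
  for (it in seq_len(40)) {
    eb <- exp(b)
    sc <- matrix(0, G, n); info <- matrix(0, G, n)
    for (i in seq_len(n)) {
      Mu <- eb * d[i]
      sc <- sc + k * (Y[, i] - Mu) / (k + Mu)
      info <- info + k * Mu / (k + Mu)
    }
    Mu_self <- eb * d_m
    sc <- sc - k * (Y - Mu_self) / (k + Mu_self)
    info <- info - k * Mu_self / (k + Mu_self)
    step <- sc / pmax(info, 1e-12)
    step <- pmin(pmax(step, -5), 5)
    b <- pmin(pmax(b + step, -.ETA_CLAMP), .ETA_CLAMP)
    if (max(abs(step)) < 1e-12) break
  }
  eb <- exp(b)
  ll <- matrix(0, G, n)
  for (i in seq_len(n))
    ll <- ll + dnbinom(Y[, i], size = k, mu = pmax(eb * d[i], .MU_EPS),
                       log = TRUE)
  ll <- ll - dnbinom(Y, size = k, mu = pmax(eb * d_m, .MU_EPS), log = TRUE)
  list(b = b, ll = ll)
}

.nb_point_ll <- function(y, phi) .nb_ll_sat(y, phi)

.new_signature <- function(gene, log2fc, p, kind, id, phi) {
  sig <- data.frame(gene = gene, log2fc = log2fc, p = p, fdr = bh_fdr(p),
                    stringsAsFactors = FALSE)
  attr(sig, "contrast_kind") <- kind
  attr(sig, "contrast_id") <- id
  attr(sig, "dispersion") <- phi
  class(sig) <- c("rc_signature", "data.frame")
  sig
}

# two-group contrast (indicator columns vs normals) via the general
# IRLS route; used by the group and subtype signature kinds
.two_group_signature <- function(Y, offsets, is_case, phi, kind, id) {
  X <- cbind(intercept = 1, case = as.numeric(is_case))
  full <- fit_nb_glm(Y, X, offsets, dispersion = phi)
  red <- fit_nb_glm(Y, X[, 1, drop = FALSE], offsets, dispersion = phi)
  p <- lrt(full, red, df = 1)
  log2fc <- full$coefficients[, "case"] / log(2)
  zero <- rowSums(Y) == 0
  p[zero] <- 1; log2fc[zero] <- 0
  .new_signature(rownames(Y), log2fc, p, kind, id, phi)
}

#' Generate a family of tumour or normal-control signatures
#'
#' * `group`: all tumours vs all normals (one signature).
#' * `subtype`: each subtype's tumours vs all normals.
#' * `sample`: each tumour sample vs all normals (design = intercept +
#'   indicator of that sample; dispersion fixed at the cohort value).
#' * `normal_control`: each normal vs all the other normals -- the
#'   empirical false-positive yardstick for the sample signatures.
#'
#' Log2 fold changes are the contrast coefficient divided by `ln 2`;
#' p-values come from the likelihood-ratio test and FDRs from
#' Benjamini-Hochberg, computed within each signature separately.
#' Genes with all-zero counts within a contrast get `p = 1`,
#' `log2fc = 0`; fold changes of singleton contrasts floor the
#' saturated count at 0.5 so they stay finite.
#'
#' @param counts filtered gene x sample count matrix.
#' @param metadata sample metadata with `sample_id`, `tissue`
#'   (`"tumour"`/`"normal"`) and `subtype` columns, rows matching the
#'   columns of `counts`.
#' @param dispersion cohort dispersion estimate (see
#'   [estimate_dispersion()]).
#' @param kind one of `"group"`, `"subtype"`, `"sample"`,
#'   `"normal_control"`.
#' @param offsets per-sample log effective library sizes; default
#'   `log(effective_lib_sizes(counts))` (upper-quartile scaling, robust
#'   to a few dominant genes).
#' @return a named list of `rc_signature` data.frames (gene, log2fc, p,
#'   fdr), one per contrast.
#' @export
make_signatures <- function(counts, metadata, dispersion,
                            kind = c("group", "subtype", "sample",
                                     "normal_control"),
                            offsets = NULL) {
  kind <- match.arg(kind)
  Y <- as.matrix(counts)
  .check(identical(metadata$sample_id, colnames(Y)),
         "metadata rows must match count columns (sample_id order)")
  if (is.null(offsets)) offsets <- log(effective_lib_sizes(Y))
  phi <- dispersion
  is_norm <- metadata$tissue == "normal"
  .check(sum(is_norm) >= 2, "need >= 2 normal samples")
  d <- exp(offsets)

  if (kind == "group") {
    sig <- .two_group_signature(Y, offsets, !is_norm, phi, "group", "group")
    return(list(group = sig))
  }

  if (kind == "subtype") {
    subs <- sort(unique(metadata$subtype[!is_norm]))
    subs <- subs[!is.na(subs)]
    out <- list()
    for (s in subs) {
      in_sub <- !is_norm & !is.na(metadata$subtype) & metadata$subtype == s
      if (!any(in_sub)) { warning("subtype ", s, " has 0 samples; skipped")
        next }
      sel <- is_norm | in_sub
      out[[as.character(s)]] <- .two_group_signature(
        Y[, sel, drop = FALSE], offsets[sel], in_sub[sel], phi,
        "subtype", as.character(s))
    }
    return(out)
  }

  if (kind == "sample") {
    Yn <- Y[, is_norm, drop = FALSE]; dn <- d[is_norm]
    Yt <- Y[, !is_norm, drop = FALSE]; dt <- d[!is_norm]
    ids <- metadata$sample_id[!is_norm]
    base <- .nb_int_fit(Yn, dn, phi)
    red <- .nb_int_fit_plus(Yn, dn, Yt, dt, phi)
    ll_full <- base$ll + .nb_point_ll(Yt, phi)
    stat <- pmax(0, 2 * (ll_full - red$ll))
    pmat <- matrix(pchisq(stat, df = 1, lower.tail = FALSE),
                   nrow(Y), ncol(Yt))
    fc <- (log(pmax(Yt, 0.5)) -
             matrix(log(dt), nrow(Y), ncol(Yt), byrow = TRUE) -
             base$b) / log(2)
    out <- list()
    for (j in seq_along(ids)) {
      p <- pmat[, j]; l2 <- fc[, j]
      zero <- rowSums(Yn) == 0 & Yt[, j] == 0
      p[zero] <- 1; l2[zero] <- 0
      out[[ids[j]]] <- .new_signature(rownames(Y), l2, p, "sample",
                                      ids[j], phi)
    }
    return(out)
  }

  ## normal_control: each normal vs the other normals
  Yn <- Y[, is_norm, drop = FALSE]; dn <- d[is_norm]
  ids <- metadata$sample_id[is_norm]
  red <- .nb_int_fit(Yn, dn, phi)                  # pooled intercept
  loo <- .nb_int_fit_minus(Yn, dn, phi)
  ll_full <- loo$ll + .nb_point_ll(Yn, phi)
  stat <- pmax(0, 2 * (ll_full - red$ll))
  pmat <- matrix(pchisq(stat, df = 1, lower.tail = FALSE),
                 nrow(Y), ncol(Yn))
  fc <- (log(pmax(Yn, 0.5)) -
           matrix(log(dn), nrow(Y), ncol(Yn), byrow = TRUE) - loo$b) / log(2)
  out <- list()
  for (j in seq_along(ids)) {
    p <- pmat[, j]; l2 <- fc[, j]
    zero <- rowSums(Yn) == 0
    p[zero] <- 1; l2[zero] <- 0
    out[[ids[j]]] <- .new_signature(rownames(Y), l2, p, "normal_control",
                                    ids[j], phi)
  }
  out
}

#' Number of genes in a signature under an FDR cutoff
#'
#' @param sig an `rc_signature`.
#' @param fdr_cutoff cutoff in `(0, 1]`; genes count when
#'   `fdr < fdr_cutoff` (strict).
#' @return integer count.
#' @export
signature_size <- function(sig, fdr_cutoff) {
  .check(fdr_cutoff > 0 && fdr_cutoff <= 1, "fdr_cutoff must be in (0, 1]")
  sum(sig$fdr < fdr_cutoff)
}
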