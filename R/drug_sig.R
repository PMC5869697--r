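# Per-drug gene signatures from perturbation expression matrices:
# ordinary least squares per gene with drug concentration as a linear
# covariate (0 for vehicle controls) and cell line / duration / batch
# as categorical covariates, followed by empirical-Bayes moderation of
# the residual variances. Drugs without any control column, or whose
# design collapses to rank deficiency, are flagged UNPROCESSABLE --
# the mechanism behind the small percentage of library drugs excluded
# from downstream analysis.

#' Build the linear-model design for one drug
#'
#' Intercept + concentration (linear, untransformed) + indicator blocks
#' for cell line, duration and batch. A categorical block is included
#' only when it has more than one distinct level (reference level =
#' first in lexicographic order); the duration block in particular is
#' included iff there is more than one distinct duration.
#'
#' @param meta per-experiment metadata for a single drug: data.frame
#'   with `concentration`, `cell_line`, `duration`, `batch` columns.
#' @return list with `design` (matrix or NULL), `status`
#'   (`"OK"`/`"UNPROCESSABLE"`) and `reason`.
#' @export
build_design <- function(meta) {
  need <- c("concentration", "cell_line", "duration", "batch")
  .check(all(need %in% names(meta)),
         paste("metadata must contain:", paste(need, collapse = ", ")))
  if (!any(meta$concentration == 0))
    return(list(design = NULL, status = "UNPROCESSABLE",
                reason = "no control samples (no concentration-0 columns)"))
  if (!any(meta$concentration > 0))
    return(list(design = NULL, status = "UNPROCESSABLE",
                reason = "no treated samples"))
  X <- cbind(intercept = 1, concentration = meta$concentration)
  for (v in c("cell_line", "duration", "batch")) {
    lev <- sort(unique(as.character(meta[[v]])))
    if (length(lev) > 1) {
      blk <- sapply(lev[-1], function(l) as.numeric(meta[[v]] == l))
      colnames(blk) <- paste0(v, lev[-1])
      X <- cbind(X, blk)
    }
  }
  if (qr(X)$rank < ncol(X))
    return(list(design = NULL, status = "UNPROCESSABLE",
                reason = "rank-deficient design after dropping levels"))
  list(design = X, status = "OK", reason = NA_character_)
}

#' Gene-wise ordinary least squares for one drug
#'
#' @param expr gene x experiment log-expression matrix.
#' @param design result of [build_design()] (or a design matrix).
#' @return list with per-gene `slope` (concentration coefficient),
#'   `s2` (residual variance), `df` (residual degrees of freedom) and
#'   the design-based unscaled slope variance factor `v`.
#' @export
fit_drug_model <- function(expr, design) {
  if (is.list(design)) {
    if (!identical(design$status, "OK"))
      stop("cannot fit an UNPROCESSABLE drug: ", design$reason,
           call. = FALSE)
    design <- design$design
  }
  X <- as.matrix(design)
  E <- as.matrix(expr)
  n <- ncol(E); p <- ncol(X)
  df <- n - p
  if (df < 1)
    stop("no residual degrees of freedom (n = ", n, ", p = ", p, ")",
         call. = FALSE)
  fit <- stats::lm.fit(X, t(E))
  cf <- fit$coefficients
  res <- as.matrix(fit$residuals)
  s2 <- colSums(res^2) / df
  v <- diag(solve(crossprod(X)))[["concentration"]]
  list(slope = cf["concentration", ], s2 = s2,
       df = rep(df, nrow(E)), v = v, genes = rownames(E))
}

# Newton inversion of the trigamma function (for the prior df estimate)
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in seq_len(50)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Empirical-Bayes variance moderation of gene-wise fits
#'
#' The gene variances `s2_g` are modelled as scaled-F draws around a
#' prior variance `s0_sq` with prior degrees of freedom `d0`; the
#' hyperparameters are estimated by matching the mean and variance of
#' `log s2` (digamma/trigamma moments). Posterior variances
#' `(d0 s0_sq + df s2) / (d0 + df)` shrink each gene toward the prior,
#' and the moderated t uses `d0 + df` degrees of freedom. If the
#' observed log-variance spread is no larger than sampling noise the
#' prior dominates (`d0 = Inf`, all posterior variances equal
#' `s0_sq`). `d0` is clamped to `[0.1, 1e6]` before the infinity
#' branch for numerical stability.
#'
#' @param fits result of [fit_drug_model()].
#' @param fdr_cutoff FDR threshold used for the %DEG quality score
#'   (default 0.5).
#' @param d0,s0_sq optional hyperparameter overrides (`d0 = 0` gives
#'   ordinary t-statistics; `d0 = Inf` fully pooled variances).
#' @return an `rc_drug_signature`: data.frame (gene, slope,
#'   moderated_t, p, fdr) with attributes `pct_deg`, `d0`, `s0_sq`,
#'   `n_experiments`.
#' @export
ebayes_moderate <- function(fits, fdr_cutoff = 0.5, d0 = NULL,
                            s0_sq = NULL) {
  s2 <- pmax(fits$s2, 1e-12)
  df <- fits$df
  .check(length(s2) >= 10,
         "need >= 10 genes to estimate moderation hyperparameters")
  if (is.null(d0) || is.null(s0_sq)) {
    z <- log(s2)
    e <- z - digamma(df / 2) + log(df / 2)
    evar <- var(e) * (length(e) - 1) / length(e) - mean(trigamma(df / 2))
    if (is.na(evar) || evar <= 0) {
      d0 <- Inf
      s0_sq <- exp(mean(e))
    } else {
      d0 <- 2 * .trigamma_inverse(evar)
      d0 <- min(max(d0, 0.1), 1e6)
      if (d0 >= 1e6) d0 <- Inf
      s0_sq <- if (is.infinite(d0)) exp(mean(e))
               else exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    }
  }
  post <- if (is.infinite(d0)) rep(s0_sq, length(s2))
          else if (d0 == 0) s2
          else (d0 * s0_sq + df * s2) / (d0 + df)
  tstat <- fits$slope / sqrt(post * fits$v)
  tdf <- d0 + df
  p <- 2 * pt(-abs(tstat), df = tdf)
  sig <- data.frame(gene = fits$genes, slope = fits$slope,
                    moderated_t = tstat, p = p, fdr = bh_fdr(p),
                    stringsAsFactors = FALSE)
  attr(sig, "d0") <- d0
  attr(sig, "s0_sq") <- s0_sq
  attr(sig, "pct_deg") <- 100 * mean(sig$fdr < fdr_cutoff)
  attr(sig, "n_experiments") <- NA_integer_
  class(sig) <- c("rc_drug_signature", "data.frame")
  sig
}

#' Percentage of differentially expressed genes in a drug signature
#'
#' The signature-quality covariate: the percentage of the drug's genes
#' with FDR under the (deliberately liberal) cutoff.
#'
#' @param sig an `rc_drug_signature`.
#' @param fdr_cutoff default 0.5.
#' @return percentage in `[0, 100]`.
#' @export
pct_deg <- function(sig, fdr_cutoff = 0.5) {
  .check(nrow(sig) > 0, "empty signature")
  100 * mean(sig$fdr < fdr_cutoff)
}

#' Fit signatures for every drug in a panel
#'
#' @param panel an `rc_drug_panel` (or list with `expr` and `meta`).
#' @param fdr_cutoff %DEG cutoff passed to [ebayes_moderate()].
#' @return list with `signatures` (named list of `rc_drug_signature`
#'   for processable drugs) and `status` (data.frame: drug, status,
#'   reason, pct_deg, n_experiments, n_cell_lines).
#' @export
drug_signatures <- function(panel, fdr_cutoff = 0.5) {
  meta <- panel$meta
  drugs <- unique(meta$drug)
  sigs <- list()
  status <- vector("list", length(drugs))
  for (i in seq_along(drugs)) {
    dmeta <- meta[meta$drug == drugs[i], , drop = FALSE]
    des <- build_design(dmeta)
    rec <- data.frame(drug = drugs[i], status = des$status,
                      reason = des$reason, pct_deg = NA_real_,
                      n_experiments = nrow(dmeta),
                      n_cell_lines = length(unique(dmeta$cell_line)),
                      stringsAsFactors = FALSE)
    if (des$status == "OK") {
      E <- panel$expr[, dmeta$column_id, drop = FALSE]
      fits <- tryCatch(fit_drug_model(E, des), error = function(e) NULL)
      if (is.null(fits)) {
        rec$status <- "UNPROCESSABLE"
        rec$reason <- "no residual degrees of freedom"
      } else {
        sig <- ebayes_moderate(fits, fdr_cutoff = fdr_cutoff)
        attr(sig, "n_experiments") <- nrow(dmeta)
        sigs[[drugs[i]]] <- sig
        rec$pct_deg <- attr(sig, "pct_deg")
      }
    }
    status[[i]] <- rec
  }
  list(signatures = sigs,
       status = do.call(rbind, c(status, list(make.row.names = FALSE))))
}
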