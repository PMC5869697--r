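# Negative binomial generalized log-linear models, fitted gene-wise by
# IRLS vectorized across genes, with a cohort-wide common dispersion
# estimated by profile likelihood. The variance model is
# var = mu + phi * mu^2 (phi = 0 is the Poisson limit).

.MU_EPS <- 1e-10
.ETA_CLAMP <- 30

# log-likelihood matrix/vector; phi == 0 uses the Poisson limit
.nb_ll <- function(y, mu, phi) {
  mu <- pmax(mu, .MU_EPS)
  if (phi == 0) dpois(y, mu, log = TRUE)
  else dnbinom(y, size = 1 / phi, mu = mu, log = TRUE)
}

# saturated per-observation log-likelihood (mu = y)
.nb_ll_sat <- function(y, phi) {
  out <- .nb_ll(y, pmax(y, .MU_EPS), phi)
  out[y == 0] <- 0
  out
}

#' Fit gene-wise negative binomial GLMs
#'
#' Fits `log mu_gi = x_i' beta_g + offset_i` for every gene at a fixed
#' dispersion, by iteratively reweighted least squares vectorized
#' across genes. Starting values come from a least-squares fit to
#' `log(counts + 0.5)`; iteration stops when the relative deviance
#' change falls below 1e-8 or after 50 iterations (the convergence
#' flag records which).
#'
#' @param counts gene x sample matrix of non-negative integers.
#' @param design sample x coefficient model matrix (full rank).
#' @param offsets per-sample offset, normally log effective library
#'   size; default `log(colSums(counts))`.
#' @param dispersion NB dispersion phi >= 0.
#' @return object of class `"rc_nbfit"`: `coefficients` (gene x p),
#'   `fitted` (gene x sample mu), `loglik` (per gene), `converged`,
#'   `dispersion`, `design`, `offsets`.
#' @export
fit_nb_glm <- function(counts, design, offsets = NULL, dispersion = 0) {
  Y <- as.matrix(counts)
  X <- as.matrix(design)
  G <- nrow(Y); n <- ncol(Y); p <- ncol(X)
  .check(nrow(X) == n, "design rows must match samples")
  .check(dispersion >= 0, "dispersion must be >= 0")
  if (sum(Y) == 0) stop("all-zero count matrix", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1, p)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(offsets)) offsets <- log(colSums(Y))
  .check(length(offsets) == n, "offsets must have one value per sample")
  phi <- dispersion

  off_m <- matrix(offsets, G, n, byrow = TRUE)
  Z0 <- log(Y + 0.5) - off_m
  B <- solve(crossprod(X), crossprod(X, t(Z0)))          # p x G

  xp_idx <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  XP <- X[, xp_idx[, 1], drop = FALSE] * X[, xp_idx[, 2], drop = FALSE]

  ll_sat <- rowSums(.nb_ll_sat(Y, phi))
  dev <- rep(Inf, G)
  converged <- rep(FALSE, G)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    Eta <- pmin(pmax(t(B) %*% t(X) + off_m, -.ETA_CLAMP), .ETA_CLAMP)
    Mu <- pmax(exp(Eta), .MU_EPS)
    W <- if (phi == 0) Mu else Mu / (1 + phi * Mu)
    Zw <- (Eta - off_m) + (Y - Mu) / Mu
    A <- W %*% XP                                        # G x p(p+1)/2
    bvec <- (W * Zw) %*% X                               # G x p
    B <- .solve_genewise(A, bvec, p, xp_idx)

    Eta2 <- pmin(pmax(t(B) %*% t(X) + off_m, -.ETA_CLAMP), .ETA_CLAMP)
    ll <- rowSums(.nb_ll(Y, exp(Eta2), phi))
    dev_new <- 2 * (ll_sat - ll)
    done <- abs(dev_new - dev) / (abs(dev_new) + 0.1) < 1e-8
    converged <- converged | done
    dev <- dev_new
    if (all(converged) || iter >= 50L) break
  }
  Eta <- pmin(pmax(t(B) %*% t(X) + off_m, -.ETA_CLAMP), .ETA_CLAMP)
  Mu <- pmax(exp(Eta), .MU_EPS)
  ll <- rowSums(.nb_ll(Y, Mu, phi))
  coefs <- t(B)
  dimnames(coefs) <- list(rownames(Y), colnames(X))
  structure(list(coefficients = coefs, fitted = Mu, loglik = ll,
                 deviance = 2 * (ll_sat - ll), converged = converged,
                 dispersion = phi, design = X, offsets = offsets,
                 iterations = iter),
            class = "rc_nbfit")
}

# solve the per-gene p x p weighted least squares systems; A holds the
# upper triangle of X'WX per gene, b the right-hand sides
.solve_genewise <- function(A, b, p, xp_idx) {
  G <- nrow(A)
  if (p == 1L) return(matrix(b / pmax(A, 1e-12), 1L, G))
  if (p == 2L) {
    a11 <- A[, 1]; a12 <- A[, 2]; a22 <- A[, 3]
    det <- pmax(a11 * a22 - a12^2, 1e-12)
    return(rbind((a22 * b[, 1] - a12 * b[, 2]) / det,
                 (a11 * b[, 2] - a12 * b[, 1]) / det))
  }
  B <- matrix(0, p, G)
  M <- matrix(0, p, p)
  lower <- cbind(xp_idx[, 2], xp_idx[, 1])
  for (g in seq_len(G)) {
    M[xp_idx] <- A[g, ]
    M[lower] <- A[g, ]
    B[, g] <- tryCatch(solve(M + diag(1e-10, p), b[g, ]),
                       error = function(e) rep(0, p))
  }
  B
}

#' Estimate a common NB dispersion by profile likelihood
#'
#' For each candidate phi the gene-wise GLMs are re-fitted and the
#' per-gene log-likelihoods summed; the profile is maximized on a
#' log-spaced grid over `[1e-4, 10]` (plus the Poisson boundary 0) and
#' refined by golden-section search between the bracketing grid points.
#'
#' @inheritParams fit_nb_glm
#' @return the dispersion estimate (a single number >= 0).
#' @export
estimate_dispersion <- function(counts, design, offsets = NULL) {
  Y <- as.matrix(counts)
  X <- as.matrix(design)
  .check(nrow(X) - ncol(X) >= 2,
         "need >= 2 residual degrees of freedom to estimate dispersion")
  if (sum(Y) == 0) stop("all-zero count matrix", call. = FALSE)
  if (is.null(offsets)) offsets <- log(colSums(Y))
  prof <- function(phi)
    sum(fit_nb_glm(Y, X, offsets, dispersion = phi)$loglik)
  grid <- c(0, 10^seq(-4, 1, length.out = 12))
  ll <- vapply(grid, prof, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  if (lo == hi) return(lo)
  ## golden-section search on [lo, hi]
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- prof(c1); f2 <- prof(c2)
  for (k in seq_len(45)) {
    if (f1 >= f2) { b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- prof(c1)
    } else { a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- prof(c2)
    }
    if ((b - a) < 1e-5 * (1 + b)) break
  }
  phi <- (a + b) / 2
  ## the Poisson boundary may still dominate the refined interior point
  if (ll[1] >= prof(phi)) 0 else phi
}

#' Likelihood ratio test between nested gene-wise fits
#'
#' @param full,reduced `rc_nbfit` objects on the same data; the reduced
#'   design must be nested in the full design.
#' @param df degrees of freedom; defaults to the difference in the
#'   number of coefficients.
#' @return per-gene p-values from the upper chi-square tail of
#'   `2 * (ll_full - ll_reduced)` (negative statistics clamped to 0).
#' @export
lrt <- function(full, reduced, df = NULL) {
  stopifnot(inherits(full, "rc_nbfit"), inherits(reduced, "rc_nbfit"))
  pf <- ncol(full$design); pr <- ncol(reduced$design)
  if (pr > pf) stop("reduced model has more coefficients than full",
                    call. = FALSE)
  fit <- stats::lm.fit(full$design, reduced$design)
  if (max(abs(as.matrix(fit$residuals))) > 1e-8)
    stop("designs are not nested: reduced columns outside the span of ",
         "the full design", call. = FALSE)
  if (is.null(df)) df <- pf - pr
  .check(df >= 1, "df must be >= 1")
  stat <- pmax(0, 2 * (full$loglik - reduced$loglik))
  pchisq(stat, df = df, lower.tail = FALSE)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Thin wrapper around `stats::p.adjust(method = "BH")` that validates
#' its input; this is the step-up procedure
#' `fdr_(i) = min_{j >= i} p_(j) * n / j`, capped at 1.
#'
#' @param p vector of p-values in `[0, 1]` (no missing values).
#' @return FDR vector in the input order.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(is.nan(p)))
    stop("p contains missing/NaN values", call. = FALSE)
  .check(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
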