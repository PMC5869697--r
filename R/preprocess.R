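# Within-sample (gene length) and between-sample (sequencing depth)
# normalization, and filtering of lowly expressed genes. Differential
# expression downstream consumes RAW counts with library-size offsets;
# normalized values feed diagnostics only (count models need integers).

#' Counts per million
#'
#' @param counts non-negative gene x sample matrix.
#' @return matrix of the same shape; every column sums to 1e6.
#' @export
cpm <- function(counts) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  bad <- lib <= 0
  if (any(bad))
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[bad], collapse = ", "), call. = FALSE)
  sweep(counts, 2, lib, "/") * 1e6
}

#' Filter lowly expressed genes on a CPM cutoff
#'
#' A gene is retained iff its CPM exceeds `cpm_cutoff` (strictly) in at
#' least `ceiling(min_fraction * n_samples)` samples. The rule is
#' evaluated on all samples jointly -- tumour and normal alike -- so
#' selection is irrespective of tissue type.
#'
#' @param counts gene x sample count matrix.
#' @param cpm_cutoff CPM threshold (default 0.5).
#' @param min_fraction minimum fraction of samples above the cutoff
#'   (default 1/6; "at least" semantics, hence the ceiling).
#' @return the row-subset count matrix.
#' @export
filter_low_expressed <- function(counts, cpm_cutoff = 0.5,
                                 min_fraction = 1 / 6) {
  .check(cpm_cutoff >= 0, "cpm_cutoff must be >= 0")
  .check(min_fraction > 0 && min_fraction <= 1,
         "min_fraction must lie in (0, 1]")
  x <- cpm(counts)
  need <- ceiling(min_fraction * ncol(counts))
  keep <- rowSums(x > cpm_cutoff) >= need
  counts[keep, , drop = FALSE]
}

#' Effective library sizes by upper-quartile normalization
#'
#' Raw column totals are easily distorted by a handful of dominant
#' genes; scaling each library size by the sample's upper quartile of
#' non-zero CPM (normalized to a unit geometric mean) gives the
#' effective depths used as GLM offsets throughout the pipeline.
#'
#' @param counts gene x sample count matrix.
#' @return named vector of effective library sizes.
#' @export
effective_lib_sizes <- function(counts) {
  lib <- colSums(counts)
  uq <- apply(cpm(counts), 2, .upper_quartile_nz)
  fac <- uq / exp(mean(log(uq)))
  lib * fac
}

.upper_quartile_nz <- function(v) {
  nz <- v[v > 0]
  if (!length(nz)) return(NA_real_)
  quantile(nz, 0.75, names = FALSE)
}

#' Normalize counts by gene length and sequencing depth
#'
#' Step 1 divides each gene by its length in kilobases (within-sample);
#' step 2 rescales each column so its upper quartile of non-zero values
#' matches the global upper quartile (between-sample), or performs full
#' quantile normalization when `method = "full"`.
#'
#' @param counts gene x sample count matrix.
#' @param lengths named vector of gene lengths in bp covering every row.
#' @param method `"upperquartile"` (default) or `"full"` quantile.
#' @return list of class `"rc_normalized"`: `matrix`,
#'   `length_normalized`, `depth_normalized`, `effective_lib_size`.
#' @export
normalize_length_depth <- function(counts, lengths,
                                   method = c("upperquartile", "full")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing))
    stop("missing gene length for: ",
         paste(head(missing, 10), collapse = ", "),
         if (length(missing) > 10) " ...", call. = FALSE)
  len <- lengths[rownames(counts)]
  .check(all(len > 0), "all gene lengths must be positive")
  r <- counts / (len / 1000)
  if (method == "upperquartile") {
    cuq <- apply(r, 2, .upper_quartile_nz)
    guq <- .upper_quartile_nz(as.vector(r))
    fac <- guq / cuq
    out <- sweep(r, 2, fac, "*")
    eff <- colSums(counts) / fac
  } else {
    o <- apply(r, 2, sort)
    ref <- rowMeans(o)
    out <- apply(r, 2, function(v)
      stats::approx(seq_along(ref), ref,
                    rank(v, ties.method = "average"))$y)
    dimnames(out) <- dimnames(r)
    eff <- colSums(counts)
  }
  structure(list(matrix = out, length_normalized = TRUE,
                 depth_normalized = TRUE, effective_lib_size = eff),
            class = "rc_normalized")
}
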