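# SVG figure analogues of the headline diagnostics: signature sizes
# against FDR cutoff, the tumour/normal size ratio, and per-drug
# negative-enrichment frequency against %DEG.

#' Plot signature sizes against FDR cutoff
#'
#' One curve per signature family: mean number of genes under the
#' cutoff across the family's contrasts, on a log-spaced cutoff grid.
#'
#' @param families named list of signature lists (e.g. `group`,
#'   `sample`, `normal_control` families from [make_signatures()]).
#' @param cutoffs FDR cutoff grid.
#' @return invisibly, the matrix of mean sizes (cutoff x family).
#' @export
plot_signature_sizes <- function(families,
                                 cutoffs = 10^seq(-3, 0, length.out = 25)) {
  sizes <- sapply(families, function(fam)
    vapply(cutoffs, function(ct)
      mean(vapply(fam, signature_size, numeric(1), fdr_cutoff = ct)),
      numeric(1)))
  matplot(cutoffs, pmax(sizes, 0.5), type = "l", log = "xy", lty = 1,
          lwd = 2, xlab = "FDR cutoff", ylab = "mean signature size",
          main = "Signature size vs FDR cutoff")
  legend("topleft", legend = colnames(sizes), lty = 1, lwd = 2,
         col = seq_len(ncol(sizes)), bty = "n")
  invisible(sizes)
}

#' Plot negative-enrichment frequency against %DEG deciles
#'
#' @param summary per-drug summary from [summarize_connectivity()].
#' @return invisibly, the per-decile mean frequencies.
#' @export
plot_neg_freq_vs_pctdeg <- function(summary) {
  m <- tapply(summary$neg_freq, summary$decile, mean)
  plot(as.integer(names(m)), m, type = "b", pch = 19,
       xlab = "%DEG decile of drug signature",
       ylab = "mean negative-enrichment frequency",
       main = "Enrichment frequency vs signature quality")
  invisible(m)
}

# write the standard run figures as SVG into the run directory
render_figures <- function(state, config) {
  dir <- config$outdir
  fams <- list()
  for (k in intersect(config$kinds, c("group", "subtype", "sample",
                                      "normal_control"))) {
    f <- state[[paste0("sigs_", k)]]
    if (!is.null(f)) fams[[k]] <- f
  }
  if (length(fams)) {
    svg(file.path(dir, "fig_signature_sizes.svg"), width = 7, height = 5)
    plot_signature_sizes(fams)
    dev.off()
  }
  if (!is.null(state$summary)) {
    svg(file.path(dir, "fig_negfreq_pctdeg.svg"), width = 7, height = 5)
    plot_neg_freq_vs_pctdeg(state$summary)
    dev.off()
  }
  invisible(NULL)
}
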