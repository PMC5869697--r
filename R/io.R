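# TSV readers/writers (genes as rows, first column the gene id),
# JSON sidecars, and gene-id mapping. TSV is the canonical
# interchange so fixtures stay diff-able.

.write_tsv <- function(df, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    df <- data.frame(setNames(list(rownames(df)), rownames_as),
                     as.data.frame(df), check.names = FALSE,
                     stringsAsFactors = FALSE)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' Emits `counts.tsv` (gene rows, sample columns), `gene_lengths.tsv`
#' (gene, length_bp), `samples.tsv`, `truth.tsv`, and a
#' `manifest.json` with file checksums.
#'
#' @param cohort an `rc_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(cohort$counts, file.path(dir, "counts.tsv"), "gene")
  .write_tsv(data.frame(gene = names(cohort$gene_lengths),
                        length_bp = as.integer(cohort$gene_lengths)),
             file.path(dir, "gene_lengths.tsv"))
  .write_tsv(cohort$samples, file.path(dir, "samples.tsv"))
  .write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  files <- c("counts.tsv", "gene_lengths.tsv", "samples.tsv", "truth.tsv")
  jsonlite::write_json(
    list(files = as.list(tools::md5sum(file.path(dir, files)))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a gene x sample count matrix from TSV
#'
#' First column = gene id, remaining columns = samples.
#'
#' @param path TSV file.
#' @return integer matrix with gene rownames.
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Read gene lengths from a two-column TSV
#' @param path TSV with columns gene, length_bp.
#' @return named integer vector.
#' @export
read_lengths_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(df$length_bp, df$gene)
}

#' Read a sample-metadata TSV
#' @param path TSV with sample_id, patient_id, tissue, subtype, stage,
#'   depth columns.
#' @return data.frame.
#' @export
read_samples_tsv <- function(path)
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(subtype = "character", stage = "character"))

#' Write a drug panel to a directory
#'
#' One expression TSV per drug plus `drug_metadata.tsv`,
#' `drug_truth.tsv` and a checksum manifest.
#'
#' @param panel an `rc_drug_panel`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_drug_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (d in unique(panel$meta$drug)) {
    cols <- panel$meta$column_id[panel$meta$drug == d]
    f <- paste0(d, ".tsv")
    .write_tsv(round(panel$expr[, cols, drop = FALSE], 6),
               file.path(dir, f), "gene")
    files <- c(files, f)
  }
  .write_tsv(panel$meta, file.path(dir, "drug_metadata.tsv"))
  .write_tsv(panel$truth, file.path(dir, "drug_truth.tsv"))
  files <- c(files, "drug_metadata.tsv", "drug_truth.tsv")
  jsonlite::write_json(
    list(files = as.list(tools::md5sum(file.path(dir, files)))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Write a list of signatures as one combined TSV plus a JSON sidecar
#'
#' @param sigs named list of `rc_signature` or `rc_drug_signature`.
#' @param path output TSV path (sidecar gets extension `.json`).
#' @return `path`, invisibly.
#' @export
write_signatures_tsv <- function(sigs, path) {
  rows <- lapply(names(sigs), function(id) {
    s <- sigs[[id]]
    data.frame(contrast_id = id, as.data.frame(s),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, 8)
  .write_tsv(df, path)
  side <- lapply(names(sigs), function(id) {
    s <- sigs[[id]]
    list(contrast_kind = attr(s, "contrast_kind"),
         contrast_id = id, dispersion = attr(s, "dispersion"),
         pct_deg = attr(s, "pct_deg"), n_genes = nrow(s))
  })
  jsonlite::write_json(side, paste0(tools::file_path_sans_ext(path),
                                    ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Re-key a count matrix through a gene-id mapping table
#'
#' Unmapped genes are dropped (count reported via `message`);
#' many-to-one collisions keep the source row with the larger total
#' count.
#'
#' @param counts gene x sample matrix.
#' @param mapping two-column data.frame (from, to), e.g. an
#'   Entrez-to-Ensembl table read from a local TSV.
#' @return re-keyed matrix.
#' @export
map_gene_ids <- function(counts, mapping) {
  .check(is.data.frame(mapping) && ncol(mapping) >= 2 && nrow(mapping) > 0,
         "mapping must be a non-empty two-column data.frame")
  from <- as.character(mapping[[1]]); to <- as.character(mapping[[2]])
  idx <- match(rownames(counts), from)
  unmapped <- is.na(idx)
  if (any(unmapped))
    message(sum(unmapped), " gene(s) had no mapping and were dropped")
  m <- counts[!unmapped, , drop = FALSE]
  new <- to[idx[!unmapped]]
  if (anyDuplicated(new)) {
    tot <- rowSums(m)
    keep <- !logical(nrow(m))
    for (dup in unique(new[duplicated(new)])) {
      rows <- which(new == dup)
      drop <- rows[-which.max(tot[rows])]
      keep[drop] <- FALSE
    }
    message(sum(!keep), " row(s) dropped on many-to-one collisions ",
            "(larger total count kept)")
    m <- m[keep, , drop = FALSE]
    new <- new[keep]
  }
  rownames(m) <- new
  m
}
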