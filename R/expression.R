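#' Expression matrix container
#'
#' Holds a genes x samples matrix of raw counts together with a per-gene
#' biotype label (e.g. `"protein_coding"`) and a per-sample group label
#' (`"control"` or `"patient"`). All downstream filtering, normalization and
#' correlation steps operate on this container.
#'
#' @param counts Non-negative integer matrix, genes in rows, samples in
#'   columns; both dimensions must carry unique names.
#' @param biotype Optional character vector of per-gene biotype labels, named
#'   by gene id or in row order. Missing labels become `NA`.
#' @param group Optional character vector of per-sample labels, `"control"` or
#'   `"patient"`, named by sample id or in column order.
#' @return An object of class `expression_matrix`: a list with elements
#'   `counts`, `gene_ids`, `sample_ids`, `biotype`, `group`.
#' @export
expression_matrix <- function(counts, biotype = NULL, group = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_rtc("counts must have gene row names and sample column names")
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1]
    stop_rtc("duplicate gene id: ", dup)
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- colnames(counts)[duplicated(colnames(counts))][1]
    stop_rtc("duplicate sample id: ", dup)
  }
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop_rtc("counts must be non-negative integers")
  }
  storage.mode(counts) <- "double"
  gene_ids <- rownames(counts)
  sample_ids <- colnames(counts)
  biotype <- align_labels(biotype, gene_ids, "biotype")
  group <- align_labels(group, sample_ids, "group")
  if (!all(is.na(group) | group %in% c("control", "patient"))) {
    stop_rtc("group labels must be 'control' or 'patient'")
  }
  structure(
    list(counts = counts, gene_ids = gene_ids, sample_ids = sample_ids,
         biotype = biotype, group = group),
    class = "expression_matrix"
  )
}

align_labels <- function(x, ids, what) {
  if (is.null(x)) {
    return(stats::setNames(rep(NA_character_, length(ids)), ids))
  }
  nm <- names(x)
  x <- stats::setNames(as.character(x), nm)
  if (!is.null(nm)) {
    out <- stats::setNames(unname(x[ids]), ids)
  } else if (length(x) == length(ids)) {
    out <- stats::setNames(x, ids)
  } else {
    stop_rtc(what, " must be named or match the number of ids")
  }
  out
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", length(x$gene_ids), "genes x",
      length(x$sample_ids), "samples\n")
  grp <- table(x$group, useNA = "ifany")
  cat("  groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

subset_genes <- function(m, keep) {
  expression_matrix(m$counts[keep, , drop = FALSE],
                    biotype = m$biotype[keep], group = m$group)
}

#' Read a TSV count matrix
#'
#' Parses a tab-separated matrix with a header row of sample ids and one row
#' per gene (first column = gene id). Entries must be non-negative integers.
#' Duplicated gene ids, ragged rows, and negative or non-integer entries are
#' hard errors that name the offending id or line.
#'
#' @param path Path to the TSV file.
#' @param biotype_map Optional biotype annotation: a named character vector,
#'   a two-column data frame (gene_id, biotype), or a path to a two-column TSV.
#' @param group Optional per-sample group labels (see [expression_matrix()]).
#' @return An [expression_matrix()].
#' @export
read_counts <- function(path, biotype_map = NULL, group = NULL) {
  if (!file.exists(path)) stop_rtc("counts file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop_rtc("counts file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  # header may or may not carry a leading gene-id column name
  n_samples <- length(fields[[2]]) - 1L
  sample_ids <- if (length(header) == n_samples) header else header[-1]
  if (length(sample_ids) != n_samples) {
    stop_rtc("header has ", length(sample_ids), " sample ids but line 2 has ",
             n_samples, " value columns")
  }
  body <- fields[-1]
  widths <- lengths(body)
  bad <- which(widths != n_samples + 1L)
  if (length(bad) > 0L) {
    stop_rtc("ragged row at line ", bad[1] + 1L, ": expected ",
             n_samples + 1L, " fields, found ", widths[bad[1]])
  }
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(gene_ids)) {
    stop_rtc("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1])
  }
  vals <- vapply(body, function(f) f[-1], character(n_samples))
  vals <- if (n_samples == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (!all(grepl("^[0-9]+$", vals))) {
    off <- vals[!grepl("^[0-9]+$", vals)][1]
    stop_rtc("invalid count entry '", off, "': counts must be non-negative integers")
  }
  counts <- matrix(as.numeric(vals), nrow = length(gene_ids),
                   dimnames = list(gene_ids, sample_ids))
  expression_matrix(counts, biotype = resolve_biotype_map(biotype_map),
                    group = group)
}

resolve_biotype_map <- function(biotype_map) {
  if (is.null(biotype_map)) return(NULL)
  if (is.character(biotype_map) && length(biotype_map) == 1L &&
      file.exists(biotype_map)) {
    df <- utils::read.delim(biotype_map, header = TRUE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop_rtc("biotype map must have two columns")
    return(stats::setNames(as.character(df[[2]]), as.character(df[[1]])))
  }
  if (is.data.frame(biotype_map)) {
    return(stats::setNames(as.character(biotype_map[[2]]),
                           as.character(biotype_map[[1]])))
  }
  biotype_map
}

control_columns <- function(m) {
  which(!is.na(m$group) & m$group == "control")
}

#' Filter genes on control-sample counts
#'
#' Two-stage filter evaluated on control columns only, mirroring how a
#' reference gene set is derived from the healthy cohort before network
#' construction. Stage 1 drops genes with zero counts in every control
#' sample. Stage 2 keeps genes with at least `min_count` counts in at least
#' one control (`mode = "any_sample"`) or in every control
#' (`mode = "all_samples"`, the robustness variant). Patient columns are never
#' consulted; gene order is preserved.
#'
#' @param m An [expression_matrix()] with at least one control sample.
#' @param mode `"any_sample"` or `"all_samples"`.
#' @param min_count Minimum count threshold (default 10).
#' @return The filtered [expression_matrix()].
#' @export
filter_genes <- function(m, mode = c("any_sample", "all_samples"),
                         min_count = 10) {
  mode <- match.arg(mode)
  if (min_count < 1) stop_rtc("min_count must be >= 1")
  ctrl <- control_columns(m)
  if (length(ctrl) == 0L) stop_rtc("no control samples in expression matrix")
  cc <- m$counts[, ctrl, drop = FALSE]
  keep1 <- rowSums(cc) > 0
  keep2 <- if (mode == "any_sample") {
    apply(cc, 1, max) >= min_count
  } else {
    apply(cc, 1, min) >= min_count
  }
  subset_genes(m, keep1 & keep2)
}

#' Restrict to protein-coding genes
#'
#' @param m An [expression_matrix()] with biotype labels.
#' @return The [expression_matrix()] containing only genes labeled
#'   `"protein_coding"`.
#' @export
restrict_protein_coding <- function(m) {
  if (all(is.na(m$biotype))) stop_rtc("no biotype labels present")
  keep <- !is.na(m$biotype) & m$biotype == "protein_coding"
  if (!any(keep)) stop_rtc("no protein-coding genes remain")
  subset_genes(m, keep)
}

#' Per-gene coefficient of variation
#'
#' CV in percent: the ratio of the standard deviation to the mean read count,
#' multiplied by 100. The sample (n-1) standard deviation is used. Genes with
#' mean 0 get `cv_percent = NA` (undefined), not an error.
#'
#' @param m An [expression_matrix()] with at least two samples.
#' @return A data frame with columns `gene_id`, `mean_count`, `sd_count`,
#'   `cv_percent`.
#' @export
gene_cv <- function(m) {
  if (length(m$sample_ids) < 2L) stop_rtc("CV requires >= 2 samples")
  mu <- rowMeans(m$counts)
  sdv <- apply(m$counts, 1, stats::sd)
  cv <- ifelse(mu == 0, NA_real_, sdv / mu * 100)
  data.frame(gene_id = m$gene_ids, mean_count = mu, sd_count = sdv,
             cv_percent = cv, row.names = NULL, stringsAsFactors = FALSE)
}

#' Normalize a count matrix
#'
#' `"log2_cpm"` scales each sample to counts per million and applies
#' `log2(x + 1)`; `"raw"` returns the counts unchanged as doubles. The log-CPM
#' transform is the default input scale for the correlation reference; raw
#' mode is retained for sensitivity analysis.
#'
#' @param m An [expression_matrix()].
#' @param method `"log2_cpm"` or `"raw"`.
#' @return A numeric matrix with the same dimensions and dimnames as the
#'   counts.
#' @export
normalize_counts <- function(m, method = c("log2_cpm", "raw")) {
  method <- match.arg(method)
  x <- m$counts
  if (method == "raw") return(x)
  totals <- colSums(x)
  if (any(totals == 0)) {
    stop_rtc("sample with zero total count: ",
             colnames(x)[totals == 0][1])
  }
  log2(sweep(x, 2, totals, "/") * 1e6 + 1)
}
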