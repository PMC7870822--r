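#' Gene set catalog
#'
#' @param sets Named list of character vectors (no empty sets, unique names).
#' @param source Source tag.
#' @return Object of class `gene_set_catalog`.
#' @export
gene_set_catalog <- function(sets, source = "unknown") {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop_rtc("all gene sets must be named")
  }
  if (anyDuplicated(names(sets))) {
    stop_rtc("duplicate gene set name: ",
             names(sets)[duplicated(names(sets))][1])
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0L)) stop_rtc("empty gene set not allowed")
  structure(list(sets = sets, source = source), class = "gene_set_catalog")
}

#' @export
print.gene_set_catalog <- function(x, ...) {
  cat("gene_set_catalog:", length(x$sets), "sets from", x$source, "\n")
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Each line: set name, description, then member gene ids, tab-separated.
#' Duplicate set names and lines with fewer than 3 fields are hard errors;
#' duplicate members within a set are collapsed.
#'
#' @param path Path to the GMT file.
#' @return A [gene_set_catalog()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_rtc("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop_rtc("GMT line ", short[1], " has ", lengths(fields)[short[1]],
             " field(s); expected >= 3")
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop_rtc("duplicate gene set name: ", nm[duplicated(nm)][1])
  }
  sets <- stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])), nm)
  gene_set_catalog(sets, source = basename(path))
}

#' Write a catalog as GMT
#'
#' @param catalog A [gene_set_catalog()].
#' @param path Output path.
#' @export
write_gmt <- function(catalog, path) {
  lines <- vapply(names(catalog$sets), function(nm) {
    paste(c(nm, catalog$source, catalog$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false discovery rate control; input order is preserved.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop_rtc("p-values must be in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Hypergeometric over-representation of gene sets in a network
#'
#' One-tailed (upper) hypergeometric test per set: with a universe of N
#' genes of which K belong to the set, and n network genes drawn from the
#' universe, `p = P[X >= k]` where k is the number of network genes in the
#' set. Benjamini-Hochberg q-values are computed across all sets in the
#' catalog. Network genes outside the universe are dropped with a log note;
#' sets with no members in the universe are omitted.
#'
#' @param network_genes Character vector of network gene ids.
#' @param catalog A [gene_set_catalog()].
#' @param universe Character vector: the gene universe.
#' @return Data frame sorted by p: `set_name`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   `log_p` (`-log10 p`).
#' @export
hypergeom_enrich <- function(network_genes, catalog, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop_rtc("empty universe")
  network_genes <- unique(network_genes)
  if (length(network_genes) == 0L) stop_rtc("empty network gene set")
  dropped <- sum(!(network_genes %in% universe))
  if (dropped > 0L) {
    message(dropped, " network gene(s) outside the universe dropped")
  }
  ng <- intersect(network_genes, universe)
  if (length(ng) == 0L) stop_rtc("no network genes in the universe")
  N <- length(universe)
  n <- length(ng)
  rows <- lapply(names(catalog$sets), function(nm) {
    set <- intersect(catalog$sets[[nm]], universe)
    K <- length(set)
    if (K == 0L) {
      message("set '", nm, "' absent from universe: omitted")
      return(NULL)
    }
    k <- length(intersect(ng, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_rtc("no catalog set overlaps the universe")
  out$q <- benjamini_hochberg(out$p)
  out$log_p <- -log10(out$p)
  out[order(out$p), , drop = FALSE]
}

#' Hypergeometric overlap test between two gene sets
#'
#' Tests whether the overlap `k = |A ∩ B|` within a common universe is
#' larger than expected by chance: upper-tail hypergeometric p with
#' parameters `(N = |universe|, K = |A|, n = |B|)`. Symmetric in A and B.
#'
#' @param setA,setB Nonempty character vectors.
#' @param universe Character vector: the common universe.
#' @return List: `k` (overlap size), `p`.
#' @export
set_overlap_test <- function(setA, setB, universe) {
  universe <- unique(universe)
  A <- intersect(unique(setA), universe)
  B <- intersect(unique(setB), universe)
  if (length(A) == 0L || length(B) == 0L) {
    stop_rtc("both sets must be nonempty within the universe")
  }
  k <- length(intersect(A, B))
  N <- length(universe)
  p <- stats::phyper(k - 1, length(A), N - length(A), length(B),
                     lower.tail = FALSE)
  list(k = k, p = p)
}

#' Endophenotype enrichment across a cohort
#'
#' Runs [hypergeom_enrich()] on each patient's node set (correction per
#' patient across the catalog), then summarizes each set's cohort frequency:
#' the fraction of patients with `q` below the threshold.
#'
#' @param cohort Nonempty list of networks.
#' @param catalog A [gene_set_catalog()].
#' @param universe Gene universe; the recommended default is the intersection
#'   of interactome proteins with the filtered expression genes.
#' @param q_threshold Per-patient significance threshold on q (default 0.05).
#' @return List: `per_patient` (long data frame with a `patient_id` column),
#'   `frequency` (data frame `set_name`, `n_enriched`, `frequency`).
#' @export
enrich_cohort <- function(cohort, catalog, universe, q_threshold = 0.05) {
  if (length(cohort) == 0L) stop_rtc("empty cohort")
  empty <- vapply(cohort, function(net) length(net$nodes) == 0L, logical(1))
  if (any(empty)) {
    message(sum(empty), " empty network(s) omitted from enrichment")
    cohort <- cohort[!empty]
    if (length(cohort) == 0L) stop_rtc("all networks empty")
  }
  tabs <- lapply(cohort, function(net) {
    tb <- hypergeom_enrich(net$nodes, catalog, universe)
    tb$patient_id <- net$patient_id
    tb
  })
  per_patient <- do.call(rbind, tabs)
  freq <- do.call(rbind, lapply(split(per_patient, per_patient$set_name),
    function(d) data.frame(set_name = d$set_name[1],
                           n_enriched = sum(d$q < q_threshold),
                           frequency = mean(d$q < q_threshold),
                           stringsAsFactors = FALSE)))
  rownames(freq) <- NULL
  list(per_patient = per_patient, frequency = freq)
}
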