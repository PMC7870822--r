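#' Interactome container
#'
#' A simple undirected graph of experimentally supported protein-protein
#' interactions: no self-loops, no duplicate edges, endpoints stored in
#' canonical (lexicographic) order, with per-edge source tags.
#'
#' @param edges Data frame with columns `a`, `b` (and optionally `sources`).
#' @param sources Optional character vector of per-edge source tags (used when
#'   `edges` lacks a `sources` column).
#' @return An object of class `interactome`: list with `proteins` (character
#'   vector) and `edges` (data frame `a`, `b`, `sources` with `a < b`).
#' @export
interactome <- function(edges, sources = NULL) {
  if (nrow(edges) == 0L) stop_rtc("interactome has no edges")
  pairs <- canonicalize_pairs(edges$a, edges$b)
  src <- edges$sources %||% sources %||% rep("unknown", nrow(pairs))
  loops <- pairs$a == pairs$b
  if (any(loops)) {
    message("dropping ", sum(loops), " self-loop(s)")
    pairs <- pairs[!loops, , drop = FALSE]
    src <- src[!loops]
  }
  if (nrow(pairs) == 0L) stop_rtc("interactome has no edges after removing self-loops")
  key <- paste(pairs$a, pairs$b, sep = "|")
  merged <- tapply(src, key, function(s) {
    paste(sort(unique(unlist(strsplit(s, ";", fixed = TRUE)))), collapse = ";")
  })
  uk <- sort(names(merged))
  pr <- key_to_pairs(uk)
  out <- data.frame(a = pr$a, b = pr$b,
                    sources = as.character(merged[uk]),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(
    list(proteins = sort(unique(c(out$a, out$b))), edges = out),
    class = "interactome"
  )
}

#' @export
print.interactome <- function(x, ...) {
  cat("interactome:", length(x$proteins), "proteins,",
      nrow(x$edges), "interactions\n")
  invisible(x)
}

edge_keys <- function(i) paste(i$edges$a, i$edges$b, sep = "|")

#' Read and consolidate interactome edge lists
#'
#' Consolidates one or more edge-list files into a single simple undirected
#' interactome. TSV files contribute their first two columns; `.sif` files
#' ("A pp B") contribute columns one and three. Pair order is canonicalized,
#' self-loops are dropped with a logged count, and duplicate edges across
#' sources are merged with their source tags unioned.
#'
#' @param paths Character vector of edge-list file paths.
#' @param tags Source names, one per file (default: file base names).
#' @return An [interactome()].
#' @export
read_interactome <- function(paths, tags = NULL) {
  tags <- tags %||% basename(paths)
  if (length(tags) != length(paths)) stop_rtc("one tag per file required")
  parts <- lapply(seq_along(paths), function(k) {
    path <- paths[k]
    if (!file.exists(path)) stop_rtc("interactome file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sif <- grepl("\\.sif$", path, ignore.case = TRUE)
    fields <- strsplit(lines, if (sif) "[ \t]+" else "\t")
    need <- if (sif) 3L else 2L
    widths <- lengths(fields)
    # tolerate an explicit header line in TSV inputs (as written by
    # write_interactome, or gene_a/gene_b-style column names)
    start <- 1L
    if (!sif && widths[1] >= need) {
      f1 <- tolower(fields[[1]])
      canonical <- identical(f1[1:2], c("a", "b")) && widths[1] >= 3 &&
        f1[3] == "sources"
      named <- f1[1] %in% c("gene_a", "interactor_a", "protein_a", "node_a")
      if (canonical || named) start <- 2L
    }
    bad <- which(widths < need)
    bad <- bad[bad >= start]
    if (length(bad) > 0L) {
      stop_rtc("line ", bad[1], " of ", path, " has ", widths[bad[1]],
               " column(s); expected >= ", need)
    }
    if (start > length(fields)) return(NULL)
    idx <- seq.int(start, length(fields))
    ai <- vapply(fields[idx], `[[`, character(1), 1L)
    bi <- vapply(fields[idx], `[[`, character(1), if (sif) 3L else 2L)
    data.frame(a = ai, b = bi, sources = tags[k], stringsAsFactors = FALSE)
  })
  all_edges <- do.call(rbind, parts)
  if (is.null(all_edges) || nrow(all_edges) == 0L) {
    stop_rtc("no edges found in any input file")
  }
  interactome(all_edges)
}

#' Write an interactome as a canonical TSV edge list
#'
#' @param i An [interactome()].
#' @param path Output path.
#' @export
write_interactome <- function(i, path) {
  utils::write.table(i$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Intersect candidate gene pairs with the interactome
#'
#' @param i An [interactome()].
#' @param pairs Data frame (or 2-column matrix) of unordered gene pairs.
#' @return Data frame `a`, `b` of the pairs that are interactome edges, in
#'   canonical order. The empty intersection is allowed.
#' @export
induced_edges <- function(i, pairs) {
  if (is.matrix(pairs)) pairs <- data.frame(a = pairs[, 1], b = pairs[, 2])
  if (nrow(pairs) == 0L) {
    return(data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE))
  }
  keys <- unique(pair_key(pairs[[1]], pairs[[2]]))
  key_to_pairs(sort(intersect(keys, edge_keys(i))))
}

#' Fraction of query genes present in the interactome
#'
#' Coverage report used when matching expression gene ids to the interactome
#' namespace; no automatic id mapping is attempted.
#'
#' @param i An [interactome()].
#' @param genes Character vector of gene ids.
#' @return Fraction in `[0, 1]`.
#' @export
interactome_coverage <- function(i, genes) {
  if (length(genes) == 0L) return(NA_real_)
  mean(genes %in% i$proteins)
}
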