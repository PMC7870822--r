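# Shared fixture builders and independent oracles.

make_counts <- function(mat, genes = NULL, samples = NULL) {
  genes <- genes %||% sprintf("g%d", seq_len(nrow(mat)))
  samples <- samples %||% sprintf("s%d", seq_len(ncol(mat)))
  dimnames(mat) <- list(genes, samples)
  mat
}

`%||%` <- function(x, y) if (is.null(x)) y else x

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

toy_interactome <- function(pairs) {
  interactome(data.frame(a = pairs[, 1], b = pairs[, 2],
                         sources = "toy", stringsAsFactors = FALSE))
}

# a reticulotype built directly from an edge list (for topology/overlap tests)
make_net <- function(id, a, b = NULL) {
  if (is.null(b)) {
    edges <- data.frame(a = character(0), b = character(0),
                        stringsAsFactors = FALSE)
  } else {
    swap <- b < a
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    edges <- data.frame(a = a, b = b, stringsAsFactors = FALSE)
  }
  structure(list(patient_id = id, nodes = sort(unique(c(edges$a, edges$b))),
                 edges = edges, records = edges, params = list()),
            class = "reticulotype")
}

# independent Pearson correlation oracle (two-pass centered formula)
pearson_oracle <- function(x, y) {
  dx <- x - sum(x) / length(x)
  dy <- y - sum(y) / length(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Floyd-Warshall all-pairs shortest paths on an adjacency matrix
floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# brute-force topology metrics from an adjacency matrix (nodes with degree
# >= 1 only, matching a network that stores no isolated nodes)
topology_oracle <- function(adj) {
  deg <- rowSums(adj)
  keep <- deg > 0
  adj <- adj[keep, keep, drop = FALSE]
  deg <- rowSums(adj)
  nv <- nrow(adj)
  ne <- sum(adj) / 2
  d <- floyd_warshall(adj)
  ut <- d[upper.tri(d)]
  fin <- ut[is.finite(ut)]
  list(n_nodes = nv, n_edges = ne,
       density = 2 * ne / (nv * (nv - 1)),
       diameter = max(fin),
       cpl = mean(fin),
       heterogeneity = sqrt(mean(deg^2) - mean(deg)^2) / mean(deg),
       n_components = sum(sapply(seq_len(nv), function(i)
         all(!is.finite(d[i, seq_len(nv) < i])))))
}

# exhaustive upper-tail hypergeometric by enumerating all n-subsets
hyper_enum_oracle <- function(N, K, n, k) {
  universe <- seq_len(N)
  inset <- universe <= K
  draws <- utils::combn(N, n)
  mean(colSums(matrix(inset[draws], nrow = n)) >= k)
}

# Benjamini-Hochberg step-up by hand
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# small synthetic cohort with one perturbed module in patient 1 only
one_module_spec <- function(seed, n_patients = 3, effect = "flip") {
  cohort_spec(
    n_genes = 60, n_controls = 5, n_patients = n_patients,
    modules = list(list(name = "fibrosis", size = 12, rho = 0.9)),
    perturbations = c(list(list(list(module = "fibrosis", effect = effect))),
                      rep(list(list()), n_patients - 1)),
    noncoding_frac = 0, seed = seed)
}
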