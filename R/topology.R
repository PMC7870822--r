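as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Topology summary of one network
#'
#' Density `2E / (V (V - 1))`; diameter = largest finite shortest-path
#' distance; characteristic path length = mean shortest-path distance over
#' connected ordered pairs (self-pairs excluded, disconnected pairs ignored,
#' flagged when the network has more than one component); heterogeneity =
#' sqrt(population variance of the degree sequence) / mean degree. An empty
#' network returns all metrics as `NA`.
#'
#' @param net A [build_reticulotype()] network.
#' @return One-row data frame: `patient_id`, `n_nodes`, `n_edges`, `density`,
#'   `diameter`, `characteristic_path_length`, `heterogeneity`,
#'   `n_components`, `path_metrics_partial`.
#' @export
network_topology <- function(net) {
  if (nrow(net$edges) == 0L) {
    return(data.frame(patient_id = net$patient_id, n_nodes = 0L,
                      n_edges = 0L, density = NA_real_, diameter = NA_real_,
                      characteristic_path_length = NA_real_,
                      heterogeneity = NA_real_, n_components = 0L,
                      path_metrics_partial = NA, stringsAsFactors = FALSE))
  }
  g <- as_igraph(net)
  nv <- igraph::vcount(g)
  ne <- igraph::ecount(g)
  d <- igraph::distances(g)
  finite <- d[upper.tri(d)][is.finite(d[upper.tri(d)])]
  deg <- igraph::degree(g)
  het <- sqrt(mean(deg^2) - mean(deg)^2) / mean(deg)
  comps <- igraph::components(g)$no
  data.frame(
    patient_id = net$patient_id, n_nodes = nv, n_edges = ne,
    density = 2 * ne / (nv * (nv - 1)),
    diameter = max(finite),
    characteristic_path_length = mean(finite),
    heterogeneity = het,
    n_components = comps,
    path_metrics_partial = comps > 1L,
    stringsAsFactors = FALSE
  )
}

#' Topology table for a cohort
#'
#' @param cohort List of networks.
#' @return Data frame, one [network_topology()] row per network.
#' @export
topology_table <- function(cohort) {
  do.call(rbind, lapply(cohort, network_topology))
}

#' Overlap coefficient between two sets
#'
#' `O(A, B) = |A ∩ B| / min(|A|, |B|)`: the size of the intersection
#' divided by the size of the smaller set. 1 = full overlap, 0 = no overlap.
#'
#' @param A,B Nonempty vectors treated as sets.
#' @return Numeric in `[0, 1]`.
#' @export
overlap_coefficient <- function(A, B) {
  A <- unique(A)
  B <- unique(B)
  if (length(A) == 0L || length(B) == 0L) {
    stop_rtc("overlap coefficient undefined for empty sets")
  }
  length(intersect(A, B)) / min(length(A), length(B))
}

net_sets <- function(cohort, mode) {
  if (mode == "node") {
    lapply(cohort, function(n) n$nodes)
  } else {
    lapply(cohort, function(n) {
      if (nrow(n$edges) == 0L) character(0) else pair_key(n$edges$a, n$edges$b)
    })
  }
}

#' Pairwise node or edge overlap between networks
#'
#' Applies [overlap_coefficient()] to node sets or canonical edge sets for
#' every pair of networks. With a second cohort a rectangular matrix is
#' returned (rows = first cohort, columns = second). Networks empty in the
#' requested mode yield `NA` rows/columns.
#'
#' @param cohort List of networks (>= 2 unless `cohort2` is given).
#' @param mode `"node"` or `"edge"`.
#' @param cohort2 Optional second cohort for cross-cohort overlap.
#' @return Numeric matrix with patient ids as dimnames; symmetric with unit
#'   diagonal in the single-cohort case.
#' @export
pairwise_overlap <- function(cohort, mode = c("node", "edge"),
                             cohort2 = NULL) {
  mode <- match.arg(mode)
  sets1 <- net_sets(cohort, mode)
  ids1 <- vapply(cohort, function(n) n$patient_id, character(1))
  sets2 <- if (is.null(cohort2)) sets1 else net_sets(cohort2, mode)
  ids2 <- if (is.null(cohort2)) ids1 else
    vapply(cohort2, function(n) n$patient_id, character(1))
  if (is.null(cohort2) && length(cohort) < 2L) {
    stop_rtc("need >= 2 networks for pairwise overlap")
  }
  empty1 <- lengths(sets1) == 0L
  empty2 <- lengths(sets2) == 0L
  if (any(empty1) || any(empty2)) {
    message("network(s) empty in ", mode, " mode: overlap set to NA")
  }
  out <- matrix(NA_real_, length(sets1), length(sets2),
                dimnames = list(ids1, ids2))
  for (i in seq_along(sets1)) {
    for (j in seq_along(sets2)) {
      if (!empty1[i] && !empty2[j]) {
        out[i, j] <- overlap_coefficient(sets1[[i]], sets2[[j]])
      }
    }
  }
  out
}

#' Edges unique to each patient network
#'
#' @param cohort List of >= 2 networks.
#' @return Named list (by patient id) of data frames `a`, `b`: the edges
#'   present in that patient's network and absent from every other network.
#' @export
unique_edges <- function(cohort) {
  if (length(cohort) < 2L) stop_rtc("need >= 2 networks")
  keys <- net_sets(cohort, "edge")
  ids <- vapply(cohort, function(n) n$patient_id, character(1))
  tab <- table(unlist(keys))
  singletons <- names(tab)[tab == 1L]
  out <- lapply(keys, function(k) key_to_pairs(sort(intersect(k, singletons))))
  stats::setNames(out, ids)
}

#' Unique edges touching a feature gene set
#'
#' Counts, per patient, the unique edges (see [unique_edges()]) with at least
#' one endpoint in a named gene set -- e.g. "unique fibrosis edges", used as a
#' per-patient fibrosis-burden proxy.
#'
#' @param cohort List of >= 2 networks.
#' @param feature_set Nonempty character vector of gene ids.
#' @param feature_set_name Label recorded in the report.
#' @return Data frame: `patient_id`, `n_unique_edges`,
#'   `n_unique_feature_edges`, `feature_set_name`.
#' @export
unique_feature_edges <- function(cohort, feature_set,
                                 feature_set_name = "feature") {
  if (length(feature_set) == 0L) stop_rtc("feature_set must be nonempty")
  ue <- unique_edges(cohort)
  rows <- lapply(names(ue), function(id) {
    e <- ue[[id]]
    data.frame(patient_id = id, n_unique_edges = nrow(e),
               n_unique_feature_edges =
                 sum(e$a %in% feature_set | e$b %in% feature_set),
               feature_set_name = feature_set_name,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Grubbs test for a single outlier
#'
#' Two-sided, single-outlier Grubbs test: `G = max |x - mean| / sd` (sample
#' sd), compared against the t-distribution critical value
#' `((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(alpha / (2n), n - 2)` (upper tail). One outlier per test, no
#' iteration. A constant vector yields no outlier.
#'
#' @param values Numeric vector of length >= 3.
#' @param alpha Significance level (default 0.05).
#' @return List: `index` (index of the flagged value, or `NA`), `G`,
#'   `critical`, `p` (two-sided), `outlier` (logical).
#' @export
grubbs_test <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3L) stop_rtc("Grubbs test requires >= 3 values")
  s <- stats::sd(values)
  if (s == 0) {
    message("constant values: no outlier")
    return(list(index = NA_integer_, G = NA_real_, critical = NA_real_,
                p = NA_real_, outlier = FALSE))
  }
  dev <- abs(values - mean(values))
  G <- max(dev) / s
  tcrit <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  critical <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
  denom <- (n - 1)^2 - n * G^2
  p <- if (denom <= 0) 0 else {
    tg <- sqrt(n * (n - 2) * G^2 / denom)
    min(1, 2 * n * stats::pt(tg, df = n - 2, lower.tail = FALSE))
  }
  list(index = if (G > critical) which.max(dev) else NA_integer_,
       G = G, critical = critical, p = p, outlier = G > critical)
}
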