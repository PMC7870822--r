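#' Fit the reference correlation model
#'
#' Computes the all-pairs Pearson correlation matrix over the control cohort.
#' This fixed reference is perturbed one patient at a time by [perturb()].
#' Genes with zero variance across controls are flagged invalid for all their
#' pairs (an undefined correlation must not silently become 0).
#'
#' @param controls Numeric matrix (genes x control samples), typically the
#'   control columns of [normalize_counts()] output. At least 3 samples and
#'   2 genes are required; fewer than 3 reference samples leaves the
#'   correlation change statistic undefined.
#' @return An object of class `ref_corr_model`: list with `gene_ids`,
#'   `n_reference`, `r` (correlation matrix, `NA` where invalid),
#'   `valid_gene` (logical), and `controls` (the input matrix, retained so
#'   perturbed correlations can be recomputed).
#' @export
fit_reference <- function(controls) {
  if (!is.matrix(controls)) stop_rtc("controls must be a matrix")
  if (ncol(controls) < 3L) stop_rtc("need >= 3 control samples to fit the reference")
  if (nrow(controls) < 2L) stop_rtc("need >= 2 genes")
  if (is.null(rownames(controls))) stop_rtc("controls must have gene row names")
  valid <- apply(controls, 1, stats::sd) > 0
  r <- suppressWarnings(stats::cor(t(controls)))
  r[!valid, ] <- NA_real_
  r[, !valid] <- NA_real_
  diag(r) <- ifelse(valid, 1, NA_real_)
  structure(
    list(gene_ids = rownames(controls), n_reference = ncol(controls),
         r = r, valid_gene = valid, controls = controls),
    class = "ref_corr_model"
  )
}

#' @export
print.ref_corr_model <- function(x, ...) {
  m <- length(x$gene_ids)
  cat("ref_corr_model:", m, "genes,", x$n_reference, "reference samples,",
      format(count_pairs(m), big.mark = ","), "gene pairs\n")
  invisible(x)
}

#' Number of distinct unordered gene pairs
#'
#' @param m Number of genes (>= 2).
#' @return `m * (m - 1) / 2`.
#' @export
count_pairs <- function(m) {
  if (length(m) != 1L || is.na(m) || m < 2 || m != round(m)) {
    stop_rtc("m must be a single integer >= 2")
  }
  m <- as.numeric(m)
  m * (m - 1) / 2
}

#' Correlation-perturbation Z statistic
#'
#' The sample-specific-network statistic for the change in a Pearson
#' correlation when one sample is added to a reference of n samples:
#' `z = (r_prime - r) / sigma` with `sigma = (1 - r^2) / (n - 1)`, compared
#' against the standard normal (two-sided). For example, r = 0, n = 5,
#' r' = 0.9 gives z = 3.6.
#'
#' @param r Reference correlation(s).
#' @param r_prime Correlation(s) after adding the sample.
#' @param n Number of reference samples.
#' @return Data frame with `delta`, `z`, `p`. Where `|r| = 1` (sigma 0),
#'   `z` is 0 for zero delta and signed `Inf` otherwise.
#' @export
delta_pcc_z <- function(r, r_prime, n) {
  delta <- r_prime - r
  sigma <- (1 - r^2) / (n - 1)
  z <- ifelse(sigma == 0,
              ifelse(delta == 0, 0, sign(delta) * Inf),
              delta / sigma)
  data.frame(delta = delta, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Test correlation perturbation by one patient profile
#'
#' Adds a single patient's profile to the reference matrix, recomputes each
#' pair's Pearson correlation r' over the n+1 samples, and tests the change
#' `delta = r' - r` with the sample-specific-network Z statistic
#' `z = delta / ((1 - r^2) / (n - 1))` (n = number of reference samples),
#' two-sided normal p, and Bonferroni adjustment over the tested family.
#'
#' @param model A [fit_reference()] model.
#' @param patient_profile Numeric vector on the same scale as the reference
#'   matrix, named by (or aligned with) the model's gene ids.
#' @param alpha Significance level applied to the Bonferroni-adjusted p
#'   (default 0.05).
#' @param family `"tested_pairs"` tests every valid gene pair (the default;
#'   test first, map to the interactome second). `"interactome_pairs"`
#'   restricts testing to interactome edges for tractability; the Bonferroni
#'   family is then the number of interactome pairs actually tested.
#' @param interactome An [interactome()]; required for
#'   `family = "interactome_pairs"`.
#' @return Data frame of perturbation records for tested pairs only:
#'   `gene_a`, `gene_b`, `r`, `r_prime`, `delta`, `z`, `p`, `p_adjusted`,
#'   `significant`. Pairs with `|r| = 1` and nonzero delta get `z = +/-Inf`,
#'   `p = 0` (logged).
#' @export
perturb <- function(model, patient_profile, alpha = 0.05,
                    family = c("tested_pairs", "interactome_pairs"),
                    interactome = NULL) {
  family <- match.arg(family)
  if (alpha <= 0 || alpha >= 1) stop_rtc("alpha must be in (0, 1)")
  ids <- model$gene_ids
  if (!is.null(names(patient_profile))) {
    if (!setequal(names(patient_profile), ids)) {
      stop_rtc("patient profile gene ids do not match the reference model")
    }
    patient_profile <- patient_profile[ids]
  } else if (length(patient_profile) != length(ids)) {
    stop_rtc("patient profile length does not match the reference model")
  }
  aug <- cbind(model$controls, patient_profile)
  r1 <- suppressWarnings(stats::cor(t(aug)))
  valid <- model$valid_gene

  if (family == "tested_pairs") {
    idx <- which(upper.tri(model$r), arr.ind = TRUE)
    keep <- valid[idx[, 1]] & valid[idx[, 2]]
    idx <- idx[keep, , drop = FALSE]
    ga <- ids[idx[, 1]]
    gb <- ids[idx[, 2]]
  } else {
    if (is.null(interactome)) {
      stop_rtc("interactome required for family = 'interactome_pairs'")
    }
    ed <- interactome$edges
    keep <- ed$a %in% ids & ed$b %in% ids
    ed <- ed[keep, , drop = FALSE]
    ia <- match(ed$a, ids)
    ib <- match(ed$b, ids)
    ok <- valid[ia] & valid[ib]
    idx <- cbind(ia[ok], ib[ok])
    ga <- ed$a[ok]
    gb <- ed$b[ok]
  }
  if (nrow(idx) == 0L) stop_rtc("no valid gene pairs to test")

  r0 <- model$r[idx]
  rp <- r1[idx]
  n <- model$n_reference
  st <- delta_pcc_z(r0, rp, n)
  delta <- st$delta
  z <- st$z
  p <- st$p
  n_degenerate <- sum(abs(r0) == 1 & delta != 0)
  if (n_degenerate > 0) {
    message(n_degenerate,
            " pair(s) with |r| = 1 and nonzero delta: z set to signed Inf")
  }
  fam_size <- length(p)
  p_adj <- pmin(1, p * fam_size)
  pr <- canonicalize_pairs(ga, gb)
  out <- data.frame(
    gene_a = pr$a, gene_b = pr$b, r = r0, r_prime = rp, delta = delta,
    z = z, p = p, p_adjusted = p_adj, significant = p_adj < alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "family") <- family
  attr(out, "family_size") <- fam_size
  attr(out, "alpha") <- alpha
  out
}

#' Build one patient's reticulotype
#'
#' Intersects the significant perturbation records with the interactome:
#' edges are significant gene pairs that are also physical protein-protein
#' interactions; nodes are the endpoints of retained edges (no isolated
#' nodes). Per-edge provenance (r, r', z, p) is attached so downstream
#' modules never recompute.
#'
#' @param records Perturbation records from [perturb()].
#' @param interactome An [interactome()].
#' @param patient_id Identifier for the patient.
#' @return An object of class `reticulotype`: list with `patient_id`,
#'   `nodes`, `edges` (data frame `a`, `b`), `records` (records for retained
#'   edges), `params`.
#' @export
build_reticulotype <- function(records, interactome, patient_id) {
  sig <- records[records$significant, , drop = FALSE]
  keys <- pair_key(sig$gene_a, sig$gene_b)
  hit <- keys %in% edge_keys(interactome)
  sig <- sig[hit, , drop = FALSE]
  edges <- data.frame(a = sig$gene_a, b = sig$gene_b,
                      stringsAsFactors = FALSE, row.names = NULL)
  if (nrow(edges) == 0L) {
    message("patient ", patient_id,
            ": no significant pair maps to the interactome (empty network)")
  }
  structure(
    list(patient_id = patient_id,
         nodes = sort(unique(c(edges$a, edges$b))),
         edges = edges,
         records = sig,
         params = list(alpha = attr(records, "alpha"),
                       family = attr(records, "family"),
                       family_size = attr(records, "family_size"))),
    class = "reticulotype"
  )
}

#' @export
print.reticulotype <- function(x, ...) {
  cat("reticulotype '", x$patient_id, "': ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Build reticulotypes for a whole cohort
#'
#' Applies the gene filters, normalizes, fits the reference correlation model
#' once on the control columns, then perturbs it with each patient profile in
#' turn (the patient is removed between iterations; the reference is never
#' refitted). Deterministic given the configuration.
#'
#' @param m An [expression_matrix()] with control and patient groups.
#' @param interactome An [interactome()].
#' @param config Named list of options: `filter_mode` ("any_sample"),
#'   `min_count` (10), `protein_coding_only` (TRUE), `normalization`
#'   ("log2_cpm"), `alpha` (0.05), `family` ("tested_pairs").
#' @return Named list of [build_reticulotype()] networks, one per patient
#'   sample.
#' @export
run_cohort <- function(m, interactome, config = list()) {
  cfg <- utils::modifyList(
    list(filter_mode = "any_sample", min_count = 10,
         protein_coding_only = TRUE, normalization = "log2_cpm",
         alpha = 0.05, family = "tested_pairs"),
    config
  )
  n_raw <- length(m$gene_ids)
  m <- filter_genes(m, mode = cfg$filter_mode, min_count = cfg$min_count)
  n_filtered <- length(m$gene_ids)
  if (isTRUE(cfg$protein_coding_only)) m <- restrict_protein_coding(m)
  n_coding <- length(m$gene_ids)
  message("gene funnel: ", n_raw, " raw -> ", n_filtered,
          " after count filter -> ", n_coding, " protein-coding")
  message("interactome coverage of filtered genes: ",
          round(interactome_coverage(interactome, m$gene_ids), 3))
  x <- normalize_counts(m, method = cfg$normalization)
  ctrl <- control_columns(m)
  pats <- which(!is.na(m$group) & m$group == "patient")
  model <- fit_reference(x[, ctrl, drop = FALSE])
  nets <- lapply(pats, function(j) {
    rec <- perturb(model, x[, j], alpha = cfg$alpha, family = cfg$family,
                   interactome = interactome)
    net <- build_reticulotype(rec, interactome, m$sample_ids[j])
    net$params <- c(net$params,
                    list(normalization = cfg$normalization,
                         n_reference = model$n_reference,
                         n_genes = length(model$gene_ids)))
    message("patient ", m$sample_ids[j], ": family_size=",
            net$params$family_size, " nodes=", length(net$nodes),
            " edges=", nrow(net$edges))
    net
  })
  stats::setNames(nets, m$sample_ids[pats])
}
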