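#' Specify a synthetic cohort
#'
#' Full parameterization of a generated cohort with known ground truth. The
#' count model is a negative-binomial observation layer over a latent
#' Gaussian factor model: genes in a module share a per-sample latent factor
#' with loading `sqrt(rho)`, giving pairwise latent correlation `rho`;
#' biological spread on the log scale is `tau`. A patient perturbation either
#' decouples a module (all loadings 0: every within-module pair loses its
#' correlation) or flips it (the loading of alternate module genes is
#' negated, so pairs spanning the two sign groups flip latent correlation
#' `rho -> -rho`; same-sign pairs are untouched).
#'
#' @param n_genes Total number of genes.
#' @param n_controls Number of control samples (default 5, the small-n regime
#'   the perturbation statistic is used in).
#' @param n_patients Number of patient samples.
#' @param modules List of `list(name, size, rho)`: disjoint gene modules with
#'   within-module latent correlation `rho` in `[0, 1)`.
#' @param perturbations List of length `n_patients`; each element a list of
#'   `list(module, effect)` with effect `"decouple"` or `"flip"` (may be
#'   empty for a null patient).
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`; default 0.1).
#' @param log_mean_range Range of per-gene baseline log mean counts (default
#'   `log(100)` to `log(2000)`: the moderately-to-highly expressed genes that
#'   dominate co-expression structure).
#' @param tau Biological standard deviation on the natural-log scale
#'   (default 1.0; large enough that the declared latent module correlation
#'   survives the count-level observation noise, and implying a latent CV
#'   near 130 percent, within the range reported for heterogeneous disease
#'   cohorts).
#' @param ppi_fraction Fraction of within-module gene pairs included as
#'   interactome edges (default 0.5).
#' @param background_prob Erdos-Renyi probability for background interactome
#'   edges among remaining pairs (default 0.0016, matching the density of a
#'   consolidated human interactome of ~15k proteins and ~190k interactions).
#' @param noncoding_frac Fraction of non-module genes labeled as non-coding
#'   (default 0.1), exercising the protein-coding filter.
#' @param clinical List `variable`, `intercept`, `slope`, `noise_sd`: the
#'   clinical variable is `intercept + slope * burden + noise`, where burden
#'   is the patient's number of planted perturbed pairs covered by the
#'   interactome.
#' @param seed Integer seed; all randomness flows from it via one stream.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_genes, n_controls = 5, n_patients,
                        modules = list(), perturbations = NULL,
                        dispersion = 0.1,
                        log_mean_range = c(log(100), log(2000)),
                        tau = 1.0, ppi_fraction = 0.5,
                        background_prob = 0.0016, noncoding_frac = 0.1,
                        clinical = list(variable = "CO", intercept = 6,
                                        slope = -0.04, noise_sd = 0.5),
                        seed = 1) {
  perturbations <- perturbations %||% rep(list(list()), n_patients)
  if (length(perturbations) != n_patients) {
    stop_rtc("need one perturbation list per patient")
  }
  modules <- lapply(modules, function(m) {
    m$size <- m$size %||% length(m$genes)
    m
  })
  sizes <- vapply(modules, function(m) m$size, numeric(1))
  if (any(sizes < 2)) stop_rtc("modules need >= 2 genes")
  if (sum(sizes) > n_genes) stop_rtc("module gene counts exceed n_genes")
  rhos <- vapply(modules, function(m) m$rho, numeric(1))
  if (any(rhos < 0 | rhos >= 1)) stop_rtc("module rho must be in [0, 1)")
  nms <- vapply(modules, function(m) m$name, character(1))
  if (anyDuplicated(nms)) stop_rtc("duplicate module name")
  for (p in perturbations) {
    for (pe in p) {
      if (!pe$module %in% nms) stop_rtc("unknown module in perturbation: ", pe$module)
      if (!pe$effect %in% c("decouple", "flip")) {
        stop_rtc("unknown perturbation effect: ", pe$effect)
      }
    }
  }
  if (ppi_fraction < 0 || ppi_fraction > 1 ||
      background_prob < 0 || background_prob > 1 ||
      noncoding_frac < 0 || noncoding_frac > 1) {
    stop_rtc("fractions and probabilities must be in [0, 1]")
  }
  if (n_controls < 3) stop_rtc("n_controls must be >= 3")
  structure(
    list(n_genes = n_genes, n_controls = n_controls, n_patients = n_patients,
         modules = modules, perturbations = perturbations,
         dispersion = dispersion, log_mean_range = log_mean_range, tau = tau,
         ppi_fraction = ppi_fraction, background_prob = background_prob,
         noncoding_frac = noncoding_frac, clinical = clinical,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Module membership: a module may name its genes explicitly (indices into
# the gene pool), letting two cohort specs wire the same genes into different
# module partitions; otherwise consecutive blocks are assigned.
module_gene_ids <- function(spec) {
  ids <- sprintf("G%04d", seq_len(spec$n_genes))
  taken <- integer(0)
  members <- vector("list", length(spec$modules))
  for (k in seq_along(spec$modules)) {
    m <- spec$modules[[k]]
    if (!is.null(m$genes)) {
      gi <- as.integer(m$genes)
      if (any(gi < 1 | gi > spec$n_genes)) stop_rtc("module gene index out of range")
      members[[k]] <- ids[gi]
      taken <- c(taken, gi)
    } else {
      free <- setdiff(seq_len(spec$n_genes), taken)
      if (length(free) < m$size) stop_rtc("module gene counts exceed n_genes")
      gi <- free[seq_len(m$size)]
      members[[k]] <- ids[gi]
      taken <- c(taken, gi)
    }
  }
  if (anyDuplicated(taken)) stop_rtc("modules share genes")
  names(members) <- vapply(spec$modules, function(m) m$name, character(1))
  list(ids = ids, members = members)
}

# Alternating sign assignment used by the "flip" effect: odd positions keep
# their loading, even positions are negated in the perturbed sample.
flip_signs <- function(size) rep_len(c(1, -1), size)

# standard normal conditioned on |f| >= lo, symmetric in sign
truncated_normal_tail <- function(lo) {
  u <- stats::runif(1, stats::pnorm(lo), 1)
  stats::qnorm(u) * sample(c(-1, 1), 1)
}

planted_pairs <- function(spec, members) {
  lapply(spec$perturbations, function(p) {
    keys <- character(0)
    for (pe in p) {
      g <- members[[pe$module]]
      if (pe$effect == "decouple") {
        cmb <- utils::combn(g, 2)
        keys <- c(keys, pair_key(cmb[1, ], cmb[2, ]))
      } else {
        s <- flip_signs(length(g))
        pos <- g[s > 0]
        neg <- g[s < 0]
        cross <- expand.grid(a = pos, b = neg, stringsAsFactors = FALSE)
        keys <- c(keys, pair_key(cross$a, cross$b))
      }
    }
    sort(unique(keys))
  })
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws control and patient count profiles from the spec's latent-factor
#' negative-binomial model, an interactome covering the declared fraction of
#' within-module pairs plus random background, a gene-set catalog naming the
#' modules, and a clinical table that is a noisy linear function of each
#' patient's planted perturbation burden. Fully reproducible from the seed.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `synthetic_cohort`: list with `expression`
#'   ([expression_matrix()]), `interactome`, `catalog`, `clinical`, `truth`
#'   (per-patient perturbed pair keys, module membership, clinical
#'   parameters), and `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  mg <- module_gene_ids(spec)
  ids <- mg$ids
  members <- mg$members
  n <- spec$n_genes
  in_module <- ids %in% unlist(members)

  baseline <- stats::runif(n, spec$log_mean_range[1], spec$log_mean_range[2])
  biotype <- rep("protein_coding", n)
  bg_idx <- which(!in_module)
  n_nc <- round(spec$noncoding_frac * length(bg_idx))
  if (n_nc > 0) biotype[sample(bg_idx, n_nc)] <- "lincRNA"
  names(biotype) <- ids

  rho_of <- stats::setNames(vapply(spec$modules, function(m) m$rho, numeric(1)),
                            names(members))

  draw_sample <- function(effects) {
    z <- stats::rnorm(n)
    for (nm in names(members)) {
      gi <- match(members[[nm]], ids)
      eff <- effects[nm] %||% "none"
      if (is.na(eff)) eff <- "none"
      if (eff == "decouple") next  # pure idiosyncratic noise, unit variance
      rho <- rho_of[[nm]]
      # a flipped module factor is drawn conditional on the program being
      # active (|f| >= 1): otherwise the planted rewiring would be absent
      # from the sample and the truth labels vacuous
      f <- if (eff == "flip") {
        truncated_normal_tail(1)
      } else {
        stats::rnorm(1)
      }
      s <- if (eff == "flip") flip_signs(length(gi)) else rep(1, length(gi))
      z[gi] <- s * sqrt(rho) * f + sqrt(1 - rho) * z[gi]
    }
    mu <- exp(baseline + spec$tau * z)
    stats::rnbinom(n, mu = mu, size = 1 / spec$dispersion)
  }

  sample_ids <- c(sprintf("C%d", seq_len(spec$n_controls)),
                  sprintf("P%d", seq_len(spec$n_patients)))
  group <- c(rep("control", spec$n_controls), rep("patient", spec$n_patients))
  counts <- matrix(0, n, length(sample_ids), dimnames = list(ids, sample_ids))
  for (j in seq_len(spec$n_controls)) counts[, j] <- draw_sample(c(none = "none"))
  for (k in seq_len(spec$n_patients)) {
    p <- spec$perturbations[[k]]
    effects <- stats::setNames(vapply(p, function(pe) pe$effect, character(1)),
                               vapply(p, function(pe) pe$module, character(1)))
    counts[, spec$n_controls + k] <- draw_sample(effects)
  }
  expr <- expression_matrix(counts, biotype = biotype, group = group)

  # interactome: declared fraction of within-module pairs + ER background
  mod_keys <- unlist(lapply(members, function(g) {
    cmb <- utils::combn(g, 2)
    pair_key(cmb[1, ], cmb[2, ])
  }), use.names = FALSE)
  n_keep <- round(spec$ppi_fraction * length(mod_keys))
  kept_mod <- if (n_keep > 0) sort(sample(mod_keys, n_keep)) else character(0)
  cmb_all <- utils::combn(ids, 2)
  all_keys <- pair_key(cmb_all[1, ], cmb_all[2, ])
  bg_pool <- setdiff(all_keys, mod_keys)
  bg_keep <- bg_pool[stats::runif(length(bg_pool)) < spec$background_prob]
  edge_df <- key_to_pairs(sort(c(kept_mod, bg_keep)))
  edge_df$sources <- "synthetic"
  inter <- interactome(edge_df)

  catalog <- gene_set_catalog(members, source = "synthetic_modules")

  planted <- planted_pairs(spec, members)
  names(planted) <- sprintf("P%d", seq_len(spec$n_patients))
  burden <- vapply(planted, function(k) length(intersect(k, edge_keys(inter))),
                   numeric(1))
  cl <- spec$clinical
  clin_val <- cl$intercept + cl$slope * burden +
    stats::rnorm(spec$n_patients, 0, cl$noise_sd)
  clinical <- data.frame(patient_id = names(planted), stringsAsFactors = FALSE)
  clinical[[cl$variable]] <- clin_val

  membership <- rep(NA_character_, n)
  names(membership) <- ids
  for (nm in names(members)) membership[members[[nm]]] <- nm

  structure(
    list(expression = expr, interactome = inter, catalog = catalog,
         clinical = clinical,
         truth = list(perturbed_pairs = planted,
                      module_membership = membership,
                      planted_burden = burden,
                      clinical_params = cl),
         spec = spec),
    class = "synthetic_cohort"
  )
}

#' Recall and precision against planted ground truth
#'
#' For each patient network: recall is the fraction of planted,
#' interactome-covered pairs recovered as edges; precision is the fraction of
#' network edges that are planted pairs. An empty network has undefined
#' precision (`NA`); a patient with no covered planted pairs has undefined
#' recall.
#'
#' @param networks Named list of networks built from the generated cohort.
#' @param truth The `truth` element of a [simulate_cohort()] result.
#' @param interactome The cohort's interactome.
#' @return Data frame: `patient_id`, `recall`, `precision`,
#'   `n_planted_covered`, `n_edges`.
#' @export
truth_recall <- function(networks, truth, interactome) {
  ik <- edge_keys(interactome)
  rows <- lapply(networks, function(net) {
    id <- net$patient_id
    if (!id %in% names(truth$perturbed_pairs)) {
      stop_rtc("patient absent from truth: ", id)
    }
    planted <- truth$perturbed_pairs[[id]]
    covered <- intersect(planted, ik)
    ek <- if (nrow(net$edges) == 0L) character(0) else
      pair_key(net$edges$a, net$edges$b)
    data.frame(
      patient_id = id,
      recall = if (length(covered) == 0L) NA_real_ else
        length(intersect(ek, covered)) / length(covered),
      precision = if (length(ek) == 0L) NA_real_ else
        length(intersect(ek, planted)) / length(ek),
      n_planted_covered = length(covered),
      n_edges = length(ek),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
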