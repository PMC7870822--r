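# End-to-end orchestration: simulate -> build -> analyze, driven by a single
# YAML configuration. Outputs are deterministic given config + seed; the run
# log records the gene funnel, family sizes, and per-patient network sizes.

#' Read and validate a pipeline run configuration
#'
#' @param path Path to a YAML configuration file. Top-level keys: `seed`,
#'   `outdir`, `paths` (counts, biotypes, interactome, gene_sets, clinical,
#'   samples), `samples` (`controls`: character vector), `simulate` (a
#'   [cohort_spec()] parameterization), `build` (filter_mode, min_count,
#'   protein_coding_only, normalization, alpha, family), `analyze`
#'   (feature_set, q_threshold, association: variables, method).
#' @return The configuration list, with the file's MD5 checksum attached as
#'   attribute `"md5"` (embedded in every output).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_rtc("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  alpha <- cfg$build$alpha %||% 0.05
  if (alpha <= 0 || alpha >= 1) stop_rtc("alpha must be in (0, 1)")
  attr(cfg, "md5") <- unname(tools::md5sum(path))
  cfg
}

config_hash <- function(config) {
  h <- attr(config, "md5")
  if (!is.null(h)) return(h)
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

write_output_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_md5: ", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# run `expr` while teeing message() output into a log file
with_run_log <- function(log_path, expr) {
  log <- character(0)
  res <- withCallingHandlers(expr, message = function(m) {
    log <<- c(log, sub("\n$", "", conditionMessage(m)))
    invokeRestart("muffleMessage")
  })
  writeLines(c(paste("#", format(Sys.time())), log), log_path)
  res
}

spec_from_config <- function(config) {
  sc <- config$simulate
  if (is.null(sc)) stop_rtc("config has no 'simulate' section")
  mods <- lapply(sc$modules, function(m) {
    list(name = m$name, size = m$size, rho = m$rho, genes = m$genes)
  })
  perts <- lapply(sc$perturbations %||% rep(list(list()), sc$n_patients),
                  function(p) lapply(p, function(pe) {
                    list(module = pe$module, effect = pe$effect)
                  }))
  cohort_spec(
    n_genes = sc$n_genes, n_controls = sc$n_controls %||% 5,
    n_patients = sc$n_patients, modules = mods, perturbations = perts,
    dispersion = sc$dispersion %||% 0.1,
    log_mean_range = sc$log_mean_range %||% c(log(100), log(2000)),
    tau = sc$tau %||% 1.0, ppi_fraction = sc$ppi_fraction %||% 0.5,
    background_prob = sc$background_prob %||% 0.0016,
    noncoding_frac = sc$noncoding_frac %||% 0.1,
    clinical = sc$clinical %||% list(variable = "CO", intercept = 6,
                                     slope = -0.04, noise_sd = 0.5),
    seed = config$seed %||% 1
  )
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Writes `counts.tsv`, `biotypes.tsv`, `samples.tsv`, `interactome.tsv`,
#' `gene_sets.gmt`, `clinical.csv`, and `truth.json` under `dir`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- cohort$expression
  counts <- data.frame(gene_id = m$gene_ids, m$counts, check.names = FALSE,
                       stringsAsFactors = FALSE)
  utils::write.table(counts, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = m$gene_ids, biotype = m$biotype),
    file.path(dir, "biotypes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = m$sample_ids, group = m$group),
    file.path(dir, "samples.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_interactome(cohort$interactome, file.path(dir, "interactome.tsv"))
  write_gmt(cohort$catalog, file.path(dir, "gene_sets.gmt"))
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(perturbed_pairs = cohort$truth$perturbed_pairs,
         module_membership = as.list(cohort$truth$module_membership),
         planted_burden = as.list(cohort$truth$planted_burden),
         clinical_params = cohort$truth$clinical_params),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Generate the configured synthetic cohort on disk
#'
#' Validates the spec before any sampling or writing, so an invalid spec
#' leaves no partial files.
#'
#' @param config A pipeline configuration (see [read_run_config()]).
#' @return The cohort, invisibly.
#' @export
run_simulate <- function(config) {
  spec <- spec_from_config(config)
  cohort <- simulate_cohort(spec)
  outdir <- config$outdir %||% "."
  write_cohort(cohort, file.path(outdir, "cohort"))
  invisible(cohort)
}

resolve_groups <- function(config, counts_path, sample_ids) {
  ctrl <- config$samples$controls
  if (is.null(ctrl)) {
    samples_path <- config$paths$samples %||%
      file.path(dirname(counts_path), "samples.tsv")
    if (!file.exists(samples_path)) {
      stop_rtc("no control sample assignment: set samples.controls or provide ",
               samples_path)
    }
    st <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
    return(stats::setNames(st$group, st$sample_id)[sample_ids])
  }
  ifelse(sample_ids %in% ctrl, "control", "patient")
}

#' Build all patient networks from the configured inputs
#'
#' Executes expression filtering, interactome consolidation, and network
#' construction; writes one edge-list TSV and one JSON summary per patient
#' under `<outdir>/networks/`, plus `build_log.txt` recording the gene
#' funnel, interactome coverage, Bonferroni family sizes, and per-patient
#' node/edge counts.
#'
#' @param config A pipeline configuration.
#' @return Named list of networks, invisibly.
#' @export
run_build <- function(config) {
  p <- config$paths
  for (key in c("counts", "interactome")) {
    if (is.null(p[[key]])) stop_rtc("config paths missing: ", key)
  }
  miss <- !file.exists(unlist(p[c("counts", "interactome")]))
  if (any(miss)) {
    stop_rtc("input file not found: ",
             unlist(p[c("counts", "interactome")])[miss][1])
  }
  outdir <- config$outdir %||% "."
  netdir <- file.path(outdir, "networks")
  dir.create(netdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)

  nets <- with_run_log(file.path(outdir, "build_log.txt"), {
    m <- read_counts(p$counts, biotype_map = p$biotypes)
    m$group <- resolve_groups(config, p$counts, m$sample_ids)
    inter <- read_interactome(unlist(p$interactome))
    run_cohort(m, inter, config$build %||% list())
  })
  for (net in nets) {
    utils::write.table(
      net$records, file.path(netdir, paste0(net$patient_id, "_edges.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      c(list(patient_id = net$patient_id, n_nodes = length(net$nodes),
             n_edges = nrow(net$edges), config_md5 = hash), net$params),
      file.path(netdir, paste0(net$patient_id, "_summary.json")),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(nets)
}

read_networks <- function(netdir) {
  files <- sort(list.files(netdir, pattern = "_edges\\.tsv$",
                           full.names = TRUE))
  if (length(files) == 0L) stop_rtc("no network edge files under ", netdir)
  nets <- lapply(files, function(f) {
    pid <- sub("_edges\\.tsv$", "", basename(f))
    rec <- utils::read.delim(f, stringsAsFactors = FALSE,
                             colClasses = c(gene_a = "character",
                                            gene_b = "character"))
    sumf <- file.path(netdir, paste0(pid, "_summary.json"))
    params <- if (file.exists(sumf)) jsonlite::read_json(sumf) else list()
    edges <- data.frame(a = rec$gene_a, b = rec$gene_b,
                        stringsAsFactors = FALSE)
    structure(list(patient_id = pid,
                   nodes = sort(unique(c(edges$a, edges$b))),
                   edges = edges, records = rec, params = params),
              class = "reticulotype")
  })
  stats::setNames(nets, vapply(nets, function(n) n$patient_id, character(1)))
}

#' Analyze built networks: topology, overlap, unique edges, enrichment,
#' clinical association
#'
#' Writes `topology.csv`, `overlap_node.csv`, `overlap_edge.csv`,
#' `unique_edges.csv`, `enrichment.csv`, `enrichment_frequency.csv`, and
#' `association.csv` under the output directory; every file embeds the
#' configuration checksum. Overlap matrices are skipped (with a log note)
#' for a single network; enrichment and association are skipped when the
#' gene-set or clinical inputs are not configured.
#'
#' @param config A pipeline configuration.
#' @param networks Optional networks from [run_build()]; read back from
#'   `<outdir>/networks/` when omitted.
#' @return List of the computed tables, invisibly.
#' @export
run_analyze <- function(config, networks = NULL) {
  outdir <- config$outdir %||% "."
  hash <- config_hash(config)
  p <- config$paths
  acfg <- config$analyze %||% list()
  out <- list()

  with_run_log(file.path(outdir, "analyze_log.txt"), {
    nets <- networks %||% read_networks(file.path(outdir, "networks"))
    out$topology <- topology_table(nets)
    write_output_csv(out$topology, file.path(outdir, "topology.csv"), hash)

    if (length(nets) >= 2L) {
      for (mode in c("node", "edge")) {
        ov <- pairwise_overlap(nets, mode = mode)
        df <- data.frame(patient_id = rownames(ov), ov, check.names = FALSE)
        write_output_csv(df, file.path(outdir, paste0("overlap_", mode,
                                                      ".csv")), hash)
        out[[paste0("overlap_", mode)]] <- ov
      }
    } else {
      message("single network: overlap matrices skipped")
    }

    catalog <- NULL
    if (!is.null(p$gene_sets) && file.exists(p$gene_sets)) {
      catalog <- read_gmt(p$gene_sets)
    }
    feature_name <- acfg$feature_set %||%
      if (!is.null(catalog)) names(catalog$sets)[1] else NULL
    if (length(nets) >= 2L && !is.null(catalog) &&
        feature_name %in% names(catalog$sets)) {
      out$unique_edges <- unique_feature_edges(
        nets, catalog$sets[[feature_name]], feature_name)
      write_output_csv(out$unique_edges,
                       file.path(outdir, "unique_edges.csv"), hash)
    }

    if (!is.null(catalog)) {
      universe <- enrichment_universe(config, nets)
      enr <- enrich_cohort(nets, catalog, universe,
                           q_threshold = acfg$q_threshold %||% 0.05)
      out$enrichment <- enr$per_patient
      write_output_csv(enr$per_patient, file.path(outdir, "enrichment.csv"),
                       hash)
      write_output_csv(enr$frequency,
                       file.path(outdir, "enrichment_frequency.csv"), hash)
    } else {
      message("no gene sets configured: enrichment skipped")
    }

    if (!is.null(p$clinical) && file.exists(p$clinical) &&
        !is.null(out$unique_edges)) {
      clinical <- read_clinical(p$clinical)
      vars <- acfg$association$variables %||%
        setdiff(names(clinical), "patient_id")
      out$association <- association_report(
        out$unique_edges, clinical, vars,
        method = acfg$association$method %||% "pearson")
      write_output_csv(out$association, file.path(outdir, "association.csv"),
                       hash)
    } else {
      message("clinical association skipped (no clinical input or no ",
              "unique-edge report)")
    }
  })
  invisible(out)
}

# default enrichment universe: interactome proteins that survive the
# expression filters; falls back to interactome proteins alone
enrichment_universe <- function(config, nets) {
  p <- config$paths
  inter <- read_interactome(unlist(p$interactome))
  mode <- config$analyze$universe %||% "interactome_expressed"
  if (mode == "interactome_only" || is.null(p$counts) ||
      !file.exists(p$counts)) {
    return(inter$proteins)
  }
  m <- read_counts(p$counts, biotype_map = p$biotypes)
  m$group <- resolve_groups(config, p$counts, m$sample_ids)
  bcfg <- config$build %||% list()
  m <- filter_genes(m, mode = bcfg$filter_mode %||% "any_sample",
                    min_count = bcfg$min_count %||% 10)
  if (isTRUE(bcfg$protein_coding_only %||% TRUE)) {
    m <- restrict_protein_coding(m)
  }
  intersect(inter$proteins, m$gene_ids)
}

#' Run the full pipeline: simulate (if configured), build, analyze
#'
#' @param config A pipeline configuration.
#' @return The analysis tables, invisibly.
#' @export
run_all <- function(config) {
  if (!is.null(config$simulate)) {
    run_simulate(config)
    d <- file.path(config$outdir %||% ".", "cohort")
    config$paths <- utils::modifyList(
      list(counts = file.path(d, "counts.tsv"),
           biotypes = file.path(d, "biotypes.tsv"),
           samples = file.path(d, "samples.tsv"),
           interactome = file.path(d, "interactome.tsv"),
           gene_sets = file.path(d, "gene_sets.gmt"),
           clinical = file.path(d, "clinical.csv")),
      config$paths %||% list())
  }
  nets <- run_build(config)
  run_analyze(config, networks = nets)
}
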