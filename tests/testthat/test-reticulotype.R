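norm_expr <- function(counts, n_ctrl) {
  grp <- c(rep("control", n_ctrl), rep("patient", ncol(counts) - n_ctrl))
  m <- expression_matrix(counts, group = grp)
  normalize_counts(m, "raw")
}

test_that("fit_reference computes pairwise r and flags zero-variance genes", {
  x <- make_counts(rbind(c(1, 2, 3, 4, 5),
                         c(2, 4, 6, 8, 10),
                         c(7, 7, 7, 7, 7),
                         c(5, 1, 4, 2, 8)))
  model <- fit_reference(x)
  expect_equal(model$r["g1", "g2"], 1)
  expect_false(model$valid_gene[["g3"]])
  expect_true(all(is.na(model$r["g3", ])))
  expect_equal(model$n_reference, 5L)
  # 4 genes -> 6 distinct pairs
  expect_equal(count_pairs(length(model$gene_ids)), 6)
  expect_error(fit_reference(x[, 1:2]), "3 control")
})

test_that("count_pairs is m(m-1)/2 and rejects m < 2", {
  expect_equal(count_pairs(2), 1)
  expect_equal(count_pairs(3), 3)
  expect_equal(count_pairs(100), 4950)
  expect_error(count_pairs(1), ">= 2")
})

test_that("the perturbation statistic matches its worked example", {
  st <- delta_pcc_z(r = 0, r_prime = 0.9, n = 5)
  expect_equal(st$z, 3.6)
  # two-sided normal tail at 3.6 (frozen from 2 * (1 - pnorm(3.6)))
  expect_equal(st$p, 3.1821718e-04, tolerance = 1e-6)
  # null case: r' = r
  null <- delta_pcc_z(0.4, 0.4, 5)
  expect_equal(null$z, 0)
  expect_equal(null$p, 1)
  # degenerate |r| = 1 with nonzero delta
  dg <- delta_pcc_z(1, 0.5, 5)
  expect_equal(dg$z, -Inf)
  expect_equal(dg$p, 0)
})

test_that("perturb records match brute-force recomputation to 1e-12", {
  set.seed(101)
  for (rep in 1:40) {
    n_genes <- sample(3:6, 1)
    n_ctrl <- sample(3:7, 1)
    x <- make_counts(matrix(rnorm(n_genes * (n_ctrl + 1)), n_genes))
    model <- fit_reference(x[, 1:n_ctrl, drop = FALSE])
    rec <- perturb(model, x[, n_ctrl + 1])
    for (i in seq_len(nrow(rec))) {
      g1 <- rec$gene_a[i]
      g2 <- rec$gene_b[i]
      r_bf <- pearson_oracle(x[g1, 1:n_ctrl], x[g2, 1:n_ctrl])
      rp_bf <- pearson_oracle(x[g1, ], x[g2, ])
      expect_equal(rec$r[i], r_bf, tolerance = 1e-12)
      expect_equal(rec$r_prime[i], rp_bf, tolerance = 1e-12)
      expect_equal(rec$delta[i], rec$r_prime[i] - rec$r[i])
    }
  }
})

test_that("Bonferroni family is the tested-pair count; invalid genes excluded", {
  set.seed(5)
  x <- make_counts(matrix(rnorm(30), 5, 6))
  x["g4", 1:5] <- 3  # constant in reference
  model <- fit_reference(x[, 1:5])
  rec <- perturb(model, x[, 6])
  expect_equal(attr(rec, "family_size"), count_pairs(4))  # g4 dropped
  expect_false(any(rec$gene_a == "g4" | rec$gene_b == "g4"))
  expect_equal(rec$p_adjusted, pmin(1, rec$p * nrow(rec)))
  expect_true(all(rec$p_adjusted >= rec$p))
})

test_that("interactome_pairs family restricts testing to interactome edges", {
  set.seed(6)
  x <- make_counts(matrix(rnorm(36), 6, 6))
  model <- fit_reference(x[, 1:5])
  i <- toy_interactome(cbind(c("g1", "g2"), c("g2", "g5")))
  rec <- perturb(model, x[, 6], family = "interactome_pairs", interactome = i)
  expect_equal(nrow(rec), 2L)
  expect_equal(attr(rec, "family_size"), 2L)
  expect_setequal(paste(rec$gene_a, rec$gene_b), c("g1 g2", "g2 g5"))
  expect_error(perturb(model, x[, 6], family = "interactome_pairs"),
               "interactome")
})

test_that("decreasing alpha never adds edges", {
  set.seed(31)
  x <- make_counts(matrix(rnorm(80), 8, 10))
  model <- fit_reference(x[, 1:9])
  i <- toy_interactome(t(combn(sprintf("g%d", 1:8), 2)))
  edges_at <- function(alpha) {
    rec <- perturb(model, x[, 10], alpha = alpha)
    net <- build_reticulotype(rec, i, "p")
    paste(net$edges$a, net$edges$b)
  }
  alphas <- c(0.001, 0.01, 0.05, 0.2, 0.5)
  sets <- lapply(alphas, edges_at)
  for (k in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[k]] %in% sets[[k + 1]]))
  }
})

test_that("relabeling genes by a permutation permutes the network identically", {
  set.seed(12)
  x <- make_counts(matrix(rnorm(60), 6, 10))
  i <- toy_interactome(t(combn(rownames(x), 2)))
  model <- fit_reference(x[, 1:9])
  net <- build_reticulotype(perturb(model, x[, 10]), i, "p")

  perm <- setNames(sprintf("h%d", sample(6)), rownames(x))
  x2 <- x
  rownames(x2) <- unname(perm[rownames(x)])
  i2 <- toy_interactome(cbind(unname(perm[i$edges$a]), unname(perm[i$edges$b])))
  model2 <- fit_reference(x2[, 1:9])
  net2 <- build_reticulotype(perturb(model2, x2[, 10]), i2, "p")

  k1 <- sort(paste(pmin(perm[net$edges$a], perm[net$edges$b]),
                   pmax(perm[net$edges$a], perm[net$edges$b])))
  k2 <- sort(paste(net2$edges$a, net2$edges$b))
  expect_identical(k1, k2)
})

test_that("build_reticulotype intersects significant pairs with the interactome", {
  rec <- data.frame(gene_a = c("A", "A", "B"), gene_b = c("B", "C", "D"),
                    r = 0, r_prime = 0.9, delta = 0.9, z = 5, p = 1e-6,
                    p_adjusted = c(1e-5, 1e-5, 0.9),
                    significant = c(TRUE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  i <- toy_interactome(cbind(c("A", "B"), c("B", "D")))
  net <- build_reticulotype(rec, i, "pt1")
  expect_equal(paste(net$edges$a, net$edges$b), "A B")
  expect_setequal(net$nodes, c("A", "B"))
  expect_equal(nrow(net$records), 1L)

  rec$significant <- FALSE
  expect_message(empty <- build_reticulotype(rec, i, "pt1"), "empty")
  expect_equal(length(empty$nodes), 0L)

  rec$significant <- TRUE
  sat <- build_reticulotype(rec, i, "pt1")
  expect_equal(nrow(sat$edges), nrow(i$edges))
})

test_that("run_cohort fits one reference and returns one network per patient", {
  co <- simulate_cohort(one_module_spec(seed = 17, n_patients = 3))
  nets <- suppressMessages(run_cohort(co$expression, co$interactome, list()))
  expect_named(nets, c("P1", "P2", "P3"))
  expect_s3_class(nets$P1, "reticulotype")

  # patient 1 carries the planted module perturbation; null patients may at
  # most pick up the occasional false positive of the heavy-tailed small-n
  # statistic, never a substantial share of the planted pairs
  planted <- co$truth$perturbed_pairs$P1
  covered <- length(intersect(planted,
                              paste0(co$interactome$edges$a, "|",
                                     co$interactome$edges$b)))
  net_keys <- lapply(nets, function(n) {
    if (nrow(n$edges) == 0) character(0) else paste0(n$edges$a, "|", n$edges$b)
  })
  hits <- vapply(net_keys, function(k) length(intersect(k, planted)),
                 numeric(1))
  expect_gt(hits[["P1"]] / covered, 0.3)
  expect_lt(hits[["P2"]] / covered, hits[["P1"]] / covered / 2)
  expect_lt(hits[["P3"]] / covered, hits[["P1"]] / covered / 2)

  no_pat <- co$expression
  keep <- no_pat$group == "control"
  no_pat <- expression_matrix(no_pat$counts[, keep], biotype = no_pat$biotype,
                              group = no_pat$group[keep])
  expect_length(suppressMessages(
    run_cohort(no_pat, co$interactome, list())), 0)
})

test_that("the Z statistic is calibrated at a moderate reference size", {
  # the (1 - r^2)/(n - 1) scale is an asymptotic result: at n = 30 the null
  # z should be close to standard normal
  set.seed(202)
  zs <- c()
  for (rep in 1:400) {
    x <- rnorm(31)
    y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(31)
    r0 <- cor(x[1:30], y[1:30])
    r1 <- cor(x, y)
    zs <- c(zs, delta_pcc_z(r0, r1, 30)$z)
  }
  expect_gt(sd(zs), 0.85)
  expect_lt(sd(zs), 1.25)
})
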