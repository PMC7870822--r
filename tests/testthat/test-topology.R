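test_that("topology summary matches hand-enumerated small graphs", {
  path3 <- make_net("p", c("A", "B"), c("B", "C"))
  tp <- network_topology(path3)
  expect_equal(tp$n_nodes, 3L)
  expect_equal(tp$n_edges, 2L)
  expect_equal(tp$density, 2 / 3)
  expect_equal(tp$diameter, 2)
  expect_equal(tp$characteristic_path_length, 4 / 3)
  # degrees (1, 2, 1): population variance 2/9, mean 4/3
  expect_equal(tp$heterogeneity, sqrt(2 / 9) / (4 / 3))

  tri <- make_net("t", c("A", "A", "B"), c("B", "C", "C"))
  tt <- network_topology(tri)
  expect_equal(tt$density, 1)
  expect_equal(tt$diameter, 1)
  expect_equal(tt$characteristic_path_length, 1)
  expect_equal(tt$heterogeneity, 0)
  expect_equal(tt$n_components, 1L)

  empty <- make_net("e", character(0))
  te <- network_topology(empty)
  expect_equal(te$n_nodes, 0L)
  expect_true(is.na(te$density))

  two_comp <- make_net("d", c("A", "C"), c("B", "D"))
  td <- network_topology(two_comp)
  expect_equal(td$n_components, 2L)
  expect_true(td$path_metrics_partial)
  expect_equal(td$characteristic_path_length, 1)  # disconnected pairs ignored
})

test_that("topology metrics agree with a brute-force shortest-path oracle", {
  set.seed(77)
  # exhaustive over all labelled graphs on 4 nodes, random graphs on 5-7
  adjs <- list()
  pairs4 <- t(combn(4, 2))
  for (bits in 0:63) {
    adj <- matrix(0, 4, 4)
    on <- which(bitwAnd(bits, 2^(0:5)) > 0)
    for (e in on) {
      adj[pairs4[e, 1], pairs4[e, 2]] <- 1
      adj[pairs4[e, 2], pairs4[e, 1]] <- 1
    }
    adjs[[length(adjs) + 1]] <- adj
  }
  for (rep in 1:150) {
    nv <- sample(5:7, 1)
    adj <- matrix(0, nv, nv)
    up <- upper.tri(adj)
    adj[up] <- rbinom(sum(up), 1, runif(1, 0.2, 0.8))
    adj <- adj + t(adj)
    adjs[[length(adjs) + 1]] <- adj
  }
  for (adj in adjs) {
    if (sum(adj) == 0) next
    nv <- nrow(adj)
    rownames(adj) <- colnames(adj) <- sprintf("n%d", seq_len(nv))
    idx <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
    net <- make_net("x", rownames(adj)[idx[, 1]], rownames(adj)[idx[, 2]])
    got <- network_topology(net)
    want <- topology_oracle(adj)
    expect_equal(got$n_nodes, want$n_nodes)
    expect_equal(got$n_edges, want$n_edges)
    expect_equal(got$density, want$density)
    expect_equal(got$diameter, want$diameter)
    expect_equal(got$characteristic_path_length, want$cpl)
    expect_equal(got$heterogeneity, want$heterogeneity)
    expect_equal(got$n_components, want$n_components)
  }
})

test_that("overlap coefficient is intersection over the smaller set", {
  expect_equal(overlap_coefficient(c("a", "b", "c"), c("b", "c", "d")), 2 / 3)
  expect_equal(overlap_coefficient(letters[1:4], letters[1:4]), 1)
  expect_equal(overlap_coefficient(c("a", "b"), c("x", "y")), 0)
  expect_error(overlap_coefficient(character(0), "a"), "empty")
})

test_that("overlap coefficient dominates the Jaccard index", {
  set.seed(9)
  for (rep in 1:50) {
    A <- sample(letters, sample(2:10, 1))
    B <- sample(letters, sample(2:10, 1))
    ov <- overlap_coefficient(A, B)
    jac <- length(intersect(A, B)) / length(union(A, B))
    expect_gte(ov, jac)
    # O = I/min and J = I/union agree exactly when the intersection is empty
    # or the two sets coincide; strict nesting gives O = 1 > J
    agree <- length(intersect(A, B)) == 0 || setequal(A, B)
    expect_equal(abs(ov - jac) < 1e-12, agree)
    if (all(A %in% B) && !setequal(A, B)) expect_equal(ov, 1)
  }
})

test_that("pairwise overlap handles both modes, rectangles, and empties", {
  n1 <- make_net("n1", c("A", "B"), c("B", "C"))
  n2 <- make_net("n2", c("B", "C"), c("C", "D"))
  nets <- list(n1, n2)
  ove <- pairwise_overlap(nets, "edge")
  ovn <- pairwise_overlap(nets, "node")
  expect_equal(ove["n1", "n2"], 1 / 2)
  expect_equal(ovn["n1", "n2"], 2 / 3)
  expect_equal(diag(ove), c(n1 = 1, n2 = 1))
  expect_equal(ove, t(ove))

  triple <- list(n1, make_net("c2", c("A", "B"), c("B", "C")),
                 make_net("c3", c("A", "B"), c("B", "C")))
  expect_true(all(pairwise_overlap(triple, "edge") == 1))

  disj <- list(make_net("a", "A", "B"), make_net("b", "C", "D"))
  expect_true(all(pairwise_overlap(disj, "node")[1, 2] == 0))

  rect <- pairwise_overlap(list(n1, n2), "node", list(n1, n2, make_net("n3", "C", "D")))
  expect_equal(dim(rect), c(2L, 3L))

  with_empty <- list(n1, make_net("z", character(0)))
  expect_message(ovz <- pairwise_overlap(with_empty, "edge"), "empty")
  expect_true(is.na(ovz["n1", "z"]))

  expect_error(pairwise_overlap(list(n1), "node"), ">= 2")
})

test_that("pairwise overlap is invariant to cohort ordering", {
  set.seed(13)
  nets <- lapply(1:4, function(k) {
    pr <- t(combn(LETTERS[1:6], 2))[sample(15, 6), ]
    make_net(paste0("p", k), pr[, 1], pr[, 2])
  })
  ov <- pairwise_overlap(nets, "edge")
  perm <- c(3, 1, 4, 2)
  ov2 <- pairwise_overlap(nets[perm], "edge")
  expect_equal(ov2, ov[perm, perm])
})

test_that("unique edges are those absent from every other network", {
  p1 <- make_net("P1", c("A", "B"), c("B", "C"))
  p2 <- make_net("P2", "B", "C")
  ue <- unique_edges(list(p1, p2))
  expect_equal(paste(ue$P1$a, ue$P1$b), "A B")
  expect_equal(nrow(ue$P2), 0L)

  same <- list(p1, make_net("P2", c("A", "B"), c("B", "C")))
  expect_true(all(vapply(unique_edges(same), nrow, integer(1)) == 0L))

  disj <- list(make_net("x", "A", "B"), make_net("y", "C", "D"),
               make_net("z", "E", "F"))
  ud <- unique_edges(disj)
  expect_equal(vapply(ud, nrow, integer(1)), c(x = 1L, y = 1L, z = 1L))

  # sum of unique edges never exceeds the union of all edge sets
  set.seed(3)
  nets <- lapply(1:4, function(k) {
    pr <- t(combn(LETTERS[1:6], 2))[sample(15, 7), ]
    make_net(paste0("p", k), pr[, 1], pr[, 2])
  })
  un <- unique_edges(nets)
  all_keys <- unlist(lapply(nets, function(n) paste(n$edges$a, n$edges$b)))
  expect_lte(sum(vapply(un, nrow, integer(1))), length(unique(all_keys)))
})

test_that("unique feature edges count unique edges touching the gene set", {
  p1 <- make_net("P1", c("A", "C"), c("B", "D"))
  p2 <- make_net("P2", "E", "F")
  rep1 <- unique_feature_edges(list(p1, p2), "A", "featA")
  expect_equal(rep1$n_unique_feature_edges[rep1$patient_id == "P1"], 1L)
  expect_true(all(rep1$n_unique_feature_edges <= rep1$n_unique_edges))

  rep2 <- unique_feature_edges(list(p1, p2), LETTERS[1:6], "all")
  expect_equal(rep2$n_unique_feature_edges, rep2$n_unique_edges)
  expect_error(unique_feature_edges(list(p1, p2), character(0)), "nonempty")
})

test_that("Grubbs test flags a single two-sided outlier", {
  g <- grubbs_test(c(1, 1, 1, 10), alpha = 0.05)
  expect_equal(g$G, 1.5)
  expect_equal(g$critical, 1.4812, tolerance = 1e-3)
  expect_true(g$outlier)
  expect_equal(g$index, 4L)
  expect_lt(g$p, 0.05)

  g2 <- grubbs_test(c(1, 2, 3), alpha = 0.05)
  expect_equal(g2$G, 1)
  expect_false(g2$outlier)

  expect_message(g3 <- grubbs_test(c(5, 5, 5, 5)), "constant")
  expect_false(g3$outlier)
  expect_error(grubbs_test(c(1, 2)), ">= 3")
})
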