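test_that("build_graph symmetrizes, deduplicates and binarizes the adjacency", {
  nodes <- data.frame(id = c("P1", "H1", "D1"),
                      node_type = c("prescription", "herb", "disease"),
                      label = c("P1", "H1", "D1"),
                      role = c("target", "none", "none"))
  edges <- data.frame(source = c("P1", "P1"), target = c("H1", "D1"),
                      relation = c("prescription-herb", "prescription-disease"))
  g <- build_graph(nodes, edges)
  expect_equal(Matrix::nnzero(g$A), 4)  # two undirected edges, stored both ways
  expect_true(Matrix::isSymmetric(g$A))

  # duplicate edge (twice, and once reversed) still yields a single 1
  edges3 <- rbind(edges, data.frame(source = c("P1", "H1"),
                                    target = c("H1", "P1"),
                                    relation = "prescription-herb"))
  g3 <- build_graph(nodes, edges3)
  expect_equal(as.numeric(g3$A["P1", "H1"]), 1)
  expect_equal(as.matrix(g3$A), as.matrix(g$A))

  # input edge order never changes A
  g_rev <- build_graph(nodes, edges3[rev(seq_len(nrow(edges3))), ])
  expect_equal(as.matrix(g_rev$A), as.matrix(g$A))
})

test_that("build_graph rejects schema violations with typed errors", {
  nodes <- toy_nodes(); edges <- toy_edges()

  bad <- nodes; bad$node_type[4] <- "mineral"
  expect_error(build_graph(bad, edges), class = "prescsim_schema_error")

  bad <- nodes; bad$id[2] <- "P1"
  expect_error(build_graph(bad, edges), class = "prescsim_schema_error")

  bad <- nodes; bad$role[4] <- "target"  # role on a herb
  expect_error(build_graph(bad, edges), class = "prescsim_schema_error")

  dangling <- rbind(edges, data.frame(source = "P1", target = "NOPE",
                                      relation = "prescription-herb"))
  expect_error(build_graph(nodes, dangling),
               class = "prescsim_referential_error")

  mismatch <- rbind(edges, data.frame(source = "P1", target = "D1",
                                      relation = "prescription-herb"))
  expect_error(build_graph(nodes, mismatch), class = "prescsim_schema_error")

  selfie <- rbind(edges, data.frame(source = "P1", target = "P1",
                                    relation = "prescription-herb"))
  expect_error(build_graph(nodes, selfie), class = "prescsim_schema_error")
})

test_that("a node table at the study's full scale yields N = 15210", {
  counts <- c(prescription = 87, disease = 84, symptom = 113,
              disease_target = 10856, herb = 183, property = 5, flavor = 12,
              meridian = 12, category = 35, ingredient = 1294,
              ingredient_target = 2529)
  nodes <- do.call(rbind, lapply(names(counts), function(tp) {
    ids <- sprintf("%s_%05d", tp, seq_len(counts[[tp]]))
    data.frame(id = ids, node_type = tp, label = ids, role = "none")
  }))
  nodes$role[nodes$node_type == "prescription"] <-
    rep(c("target", "candidate"), c(20, 67))
  g <- build_graph(nodes, toy_edges()[0, ])
  expect_equal(nrow(g$nodes), 15210)
  expect_equal(dim(g$A), c(15210, 15210))
})

test_that("normalize_adjacency matches the dense brute-force oracle", {
  # closed forms first
  K3 <- matrix(1, 3, 3) - diag(3)
  expect_equal(as.matrix(normalize_adjacency(K3)),
               matrix(1 / 3, 3, 3), tolerance = 1e-12, ignore_attr = TRUE)

  path <- matrix(0, 3, 3); path[1, 2] <- path[2, 1] <- 1
  path[2, 3] <- path[3, 2] <- 1
  S <- as.matrix(normalize_adjacency(path))
  expect_equal(diag(S), c(0.5, 1 / 3, 0.5), tolerance = 1e-12)
  expect_equal(S[1, 2], 1 / sqrt(6), tolerance = 1e-12)
  expect_equal(S[2, 3], 1 / sqrt(6), tolerance = 1e-12)

  expect_equal(as.matrix(normalize_adjacency(matrix(0, 1, 1))),
               matrix(1), ignore_attr = TRUE)

  # oracle equivalence on random graphs, isolated nodes included
  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:20, 1)
    A <- random_adjacency(n, p = runif(1, 0.1, 0.6))
    expect_equal(as.matrix(normalize_adjacency(A)), dense_normalize(A),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("normalized adjacency of a connected graph has spectral radius 1", {
  set.seed(21)
  for (i in 1:5) {
    n <- sample(4:15, 1)
    A <- random_adjacency(n, 0.4)
    ring <- cbind(seq_len(n), c(2:n, 1))  # force connectivity
    A[ring] <- 1; A[ring[, 2:1]] <- 1
    ev <- eigen(as.matrix(normalize_adjacency(A)), symmetric = TRUE,
                only.values = TRUE)$values
    expect_equal(max(abs(ev)), 1, tolerance = 1e-8)
    expect_true(all(as.matrix(normalize_adjacency(A)) >= 0))
    expect_true(all(as.matrix(normalize_adjacency(A)) <= 1))
  }
})

test_that("normalize_adjacency validates its input", {
  expect_error(normalize_adjacency(matrix(0, 2, 3)),
               class = "prescsim_shape_error")
  asym <- matrix(c(0, 1, 0, 0), 2, 2)
  expect_error(normalize_adjacency(asym), class = "prescsim_shape_error")
  expect_error(normalize_adjacency(matrix(c(0, 2, 2, 0), 2, 2)),
               class = "prescsim_shape_error")
  expect_error(normalize_adjacency(diag(2)), class = "prescsim_shape_error")
})

test_that("init_features produces identity or identity-plus-type encodings", {
  g <- toy_graph()
  n <- nrow(g$nodes)

  X <- init_features(g, "identity")
  expect_equal(as.matrix(X), diag(n), ignore_attr = TRUE)

  X2 <- init_features(g, "type-onehot-plus-identity")
  expect_equal(ncol(X2), n + 11)
  expect_equal(unname(Matrix::rowSums(X2)), rep(2, n))
  expect_true(all(Matrix::rowSums(abs(X2)) > 0))
  expect_true(all(Matrix::rowSums(abs(X)) > 0))

  expect_error(init_features(g, "word2vec"), class = "prescsim_config_error")
})

test_that("attribute_set unrolls the schema paths from a prescription", {
  g <- toy_graph()
  # P1: herbs H1,H2; disease D1; H1 carries flavor/property/meridian/category
  expect_setequal(attribute_set(g, "P1"),
                  c("H1", "H2", "D1", "FL1", "PR1", "ME1", "CA1"))
  expect_setequal(attribute_set(g, "P1", included_types = "herb"),
                  c("H1", "H2"))
  # molecular chain reachable only through herbs/diseases
  expect_setequal(
    attribute_set(g, "P1", included_types = c("ingredient", "ingredient_target",
                                              "disease_target")),
    c("IN1", "IT1", "DT1"))
  # P3 has no ingredients under its herb H2: empty contribution is fine
  expect_length(attribute_set(g, "P3", included_types = "ingredient_target"), 0)
  expect_error(attribute_set(g, "H1"), class = "prescsim_usage_error")
})

test_that("attribute_set is monotone in the included type subset", {
  g <- toy_graph()
  set.seed(31)
  for (i in 1:25) {
    small <- sample(NODE_TYPES, sample(1:5, 1))
    large <- union(small, sample(NODE_TYPES, sample(1:6, 1)))
    for (p in c("P1", "P2", "P3")) {
      expect_true(all(attribute_set(g, p, small) %in%
                        attribute_set(g, p, large)))
    }
  }
})
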