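test_that("gcn_layer reduces to the propagation matrix and matches a dense oracle", {
  set.seed(41)
  A <- random_adjacency(5, 0.5)
  S <- normalize_adjacency(A)

  # W = I, identity activation, H = I: the layer returns S itself
  out <- gcn_layer(diag(5), S, diag(5), activation = "identity")
  expect_equal(out, as.matrix(S), tolerance = 1e-12, ignore_attr = TRUE)

  # zero input maps to activation(0) = 0 for every nonlinearity here
  expect_equal(gcn_layer(matrix(0, 5, 3), S, matrix(rnorm(9), 3, 3)),
               matrix(0, 5, 3))

  # dense brute-force evaluation oracle, several graphs and activations
  for (i in 1:10) {
    n <- sample(2:20, 1)
    A <- random_adjacency(n, 0.4)
    H <- matrix(rnorm(n * 4), n, 4)
    W <- matrix(rnorm(4 * 3), 4, 3)
    Sd <- dense_normalize(A)
    Z <- Sd %*% H %*% W
    expect_equal(gcn_layer(H, normalize_adjacency(A), W, "tanh"),
                 tanh(Z), tolerance = 1e-6)
    expect_equal(gcn_layer(H, normalize_adjacency(A), W, "prelu", 0.25),
                 ifelse(Z > 0, Z, 0.25 * Z), tolerance = 1e-6)
  }

  expect_error(gcn_layer(matrix(0, 4, 2), S, matrix(0, 2, 2)),
               class = "prescsim_shape_error")
  expect_error(gcn_layer(matrix(0, 5, 3), S, matrix(0, 2, 2)),
               class = "prescsim_shape_error")
})

test_that("corruption permutes feature rows, keeps structure, and is seedable", {
  X <- matrix(rnorm(20), 5, 4)
  A <- random_adjacency(5)

  set.seed(1); c1 <- corrupt_features(X, A)
  set.seed(1); c2 <- corrupt_features(X, A)
  expect_identical(c1$perm, c2$perm)
  expect_identical(c1$X_hat, c2$X_hat)

  # multiset of rows is preserved
  expect_equal(sort(rowSums(c1$X_hat^2)), sort(rowSums(X^2)))
  expect_identical(c1$A_hat, A)
  expect_equal(nrow(c1$X_hat), nrow(X))

  # N = 1: the only permutation is the identity
  expect_equal(corrupt_features(X[1, , drop = FALSE], A[1, 1, drop = FALSE])$X_hat,
               X[1, , drop = FALSE])
})

test_that("readout and discriminator obey their closed forms", {
  expect_equal(readout(matrix(0, 4, 3)), rep(0.5, 3))
  h <- c(0.3, -1.2)
  expect_equal(readout(matrix(h, 1, 2, byrow = TRUE)), 1 / (1 + exp(-h)))
  expect_equal(readout(rbind(c(2, 0), c(-2, 0))), c(0.5, 0.5))
  expect_error(readout(matrix(0, 0, 3)), class = "prescsim_usage_error")

  W <- diag(2)
  expect_equal(discriminate(c(0, 0), c(0.4, 0.6), W), 0.5)
  e1 <- c(1, 0)
  expect_equal(discriminate(e1, e1, W), 1 / (1 + exp(-1)), tolerance = 1e-9)

  # bilinearity: doubling h doubles the logit
  set.seed(5)
  h <- rnorm(4); s <- runif(4); W4 <- matrix(rnorm(16), 4, 4)
  logit <- function(p) log(p / (1 - p))
  expect_equal(logit(discriminate(2 * h, s, W4)),
               2 * logit(discriminate(h, s, W4)), tolerance = 1e-9)
  expect_error(discriminate(c(1, 2, 3), c(1, 2), W), class = "prescsim_shape_error")
})

test_that("the DGI objective matches hand arithmetic and never diverges", {
  expect_equal(dgi_objective(rep(0.5, 4), rep(0.5, 4)), log(0.5),
               tolerance = 1e-12)
  expect_equal(dgi_objective(c(0.9, 0.8), c(0.1, 0.2)),
               (log(0.9) + log(0.8) + log(0.9) + log(0.8)) / 4,
               tolerance = 1e-12)
  # perfectly separated scores approach the supremum 0 from below
  near <- dgi_objective(rep(1 - 1e-9, 3), rep(1e-9, 3))
  expect_lt(near, 0)
  expect_gt(near, -1e-6)
  # exact 0/1 scores are clamped, never -Inf
  expect_true(is.finite(dgi_objective(c(0, 1), c(0, 1))))
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(51)
  n <- 6; d <- 3
  A <- random_adjacency(n, 0.5)
  S <- normalize_adjacency(A)
  X <- matrix(rnorm(n * 4), n, 4)
  config <- make_train_config(hidden_units = d, epochs = 1, n_layers = 2,
                              activation = "prelu", seed = 1)
  params <- prescsim:::init_encoder_params(ncol(X), config)
  perm <- sample.int(n)
  X_hat <- X[perm, ]

  loss_at <- function(p) prescsim:::dgi_loss_and_grad(S, X, X_hat, p, config)$objective
  res <- prescsim:::dgi_loss_and_grad(S, X, X_hat, params, config)
  eps <- 1e-6

  num_grad <- function(get, set) {
    p1 <- set(params, get(params) + eps)
    p2 <- set(params, get(params) - eps)
    (loss_at(p1) - loss_at(p2)) / (2 * eps)
  }
  # a sample of coordinates from every parameter tensor
  for (l in 1:2) {
    for (idx in list(c(1, 1), c(2, 3))) {
      g_num <- num_grad(function(p) p$W[[l]][idx[1], idx[2]],
                        function(p, v) { p$W[[l]][idx[1], idx[2]] <- v; p })
      expect_equal(res$grad$W[[l]][idx[1], idx[2]], g_num, tolerance = 1e-5)
    }
    g_num <- num_grad(function(p) p$alpha[l],
                      function(p, v) { p$alpha[l] <- v; p })
    expect_equal(res$grad$alpha[l], g_num, tolerance = 1e-5)
  }
  for (idx in list(c(1, 1), c(3, 2), c(2, 3))) {
    g_num <- num_grad(function(p) p$W_disc[idx[1], idx[2]],
                      function(p, v) { p$W_disc[idx[1], idx[2]] <- v; p })
    expect_equal(res$grad$W_disc[idx[1], idx[2]], g_num, tolerance = 1e-5)
  }
})

test_that("training is reproducible, learns, and epochs = 0 is a pure forward pass", {
  mg <- mini_graph(seed = 3)

  cfg0 <- make_train_config(hidden_units = 8, epochs = 0, seed = 9)
  e0 <- train_dgi(mg$graph, cfg0)
  expect_equal(nrow(e0$H), nrow(mg$graph$nodes))
  expect_true(is.na(e0$objective))
  expect_true(all(e0$summary > 0 & e0$summary < 1))

  cfg <- make_train_config(hidden_units = 16, epochs = 26, seed = 9)
  e1 <- train_dgi(mg$graph, cfg)
  e2 <- train_dgi(mg$graph, cfg)
  expect_identical(e1$H, e2$H)

  # learning occurs: late objective beats the first epoch
  expect_gt(mean(tail(e1$objective_trace, 5)), e1$objective_trace[1])
  expect_equal(rownames(e1$H), mg$graph$nodes$id)
})

test_that("structurally identical prescriptions differ only via their own one-hot columns", {
  nodes <- data.frame(id = c("P1", "P2", "H1", "D1"),
                      node_type = c("prescription", "prescription", "herb",
                                    "disease"),
                      label = c("P1", "P2", "H1", "D1"),
                      role = c("target", "candidate", "none", "none"))
  edges <- data.frame(source = c("P1", "P1", "P2", "P2"),
                      target = c("H1", "D1", "H1", "D1"),
                      relation = rep(c("prescription-herb",
                                       "prescription-disease"), 2))
  g <- build_graph(nodes, edges)
  S <- normalize_adjacency(g$A)
  set.seed(61)
  W <- matrix(rnorm(4 * 3), 4, 3)
  H <- gcn_layer(diag(4), S, W, activation = "identity")
  # identical neighborhoods: the embedding gap is exactly the self-loop
  # weight times the gap between their own one-hot feature rows of W
  c_self <- as.numeric(S[1, 1])
  expect_equal(as.numeric(S[2, 2]), c_self, tolerance = 1e-12)
  expect_equal(H[1, ] - H[2, ], c_self * (W[1, ] - W[2, ]),
               tolerance = 1e-9)
})
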