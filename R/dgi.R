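#' @name dgi
#' @title Graph convolutional encoder trained with Deep Graph Infomax
#' @description
#' The encoder is a stack of graph-convolution layers
#' \deqn{H^{(l+1)} = \sigma(\tilde D^{-1/2} \tilde A \tilde D^{-1/2} H^{(l)} W^{(l)})}
#' trained without labels by maximizing the mutual information between each
#' node embedding \eqn{h_i} and a global graph summary
#' \eqn{s = \sigma(\frac{1}{N}\sum_i h_i)}. Negative samples come from a
#' corruption function that randomly permutes the feature rows while keeping
#' the adjacency; a bilinear discriminator \eqn{\sigma(h_i^T W s)} scores
#' patch-summary pairs and the binary cross-entropy objective pushes true
#' pairs towards 1 and corrupted pairs towards 0. Both encoder passes share
#' the same weights. Gradients are computed analytically (the network is a
#' short chain of matrix products) and optimized with Adam.
NULL

ACTIVATIONS <- list(
  prelu = list(
    fn = function(z, alpha) ifelse(z > 0, z, alpha * z),
    grad = function(z, alpha) ifelse(z > 0, 1, alpha),
    learnable = TRUE
  ),
  relu = list(
    fn = function(z, alpha) pmax(z, 0),
    grad = function(z, alpha) (z > 0) * 1,
    learnable = FALSE
  ),
  tanh = list(
    fn = function(z, alpha) tanh(z),
    grad = function(z, alpha) 1 - tanh(z)^2,
    learnable = FALSE
  ),
  identity = list(
    fn = function(z, alpha) z,
    grad = function(z, alpha) array(1, dim(z)),
    learnable = FALSE
  )
)

#' Training configuration for the DGI encoder
#'
#' Defaults follow the stability-based hyperparameter selection: 128 hidden
#' units and 26 epochs minimize the dispersion (SD/CV) of the similarity
#' outputs. Learning rate, depth and activation are not dictated by the
#' stability procedure; the defaults are the standard transductive setup
#' (one layer, PReLU, Adam at 1e-3, full-graph batches, one corruption
#' draw per epoch).
#'
#' @param hidden_units embedding width d.
#' @param epochs number of full-graph training iterations.
#' @param learning_rate Adam step size.
#' @param n_layers number of graph-convolution layers.
#' @param seed integer seed controlling initialization and corruption.
#' @param activation encoder nonlinearity: `"prelu"`, `"relu"`, `"tanh"`
#'   or `"identity"` (readout and discriminator are always sigmoid).
#' @return a `train_config` list.
#' @export
make_train_config <- function(hidden_units = 128L, epochs = 26L,
                              learning_rate = 1e-3, n_layers = 1L,
                              seed = 1L, activation = "prelu") {
  stopifnot(hidden_units >= 1, epochs >= 0, learning_rate > 0, n_layers >= 1)
  if (!activation %in% names(ACTIVATIONS))
    stopf("unknown activation '%s'", activation, class = "prescsim_config_error")
  structure(list(hidden_units = as.integer(hidden_units),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 n_layers = as.integer(n_layers),
                 seed = as.integer(seed),
                 activation = activation),
            class = "train_config")
}

glorot <- function(nrow, ncol) {
  limit <- sqrt(6 / (nrow + ncol))
  matrix(runif(nrow * ncol, -limit, limit), nrow, ncol)
}

# Layer weights W^(l), PReLU slopes, bilinear discriminator weight W.
init_encoder_params <- function(n_features, config) {
  d <- config$hidden_units
  dims <- c(n_features, rep(d, config$n_layers))
  W <- lapply(seq_len(config$n_layers),
              function(l) glorot(dims[l], dims[l + 1]))
  list(W = W,
       alpha = rep(0.25, config$n_layers),
       W_disc = glorot(d, d))
}

#' One graph-convolution layer
#'
#' Computes \eqn{\sigma(\tilde D^{-1/2}\tilde A\tilde D^{-1/2} H W)} for a
#' pre-normalized propagation matrix.
#'
#' @param H input node representations (N x F).
#' @param A_norm normalized adjacency from [normalize_adjacency()].
#' @param W layer weight matrix (F x F').
#' @param activation nonlinearity name.
#' @param alpha PReLU negative slope (ignored by other activations).
#' @return dense N x F' matrix.
#' @export
gcn_layer <- function(H, A_norm, W, activation = "prelu", alpha = 0.25) {
  if (ncol(A_norm) != nrow(H))
    stopf("A_norm is %d-column but H has %d rows", ncol(A_norm), nrow(H),
          class = "prescsim_shape_error")
  if (nrow(W) != ncol(H))
    stopf("W has %d rows but H has %d columns", nrow(W), ncol(H),
          class = "prescsim_shape_error")
  act <- ACTIVATIONS[[match.arg(activation, names(ACTIVATIONS))]]
  Z <- as.matrix((A_norm %*% H) %*% W)
  act$fn(Z, alpha)
}

#' Corruption function: shuffle feature rows, keep the structure
#'
#' Produces a negative sample by permuting the rows of the feature matrix
#' uniformly at random while leaving the adjacency untouched, so corrupted
#' node count M equals N and the feature-row multiset is preserved. Draws
#' from the current RNG state; seed upstream for reproducibility.
#'
#' @param X feature matrix.
#' @param A adjacency matrix (returned unchanged).
#' @param perm optional explicit permutation (for testing).
#' @return list with `X_hat`, `A_hat` and the `perm` used.
#' @export
corrupt_features <- function(X, A, perm = NULL) {
  n <- nrow(X)
  if (is.null(perm)) perm <- sample.int(n)
  stopifnot(length(perm) == n)
  list(X_hat = X[perm, , drop = FALSE], A_hat = A, perm = perm)
}

#' Readout: graph-level summary vector
#'
#' \eqn{s = \sigma(\frac{1}{N} \sum_i h_i)}, the sigmoid of the columnwise
#' mean embedding; entries lie in (0, 1).
#'
#' @param H N x d embedding matrix.
#' @return length-d numeric vector.
#' @export
readout <- function(H) {
  H <- as.matrix(H)
  if (!nrow(H)) stopf("readout of an empty embedding matrix",
                      class = "prescsim_usage_error")
  sigmoid(colMeans(H))
}

#' Bilinear discriminator
#'
#' Probability score \eqn{\sigma(h^T W s)} that a patch-summary pair comes
#' from the true graph rather than the corrupted one.
#'
#' @param h node embedding (length d).
#' @param s graph summary (length d).
#' @param W d x d discriminator weight.
#' @return scalar in (0, 1).
#' @export
discriminate <- function(h, s, W) {
  if (length(h) != nrow(W) || length(s) != ncol(W))
    stopf("discriminator dims: |h|=%d, |s|=%d, W is %dx%d",
          length(h), length(s), nrow(W), ncol(W),
          class = "prescsim_shape_error")
  sigmoid(drop(crossprod(h, W %*% s)))
}

#' DGI binary cross-entropy objective
#'
#' \deqn{L = \frac{1}{N+M}\left(\sum_i \log D(h_i, s) +
#'   \sum_j \log(1 - D(\hat h_j, s))\right)}
#' Training maximizes L (equivalently minimizes -L). Scores are clamped to
#' `[1e-12, 1 - 1e-12]` so the logs stay finite.
#'
#' @param pos_scores discriminator scores of true pairs.
#' @param neg_scores discriminator scores of corrupted pairs.
#' @return scalar objective value (<= 0, approaching 0 under perfect
#'   separation; `log(0.5)` when scores are uninformative).
#' @export
dgi_objective <- function(pos_scores, neg_scores) {
  eps <- 1e-12
  p <- pmin(pmax(pos_scores, eps), 1 - eps)
  q <- pmin(pmax(neg_scores, eps), 1 - eps)
  (sum(log(p)) + sum(log1p(-q))) / (length(p) + length(q))
}

encoder_forward <- function(S, X, params, config) {
  act <- ACTIVATIONS[[config$activation]]
  H <- X
  P_list <- vector("list", config$n_layers)
  Z_list <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    P <- S %*% H
    Z <- as.matrix(P %*% params$W[[l]])
    P_list[[l]] <- P
    Z_list[[l]] <- Z
    H <- act$fn(Z, params$alpha[l])
  }
  list(H = H, P = P_list, Z = Z_list)
}

# Backprop of dL/dH_top through the encoder stack; accumulates into the
# gradient list `grad` (same shapes as params). S is symmetric.
encoder_backward <- function(dH, fwd, S, params, config, grad) {
  act <- ACTIVATIONS[[config$activation]]
  for (l in rev(seq_len(config$n_layers))) {
    Z <- fwd$Z[[l]]
    dZ <- dH * act$grad(Z, params$alpha[l])
    grad$W[[l]] <- grad$W[[l]] + as.matrix(crossprod(fwd$P[[l]], dZ))
    if (act$learnable)  # dH, not dZ: alpha acts after the linear map
      grad$alpha[l] <- grad$alpha[l] + sum(dH * pmin(Z, 0))
    if (l > 1)
      dH <- as.matrix(S %*% (dZ %*% t(params$W[[l]])))
  }
  grad
}

# Objective value and analytic gradient of L w.r.t. all parameters for one
# positive/corrupted pair of encoder passes. The summary s is read out from
# the positive embeddings only.
dgi_loss_and_grad <- function(S, X, X_hat, params, config) {
  fwd_pos <- encoder_forward(S, X, params, config)
  fwd_neg <- encoder_forward(S, X_hat, params, config)
  H <- fwd_pos$H
  Hn <- fwd_neg$H
  n <- nrow(H); m <- nrow(Hn)

  mvec <- colMeans(H)
  s <- sigmoid(mvec)
  Ws <- drop(params$W_disc %*% s)
  z_pos <- drop(H %*% Ws)
  z_neg <- drop(Hn %*% Ws)
  p_pos <- sigmoid(z_pos)
  p_neg <- sigmoid(z_neg)
  L <- dgi_objective(p_pos, p_neg)

  # d L / d z: positives (1 - p)/(N+M), negatives -p/(N+M)
  g_pos <- (1 - p_pos) / (n + m)
  g_neg <- -p_neg / (n + m)

  u <- drop(crossprod(H, g_pos) + crossprod(Hn, g_neg))  # sum g_i h_i
  grad <- list(W = lapply(params$W, function(w) array(0, dim(w))),
               alpha = numeric(length(params$alpha)),
               W_disc = u %o% s)

  ds <- drop(crossprod(params$W_disc, u))
  dm <- ds * s * (1 - s)
  dH_pos <- g_pos %o% Ws + matrix(dm, n, length(dm), byrow = TRUE) / n
  dH_neg <- g_neg %o% Ws

  grad <- encoder_backward(dH_pos, fwd_pos, S, params, config, grad)
  grad <- encoder_backward(dH_neg, fwd_neg, S, params, config, grad)
  list(objective = L, grad = grad, H = H, s = s)
}

adam_init <- function(params) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else array(0, dim(x) %||% length(x))
  list(m = zero(params), v = zero(params), t = 0)
}

# One Adam ascent step on the objective (gradients point uphill).
adam_step <- function(params, grad, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^state$t)
    vhat <- v / (1 - beta2^state$t)
    list(p = p + lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  for (l in seq_along(params$W)) {
    r <- upd(params$W[[l]], grad$W[[l]], state$m$W[[l]], state$v$W[[l]])
    params$W[[l]] <- r$p; state$m$W[[l]] <- r$m; state$v$W[[l]] <- r$v
  }
  r <- upd(params$alpha, grad$alpha, state$m$alpha, state$v$alpha)
  params$alpha <- r$p; state$m$alpha <- r$m; state$v$alpha <- r$v
  r <- upd(params$W_disc, grad$W_disc, state$m$W_disc, state$v$W_disc)
  params$W_disc <- r$p; state$m$W_disc <- r$m; state$v$W_disc <- r$v
  list(params = params, state = state)
}

#' Train the DGI encoder on a knowledge graph
#'
#' Runs `epochs` full-graph iterations: encode the true graph, encode a
#' corrupted copy (feature rows permuted) with the same weights, read the
#' summary out of the true embeddings, score both with the bilinear
#' discriminator and take one Adam ascent step on the binary cross-entropy
#' objective. Fully reproducible given `config$seed`; `epochs = 0` returns
#' the embeddings under the initial weights.
#'
#' @param graph a `knowledge_graph`.
#' @param config a [make_train_config()] list.
#' @return an `embedding_set`: `H` (N x d, rows named by node id), the
#'   graph `summary` vector, `node_ids`, per-epoch `objective_trace`, the
#'   final `objective` and the `config` used.
#' @export
train_dgi <- function(graph, config = make_train_config()) {
  stopifnot(inherits(graph, "knowledge_graph"))
  S <- normalize_adjacency(graph$A)
  X <- as(graph$X, "CsparseMatrix")

  set.seed(derive_seed(config$seed, "dgi-init"))
  params <- init_encoder_params(ncol(X), config)
  state <- adam_init(params)
  trace <- numeric(config$epochs)

  set.seed(derive_seed(config$seed, "dgi-train"))
  for (epoch in seq_len(config$epochs)) {
    corrupted <- corrupt_features(X, graph$A)
    res <- dgi_loss_and_grad(S, X, corrupted$X_hat, params, config)
    if (!is.finite(res$objective))
      stopf("non-finite objective at epoch %d (hidden=%d, lr=%g)",
            epoch, config$hidden_units, config$learning_rate,
            class = "prescsim_training_error")
    trace[epoch] <- res$objective
    stepped <- adam_step(params, res$grad, state, config$learning_rate)
    params <- stepped$params
    state <- stepped$state
  }

  fwd <- encoder_forward(S, X, params, config)
  H <- fwd$H
  rownames(H) <- graph$nodes$id
  s <- readout(H)
  structure(list(H = H, summary = s, node_ids = graph$nodes$id,
                 objective_trace = trace,
                 objective = if (config$epochs) trace[config$epochs] else NA_real_,
                 config = config, params = params),
            class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("<embedding_set> %d nodes x %d dims, %d epochs, objective %.5f\n",
              nrow(x$H), ncol(x$H), x$config$epochs, x$objective))
  invisible(x)
}
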