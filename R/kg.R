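#' @name kg
#' @title Heterogeneous prescription knowledge graph
#' @description
#' The graph has 11 node types spanning the three dimensions of prescription
#' information: the prescription itself; disease-side information (disease,
#' symptom, disease target); and herb-side information (herb, property,
#' flavor, meridian, category, ingredient, ingredient target). Edges follow
#' a fixed relation schema (e.g. a prescription links to its herbs, an herb
#' to its flavors) and are stored undirected and unweighted: the adjacency
#' matrix A is binary symmetric with zero diagonal, duplicate input edges
#' collapsing to a single 1.
NULL

#' Closed vocabulary of node types
#' @export
NODE_TYPES <- c(
  "prescription", "disease", "symptom", "disease_target",
  "herb", "property", "flavor", "meridian", "category",
  "ingredient", "ingredient_target"
)

#' Relation schema: each relation joins exactly two node types
#' @export
RELATION_SCHEMA <- list(
  "prescription-disease"        = c("prescription", "disease"),
  "prescription-symptom"        = c("prescription", "symptom"),
  "prescription-herb"           = c("prescription", "herb"),
  "disease-disease_target"      = c("disease", "disease_target"),
  "herb-property"               = c("herb", "property"),
  "herb-flavor"                 = c("herb", "flavor"),
  "herb-meridian"               = c("herb", "meridian"),
  "herb-category"               = c("herb", "category"),
  "herb-ingredient"             = c("herb", "ingredient"),
  "ingredient-ingredient_target" = c("ingredient", "ingredient_target")
)

# Non-molecular attribute types used for the Jaccard sets: disease targets,
# ingredients and ingredient targets are deliberately absent.
JACCARD_DEFAULT_TYPES <- c(
  "disease", "symptom", "herb", "property", "flavor", "meridian", "category"
)

validate_node_table <- function(nodes) {
  required <- c("id", "node_type", "label")
  missing <- setdiff(required, names(nodes))
  if (length(missing))
    stopf("node table lacks column(s): %s", paste(missing, collapse = ", "),
          class = "prescsim_schema_error")
  if (!"role" %in% names(nodes)) nodes$role <- "none"
  nodes$role[is.na(nodes$role) | nodes$role == ""] <- "none"
  nodes$id <- as.character(nodes$id)
  nodes$node_type <- as.character(nodes$node_type)
  nodes$role <- as.character(nodes$role)

  dup <- nodes$id[duplicated(nodes$id)]
  if (length(dup))
    stopf("duplicate node id(s): %s", paste(unique(dup), collapse = ", "),
          class = "prescsim_schema_error")
  bad_type <- setdiff(unique(nodes$node_type), NODE_TYPES)
  if (length(bad_type))
    stopf("unknown node_type(s): %s", paste(bad_type, collapse = ", "),
          class = "prescsim_schema_error")
  bad_role <- setdiff(unique(nodes$role), c("target", "candidate", "none"))
  if (length(bad_role))
    stopf("unknown role(s): %s", paste(bad_role, collapse = ", "),
          class = "prescsim_schema_error")
  misplaced <- nodes$role != "none" & nodes$node_type != "prescription"
  if (any(misplaced))
    stopf("role set on non-prescription node(s): %s",
          paste(nodes$id[misplaced], collapse = ", "),
          class = "prescsim_schema_error")
  nodes[, c("id", "node_type", "label", "role")]
}

validate_edge_table <- function(edges, nodes) {
  required <- c("source", "target", "relation")
  missing <- setdiff(required, names(edges))
  if (length(missing))
    stopf("edge table lacks column(s): %s", paste(missing, collapse = ", "),
          class = "prescsim_schema_error")
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$relation <- as.character(edges$relation)

  bad_rel <- setdiff(unique(edges$relation), names(RELATION_SCHEMA))
  if (length(bad_rel))
    stopf("unknown relation(s): %s", paste(bad_rel, collapse = ", "),
          class = "prescsim_schema_error")

  known <- c(edges$source, edges$target) %in% nodes$id
  if (!all(known)) {
    rows <- which(!(edges$source %in% nodes$id) | !(edges$target %in% nodes$id))
    stopf("edge row(s) %s reference unknown node id(s)",
          paste(rows, collapse = ", "), class = "prescsim_referential_error")
  }
  if (any(edges$source == edges$target))
    stopf("self-edge(s) at row(s) %s",
          paste(which(edges$source == edges$target), collapse = ", "),
          class = "prescsim_schema_error")

  type_of <- setNames(nodes$node_type, nodes$id)
  for (i in seq_len(nrow(edges))) {
    sig <- RELATION_SCHEMA[[edges$relation[i]]]
    got <- sort(c(type_of[[edges$source[i]]], type_of[[edges$target[i]]]))
    if (!identical(got, sort(sig)))
      stopf("edge row %d: relation '%s' expects types {%s}, got {%s}",
            i, edges$relation[i], paste(sig, collapse = ", "),
            paste(got, collapse = ", "), class = "prescsim_schema_error")
  }
  edges[, c("source", "target", "relation")]
}

#' Build a knowledge graph from node and edge tables
#'
#' Validates both tables against the 11-type vocabulary and the relation
#' schema, then assembles a binary symmetric adjacency matrix. Duplicate
#' edges (in either orientation) collapse to a single 1 — the graph is
#' unweighted by construction. Node ordering is the input-table order and
#' is shared by the adjacency, the feature matrix and any embeddings
#' computed later.
#'
#' @param nodes data.frame with columns `id`, `node_type`, `label` and
#'   optionally `role` (`"target"`/`"candidate"` for prescriptions,
#'   `"none"` otherwise).
#' @param edges data.frame with columns `source`, `target`, `relation`.
#' @param feature_scheme initial node-feature scheme, see [init_features()].
#' @return an object of class `knowledge_graph`: list with `nodes`, `edges`,
#'   sparse adjacency `A` and feature matrix `X`.
#' @export
#' @examples
#' nodes <- data.frame(
#'   id = c("P1", "H1", "D1"),
#'   node_type = c("prescription", "herb", "disease"),
#'   label = c("P1", "H1", "D1"),
#'   role = c("target", "none", "none")
#' )
#' edges <- data.frame(
#'   source = c("P1", "P1"), target = c("H1", "D1"),
#'   relation = c("prescription-herb", "prescription-disease")
#' )
#' g <- build_graph(nodes, edges)
#' Matrix::nnzero(g$A)  # 4: two undirected edges
build_graph <- function(nodes, edges, feature_scheme = "identity") {
  nodes <- validate_node_table(as.data.frame(nodes))
  edges <- validate_edge_table(as.data.frame(edges), nodes)
  n <- nrow(nodes)
  idx <- setNames(seq_len(n), nodes$id)

  if (nrow(edges)) {
    i <- idx[edges$source]
    j <- idx[edges$target]
    # symmetrize and deduplicate: store each undirected pair once, both ways
    lo <- pmin(i, j); hi <- pmax(i, j)
    keep <- !duplicated(cbind(lo, hi))
    lo <- lo[keep]; hi <- hi[keep]
    A <- sparseMatrix(i = c(lo, hi), j = c(hi, lo), x = 1, dims = c(n, n),
                      dimnames = list(nodes$id, nodes$id))
  } else {
    A <- sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                      dims = c(n, n), dimnames = list(nodes$id, nodes$id))
  }
  g <- structure(
    list(nodes = nodes, edges = edges, A = A, X = NULL),
    class = "knowledge_graph"
  )
  g$X <- init_features(g, feature_scheme)
  g
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf("<knowledge_graph> %d nodes, %d undirected edges\n",
              nrow(x$nodes), Matrix::nnzero(x$A) / 2))
  tab <- table(factor(x$nodes$node_type, levels = NODE_TYPES))
  cat(paste(sprintf("  %-17s %d", names(tab), as.integer(tab)),
            collapse = "\n"), "\n")
  roles <- table(x$nodes$role[x$nodes$node_type == "prescription"])
  cat("  prescription roles:",
      paste(sprintf("%s=%d", names(roles), as.integer(roles)), collapse = " "),
      "\n")
  invisible(x)
}

#' Symmetrically normalized adjacency with self-connections
#'
#' Computes the graph-convolution propagation matrix
#' \deqn{\tilde D^{-1/2} (A + I) \tilde D^{-1/2}}
#' where \eqn{\tilde D} is the degree matrix of \eqn{A + I}. The result is
#' symmetric with entries in `[0, 1]` and spectral radius 1 on connected
#' graphs; a node isolated before the self-loop gets diagonal entry 1.
#'
#' @param A binary symmetric adjacency matrix (dense or `Matrix` sparse)
#'   with zero diagonal.
#' @return sparse symmetric normalized matrix of the same dimension.
#' @export
#' @examples
#' A <- matrix(1, 3, 3) - diag(3)  # triangle: every entry becomes 1/3
#' normalize_adjacency(A)
normalize_adjacency <- function(A) {
  A <- as(as(A, "CsparseMatrix"), "generalMatrix")
  if (nrow(A) != ncol(A))
    stopf("adjacency must be square, got %d x %d", nrow(A), ncol(A),
          class = "prescsim_shape_error")
  if (!Matrix::isSymmetric(A))
    stopf("adjacency must be symmetric", class = "prescsim_shape_error")
  vals <- unique(A@x)
  if (length(setdiff(vals, c(0, 1))))
    stopf("adjacency must be binary", class = "prescsim_shape_error")
  if (any(Matrix::diag(A) != 0))
    stopf("adjacency must have zero diagonal", class = "prescsim_shape_error")
  At <- A + Diagonal(nrow(A))
  d_inv_sqrt <- Diagonal(x = 1 / sqrt(Matrix::rowSums(At)))
  S <- d_inv_sqrt %*% At %*% d_inv_sqrt
  dimnames(S) <- dimnames(A)
  S
}

#' Initialize node features
#'
#' The input data carry no numeric node attributes, so features are
#' synthetic encodings of identity and (optionally) type:
#' * `"identity"`: `X = I`, the standard featureless transductive setup —
#'   each node's embedding is learned freely.
#' * `"type-onehot-plus-identity"`: identity block plus an 11-column
#'   one-hot block over the full node-type vocabulary, so each row sums
#'   to 2 and same-typed nodes share a feature column.
#'
#' @param graph a `knowledge_graph`.
#' @param scheme feature scheme name.
#' @return a sparse N x F feature matrix with no all-zero rows.
#' @export
init_features <- function(graph, scheme = c("identity", "type-onehot-plus-identity")) {
  if (!scheme[1] %in% c("identity", "type-onehot-plus-identity"))
    stopf("unknown feature scheme '%s'", scheme[1],
          class = "prescsim_config_error")
  scheme <- scheme[1]
  n <- nrow(graph$nodes)
  I <- Diagonal(n)
  rownames(I) <- graph$nodes$id
  if (scheme == "identity") return(I)
  type_idx <- match(graph$nodes$node_type, NODE_TYPES)
  onehot <- sparseMatrix(i = seq_len(n), j = type_idx, x = 1,
                         dims = c(n, length(NODE_TYPES)))
  X <- cbind(I, onehot)
  rownames(X) <- graph$nodes$id
  X
}

neighbors_of <- function(graph, ids, type = NULL) {
  if (!length(ids)) return(character(0))
  cols <- match(ids, graph$nodes$id)
  nb <- which(Matrix::rowSums(graph$A[, cols, drop = FALSE]) > 0)
  out <- graph$nodes$id[nb]
  if (!is.null(type)) out <- out[graph$nodes$node_type[nb] %in% type]
  out
}

#' Attribute set of a prescription
#'
#' The set of knowledge-graph nodes that describe a prescription, used by
#' the Jaccard metric. Nodes are gathered along the schema paths out of the
#' prescription — direct neighbors (diseases, symptoms, herbs), then the
#' attributes and ingredients of its herbs and the targets of its diseases,
#' then the targets of those ingredients — and filtered to `included_types`.
#' The default subset covers diseases, symptoms, herbs and the four herb
#' attributes; molecular nodes (disease targets, ingredients, ingredient
#' targets) are excluded by default because presence/absence of thousands
#' of shared proteins would swamp the set comparison.
#'
#' @param graph a `knowledge_graph`.
#' @param prescription_id id of a prescription node.
#' @param included_types node types to keep.
#' @return character vector of node ids (possibly empty).
#' @export
attribute_set <- function(graph, prescription_id,
                          included_types = JACCARD_DEFAULT_TYPES) {
  pos <- match(prescription_id, graph$nodes$id)
  if (is.na(pos) || graph$nodes$node_type[pos] != "prescription")
    stopf("'%s' is not a prescription node", prescription_id,
          class = "prescsim_usage_error")
  included_types <- match.arg(included_types, NODE_TYPES, several.ok = TRUE)

  direct <- neighbors_of(graph, prescription_id)
  herbs <- direct[graph$nodes$node_type[match(direct, graph$nodes$id)] == "herb"]
  diseases <- direct[graph$nodes$node_type[match(direct, graph$nodes$id)] == "disease"]

  pool <- direct
  herb_attr_types <- intersect(included_types,
                               c("property", "flavor", "meridian", "category"))
  if (length(herb_attr_types))
    pool <- c(pool, neighbors_of(graph, herbs, herb_attr_types))
  ingredients <- character(0)
  if (any(c("ingredient", "ingredient_target") %in% included_types)) {
    ingredients <- neighbors_of(graph, herbs, "ingredient")
    pool <- c(pool, ingredients)
  }
  if ("ingredient_target" %in% included_types)
    pool <- c(pool, neighbors_of(graph, ingredients, "ingredient_target"))
  if ("disease_target" %in% included_types)
    pool <- c(pool, neighbors_of(graph, diseases, "disease_target"))

  pool <- unique(pool)
  keep <- graph$nodes$node_type[match(pool, graph$nodes$id)] %in% included_types
  sort(pool[keep])
}

#' Per-type node counts and per-relation edge counts
#'
#' @param graph a `knowledge_graph`.
#' @return list with `n_nodes`, `n_edges`, `nodes_per_type`,
#'   `edges_per_relation`, `prescription_roles` (JSON-ready).
#' @export
graph_summary <- function(graph) {
  list(
    n_nodes = nrow(graph$nodes),
    n_edges = nrow(unique(graph$edges)),
    nodes_per_type = as.list(table(factor(graph$nodes$node_type,
                                          levels = NODE_TYPES))),
    edges_per_relation = as.list(table(factor(graph$edges$relation,
                                              levels = names(RELATION_SCHEMA)))),
    prescription_roles = as.list(table(
      graph$nodes$role[graph$nodes$node_type == "prescription"]
    ))
  )
}
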