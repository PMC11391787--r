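#' @name synthetic
#' @title Synthetic knowledge graphs with planted prescription clusters
#' @description
#' Generates graphs with the statistical shape the similarity method
#' assumes: the node-type proportions of the study dataset (87
#' prescriptions split 20 target / 67 candidate, plus diseases, symptoms,
#' herbs, herb attributes, ingredients and protein targets), and planted
#' clusters of prescriptions that draw part of their herbs, diseases and
#' symptoms from a shared pool. Same-cluster target/candidate pairs are
#' the designated-similar ground truth, so similarity recovery is testable
#' end to end without any external data. Identifiers are opaque
#' (`P001`, `H01`, ...): the generator emulates structure, not
#' pharmacology.
NULL

#' Parameters for the synthetic knowledge-graph generator
#'
#' Defaults keep the study's full prescription split (20 targets, 67
#' candidates, so the pipeline emits the full 1340-pair grid) and scale
#' the remaining node types to roughly one tenth of the study dataset
#' (~1.6k nodes total) so the whole pipeline runs in seconds. The
#' property/flavor/meridian vocabularies stay at their full sizes (5, 12,
#' 12): they are closed pharmacopoeia vocabularies, not samples.
#' `full_scale = TRUE` restores the full dataset scale (~15k nodes).
#'
#' @param n_target,n_candidate prescription counts by role.
#' @param n_disease,n_symptom,n_disease_target,n_herb,n_property,n_flavor,n_meridian,n_category,n_ingredient,n_ingredient_target per-type node counts.
#' @param n_clusters number of planted prescription clusters.
#' @param within_cluster_overlap fraction (0-1) of each prescription's
#'   herb/disease/symptom slots drawn from its cluster's shared pool.
#' @param herbs_per_presc,diseases_per_presc,symptoms_per_presc
#'   attribute-link counts per prescription (`background_degree`).
#' @param full_scale if `TRUE`, override counts with the full dataset
#'   scale.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return a `synthetic_params` list.
#' @export
synthetic_params <- function(n_target = 20L, n_candidate = 67L,
                             n_disease = 9L, n_symptom = 12L,
                             n_disease_target = 1086L,
                             n_herb = 19L, n_property = 5L, n_flavor = 12L,
                             n_meridian = 12L, n_category = 4L,
                             n_ingredient = 130L, n_ingredient_target = 253L,
                             n_clusters = 4L, within_cluster_overlap = 0.8,
                             herbs_per_presc = 5L, diseases_per_presc = 2L,
                             symptoms_per_presc = 4L,
                             full_scale = FALSE, seed = 1L) {
  if (full_scale) {
    n_disease <- 84L; n_symptom <- 113L; n_disease_target <- 10856L
    n_herb <- 183L; n_property <- 5L; n_flavor <- 12L; n_meridian <- 12L
    n_category <- 35L; n_ingredient <- 1294L; n_ingredient_target <- 2529L
  }
  p <- list(n_target = n_target, n_candidate = n_candidate,
            n_disease = n_disease, n_symptom = n_symptom,
            n_disease_target = n_disease_target, n_herb = n_herb,
            n_property = n_property, n_flavor = n_flavor,
            n_meridian = n_meridian, n_category = n_category,
            n_ingredient = n_ingredient,
            n_ingredient_target = n_ingredient_target,
            n_clusters = n_clusters,
            within_cluster_overlap = within_cluster_overlap,
            herbs_per_presc = herbs_per_presc,
            diseases_per_presc = diseases_per_presc,
            symptoms_per_presc = symptoms_per_presc,
            seed = as.integer(seed))
  counts <- unlist(p[startsWith(names(p), "n_")])
  if (any(counts < 1))
    stopf("all counts must be positive", class = "prescsim_parameter_error")
  if (p$within_cluster_overlap < 0 || p$within_cluster_overlap > 1)
    stopf("within_cluster_overlap must lie in [0, 1]",
          class = "prescsim_parameter_error")
  if (p$herbs_per_presc > p$n_herb || p$diseases_per_presc > p$n_disease ||
      p$symptoms_per_presc > p$n_symptom)
    stopf("per-prescription draw exceeds its pool",
          class = "prescsim_parameter_error")
  structure(p, class = "synthetic_params")
}

ids_for <- function(prefix, n) sprintf("%s%0*d", prefix, nchar(n), seq_len(n))

# Draw one prescription's attribute set: the first round(overlap * k)
# elements are the cluster's fixed shared slice, the remainder uniform
# from outside that slice (so overlap = 1 makes same-cluster sets equal).
draw_slots <- function(shared, all_ids, k) {
  extras <- k - length(shared)
  if (extras > 0) {
    free <- setdiff(all_ids, shared)
    c(shared, sample(free, min(extras, length(free))))
  } else shared
}

#' Generate a synthetic knowledge graph with planted clusters
#'
#' Prescriptions (targets and candidates interleaved) are assigned
#' round-robin to `n_clusters` clusters. Each cluster owns a fixed pool of
#' herbs, diseases and symptoms; every member takes
#' `round(overlap * k)` of its k attribute slots from that pool and fills
#' the rest uniformly from the background, so the expected attribute
#' sharing of same-cluster pairs rises with `within_cluster_overlap`.
#' Herbs get 1 property, 1 category, 1-3 flavors and 1-3 meridians;
#' ingredients attach to 1-2 herbs, ingredient targets to 1-2 ingredients
#' and disease targets to a disease, mirroring the layered sparsity of the
#' curated dataset.
#'
#' @param params a [synthetic_params()] list.
#' @return list with `nodes`, `edges` (build_graph-ready data.frames) and
#'   `truth`: cluster assignment per prescription plus the
#'   designated-similar (target, candidate) pairs.
#' @export
simulate_kg <- function(params = synthetic_params()) {
  stopifnot(inherits(params, "synthetic_params"))
  set.seed(derive_seed(params$seed, "simulate"))
  p <- params

  presc <- c(ids_for("PT", p$n_target), ids_for("PC", p$n_candidate))
  roles <- c(rep("target", p$n_target), rep("candidate", p$n_candidate))
  pools <- list(
    disease = ids_for("D", p$n_disease),
    symptom = ids_for("SY", p$n_symptom),
    disease_target = ids_for("DT", p$n_disease_target),
    herb = ids_for("H", p$n_herb),
    property = ids_for("PR", p$n_property),
    flavor = ids_for("FL", p$n_flavor),
    meridian = ids_for("ME", p$n_meridian),
    category = ids_for("CA", p$n_category),
    ingredient = ids_for("IN", p$n_ingredient),
    ingredient_target = ids_for("IT", p$n_ingredient_target)
  )

  nodes <- rbind(
    data.frame(id = presc, node_type = "prescription", label = presc,
               role = roles),
    do.call(rbind, lapply(names(pools), function(tp)
      data.frame(id = pools[[tp]], node_type = tp, label = pools[[tp]],
                 role = "none")))
  )

  # round-robin over an interleaved order so every cluster holds both roles
  cluster <- setNames(rep_len(seq_len(p$n_clusters), length(presc)), presc)

  # Disjoint shared slices: each cluster's pool is a distinct block of a
  # random permutation, so planted clusters are identifiable rather than
  # blurred into each other by pool collisions.
  shared_of <- function(pool, k, what) {
    n_shared <- round(p$within_cluster_overlap * k)
    if (n_shared * p$n_clusters > length(pool))
      stopf("%d clusters x %d shared %s exceed the %d-element pool",
            p$n_clusters, n_shared, what, length(pool),
            class = "prescsim_parameter_error")
    perm <- sample(pool)
    lapply(seq_len(p$n_clusters), function(cl)
      if (n_shared > 0) perm[seq_len(n_shared) + (cl - 1) * n_shared]
      else character(0))
  }
  shared_herb <- shared_of(pools$herb, p$herbs_per_presc, "herbs")
  shared_dis <- shared_of(pools$disease, p$diseases_per_presc, "diseases")
  shared_sym <- shared_of(pools$symptom, p$symptoms_per_presc, "symptoms")

  edge <- function(src, dst, rel)
    data.frame(source = src, target = dst, relation = rel)

  edges <- vector("list", length(presc) + 6)
  k <- 0
  herb_sets <- setNames(vector("list", length(presc)), presc)
  for (pr in presc) {
    cl <- cluster[[pr]]
    herbs <- draw_slots(shared_herb[[cl]], pools$herb, p$herbs_per_presc)
    dis <- draw_slots(shared_dis[[cl]], pools$disease, p$diseases_per_presc)
    sym <- draw_slots(shared_sym[[cl]], pools$symptom, p$symptoms_per_presc)
    herb_sets[[pr]] <- sort(herbs)
    k <- k + 1
    edges[[k]] <- rbind(
      edge(pr, herbs, "prescription-herb"),
      edge(pr, dis, "prescription-disease"),
      edge(pr, sym, "prescription-symptom")
    )
  }

  n_herbs <- length(pools$herb)
  k <- k + 1
  edges[[k]] <- rbind(
    edge(pools$herb, sample(pools$property, n_herbs, replace = TRUE),
         "herb-property"),
    edge(pools$herb, sample(pools$category, n_herbs, replace = TRUE),
         "herb-category")
  )
  # herbs draw 1-3 flavors and 1-3 meridians each
  flav <- lapply(pools$herb, function(h)
    sample(pools$flavor, sample(1:3, 1)))
  merid <- lapply(pools$herb, function(h)
    sample(pools$meridian, sample(1:3, 1)))
  k <- k + 1
  edges[[k]] <- rbind(
    edge(rep(pools$herb, lengths(flav)), unlist(flav), "herb-flavor"),
    edge(rep(pools$herb, lengths(merid)), unlist(merid), "herb-meridian")
  )
  # each ingredient belongs to 1-2 herbs; each ingredient target to 1-2
  # ingredients; each disease target to one disease
  ing_owner <- lapply(pools$ingredient, function(i)
    sample(pools$herb, sample(1:2, 1)))
  k <- k + 1
  edges[[k]] <- edge(rep(pools$ingredient, lengths(ing_owner)),
                     unlist(ing_owner), "herb-ingredient")
  it_owner <- lapply(pools$ingredient_target, function(i)
    sample(pools$ingredient, sample(1:2, 1)))
  k <- k + 1
  edges[[k]] <- edge(rep(pools$ingredient_target, lengths(it_owner)),
                     unlist(it_owner), "ingredient-ingredient_target")
  k <- k + 1
  edges[[k]] <- edge(pools$disease_target,
                     sample(pools$disease, p$n_disease_target, replace = TRUE),
                     "disease-disease_target")

  edges <- do.call(rbind, edges[seq_len(k)])
  # canonical orientation: relation signature order (source type first)
  type_of <- setNames(nodes$node_type, nodes$id)
  swap <- mapply(function(s, t, r) type_of[[s]] != RELATION_SCHEMA[[r]][1],
                 edges$source, edges$target, edges$relation, USE.NAMES = FALSE)
  tmp <- edges$source[swap]
  edges$source[swap] <- edges$target[swap]
  edges$target[swap] <- tmp
  edges <- unique(edges)
  rownames(edges) <- NULL

  targets <- presc[roles == "target"]
  candidates <- presc[roles == "candidate"]
  similar <- expand.grid(target_id = targets, candidate_id = candidates,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  similar <- similar[cluster[similar$target_id] ==
                       cluster[similar$candidate_id], ]
  rownames(similar) <- NULL

  list(nodes = nodes, edges = edges,
       truth = list(clusters = cluster,
                    similar_pairs = similar,
                    herb_sets = herb_sets,
                    params = unclass(params)))
}

#' Cluster-recovery separation score
#'
#' Mean similarity of designated-similar (same-cluster) target/candidate
#' pairs minus the mean over all other pairs. Positive separation means
#' the metric recovers the planted structure.
#'
#' @param similarity_table output of [pairwise_similarity()].
#' @param ground_truth the `truth` element of [simulate_kg()].
#' @return scalar separation score.
#' @export
recovery_metric <- function(similarity_table, ground_truth) {
  sp <- ground_truth$similar_pairs
  if (is.null(sp) || !nrow(sp))
    stopf("ground truth designates no similar pairs",
          class = "prescsim_usage_error")
  key <- function(t, c) paste(t, c, sep = "\r")
  is_similar <- key(similarity_table$target_id,
                    similarity_table$candidate_id) %in%
    key(sp$target_id, sp$candidate_id)
  if (!any(is_similar))
    stopf("no designated pair present in the similarity table",
          class = "prescsim_usage_error")
  mean(similarity_table$value[is_similar]) -
    mean(similarity_table$value[!is_similar])
}
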