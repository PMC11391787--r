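# Fixtures are built in code; nothing is read from disk except through the
# package's own readers (exercised in test-io).

# Minimal typed graph: two prescriptions sharing one herb, with the full
# attribute chain hanging off the herbs.
toy_nodes <- function() {
  data.frame(
    id = c("P1", "P2", "P3", "H1", "H2", "D1", "SY1", "FL1", "PR1", "ME1",
           "CA1", "IN1", "IT1", "DT1"),
    node_type = c("prescription", "prescription", "prescription", "herb",
                  "herb", "disease", "symptom", "flavor", "property",
                  "meridian", "category", "ingredient", "ingredient_target",
                  "disease_target"),
    label = c("P1", "P2", "P3", "H1", "H2", "D1", "SY1", "FL1", "PR1", "ME1",
              "CA1", "IN1", "IT1", "DT1"),
    role = c("target", "candidate", "candidate", rep("none", 11)),
    stringsAsFactors = FALSE
  )
}

toy_edges <- function() {
  data.frame(
    source = c("P1", "P1", "P1", "P2", "P2", "P3", "H1", "H1", "H1", "H1",
               "H1", "IN1", "D1"),
    target = c("H1", "H2", "D1", "H1", "SY1", "H2", "FL1", "PR1", "ME1",
               "CA1", "IN1", "IT1", "DT1"),
    relation = c("prescription-herb", "prescription-herb",
                 "prescription-disease", "prescription-herb",
                 "prescription-symptom", "prescription-herb", "herb-flavor",
                 "herb-property", "herb-meridian", "herb-category",
                 "herb-ingredient", "ingredient-ingredient_target",
                 "disease-disease_target"),
    stringsAsFactors = FALSE
  )
}

toy_graph <- function() build_graph(toy_nodes(), toy_edges())

# Random symmetric binary adjacency with zero diagonal.
random_adjacency <- function(n, p = 0.3) {
  A <- matrix(0, n, n)
  upper <- which(upper.tri(A))
  A[upper] <- rbinom(length(upper), 1, p)
  A + t(A)
}

# Brute-force dense oracle for the normalized propagation matrix,
# independent of the Matrix-based implementation.
dense_normalize <- function(A) {
  At <- A + diag(nrow(A))
  d <- rowSums(At)
  Dm <- diag(1 / sqrt(d), nrow(A))
  Dm %*% At %*% Dm
}

# Element-enumeration Jaccard oracle over an explicit universe.
jaccard_enum_oracle <- function(a, b, universe) {
  inter <- 0; un <- 0
  for (el in universe) {
    ina <- el %in% a; inb <- el %in% b
    if (ina && inb) inter <- inter + 1
    if (ina || inb) un <- un + 1
  }
  if (un == 0) 0 else inter / un
}

# Small planted-cluster graph (~200 nodes) that trains in well under a
# second; used wherever full 1/10 scale is not needed.
mini_synthetic_params <- function(seed = 1L, overlap = 0.8) {
  synthetic_params(
    n_target = 5L, n_candidate = 10L, n_disease = 8L, n_symptom = 10L,
    n_disease_target = 80L, n_herb = 15L, n_category = 4L,
    n_ingredient = 30L, n_ingredient_target = 40L, n_clusters = 2L,
    herbs_per_presc = 4L, diseases_per_presc = 2L, symptoms_per_presc = 3L,
    within_cluster_overlap = overlap, seed = seed
  )
}

mini_graph <- function(seed = 1L, overlap = 0.8) {
  sim <- simulate_kg(mini_synthetic_params(seed = seed, overlap = overlap))
  list(graph = build_graph(sim$nodes, sim$edges), truth = sim$truth)
}
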