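#' @name similarity
#' @title Prescription-pair similarity, summary statistics and screening
#' @description
#' Two complementary views of how alike two prescriptions are: cosine
#' similarity of their learned embedding vectors (sensitive to the whole
#' multidimensional neighborhood, range \[-1, 1\]) and the Jaccard
#' coefficient of their attribute sets (presence/absence of shared
#' diseases, symptoms, herbs and herb attributes, range \[0, 1\]).
#' Similarities are computed for every target x candidate pair, their
#' distribution is summarized (mean, extremes, SD, excess kurtosis,
#' skewness, P25/P75/P95), and high-similarity pairs are retained by an
#' inclusive threshold screen with rule-based exclusions.
NULL

#' Cosine similarity of two vectors
#'
#' `u . v / (||u|| ||v||)`, clipped to `[-1, 1]` against floating-point
#' rounding. A zero-norm vector yields 0 with a warning: a degenerate
#' embedding carries no directional information.
#'
#' @param u,v numeric vectors of equal length.
#' @return scalar in `[-1, 1]`.
#' @export
#' @examples
#' cosine_similarity(c(3, 4), c(3, 4))   # 1
#' cosine_similarity(c(1, 0), c(0, 1))   # 0
cosine_similarity <- function(u, v) {
  if (length(u) != length(v))
    stopf("vector lengths differ: %d vs %d", length(u), length(v),
          class = "prescsim_shape_error")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    warnf("cosine of a zero-norm vector defined as 0")
    return(0)
  }
  min(1, max(-1, sum(u * v) / (nu * nv)))
}

#' Jaccard coefficient of two sets
#'
#' `|a intersect b| / |a union b|`; two empty sets give 0 (no shared
#' features, rather than an error, so degenerate prescriptions survive
#' bulk computation).
#'
#' @param a,b vectors treated as sets (duplicates ignored).
#' @return scalar in `[0, 1]`.
#' @export
#' @examples
#' jaccard_coefficient(c("a", "b", "c"), c("b", "c", "d"))  # 0.5
jaccard_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  un <- length(union(a, b))
  if (un == 0) return(0)
  length(intersect(a, b)) / un
}

#' All target x candidate prescription similarities
#'
#' Emits one record per (target, candidate) prescription pair — with the
#' study's 20 targets and 67 candidates that is 1340 values per metric.
#' Cosine compares embedding vectors (all node information flows into them
#' through the graph); Jaccard compares attribute sets restricted to the
#' non-molecular types (see [attribute_set()]).
#'
#' @param graph a `knowledge_graph` whose prescriptions carry
#'   `"target"`/`"candidate"` roles.
#' @param embeddings an `embedding_set` (required for cosine, ignored for
#'   Jaccard).
#' @param metric `"cosine"` or `"jaccard"`.
#' @param included_types attribute types for the Jaccard sets.
#' @return a `similarity_table` data.frame with columns `target_id`,
#'   `candidate_id`, `metric`, `value`.
#' @export
pairwise_similarity <- function(graph, embeddings = NULL,
                                metric = c("cosine", "jaccard"),
                                included_types = JACCARD_DEFAULT_TYPES) {
  metric <- match.arg(metric)
  pres <- graph$nodes[graph$nodes$node_type == "prescription", ]
  targets <- pres$id[pres$role == "target"]
  candidates <- pres$id[pres$role == "candidate"]
  if (!length(targets) || !length(candidates))
    stopf("graph needs at least one target and one candidate prescription",
          class = "prescsim_usage_error")

  grid <- expand.grid(target_id = targets, candidate_id = candidates,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (metric == "cosine") {
    if (is.null(embeddings))
      stopf("cosine similarity requires trained embeddings",
            class = "prescsim_usage_error")
    H <- embeddings$H
    rown <- rownames(H)
    miss <- setdiff(c(targets, candidates), rown)
    if (length(miss))
      stopf("embeddings lack prescription(s): %s", paste(miss, collapse = ", "),
            class = "prescsim_usage_error")
    # row-normalize once; cosine of every pair is then a dot product
    V <- H[c(targets, candidates), , drop = FALSE]
    nrm <- sqrt(rowSums(V^2))
    zero <- nrm == 0
    if (any(zero)) warnf("cosine of a zero-norm vector defined as 0")
    nrm[zero] <- 1
    V <- V / nrm
    V[zero, ] <- 0
    Ct <- V[targets, , drop = FALSE] %*% t(V[candidates, , drop = FALSE])
    vals <- pmin(1, pmax(-1, Ct[cbind(match(grid$target_id, targets),
                                      match(grid$candidate_id, candidates))]))
  } else {
    sets <- lapply(setNames(nm = c(targets, candidates)), attribute_set,
                   graph = graph, included_types = included_types)
    vals <- mapply(function(t, c) jaccard_coefficient(sets[[t]], sets[[c]]),
                   grid$target_id, grid$candidate_id, USE.NAMES = FALSE)
  }
  out <- data.frame(target_id = grid$target_id,
                    candidate_id = grid$candidate_id,
                    metric = metric, value = vals,
                    stringsAsFactors = FALSE)
  class(out) <- c("similarity_table", "data.frame")
  out
}

#' Distribution summary of similarity values
#'
#' Mean, maximum, minimum, sample standard deviation (n-1 denominator),
#' excess kurtosis and skewness (bias-adjusted sample estimators, so a
#' normal sample scores ~0 kurtosis), and the 25th/75th/95th percentiles
#' by linear interpolation between order statistics.
#'
#' @param values numeric vector (similarity values).
#' @return a `summary_stats` list with fields `mean`, `max`, `min`, `sd`,
#'   `kurtosis`, `skewness`, `p25`, `p75`, `p95`, `n`. With fewer than
#'   two (for sd) or four (for the shape moments) values the undefined
#'   entries are `NA` and flagged via a warning.
#' @export
summary_stats <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 1) stopf("no values to summarize", class = "prescsim_usage_error")
  out <- list(mean = mean(values), max = max(values), min = min(values),
              sd = NA_real_, kurtosis = NA_real_, skewness = NA_real_,
              p25 = unname(quantile(values, 0.25, type = 7)),
              p75 = unname(quantile(values, 0.75, type = 7)),
              p95 = unname(quantile(values, 0.95, type = 7)),
              n = n)
  if (n >= 2) out$sd <- sd(values) else
    warnf("sd undefined for n < 2")
  if (n >= 3 && isTRUE(out$sd > 0)) {
    # bias-adjusted Fisher-Pearson skewness
    g1 <- mean((values - out$mean)^3) / (mean((values - out$mean)^2))^1.5
    out$skewness <- g1 * sqrt(n * (n - 1)) / (n - 2)
  } else warnf("skewness undefined for n < 3 or constant data")
  if (n >= 4 && isTRUE(out$sd > 0)) {
    # bias-adjusted excess kurtosis (normal -> 0)
    g2 <- mean((values - out$mean)^4) / (mean((values - out$mean)^2))^2 - 3
    out$kurtosis <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  } else warnf("kurtosis undefined for n < 4 or constant data")
  structure(out, class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf(paste0("n = %d  mean %.4f  min %.4f  max %.4f  sd %.4f\n",
                     "kurtosis %.4f  skewness %.4f  P25 %.4f  P75 %.4f  P95 %.4f\n"),
              x$n, x$mean, x$min, x$max, x$sd,
              x$kurtosis, x$skewness, x$p25, x$p75, x$p95))
  invisible(x)
}

#' Threshold screen on a similarity table
#'
#' Retains pairs whose value is greater than or equal to the threshold —
#' inclusive, so pairs sitting exactly at the cut (as several do at the
#' cosine 0.77 threshold) are kept.
#'
#' @param table a single-metric `similarity_table`.
#' @param threshold screening threshold (study defaults: cosine 0.77, the
#'   P95 of the cosine distribution; Jaccard 0.50).
#' @return a `screen_result`: list with `metric`, `threshold`, retained
#'   `pairs` and an `excluded` data.frame (empty until
#'   [apply_exclusions()]).
#' @export
screen_pairs <- function(table, threshold) {
  stopifnot(is.data.frame(table), is.numeric(threshold))
  if (length(unique(table$metric)) > 1)
    stopf("screen expects a single-metric table", class = "prescsim_usage_error")
  keep <- table$value >= threshold
  excluded <- table[0, , drop = FALSE]
  excluded$reason <- character(0)
  structure(list(metric = unique(table$metric), threshold = threshold,
                 pairs = table[keep, , drop = FALSE],
                 excluded = excluded),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %s >= %.2f: %d retained, %d excluded\n",
              x$metric, x$threshold, nrow(x$pairs), nrow(x$excluded)))
  invisible(x)
}

#' Remove screened pairs matching exclusion rules
#'
#' After threshold screening, pairs are dropped when either prescription
#' carries an excluded annotation: `pediatric` (pediatric-disease
#' prescriptions limit the universality of later experiments) and
#' `respiratory_only` (prescriptions that only treat cough/asthma-type
#' respiratory disease are likely false positives, since every
#' prescription in the study treats those). Annotations are caller
#' supplied; pairs whose prescriptions lack an annotation row are retained
#' with a warning.
#'
#' @param result a `screen_result`.
#' @param annotations data.frame with columns `prescription_id`,
#'   `pediatric`, `respiratory_only` (logical).
#' @param rules character subset of `c("pediatric", "respiratory_only")`;
#'   an empty vector leaves the result unchanged.
#' @return the updated `screen_result`, excluded pairs tagged with the
#'   first matching rule name.
#' @export
apply_exclusions <- function(result, annotations,
                             rules = c("pediatric", "respiratory_only")) {
  stopifnot(inherits(result, "screen_result"))
  if (!length(rules)) return(result)
  rules <- match.arg(rules, c("pediatric", "respiratory_only"),
                     several.ok = TRUE)
  missing_cols <- setdiff(c("prescription_id", rules), names(annotations))
  if (length(missing_cols))
    stopf("annotations lack column(s): %s", paste(missing_cols, collapse = ", "),
          class = "prescsim_schema_error")

  pairs <- result$pairs
  if (!nrow(pairs)) return(result)
  ann_idx <- match(pairs$target_id, annotations$prescription_id)
  cand_idx <- match(pairs$candidate_id, annotations$prescription_id)
  unannotated <- unique(c(pairs$target_id[is.na(ann_idx)],
                          pairs$candidate_id[is.na(cand_idx)]))
  if (length(unannotated))
    warnf("no annotation for prescription(s) %s; their pairs are retained",
          paste(unannotated, collapse = ", "))

  reason <- rep(NA_character_, nrow(pairs))
  for (rule in rules) {
    flag <- annotations[[rule]]
    hit <- (!is.na(ann_idx) & flag[ann_idx] %in% TRUE) |
           (!is.na(cand_idx) & flag[cand_idx] %in% TRUE)
    reason[is.na(reason) & hit] <- rule
  }
  drop <- !is.na(reason)
  excluded <- pairs[drop, , drop = FALSE]
  excluded$reason <- reason[drop]
  result$pairs <- pairs[!drop, , drop = FALSE]
  result$excluded <- rbind(result$excluded, excluded)
  result
}
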