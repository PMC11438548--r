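#' Construct a condition network object
#'
#' A weighted condition-specific network: the general network's candidate
#' edges with per-edge predicted probabilities, plus the probability
#' threshold defining its unweighted version.
#'
#' @param condition_id string
#' @param edges two-column matrix of protein pairs
#' @param probability numeric vector in (0,1), one per edge
#' @param threshold probability cutoff for the unweighted network
#' @return object of class \code{condition_network}
#' @export
condition_network <- function(condition_id, edges, probability,
                              threshold = 0.39) {
  edges <- canonical_pairs(as.matrix(edges)[, 1], as.matrix(edges)[, 2])
  stopifnot(length(probability) == nrow(edges))
  ord <- order(edge_keys(edges))
  structure(
    list(condition_id = condition_id, edges = edges[ord, , drop = FALSE],
         probability = probability[ord], threshold = threshold,
         nodes = sort(unique(c(edges[, 1], edges[, 2])))),
    class = "condition_network")
}

#' @export
print.condition_network <- function(x, ...) {
  cat(sprintf(
    "condition_network '%s': %d edges, %d above threshold %.2f\n",
    x$condition_id, length(x$probability),
    sum(x$probability >= x$threshold), x$threshold))
  invisible(x)
}

#' Edges of the thresholded (unweighted) network
#' @param net a \code{condition_network}
#' @return two-column character matrix
#' @export
thresholded_edges <- function(net) {
  net$edges[net$probability >= net$threshold, , drop = FALSE]
}

#' Build a condition-specific network from a trained model
#'
#' One forward pass over all candidate edges of the dataset (built from the
#' condition's median-collapsed features); the probability threshold
#' defines the attached unweighted version.
#'
#' @param model a \code{spider_model}
#' @param dataset a \code{spider_dataset} for the target condition
#' @param threshold probability cutoff (default 0.39, the F1-maximizing
#'   value on held-out cell-line data in the original study design)
#' @return a \code{condition_network}
#' @export
build_network <- function(model, dataset, threshold = 0.39) {
  p <- predict(model, dataset)
  condition_network(dataset$condition_id, dataset$net$edges, p, threshold)
}

#' Tissue ontology from a parent-child edge list
#'
#' @param parents two-column matrix/data.frame (parent, child); must form a
#'   single rooted tree
#' @return object of class \code{tissue_ontology} with a parent lookup
#' @export
tissue_ontology <- function(parents) {
  parents <- as.matrix(parents)
  child <- as.character(parents[, 2])
  parent <- as.character(parents[, 1])
  if (anyDuplicated(child)) stop("a node has two parents; not a tree")
  nodes <- unique(c(parent, child))
  roots <- setdiff(parent, child)
  if (length(unique(roots)) != 1) stop("ontology must have a single root")
  pmap <- setNames(parent, child)
  # reject cycles by walking each node to the root
  for (v in nodes) {
    seen <- character(); cur <- v
    while (cur %in% names(pmap)) {
      if (cur %in% seen) stop("cycle in ontology")
      seen <- c(seen, cur); cur <- pmap[[cur]]
    }
  }
  structure(list(parent = pmap, root = unique(roots), nodes = nodes),
            class = "tissue_ontology")
}

ancestor_path <- function(ont, v) {
  path <- v
  while (v %in% names(ont$parent)) {
    v <- ont$parent[[v]]
    path <- c(path, v)
  }
  path
}

#' Ontology distance between two tissues
#'
#' Sum of the path lengths from each tissue to their lowest common
#' ancestor in the tissue-ontology tree.
#'
#' @param ont a \code{tissue_ontology}
#' @param a,b tissue node IDs
#' @return non-negative integer
#' @export
ontology_distance <- function(ont, a, b) {
  if (!(a %in% ont$nodes) || !(b %in% ont$nodes))
    stop("unknown tissue node")
  pa <- ancestor_path(ont, a)
  pb <- ancestor_path(ont, b)
  common <- intersect(pa, pb)
  if (length(common) == 0) stop("no common ancestor")
  lca <- common[1]  # pa is ordered from a up to the root
  (match(lca, pa) - 1L) + (match(lca, pb) - 1L)
}

#' Pearson distance between two condition networks
#'
#' 1 - r between the probability vectors over the shared edge universe.
#'
#' @param na,nb \code{condition_network}s over the same candidate edges
#' @return distance in [0,2]
#' @export
network_distance <- function(na, nb) {
  ka <- edge_keys(na$edges); kb <- edge_keys(nb$edges)
  if (!identical(ka, kb)) {
    shared <- intersect(ka, kb)
    if (length(shared) < 2) stop("networks share too few edges")
    pa <- na$probability[match(shared, ka)]
    pb <- nb$probability[match(shared, kb)]
  } else {
    pa <- na$probability; pb <- nb$probability
  }
  if (sd(pa) == 0 || sd(pb) == 0)
    stop("constant probability vector; Pearson distance undefined")
  1 - cor(pa, pb)
}

#' Correlation between network distances and ontology distances
#'
#' Pearson correlation, over all tissue pairs, between the ontology
#' distance and the Pearson distance of the corresponding condition
#' networks. Requires at least 3 tissues (one pair gives an undefined
#' correlation).
#'
#' @param networks named list of \code{condition_network}s; names are
#'   tissue node IDs in the ontology
#' @param ont a \code{tissue_ontology}
#' @return list(correlation, pairs = data.frame per tissue pair)
#' @export
ontology_correlation <- function(networks, ont) {
  k <- length(networks)
  if (k < 3) stop("need >= 3 tissues; correlation undefined otherwise")
  ids <- names(networks)
  pairs <- t(combn(k, 2))
  od <- numeric(nrow(pairs)); nd <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    od[r] <- ontology_distance(ont, ids[i], ids[j])
    nd[r] <- network_distance(networks[[i]], networks[[j]])
  }
  if (sd(od) == 0 || sd(nd) == 0)
    stop("degenerate distances; correlation undefined")
  list(correlation = cor(od, nd),
       pairs = data.frame(a = ids[pairs[, 1]], b = ids[pairs[, 2]],
                          ontology = od, network = nd))
}

# degree percentile per node over a fixed node universe (mid-rank ties,
# scaled to [0,1]); nodes absent from the edge set have degree 0
degree_percentile <- function(edges, universe) {
  deg <- setNames(numeric(length(universe)), universe)
  if (nrow(edges) > 0) {
    tab <- table(c(edges[, 1], edges[, 2]))
    deg[names(tab)] <- as.numeric(tab)
  }
  rank(deg, ties.method = "average") / length(deg)
}

#' Degree-percentile enrichment of a tissue protein set
#'
#' For every protein of the general network, computes the change in degree
#' percentile between the thresholded condition network and the general
#' network, then compares the changes of the tissue-annotated proteins
#' against all other proteins with a two-sample Wilcoxon rank-sum test
#' (normal approximation with continuity correction when both groups have
#' >= 20 members, exact otherwise).
#'
#' @param net a \code{condition_network}
#' @param general the \code{general_network}
#' @param tissue_proteins character vector of annotated proteins
#' @param min_size minimum annotated-set size after intersection with the
#'   network nodes (default 25); smaller sets are skipped (returns NULL
#'   with a message)
#' @param alternative passed to \code{wilcox.test} (default two-sided)
#' @return list(p_value, median_diff = median delta in tissue set minus
#'   median delta elsewhere, n_tissue) or NULL when skipped
#' @export
degree_enrichment <- function(net, general, tissue_proteins, min_size = 25,
                              alternative = "two.sided") {
  universe <- general$nodes
  in_set <- universe %in% tissue_proteins
  if (sum(in_set) < min_size) {
    message(sprintf("tissue set has %d < %d proteins in the network; skipped",
                    sum(in_set), min_size))
    return(NULL)
  }
  pct_gen <- degree_percentile(general$edges, universe)
  pct_cond <- degree_percentile(thresholded_edges(net), universe)
  delta <- pct_cond - pct_gen
  x <- delta[in_set]; yv <- delta[!in_set]
  if (length(unique(delta)) == 1)
    return(list(p_value = 1, median_diff = 0, n_tissue = sum(in_set)))
  exact <- min(length(x), length(yv)) < 20
  wt <- suppressWarnings(
    wilcox.test(x, yv, alternative = alternative, exact = exact,
                correct = TRUE))
  list(p_value = wt$p.value,
       median_diff = median(x) - median(yv),
       n_tissue = sum(in_set))
}
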