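#' Weighted adjacency matrix of a condition network
#' @keywords internal
adjacency_matrix <- function(net, nodes = NULL) {
  if (is.null(nodes)) nodes <- net$nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  ia <- match(net$edges[, 1], nodes)
  ib <- match(net$edges[, 2], nodes)
  ok <- !is.na(ia) & !is.na(ib)
  A[cbind(ia[ok], ib[ok])] <- net$probability[ok]
  A[cbind(ib[ok], ia[ok])] <- net$probability[ok]
  A
}

#' Network propagation with restart
#'
#' Iterates s <- alpha * W s + (1 - alpha) * p0 to its fixed point, where W
#' is the degree-normalized weighted adjacency (stochastic normalization,
#' W = D^-1 A by default; symmetric normalization D^-1/2 A D^-1/2 as an
#' option) and p0 is uniform over the seed genes. alpha trades network
#' smoothing against the prior (default 0.8). Convergence is guaranteed for
#' alpha < 1.
#'
#' @param net a \code{condition_network} (weighted); probabilities are the
#'   edge weights
#' @param seed_genes character vector of seed nodes (must be in the network)
#' @param alpha restart trade-off in [0,1)
#' @param tolerance L1 convergence tolerance (default 1e-8)
#' @param max_iterations iteration cap (default 1e4)
#' @param normalization "row" (stochastic) or "symmetric"
#' @return named per-gene score vector
#' @export
propagate <- function(net, seed_genes, alpha = 0.8, tolerance = 1e-8,
                      max_iterations = 10000L,
                      normalization = c("row", "symmetric")) {
  normalization <- match.arg(normalization)
  stopifnot(alpha >= 0, alpha < 1)
  nodes <- net$nodes
  seed_genes <- unique(seed_genes)
  if (!all(seed_genes %in% nodes))
    stop("seed genes must be nodes of the network")
  A <- adjacency_matrix(net)
  deg <- rowSums(A)
  if (all(deg[seed_genes] == 0)) {
    warning("all seeds are isolated; returning the restart prior only")
  }
  dinv <- ifelse(deg > 0, 1 / deg, 0)
  W <- if (normalization == "row") A * dinv else {
    dh <- sqrt(dinv)
    (A * dh) * rep(dh, each = nrow(A))
  }
  p0 <- setNames(numeric(length(nodes)), nodes)
  p0[seed_genes] <- 1 / length(seed_genes)
  s <- p0
  for (it in seq_len(max_iterations)) {
    s_new <- alpha * drop(W %*% s) + (1 - alpha) * p0
    if (sum(abs(s_new - s)) < tolerance) {
      s <- s_new
      break
    }
    s <- s_new
  }
  setNames(s, nodes)
}

#' Cross-validated disease-gene prediction by propagation
#'
#' Splits the gene set into folds; each fold is ranked by propagating from
#' the genes of the remaining folds, and the AUROC of held-out members
#' against all non-member genes is recorded (seed genes are excluded from
#' the evaluated ranking). Returns the mean over folds. Gene sets smaller
#' than \code{min_size} after restriction to network nodes are skipped.
#'
#' @param net a \code{condition_network}
#' @param gene_set character vector of disease genes
#' @param folds number of folds (default 3)
#' @param seed integer seed for the fold assignment
#' @param alpha restart trade-off
#' @param min_size minimum usable gene-set size (default 25)
#' @return mean AUROC, or NULL when the set is skipped
#' @export
cv_disease_genes <- function(net, gene_set, folds = 3L, seed = 1L,
                             alpha = 0.8, min_size = 25) {
  genes <- intersect(unique(gene_set), net$nodes)
  if (length(genes) < min_size) {
    message(sprintf("gene set has %d < %d genes in the network; skipped",
                    length(genes), min_size))
    return(NULL)
  }
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), length(genes)))
  aucs <- numeric(folds)
  for (f in seq_len(folds)) {
    held <- genes[fold_of == f]
    seeds <- genes[fold_of != f]
    sc <- propagate(net, seeds, alpha = alpha)
    eval_nodes <- setdiff(net$nodes, seeds)
    y <- as.integer(eval_nodes %in% held)
    aucs[f] <- auroc(sc[eval_nodes], y)
  }
  mean(aucs)
}

#' Co-abundance features from a single sample and its nearest neighbors
#'
#' For datasets with one measurement per sample, the co-abundance of a
#' protein pair is computed over the sample itself plus its k most similar
#' samples (cosine similarity of the samples' protein-abundance vectors).
#'
#' @param sample_id column name of the focal sample in \code{pool}
#' @param pool protein x sample abundance matrix containing the sample
#' @param k number of neighbors (default 5); a smaller pool is used whole,
#'   with a warning
#' @return list(neighbors = selected sample IDs, abundance = protein x
#'   (k+1) matrix restricted to the focal sample and its neighbors)
#' @export
nearest_sample_coabundance <- function(sample_id, pool, k = 5L) {
  stopifnot(sample_id %in% colnames(pool))
  x <- pool[, sample_id]
  others <- setdiff(colnames(pool), sample_id)
  if (length(others) < k) {
    warning(sprintf("pool has %d other samples < k=%d; using all",
                    length(others), k))
    k <- length(others)
  }
  cosine <- vapply(others, function(s) {
    yv <- pool[, s]
    ok <- !is.na(x) & !is.na(yv)
    nx <- sqrt(sum(x[ok]^2)); ny <- sqrt(sum(yv[ok]^2))
    if (nx == 0 || ny == 0) return(-Inf)
    sum(x[ok] * yv[ok]) / (nx * ny)
  }, numeric(1))
  nb <- names(sort(cosine, decreasing = TRUE))[seq_len(k)]
  list(neighbors = nb,
       abundance = pool[, c(sample_id, nb), drop = FALSE])
}

#' Consensus network: edgewise mean of sample-specific networks
#'
#' @param sample_networks list of \code{condition_network}s over the same
#'   candidate edge set
#' @param condition_id ID for the output network
#' @param threshold probability cutoff for the consensus (default: the
#'   first input's threshold)
#' @return a \code{condition_network}
#' @export
consensus_network <- function(sample_networks, condition_id = "consensus",
                              threshold = NULL) {
  stopifnot(length(sample_networks) >= 1)
  k0 <- edge_keys(sample_networks[[1]]$edges)
  probs <- vapply(sample_networks, function(nw) {
    if (!identical(edge_keys(nw$edges), k0))
      stop("sample networks must share the same candidate edge set")
    nw$probability
  }, numeric(length(k0)))
  if (is.null(threshold)) threshold <- sample_networks[[1]]$threshold
  condition_network(condition_id, sample_networks[[1]]$edges,
                    rowMeans(cbind(probs)), threshold)
}

#' Top-K enrichment of a gold-standard gene set in a ranking
#'
#' (n/K) / (|CGC|/N): the fraction of the top K ranked genes that belong to
#' the gold-standard set, relative to the set's background rate among the N
#' network proteins.
#'
#' @param ranked_genes character vector, best first
#' @param cgc gold-standard gene set
#' @param k cutoff (<= N)
#' @param n_network number of proteins N in the network (default: length of
#'   the ranking)
#' @return enrichment ratio (1 = background)
#' @export
driver_enrichment <- function(ranked_genes, cgc, k,
                              n_network = length(ranked_genes)) {
  stopifnot(k >= 1, k <= n_network, length(cgc) >= 1)
  n_hit <- sum(ranked_genes[seq_len(k)] %in% cgc)
  (n_hit / k) / (length(cgc) / n_network)
}

#' Rank candidate driver genes from per-sample mutation profiles
#'
#' Propagates each sample's mutated gene set (point mutations and copy-
#' number alterations as one undifferentiated set) over the consensus
#' network and averages the resulting scores over samples. Seed genes keep
#' their propagation scores.
#'
#' @param consensus a \code{condition_network}
#' @param samples_mutations named list: sample -> character vector of
#'   mutated genes
#' @param alpha restart trade-off
#' @return data.frame(gene, score) sorted by decreasing score
#' @export
score_drivers <- function(consensus, samples_mutations, alpha = 0.8) {
  stopifnot(length(samples_mutations) >= 1)
  total <- setNames(numeric(length(consensus$nodes)), consensus$nodes)
  used <- 0L
  for (mut in samples_mutations) {
    seeds <- intersect(unique(mut), consensus$nodes)
    if (length(seeds) == 0) next
    total <- total + propagate(consensus, seeds, alpha = alpha)
    used <- used + 1L
  }
  if (used == 0) stop("no sample has mutated genes in the network")
  sc <- total / used
  ord <- order(-sc, names(sc))
  data.frame(gene = names(sc)[ord], score = unname(sc)[ord],
             stringsAsFactors = FALSE)
}
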