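#' Node-removal (NR) baseline
#'
#' Keeps only nodes whose genes are expressed at or above the threshold and
#' the edges among them; missing expression counts as unexpressed. For
#' scoring, retained edges get 1 and removed edges 0.
#'
#' @param net a \code{general_network}
#' @param expression named per-gene numeric vector (normalized)
#' @param threshold expression cutoff
#' @return list(nodes, edges = integer indices of retained edges,
#'   scores = 0/1 per edge of \code{net})
#' @export
node_removal <- function(net, expression, threshold) {
  ex <- expression[match(net$nodes, names(expression))]
  ex[is.na(ex)] <- -Inf
  keep_node <- ex >= threshold
  names(keep_node) <- net$nodes
  keep <- keep_node[net$edges[, 1]] & keep_node[net$edges[, 2]]
  list(nodes = net$nodes[keep_node],
       edges = which(keep),
       scores = as.numeric(keep))
}

#' Edge-reweighting (ERW) baseline
#'
#' Multiplies each edge weight by rw^n, where n in 0..2 counts the edge's
#' endpoints whose genes are lowly expressed or unexpressed (below the
#' threshold; missing expression counts as unexpressed).
#'
#' @param net a \code{general_network}
#' @param expression named per-gene numeric vector
#' @param threshold expression cutoff
#' @param rw penalty factor in (0,1], default 0.001
#' @param weights per-edge base weights (default 1)
#' @return numeric score per edge of \code{net}
#' @export
edge_reweight <- function(net, expression, threshold, rw = 0.001,
                          weights = NULL) {
  stopifnot(rw > 0, rw <= 1)
  if (is.null(weights)) weights <- rep(1, n_edges(net))
  ex <- expression[match(net$nodes, names(expression))]
  ex[is.na(ex)] <- -Inf
  low <- ex < threshold
  names(low) <- net$nodes
  n <- as.integer(low[net$edges[, 1]]) + as.integer(low[net$edges[, 2]])
  weights * rw^n
}

#' Calibrated co-abundance baseline
#'
#' Scores each candidate edge by the Pearson correlation of its endpoints'
#' abundance profiles, then calibrates the raw correlations to
#' probabilities with a univariate logistic model whose training label is
#' co-membership of the pair in some annotated protein complex. The
#' monotone link preserves the correlation ranking.
#'
#' @param net a \code{general_network}
#' @param abundance protein x sample matrix (>= 3 samples)
#' @param complexes list of character vectors (complex memberships)
#' @return list(raw = per-edge correlation, calibrated = per-edge
#'   probability, model = fitted glm or NULL if calibration degenerate)
#' @export
coabundance_baseline <- function(net, abundance, complexes) {
  if (ncol(abundance) < 3) stop("need >= 3 samples for co-abundance")
  am <- match(net$edges[, 1], rownames(abundance))
  bm <- match(net$edges[, 2], rownames(abundance))
  raw <- numeric(n_edges(net))
  ok <- which(!is.na(am) & !is.na(bm))
  for (i in ok) raw[i] <- coabundance(abundance[am[i], ], abundance[bm[i], ])

  keys <- edge_keys(net$edges)
  pos_keys <- unlist(lapply(complexes, function(members) {
    members <- intersect(members, net$nodes)
    if (length(members) < 2) return(character())
    pr <- t(combn(sort(members), 2))
    edge_keys(pr)
  }))
  y <- as.integer(keys %in% pos_keys)
  if (all(y == 1) || all(y == 0)) {
    warning("no positive or no negative complex pairs; returning raw correlations")
    return(list(raw = raw, calibrated = raw, model = NULL))
  }
  fit <- glm(y ~ raw, family = binomial())
  list(raw = raw, calibrated = unname(predict(fit, type = "response")),
       model = fit)
}

#' Threshold-sweep evaluation of the NR/ERW baselines
#'
#' The expression threshold is the ranking knob of both unsupervised
#' baselines: each edge receives, as its composite score, the mean of its
#' per-threshold baseline score over the threshold grid (mean survival
#' indicator for NR; mean reweighted score for ERW), and the resulting
#' ranking is scored with the package's ranking metrics.
#'
#' @param net a \code{general_network}
#' @param expression named per-gene numeric vector
#' @param labels 0/1 per edge of \code{net}
#' @param method "nr" or "erw"
#' @param thresholds threshold grid; default: the sorted unique expression
#'   values observed on the network's nodes
#' @param rw ERW penalty factor
#' @return list(auroc, auprc, scores)
#' @export
sweep_threshold <- function(net, expression, labels, method = c("nr", "erw"),
                            thresholds = NULL, rw = 0.001) {
  method <- match.arg(method)
  if (is.null(thresholds)) {
    ex <- expression[match(net$nodes, names(expression))]
    thresholds <- sort(unique(ex[!is.na(ex)]))
  }
  if (length(thresholds) == 0) stop("empty threshold grid")
  scores <- numeric(n_edges(net))
  for (t in thresholds) {
    scores <- scores + if (method == "nr")
      node_removal(net, expression, t)$scores
    else edge_reweight(net, expression, t, rw = rw)
  }
  scores <- scores / length(thresholds)
  list(auroc = auroc(scores, labels), auprc = auprc(scores, labels),
       scores = scores)
}
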