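#' Count assay names into the fixed technique-category vector
#'
#' Maps a vector of assay names (one entry per detection event) onto the
#' 11-category technique vocabulary; names not in the vocabulary fall into
#' the terminal "other" category.
#'
#' @param assays character vector of assay category names
#' @return named integer vector of length 11 (order of
#'   \code{TECHNIQUE_CATEGORIES})
#' @export
technique_vector <- function(assays) {
  assays[!(assays %in% TECHNIQUE_CATEGORIES)] <- "other"
  table(factor(assays, levels = TECHNIQUE_CATEGORIES))
}

#' Min-max normalize a named vector to [0,1]
#'
#' All-identical values map to 0 (degenerate range).
#' @keywords internal
minmax <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (!is.finite(rng[1]) || rng[2] - rng[1] <= 0) {
    x[] <- 0
    return(x)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Normalize gene expression to per-gene values in [0,1]
#'
#' TPM-scale input is first transformed to log2(x+1); log-scale input is
#' used as-is. Samples are collapsed to the per-gene median, then min-max
#' normalized across genes. Genes with no observed sample yield NA (the
#' dataset assembly turns these into a zero feature plus a missingness
#' flag).
#'
#' @param raw gene x sample non-negative numeric matrix (NAs = masked)
#' @param scale "tpm" or "log"
#' @return named numeric vector in [0,1] (NA where fully masked)
#' @export
normalize_expression <- function(raw, scale = c("log", "tpm")) {
  scale <- match.arg(scale)
  m <- as.matrix(raw)
  if (any(m < 0, na.rm = TRUE)) stop("expression values must be non-negative")
  if (scale == "tpm") m <- log2(m + 1)
  med <- apply(m, 1, median, na.rm = TRUE)
  med[is.nan(med)] <- NA_real_
  obs <- !is.na(med)
  if (!any(obs)) return(med)
  out <- med
  out[obs] <- minmax(med[obs])
  out
}

#' Normalize protein abundance to per-protein values in [0,1]
#'
#' Median across samples, then min-max across proteins (no log step).
#' @param raw protein x sample numeric matrix (NAs = masked)
#' @return named numeric vector in [0,1] (NA where fully masked)
#' @export
normalize_abundance <- function(raw) {
  m <- as.matrix(raw)
  med <- apply(m, 1, median, na.rm = TRUE)
  med[is.nan(med)] <- NA_real_
  obs <- !is.na(med)
  if (!any(obs)) return(med)
  out <- med
  out[obs] <- minmax(med[obs])
  out
}

#' Pearson co-abundance of two sample profiles
#'
#' Pearson correlation over the shared (pairwise-complete) samples.
#' Returns 0 when fewer than 3 shared samples are available or either
#' profile has zero variance, keeping the feature total and bounded.
#'
#' @param a,b numeric vectors of equal length
#' @return correlation in [-1,1]
#' @export
coabundance <- function(a, b) {
  if (length(a) != length(b)) stop("profiles must share samples")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) return(0)
  a <- a[ok]; b <- b[ok]
  if (sd(a) == 0 || sd(b) == 0) return(0)
  r <- cor(a, b)
  if (!is.finite(r)) 0 else r
}

#' Localization probability vector of a protein
#'
#' Mass 1/k at each of the protein's k annotated compartments (restricted
#' to the supplied ordered compartment list); the zero vector when the
#' protein has no annotation in the list.
#'
#' @param protein protein ID
#' @param annotations multimap from \code{read_annotations}
#' @param compartments ordered character vector (the compartment universe)
#' @return numeric probability vector of length \code{length(compartments)}
#' @export
localization_vector <- function(protein, annotations, compartments) {
  v <- numeric(length(compartments))
  names(v) <- compartments
  hits <- intersect(annotations[[protein]], compartments)
  if (length(hits)) v[hits] <- 1 / length(hits)
  v
}

#' Co-localization of two localization vectors
#'
#' Pearson correlation of the two vectors; 0 if either vector is constant
#' (including all-zero, i.e. unannotated).
#'
#' @param u,v numeric vectors of equal length >= 2
#' @return correlation in [-1,1]
#' @export
colocalization <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  if (length(u) < 2) stop("vectors must have length >= 2")
  if (sd(u) == 0 || sd(v) == 0) return(0)
  r <- cor(u, v)
  if (!is.finite(r)) 0 else r
}

#' Assemble a labeled candidate-edge dataset for one condition
#'
#' Builds the node features (normalized expression and abundance with
#' missingness indicators, localization vectors), edge features
#' (co-abundance, co-localization, log1p technique counts) and 0/1 labels
#' over the full candidate edge set of the general network. Gold edges that
#' fall outside the candidate universe are dropped with a warning (the
#' general network typically covers only most of a condition's
#' interactions).
#'
#' @param net a \code{general_network}
#' @param profile a \code{condition_profile}
#' @param annotations multimap from \code{read_annotations}
#' @param compartments ordered compartment universe; default: sorted set of
#'   distinct compartments occurring in \code{annotations}
#' @param use_techniques logical; FALSE zeroes the technique block (e.g.
#'   when assay provenance is uninformative for the organism)
#' @return object of class \code{spider_dataset}: node feature matrices,
#'   m x 13 edge feature matrix, labels (NA when no gold standard), and the
#'   underlying network
#' @export
assemble_dataset <- function(net, profile, annotations,
                             compartments = NULL, use_techniques = TRUE) {
  if (n_edges(net) == 0) stop("empty candidate edge set")
  if (is.null(compartments))
    compartments <- sort(unique(unlist(annotations, use.names = FALSE)))
  nodes <- net$nodes
  n <- length(nodes)

  expr <- normalize_expression(profile$gene_expression, profile$scale)
  abund <- normalize_abundance(profile$protein_abundance)
  ex <- expr[match(nodes, names(expr))]
  ab <- abund[match(nodes, names(abund))]
  ex_miss <- as.numeric(is.na(ex)); ex[is.na(ex)] <- 0
  ab_miss <- as.numeric(is.na(ab)); ab[is.na(ab)] <- 0

  loc <- matrix(0, n, length(compartments),
                dimnames = list(nodes, compartments))
  for (p in intersect(names(annotations), nodes))
    loc[p, ] <- localization_vector(p, annotations, compartments)

  edges <- net$edges
  ia <- match(edges[, 1], nodes); ib <- match(edges[, 2], nodes)

  abm <- profile$protein_abundance
  am <- match(edges[, 1], rownames(abm)); bm <- match(edges[, 2], rownames(abm))
  coab <- numeric(nrow(edges))
  both <- which(!is.na(am) & !is.na(bm))
  for (i in both) coab[i] <- coabundance(abm[am[i], ], abm[bm[i], ])

  coloc <- numeric(nrow(edges))
  nz <- rowSums(loc != 0) > 0
  for (i in seq_len(nrow(edges)))
    if (nz[ia[i]] && nz[ib[i]])
      coloc[i] <- colocalization(loc[ia[i], ], loc[ib[i], ])

  tech <- if (use_techniques) log1p(net$technique_counts) else
    matrix(0, nrow(edges), N_TECHNIQUES)
  edge_features <- cbind(coabundance = coab, colocalization = coloc, tech)

  labels <- rep(NA_integer_, nrow(edges))
  if (!is.null(profile$gold_edges)) {
    keys <- edge_keys(edges)
    gk <- edge_keys(profile$gold_edges)
    outside <- sum(!(gk %in% keys))
    if (outside > 0)
      warning(sprintf("%d gold edge(s) outside the candidate universe dropped",
                      outside))
    labels <- as.integer(keys %in% gk)
  }

  structure(
    list(condition_id = profile$condition_id, net = net, nodes = nodes,
         node_features = list(
           expression = cbind(value = unname(ex), missing = ex_miss),
           abundance = cbind(value = unname(ab), missing = ab_miss),
           localization = loc),
         edge_features = edge_features,
         edge_index = cbind(a = ia, b = ib),
         labels = labels, compartments = compartments),
    class = "spider_dataset"
  )
}

#' @export
print.spider_dataset <- function(x, ...) {
  cat(sprintf(
    "spider_dataset '%s': %d nodes, %d candidate edges, %s\n",
    x$condition_id, length(x$nodes), nrow(x$edge_index),
    if (all(is.na(x$labels))) "unlabeled"
    else sprintf("positive rate %.3f", mean(x$labels))))
  invisible(x)
}
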