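#' Canonicalize an edge table
#'
#' Orders each pair lexicographically and returns a two-column character
#' matrix. Self-loops are kept here; callers decide how to treat them.
#'
#' @param a,b character vectors of endpoint IDs
#' @return m x 2 character matrix with a <= b per row
#' @keywords internal
canonical_pairs <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  cbind(a, b, deparse.level = 0)
}

#' Edge key strings ("a|b") for canonical pairs
#' @keywords internal
edge_keys <- function(pairs) paste(pairs[, 1], pairs[, 2], sep = "|")

#' Construct a general PPI network object
#'
#' The general network is the condition-agnostic candidate universe of
#' interactions. Edges are stored once, under lexicographic endpoint order,
#' with an optional per-edge vector of detection-technique counts over the
#' 11 assay categories.
#'
#' @param edges two-column matrix/data.frame of protein IDs
#' @param technique_counts optional numeric matrix (one row per edge, 11
#'   columns); duplicate edges have their counts summed
#' @param nodes optional superset of node IDs (isolated nodes allowed)
#' @return an object of class \code{general_network} with elements
#'   \code{nodes} (sorted character vector), \code{edges} (m x 2 character
#'   matrix, canonical order, sorted by key) and \code{technique_counts}
#'   (m x 11 matrix)
#' @export
general_network <- function(edges, technique_counts = NULL, nodes = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) < 2) stop("edges must have two columns")
  pairs <- canonical_pairs(edges[, 1], edges[, 2])
  loop <- pairs[, 1] == pairs[, 2]
  if (any(loop)) {
    warning(sprintf("dropping %d self-loop(s)", sum(loop)))
    pairs <- pairs[!loop, , drop = FALSE]
    if (!is.null(technique_counts))
      technique_counts <- technique_counts[!loop, , drop = FALSE]
  }
  if (is.null(technique_counts)) {
    technique_counts <- matrix(0, nrow(pairs), N_TECHNIQUES)
  } else {
    technique_counts <- as.matrix(technique_counts)
    if (nrow(technique_counts) != nrow(pairs))
      stop("technique_counts must have one row per edge")
    if (any(technique_counts < 0))
      stop("technique counts must be non-negative")
  }
  keys <- edge_keys(pairs)
  if (anyDuplicated(keys)) {
    grp <- match(keys, unique(keys))
    technique_counts <- rowsum(technique_counts, grp, reorder = TRUE)
    pairs <- pairs[!duplicated(keys), , drop = FALSE]
    keys <- unique(keys)
  }
  ord <- order(keys)
  pairs <- pairs[ord, , drop = FALSE]
  technique_counts <- technique_counts[ord, , drop = FALSE]
  colnames(technique_counts) <- TECHNIQUE_CATEGORIES
  all_nodes <- sort(unique(c(pairs[, 1], pairs[, 2], as.character(nodes))))
  structure(
    list(nodes = all_nodes, edges = pairs,
         technique_counts = technique_counts),
    class = "general_network"
  )
}

#' @export
print.general_network <- function(x, ...) {
  cat(sprintf("general_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of edges in a general network
#' @param net a \code{general_network}
#' @export
n_edges <- function(net) nrow(net$edges)

#' Read a general network from a TSV edge list
#'
#' Expects at least two columns (protein IDs). With
#' \code{has_technique_columns = TRUE}, 11 additional integer columns of
#' per-assay detection counts follow. Duplicate rows are merged (counts
#' summed); self-loop rows are dropped with a warning.
#'
#' @param path file path
#' @param has_technique_columns logical
#' @param header logical; does the file carry a header row
#' @return a \code{general_network}
#' @export
read_edge_list <- function(path, has_technique_columns = FALSE,
                           header = FALSE) {
  if (length(readLines(path, n = 1)) == 0)
    return(general_network(matrix(character(), 0, 2)))
  df <- tryCatch(
    read.delim(path, header = header, colClasses = "character",
               stringsAsFactors = FALSE, blank.lines.skip = TRUE),
    error = function(e) stop("cannot parse edge list: ", conditionMessage(e))
  )
  if (nrow(df) == 0)
    return(general_network(matrix(character(), 0, 2)))
  need <- if (has_technique_columns) 2 + N_TECHNIQUES else 2
  if (ncol(df) < need)
    stop(sprintf("edge list needs %d columns, found %d", need, ncol(df)))
  tc <- NULL
  if (has_technique_columns) {
    tc <- matrix(NA_real_, nrow(df), N_TECHNIQUES)
    for (j in seq_len(N_TECHNIQUES)) {
      v <- suppressWarnings(as.numeric(df[[2 + j]]))
      bad <- which(is.na(v) & !is.na(df[[2 + j]]) & df[[2 + j]] != "NA")
      if (length(bad))
        stop(sprintf("malformed technique count at line %d", bad[1]))
      tc[, j] <- v
    }
    if (anyNA(tc)) stop("missing technique counts are not allowed")
    if (any(tc < 0)) stop("negative technique count")
  }
  general_network(cbind(df[[1]], df[[2]]), technique_counts = tc)
}

#' Read a numeric gene x sample (or protein x sample) matrix from TSV
#'
#' First column holds row IDs, header holds sample IDs. Cells that are
#' empty or "NA" are masked (NA), never zero-filled; non-numeric cells are
#' a parse error.
#'
#' @param path file path
#' @return numeric matrix with dimnames
#' @export
read_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix file needs row IDs plus >=1 sample column")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate row IDs: ", paste(unique(ids[duplicated(ids)]),
                                      collapse = ", "))
  m <- matrix(NA_real_, nrow(df), ncol(df) - 1,
              dimnames = list(ids, colnames(df)[-1]))
  for (j in seq_len(ncol(df) - 1)) {
    raw <- df[[j + 1]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & !(raw %in% c("", "NA", "NaN")) & !is.na(raw))
    if (length(bad))
      stop(sprintf("non-numeric cell '%s' at row %d, column %d",
                   raw[bad[1]], bad[1], j + 1))
    m[, j] <- v
  }
  m
}

#' Write a numeric matrix as TSV (inverse of read_matrix)
#' @param m numeric matrix with dimnames
#' @param path file path
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein-to-compartment annotation table
#'
#' Two-column TSV (protein, compartment). Returns a multimap as a named
#' list of character vectors; duplicated rows are stored once. Proteins
#' absent from the file simply have no entry (treated as the empty set).
#'
#' @param path file path
#' @return named list: protein ID -> character vector of compartments
#' @export
read_annotations <- function(path) {
  df <- read.delim(path, header = FALSE, colClasses = "character",
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(structure(list(), names = character()))
  if (ncol(df) < 2) stop("annotation file needs two columns")
  df <- unique(df[, 1:2])
  split(df[[2]], df[[1]])
}

#' Construct a condition profile
#'
#' Bundles one condition's gene-expression matrix (with a scale tag),
#' protein-abundance matrix and, for training conditions, the gold-standard
#' set of condition-specific edges.
#'
#' @param condition_id string
#' @param gene_expression gene x sample numeric matrix; non-negative on the
#'   declared scale
#' @param protein_abundance protein x sample numeric matrix
#' @param gold_edges optional two-column matrix of protein pairs
#' @param scale "tpm" (log2(x+1) applied during normalization) or "log"
#' @return object of class \code{condition_profile}
#' @export
condition_profile <- function(condition_id, gene_expression,
                              protein_abundance, gold_edges = NULL,
                              scale = c("log", "tpm")) {
  scale <- match.arg(scale)
  if (ncol(gene_expression) < 1 || ncol(protein_abundance) < 1)
    stop("at least one sample is required")
  if (!is.null(gold_edges)) {
    gold_edges <- canonical_pairs(as.matrix(gold_edges)[, 1],
                                  as.matrix(gold_edges)[, 2])
    gold_edges <- gold_edges[!duplicated(edge_keys(gold_edges)), ,
                             drop = FALSE]
  }
  structure(
    list(condition_id = condition_id, gene_expression = gene_expression,
         protein_abundance = protein_abundance, gold_edges = gold_edges,
         scale = scale),
    class = "condition_profile"
  )
}

#' Run configuration
#'
#' Collects the tunable knobs of a full run: model hyperparameters, node
#' split fractions, seeding, the edge probability threshold used to
#' binarize predicted networks, the propagation restart trade-off alpha,
#' the edge-reweighting penalty rw and the expression threshold defining
#' "expressed".
#'
#' @param embedding_size protein embedding dimension
#' @param learning_rate Adam learning rate
#' @param dropout dropout probability of the feed-forward blocks
#' @param epochs training epochs
#' @param weight_decay Adam L2 weight decay
#' @param split_fractions train/validation/test node fractions (sum to 1)
#' @param seed integer seed governing split, initialization and sampling
#' @param edge_threshold probability cutoff for the unweighted network
#' @param alpha propagation smoothing-vs-prior trade-off in [0,1)
#' @param rw edge-reweighting penalty factor in (0,1]
#' @param expression_threshold normalized-expression cutoff for "expressed"
#' @return object of class \code{run_config}
#' @export
run_config <- function(embedding_size = 64, learning_rate = 1e-3,
                       dropout = 0.3, epochs = 750, weight_decay = 0.01,
                       split_fractions = c(0.70, 0.15, 0.15), seed = 1L,
                       edge_threshold = 0.39, alpha = 0.8, rw = 0.001,
                       expression_threshold = 0.2) {
  stopifnot(abs(sum(split_fractions) - 1) < 1e-8,
            learning_rate > 0, learning_rate <= 1,
            dropout >= 0, dropout < 1,
            alpha >= 0, alpha < 1,
            rw > 0, rw <= 1)
  structure(
    list(embedding_size = as.integer(embedding_size),
         learning_rate = learning_rate, dropout = dropout,
         epochs = as.integer(epochs), weight_decay = weight_decay,
         split_fractions = split_fractions, seed = as.integer(seed),
         edge_threshold = edge_threshold, alpha = alpha, rw = rw,
         expression_threshold = expression_threshold),
    class = "run_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' Fields mirror \code{run_config()}; absent fields keep their defaults.
#'
#' @param path file path (.json parsed with jsonlite, otherwise YAML)
#' @return object of class \code{run_config}
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  }
  known <- names(formals(run_config))
  do.call(run_config, vals[intersect(names(vals), known)])
}

#' Write a predicted condition network to TSV
#'
#' Columns: protein_a, protein_b, probability (>= 6 decimals),
#' passes_threshold (0/1). \code{read_condition_network} inverts it.
#'
#' @param net a \code{condition_network}
#' @param path file path
#' @export
write_condition_network <- function(net, path) {
  df <- data.frame(
    protein_a = net$edges[, 1], protein_b = net$edges[, 2],
    probability = sprintf("%.8f", net$probability),
    passes_threshold = as.integer(net$probability >= net$threshold),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a condition network written by write_condition_network
#' @param path file path
#' @param condition_id optional ID to attach
#' @param threshold probability threshold; if NULL, recovered as the
#'   smallest probability flagged as passing (1 if none pass)
#' @return a \code{condition_network}
#' @export
read_condition_network <- function(path, condition_id = "condition",
                                   threshold = NULL) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "numeric",
                                  "integer"))
  if (is.null(threshold)) {
    threshold <- if (any(df$passes_threshold == 1))
      min(df$probability[df$passes_threshold == 1]) else 1
  }
  condition_network(condition_id,
                    edges = cbind(df$protein_a, df$protein_b),
                    probability = df$probability, threshold = threshold)
}
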