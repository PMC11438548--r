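# Synthetic inputs with a planted, recoverable condition-specific
# interaction rule. The generator emulates the statistical shape of the
# real inputs: a general candidate network with per-assay detection counts,
# per-condition expression/abundance replicates, GO-style compartment
# annotations, gold-standard condition edges, a condition similarity tree,
# and disease/driver gene sets. The planted edge-activity rule combines
# endpoint expression, co-localization and co-abundance, so part of the
# signal is invisible to expression-only baselines by construction.

#' Configuration of the synthetic-data generator
#'
#' @param n_proteins number of proteins (default 600)
#' @param n_edges number of candidate edges (default 5000)
#' @param n_conditions number of conditions, laid out as leaves of a
#'   balanced binary similarity tree (default 2)
#' @param n_samples replicate samples per condition (default 5)
#' @param n_compartments localization compartment universe size (default 63)
#' @param rule_weights named weights of the planted activity rule
#'   (expression, colocalization, coabundance)
#' @param noise_sd logit noise of the planted rule (default 0.25)
#' @param label_flip_rate fraction of gold labels flipped (default 0.02)
#' @param positive_rate target fraction of active edges per condition
#' @param branch_sd per-tree-edge drift of latent expression (default 0.6)
#' @param module_size proteins per co-abundance module (default 20)
#' @param expr_sample_sd replicate noise of expression samples
#' @param abund_sample_sd replicate noise of abundance samples
#' @param degree_model "uniform" (G(n,m)) or "powerlaw"
#' @param seed integer master seed
#' @return object of class \code{synth_config}
#' @export
synth_config <- function(n_proteins = 600L, n_edges = 5000L,
                         n_conditions = 2L, n_samples = 5L,
                         n_compartments = 63L,
                         rule_weights = c(expression = 3, colocalization = 2,
                                          coabundance = 2),
                         noise_sd = 0.25, label_flip_rate = 0.02,
                         positive_rate = 0.15, branch_sd = 0.6,
                         module_size = 20L, expr_sample_sd = 0.5,
                         abund_sample_sd = 0.3,
                         degree_model = c("uniform", "powerlaw"),
                         seed = 1L) {
  degree_model <- match.arg(degree_model)
  stopifnot(n_proteins > 0, n_edges > 0, n_conditions > 0, n_samples > 0,
            label_flip_rate >= 0, label_flip_rate < 0.5,
            positive_rate > 0, positive_rate < 1)
  structure(
    list(n_proteins = as.integer(n_proteins), n_edges = as.integer(n_edges),
         n_conditions = as.integer(n_conditions),
         n_samples = as.integer(n_samples),
         n_compartments = as.integer(n_compartments),
         rule_weights = rule_weights, noise_sd = noise_sd,
         label_flip_rate = label_flip_rate, positive_rate = positive_rate,
         branch_sd = branch_sd, module_size = as.integer(module_size),
         expr_sample_sd = expr_sample_sd, abund_sample_sd = abund_sample_sd,
         degree_model = degree_model, seed = as.integer(seed)),
    class = "synth_config")
}

synth_protein_ids <- function(cfg)
  sprintf("P%04d", seq_len(cfg$n_proteins))

#' Generate the synthetic general network
#'
#' A random graph over the configured protein universe (uniform G(n,m) or
#' power-law degree distribution) with sparse random technique-count
#' vectors over the 11 assay categories.
#'
#' @param cfg a \code{synth_config}
#' @return a \code{general_network}
#' @export
generate_general_network <- function(cfg) {
  set.seed(cfg$seed)
  ids <- synth_protein_ids(cfg)
  g <- if (cfg$degree_model == "uniform") {
    igraph::sample_gnm(cfg$n_proteins, cfg$n_edges)
  } else {
    igraph::sample_fitness_pl(cfg$n_proteins, cfg$n_edges, 2.5)
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- cbind(ids[el[, 1]], ids[el[, 2]])
  tc <- matrix(rpois(nrow(edges) * N_TECHNIQUES, 0.4),
               nrow(edges), N_TECHNIQUES)
  # every edge was detected at least once somewhere
  none <- rowSums(tc) == 0
  tc[cbind(which(none),
           sample.int(N_TECHNIQUES, sum(none), replace = TRUE))] <- 1
  general_network(edges, technique_counts = tc, nodes = ids)
}

#' Balanced binary similarity tree over the conditions
#'
#' Conditions are the leaves \code{cond_1..cond_k}; internal nodes are
#' \code{anc_*} with a single root. For one condition the tree degenerates
#' to a root-leaf pair.
#'
#' @param cfg a \code{synth_config}
#' @return list(parents = two-column matrix (parent, child), leaves)
#' @export
synth_condition_tree <- function(cfg) {
  k <- cfg$n_conditions
  leaves <- sprintf("cond_%d", seq_len(k))
  if (k == 1)
    return(list(parents = cbind("anc_root", leaves), leaves = leaves))
  nodes <- as.list(leaves)
  parents <- NULL
  counter <- 0L
  while (length(nodes) > 1) {
    nxt <- list()
    i <- 1
    while (i <= length(nodes)) {
      if (i + 1 <= length(nodes)) {
        counter <- counter + 1L
        anc <- if (length(nodes) == 2) "anc_root" else
          sprintf("anc_%d", counter)
        parents <- rbind(parents, cbind(anc, c(nodes[[i]][1],
                                               nodes[[i + 1]][1])))
        nxt[[length(nxt) + 1]] <- anc
        i <- i + 2
      } else {
        nxt[[length(nxt) + 1]] <- nodes[[i]]
        i <- i + 1
      }
    }
    nodes <- nxt
  }
  list(parents = parents, leaves = leaves)
}

# Deterministic shared structure: compartment annotations, co-abundance
# modules, and the latent per-condition expression levels obtained by a
# Gaussian walk along the condition tree. Recomputed identically from the
# master seed on every call.
synth_shared <- function(cfg, net) {
  ids <- synth_protein_ids(cfg)
  set.seed(cfg$seed + 104729L)
  compartments <- sprintf("C%02d", seq_len(cfg$n_compartments))
  n_ann <- sample(1:3, cfg$n_proteins, replace = TRUE)
  annotations <- lapply(seq_len(cfg$n_proteins), function(i)
    sort(sample(compartments, n_ann[i])))
  names(annotations) <- ids

  module <- ((seq_len(cfg$n_proteins) - 1L) %/% cfg$module_size) + 1L
  module <- sample(module)  # membership decoupled from ID order
  names(module) <- ids

  tree <- synth_condition_tree(cfg)
  ont <- tissue_ontology(tree$parents)
  z_root <- rnorm(cfg$n_proteins)
  walk <- new.env()
  assign(ont$root, z_root, envir = walk)
  fill <- function(node) {
    for (child in tree$parents[tree$parents[, 1] == node, 2]) {
      assign(child, get(node, envir = walk) +
               rnorm(cfg$n_proteins, 0, cfg$branch_sd), envir = walk)
      fill(child)
    }
  }
  fill(ont$root)
  latent <- lapply(tree$leaves, function(l)
    setNames(plogis(get(l, envir = walk)), ids))
  names(latent) <- tree$leaves

  loc <- matrix(0, cfg$n_proteins, cfg$n_compartments,
                dimnames = list(ids, compartments))
  for (i in seq_len(cfg$n_proteins))
    loc[i, annotations[[i]]] <- 1 / n_ann[i]

  list(ids = ids, compartments = compartments, annotations = annotations,
       module = module, tree = tree, ontology = ont, latent = latent,
       localization = loc)
}

# planted activity logit for every candidate edge of `net` in condition c.
# An optional "technique" rule weight adds a detection-count component
# (absent from the default rule); it supports transfer benchmarks where the
# target condition depends on a signal the source rule ignores.
planted_logit <- function(cfg, net, shared, condition, noise = TRUE) {
  e <- shared$latent[[condition]]
  ia <- net$edges[, 1]; ib <- net$edges[, 2]
  expr_term <- pmin(e[ia], e[ib])
  coloc <- vapply(seq_len(n_edges(net)), function(i)
    colocalization(shared$localization[ia[i], ],
                   shared$localization[ib[i], ]), numeric(1))
  same_mod <- as.numeric(shared$module[ia] == shared$module[ib])
  w <- cfg$rule_weights
  lg <- w[["expression"]] * expr_term +
    w[["colocalization"]] * pmax(coloc, 0) +
    w[["coabundance"]] * same_mod
  if ("technique" %in% names(w) && w[["technique"]] != 0) {
    tech <- log1p(rowSums(net$technique_counts))
    lg <- lg + w[["technique"]] * tech / max(tech)
  }
  if (noise) lg <- lg + rnorm(length(lg), 0, cfg$noise_sd)
  unname(lg)
}

#' Generate one synthetic condition
#'
#' Draws replicate expression and abundance samples around the condition's
#' latent levels (co-abundance structure induced by shared per-module
#' latent sample factors), computes the planted activity logit for every
#' candidate edge (high when both endpoints are expressed, co-localized and
#' co-abundant), thresholds it at the configured positive rate to obtain
#' the gold-standard edge set, and flips labels at the configured rate.
#' Conditions are tied together by the similarity tree, so sibling
#' conditions share more gold edges than distant ones.
#'
#' @param cfg a \code{synth_config}
#' @param net the \code{general_network} from \code{generate_general_network}
#' @param condition_index integer in 1..n_conditions
#' @param rule_weights optional override of the planted rule weights for
#'   this condition (e.g. to create a shifted target condition for
#'   transfer-learning benchmarks)
#' @return list(profile = \code{condition_profile}, annotations,
#'   compartments, truth = list(latent expression, logits, gold keys))
#' @export
generate_condition <- function(cfg, net, condition_index = 1L,
                               rule_weights = NULL) {
  stopifnot(condition_index >= 1, condition_index <= cfg$n_conditions)
  shared <- synth_shared(cfg, net)
  cond <- shared$tree$leaves[condition_index]
  ccfg <- cfg
  if (!is.null(rule_weights)) ccfg$rule_weights <- rule_weights

  set.seed(cfg$seed + 9973L * condition_index)
  e <- shared$latent[[cond]]
  n <- cfg$n_proteins
  ns <- cfg$n_samples

  # expression replicates on log scale (median ~ 8 * latent level)
  expr <- matrix(pmax(0, 8 * e + rnorm(n * ns, 0, cfg$expr_sample_sd)),
                 n, ns, dimnames = list(shared$ids,
                                        sprintf("%s_s%d", cond, 1:ns)))

  # abundance: per-module latent sample factor plants co-abundance
  ab_level <- pmin(1, pmax(0, e + rnorm(n, 0, 0.3)))
  zmod <- matrix(rnorm(max(shared$module) * ns), max(shared$module), ns)
  abund <- matrix(0, n, ns, dimnames = dimnames(expr))
  for (s in seq_len(ns))
    abund[, s] <- pmax(0, 4 * ab_level + zmod[shared$module, s] +
                         rnorm(n, 0, cfg$abund_sample_sd))

  lg <- planted_logit(ccfg, net, shared, cond, noise = TRUE)
  cut <- quantile(lg, 1 - cfg$positive_rate)
  gold <- lg >= cut
  flip <- runif(length(gold)) < cfg$label_flip_rate
  gold <- xor(gold, flip)

  profile <- condition_profile(
    condition_id = cond, gene_expression = expr, protein_abundance = abund,
    gold_edges = net$edges[gold, , drop = FALSE], scale = "log")
  list(profile = profile, annotations = shared$annotations,
       compartments = shared$compartments,
       truth = list(latent_expression = e, logit = lg,
                    gold_keys = edge_keys(net$edges[gold, , drop = FALSE]),
                    module = shared$module, tree = shared$tree))
}

#' Planted disease/driver gene sets and per-sample mutation profiles
#'
#' The disease set is a connected module grown by breadth-first search in
#' the condition's gold-standard network; the driver module is grown the
#' same way from a different start. Per-sample mutation sets are noisy
#' subsamples of the *observed half* of the driver module plus random
#' decoy genes; the other half of the module is never mutated in any
#' sample, so ranking it highly requires network proximity rather than
#' seed membership — that held-back half is what makes driver-enrichment
#' comparisons between networks informative. The gold-standard driver list
#' (CGC analog) is the full driver module plus decoys.
#'
#' @param cfg a \code{synth_config}
#' @param condition output of \code{generate_condition}
#' @param net the \code{general_network}
#' @param set_size target module size (default 40)
#' @param n_mut_samples number of mutation profiles (default 20)
#' @return list(disease_genes, driver_module, cgc, samples_mutations)
#' @export
generate_disease_and_driver_sets <- function(cfg, condition, net,
                                             set_size = 40L,
                                             n_mut_samples = 20L) {
  gold <- condition$profile$gold_edges
  if (is.null(gold) || nrow(gold) == 0) stop("condition has no gold edges")
  g <- igraph::graph_from_edgelist(gold, directed = FALSE)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  core <- names(comp$membership)[comp$membership == big]
  if (length(core) < 2 * set_size)
    stop("gold network too sparse for the requested module size")

  set.seed(cfg$seed + 524287L)
  grow <- function(start) {
    bfs <- igraph::bfs(g, root = start, unreachable = FALSE)$order
    ids <- names(bfs)[!is.na(bfs)]
    ids[seq_len(min(set_size, length(ids)))]
  }
  deg <- igraph::degree(g)[core]
  start1 <- names(sort(deg, decreasing = TRUE))[1]
  disease <- grow(start1)
  remaining <- setdiff(core, disease)
  start2 <- names(sort(igraph::degree(g)[remaining], decreasing = TRUE))[1]
  driver <- grow(start2)

  decoys <- sample(setdiff(net$nodes, c(disease, driver)), set_size)
  cgc <- sort(c(driver, decoys[seq_len(max(1L, set_size %/% 4L))]))

  observed <- driver[seq_len(ceiling(length(driver) / 2))]
  samples_mutations <- lapply(seq_len(n_mut_samples), function(i) {
    hit <- observed[runif(length(observed)) < 0.5]
    noise <- sample(setdiff(net$nodes, driver), 10)
    sort(unique(c(hit, noise)))
  })
  names(samples_mutations) <- sprintf("sample_%02d", seq_len(n_mut_samples))

  list(disease_genes = sort(disease), driver_module = sort(driver),
       cgc = cgc, samples_mutations = samples_mutations)
}

#' Write a complete synthetic input bundle to disk
#'
#' Emits the general network (with technique counts), per-condition
#' expression/abundance matrices and gold edge lists, the annotation table,
#' the condition tree, and a JSON manifest of the planted ground truth.
#' Every file parses back through the package's readers.
#'
#' @param cfg a \code{synth_config}
#' @param out_dir output directory (created if needed)
#' @return invisibly, the manifest list
#' @export
simulate_bundle <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  net <- generate_general_network(cfg)
  write.table(cbind(net$edges, net$technique_counts),
              file.path(out_dir, "general_network.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  manifest <- list(config = unclass(cfg), conditions = list())
  ann_written <- FALSE
  for (ci in seq_len(cfg$n_conditions)) {
    cond <- generate_condition(cfg, net, ci)
    id <- cond$profile$condition_id
    write_matrix(cond$profile$gene_expression,
                 file.path(out_dir, sprintf("%s_expression.tsv", id)))
    write_matrix(cond$profile$protein_abundance,
                 file.path(out_dir, sprintf("%s_abundance.tsv", id)))
    write.table(cond$profile$gold_edges,
                file.path(out_dir, sprintf("%s_gold_edges.tsv", id)),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    if (!ann_written) {
      ann <- do.call(rbind, lapply(names(cond$annotations), function(p)
        cbind(p, cond$annotations[[p]])))
      write.table(ann, file.path(out_dir, "annotations.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE, col.names = FALSE)
      write.table(cond$truth$tree$parents,
                  file.path(out_dir, "condition_tree.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE, col.names = FALSE)
      ann_written <- TRUE
    }
    manifest$conditions[[id]] <- list(
      n_gold = length(cond$truth$gold_keys),
      positive_rate = length(cond$truth$gold_keys) / n_edges(net))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
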