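#' Model hyperparameters
#'
#' Defaults are the selected configuration: embedding size 64, learning
#' rate 1e-3, dropout 0.3, 750 epochs, Adam weight decay 0.01.
#'
#' @param embedding_size protein embedding dimension
#' @param learning_rate Adam learning rate
#' @param dropout dropout probability inside the feed-forward blocks
#' @param epochs number of training epochs (full passes over the train
#'   edges)
#' @param weight_decay Adam L2 penalty
#' @param batches mini-batches per epoch (default 2; 1 = full-batch). More
#'   batches mean more optimizer steps per epoch at the same epoch budget.
#' @return object of class \code{spider_hyperparameters}
#' @export
spider_hyperparameters <- function(embedding_size = 64L,
                                   learning_rate = 1e-3, dropout = 0.3,
                                   epochs = 750L, weight_decay = 0.01,
                                   batches = 2L) {
  structure(list(embedding_size = as.integer(embedding_size),
                 learning_rate = learning_rate, dropout = dropout,
                 epochs = as.integer(epochs), weight_decay = weight_decay,
                 batches = max(1L, as.integer(batches))),
            class = "spider_hyperparameters")
}

#' The default hyperparameter search grid
#' @return list of vectors to be crossed by \code{tune_spider}
#' @export
default_grid <- function() {
  list(embedding_size = c(32L, 64L, 128L),
       learning_rate = c(1e-3, 5e-4, 1e-4),
       dropout = c(0.2, 0.3, 0.4),
       epochs = c(500L, 750L, 1000L))
}

#' Node-based train/validation/test split
#'
#' Nodes are partitioned uniformly at random into train/validation/test
#' groups (default 70/15/15); an edge belongs to a split iff both its
#' endpoints do, so cross-split edges belong to no split (the standard
#' leakage control for link classification).
#'
#' @param net a \code{general_network}
#' @param fractions length-3 fractions summing to 1
#' @param seed integer seed
#' @param labels optional 0/1 labels per edge of \code{net}; when given,
#'   every split must contain at least one positive and one negative edge
#' @return object of class \code{node_split}: \code{assignment} (named
#'   factor over nodes) and integer index vectors \code{train_edges},
#'   \code{val_edges}, \code{test_edges} into the edge table of \code{net}
#' @export
split_nodes <- function(net, fractions = c(0.70, 0.15, 0.15), seed = 1L,
                        labels = NULL) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  nodes <- net$nodes
  n <- length(nodes)
  set.seed(seed)
  perm <- sample.int(n)
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  grp <- rep("test", n)
  grp[perm <= n_train] <- "train"
  grp[perm > n_train & perm <= n_train + n_val] <- "validation"
  assignment <- factor(grp, levels = c("train", "validation", "test"))
  names(assignment) <- nodes

  ga <- assignment[net$edges[, 1]]
  gb <- assignment[net$edges[, 2]]
  split <- structure(
    list(assignment = assignment,
         train_edges = which(ga == "train" & gb == "train"),
         val_edges = which(ga == "validation" & gb == "validation"),
         test_edges = which(ga == "test" & gb == "test"),
         fractions = fractions, seed = as.integer(seed)),
    class = "node_split")
  if (!is.null(labels)) {
    for (s in c("train_edges", "val_edges", "test_edges")) {
      l <- labels[split[[s]]]
      if (length(l) == 0 || all(l == 1) || all(l == 0))
        stop(sprintf(
          "%s has no positive or no negative edges; try a different seed", s))
    }
  }
  split
}

# message-passing graph: full network or restricted to train+validation
# nodes (the inductive training choice); always includes all node rows so
# that embeddings exist for every protein via self-loops
message_graph <- function(dataset, split = NULL,
                          scope = c("full", "train_val")) {
  scope <- match.arg(scope)
  ei <- dataset$edge_index
  if (scope == "train_val" && !is.null(split)) {
    keep_nodes <- names(split$assignment)[
      split$assignment %in% c("train", "validation")]
    ki <- match(keep_nodes, dataset$nodes)
    keep <- ei[, 1] %in% ki & ei[, 2] %in% ki
    ei <- ei[keep, , drop = FALSE]
  }
  build_graph(ei, length(dataset$nodes))
}

node_feature_blocks <- function(dataset) {
  list(expression = dataset$node_features$expression,
       abundance = dataset$node_features$abundance,
       localization = dataset$node_features$localization)
}

#' Train the condition-specific interaction classifier
#'
#' Adam on binary cross-entropy over the train edge set of a node-based
#' split, in \code{hp$batches} mini-batches per epoch (shuffled each
#' epoch). During training, messages are passed only over the subgraph
#' induced by train+validation nodes; prediction uses the full graph.
#'
#' @param dataset a labeled \code{spider_dataset}
#' @param split a \code{node_split}; computed from \code{hp} defaults when
#'   NULL
#' @param hp \code{spider_hyperparameters}
#' @param seed integer seed controlling split (when computed here),
#'   initialization and dropout
#' @param graph_scope message-passing graph during training
#' @param verbose print loss every 100 epochs
#' @return object of class \code{spider_model} with elements params, hp,
#'   split, compartments, loss_trace
#' @export
train_spider <- function(dataset, split = NULL,
                         hp = spider_hyperparameters(), seed = 1L,
                         graph_scope = c("train_val", "full"),
                         verbose = FALSE) {
  graph_scope <- match.arg(graph_scope)
  if (all(is.na(dataset$labels)))
    stop("dataset has no labels; a gold-standard edge set is required")
  if (is.null(split))
    split <- split_nodes(dataset$net, seed = seed, labels = dataset$labels)
  tr <- split$train_edges
  y <- dataset$labels[tr]
  if (all(y == 1) || all(y == 0))
    stop("train split has no positive or no negative edges; try a different seed")

  set.seed(seed)
  params <- init_params(hp$embedding_size, ncol(dataset$node_features$localization))
  state <- adam_init(params)
  graph <- message_graph(dataset, split, graph_scope)
  nf <- node_feature_blocks(dataset)
  batch <- dataset$edge_index[tr, , drop = FALSE]
  ef <- dataset$edge_features[tr, , drop = FALSE]

  nb <- min(hp$batches, length(tr))
  trace <- numeric(hp$epochs)
  for (ep in seq_len(hp$epochs)) {
    chunks <- if (nb == 1) list(seq_along(tr)) else
      split(sample(seq_along(tr)), cut(seq_along(tr), nb, labels = FALSE))
    loss <- 0
    for (ch in chunks) {
      fw <- nn_forward(params, nf, graph, batch[ch, , drop = FALSE],
                       ef[ch, , drop = FALSE],
                       dropout = hp$dropout, training = TRUE)
      l <- bce_loss(fw$logit, y[ch])
      if (!is.finite(l))
        stop(sprintf("non-finite loss at epoch %d; inspect features/learning rate", ep))
      loss <- loss + l * length(ch) / length(tr)
      grads <- nn_backward(params, fw$cache, bce_grad(fw$logit, y[ch]))
      upd <- adam_step(params, grads, state, hp$learning_rate,
                       hp$weight_decay)
      params <- upd$params; state <- upd$state
    }
    trace[ep] <- loss
    if (verbose && (ep %% 100 == 0 || ep == 1))
      message(sprintf("epoch %4d  loss %.4f", ep, loss))
  }
  structure(
    list(params = params, hp = hp, split = split,
         compartments = dataset$compartments, loss_trace = trace,
         seed = as.integer(seed)),
    class = "spider_model")
}

#' @export
print.spider_model <- function(x, ...) {
  cat(sprintf(
    "spider_model: embedding %d, %d epochs trained, final loss %.4f\n",
    x$hp$embedding_size, length(x$loss_trace),
    if (length(x$loss_trace)) tail_loss(x) else NA))
  invisible(x)
}

tail_loss <- function(m) m$loss_trace[length(m$loss_trace)]

#' Predict interaction probabilities for candidate edges
#'
#' One forward pass (no dropout) over the full message-passing graph.
#'
#' @param object a \code{spider_model}
#' @param dataset a \code{spider_dataset} over the same compartment universe
#' @param edges integer indices into the dataset's edge table (default all)
#' @param ... unused
#' @return numeric vector of probabilities in (0,1)
#' @export
predict.spider_model <- function(object, dataset, edges = NULL, ...) {
  if (!identical(object$compartments, dataset$compartments))
    stop("dataset compartment universe differs from the model's")
  if (is.null(edges)) edges <- seq_len(nrow(dataset$edge_index))
  graph <- message_graph(dataset, scope = "full")
  batch <- dataset$edge_index[edges, , drop = FALSE]
  if (any(is.na(batch))) stop("queried edge references an unknown node")
  fw <- nn_forward(object$params, node_feature_blocks(dataset), graph,
                   batch, dataset$edge_features[edges, , drop = FALSE])
  fw$prob
}

#' Exhaustive hyperparameter grid search
#'
#' Trains one model per grid combination and selects the one with the
#' highest validation AUPRC; ties are broken by smaller embedding size,
#' then lower learning rate.
#'
#' @param dataset labeled \code{spider_dataset}
#' @param grid named list of candidate values (see \code{default_grid})
#' @param seed integer seed (shared split across combinations)
#' @param eval_fn optional function(hp) -> AUPRC replacing the
#'   train-and-evaluate step (used for testing the selection logic)
#' @return list(hp = best \code{spider_hyperparameters}, results =
#'   data.frame of all combinations with their validation AUPRC)
#' @export
tune_spider <- function(dataset, grid = default_grid(), seed = 1L,
                        eval_fn = NULL) {
  combos <- expand.grid(embedding_size = grid$embedding_size,
                        learning_rate = grid$learning_rate,
                        dropout = grid$dropout, epochs = grid$epochs,
                        KEEP.OUT.ATTRS = FALSE)
  split <- if (is.null(eval_fn))
    split_nodes(dataset$net, seed = seed, labels = dataset$labels) else NULL
  auprcs <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    hp <- spider_hyperparameters(combos$embedding_size[i],
                                 combos$learning_rate[i],
                                 combos$dropout[i], combos$epochs[i])
    auprcs[i] <- if (!is.null(eval_fn)) eval_fn(hp) else {
      model <- train_spider(dataset, split, hp, seed = seed)
      va <- split$val_edges
      auprc(predict(model, dataset, edges = va), dataset$labels[va])
    }
  }
  ord <- order(-auprcs, combos$embedding_size, combos$learning_rate)
  best <- combos[ord[1], ]
  list(hp = spider_hyperparameters(best$embedding_size, best$learning_rate,
                                   best$dropout, best$epochs),
       results = cbind(combos, val_auprc = auprcs))
}

#' Train one model jointly on several conditions
#'
#' All conditions must share the general network (same protein universe and
#' candidate edges). Each epoch runs the node stage once per condition with
#' that condition's features and scores that condition's train edges; the
#' loss is the mean over the pooled train edges of all conditions, so the
#' train and validation pools are effectively concatenated.
#'
#' @param datasets list of labeled \code{spider_dataset}s on the same net
#' @param split shared \code{node_split} (computed at \code{seed} when NULL)
#' @param hp \code{spider_hyperparameters}
#' @param seed integer seed
#' @param graph_scope message-passing graph during training
#' @param verbose print loss every 100 epochs
#' @return a \code{spider_model}
#' @export
train_spider_combined <- function(datasets, split = NULL,
                                  hp = spider_hyperparameters(), seed = 1L,
                                  graph_scope = c("train_val", "full"),
                                  verbose = FALSE) {
  graph_scope <- match.arg(graph_scope)
  d1 <- datasets[[1]]
  for (d in datasets)
    if (!identical(d$nodes, d1$nodes) || nrow(d$edge_index) != nrow(d1$edge_index))
      stop("all datasets must share the same general network")
  if (is.null(split))
    split <- split_nodes(d1$net, seed = seed, labels = d1$labels)
  tr <- split$train_edges
  total <- length(tr) * length(datasets)

  set.seed(seed)
  params <- init_params(hp$embedding_size,
                        ncol(d1$node_features$localization))
  state <- adam_init(params)
  graph <- message_graph(d1, split, graph_scope)
  pre <- lapply(datasets, function(d) list(
    nf = node_feature_blocks(d),
    batch = d$edge_index[tr, , drop = FALSE],
    ef = d$edge_features[tr, , drop = FALSE],
    y = d$labels[tr]))

  nb <- min(hp$batches, length(tr))
  trace <- numeric(hp$epochs)
  for (ep in seq_len(hp$epochs)) {
    chunks <- if (nb == 1) list(seq_along(tr)) else
      split(sample(seq_along(tr)), cut(seq_along(tr), nb, labels = FALSE))
    loss <- 0
    for (ch in chunks) {
      grads <- NULL
      chn <- length(ch) * length(pre)
      for (pc in pre) {
        fw <- nn_forward(params, pc$nf, graph,
                         pc$batch[ch, , drop = FALSE],
                         pc$ef[ch, , drop = FALSE],
                         dropout = hp$dropout, training = TRUE)
        loss <- loss + bce_loss(fw$logit, pc$y[ch]) * length(ch) / total
        gi <- nn_backward(params, fw$cache,
                          (sigmoid(fw$logit) - pc$y[ch]) / chn)
        grads <- if (is.null(grads)) gi else Map(`+`, grads, gi)
      }
      upd <- adam_step(params, grads, state, hp$learning_rate,
                       hp$weight_decay)
      params <- upd$params; state <- upd$state
    }
    if (!is.finite(loss)) stop(sprintf("non-finite loss at epoch %d", ep))
    trace[ep] <- loss
    if (verbose && (ep %% 100 == 0 || ep == 1))
      message(sprintf("epoch %4d  loss %.4f", ep, loss))
  }
  structure(
    list(params = params, hp = hp, split = split,
         compartments = d1$compartments, loss_trace = trace,
         seed = as.integer(seed)),
    class = "spider_model")
}

# parameter names of the protein-level feature projection blocks
PROJECTION_PARAMS <- c("pe_W1", "pe_b1", "pe_W2", "pe_b2",
                       "pa_W1", "pa_b1", "pa_W2", "pa_b2",
                       "pl_W1", "pl_b1", "pl_W2", "pl_b2")

#' Fine-tune a trained model on a new condition
#'
#' Transfer learning to a data-poor condition: the per-feature projection
#' blocks (the layers that process protein-level features) are frozen and
#' the remaining layers continue training on a random fraction of the
#' target condition's train edges, at a low learning rate for few epochs to
#' avoid overfitting small training sets.
#'
#' @param model trained source \code{spider_model}
#' @param dataset labeled target \code{spider_dataset}
#' @param fraction fraction of the target train edges used, in (0,1]
#' @param split target \code{node_split} (computed at \code{seed} when NULL)
#' @param seed integer seed (edge subsampling + dropout)
#' @param learning_rate fine-tuning learning rate (default 5e-4)
#' @param epochs fine-tuning epochs (default 100)
#' @param graph_scope message-passing graph during fine-tuning
#' @return a fine-tuned \code{spider_model}
#' @export
fine_tune_spider <- function(model, dataset, fraction = 0.1, split = NULL,
                             seed = 1L, learning_rate = 5e-4,
                             epochs = 100L,
                             graph_scope = c("train_val", "full")) {
  graph_scope <- match.arg(graph_scope)
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0,1]")
  if (is.null(split))
    split <- split_nodes(dataset$net, seed = seed, labels = dataset$labels)
  set.seed(seed)
  tr <- split$train_edges
  take <- sort(sample(tr, max(1L, round(fraction * length(tr)))))
  y <- dataset$labels[take]

  params <- model$params
  state <- adam_init(params)
  graph <- message_graph(dataset, split, graph_scope)
  nf <- node_feature_blocks(dataset)
  batch <- dataset$edge_index[take, , drop = FALSE]
  ef <- dataset$edge_features[take, , drop = FALSE]

  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    fw <- nn_forward(params, nf, graph, batch, ef,
                     dropout = model$hp$dropout, training = TRUE)
    loss <- bce_loss(fw$logit, y)
    if (!is.finite(loss)) stop(sprintf("non-finite loss at epoch %d", ep))
    trace[ep] <- loss
    grads <- nn_backward(params, fw$cache, bce_grad(fw$logit, y))
    upd <- adam_step(params, grads, state, learning_rate,
                     model$hp$weight_decay, frozen = PROJECTION_PARAMS)
    params <- upd$params; state <- upd$state
  }
  out <- model
  out$params <- params
  out$split <- split
  out$loss_trace <- trace
  out$fine_tuned <- list(fraction = fraction, learning_rate = learning_rate,
                         epochs = as.integer(epochs), seed = as.integer(seed))
  out
}
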