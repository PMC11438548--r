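test_that("node splits honor fractions and the induced-edge rule", {
  cfg <- synth_config(n_proteins = 100, n_edges = 400, seed = 4)
  net <- generate_general_network(cfg)
  sp <- split_nodes(net, seed = 4)
  expect_equal(as.vector(table(sp$assignment)), c(70, 15, 15))

  # an edge belongs to a split iff both endpoints do
  asg <- sp$assignment
  for (s in c("train_edges", "val_edges", "test_edges")) {
    grp <- sub("_edges", "", s)
    grp <- c(train = "train", val = "validation", test = "test")[[grp]]
    e <- net$edges[sp[[s]], , drop = FALSE]
    expect_true(all(asg[e[, 1]] == grp & asg[e[, 2]] == grp))
  }
  cross <- setdiff(seq_len(n_edges(net)),
                   c(sp$train_edges, sp$val_edges, sp$test_edges))
  e <- net$edges[cross, , drop = FALSE]
  expect_true(all(asg[e[, 1]] != asg[e[, 2]]))

  # determinism
  sp2 <- split_nodes(net, seed = 4)
  expect_identical(sp$assignment, sp2$assignment)

  # degenerate labels are rejected with advice
  expect_error(split_nodes(net, seed = 4, labels = rep(0, n_edges(net))),
               "different seed")
})

test_that("training separates a linearly separable toy within 200 epochs", {
  # positives: both endpoints expression 1; negatives: both 0
  set.seed(10)
  n <- 40
  nodes <- sprintf("N%02d", 1:n)
  hi <- nodes[1:20]; lo <- nodes[21:40]
  edges <- rbind(t(combn(hi, 2))[sample(190, 60), ],
                 t(combn(lo, 2))[sample(190, 60), ])
  net <- general_network(edges)
  expr <- matrix(rep(rep(c(1, 0), each = 20), 2), n, 2,
                 dimnames = list(nodes, c("s1", "s2")))
  expr <- expr[order(rownames(expr)), ] * 7 + 1  # scale into log range
  abund <- expr
  gold <- t(combn(sort(hi), 2))
  prof <- condition_profile("toy", expr, abund, gold, scale = "log")
  ann <- setNames(as.list(rep("C01", n)), nodes)
  ds <- suppressWarnings(
    assemble_dataset(net, prof, ann, c("C01", "C02")))
  # use all edges as train split
  sp <- list(assignment = factor(setNames(rep("train", n), sort(nodes)),
                                 levels = c("train", "validation", "test")),
             train_edges = seq_len(n_edges(net)), val_edges = integer(),
             test_edges = integer())
  class(sp) <- "node_split"
  hp <- spider_hyperparameters(embedding_size = 16, epochs = 200)
  m <- train_spider(ds, sp, hp, seed = 1)
  p <- predict(m, ds)
  expect_equal(auroc(p, ds$labels), 1)
  # loss decreased over training
  expect_lt(m$loss_trace[length(m$loss_trace)], m$loss_trace[1])
})

test_that("training is deterministic given the seed", {
  w <- small_world(seed = 13, n_proteins = 60, n_edges = 250,
                   n_conditions = 1)
  ds <- w$datasets[[1]]
  sp <- split_nodes(w$net, seed = 13, labels = ds$labels)
  hp <- spider_hyperparameters(embedding_size = 8, epochs = 30)
  m1 <- train_spider(ds, sp, hp, seed = 99)
  m2 <- train_spider(ds, sp, hp, seed = 99)
  expect_identical(m1$params, m2$params)
  expect_identical(predict(m1, ds), predict(m2, ds))
})

test_that("grid search selects by validation AUPRC with deterministic ties", {
  grid1 <- list(embedding_size = 16L, learning_rate = 1e-3,
                dropout = 0.3, epochs = 10L)
  w <- small_world(seed = 15, n_proteins = 50, n_edges = 200,
                   n_conditions = 1)
  out1 <- tune_spider(w$datasets[[1]], grid1, seed = 15,
                      eval_fn = function(hp) 0.5)
  expect_equal(out1$hp$embedding_size, 16L)

  # rigged evaluation: argmax must be returned
  grid <- list(embedding_size = c(32L, 64L), learning_rate = c(1e-3, 5e-4),
               dropout = 0.3, epochs = c(500L, 750L))
  rig <- function(hp) {
    if (hp$embedding_size == 64 && hp$learning_rate == 1e-3 &&
          hp$epochs == 750) 0.9 else 0.1
  }
  out <- tune_spider(w$datasets[[1]], grid, seed = 1, eval_fn = rig)
  expect_equal(out$hp$embedding_size, 64L)
  expect_equal(out$hp$learning_rate, 1e-3)
  expect_equal(out$hp$epochs, 750L)

  # all-equal AUPRC: smaller embedding, then lower learning rate wins
  out_tie <- tune_spider(w$datasets[[1]], grid, seed = 1,
                         eval_fn = function(hp) 0.5)
  expect_equal(out_tie$hp$embedding_size, 32L)
  expect_equal(out_tie$hp$learning_rate, 5e-4)
})

test_that("combined training pools conditions and keeps the contracts", {
  w <- small_world(seed = 24, n_proteins = 60, n_edges = 260,
                   n_conditions = 2)
  sp <- split_nodes(w$net, seed = 24, labels = w$datasets[[1]]$labels)
  hp <- spider_hyperparameters(embedding_size = 8, epochs = 25)
  m <- train_spider_combined(w$datasets, sp, hp, seed = 24)
  # one score per condition, all probabilities, symmetric predictions
  for (ds in w$datasets) {
    p <- predict(m, ds)
    expect_true(all(p > 0 & p < 1))
  }
  ds1 <- w$datasets[[1]]
  swapped <- ds1
  swapped$edge_index <- ds1$edge_index[, 2:1]
  expect_identical(predict(m, ds1), predict(m, swapped))
})

test_that("fine-tuning freezes the protein-level projection blocks", {
  w <- small_world(seed = 24, n_proteins = 60, n_edges = 260,
                   n_conditions = 2)
  sp <- split_nodes(w$net, seed = 24, labels = w$datasets[[1]]$labels)
  hp <- spider_hyperparameters(embedding_size = 8, epochs = 25)
  m <- train_spider(w$datasets[[1]], sp, hp, seed = 24)

  expect_error(fine_tune_spider(m, w$datasets[[2]], fraction = 0),
               "fraction")
  expect_error(fine_tune_spider(m, w$datasets[[2]], fraction = 1.2),
               "fraction")

  # zero epochs: parameters unchanged
  m0 <- fine_tune_spider(m, w$datasets[[2]], fraction = 1, split = sp,
                         seed = 1, epochs = 0L)
  expect_identical(m0$params, m$params)

  mft <- fine_tune_spider(m, w$datasets[[2]], fraction = 0.5, split = sp,
                          seed = 1, epochs = 20L)
  frozen <- c("pe_W1", "pe_b1", "pe_W2", "pe_b2", "pa_W1", "pa_b1",
              "pa_W2", "pa_b2", "pl_W1", "pl_b1", "pl_W2", "pl_b2")
  for (nm in frozen)
    expect_identical(mft$params[[nm]], m$params[[nm]])
  # at least one unfrozen parameter moved
  expect_false(identical(mft$params$hd_W3, m$params$hd_W3))
})

test_that("zeroing condition-specific features collapses cross-condition predictions", {
  w <- small_world(seed = 24, n_proteins = 60, n_edges = 260,
                   n_conditions = 2)
  sp <- split_nodes(w$net, seed = 24, labels = w$datasets[[1]]$labels)
  hp <- spider_hyperparameters(embedding_size = 8, epochs = 20)
  m <- train_spider(w$datasets[[1]], sp, hp, seed = 24)
  strip <- function(ds) {
    ds$node_features$expression[] <- 0
    ds$node_features$abundance[] <- 0
    ds$edge_features[, "coabundance"] <- 0
    ds
  }
  p1 <- predict(m, strip(w$datasets[[1]]))
  p2 <- predict(m, strip(w$datasets[[2]]))
  expect_identical(p1, p2)
  # and without stripping, the two conditions differ
  expect_false(identical(predict(m, w$datasets[[1]]),
                         predict(m, w$datasets[[2]])))
})
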