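# Small programmatic fixtures shared across test files.

# tiny deterministic network: 5 nodes, 6 edges
tiny_network <- function() {
  general_network(rbind(
    c("A", "B"), c("A", "C"), c("B", "C"), c("B", "D"),
    c("C", "E"), c("D", "E")))
}

# a small synthetic world: fast enough for training tests
small_world <- function(seed = 7, n_proteins = 150, n_edges = 900,
                        n_conditions = 2) {
  cfg <- synth_config(n_proteins = n_proteins, n_edges = n_edges,
                      n_conditions = n_conditions, seed = seed)
  net <- generate_general_network(cfg)
  conds <- lapply(seq_len(n_conditions), function(i)
    generate_condition(cfg, net, i))
  datasets <- lapply(conds, function(co)
    assemble_dataset(net, co$profile, co$annotations, co$compartments))
  list(cfg = cfg, net = net, conds = conds, datasets = datasets)
}

# random rooted tree over n nodes as a parent-child matrix (node 1 = root)
random_tree <- function(n, seed) {
  set.seed(seed)
  parent <- vapply(2:n, function(i) sample.int(i - 1, 1), integer(1))
  cbind(paste0("t", parent), paste0("t", 2:n))
}

# condition network with seeded random probabilities over a general network
random_condition_network <- function(net, seed, threshold = 0.39) {
  set.seed(seed)
  condition_network("rand", net$edges, runif(n_edges(net), 0.01, 0.99),
                    threshold)
}

expect_same_network <- function(a, b) {
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$edges, b$edges)
  expect_equal(a$technique_counts, b$technique_counts,
               ignore_attr = TRUE)
}
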