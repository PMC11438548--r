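test_that("propagation matches the closed-form linear solve", {
  # 3-node path, seed at one end
  net <- condition_network("p", rbind(c("a", "b"), c("b", "c")), c(1, 1),
                           threshold = 0.5)
  s <- propagate(net, "a", alpha = 0.8, tolerance = 1e-12)
  A <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  W <- A / rowSums(A)
  p0 <- c(1, 0, 0)
  direct <- solve(diag(3) - 0.8 * W, 0.2 * p0)
  expect_equal(unname(s[c("a", "b", "c")]), direct, tolerance = 1e-6)

  # random weighted graphs vs the linear-system oracle
  for (seed in 1:4) {
    cfg <- synth_config(n_proteins = 20, n_edges = 40, seed = seed)
    g <- generate_general_network(cfg)
    cn <- random_condition_network(g, seed)
    seeds <- g$nodes[1:4]
    s <- propagate(cn, seeds, alpha = 0.8, tolerance = 1e-12)
    A <- matrix(0, 20, 20, dimnames = list(g$nodes, g$nodes))
    A[cbind(cn$edges[, 1], cn$edges[, 2])] <- cn$probability
    A <- A + t(A)
    deg <- rowSums(A)
    W <- A / ifelse(deg > 0, deg, 1)
    p0 <- setNames(numeric(20), g$nodes); p0[seeds] <- 1 / 4
    direct <- solve(diag(20) - 0.8 * W, 0.2 * p0)
    expect_equal(unname(s[g$nodes]), unname(direct), tolerance = 1e-6)
  }
})

test_that("propagation limits and invariances hold", {
  cfg <- synth_config(n_proteins = 15, n_edges = 30, seed = 3)
  g <- generate_general_network(cfg)
  cn <- random_condition_network(g, 3)
  seeds <- g$nodes[c(2, 5)]
  # alpha = 0: scores equal the restart prior exactly
  s0 <- propagate(cn, seeds, alpha = 0)
  expect_equal(unname(s0[seeds]), c(0.5, 0.5))
  expect_equal(sum(s0), 1)

  # node relabeling permutes scores identically
  set.seed(4)
  perm <- sample(nrow(cn$edges))
  cn2 <- condition_network("perm", cn$edges[perm, ], cn$probability[perm],
                           cn$threshold)
  s1 <- propagate(cn, seeds, alpha = 0.7)
  s2 <- propagate(cn2, seeds, alpha = 0.7)
  expect_equal(s1[sort(names(s1))], s2[sort(names(s2))])

  # mass conservation on a regular graph (row = column stochastic there)
  ring <- condition_network("ring", cbind(paste0("n", 1:6),
                                          paste0("n", c(2:6, 1))),
                            rep(1, 6), 0.5)
  sr <- propagate(ring, c("n1", "n4"), alpha = 0.8, tolerance = 1e-12)
  expect_equal(sum(sr), 1, tolerance = 1e-8)

  # fixed point satisfies the update equation
  A <- matrix(0, 6, 6, dimnames = list(ring$nodes, ring$nodes))
  A[cbind(ring$edges[, 1], ring$edges[, 2])] <- 1
  A <- A + t(A)
  W <- A / rowSums(A)
  p0 <- setNames(rep(0, 6), ring$nodes); p0[c("n1", "n4")] <- 0.5
  expect_equal(unname(sr[ring$nodes]),
               unname(0.8 * drop(W %*% sr[ring$nodes]) + 0.2 * p0),
               tolerance = 1e-7)
})

test_that("cross-validated disease-gene prediction recovers planted modules", {
  w <- small_world(seed = 29, n_proteins = 150, n_edges = 900,
                   n_conditions = 1)
  sets <- generate_disease_and_driver_sets(w$cfg, w$conds[[1]], w$net,
                                           set_size = 30)
  # condition network concentrated on gold edges
  keys <- paste(w$net$edges[, 1], w$net$edges[, 2])
  gk <- paste(w$conds[[1]]$profile$gold_edges[, 1],
              w$conds[[1]]$profile$gold_edges[, 2])
  p <- ifelse(keys %in% gk, 0.9, 0.05)
  cn <- condition_network("cond", w$net$edges, p, 0.5)
  gen <- condition_network("gen", w$net$edges, rep(1, n_edges(w$net)), 0.5)
  auc_cond <- cv_disease_genes(cn, sets$disease_genes, seed = 29)
  auc_gen <- cv_disease_genes(gen, sets$disease_genes, seed = 29)
  expect_gt(auc_cond, auc_gen)
  expect_gt(auc_cond, 0.7)

  # sets below the floor are skipped
  expect_message(
    expect_null(cv_disease_genes(cn, w$net$nodes[1:10], seed = 1)),
    "skipped")
})

test_that("nearest-neighbor sample pooling picks the most similar samples", {
  set.seed(55)
  pool <- matrix(rnorm(20 * 8, 10, 2), 20, 8,
                 dimnames = list(sprintf("P%02d", 1:20), paste0("s", 1:8)))
  # exact copies of s1 must be selected
  pool[, "s2"] <- pool[, "s1"]
  pool[, "s3"] <- 2 * pool[, "s1"]   # cosine 1 as well
  out <- nearest_sample_coabundance("s1", pool, k = 2)
  expect_setequal(out$neighbors, c("s2", "s3"))
  expect_equal(colnames(out$abundance), c("s1", "s2", "s3"))

  # brute-force cosine ranking oracle
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sims <- sapply(paste0("s", 2:8), function(s) cosine(pool[, "s1"], pool[, s]))
  out5 <- nearest_sample_coabundance("s1", pool, k = 5)
  expect_setequal(out5$neighbors, names(sort(sims, decreasing = TRUE))[1:5])

  expect_warning(nearest_sample_coabundance("s1", pool[, 1:3], k = 5),
                 "using all")
})

test_that("consensus network is the edgewise mean of sample networks", {
  net <- tiny_network()
  n1 <- condition_network("s1", net$edges, rep(0.2, 6), 0.39)
  n2 <- condition_network("s2", net$edges, rep(0.8, 6), 0.39)
  cons <- consensus_network(list(n1, n2))
  expect_equal(cons$probability, rep(0.5, 6))
  # idempotent on identical inputs
  expect_equal(consensus_network(list(n1, n1))$probability, n1$probability)
  # permutation invariance and edgewise bounds
  set.seed(6)
  nets <- lapply(1:4, function(i) random_condition_network(net, i))
  c1 <- consensus_network(nets)
  c2 <- consensus_network(rev(nets))
  expect_equal(c1$probability, c2$probability)
  probs <- sapply(nets, `[[`, "probability")
  expect_true(all(c1$probability >= apply(probs, 1, min) &
                    c1$probability <= apply(probs, 1, max)))
})

test_that("driver enrichment follows the top-K ratio formula", {
  genes <- sprintf("g%03d", 1:100)
  cgc <- genes[1:20]
  # top-K entirely in the gold set: N / |CGC|
  expect_equal(driver_enrichment(genes, cgc, k = 10), 100 / 20)
  # K = N covers everything: enrichment 1
  expect_equal(driver_enrichment(genes, cgc, k = 100), 1)
  # n=2, K=10, |CGC|=20, N=100 -> 1
  ranked <- c(genes[1:2], genes[30:37], genes[3:20], genes[38:100],
              genes[21:29])
  expect_equal(driver_enrichment(ranked, cgc, k = 10), 1)
  # scale-free: doubling |CGC| and N leaves the ratio unchanged
  genes2 <- sprintf("h%03d", 1:100)
  expect_equal(
    driver_enrichment(c(genes, genes2), c(cgc, genes2[1:20]), k = 10),
    driver_enrichment(genes, cgc, k = 10) *
      (40 / 200)^-1 * (20 / 100))
})

test_that("driver scoring averages per-sample propagations", {
  cfg <- synth_config(n_proteins = 30, n_edges = 80, seed = 9)
  g <- generate_general_network(cfg)
  cn <- random_condition_network(g, 9)
  muts <- list(s1 = g$nodes[1:3])
  r1 <- score_drivers(cn, muts)
  direct <- propagate(cn, g$nodes[1:3], alpha = 0.8)
  expect_equal(setNames(r1$score, r1$gene)[names(direct)], direct)
  # two identical samples equal one
  r2 <- score_drivers(cn, list(s1 = g$nodes[1:3], s2 = g$nodes[1:3]))
  expect_equal(r1$score, r2$score)
  expect_identical(r1$gene, r2$gene)
})
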