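test_that("expression normalization: log transform, median collapse, min-max", {
  raw <- matrix(c(0, 0, 1, 1, 3, 3), 3, 2, byrow = TRUE,
                dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  # TPM medians {0,1,3} -> log2 {0,1,2} -> min-max {0, 0.5, 1}
  expect_equal(unname(normalize_expression(raw, "tpm")), c(0, 0.5, 1))
  # single gene: degenerate min-max maps to 0
  expect_equal(unname(normalize_expression(raw[1, , drop = FALSE], "tpm")), 0)
  # permuting sample columns leaves the median unchanged
  wide <- matrix(runif(40), 4, 10, dimnames = list(paste0("g", 1:4), NULL))
  expect_equal(normalize_expression(wide, "log"),
               normalize_expression(wide[, 10:1], "log"))
})

test_that("abundance normalization is scale-invariant with masked rows", {
  raw <- matrix(c(2, 2, 4, 4, 6, 6), 3, 2, byrow = TRUE,
                dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  expect_equal(unname(normalize_abundance(raw)), c(0, 0.5, 1))
  expect_equal(normalize_abundance(raw * 10), normalize_abundance(raw))
  raw[2, ] <- NA  # fully masked protein stays NA (assembly adds the flag)
  expect_true(is.na(normalize_abundance(raw)[["p2"]]))
})

test_that("co-abundance is Pearson r with total fallback rules", {
  expect_equal(coabundance(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(coabundance(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(coabundance(c(1, 1, 1), c(1, 2, 3)), 0)  # zero variance
  expect_equal(coabundance(c(1, 2, NA), c(1, 2, 3)), 0) # <3 shared samples
  # symmetry property over random vectors
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(5)
    expect_identical(coabundance(a, b), coabundance(b, a))
    expect_true(abs(coabundance(a, b)) <= 1)
  }
})

test_that("localization vectors spread mass uniformly over annotations", {
  comps <- sprintf("C%02d", 1:63)
  ann <- list(P1 = c("C01", "C02"), P2 = "C05")
  v1 <- localization_vector("P1", ann, comps)
  expect_equal(sum(v1), 1)
  expect_equal(unname(v1[c("C01", "C02")]), c(0.5, 0.5))
  expect_equal(sum(v1 != 0), 2)
  expect_equal(unname(localization_vector("P2", ann, comps)["C05"]), 1)
  expect_equal(sum(localization_vector("P9", ann, comps)), 0)
})

test_that("co-localization matches direct Pearson computation", {
  comps <- sprintf("C%02d", 1:63)
  ann <- list(P1 = "C01", P2 = "C02")
  u <- localization_vector("P1", ann, comps)
  v <- localization_vector("P2", ann, comps)
  expect_equal(colocalization(u, v), cor(u, v))
  expect_equal(colocalization(u, v), -1 / 62)  # disjoint one-hots, length 63
  expect_equal(colocalization(u, u), 1)
  expect_equal(colocalization(u, numeric(63)), 0)  # all-zero fallback
  set.seed(2)
  for (i in 1:10) {
    a <- runif(10); b <- runif(10)
    expect_identical(colocalization(a, b), colocalization(b, a))
  }
})

test_that("dataset assembly labels candidates and drops outside gold edges", {
  net <- tiny_network()  # 6 edges, canonical order
  expr <- matrix(runif(10, 1, 5), 5, 2,
                 dimnames = list(c("A", "B", "C", "D", "E"), c("s1", "s2")))
  abund <- expr + 1
  ann <- list(A = "C01", B = "C01", C = "C02", D = "C02", E = "C03")
  gold <- rbind(c("A", "B"), c("B", "C"))
  prof <- condition_profile("t", expr, abund, gold, scale = "log")
  ds <- assemble_dataset(net, prof, ann, sprintf("C%02d", 1:3))
  expect_equal(sum(ds$labels), 2)
  keys <- paste(net$edges[, 1], net$edges[, 2])
  expect_equal(ds$labels, as.integer(keys %in% c("A B", "B C")))

  # gold edge outside candidate universe: dropped with a warning
  prof2 <- condition_profile("t", expr, abund,
                             rbind(gold, c("A", "Z")), scale = "log")
  expect_warning(assemble_dataset(net, prof2, ann, sprintf("C%02d", 1:3)),
                 "1 gold edge")

  # technique features can be disabled (all-zero block)
  ds3 <- suppressWarnings(assemble_dataset(net, prof, ann,
                                           sprintf("C%02d", 1:3),
                                           use_techniques = FALSE))
  expect_true(all(ds3$edge_features[, -(1:2)] == 0))

  # node features bounded
  expect_true(all(ds$node_features$expression[, "value"] >= 0 &
                    ds$node_features$expression[, "value"] <= 1))
  expect_true(all(abs(ds$edge_features[, 1:2]) <= 1))
})

test_that("dataset assembly is deterministic and edge-order independent", {
  w <- small_world(seed = 21, n_proteins = 40, n_edges = 120,
                   n_conditions = 1)
  ds1 <- assemble_dataset(w$net, w$conds[[1]]$profile,
                          w$conds[[1]]$annotations, w$conds[[1]]$compartments)
  # shuffle the raw edge rows and swap orientations before rebuilding
  set.seed(9)
  perm <- sample(n_edges(w$net))
  edges <- w$net$edges[perm, ]
  flip <- runif(nrow(edges)) < 0.5
  edges[flip, ] <- edges[flip, 2:1]
  net2 <- general_network(edges, w$net$technique_counts[perm, ],
                          nodes = w$net$nodes)
  ds2 <- assemble_dataset(net2, w$conds[[1]]$profile,
                          w$conds[[1]]$annotations, w$conds[[1]]$compartments)
  expect_identical(ds1$labels, ds2$labels)
  expect_equal(ds1$edge_features, ds2$edge_features)
  expect_equal(ds1$node_features, ds2$node_features)
})

test_that("assay names map onto the fixed technique vocabulary", {
  v <- technique_vector(c("two_hybrid", "two_hybrid", "pull_down",
                          "exotic_new_assay"))
  expect_equal(unname(v[["two_hybrid"]]), 2)
  expect_equal(unname(v[["pull_down"]]), 1)
  expect_equal(unname(v[["other"]]), 1)  # unknown assays fall into "other"
  expect_equal(sum(v), 4)
  expect_length(v, 11)
})
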