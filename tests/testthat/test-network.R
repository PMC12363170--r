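test_that("buildNetwork keeps isolated nodes and rejects malformed edges", {
  net <- buildNetwork(NULL, letters[1:5])
  expect_identical(sort(networkNodes(net)), letters[1:5])
  expect_identical(nrow(networkEdges(net)), 0L)

  edges <- data.frame(feature_a = c("a", "a"), feature_b = c("b", "b"),
                      rho = c(0.8, 0.9))
  expect_error(buildNetwork(edges, letters[1:3]), "duplicate")
  expect_error(buildNetwork(data.frame(feature_a = "a", feature_b = "a"),
                            letters[1:3]), "self-loop")
  expect_error(buildNetwork(data.frame(feature_a = "a", feature_b = "z"),
                            letters[1:3]), "not in node set")

  # planted blocks appear as connected components
  fx <- blockEdges(c(4, 3))
  net2 <- buildNetwork(fx$edges, fx$nodes)
  comp <- igraph::components(asIgraph(net2))$membership
  expect_identical(length(unique(comp)), 2L)
  expect_true(all(tapply(fx$block, comp[fx$nodes], function(x)
    length(unique(x))) == 1))
})

test_that("modularityScore equals hand values and the brute-force double sum", {
  # two disjoint triangles, partition = components -> Q = 1/2
  tri <- data.frame(feature_a = c("a", "b", "c", "d", "e", "f"),
                    feature_b = c("b", "c", "a", "e", "f", "d"))
  net <- buildNetwork(tri, letters[1:6])
  part <- setNames(rep(c("x", "y"), each = 3), letters[1:6])
  expect_equal(modularityScore(net, part), 0.5)
  # single community -> exactly 0
  expect_equal(modularityScore(net, setNames(rep("z", 6), letters[1:6])), 0)
  expect_warning(q0 <- modularityScore(buildNetwork(NULL, c("a", "b")),
                                       c(a = "1", b = "2")), "no edges")
  expect_equal(q0, 0)

  # random graphs vs O(n^2) oracle, and vs igraph
  for (s in 1:20) {
    n <- sample(5:30, 1)
    net <- randomNetwork(n, 0.3, seed = s)
    g <- asIgraph(net)
    nodes <- networkNodes(net)
    part <- withr::with_seed(s, setNames(sample(1:4, n, TRUE), nodes))
    A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))[nodes, nodes]
    A[A != 0] <- 1
    q <- modularityScore(net, part)
    if (igraph::ecount(g) == 0) next
    expect_lt(abs(q - bruteModularity(A, part[nodes])), 1e-12)
    expect_lt(abs(q - igraph::modularity(g, factor(part[igraph::V(g)$name]))),
              1e-12)
  }
})

test_that("detectModules finds unambiguous optima and labels major modules", {
  fx <- blockEdges(c(5, 5))
  part <- detectModules(buildNetwork(fx$edges, fx$nodes))
  mem <- membership(part)
  expect_identical(length(unique(mem)), 2L)
  expect_true(all(tapply(fx$block, mem[fx$nodes],
                         function(x) length(unique(x))) == 1))
  expect_identical(sort(unname(majorLabels(part))), c("M1", "M2"))

  # edgeless graph: all singletons, no major labels at 20 nodes
  lonely <- detectModules(buildNetwork(NULL, sprintf("n%02d", 1:20)))
  expect_identical(length(unique(membership(lonely))), 20L)
  expect_identical(length(majorLabels(lonely)), 0L)
  expect_equal(modularityQ(lonely), 0)
})

test_that("module labels order by size then member id, and ignore node order", {
  fx <- blockEdges(c(6, 3, 1))   # 10 nodes: only the 6-block and 3-block are major
  net <- buildNetwork(fx$edges, fx$nodes)
  part <- detectModules(net)
  lab <- majorLabels(part)
  mem <- membership(part)
  sizes <- table(mem)
  expect_identical(unname(lab[order(lab)]), c("M1", "M2"))
  expect_gt(sizes[names(lab)[lab == "M1"]], sizes[names(lab)[lab == "M2"]])

  shuffled <- buildNetwork(fx$edges[sample(nrow(fx$edges)), ],
                           rev(fx$nodes))
  part2 <- detectModules(shuffled)
  expect_identical(membership(part2)[names(mem)], mem)
  expect_identical(majorLabels(part2), lab)
})

test_that("detectModules recovers planted blocks against partition quality", {
  skip_if_not_installed("mclust")
  fx <- blockEdges(c(8, 8, 8, 8))
  part <- detectModules(buildNetwork(fx$edges, fx$nodes))
  ari <- mclust::adjustedRandIndex(membership(part)[fx$nodes], fx$block)
  expect_equal(ari, 1)
  expect_gte(modularityQ(part),
             modularityScore(buildNetwork(fx$edges, fx$nodes),
                             setNames(rep(1, 32), fx$nodes)))
})

test_that("sampleSubnetwork induces on present taxa only", {
  path <- data.frame(feature_a = c("A", "B"), feature_b = c("B", "C"),
                     rho = 0.9)
  net <- buildNetwork(path, c("A", "B", "C"))
  # all present: identity
  all3 <- sampleSubnetwork(net, c(A = 0.3, B = 0.3, C = 0.4))
  expect_identical(sort(networkNodes(all3)), c("A", "B", "C"))
  expect_identical(nrow(networkEdges(all3)), 2L)
  # only the path's endpoints: two isolated nodes
  ends <- sampleSubnetwork(net, c(A = 0.5, B = 0, C = 0.5))
  expect_identical(sort(networkNodes(ends)), c("A", "C"))
  expect_identical(nrow(networkEdges(ends)), 0L)
  single <- sampleSubnetwork(net, c(B = 1))
  expect_identical(networkNodes(single), "B")

  # monotonicity: adding a present taxon never removes edges
  e1 <- networkEdges(sampleSubnetwork(net, c(A = 1, B = 1)))
  e2 <- networkEdges(sampleSubnetwork(net, c(A = 1, B = 1, C = 1)))
  expect_true(all(paste(e1$feature_a, e1$feature_b) %in%
                  paste(e2$feature_a, e2$feature_b)))
})

test_that("eigenvector centrality matches the dense eigendecomposition oracle", {
  for (s in 1:10) {
    net <- randomNetwork(sample(5:50, 1), 0.2, seed = 100 + s)
    g <- asIgraph(net)
    if (igraph::ecount(g) == 0) next
    cent <- eigenvectorCentrality(net)
    comp <- igraph::components(g)
    sizes <- comp$csize
    cand <- which(sizes == max(sizes))
    nodes <- igraph::V(g)$name
    if (length(cand) > 1) {
      reps <- vapply(cand, function(ci) min(nodes[comp$membership == ci]), "")
      cand <- cand[order(reps)][1]
    }
    keep <- nodes[comp$membership == cand[1]]
    A <- as.matrix(igraph::as_adjacency_matrix(
      igraph::induced_subgraph(g, keep), sparse = FALSE))
    A[A != 0] <- 1
    ev <- eigen(A, symmetric = TRUE)$vectors[, 1]
    ev <- abs(ev) / max(abs(ev))
    expect_lt(max(abs(cent[keep] - ev)), 1e-8)
    expect_true(all(cent[setdiff(nodes, keep)] == 0))
  }
  # complete graph: all centralities exactly 1
  k4 <- data.frame(feature_a = c("a", "a", "a", "b", "b", "c"),
                   feature_b = c("b", "c", "d", "c", "d", "d"))
  expect_equal(unname(eigenvectorCentrality(buildNetwork(k4, letters[1:4]))),
               rep(1, 4))
})

test_that("per-sample properties match hand arithmetic and the full-sample identity", {
  path <- data.frame(feature_a = c("A", "B"), feature_b = c("B", "C"),
                     rho = 0.9)
  net <- buildNetwork(path, c("A", "B", "C"))
  m <- cbind(full = c(A = 0.2, B = 0.3, C = 0.5),
             endsOnly = c(A = 0.5, B = 0, C = 0.5),
             lonely = c(A = 1, B = 0, C = 0))
  tab <- AbundanceTable(m, "relative")
  props <- sampleNetworkProperties(net, tab)

  full <- props[props$sample_id == "full", ]
  expect_equal(full$mean_degree, 4 / 3)
  expect_equal(full$linkage_density, 4 / 9)
  expect_false(full$degenerate)
  # identity with global network statistics
  expect_equal(full$n_edges, nrow(networkEdges(net)))
  expect_equal(full$modularity, modularityQ(detectModules(net)))
  expect_equal(full$centrality, mean(eigenvectorCentrality(net)))

  ends <- props[props$sample_id == "endsOnly", ]
  expect_equal(ends[, c("mean_degree", "linkage_density", "centrality")],
               data.frame(mean_degree = 0, linkage_density = 0,
                          centrality = 0), ignore_attr = TRUE)
  expect_true(props[props$sample_id == "lonely", "degenerate"])
})

test_that("module abundances add up and match hand-summed fixtures", {
  fx <- blockEdges(c(3, 3))
  net <- buildNetwork(fx$edges, fx$nodes)
  part <- detectModules(net)
  m <- matrix(c(0.1, 0.2, 0.3, 0.05, 0.15, 0.2,
                0.3, 0.1, 0.1, 0.2, 0.2, 0.1,
                0.4, 0.1, 0.1, 0.1, 0.2, 0.1), 6, 3)
  dimnames(m) <- list(fx$nodes, c("s1", "s2", "s3"))
  tab <- AbundanceTable(m, "relative")
  modAb <- moduleRelativeAbundance(part, tab)
  lab1 <- names(majorLabels(part))[majorLabels(part) == "M1"]
  members1 <- names(membership(part))[membership(part) == lab1]
  expect_equal(modAb["M1", ], colSums(m[members1, ]))
  expect_equal(colSums(modAb), colSums(m), ignore_attr = TRUE)
  # zero-abundance module
  m2 <- m; m2[members1, "s1"] <- 0
  expect_equal(moduleRelativeAbundance(part, AbundanceTable(m2, "relative"))["M1", "s1"],
               0)
})

test_that("KO-module correlates honour the filters and nulls stay quiet", {
  modAb <- rbind(M1 = seq(0.1, 1, length.out = 20),
                 M2 = rep(0.5, 20))
  colnames(modAb) <- sprintf("s%02d", 1:20)
  k1 <- plogis(modAb["M1", ]) / 2                  # monotone transform of M1
  ko <- rbind(K1 = k1,
              K2 = rep(1e-7, 20),                  # below abundance filter
              K3 = 1 - k1 - 1e-7)                  # complement closes columns
  tab <- AbundanceTable(ko, "relative")
  res <- koModuleCorrelates(tab, modAb)
  expect_true(any(res$ko == "K1" & res$module == "M1" & res$rho == 1))
  expect_false(any(res$ko == "K2"))
  expect_error(koModuleCorrelates(tab, modAb[, 1:3]), "shared samples")
})

test_that("null KO screens retain about the nominal fraction", {
  spec <- covarianceSpec(12, module_sizes = c(4, 4, 4), within_r = 0.8)
  rates <- vapply(1:10, function(s) {
    sim <- simulateCounts(spec, 100, depth = 1e4, zero_inflation = 0,
                          seed = 700 + s)
    modAb <- plantedModuleAbundance(sim$truth, sim$table)
    kon <- simulateKoTable(sim$truth, modAb, n_kos = 50, linked_fraction = 0,
                           seed = 800 + s)
    res <- koModuleCorrelates(kon$table, modAb)
    nrow(res) / (50 * nrow(modAb))
  }, numeric(1))
  expect_lte(mean(rates), 0.05)
})
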