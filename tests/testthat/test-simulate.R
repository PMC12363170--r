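test_that("buildCovariance matches its definition and rejects non-PSD specs", {
  # independence: diagonal
  s0 <- covarianceSpec(5)
  expect_equal(buildCovariance(s0), diag(5), ignore_attr = TRUE)
  # forced off-diagonal
  s1 <- covarianceSpec(2, module_sizes = 2, within_r = 0.9)
  expect_equal(buildCovariance(s1)[1, 2], 0.9)
  # eigendecomposition oracle on a mixed-sign spec
  s2 <- covarianceSpec(6, module_sizes = c(3, 3), within_r = 0.8,
                       between_r = -0.5)
  ev <- eigen(buildCovariance(s2), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  # an impossible combination is rejected at construction
  expect_error(covarianceSpec(9, module_sizes = c(3, 3, 3), within_r = 0.2,
                              between_r = -0.6),
               "positive semi-definite")
})

test_that("simulateCounts respects depth, determinism and the latent blocks", {
  spec <- covarianceSpec(10, module_sizes = c(4, 4), within_r = 0.9)
  sim <- simulateCounts(spec, 20, depth = 5000, zero_inflation = 0, seed = 2)
  expect_true(all(colSums(abundances(sim$table)) == 5000))
  sim2 <- simulateCounts(spec, 20, depth = 5000, zero_inflation = 0, seed = 2)
  expect_identical(abundances(sim$table), abundances(sim2$table))
  expect_error(simulateCounts(spec, 1, seed = 1), "n_samples")

  # clr-transform oracle: within-block correlation exceeds cross-block
  big <- simulateCounts(spec, 500, depth = 1e5, zero_inflation = 0, seed = 4)
  m <- abundances(big$table) + 0.5
  clr <- apply(m, 2, function(x) log(x) - mean(log(x)))
  cc <- cor(t(clr))
  within <- c(cc[1:4, 1:4][upper.tri(diag(4))], cc[5:8, 5:8][upper.tri(diag(4))])
  across <- cc[1:4, 5:8]
  expect_gt(min(within), max(across))

  # zero inflation adds structural zeros at about the requested rate
  zi <- simulateCounts(spec, 200, depth = 1e4, zero_inflation = 0.3, seed = 6)
  expect_gt(mean(abundances(zi$table) == 0), 0.25)
})

test_that("every taxon is recorded once in the planted membership", {
  spec <- covarianceSpec(12, module_sizes = c(4, 3), within_r = 0.7)
  sim <- simulateCounts(spec, 5, depth = 1000, zero_inflation = 0, seed = 3)
  mem <- plantedModules(sim$truth)
  expect_identical(sort(names(mem)), sort(featureIds(sim$table)))
  expect_identical(unname(table(mem)[c("block1", "block2")]),
                   table(factor(c(rep(1, 4), rep(2, 3))), dnn = NULL),
                   ignore_attr = TRUE)
})

test_that("simulateClinical couples indicators to features as specified", {
  spec <- covarianceSpec(10, module_sizes = c(4, 4), within_r = 0.8)
  sim <- simulateCounts(spec, 200, depth = 1e4, zero_inflation = 0, seed = 5)
  modAb <- plantedModuleAbundance(sim$truth, sim$table)
  feats <- data.frame(t(modAb))

  # null construction: zero effects leave the indicator independent
  nullRes <- simulateClinical(sim$truth, feats,
                              coefficients = list(IND = c(block1 = 0)),
                              noise_sd = 1, seed = 11)
  expect_lt(abs(cor(nullRes$clinical$IND, feats$block1,
                    method = "spearman")), 0.2)

  # noiseless affine case: perfect rank agreement
  exact <- simulateClinical(sim$truth, feats,
                            coefficients = list(IND = c(block1 = 2)),
                            noise_sd = 0, seed = 11)
  expect_equal(cor(exact$clinical$IND, feats$block1, method = "spearman"), 1)

  # least-squares refit recovers both coefficient signs
  two <- simulateClinical(sim$truth, feats,
                          coefficients = list(IND = c(block1 = 1, block2 = -1)),
                          noise_sd = 0.5, seed = 12)
  beta <- coef(lm(two$clinical$IND ~ feats$block1 + feats$block2))
  expect_gt(beta[2], 0)
  expect_lt(beta[3], 0)

  expect_error(simulateClinical(sim$truth, feats,
                                coefficients = list(IND = c(nope = 1)),
                                seed = 1),
               "nope")
})

test_that("simulateCohort honours the design and plants the diversity trend", {
  spec <- covarianceSpec(25)
  des <- cohortDesign(groups = c("R00", "R01", "R02", "R03", "R04"),
                      samples_per_group = c(5L, 8L, 9L, 10L, 3L),
                      ranks = 0:4, trend_profile = c(2.5, -0.4, 0.1))
  sim <- simulateCohort(des, spec, depth = 2e4, seed = 30)
  expect_identical(unname(table(sim$metadata$group)[des@groups]),
                   c(5L, 8L, 9L, 10L, 3L), ignore_attr = TRUE)
  expect_identical(ncol(sim$table), 35L)

  # convex profile recovered from observed Shannon values
  rel <- toRelative(sim$table)
  sh <- apply(abundances(rel), 2, shannonIndex)
  fit <- fitTrend(sh, sim$metadata$rank)
  expect_true(fit$convex)

  expect_error(cohortDesign(groups = c("A", "B"), samples_per_group = c(3L),
                            ranks = 0:1, trend_profile = c(1, 0, 0)))
})

test_that("a flat cohort profile leaves groups indistinguishable", {
  spec <- covarianceSpec(25)
  des <- cohortDesign(groups = c("G1", "G2", "G3"),
                      samples_per_group = rep(20L, 3), ranks = 0:2,
                      trend_profile = c(2.4, 0, 0))
  pvals <- vapply(1:20, function(s) {
    sim <- simulateCohort(des, spec, depth = 2e4, seed = 100 + s)
    sh <- apply(abundances(toRelative(sim$table)), 2, shannonIndex)
    kruskal.test(sh, factor(sim$metadata$group))$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("KO table linkage is exact, counted, and absent under the null", {
  spec <- covarianceSpec(12, module_sizes = c(6, 6), within_r = 0.8)
  sim <- simulateCounts(spec, 100, depth = 1e4, zero_inflation = 0, seed = 40)
  modAb <- plantedModuleAbundance(sim$truth, sim$table)

  ko <- simulateKoTable(sim$truth, modAb, n_kos = 50, linked_fraction = 0.2,
                        seed = 41)
  expect_identical(length(ko$truth@koLinks), 10L)
  expect_true(all(abs(colSums(abundances(ko$table)) - 1) < 1e-9))

  # zero-noise linked KO is exactly monotone in its module
  ko0 <- simulateKoTable(sim$truth, modAb, n_kos = 20, linked_fraction = 0.1,
                         noise_sd = 0, seed = 42)
  drv <- ko0$truth@koLinks[1]
  expect_equal(cor(abundances(ko0$table)[names(drv), ], modAb[drv, ],
                   method = "spearman"), 1)

  # empty table keeps a valid header
  none <- simulateKoTable(sim$truth, modAb, n_kos = 0, seed = 43)
  expect_identical(dim(abundances(none$table)), c(0L, 100L))

  # unlinked KOs rarely cross the |rho| > 0.5 screen
  crossed <- vapply(1:10, function(s) {
    kon <- simulateKoTable(sim$truth, modAb, n_kos = 50, linked_fraction = 0,
                           seed = 500 + s)
    rmax <- max(abs(cor(t(abundances(kon$table)), t(modAb),
                        method = "spearman")))
    rmax > 0.5
  }, logical(1))
  expect_gte(mean(!crossed), 0.9)
})

test_that("generators are byte-deterministic and leave the RNG state alone", {
  spec <- covarianceSpec(6, module_sizes = 3, within_r = 0.5)
  set.seed(777); before <- .Random.seed
  sim <- simulateCounts(spec, 10, depth = 1000, zero_inflation = 0.2, seed = 9)
  expect_identical(.Random.seed, before)
  sim2 <- simulateCounts(spec, 10, depth = 1000, zero_inflation = 0.2, seed = 9)
  expect_identical(sim$table, sim2$table)
})
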