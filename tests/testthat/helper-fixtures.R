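## Shared fixtures and independent oracles for the test suite.

randomCountsTable <- function(d, n, seed, depth = 1e4) {
  withr::with_seed(seed, {
    m <- matrix(rpois(d * n, lambda = depth / d), d, n)
    dimnames(m) <- list(sprintf("t%03d", seq_len(d)),
                        sprintf("s%03d", seq_len(n)))
    AbundanceTable(m, "counts")
  })
}

## Strictly positive relative table (no zeros), for log-ratio oracles.
randomRelativeTable <- function(d, n, seed) {
  withr::with_seed(seed, {
    m <- matrix(rlnorm(d * n), d, n)
    m <- sweep(m, 2, colSums(m), "/")
    dimnames(m) <- list(sprintf("t%03d", seq_len(d)),
                        sprintf("s%03d", seq_len(n)))
    AbundanceTable(m, "relative")
  })
}

## Brute-force per-pair log-ratio variance (the oracle for logRatioVariances).
bruteLogRatioVar <- function(m) {
  d <- nrow(m)
  out <- matrix(0, d, d, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(d)) for (j in seq_len(d)) {
    if (i == j) next
    out[i, j] <- var(log(m[i, ] / m[j, ]))
  }
  out
}

## Brute-force Newman-Girvan Q via the full pairwise double sum.
bruteModularity <- function(A, comm) {
  m <- sum(A) / 2
  if (m == 0) return(0)
  deg <- rowSums(A)
  q <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(A)))
    if (comm[i] == comm[j]) q <- q + A[i, j] - deg[i] * deg[j] / (2 * m)
  q / (2 * m)
}

## Random simple graph as a CoNetwork (edge probability p).
randomNetwork <- function(n, p, seed) {
  withr::with_seed(seed, {
    nodes <- sprintf("n%02d", seq_len(n))
    pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
    keep <- runif(nrow(pairs)) < p
    edges <- data.frame(feature_a = nodes[pairs[keep, 1]],
                        feature_b = nodes[pairs[keep, 2]],
                        rho = runif(sum(keep), 0.7, 1))
    buildNetwork(edges, nodes)
  })
}

## Block edge list: all within-block pairs connected.
blockEdges <- function(blockSizes) {
  nodes <- sprintf("n%02d", seq_len(sum(blockSizes)))
  block <- rep(seq_along(blockSizes), blockSizes)
  pairs <- which(upper.tri(diag(length(nodes))), arr.ind = TRUE)
  keep <- block[pairs[, 1]] == block[pairs[, 2]]
  list(nodes = nodes, block = block,
       edges = data.frame(feature_a = nodes[pairs[keep, 1]],
                          feature_b = nodes[pairs[keep, 2]],
                          rho = 0.9))
}
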