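#' Log-ratio variance matrix
#'
#' The core SparCC statistic: `t[i, j]` is the sample variance, across
#' samples, of `log((x_i + pc) / (x_j + pc))`.  It is zero exactly when two
#' features are perfectly proportional and is invariant to the compositional
#' closure (per-sample totals cancel in the ratio).
#'
#' @param table a relative [AbundanceTable-class] with at least 2 samples.
#' @param pseudocount positive value added to zeros before taking logs; the
#'   default is 1e-6 of the mean per-sample mass (i.e. 1e-6 for unit-sum
#'   columns).
#' @return symmetric matrix with zero diagonal, features in rows/columns.
#' @export
logRatioVariances <- function(table, pseudocount = NULL) {
  stopIf(!is(table, "AbundanceTable"), "table must be an AbundanceTable")
  m <- abundances(table)
  stopIf(ncol(m) < 2L, "need at least 2 samples")
  allZero <- rowSums(m > 0) == 0
  stopIf(any(allZero),
         "feature(s) constant at zero across all samples: ",
         paste(utils::head(rownames(m)[allZero], 5L), collapse = ", "),
         "; apply prevalenceAbundanceFilter() first")
  pseudocount <- pseudocount %||% (1e-6 * mean(colSums(m)))
  stopIf(pseudocount <= 0, "pseudocount must be positive")
  m[m == 0] <- pseudocount
  logRatioVariancesFromLog(log(m))
}

## t_ij = var(L_i - L_j) = V_ii + V_jj - 2 V_ij with V = cov of log rows.
logRatioVariancesFromLog <- function(L) {
  V <- stats::cov(t(L))
  v <- diag(V)
  t <- outer(v, v, "+") - 2 * V
  t <- (t + t(t)) / 2
  diag(t) <- 0
  dimnames(t) <- list(rownames(L), rownames(L))
  t
}

#' Basis correlations from a log-ratio variance matrix
#'
#' Solves the SparCC linear system for the basis (log-scale) variances
#' `omega` under the sparsity approximation `t[i, j] ~ omega_i + omega_j`,
#' then forms `rho[i, j] = (omega_i + omega_j - t[i, j]) /
#' (2 * sqrt(omega_i * omega_j))`, clamped to \[-1, 1\].  The strongest
#' correlated pair exceeding `exclusion_threshold` in absolute value is then
#' iteratively excluded from the system (its `t` entry no longer informs
#' `omega`) and the system re-solved, so strong true correlations do not
#' bias the variance estimates.  By default exclusion iterates until no
#' remaining pair exceeds the threshold (block-structured communities need
#' one round per strongly correlated pair; stopping early leaves a negative
#' closure bias on the unrelated pairs); a finite `exclusion_iterations`
#' caps the rounds.  Ties on |rho| are broken by the lexicographically
#' smallest feature pair, making the procedure deterministic.
#'
#' @param t symmetric log-ratio variance matrix from [logRatioVariances()].
#' @param exclusion_threshold |rho| above which a pair may be excluded.
#' @param exclusion_iterations maximum exclusion rounds; `NULL` (default)
#'   iterates to convergence.
#' @return list with `rho` (symmetric, unit diagonal) and `omega` (named
#'   basis variances).  Negative solved variances are floored at a tiny
#'   positive tolerance with a warning.
#' @export
basisCorrelations <- function(t, exclusion_threshold = 0.1,
                              exclusion_iterations = NULL) {
  d <- nrow(t)
  stopIf(is.null(d) || d < 4L,
         "need at least 4 features to solve the basis system")
  stopIf(max(abs(t - t(t))) > 1e-8 || any(abs(diag(t)) > 1e-8),
         "t must be symmetric with zero diagonal")
  ids <- rownames(t) %||% sprintf("f%03d", seq_len(d))
  include <- matrix(TRUE, d, d); diag(include) <- FALSE
  ## clr variances from the t identity: fallback scale for degenerate solves
  ## (a tiny floor would let the rho ratio explode to a clamped +-1)
  vclr <- rowSums(t) / d - sum(t) / (2 * d^2)
  vclr[vclr <= 0] <- 1e-10
  solveOmega <- function(incl) {
    k <- rowSums(incl)
    A <- diag(k) + incl
    b <- rowSums(t * incl)
    omega <- tryCatch(solve(A, b), error = function(e)
      stop("basis system is singular: ", conditionMessage(e), call. = FALSE))
    bad <- omega <= 0
    if (any(bad)) {
      warning("negative basis variance estimate(s) replaced by the clr variance (degenerate system)",
              call. = FALSE)
      omega[bad] <- vclr[bad]
    }
    omega
  }
  rhoFrom <- function(omega) {
    r <- (outer(omega, omega, "+") - t) / (2 * sqrt(outer(omega, omega)))
    r <- clamp((r + t(r)) / 2)
    diag(r) <- 1
    r
  }
  omega <- solveOmega(include)
  rho <- rhoFrom(omega)
  excluded <- matrix(FALSE, d, d)
  maxRounds <- exclusion_iterations %||% (d * (d - 1) / 2)
  for (iter in seq_len(maxRounds)) {
    cand <- abs(rho)
    cand[lower.tri(cand, diag = TRUE)] <- -Inf
    cand[excluded] <- -Inf
    ## keep the variance system over-determined: a feature must retain at
    ## least half its partners (and never fewer than 2), else omega degrades
    deg <- rowSums(include)
    bad <- which(deg <= pmax(2, floor(d / 2)))
    if (length(bad)) { cand[bad, ] <- -Inf; cand[, bad] <- -Inf }
    best <- max(cand)
    if (!is.finite(best) || best <= exclusion_threshold) break
    hits <- which(cand == best, arr.ind = TRUE)
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    i <- hits[1L, 1L]; j <- hits[1L, 2L]
    excluded[i, j] <- excluded[j, i] <- TRUE
    include[i, j] <- include[j, i] <- FALSE
    omega <- solveOmega(include)
    rho <- rhoFrom(omega)
  }
  dimnames(rho) <- list(ids, ids)
  list(rho = rho, omega = stats::setNames(omega, ids))
}

## One SparCC pass on a strictly positive fraction matrix (features x samples).
sparccSinglePass <- function(frac, exclusion_threshold, exclusion_iterations) {
  basisCorrelations(logRatioVariancesFromLog(log(frac)),
                    exclusion_threshold, exclusion_iterations)
}

## Draw posterior fractions from per-sample Dirichlet(counts + 1).
dirichletFractions <- function(counts) {
  g <- matrix(stats::rgamma(length(counts), shape = counts + 1),
              nrow(counts), dimnames = dimnames(counts))
  sweep(g, 2L, colSums(g), "/")
}

#' SparCC correlation estimate
#'
#' For a counts table, draws `n_resamples` per-sample Dirichlet posterior
#' fraction matrices (shape = counts + 1, guaranteeing strictly positive
#' fractions), runs the basis-correlation solver on each, and averages the
#' resulting correlation matrices.  For a relative table a single pass is run
#' with a small pseudocount on zeros (no resampling).  Fully deterministic
#' given `seed`.
#'
#' @param table a counts or relative [AbundanceTable-class] (already
#'   prevalence-filtered).
#' @param n_resamples Dirichlet resamples for the counts path (>= 1).
#' @param exclusion_threshold,exclusion_iterations passed to
#'   [basisCorrelations()].
#' @param seed integer seed.
#' @return a [CorrelationResult-class] (without p/q until
#'   [bootstrapPvalues()] is run).
#' @examples
#' sim <- simulateCounts(covarianceSpec(6, c(3, 3), 0.8), 50, 1e4, 0, seed = 7)
#' fit <- sparccEstimate(sim$table, seed = 7)
#' round(corMatrix(fit)[1:3, 1:3], 2)
#' @export
sparccEstimate <- function(table, n_resamples = 20, exclusion_threshold = 0.1,
                           exclusion_iterations = NULL, seed) {
  stopIf(!is(table, "AbundanceTable"), "table must be an AbundanceTable")
  stopIf(!isWholeNumber(n_resamples) || n_resamples < 1,
         "n_resamples must be a positive integer")
  m <- abundances(table)
  if (tableKind(table) == "relative") {
    t <- logRatioVariances(table)
    est <- basisCorrelations(t, exclusion_threshold, exclusion_iterations)
    nRes <- 1L
  } else {
    est <- withSeed(seed, {
      acc <- NULL; accOmega <- NULL
      for (r in seq_len(n_resamples)) {
        frac <- dirichletFractions(m)
        one <- sparccSinglePass(frac, exclusion_threshold, exclusion_iterations)
        acc <- if (is.null(acc)) one$rho else acc + one$rho
        accOmega <- if (is.null(accOmega)) one$omega else accOmega + one$omega
      }
      list(rho = acc / n_resamples, omega = accOmega / n_resamples)
    })
    nRes <- as.integer(n_resamples)
  }
  rho <- clamp(est$rho); diag(rho) <- 1
  new("CorrelationResult", rho = rho, omega = est$omega,
      p = matrix(numeric(), 0, 0), q = matrix(numeric(), 0, 0),
      nResamples = nRes, nBootstrap = 0L, seed = as.integer(seed))
}

#' Bootstrap pseudo-p-values and BH q-values for SparCC correlations
#'
#' Each bootstrap replicate permutes every feature's values independently
#' across samples (destroying all associations while preserving each
#' feature's marginal distribution), re-runs the SparCC estimator, and the
#' two-sided pseudo-p-value for each pair is
#' `(1 + #\{|rho_boot| >= |rho_obs|\}) / (1 + n_bootstrap)` - bounded below
#' by `1/(1 + n_bootstrap)`, so no pair gets an artifactual zero.
#' Benjamini-Hochberg adjustment is applied over the family of all unordered
#' feature pairs.
#'
#' @param table the table used for the observed estimate.
#' @param result the observed [CorrelationResult-class].
#' @param n_bootstrap number of permutation replicates (>= 20).
#' @param n_resamples Dirichlet resamples per replicate (defaults to the
#'   observed estimate's setting).
#' @param seed integer seed.
#' @return the [CorrelationResult-class] with `p` and `q` matrices attached.
#' @export
bootstrapPvalues <- function(table, result, n_bootstrap = 100,
                             n_resamples = NULL, seed) {
  stopIf(!is(result, "CorrelationResult"), "result must be a CorrelationResult")
  stopIf(!isWholeNumber(n_bootstrap) || n_bootstrap < 20,
         "n_bootstrap must be an integer >= 20")
  m <- abundances(table)
  d <- nrow(m)
  stopIf(d != nrow(result@rho), "table and result dimensions disagree")
  n_resamples <- n_resamples %||% result@nResamples
  obs <- abs(result@rho)
  exceed <- matrix(0L, d, d)
  seeds <- childSeeds(seed, n_bootstrap + 1L)
  perms <- withSeed(seeds[1L], {
    lapply(seq_len(n_bootstrap), function(b)
      vapply(seq_len(d), function(i) sample.int(ncol(m)), integer(ncol(m))))
  })
  for (b in seq_len(n_bootstrap)) {
    pm <- m
    for (i in seq_len(d)) pm[i, ] <- m[i, perms[[b]][, i]]
    permTable <- AbundanceTable(pm, tableKind(table))
    rb <- suppressWarnings(
      sparccEstimate(permTable, n_resamples = n_resamples,
                     seed = seeds[b + 1L]))
    exceed <- exceed + (abs(rb@rho) >= obs)
  }
  p <- (1 + exceed) / (1 + n_bootstrap)
  diag(p) <- 0
  dimnames(p) <- dimnames(result@rho)
  q <- bhAdjust(p)
  result@p <- p
  result@q <- q
  result@nBootstrap <- as.integer(n_bootstrap)
  result
}

#' Benjamini-Hochberg adjustment over the feature-pair family
#'
#' Standard step-up FDR adjustment ([stats::p.adjust()] with
#' `method = "BH"`), applied to the upper triangle of a symmetric pair
#' p-value matrix (the family = all unordered feature pairs) or to a plain
#' vector.
#'
#' @param p symmetric p-value matrix or numeric vector in \[0, 1\].
#' @return object of the same shape holding q-values (diagonal zero for
#'   matrices).
#' @export
bhAdjust <- function(p) {
  if (is.matrix(p)) {
    stopIf(nrow(p) != ncol(p), "p matrix must be square")
    q <- p
    ut <- upper.tri(p)
    q[ut] <- stats::p.adjust(p[ut], method = "BH")
    q[lower.tri(q)] <- t(q)[lower.tri(q)]
    diag(q) <- 0
    q
  } else {
    stats::p.adjust(p, method = "BH")
  }
}

#' Filter correlations into a significant edge list
#'
#' Default mode keeps pairs with `|rho| > r_threshold` and
#' `q < q_threshold`, retaining the correlation's sign as an edge attribute.
#' `signed_mode = TRUE` applies the threshold to the signed correlation
#' (`rho > r_threshold`), keeping positive associations only.
#'
#' @param result a bootstrapped [CorrelationResult-class].
#' @param r_threshold correlation magnitude threshold in \[0, 1\].
#' @param q_threshold FDR threshold in \[0, 1\].
#' @param signed_mode keep only positive correlations exceeding the
#'   threshold.
#' @return data.frame with columns `feature_a`, `feature_b`, `rho`, `p`,
#'   `q`, `sign`.
#' @export
edgeFilter <- function(result, r_threshold = 0.7, q_threshold = 0.05,
                       signed_mode = FALSE) {
  stopIf(!is(result, "CorrelationResult"), "result must be a CorrelationResult")
  stopIf(r_threshold < 0 || r_threshold > 1, "r_threshold must lie in [0, 1]")
  stopIf(q_threshold < 0 || q_threshold > 1, "q_threshold must lie in [0, 1]")
  rho <- result@rho
  q <- qValues(result)
  p <- pValues(result)
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  keepR <- if (signed_mode) rho[ut] > r_threshold else abs(rho[ut]) > r_threshold
  keep <- keepR & q[ut] < q_threshold
  ids <- rownames(rho)
  out <- data.frame(feature_a = ids[ut[keep, 1L]],
                    feature_b = ids[ut[keep, 2L]],
                    rho = rho[ut][keep], p = p[ut][keep], q = q[ut][keep],
                    stringsAsFactors = FALSE)
  out$sign <- ifelse(out$rho >= 0, 1L, -1L)
  out[order(out$feature_a, out$feature_b), , drop = FALSE]
}
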