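#' Create a covariance specification
#'
#' @param n_taxa total number of taxa.
#' @param module_sizes sizes of the planted correlation blocks (disjoint,
#'   summing to at most `n_taxa`; remaining taxa are uncorrelated background).
#' @param within_r,between_r intra- and inter-block correlations in (-1, 1).
#' @param log_mean,log_sd per-taxon log-scale means and standard deviations;
#'   defaults spread the means over about three natural-log units (a typical
#'   genus-level abundance range) with unit log-scale dispersion.
#' @return a validated [CovarianceSpec-class]; non-positive-semi-definite
#'   parameter combinations are rejected at construction.
#' @examples
#' covarianceSpec(12, module_sizes = c(4, 4), within_r = 0.8)
#' @export
covarianceSpec <- function(n_taxa, module_sizes = integer(), within_r = 0,
                           between_r = 0, log_mean = NULL, log_sd = NULL) {
  stopIf(!isWholeNumber(n_taxa) || n_taxa < 1, "n_taxa must be a positive integer")
  if (is.null(log_mean))
    log_mean <- seq(1.5, -1.5, length.out = n_taxa)
  if (is.null(log_sd)) log_sd <- rep(1, n_taxa)
  new("CovarianceSpec", nTaxa = as.integer(n_taxa),
      moduleSizes = as.integer(module_sizes),
      withinR = within_r, betweenR = between_r,
      logMean = log_mean, logSd = log_sd)
}

## Correlation matrix implied by a spec (blocks of within_r, between_r across
## blocks, background taxa independent).
buildCorrelation <- function(spec) {
  d <- spec@nTaxa
  R <- diag(d)
  sizes <- spec@moduleSizes
  if (length(sizes)) {
    blockOf <- rep(seq_along(sizes), sizes)
    idx <- seq_len(sum(sizes))
    same <- outer(blockOf, blockOf, "==")
    R[idx, idx] <- ifelse(same, spec@withinR, spec@betweenR)
    diag(R) <- 1
  }
  R
}

#' Latent log-scale covariance matrix of a specification
#'
#' Entries are `within_r * sd_i * sd_j` inside blocks, `between_r * sd_i *
#' sd_j` across blocks, zero for background taxa, with `log_sd^2` on the
#' diagonal.
#'
#' @param spec a [CovarianceSpec-class].
#' @return the positive semi-definite covariance matrix.
#' @export
buildCovariance <- function(spec) {
  stopIf(!is(spec, "CovarianceSpec"), "spec must be a CovarianceSpec")
  D <- diag(spec@logSd, spec@nTaxa)
  S <- D %*% buildCorrelation(spec) %*% D
  dimnames(S) <- list(taxonNames(spec@nTaxa), taxonNames(spec@nTaxa))
  S
}

taxonNames <- function(d) sprintf("taxon_%03d", seq_len(d))

plantedMembership <- function(spec) {
  sizes <- spec@moduleSizes
  mods <- c(rep(sprintf("block%d", seq_along(sizes)), sizes),
            rep("background", spec@nTaxa - sum(sizes)))
  stats::setNames(mods, taxonNames(spec@nTaxa))
}

#' Simulate compositional count tables with planted correlation blocks
#'
#' The generative model is the one SparCC targets: per sample, latent
#' log-abundances are drawn from the multivariate normal defined by `spec`,
#' exponentiated and closed to a composition, and counts are drawn
#' multinomially at the requested sequencing depth.  Structural zeros are
#' then applied as independent Bernoulli masking at rate `zero_inflation`.
#' Identical seeds reproduce the table bit-for-bit.
#'
#' @param spec a [CovarianceSpec-class].
#' @param n_samples number of samples (>= 2).
#' @param depth multinomial sequencing depth per sample.
#' @param zero_inflation structural-zero rate in \[0, 1).
#' @param seed integer seed; all randomness in the call flows through it.
#' @return list with `table` (counts [AbundanceTable-class]) and `truth`
#'   (a [SyntheticTruth-class] recording the planted block memberships).
#' @examples
#' sim <- simulateCounts(covarianceSpec(8, c(3, 3), 0.8), n_samples = 10,
#'                       depth = 1e4, zero_inflation = 0, seed = 1)
#' colSums(abundances(sim$table))
#' @export
simulateCounts <- function(spec, n_samples, depth = 1e5, zero_inflation = 0.1,
                           seed) {
  stopIf(!is(spec, "CovarianceSpec"), "spec must be a CovarianceSpec")
  stopIf(!isWholeNumber(n_samples) || n_samples < 2,
         "n_samples must be an integer >= 2 (downstream variance is undefined otherwise)")
  stopIf(depth < 1, "depth must be >= 1")
  stopIf(zero_inflation < 0 || zero_inflation >= 1,
         "zero_inflation must lie in [0, 1)")
  Sigma <- buildCovariance(spec)
  counts <- withSeed(seed, {
    Z <- MASS::mvrnorm(n_samples, mu = spec@logMean, Sigma = Sigma)
    comp <- exp(Z)
    comp <- comp / rowSums(comp)
    cnt <- apply(comp, 1L, function(p) stats::rmultinom(1L, depth, p))
    if (zero_inflation > 0) {
      mask <- matrix(stats::runif(length(cnt)) < zero_inflation, nrow(cnt))
      cnt[mask] <- 0
    }
    cnt
  })
  dimnames(counts) <- list(taxonNames(spec@nTaxa),
                           sprintf("sample_%03d", seq_len(n_samples)))
  truth <- new("SyntheticTruth", spec = spec,
               moduleOfTaxon = plantedMembership(spec),
               clinicalCoefficients = list(), koLinks = character(),
               seed = as.integer(seed))
  list(table = AbundanceTable(counts, "counts"), truth = truth)
}

#' Simulate clinical indicators coupled to network features
#'
#' Each indicator is a linear combination of named feature columns (module
#' abundances, per-sample network properties, ...) plus Gaussian noise.  The
#' coefficients are recorded in the returned truth object so recovery tests
#' can score a downstream association analysis.
#'
#' @param truth a [SyntheticTruth-class]; its stored coefficients are used
#'   when `coefficients` is not supplied.
#' @param features data.frame of per-sample feature values (rows = samples,
#'   row names = sample ids).
#' @param coefficients named list: indicator name -> named numeric vector of
#'   effect sizes per feature.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return list with `clinical` (data.frame of indicators, one row per
#'   sample) and `truth` (updated with the coefficients used).
#' @export
simulateClinical <- function(truth, features, coefficients = NULL,
                             noise_sd = 1, seed) {
  stopIf(!is(truth, "SyntheticTruth"), "truth must be a SyntheticTruth")
  stopIf(!is.data.frame(features) || is.null(rownames(features)),
         "features must be a data.frame with sample ids as row names")
  stopIf(noise_sd < 0, "noise_sd must be non-negative")
  coefficients <- coefficients %||% truth@clinicalCoefficients
  stopIf(!length(coefficients), "no clinical coefficients supplied or stored")
  for (ind in names(coefficients)) {
    missing <- setdiff(names(coefficients[[ind]]), colnames(features))
    stopIf(length(missing) > 0L,
           sprintf("indicator '%s' references absent feature(s): %s",
                   ind, paste(missing, collapse = ", ")))
  }
  n <- nrow(features)
  clin <- withSeed(seed, {
    out <- lapply(coefficients, function(beta) {
      y <- as.numeric(as.matrix(features[, names(beta), drop = FALSE]) %*% beta)
      y + stats::rnorm(n, sd = noise_sd)
    })
    as.data.frame(out, row.names = rownames(features))
  })
  truth@clinicalCoefficients <- coefficients
  list(clinical = clin, truth = truth)
}

#' Create a longitudinal cohort design
#'
#' Defaults emulate a transplant-style cohort: a healthy-control group off
#' the time gradient, a pre-transplant baseline, and five post-transplant
#' timepoints with 5, 8, 9, 10 and 3 samples.
#'
#' @param groups ordered group labels.
#' @param samples_per_group samples per group.
#' @param ranks numeric time rank per group (`NA` = off the gradient; such
#'   groups use the rank-0 trend value).
#' @param trend_profile quadratic coefficients `(intercept, linear,
#'   quadratic)` for the planted per-sample Shannon-entropy target over rank.
#' @return a validated [CohortDesign-class].
#' @export
cohortDesign <- function(groups = c("HC", "R00", "R01", "R02", "R03", "R04", "R05"),
                         samples_per_group = c(20L, 26L, 5L, 8L, 9L, 10L, 3L),
                         ranks = c(NA, 0, 1, 2, 3, 4, 5),
                         trend_profile = c(2.6, -0.4, 0.08)) {
  new("CohortDesign", groups = as.character(groups),
      samplesPerGroup = as.integer(samples_per_group),
      ranks = as.numeric(ranks), trendProfile = as.numeric(trend_profile))
}

## Exponent-tempering: solve for beta > 0 such that the Shannon entropy of
## p^beta (renormalised) equals the target. Entropy is strictly decreasing in
## beta, so the root is unique.
temperToEntropy <- function(p, targetH) {
  p <- p / sum(p)
  maxH <- log(length(p))
  targetH <- clamp(targetH, 0.02, maxH - 0.02)
  entAt <- function(beta) {
    q <- exp(beta * log(p))
    q <- q / sum(q)
    q <- q[q > 0]
    -sum(q * log(q))
  }
  root <- stats::uniroot(function(b) entAt(b) - targetH,
                         lower = 1e-4, upper = 60, tol = 1e-10)$root
  q <- exp(root * log(p))
  q / sum(q)
}

#' Simulate a longitudinal cohort with a planted diversity trend
#'
#' Generates one abundance table covering all groups.  Each sample's latent
#' composition is drawn from `spec` and then tempered so that its Shannon
#' entropy equals a planted target: the quadratic trend profile evaluated at
#' the group's time rank, plus N(0, `attribute_sd`) inter-individual jitter.
#' Counts are drawn multinomially at `depth`.  A convex profile therefore
#' yields the U-shaped first-decreasing-then-increasing diversity trajectory
#' that trend-fit tests should recover.
#'
#' @param design a [CohortDesign-class].
#' @param spec a [CovarianceSpec-class].
#' @param depth multinomial depth per sample.
#' @param attribute_sd per-sample jitter on the entropy target.
#' @param seed integer seed.
#' @return list with `table` (counts [AbundanceTable-class] whose `colData`
#'   carries `group` and `rank`), `metadata` (the same as a data.frame),
#'   `target_shannon` (planted per-sample entropy targets) and `truth`.
#' @export
simulateCohort <- function(design, spec, depth = 1e5, attribute_sd = 0.05,
                           seed) {
  stopIf(!is(design, "CohortDesign"), "design must be a CohortDesign")
  stopIf(!is(spec, "CovarianceSpec"), "spec must be a CovarianceSpec")
  Sigma <- buildCovariance(spec)
  tp <- design@trendProfile
  n <- sum(design@samplesPerGroup)
  group <- rep(design@groups, design@samplesPerGroup)
  rank <- rep(design@ranks, design@samplesPerGroup)
  rankEff <- ifelse(is.na(rank), 0, rank)
  targetMean <- tp[1] + tp[2] * rankEff + tp[3] * rankEff^2
  res <- withSeed(seed, {
    targets <- targetMean + stats::rnorm(n, sd = attribute_sd)
    Z <- MASS::mvrnorm(n, mu = spec@logMean, Sigma = Sigma)
    comp <- exp(Z)
    comp <- comp / rowSums(comp)
    cnt <- vapply(seq_len(n), function(s) {
      p <- temperToEntropy(comp[s, ], targets[s])
      stats::rmultinom(1L, depth, p)[, 1L]
    }, numeric(spec@nTaxa))
    list(counts = cnt, targets = targets)
  })
  counts <- res$counts
  dimnames(counts) <- list(taxonNames(spec@nTaxa),
                           sprintf("%s_s%03d", group, seq_len(n)))
  meta <- data.frame(sample_id = colnames(counts), group = group, rank = rank,
                     stringsAsFactors = FALSE)
  truth <- new("SyntheticTruth", spec = spec,
               moduleOfTaxon = plantedMembership(spec),
               clinicalCoefficients = list(), koLinks = character(),
               seed = as.integer(seed))
  list(table = AbundanceTable(counts, "counts",
                              sampleData = meta[, c("group", "rank")]),
       metadata = meta,
       target_shannon = stats::setNames(res$targets, colnames(counts)),
       truth = truth)
}

#' Simulate a KO functional table partially coupled to modules
#'
#' A fraction of the KOs are "linked": their relative abundance is an affine,
#' strictly increasing function of a designated planted module's total
#' abundance (modules are assigned to linked KOs round-robin), perturbed by
#' log-normal noise.  Unlinked KOs split the remaining mass according to
#' independent log-normal weights.  Columns are exact compositions; with
#' `noise_sd = 0` a linked KO is exactly monotone in its module, so its
#' Spearman correlation is 1.
#'
#' @param truth a [SyntheticTruth-class] with planted modules.
#' @param module_abundances numeric matrix of module relative abundances
#'   (rows = planted module ids, columns = samples), e.g. summed from the
#'   simulated table using [plantedModules()].
#' @param n_kos number of KOs (0 gives an empty table with a valid header).
#' @param linked_fraction fraction of KOs linked to modules in \[0, 1\].
#' @param noise_sd log-normal noise on the linked KOs.
#' @param seed integer seed.
#' @return list with `table` (relative [AbundanceTable-class] of KOs) and
#'   `truth` (updated: `@koLinks` maps each linked KO to its module).
#' @export
simulateKoTable <- function(truth, module_abundances, n_kos,
                            linked_fraction = 0.2, noise_sd = 0.3, seed) {
  stopIf(!is(truth, "SyntheticTruth"), "truth must be a SyntheticTruth")
  stopIf(!isWholeNumber(n_kos) || n_kos < 0, "n_kos must be a non-negative integer")
  stopIf(linked_fraction < 0 || linked_fraction > 1,
         "linked_fraction must lie in [0, 1]")
  koIds <- sprintf("K%05d", seq_len(n_kos))
  if (n_kos == 0L) {
    empty <- matrix(numeric(), 0L, ncol(module_abundances),
                    dimnames = list(NULL, colnames(module_abundances)))
    return(list(table = AbundanceTable(empty, "relative"), truth = truth))
  }
  mods <- rownames(module_abundances)
  stopIf(is.null(mods), "module_abundances must have module ids as row names")
  nLinked <- round(n_kos * linked_fraction)
  linkMod <- if (nLinked) mods[(seq_len(nLinked) - 1L) %% length(mods) + 1L]
             else character()
  nSamp <- ncol(module_abundances)
  vals <- withSeed(seed, {
    m <- matrix(0, n_kos, nSamp, dimnames = list(koIds,
                                                 colnames(module_abundances)))
    ## linked KOs: fraction proportional to the driving module's abundance,
    ## scaled so the linked mass stays well below 1 per sample
    if (nLinked) {
      scale <- 0.5 / nLinked
      for (i in seq_len(nLinked)) {
        drv <- module_abundances[linkMod[i], ] / max(module_abundances[linkMod[i], ])
        eps <- if (noise_sd > 0) exp(stats::rnorm(nSamp, sd = noise_sd)) else 1
        m[i, ] <- scale * drv * eps
      }
      m[seq_len(nLinked), ] <- pmin(m[seq_len(nLinked), , drop = FALSE], 0.9 / nLinked)
    }
    ## unlinked KOs share the remaining mass by independent lognormal weights
    if (n_kos > nLinked) {
      w <- matrix(exp(stats::rnorm((n_kos - nLinked) * nSamp)), ncol = nSamp)
      rest <- 1 - colSums(m[seq_len(nLinked), , drop = FALSE])
      m[(nLinked + 1L):n_kos, ] <- sweep(sweep(w, 2L, colSums(w), "/"),
                                         2L, rest, "*")
    } else {
      m <- sweep(m, 2L, colSums(m), "/")
    }
    m
  })
  truth@koLinks <- stats::setNames(linkMod, koIds[seq_len(nLinked)])
  list(table = AbundanceTable(vals, "relative"), truth = truth)
}

#' Sum planted-module abundances from a table
#'
#' Convenience used by the simulator tests and pipeline: total relative
#' abundance of each planted block per sample.
#'
#' @param truth a [SyntheticTruth-class].
#' @param table an [AbundanceTable-class] (converted to relative if counts).
#' @return matrix, planted module ids x samples.
#' @export
plantedModuleAbundance <- function(truth, table) {
  if (tableKind(table) == "counts") table <- toRelative(table)
  m <- abundances(table)
  mem <- truth@moduleOfTaxon[rownames(m)]
  mods <- setdiff(unique(mem), "background")
  out <- t(vapply(mods, function(g) colSums(m[mem == g, , drop = FALSE]),
                  numeric(ncol(m))))
  rownames(out) <- mods
  out
}
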