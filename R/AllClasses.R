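#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Taxon- or KO-by-sample abundance table
#'
#' An `AbundanceTable` is a [SummarizedExperiment::SummarizedExperiment]
#' carrying a single non-negative feature-by-sample assay plus a `kind` flag
#' distinguishing raw counts from relative abundances (fractions).  Feature
#' and sample identifiers live in the dimnames and must be unique; sample
#' metadata (group, timepoint, ...) lives in `colData`.
#'
#' For `kind = "relative"` every column of a freshly normalised table sums to
#' one; feature-filtered subsets of a relative table keep the flag but their
#' columns may sum to less than one, so validity only bounds column sums from
#' above.
#'
#' @slot kind `"counts"` or `"relative"`.
#' @seealso [AbundanceTable()], [toRelative()], [prevalenceAbundanceFilter()]
#' @export
setClass("AbundanceTable",
  contains = "SummarizedExperiment",
  representation(kind = "character"))

setValidity("AbundanceTable", function(object) {
  msg <- character()
  if (length(object@kind) != 1L || !object@kind %in% c("counts", "relative"))
    msg <- c(msg, "kind must be one of 'counts', 'relative'")
  m <- SummarizedExperiment::assay(object, withDimnames = FALSE)
  if (!is.matrix(m) || !is.numeric(m))
    msg <- c(msg, "assay must be a numeric matrix")
  else {
    if (anyNA(m) || any(m < 0))
      msg <- c(msg, "abundances must be non-negative and non-missing")
    if (nrow(m) && (is.null(rownames(object)) || anyDuplicated(rownames(object))))
      msg <- c(msg, "feature ids must be present and unique")
    if (ncol(m) && (is.null(colnames(object)) || anyDuplicated(colnames(object))))
      msg <- c(msg, "sample ids must be present and unique")
    if (identical(object@kind, "relative") && ncol(m) && nrow(m)) {
      cs <- colSums(m)
      if (any(cs > 1 + 1e-6))
        msg <- c(msg, "relative-abundance columns must not sum to more than 1")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Planted latent covariance specification for the compositional simulator
#'
#' Describes the log-scale ("basis") covariance of the taxa the simulator
#' draws from: disjoint blocks of `module_sizes` taxa share pairwise
#' correlation `within_r`, taxa in different blocks have correlation
#' `between_r`, and any taxa beyond `sum(module_sizes)` are uncorrelated
#' background.  The implied covariance matrix must be positive semi-definite;
#' construction fails otherwise.
#'
#' @slot nTaxa total number of taxa.
#' @slot moduleSizes integer sizes of the planted correlation blocks.
#' @slot withinR,betweenR intra- and inter-block correlations in (-1, 1).
#' @slot logMean,logSd per-taxon log-scale means and standard deviations.
#' @seealso [covarianceSpec()], [buildCovariance()], [simulateCounts()]
#' @export
setClass("CovarianceSpec",
  representation(nTaxa = "integer", moduleSizes = "integer",
                 withinR = "numeric", betweenR = "numeric",
                 logMean = "numeric", logSd = "numeric"))

setValidity("CovarianceSpec", function(object) {
  msg <- character()
  if (object@nTaxa < 1L) msg <- c(msg, "nTaxa must be positive")
  if (any(object@moduleSizes < 1L))
    msg <- c(msg, "module sizes must be positive")
  if (sum(object@moduleSizes) > object@nTaxa)
    msg <- c(msg, "module sizes must sum to at most nTaxa")
  for (r in c(object@withinR, object@betweenR))
    if (abs(r) >= 1) msg <- c(msg, "correlations must lie in (-1, 1)")
  if (length(object@logMean) != object@nTaxa ||
      length(object@logSd) != object@nTaxa)
    msg <- c(msg, "logMean and logSd must have length nTaxa")
  if (any(object@logSd <= 0)) msg <- c(msg, "logSd must be positive")
  if (!length(msg)) {
    ev <- eigen(buildCorrelation(object), symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) < -1e-8)
      msg <- c(msg, sprintf(
        "implied covariance is not positive semi-definite (min eigenvalue %.3g); reduce |between_r| or block sizes",
        min(ev)))
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth record for simulated data
#'
#' Carries everything a recovery test needs to score a downstream analysis of
#' a simulated table: the covariance specification, the planted module of
#' every taxon (`"background"` for unblocked taxa), the linear coefficients
#' used to couple clinical indicators to features, the KO-to-module linkage
#' map, and the seed.
#'
#' @slot spec the [CovarianceSpec-class] used.
#' @slot moduleOfTaxon named character, taxon id -> planted module id.
#' @slot clinicalCoefficients named list, indicator -> named numeric of
#'   per-feature effect sizes.
#' @slot koLinks named character, linked KO id -> driving module id.
#' @slot seed integer seed recorded verbatim.
#' @export
setClass("SyntheticTruth",
  representation(spec = "CovarianceSpec", moduleOfTaxon = "character",
                 clinicalCoefficients = "list", koLinks = "character",
                 seed = "integer"))

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  if (is.null(names(object@moduleOfTaxon)) ||
      anyDuplicated(names(object@moduleOfTaxon)))
    msg <- c(msg, "every taxon must appear exactly once in moduleOfTaxon")
  if (length(msg)) msg else TRUE
})

#' Longitudinal cohort design for the simulator
#'
#' Ordered group labels (e.g. HC, R00..R05), per-group sample counts, group
#' ranks on the post-transplant time gradient (`NA` for groups off the
#' gradient, which then use the rank-0 trend value), and a quadratic trend
#' profile `(intercept, linear, quadratic)` for the planted per-sample
#' attribute (target Shannon entropy).
#'
#' @slot groups ordered group labels.
#' @slot samplesPerGroup positive integer per group.
#' @slot ranks numeric rank per group (NA allowed).
#' @slot trendProfile numeric length-3 quadratic coefficients.
#' @seealso [cohortDesign()], [simulateCohort()]
#' @export
setClass("CohortDesign",
  representation(groups = "character", samplesPerGroup = "integer",
                 ranks = "numeric", trendProfile = "numeric"))

setValidity("CohortDesign", function(object) {
  msg <- character()
  n <- length(object@groups)
  if (!n || anyDuplicated(object@groups))
    msg <- c(msg, "groups must be non-empty and unique")
  if (length(object@samplesPerGroup) != n)
    msg <- c(msg, "samplesPerGroup must match the number of groups")
  if (any(object@samplesPerGroup < 1L))
    msg <- c(msg, "every group needs at least one sample")
  if (length(object@ranks) != n)
    msg <- c(msg, "ranks must match the number of groups")
  if (length(object@trendProfile) != 3L)
    msg <- c(msg, "trendProfile must be (intercept, linear, quadratic)")
  if (length(msg)) msg else TRUE
})

#' SparCC correlation estimate with optional edge significance
#'
#' Result of [sparccEstimate()]: the basis correlation matrix `rho` (diagonal
#' one, entries clamped to \[-1, 1\]), the estimated log-scale basis
#' variances `omega`, and - once [bootstrapPvalues()] has been run - the
#' bootstrap pseudo-p-value matrix `p` and its Benjamini-Hochberg adjusted
#' counterpart `q` over the family of all unordered feature pairs.
#'
#' @slot rho symmetric correlation matrix.
#' @slot omega named numeric basis variances.
#' @slot p,q symmetric matrices in \[0, 1\] (zero-dimension until bootstrapped).
#' @slot nResamples,nBootstrap,seed bookkeeping for reproducibility.
#' @seealso [sparccEstimate()], [bootstrapPvalues()], [edgeFilter()]
#' @export
setClass("CorrelationResult",
  representation(rho = "matrix", omega = "numeric", p = "matrix",
                 q = "matrix", nResamples = "integer", nBootstrap = "integer",
                 seed = "integer"))

setValidity("CorrelationResult", function(object) {
  msg <- character()
  r <- object@rho
  if (nrow(r) != ncol(r) || max(abs(r - t(r))) > 1e-12)
    msg <- c(msg, "rho must be symmetric")
  if (any(abs(r) > 1 + 1e-12)) msg <- c(msg, "rho must lie in [-1, 1]")
  if (nrow(r) && max(abs(diag(r) - 1)) > 1e-12)
    msg <- c(msg, "rho diagonal must be 1")
  if (length(object@omega) != nrow(r))
    msg <- c(msg, "omega length must match rho dimension")
  for (s in c("p", "q")) {
    m <- slot(object, s)
    if (length(m) && (any(m < 0) || any(m > 1)))
      msg <- c(msg, sprintf("%s values must lie in [0, 1]", s))
  }
  if (length(object@p) && length(object@q) &&
      any(object@q < object@p - 1e-12))
    msg <- c(msg, "q must be elementwise >= p")
  if (length(msg)) msg else TRUE
})

#' Co-occurrence network
#'
#' A simple undirected graph over the taxa that survived the prevalence and
#' correlation filters.  Edges carry the SparCC correlation as `weight` and
#' its sign as `sign`; taxa without significant partners remain as isolated
#' nodes.  Backed by an igraph object, available via [asIgraph()].
#'
#' @slot graph an igraph object (undirected, simple).
#' @seealso [buildNetwork()], [detectModules()], [sampleNetworkProperties()]
#' @export
setClass("CoNetwork", representation(graph = "ANY"))

setValidity("CoNetwork", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph must be an igraph object")
  if (igraph::is_directed(g)) return("graph must be undirected")
  if (any(igraph::which_loop(g))) return("graph must not contain self-loops")
  if (any(igraph::which_multiple(g)))
    return("graph must not contain duplicate edges")
  if (is.null(igraph::V(g)$name)) return("nodes must be named")
  TRUE
})

#' Module partition of a co-occurrence network
#'
#' Node-to-module assignment from [detectModules()].  Module ids are
#' canonical (the lexicographically smallest member), so the partition is
#' invariant to node input order.  Modules holding strictly more than 10% of
#' the network's nodes are "major" and labelled `M1..Mk` by descending size
#' (ties broken by smallest member id); the rest are unlabelled and pooled as
#' `"other"` by [moduleRelativeAbundance()].
#'
#' @slot membership named character, node -> module id.
#' @slot majorLabels named character, module id -> "M1".."Mk".
#' @slot modularityQ Newman-Girvan modularity of the partition.
#' @export
setClass("ModulePartition",
  representation(membership = "character", majorLabels = "character",
                 modularityQ = "numeric"))

setValidity("ModulePartition", function(object) {
  msg <- character()
  if (is.null(names(object@membership)) ||
      anyDuplicated(names(object@membership)))
    msg <- c(msg, "every node must be assigned exactly once")
  if (anyDuplicated(object@majorLabels))
    msg <- c(msg, "major labels must be unique")
  if (length(object@majorLabels) &&
      !all(names(object@majorLabels) %in% object@membership))
    msg <- c(msg, "major labels must refer to existing modules")
  q <- object@modularityQ
  if (length(q) != 1L || is.na(q) || q < -0.5 - 1e-9 || q > 1 + 1e-9)
    msg <- c(msg, "modularity must lie in [-0.5, 1]")
  if (length(msg)) msg else TRUE
})
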