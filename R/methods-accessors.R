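#' @rdname AbundanceTable-class
#' @export
setMethod("abundances", "AbundanceTable",
  function(x) SummarizedExperiment::assay(x, "abundance"))

#' @rdname AbundanceTable-class
#' @export
setMethod("tableKind", "AbundanceTable", function(x) x@kind)

#' @rdname AbundanceTable-class
#' @export
setMethod("featureIds", "AbundanceTable", function(x) rownames(x))

#' @rdname AbundanceTable-class
#' @export
setMethod("sampleIds", "AbundanceTable", function(x) colnames(x))

setMethod("show", "AbundanceTable", function(object) {
  cat(sprintf("AbundanceTable (%s): %d features x %d samples\n",
              object@kind, nrow(object), ncol(object)))
  if (ncol(SummarizedExperiment::colData(object)))
    cat("  sample metadata:",
        paste(colnames(SummarizedExperiment::colData(object)), collapse = ", "),
        "\n")
})

#' @rdname CorrelationResult-class
#' @export
setMethod("corMatrix", "CorrelationResult", function(x) x@rho)

#' @rdname CorrelationResult-class
#' @export
setMethod("basisVariances", "CorrelationResult", function(x) x@omega)

#' @rdname CorrelationResult-class
#' @export
setMethod("pValues", "CorrelationResult", function(x) {
  if (!length(x@p)) stop("no bootstrap p-values attached; run bootstrapPvalues()",
                         call. = FALSE)
  x@p
})

#' @rdname CorrelationResult-class
#' @export
setMethod("qValues", "CorrelationResult", function(x) {
  if (!length(x@q)) stop("no q-values attached; run bootstrapPvalues()",
                         call. = FALSE)
  x@q
})

setMethod("show", "CorrelationResult", function(object) {
  d <- nrow(object@rho)
  cat(sprintf("CorrelationResult: %d features (%d resamples, seed %d)\n",
              d, object@nResamples, object@seed))
  off <- object@rho[upper.tri(object@rho)]
  if (length(off))
    cat(sprintf("  |rho| range %.3f..%.3f; bootstrap: %s\n",
                min(abs(off)), max(abs(off)),
                if (length(object@p)) sprintf("%d replicates", object@nBootstrap)
                else "not attached"))
})

#' @rdname CoNetwork-class
#' @export
setMethod("asIgraph", "CoNetwork", function(x) x@graph)

#' @rdname CoNetwork-class
#' @export
setMethod("networkNodes", "CoNetwork",
  function(x) igraph::V(x@graph)$name)

#' @rdname CoNetwork-class
#' @export
setMethod("networkEdges", "CoNetwork", function(x) {
  g <- x@graph
  el <- igraph::as_edgelist(g, names = TRUE)
  data.frame(feature_a = el[, 1], feature_b = el[, 2],
             rho = if (igraph::ecount(g)) igraph::E(g)$weight else numeric(),
             sign = if (igraph::ecount(g)) igraph::E(g)$sign else integer(),
             stringsAsFactors = FALSE)
})

setMethod("show", "CoNetwork", function(object) {
  g <- object@graph
  cat(sprintf("CoNetwork: %d nodes, %d edges\n",
              igraph::vcount(g), igraph::ecount(g)))
})

#' @rdname ModulePartition-class
#' @export
setMethod("membership", "ModulePartition", function(x) x@membership)

#' @rdname ModulePartition-class
#' @export
setMethod("majorLabels", "ModulePartition", function(x) x@majorLabels)

#' @rdname ModulePartition-class
#' @export
setMethod("modularityQ", "ModulePartition", function(x) x@modularityQ)

setMethod("show", "ModulePartition", function(object) {
  sizes <- sort(table(object@membership), decreasing = TRUE)
  cat(sprintf("ModulePartition: %d nodes in %d modules (Q = %.3f)\n",
              length(object@membership), length(sizes), object@modularityQ))
  if (length(object@majorLabels)) {
    lab <- object@majorLabels
    cat("  major:", paste(sprintf("%s (%d nodes)", lab,
                                  as.integer(sizes[names(lab)])),
                          collapse = ", "), "\n")
  }
})

#' @rdname SyntheticTruth-class
#' @export
setMethod("plantedModules", "SyntheticTruth", function(x) x@moduleOfTaxon)

setMethod("show", "SyntheticTruth", function(object) {
  tab <- table(object@moduleOfTaxon)
  cat(sprintf("SyntheticTruth: %d taxa, %d planted modules (seed %d)\n",
              length(object@moduleOfTaxon),
              sum(names(tab) != "background"), object@seed))
})

setMethod("show", "CovarianceSpec", function(object) {
  cat(sprintf(
    "CovarianceSpec: %d taxa, blocks [%s], within_r = %.2f, between_r = %.2f\n",
    object@nTaxa, paste(object@moduleSizes, collapse = ", "),
    object@withinR, object@betweenR))
})

setMethod("show", "CohortDesign", function(object) {
  cat(sprintf("CohortDesign: %s (n = %s)\n",
              paste(object@groups, collapse = ", "),
              paste(object@samplesPerGroup, collapse = ", ")))
})
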