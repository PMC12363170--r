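#' Run the full synthetic-cohort network analysis pipeline
#'
#' Exercises every stage on one simulated cohort and writes all primary
#' outputs as plain text: simulate a cohort with planted correlation blocks
#' and a diversity trend; normalise and prevalence-filter; estimate SparCC
#' correlations with bootstrap FDR; build the co-occurrence network and
#' detect modules; compute per-sample subnetwork properties and module
#' abundances; simulate module-coupled clinical indicators and associate
#' them with the network features; fit the diversity time trend.  Re-running
#' with the same seed and configuration reproduces every output file
#' byte-for-byte.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed; stage seeds are derived from it.
#' @param design a [CohortDesign-class].
#' @param spec a [CovarianceSpec-class].
#' @param depth sequencing depth per sample.
#' @param n_resamples,n_bootstrap SparCC settings.
#' @param r_threshold,q_threshold edge filter settings.
#' @return invisibly, a list with the in-memory stage results.
#' @export
runPipeline <- function(out_dir, seed,
                        design = cohortDesign(),
                        spec = covarianceSpec(32, module_sizes = rep(8L, 4),
                                              within_r = 0.8),
                        depth = 1e5, n_resamples = 20, n_bootstrap = 100,
                        r_threshold = 0.7, q_threshold = 0.05) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- childSeeds(seed, 4L)
  fp <- function(f) file.path(out_dir, f)

  sim <- simulateCohort(design, spec, depth = depth, seed = seeds[1L])
  writeAbundanceTsv(sim$table, fp("abundance_counts.tsv"))
  utils::write.csv(sim$metadata, fp("metadata.csv"), row.names = FALSE)

  rel <- toRelative(sim$table)
  filt <- prevalenceAbundanceFilter(rel)
  est <- sparccEstimate(sim$table[featureIds(filt), ],
                        n_resamples = n_resamples, seed = seeds[2L])
  est <- bootstrapPvalues(sim$table[featureIds(filt), ], est,
                          n_bootstrap = n_bootstrap, seed = seeds[2L])
  edges <- edgeFilter(est, r_threshold, q_threshold)
  utils::write.table(edges, fp("edges.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  net <- buildNetwork(edges, featureIds(filt))
  part <- detectModules(net)
  memb <- membership(part)
  lab <- majorLabels(part)
  modTab <- data.frame(node = names(memb), module = unname(memb),
                       label = ifelse(memb %in% names(lab),
                                      lab[memb], "other"),
                       stringsAsFactors = FALSE)
  utils::write.table(modTab[order(modTab$node), ], fp("modules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  props <- sampleNetworkProperties(net, rel)
  utils::write.csv(props, fp("sample_network_stats.csv"), row.names = FALSE)
  modAb <- moduleRelativeAbundance(part, rel)

  features <- data.frame(t(modAb), check.names = FALSE)
  features$modularity <- props$modularity
  features$complexity <- props$linkage_density
  features$centrality <- props$centrality
  features$degree <- props$mean_degree
  rownames(features) <- props$sample_id

  modCols <- utils::head(rownames(modAb), 2L)
  coefs <- list(CR = c(stats::setNames(c(3, -3)[seq_along(modCols)], modCols),
                       modularity = -1),
                BUN = stats::setNames(2, modCols[1L]))
  clin <- simulateClinical(sim$truth, features, coefficients = coefs,
                           noise_sd = 0.5, seed = seeds[3L])
  utils::write.csv(clin$clinical, fp("clinical.csv"), row.names = TRUE)
  assoc <- spearmanAssociation(features, clin$clinical)
  assocDf <- data.frame(feature = rep(rownames(assoc$rho), ncol(assoc$rho)),
                        indicator = rep(colnames(assoc$rho),
                                        each = nrow(assoc$rho)),
                        rho = as.vector(assoc$rho), p = as.vector(assoc$p),
                        stars = as.vector(assoc$stars),
                        stringsAsFactors = FALSE)
  utils::write.csv(assocDf, fp("associations.csv"), row.names = FALSE)

  shannon <- apply(abundances(rel), 2L, shannonIndex)
  onGrad <- !is.na(sim$metadata$rank)
  trend <- fitTrend(shannon[onGrad], sim$metadata$rank[onGrad])
  jsonlite::write_json(
    list(seed = seed,
         n_samples = ncol(sim$table),
         n_features_filtered = nrow(filt),
         n_edges = nrow(edges),
         modularity_Q = modularityQ(part),
         major_modules = as.list(lab),
         shannon_trend = trend[c("coefficients", "rss", "convex", "u_shaped")]),
    fp("summary.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(sim = sim, filtered = filt, estimate = est, edges = edges,
                 network = net, partition = part, properties = props,
                 module_abundance = modAb, clinical = clin$clinical,
                 association = assoc, trend = trend))
}
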