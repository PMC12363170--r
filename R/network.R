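#' Build a co-occurrence network from a filtered edge list
#'
#' Constructs a simple undirected graph over `nodes` (every retained taxon,
#' including those without significant edges, which stay as isolated nodes).
#' Self-loops and duplicate pairs in the input are rejected.
#'
#' @param edges data.frame with `feature_a`, `feature_b` and optionally
#'   `rho` columns, e.g. from [edgeFilter()].
#' @param nodes character vector of node ids (must cover all edge endpoints).
#' @return a [CoNetwork-class].
#' @export
buildNetwork <- function(edges, nodes) {
  stopIf(anyDuplicated(nodes) > 0L, "node ids must be unique")
  if (is.null(edges) || !nrow(edges)) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, length(nodes), name = nodes)
    return(new("CoNetwork", graph = g))
  }
  a <- as.character(edges$feature_a); b <- as.character(edges$feature_b)
  loops <- a == b
  stopIf(any(loops), "self-loop(s) in edge list: ",
         paste(unique(a[loops]), collapse = ", "))
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  dup <- duplicated(key)
  stopIf(any(dup), "duplicate edge pair(s): ",
         paste(unique(gsub("\r", " -- ", key[dup])), collapse = ", "))
  missing <- setdiff(c(a, b), nodes)
  stopIf(length(missing) > 0L, "edge endpoint(s) not in node set: ",
         paste(missing, collapse = ", "))
  rho <- if ("rho" %in% names(edges)) edges$rho else rep(1, length(a))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, weight = rho,
               sign = ifelse(rho >= 0, 1L, -1L)),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  new("CoNetwork", graph = g)
}

#' Newman-Girvan modularity of a partition
#'
#' `Q = sum_c [ e_c / m - (d_c / 2m)^2 ]` over communities `c`, where `e_c`
#' is the number of intra-community edges, `d_c` the total degree of the
#' community and `m` the edge count.  The graph is treated as unweighted and
#' unsigned.  An edgeless graph has `Q = 0` (with a warning).
#'
#' @param network a [CoNetwork-class] (or igraph object).
#' @param partition named vector mapping every node to a community id.
#' @return the modularity Q.
#' @export
modularityScore <- function(network, partition) {
  g <- if (is(network, "CoNetwork")) network@graph else network
  nodes <- igraph::V(g)$name
  stopIf(is.null(names(partition)) || !all(nodes %in% names(partition)),
         "partition must cover all nodes by name")
  comm <- as.character(partition[nodes])
  m <- igraph::ecount(g)
  if (m == 0) {
    warning("graph has no edges; modularity defined as 0", call. = FALSE)
    return(0)
  }
  el <- igraph::as_edgelist(g, names = TRUE)
  cA <- comm[match(el[, 1L], nodes)]
  cB <- comm[match(el[, 2L], nodes)]
  eC <- table(factor(cA, levels = unique(comm)))[unique(comm)] * 0
  intra <- cA == cB
  if (any(intra)) {
    tab <- table(cA[intra])
    eC[names(tab)] <- tab
  }
  deg <- igraph::degree(g)
  dC <- tapply(deg, comm, sum)
  sum(eC[names(dC)] / m - (dC / (2 * m))^2)
}

#' Detect modules by deterministic greedy modularity maximisation
#'
#' Agglomerative CNM-style community detection on the unweighted, unsigned
#' graph: starting from singletons, repeatedly merge the pair of communities
#' with the largest modularity gain (ties broken by the lexicographically
#' smallest pair of community ids, a community being identified by its
#' smallest member node), and return the partition with the highest
#' modularity along the merge path.  Isolated nodes remain singleton
#' modules.  Modules holding strictly more than 10% of the network's nodes
#' are labelled `M1..Mk` by descending size (size ties broken by smallest
#' member id).  The procedure is fully deterministic and invariant to node
#' input order.
#'
#' @param network a [CoNetwork-class].
#' @param seed accepted for interface uniformity; the algorithm is
#'   deterministic and ignores it.
#' @param major_fraction strict node-share threshold for labelling a module
#'   as major.
#' @return a [ModulePartition-class].
#' @export
detectModules <- function(network, seed = NULL, major_fraction = 0.10) {
  stopIf(!is(network, "CoNetwork"), "network must be a CoNetwork")
  g <- network@graph
  nodes <- sort(igraph::V(g)$name)
  n <- length(nodes)
  stopIf(n == 0L, "network has no nodes")
  m <- igraph::ecount(g)
  if (m == 0) {
    part <- stats::setNames(nodes, nodes)
    return(makePartition(part, 0, major_fraction))
  }
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  A <- A[nodes, nodes]
  A[A != 0] <- 1
  deg <- rowSums(A)
  ## community state: each node's community is labelled by the index of its
  ## smallest member (nodes are sorted, and merges relabel to the smaller
  ## index), so representatives are lexicographically smallest members.
  comm <- seq_len(n)
  eBetween <- A               # edge counts between current communities
  dComm <- deg
  alive <- rep(TRUE, n)
  Qnow <- -sum((deg / (2 * m))^2)   # singleton partition: no intra edges
  best <- list(Q = Qnow, comm = comm)
  repeat {
    idx <- which(alive)
    if (length(idx) < 2L) break
    ## gain of merging communities a, b: e_ab/m - d_a d_b / (2 m^2);
    ## only connected pairs are candidates (disconnected merges never help)
    E <- eBetween[idx, idx, drop = FALSE]
    G <- E / m - outer(dComm[idx], dComm[idx]) / (2 * m^2)
    G[E == 0] <- -Inf
    G[lower.tri(G, diag = TRUE)] <- -Inf
    gain <- max(G)
    if (!is.finite(gain)) break
    hits <- which(G == gain, arr.ind = TRUE)
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    a <- idx[hits[1L, 1L]]; b <- idx[hits[1L, 2L]]
    comm[comm == b] <- a
    eBetween[a, ] <- eBetween[a, ] + eBetween[b, ]
    eBetween[, a] <- eBetween[, a] + eBetween[b, ]
    dComm[a] <- dComm[a] + dComm[b]
    alive[b] <- FALSE
    Qnow <- Qnow + gain
    if (Qnow > best$Q + 1e-12) best <- list(Q = Qnow, comm = comm)
  }
  part <- stats::setNames(nodes[best$comm], nodes)
  makePartition(part, modularityScore(network, part), major_fraction)
}

## Build a ModulePartition from a node -> community-representative map.
makePartition <- function(part, Q, major_fraction) {
  sizes <- table(part)
  n <- length(part)
  major <- names(sizes)[sizes > major_fraction * n]
  if (length(major)) {
    ord <- order(-as.integer(sizes[major]), major, method = "radix")
    major <- major[ord]
    labels <- stats::setNames(sprintf("M%d", seq_along(major)), major)
  } else labels <- stats::setNames(character(), character())
  new("ModulePartition", membership = part, majorLabels = labels,
      modularityQ = as.numeric(Q))
}

#' Per-sample induced subnetwork
#'
#' The subgraph of the co-occurrence network induced by the taxa present
#' (relative abundance strictly greater than zero) in one sample; edges are
#' restricted accordingly.  Taxa absent from the abundance vector count as
#' absent.
#'
#' @param network a [CoNetwork-class].
#' @param abundance named numeric vector of the sample's abundances.
#' @return a [CoNetwork-class] on the present nodes (possibly empty).
#' @export
sampleSubnetwork <- function(network, abundance) {
  stopIf(!is(network, "CoNetwork"), "network must be a CoNetwork")
  stopIf(is.null(names(abundance)), "abundance vector must be named")
  nodes <- igraph::V(network@graph)$name
  ab <- stats::setNames(rep(0, length(nodes)), nodes)
  shared <- intersect(names(abundance), nodes)
  ab[shared] <- abundance[shared]
  present <- nodes[ab > 0]
  new("CoNetwork",
      graph = igraph::induced_subgraph(network@graph, present))
}

#' Eigenvector centrality by power iteration
#'
#' Power iteration on `A + I` (the shift removes sign ambiguity on bipartite
#' components) restricted to the largest connected component (ties broken by
#' the component containing the smallest node id); the result is normalised
#' so its maximum is 1 and nodes outside the component get 0.  Components
#' without edges get all-zero centrality.
#'
#' @param network a [CoNetwork-class] or igraph object.
#' @param tol convergence tolerance on the sup-norm change.
#' @param max_iter iteration cap.
#' @return named numeric vector of centralities in \[0, 1\].
#' @export
eigenvectorCentrality <- function(network, tol = 1e-12, max_iter = 10000) {
  g <- if (is(network, "CoNetwork")) network@graph else network
  nodes <- igraph::V(g)$name
  out <- stats::setNames(rep(0, length(nodes)), nodes)
  if (!length(nodes) || igraph::ecount(g) == 0) return(out)
  compo <- igraph::components(g)
  sizes <- compo$csize
  cand <- which(sizes == max(sizes))
  ## tie-break: component containing the smallest node id
  if (length(cand) > 1L) {
    reps <- vapply(cand, function(ci) min(nodes[compo$membership == ci]), "")
    cand <- cand[order(reps)][1L]
  }
  keep <- nodes[compo$membership == cand[1L]]
  sub <- igraph::induced_subgraph(g, keep)
  if (igraph::ecount(sub) == 0) return(out)
  A <- as.matrix(igraph::as_adjacency_matrix(sub, sparse = FALSE))
  A[A != 0] <- 1
  v <- rep(1, nrow(A))
  for (it in seq_len(max_iter)) {
    w <- A %*% v + v
    w <- w / max(w)
    if (max(abs(w - v)) < tol) { v <- w; break }
    v <- w
  }
  out[rownames(A)] <- as.numeric(v / max(v))
  out
}

#' Per-sample subnetwork topological properties
#'
#' For every sample: extract the induced subnetwork of present taxa and
#' report node and edge counts, mean degree (`2E/N`), linkage density (mean
#' degree divided by node count), modularity of a fresh module detection on
#' the subnetwork, and the mean max-normalised eigenvector centrality over
#' present nodes.  Subnetworks with fewer than 2 nodes are degenerate: all
#' properties are 0 and the `degenerate` flag is set (keeping downstream
#' feature tables rectangular).
#'
#' @param network a [CoNetwork-class].
#' @param table a relative [AbundanceTable-class]; presence = abundance > 0.
#' @return data.frame with one row per sample: `sample_id`, `n_nodes`,
#'   `n_edges`, `modularity`, `mean_degree`, `linkage_density`,
#'   `centrality`, `degenerate`.
#' @export
sampleNetworkProperties <- function(network, table) {
  stopIf(!is(network, "CoNetwork"), "network must be a CoNetwork")
  stopIf(!is(table, "AbundanceTable"), "table must be an AbundanceTable")
  stopIf(tableKind(table) != "relative", "table must be relative abundances")
  m <- abundances(table)
  rows <- lapply(colnames(m), function(s) {
    sub <- sampleSubnetwork(network, m[, s])
    g <- sub@graph
    nN <- igraph::vcount(g); nE <- igraph::ecount(g)
    if (nN < 2L)
      return(data.frame(sample_id = s, n_nodes = nN, n_edges = nE,
                        modularity = 0, mean_degree = 0, linkage_density = 0,
                        centrality = 0, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    meanDeg <- 2 * nE / nN
    Q <- if (nE == 0) 0 else modularityQ(detectModules(sub))
    cent <- mean(eigenvectorCentrality(sub))
    data.frame(sample_id = s, n_nodes = nN, n_edges = nE, modularity = Q,
               mean_degree = meanDeg, linkage_density = meanDeg / nN,
               centrality = cent, degenerate = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Module relative abundances per sample
#'
#' Sums the relative abundances of each labelled (major) module's member taxa
#' per sample; members of unlabelled modules are pooled as `"other"`.
#'
#' @param partition a [ModulePartition-class].
#' @param table a relative [AbundanceTable-class] containing the partition's
#'   nodes.
#' @return matrix, labelled modules (+ `"other"`) x samples.
#' @export
moduleRelativeAbundance <- function(partition, table) {
  stopIf(!is(partition, "ModulePartition"), "partition must be a ModulePartition")
  stopIf(tableKind(table) != "relative", "table must be relative abundances")
  m <- abundances(table)
  nodes <- names(partition@membership)
  missing <- setdiff(nodes, rownames(m))
  stopIf(length(missing) > 0L, "partition node(s) missing from table: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  labelOf <- stats::setNames(rep("other", length(nodes)), nodes)
  lab <- partition@majorLabels
  for (mod in names(lab))
    labelOf[nodes[partition@membership == mod]] <- lab[[mod]]
  groups <- c(unname(lab)[order(unname(lab))], "other")
  out <- t(vapply(groups, function(gl) {
    members <- nodes[labelOf == gl]
    if (!length(members)) rep(0, ncol(m))
    else colSums(m[members, , drop = FALSE])
  }, numeric(ncol(m))))
  dimnames(out) <- list(groups, colnames(m))
  out
}

#' KO-to-module functional correlates
#'
#' Screens KOs by mean relative abundance, then Spearman-correlates every
#' retained KO against every labelled module's per-sample abundance, keeping
#' pairs with `p < p_threshold` and `|rho| > r_threshold` (or `rho >
#' r_threshold` in signed mode) as the module's related functions.
#'
#' @param ko_table a relative [AbundanceTable-class] of KOs.
#' @param module_abundances matrix from [moduleRelativeAbundance()] (the
#'   `"other"` row is ignored).
#' @param min_mean_abund KO mean-abundance screen (default 0.001% = 1e-5).
#' @param p_threshold,r_threshold significance and correlation thresholds.
#' @param signed_mode keep positive correlations only.
#' @return data.frame with columns `ko`, `module`, `rho`, `p`.
#' @export
koModuleCorrelates <- function(ko_table, module_abundances,
                               min_mean_abund = 1e-5, p_threshold = 0.05,
                               r_threshold = 0.5, signed_mode = FALSE) {
  stopIf(!is(ko_table, "AbundanceTable"), "ko_table must be an AbundanceTable")
  shared <- intersect(sampleIds(ko_table), colnames(module_abundances))
  stopIf(length(shared) < 5L, "need at least 5 shared samples")
  km <- abundances(ko_table)[, shared, drop = FALSE]
  ma <- module_abundances[setdiff(rownames(module_abundances), "other"),
                          shared, drop = FALSE]
  keepKo <- rowMeans(km) > min_mean_abund
  km <- km[keepKo, , drop = FALSE]
  out <- list()
  for (ko in rownames(km)) for (mod in rownames(ma)) {
    ct <- suppressWarnings(
      stats::cor.test(km[ko, ], ma[mod, ], method = "spearman",
                      exact = FALSE))
    if (is.na(ct$estimate)) next
    keep <- if (signed_mode) ct$estimate > r_threshold
            else abs(ct$estimate) > r_threshold
    if (keep && ct$p.value < p_threshold)
      out[[length(out) + 1L]] <- data.frame(
        ko = ko, module = mod, rho = unname(ct$estimate),
        p = ct$p.value, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(ko = character(), module = character(),
                      rho = numeric(), p = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Export a network for external tools
#'
#' Writes the edge list as TSV (`feature_a`, `feature_b`, `rho`, `sign`) or
#' the full graph as GraphML (for Gephi/Cytoscape).
#'
#' @param network a [CoNetwork-class].
#' @param path output file.
#' @param format `"tsv"` or `"graphml"`.
#' @return invisibly, `path`.
#' @export
exportNetwork <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(networkEdges(network), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    igraph::write_graph(network@graph, path, format = "graphml")
  }
  invisible(path)
}
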