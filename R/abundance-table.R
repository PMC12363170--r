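#' Construct an abundance table
#'
#' @param values non-negative numeric matrix, features in rows and samples in
#'   columns, with unique dimnames.
#' @param kind `"counts"` for raw counts, `"relative"` for fractions.
#' @param sampleData optional `data.frame`/`DataFrame` of per-sample metadata
#'   (one row per column of `values`).
#' @return an [AbundanceTable-class] object.
#' @examples
#' m <- matrix(c(2, 2, 1, 3), 2, 2,
#'             dimnames = list(c("taxonA", "taxonB"), c("s1", "s2")))
#' AbundanceTable(m, "counts")
#' @export
AbundanceTable <- function(values, kind = c("counts", "relative"),
                           sampleData = NULL) {
  kind <- match.arg(kind)
  stopIf(!is.matrix(values) || !is.numeric(values),
         "values must be a numeric matrix")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("feature_%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("sample_%03d", seq_len(ncol(values)))
  cd <- if (is.null(sampleData)) S4Vectors::DataFrame(row.names = colnames(values))
        else S4Vectors::DataFrame(sampleData, row.names = colnames(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = values), colData = cd)
  new("AbundanceTable", se, kind = kind)
}

#' Read and write abundance tables as TSV
#'
#' The on-disk format is plain tab-separated text: first column holds the
#' feature ids (header `feature_id`), remaining columns are samples.
#' `readAbundanceTsv(writeAbundanceTsv(x, f), kind)` round-trips ids and
#' values exactly.
#'
#' @param path file path.
#' @param kind `"counts"` or `"relative"`.
#' @return `readAbundanceTsv` returns an [AbundanceTable-class];
#'   `writeAbundanceTsv` invisibly returns `path`.
#' @export
readAbundanceTsv <- function(path, kind = c("counts", "relative")) {
  kind <- match.arg(kind)
  stopIf(!file.exists(path), "file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = NA,
                          stringsAsFactors = FALSE)
  stopIf(ncol(df) < 2L, "expected a feature-id column plus >= 1 sample column")
  ids <- as.character(df[[1L]])
  dup <- ids[duplicated(ids)]
  stopIf(length(dup) > 0L, "duplicate feature id(s): ",
         paste(unique(dup), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  stopIf(!is.numeric(m), "non-numeric abundance values in ", path)
  bad <- which(m < 0, arr.ind = TRUE)
  stopIf(nrow(bad) > 0L,
         sprintf("negative value at feature '%s', sample '%s'",
                 ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
  rownames(m) <- ids
  AbundanceTable(m, kind)
}

#' @rdname readAbundanceTsv
#' @param table an [AbundanceTable-class].
#' @export
writeAbundanceTsv <- function(table, path) {
  stopIf(!is(table, "AbundanceTable"), "table must be an AbundanceTable")
  m <- abundances(table)
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Divides each sample (column) by its total.  All-zero samples are passed
#' through as zeros and reported in a warning; within every other sample the
#' rank order of features is preserved exactly.
#'
#' @param table a counts [AbundanceTable-class].
#' @return a relative [AbundanceTable-class].
#' @export
toRelative <- function(table) {
  stopIf(!is(table, "AbundanceTable"), "table must be an AbundanceTable")
  stopIf(tableKind(table) != "counts", "table is already relative")
  m <- abundances(table)
  if (!length(m))
    return(AbundanceTable(m, "relative",
                          as.data.frame(SummarizedExperiment::colData(table))))
  cs <- colSums(m)
  zero <- cs == 0
  if (any(zero))
    warning("all-zero sample(s) left as zeros: ",
            paste(colnames(m)[zero], collapse = ", "), call. = FALSE)
  cs[zero] <- 1
  rel <- sweep(m, 2L, cs, "/")
  AbundanceTable(rel, "relative",
                 as.data.frame(SummarizedExperiment::colData(table)))
}

## Subset an AbundanceTable to a feature index, keeping kind and metadata.
## (Plain SE subsetting would also work; this keeps validity relaxed for
## relative subsets and is used by every filter.)
subsetFeatures <- function(table, idx) {
  m <- abundances(table)[idx, , drop = FALSE]
  AbundanceTable(m, tableKind(table),
                 as.data.frame(SummarizedExperiment::colData(table)))
}

#' Prevalence and mean-abundance feature filter
#'
#' Keeps features whose occurrence (fraction of samples with a strictly
#' positive value) strictly exceeds `min_occurrence` and whose mean relative
#' abundance over *all* samples (zeros included) strictly exceeds
#' `min_mean_abund`.  Defaults implement the conventional screen of more than
#' 70% occurrence and mean relative abundance above 0.001% (1e-5) applied
#' before network construction.  Feature order is preserved and the filter is
#' idempotent.
#'
#' @param table a relative [AbundanceTable-class].
#' @param min_occurrence occurrence threshold in \[0, 1\].
#' @param min_mean_abund mean relative-abundance threshold in \[0, 1\].
#' @return the filtered [AbundanceTable-class].
#' @export
prevalenceAbundanceFilter <- function(table, min_occurrence = 0.70,
                                      min_mean_abund = 1e-5) {
  stopIf(!is(table, "AbundanceTable"), "table must be an AbundanceTable")
  stopIf(tableKind(table) != "relative",
         "filter operates on relative abundances; call toRelative() first")
  stopIf(min_occurrence < 0 || min_occurrence > 1 ||
         min_mean_abund < 0 || min_mean_abund > 1,
         "thresholds must lie in [0, 1]")
  m <- abundances(table)
  if (!nrow(m)) return(table)
  occ <- rowMeans(m > 0)
  mu <- rowMeans(m)
  subsetFeatures(table, occ > min_occurrence & mu > min_mean_abund)
}

#' Top-k features by mean relative abundance
#'
#' Ranks features by decreasing mean relative abundance; ties are broken
#' lexicographically by feature id (the smaller id ranks first).  Asking for
#' more features than exist returns all of them with a warning.
#'
#' @param table an [AbundanceTable-class].
#' @param k number of features to keep.
#' @return an [AbundanceTable-class] with the `k` selected features, in rank
#'   order.
#' @export
topKFeatures <- function(table, k = 50) {
  stopIf(!is(table, "AbundanceTable"), "table must be an AbundanceTable")
  stopIf(!isWholeNumber(k) || k < 1, "k must be a positive integer")
  m <- abundances(table)
  if (k > nrow(m)) {
    warning(sprintf("k = %d exceeds the %d available features; returning all",
                    k, nrow(m)), call. = FALSE)
    k <- nrow(m)
  }
  mu <- rowMeans(m)
  ord <- order(-mu, rownames(m), method = "radix")
  subsetFeatures(table, ord[seq_len(k)])
}
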