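#' Shannon diversity index
#'
#' `H = -sum p_i log p_i` (natural log) over the positive entries of the
#' normalised vector; invariant to rescaling of the input.  Computed with
#' [vegan::diversity()].
#'
#' @param x non-negative abundance vector with positive sum.
#' @return the Shannon index.
#' @examples
#' shannonIndex(rep(1, 4))  # log(4)
#' @export
shannonIndex <- function(x) {
  stopIf(any(x < 0) || anyNA(x), "abundances must be non-negative")
  stopIf(sum(x) <= 0, "vector sums to zero; Shannon index undefined")
  unname(vegan::diversity(x, index = "shannon"))
}

#' Bray-Curtis distance matrix
#'
#' `d(u, v) = 1 - 2 * sum_i min(u_i, v_i) / (sum u + sum v)` for every sample
#' pair, via [vegan::vegdist()].  A pair of all-zero samples has undefined
#' Bray-Curtis distance; it is reported as 0 with a warning.
#'
#' @param table an [AbundanceTable-class] (samples in columns).
#' @return symmetric distance matrix with sample ids as dimnames.
#' @export
brayCurtis <- function(table) {
  stopIf(!is(table, "AbundanceTable"), "table must be an AbundanceTable")
  m <- abundances(table)
  stopIf(ncol(m) < 2L, "need at least 2 samples")
  d <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  if (anyNA(d)) {
    warning("all-zero sample pair(s); Bray-Curtis distance set to 0",
            call. = FALSE)
    d[is.na(d)] <- 0
  }
  diag(d) <- 0
  d
}

#' Within-group beta-diversity dispersion and its group comparison
#'
#' Collects, per group, the pairwise distances among that group's samples,
#' and compares the groups' within-group distance distributions by
#' Kruskal-Wallis.  Groups with fewer than 2 samples carry no within-group
#' distance and are excluded with a warning.
#'
#' @param d symmetric distance matrix with sample ids as dimnames.
#' @param groups named vector (sample id -> group label) or vector aligned
#'   with the matrix order.
#' @return list with `distances` (named list of per-group distance vectors),
#'   `kruskal` (the [stats::kruskal.test()] result, or `NULL` when
#'   degenerate) and `degenerate` (flag: all distances identical).
#' @export
withinGroupDispersion <- function(d, groups) {
  ids <- rownames(d)
  stopIf(is.null(ids), "distance matrix must carry sample ids")
  g <- if (!is.null(names(groups))) groups[ids] else
    stats::setNames(groups, ids)
  lv <- unique(as.character(g))
  dists <- list()
  for (grp in lv) {
    s <- ids[g == grp]
    if (length(s) < 2L) {
      warning(sprintf("group '%s' has < 2 samples; excluded", grp),
              call. = FALSE)
      next
    }
    sub <- d[s, s]
    dists[[grp]] <- sub[upper.tri(sub)]
  }
  stopIf(length(dists) < 2L, "need >= 2 groups with >= 2 samples each")
  vals <- unlist(dists, use.names = FALSE)
  fac <- factor(rep(names(dists), lengths(dists)))
  degenerate <- length(unique(vals)) < 2L
  kw <- if (degenerate) NULL else stats::kruskal.test(vals, fac)
  if (degenerate)
    warning("all within-group distances identical; test degenerate",
            call. = FALSE)
  list(distances = dists, kruskal = kw, degenerate = degenerate)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance via [vegan::adonis2()]
#' (Gower-centred partition of squared distances, pseudo-F, `R^2 =
#' SS_between / SS_total`, p by unrestricted label permutation with a fixed
#' seed).  With a multi-column `groups` data.frame the decomposition is
#' sequential (`by = "terms"`), so factor `R^2` values can be compared in
#' the stated order.
#'
#' @param d symmetric distance matrix.
#' @param groups vector of group labels, or a data.frame of factors (rows
#'   aligned with the matrix's sample ids).
#' @param n_perm number of permutations (a warning below 99).
#' @param seed integer seed for the permutations.
#' @return data.frame with one row per term: `term`, `df`, `pseudo_F`,
#'   `R2`, `p`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed) {
  stopIf(is.null(rownames(d)), "distance matrix must carry sample ids")
  if (n_perm < 99)
    warning("fewer than 99 permutations gives a very coarse p-value",
            call. = FALSE)
  if (!is.data.frame(groups))
    groups <- data.frame(group = as.character(groups),
                         stringsAsFactors = FALSE)
  stopIf(nrow(groups) != nrow(d), "groups must align with the distance matrix")
  for (cn in colnames(groups)) {
    f <- factor(groups[[cn]])
    stopIf(nlevels(f) < 2L, sprintf("factor '%s' has a single level", cn))
    stopIf(nlevels(f) >= nrow(groups),
           sprintf("factor '%s' has all-distinct labels (no residual df)", cn))
    groups[[cn]] <- f
  }
  dd <- stats::as.dist(d)
  fm <- stats::as.formula(
    paste("dd ~", paste(colnames(groups), collapse = " + ")))
  res <- withSeed(seed,
    vegan::adonis2(fm, data = groups, permutations = n_perm, by = "terms"))
  terms <- rownames(res)
  keep <- !terms %in% c("Residual", "Total")
  data.frame(term = terms[keep], df = res$Df[keep], pseudo_F = res$F[keep],
             R2 = res$R2[keep], p = res$`Pr(>F)`[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Kruskal-Wallis abundance screen
#'
#' Applies a tie-corrected Kruskal-Wallis test to every feature of a table
#' (typically the top-k most abundant features) across groups and retains
#' features with `p < alpha`.  Unadjusted by default, mirroring the common
#' screening procedure; `adjust = "BH"` switches to FDR-adjusted retention.
#' Features constant across all samples are flagged degenerate with `p = 1`.
#'
#' @param table an [AbundanceTable-class].
#' @param groups group labels aligned with the samples (or named by sample
#'   id).
#' @param alpha retention threshold.
#' @param adjust `"none"` (default) or a [stats::p.adjust()] method.
#' @return data.frame with `feature`, `H`, `p`, `p_used`, `retained`,
#'   `degenerate`.
#' @export
kruskalWallisScreen <- function(table, groups, alpha = 0.05, adjust = "none") {
  stopIf(!is(table, "AbundanceTable"), "table must be an AbundanceTable")
  m <- abundances(table)
  g <- if (!is.null(names(groups))) groups[colnames(m)] else groups
  stopIf(length(g) != ncol(m), "groups must align with the samples")
  fac <- factor(as.character(g))
  stopIf(nlevels(fac) < 2L, "need at least 2 groups")
  rows <- lapply(rownames(m), function(f) {
    x <- m[f, ]
    if (length(unique(x)) < 2L)
      return(data.frame(feature = f, H = 0, p = 1, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    kw <- stats::kruskal.test(x, fac)
    data.frame(feature = f, H = unname(kw$statistic), p = kw$p.value,
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_used <- if (identical(adjust, "none")) out$p
                else stats::p.adjust(out$p, method = adjust)
  out$retained <- !out$degenerate & out$p_used < alpha
  out
}

#' Quadratic least-squares time-trend fit
#'
#' Fits `y = b0 + b1 * r + b2 * r^2` over integer group ranks by ordinary
#' least squares - the minimal family expressing both the U-shaped
#' (first-decreasing-then-increasing) and inverse-U trajectories seen over
#' ordered post-transplant timepoints.  The fit is classified convex when
#' the quadratic coefficient is positive, and flagged `u_shaped` when
#' additionally the vertex falls strictly inside the observed rank range.
#'
#' @param values numeric response per sample.
#' @param ranks integer group rank per sample (>= 3 distinct values).
#' @return list with `coefficients` (intercept, linear, quadratic), `rss`,
#'   `fitted`, `convex`, `vertex`, `u_shaped`.
#' @export
fitTrend <- function(values, ranks) {
  keep <- stats::complete.cases(values, ranks)
  values <- values[keep]; ranks <- ranks[keep]
  stopIf(length(unique(ranks)) < 3L,
         "need at least 3 distinct ranks to fit a quadratic")
  fit <- stats::lm(values ~ ranks + I(ranks^2))
  beta <- stats::setNames(unname(stats::coef(fit)),
                          c("intercept", "linear", "quadratic"))
  beta[is.na(beta)] <- 0
  ## numerically-zero coefficients (constant data) must not flip convexity
  scaleY <- max(abs(values), 1)
  beta[abs(beta) < 1e-10 * scaleY] <- 0
  fitted <- beta[1] + beta[2] * ranks + beta[3] * ranks^2
  vertex <- if (abs(beta[3]) > 1e-12) -beta[2] / (2 * beta[3]) else NA_real_
  list(coefficients = beta,
       rss = sum((values - fitted)^2),
       fitted = unname(fitted),
       convex = unname(beta[3] > 0),
       vertex = unname(vertex),
       u_shaped = unname(beta[3] > 0 && !is.na(vertex) &&
                         vertex > min(ranks) && vertex < max(ranks)))
}
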