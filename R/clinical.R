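#' CKD-EPI estimated glomerular filtration rate
#'
#' Piecewise power-law eGFR from serum creatinine, age and sex.  The default
#' is the 2021 race-free refit
#' (`142 * min(Scr/k, 1)^a * max(Scr/k, 1)^-1.200 * 0.9938^age * 1.012[female]`,
#' with `k = 0.7/0.9` and `a = -0.241/-0.302` for female/male); the 2009
#' equation is available, in which case the optional race coefficient
#' (1.159) can be applied.  Creatinine must come with an explicit unit:
#' `"umol/L"` values are converted to mg/dL by dividing by 88.42, and
#' unit-less input is refused rather than guessed.
#'
#' @param creatinine serum creatinine (vectorised).
#' @param age age in years (> 0).
#' @param sex `"male"` or `"female"` (recycled).
#' @param unit `"mg/dL"` or `"umol/L"`; no default.
#' @param version `"2021"` (default) or `"2009"`.
#' @param race for `version = "2009"` only: `"black"` applies the 1.159
#'   coefficient; default `"other"`.
#' @return eGFR in mL/min/1.73 m^2.
#' @examples
#' ckdEpiEgfr(0.9, age = 40, sex = "male", unit = "mg/dL")    # ~110.7
#' ckdEpiEgfr(0.6, age = 60, sex = "female", unit = "mg/dL")  # ~102.7
#' @export
ckdEpiEgfr <- function(creatinine, age, sex, unit, version = c("2021", "2009"),
                       race = "other") {
  version <- match.arg(version)
  stopIf(missing(unit) || is.null(unit),
         "creatinine unit must be given explicitly ('mg/dL' or 'umol/L')")
  unit <- match.arg(unit, c("mg/dL", "umol/L"))
  stopIf(missing(sex) || anyNA(sex), "sex is required")
  stopIf(missing(age) || anyNA(age) || any(age <= 0), "age must be positive")
  stopIf(anyNA(creatinine) || any(creatinine <= 0),
         "creatinine must be positive and non-missing")
  scr <- if (unit == "umol/L") creatinine / 88.42 else creatinine
  n <- max(length(scr), length(age), length(sex))
  scr <- rep_len(scr, n); age <- rep_len(age, n)
  sex <- rep_len(as.character(sex), n)
  stopIf(!all(sex %in% c("male", "female")), "sex must be 'male' or 'female'")
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  if (version == "2021") {
    alpha <- ifelse(female, -0.241, -0.302)
    egfr <- 142 * pmin(scr / kappa, 1)^alpha * pmax(scr / kappa, 1)^-1.200 *
      0.9938^age * ifelse(female, 1.012, 1)
  } else {
    alpha <- ifelse(female, -0.329, -0.411)
    raceCoef <- ifelse(rep_len(as.character(race), n) == "black", 1.159, 1)
    egfr <- 141 * pmin(scr / kappa, 1)^alpha * pmax(scr / kappa, 1)^-1.209 *
      0.993^age * ifelse(female, 1.018, 1) * raceCoef
  }
  unname(egfr)
}

#' Spearman association matrix with significance stars
#'
#' Tie-corrected Spearman correlation of every feature column (module
#' abundances, per-sample network properties, ...) against every clinical
#' indicator, with two-sided p-values and star annotation at 0.05 / 0.01 /
#' 0.001.  Missing values are handled pairwise-complete; pairs with fewer
#' than `min_n` complete observations, or a constant margin, are reported as
#' `NA` and flagged.
#'
#' @param features data.frame of per-sample features (row names = sample
#'   ids).
#' @param clinical data.frame of indicators (row names = sample ids).
#' @param min_n minimum complete pairs per correlation.
#' @return list with matrices `rho`, `p`, `n`, `stars` (features x
#'   indicators) and `flagged` (logical: undefined correlations).
#' @export
spearmanAssociation <- function(features, clinical, min_n = 5) {
  shared <- intersect(rownames(features), rownames(clinical))
  stopIf(length(shared) < min_n,
         sprintf("need at least %d shared samples", min_n))
  f <- features[shared, , drop = FALSE]
  cl <- clinical[shared, , drop = FALSE]
  nf <- ncol(f); ni <- ncol(cl)
  rho <- p <- matrix(NA_real_, nf, ni,
                     dimnames = list(colnames(f), colnames(cl)))
  nMat <- matrix(0L, nf, ni, dimnames = dimnames(rho))
  for (i in seq_len(nf)) for (j in seq_len(ni)) {
    x <- f[[i]]; y <- cl[[j]]
    ok <- stats::complete.cases(x, y)
    nMat[i, j] <- sum(ok)
    if (sum(ok) < min_n) next
    if (length(unique(x[ok])) < 2L || length(unique(y[ok])) < 2L) next
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                           exact = FALSE))
    rho[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  list(rho = rho, p = p, n = nMat,
       stars = matrix(starsForP(p), nf, ni, dimnames = dimnames(rho)),
       flagged = is.na(rho))
}

## Balanced disjoint CV fold assignment (sizes within 1 of each other).
cvFolds <- function(n, k) {
  sample(rep_len(seq_len(k), n))
}

#' Cross-validated random forest for eGFR with permutation significance
#'
#' Tunes the per-split candidate-feature count (`mtry`) by k-fold
#' cross-validation minimising RMSE, refits on all samples, and reports
#' per-feature permutation importance (mean increase in out-of-bag MSE when
#' a feature is permuted, [randomForest::importance()] with
#' `scale = FALSE`).  Significance comes from response-permutation
#' replicates: the response is permuted, the forest refit, and both the
#' importance null (per feature) and the out-of-bag `R^2` null (model level)
#' are accumulated; p-values use the add-one rule
#' `(1 + #\{null >= observed\}) / (1 + B)`.  Fully seeded.
#'
#' @param features data.frame of predictors (row names = sample ids).
#' @param egfr numeric response aligned with `features` rows.
#' @param n_folds CV folds (samples must number at least `2 * n_folds`).
#' @param n_trees trees per forest.
#' @param mtry_grid candidate `mtry` values (default: 1..p, thinned).
#' @param n_importance_perms response-permutation replicates.
#' @param seed integer seed.
#' @return list with `best_mtry`, `cv_rmse`, `cv_r2`, `oob_r2`,
#'   `importance` (data.frame: feature, inc_mse, p), `model_p`, `seed`,
#'   `folds`.
#' @export
rfEgfr <- function(features, egfr, n_folds = 10, n_trees = 500,
                   mtry_grid = NULL, n_importance_perms = 100, seed) {
  stopIf(!is.data.frame(features), "features must be a data.frame")
  ok <- stats::complete.cases(features, egfr)
  if (any(!ok)) {
    message(sum(!ok), " sample(s) dropped for missing values")
    features <- features[ok, , drop = FALSE]; egfr <- egfr[ok]
  }
  n <- nrow(features); p <- ncol(features)
  stopIf(n < 2 * n_folds,
         sprintf("need at least %d samples for %d-fold CV", 2 * n_folds, n_folds))
  stopIf(stats::var(egfr) == 0, "constant response; nothing to model")
  mtry_grid <- mtry_grid %||% unique(pmax(1L, pmin(p, c(
    1L, floor(sqrt(p)), floor(p / 3), floor(p / 2), p))))
  X <- as.matrix(features)
  seeds <- childSeeds(seed, 3L + n_importance_perms)
  folds <- withSeed(seeds[1L], cvFolds(n, n_folds))
  cv <- withSeed(seeds[2L], {
    vapply(mtry_grid, function(mt) {
      pred <- numeric(n)
      for (f in seq_len(n_folds)) {
        tr <- folds != f
        fit <- randomForest::randomForest(X[tr, , drop = FALSE], egfr[tr],
                                          ntree = n_trees, mtry = mt)
        pred[!tr] <- stats::predict(fit, X[!tr, , drop = FALSE])
      }
      sqrt(mean((pred - egfr)^2))
    }, numeric(1L))
  })
  bestMtry <- mtry_grid[which.min(cv)]
  cvRmse <- min(cv)
  cvR2 <- 1 - cvRmse^2 / mean((egfr - mean(egfr))^2)
  finalFit <- withSeed(seeds[3L],
    randomForest::randomForest(X, egfr, ntree = n_trees, mtry = bestMtry,
                               importance = TRUE))
  impObs <- randomForest::importance(finalFit, type = 1, scale = FALSE)[, 1L]
  oobR2 <- 1 - mean((finalFit$predicted - egfr)^2) /
    mean((egfr - mean(egfr))^2)
  impExceed <- rep(0L, p)
  r2Exceed <- 0L
  for (b in seq_len(n_importance_perms)) {
    res <- withSeed(seeds[3L + b], {
      yPerm <- sample(egfr)
      fitB <- randomForest::randomForest(X, yPerm, ntree = n_trees,
                                         mtry = bestMtry, importance = TRUE)
      list(imp = randomForest::importance(fitB, type = 1, scale = FALSE)[, 1L],
           r2 = 1 - mean((fitB$predicted - yPerm)^2) /
             mean((yPerm - mean(yPerm))^2))
    })
    impExceed <- impExceed + (res$imp >= impObs)
    r2Exceed <- r2Exceed + (res$r2 >= oobR2)
  }
  impP <- (1 + impExceed) / (1 + n_importance_perms)
  list(best_mtry = bestMtry, cv_rmse = cvRmse, cv_r2 = cvR2, oob_r2 = oobR2,
       importance = data.frame(feature = colnames(features),
                               inc_mse = unname(impObs), p = unname(impP),
                               stars = starsForP(unname(impP)),
                               stringsAsFactors = FALSE),
       model_p = (1 + r2Exceed) / (1 + n_importance_perms),
       seed = as.integer(seed), folds = folds)
}
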