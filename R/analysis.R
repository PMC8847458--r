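# Downstream analysis of per-cycle parameter tables: robust outlier
# removal, random-forest classification of individual step cycles, and
# correlation-matrix PCA with factor loadings.

.asParamDf <- function(table) {
  if (is(table, "GaitParameterTable")) paramTable(table)
  else as.data.frame(table)
}

.medianImpute <- function(df) {
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (anyNA(v)) {
      med <- median(v, na.rm = TRUE)
      if (is.na(med)) med <- 0
      v[is.na(v)] <- med
      df[[j]] <- v
    }
  }
  df
}

#' Remove outlier cycles by modified z-score
#'
#' A row is dropped iff any parameter's modified z-score
#' `0.6745 * (x - median) / MAD` exceeds `zCutoff` in absolute value.
#' The median/MAD basis is robust to the heavy-tailed cycles of injured
#' gait. Columns with zero MAD are skipped with a warning; missing
#' values never trigger removal. Row order is preserved and group
#' labels follow the surviving rows.
#'
#' @param table a [GaitParameterTable] or data.frame.
#' @param zCutoff modified z-score cutoff, > 0; default 3.5.
#' @return object of the same kind with outlier rows removed; the
#'   number dropped is recorded in `metadata(...)$outliersRemoved`
#'   (or attribute `outliersRemoved` for data.frames).
#' @export
removeOutliers <- function(table, zCutoff = 3.5) {
  stopifnot(zCutoff > 0)
  df <- .asParamDf(table)
  if (!nrow(df)) stop("table is empty")
  bad <- rep(FALSE, nrow(df))
  for (nm in names(df)) {
    v <- df[[nm]]
    if (!is.numeric(v)) next
    med <- median(v, na.rm = TRUE)
    madv <- mad(v, constant = 1, na.rm = TRUE)
    if (is.na(madv) || madv == 0) {
      warning("column '", nm, "' has zero MAD; skipped in outlier scoring")
      next
    }
    z <- 0.6745 * (v - med) / madv
    bad <- bad | (!is.na(z) & abs(z) > zCutoff)
  }
  keep <- !bad
  if (is(table, "GaitParameterTable")) {
    md <- table@metadata
    md$outliersRemoved <- sum(bad)
    grp <- groupLabels(table)
    out <- GaitParameterTable(df[keep, , drop = FALSE],
                              paramCategories(table),
                              group = if (length(grp)) droplevels(grp[keep])
                              else grp,
                              metadata = md)
    out
  } else {
    out <- df[keep, , drop = FALSE]
    attr(out, "outliersRemoved") <- sum(bad)
    out
  }
}

#' Random-forest classification of individual step cycles
#'
#' Rows (individual step cycles) are split uniformly at random into
#' train/test sets (default 75%/25%), and a forest of 100
#' unlimited-depth trees with Gini impurity splitting is trained on the
#' training rows. Accuracy, the confusion matrix and the Gini
#' importances are computed on / reported for the held-out test rows
#' only. Missing values are median-imputed per column first.
#' Importances (mean decrease in Gini impurity) are normalised to sum 1
#' and ranked descending. Reproducible bit-for-bit at a fixed seed.
#'
#' @param table a labeled [GaitParameterTable] (see
#'   [generateGroupDataset()]), or a data.frame with `labels` supplied.
#' @param labels group factor, one entry per row (ignored when `table`
#'   carries labels).
#' @param seed integer RNG seed for the split and the forest.
#' @param testFraction held-out fraction, in (0, 1); default 0.25.
#' @param ntree number of trees; default 100.
#' @return a [GaitClassification].
#' @export
runRandomForest <- function(table, labels = NULL, seed = 1,
                            testFraction = 0.25, ntree = 100) {
  df <- .asParamDf(table)
  y <- if (is(table, "GaitParameterTable") && length(groupLabels(table)))
    groupLabels(table) else labels
  if (is.null(y)) stop("no group labels supplied")
  y <- droplevels(factor(y))
  if (length(y) != nrow(df)) stop("labels must match the number of rows")
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (nrow(df) < 8) stop("need at least 8 rows")
  df <- .medianImpute(df)
  # drop non-finite leftovers (all-NA columns imputed to 0 already)
  df <- df[, vapply(df, function(v) all(is.finite(v)), logical(1)),
           drop = FALSE]
  n <- nrow(df)
  res <- .withSeed(seed, {
    trainIdx <- sample.int(n, round((1 - testFraction) * n))
    trainY <- y[trainIdx]
    if (nlevels(droplevels(trainY)) < nlevels(y))
      stop("a class is absent from the training split; ",
           "re-split with stratification or more rows")
    rf <- randomForest(x = df[trainIdx, , drop = FALSE], y = trainY,
                       ntree = ntree)
    testIdx <- setdiff(seq_len(n), trainIdx)
    pred <- predict(rf, df[testIdx, , drop = FALSE])
    list(rf = rf, trainIdx = trainIdx, testIdx = testIdx, pred = pred)
  })
  truth <- factor(y[res$testIdx], levels = levels(y))
  pred <- factor(res$pred, levels = levels(y))
  confusion <- unclass(as.matrix(table(true = truth, predicted = pred)))
  dimnames(confusion) <- list(true = levels(y), predicted = levels(y))
  imp <- res$rf$importance[, "MeanDecreaseGini"]
  imp <- sort(imp / sum(imp), decreasing = TRUE)
  GaitClassification(accuracy = mean(pred == truth),
                     confusion = confusion, importance = imp,
                     trainSize = length(res$trainIdx),
                     testSize = length(res$testIdx), seed = seed)
}

#' Principal component analysis of standardized gait parameters
#'
#' Columns are median-imputed, zero-variance columns dropped with a
#' warning, and the rest standardized to mean 0, sd 1 (the parameters
#' mix px, s, %, and degrees, so correlation-structure PCA is used).
#' Eigendecomposition yields per-cycle scores, factor loadings
#' (eigenvectors scaled by the square root of their eigenvalues) and
#' explained-variance ratios for all components.
#'
#' @param table a [GaitParameterTable] or data.frame; >= 2 rows.
#' @return a [GaitPCA].
#' @export
runPCA <- function(table) {
  df <- .asParamDf(table)
  if (nrow(df) < 2) stop("need at least 2 rows for PCA")
  df <- .medianImpute(df)
  keep <- vapply(df, function(v) is.finite(var(v)) && var(v) > 0,
                 logical(1))
  dropped <- names(df)[!keep]
  if (length(dropped))
    warning("dropping zero-variance columns: ",
            paste(dropped, collapse = ", "))
  df <- df[, keep, drop = FALSE]
  if (!ncol(df)) stop("no varying columns left for PCA")
  pr <- prcomp(as.matrix(df), center = TRUE, scale. = TRUE)
  ev <- pr$sdev^2
  load <- pr$rotation %*% diag(pr$sdev, length(pr$sdev))
  dimnames(load) <- dimnames(pr$rotation)
  GaitPCA(scores = pr$x, rotation = pr$rotation, loadings = load,
          explainedVar = ev / sum(ev), center = pr$center,
          scale = pr$scale, dropped = dropped)
}

#' Top factor loadings of a principal component
#'
#' The `k` parameters with the largest absolute loading on the given
#' component, descending, with signed values; ties broken by stable
#' column order.
#'
#' @param result a [GaitPCA].
#' @param component component index, within range.
#' @param k number of parameters to report, >= 1.
#' @return data.frame with columns `parameter` and `loading`.
#' @export
topFactorLoadings <- function(result, component = 1, k = 3) {
  stopifnot(k >= 1)
  p <- nrow(result@loadings)
  if (component < 1 || component > ncol(result@loadings))
    stop("component out of range")
  if (k > p) {
    warning("k exceeds parameter count; truncated to ", p)
    k <- p
  }
  l <- result@loadings[, component]
  ord <- order(-abs(l))
  data.frame(parameter = rownames(result@loadings)[ord][seq_len(k)],
             loading = unname(l[ord][seq_len(k)]),
             stringsAsFactors = FALSE)
}
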