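#' @include AllClasses.R
NULL

## Exploratory statistics used to screen candidate resistance drivers:
## Pearson correlation against the confirmed-resistance indicator,
## chi-square association for categorical drivers, PCA retention on the
## correlation matrix, and correlation-distance clustering to thin
## redundant drivers.

#' Pearson correlation with an importance flag
#'
#' Product-moment correlation of two driver series. A driver is flagged
#' important when `|r|` exceeds 0.2, the screening threshold used to
#' shortlist drivers against the confirmed-resistance indicator.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with elements `r`, `n` and `important`.
#' @examples
#' pearsonR(c(1, 2, 3, 4), c(1, 3, 2, 4))$r   # 0.8
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  r <- stats::cor(x, y)
  list(r = r, n = length(x), important = abs(r) > 0.2)
}

#' Chi-square test of association on a contingency table
#'
#' Expected counts are `row total x column total / grand total`; the
#' statistic is the sum of `(O - E)^2 / E` over all cells, without
#' continuity correction; the p-value is the upper tail of the
#' chi-square distribution with `(rows - 1)(cols - 1)` degrees of
#' freedom. Used for categorical drivers (land use / land cover, IRS
#' insecticide type) against the confirmed-resistance state.
#'
#' @param table numeric matrix of non-negative counts, at least 2 x 2,
#'   with no zero row or column total.
#' @return list with `statistic`, `df`, `p_value`, `observed`,
#'   `expected`.
#' @examples
#' chiSquare(matrix(c(10, 20, 20, 10), 2))$statistic  # 6.667
#' @export
chiSquare <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("contingency table must be at least 2 x 2")
  if (any(table < 0) || any(!is.finite(table)))
    stop("counts must be finite and non-negative")
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0))
    stop("zero marginal total: drop empty rows/columns first")
  expected <- outer(rs, cs) / sum(table)
  statistic <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  list(statistic = statistic, df = df,
       p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
       observed = table, expected = expected)
}

#' Principal-component retention of drivers
#'
#' Standardizes the driver columns and eigen-decomposes their correlation
#' matrix (via [stats::prcomp()]). Principal components are retained up
#' to the smallest count whose cumulative proportion of variance
#' strictly exceeds `varThreshold` (0.80 by default); a driver is
#' retained when the absolute value of its loading on any retained
#' component exceeds `loadingThreshold` (0.25). Kaiser flags
#' (eigenvalue > 1) are reported but not enforced.
#'
#' @param X numeric matrix or data.frame, samples x drivers, with named
#'   columns; at least 2 non-constant columns.
#' @param varThreshold cumulative-variance retention threshold.
#' @param loadingThreshold absolute-loading retention threshold.
#' @return list with `eigenvalues`, `proportion`, `cumulative`,
#'   `retainedPcCount`, `loadings` (drivers x PCs), `retainedDrivers`,
#'   `kaiser`.
#' @export
pcaSelect <- function(X, varThreshold = 0.80, loadingThreshold = 0.25) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("at least 2 driver columns are required")
  if (is.null(colnames(X))) colnames(X) <- paste0("driver", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant driver column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  if (nrow(X) <= ncol(X))
    warning("fewer samples than drivers + 1; loadings may be unstable")
  p <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ev <- p$sdev^2
  prop <- ev / sum(ev)
  cum <- cumsum(prop)
  ## strict "> threshold", guarded against floating-point noise when the
  ## cumulative proportion lands exactly on the threshold
  k <- which(cum > varThreshold + 1e-9)[1]
  loadings <- p$rotation
  retained <- rownames(loadings)[
    apply(abs(loadings[, seq_len(k), drop = FALSE]), 1,
          function(v) any(v > loadingThreshold))]
  list(eigenvalues = ev, proportion = prop, cumulative = cum,
       retainedPcCount = as.integer(k), loadings = loadings,
       retainedDrivers = retained, kaiser = ev > 1)
}

#' Cluster drivers by correlation distance
#'
#' Agglomerative (average-linkage) clustering of the drivers under the
#' distance `1 - |r|`, so perfectly correlated or anti-correlated
#' drivers merge at height 0 and independent ones near height 1. Used to
#' spot redundant driver groups before thinning them to one
#' representative each.
#'
#' @param X samples x drivers matrix with named columns.
#' @param h optional dendrogram cut height in [0, 1]; when given, flat
#'   cluster labels are returned as well.
#' @return list with `hclust` (the tree) and, when `h` is given,
#'   `clusters` (named integer vector).
#' @export
clusterDrivers <- function(X, h = NULL) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("at least 2 drivers are required")
  if (is.null(colnames(X))) colnames(X) <- paste0("driver", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant driver column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  d <- stats::as.dist(1 - abs(stats::cor(X)))
  hc <- stats::hclust(d, method = "average")
  out <- list(hclust = hc)
  if (!is.null(h)) out$clusters <- stats::cutree(hc, h = h)
  out
}

#' Full driver-selection pipeline
#'
#' Combines the exploratory screens into one selection: PCA retention of
#' continuous drivers, `|r| > rThreshold` correlation screening against
#' the confirmed-resistance indicator, chi-square significance for
#' categorical drivers, and one-representative-per-cluster thinning
#' (keeping the member with maximal `|r|` against the indicator; ties
#' break lexicographically by driver name). Full provenance for every
#' driver is recorded.
#'
#' @param X samples x continuous-drivers matrix with named columns.
#' @param y per-sample confirmed-resistance indicator (0/1 or logical).
#' @param categorical optional named list of per-sample categorical
#'   driver vectors (factors or codes), tested by [chiSquare()] against
#'   `y`.
#' @param varThreshold,loadingThreshold passed to [pcaSelect()].
#' @param rThreshold importance threshold on `|r|` (default 0.2).
#' @param alpha chi-square significance level (default 0.05).
#' @param clusterCut dendrogram cut height for thinning (default 0.5:
#'   drivers correlated above 0.5 in absolute value fall in one group).
#' @return list with the component results (`pca`, `clustering`,
#'   `correlations`, `chiSquare`), a `provenance` data.frame, and
#'   `finalDrivers`.
#' @export
selectDrivers <- function(X, y, categorical = NULL,
                          varThreshold = 0.80, loadingThreshold = 0.25,
                          rThreshold = 0.2, alpha = 0.05,
                          clusterCut = 0.5) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y must be aligned")
  pca <- pcaSelect(X, varThreshold, loadingThreshold)
  cl <- clusterDrivers(X, h = clusterCut)
  rvals <- vapply(colnames(X), function(nm) {
    if (stats::sd(y) == 0) 0 else stats::cor(X[, nm], y)
  }, 0)
  prov <- data.frame(
    driver = colnames(X),
    kind = "continuous",
    r = unname(rvals),
    important = abs(rvals) > rThreshold,
    pca_retained = colnames(X) %in% pca$retainedDrivers,
    cluster = unname(cl$clusters[colnames(X)]),
    stringsAsFactors = FALSE)
  ## one representative per cluster among the screened survivors
  cand <- prov[prov$important & prov$pca_retained, , drop = FALSE]
  finals <- character()
  for (g in sort(unique(cand$cluster))) {
    members <- cand[cand$cluster == g, , drop = FALSE]
    members <- members[order(-abs(members$r), members$driver), ,
                       drop = FALSE]
    finals <- c(finals, members$driver[1])
  }
  prov$selected <- prov$driver %in% finals
  chis <- NULL
  if (length(categorical)) {
    chis <- lapply(categorical, function(v) {
      tab <- table(v, y)
      chiSquare(as.matrix(tab))
    })
    catp <- vapply(chis, function(z) z$p_value, 0)
    catProv <- data.frame(
      driver = names(categorical), kind = "categorical",
      r = NA_real_, important = NA, pca_retained = NA,
      cluster = NA_integer_, selected = catp < alpha,
      stringsAsFactors = FALSE)
    catProv$p_value <- catp
    prov$p_value <- NA_real_
    prov <- rbind(prov, catProv)
    finals <- c(finals, names(categorical)[catp < alpha])
  }
  list(pca = pca, clustering = cl, correlations = rvals,
       chiSquare = chis, provenance = prov,
       finalDrivers = finals)
}

#' Export a selection report as JSON plus a loadings CSV
#'
#' @param report result of [selectDrivers()].
#' @param jsonPath output JSON path (provenance and final drivers).
#' @param loadingsPath optional CSV path for the PCA loading table.
#' @return `jsonPath`, invisibly.
#' @export
writeSelectionReport <- function(report, jsonPath, loadingsPath = NULL) {
  doc <- list(final_drivers = report$finalDrivers,
              retained_pc_count = report$pca$retainedPcCount,
              eigenvalues = report$pca$eigenvalues,
              cumulative = report$pca$cumulative,
              provenance = report$provenance)
  jsonlite::write_json(doc, jsonPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  if (!is.null(loadingsPath))
    utils::write.csv(report$pca$loadings, loadingsPath)
  invisible(jsonPath)
}
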