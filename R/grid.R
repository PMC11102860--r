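#' @include AllClasses.R
NULL

#' Build a regular lattice over a planar study area
#'
#' Divides a `width` x `height` km rectangle into square cells of side
#' `cellSize` km (5 km by default). Partial cells at the right/top edges
#' are kept, so `nCols = ceiling(width / cellSize)` and
#' `nRows = ceiling(height / cellSize)`.
#'
#' @param originX,originY planar coordinates (km) of the lower-left corner.
#' @param width,height extent of the study area (km), both positive.
#' @param cellSize cell side (km), positive.
#' @return a [GridSpec-class].
#' @examples
#' buildGrid(0, 0, 50, 50)          # 10 x 10 cells of 5 km
#' buildGrid(0, 0, 12, 5, 5)        # 1 row x 3 cols (partial last column)
#' @export
buildGrid <- function(originX, originY, width, height, cellSize = 5) {
  if (!all(is.finite(c(originX, originY, width, height, cellSize))) ||
      width <= 0 || height <= 0 || cellSize <= 0)
    stop("width, height and cellSize must be positive finite numbers")
  new("GridSpec", originX = as.numeric(originX),
      originY = as.numeric(originY), cellSize = as.numeric(cellSize),
      nRows = as.integer(ceiling(height / cellSize)),
      nCols = as.integer(ceiling(width / cellSize)))
}

#' Map planar points to lattice cells
#'
#' Each cell is a half-open square, closed on its lower/left edges, so
#' every in-bounds point belongs to exactly one cell; a point exactly on
#' an interior boundary falls in the cell to its right/above.
#'
#' @param x,y planar coordinates (km); vectors of equal length.
#' @param grid a [GridSpec-class].
#' @return data.frame with 1-based columns `i` (row, increasing with y)
#'   and `j` (column, increasing with x).
#' @examples
#' g <- buildGrid(0, 0, 50, 50)
#' pointToCell(2.4, 2.4, g)   # cell (1, 1)
#' pointToCell(5, 0, g)       # cell (1, 2): boundary goes right
#' @export
pointToCell <- function(x, y, grid) {
  stopifnot(is(grid, "GridSpec"), length(x) == length(y))
  s <- grid@cellSize
  j <- floor((x - grid@originX) / s) + 1
  i <- floor((y - grid@originY) / s) + 1
  bad <- !is.finite(i) | !is.finite(j) |
    i < 1 | i > grid@nRows | j < 1 | j > grid@nCols
  if (any(bad))
    stop(sprintf("%d point(s) outside the grid bounding box", sum(bad)))
  data.frame(i = as.integer(i), j = as.integer(j))
}

#' Cell centroids of a lattice
#'
#' @param grid a [GridSpec-class].
#' @return data.frame with one row per cell: `i`, `j`, `x_center`,
#'   `y_center`, in column-major cell order.
#' @examples
#' cellCentroids(buildGrid(0, 0, 5, 5, 5))  # single centroid (2.5, 2.5)
#' @export
cellCentroids <- function(grid) {
  stopifnot(is(grid, "GridSpec"))
  idx <- expand.grid(i = seq_len(grid@nRows), j = seq_len(grid@nCols))
  s <- grid@cellSize
  data.frame(i = idx$i, j = idx$j,
             x_center = grid@originX + (idx$j - 0.5) * s,
             y_center = grid@originY + (idx$i - 0.5) * s)
}

#' Construct a monthly time axis
#'
#' @param startYear,startMonth first calendar month of the axis.
#' @param nSteps number of consecutive monthly steps.
#' @return a [TimeAxis-class].
#' @examples
#' TimeAxis(2000, 1, 24)
#' @export
TimeAxis <- function(startYear, startMonth = 1, nSteps) {
  new("TimeAxis", startYear = as.integer(startYear),
      startMonth = as.integer(startMonth), nSteps = as.integer(nSteps))
}

## step -> (year, month) table; month index counted from year 0 January
.axisMonths <- function(axis) {
  k <- axis@startYear * 12L + (axis@startMonth - 1L) + seq_len(axis@nSteps) - 1L
  data.frame(step = seq_len(axis@nSteps),
             year = k %/% 12L, month = k %% 12L + 1L)
}

#' Calendar months covered by a time axis
#'
#' @param axis a [TimeAxis-class].
#' @return data.frame with columns `step`, `year`, `month`.
#' @export
axisMonths <- function(axis) {
  stopifnot(is(axis, "TimeAxis"))
  .axisMonths(axis)
}

#' Interpolate yearly driver values to a monthly axis
#'
#' Yearly values are anchored at January of their year; months between
#' anchors are linearly interpolated and months before the first / after
#' the last anchor are held constant at the nearest anchor. Anchored
#' months reproduce their yearly value exactly. This is the bridge from
#' annually reported driver databases to the model's monthly clock.
#'
#' @param yearlyValues named numeric vector; names are calendar years.
#' @param axis a [TimeAxis-class].
#' @return numeric vector of length `nSteps(axis)`.
#' @examples
#' ax <- TimeAxis(2000, 1, 24)
#' interpolateToMonthly(c("2000" = 12, "2001" = 24), ax)[7]  # July 2000: 18
#' @export
interpolateToMonthly <- function(yearlyValues, axis) {
  stopifnot(is(axis, "TimeAxis"))
  if (length(yearlyValues) == 0L)
    stop("at least one yearly anchor is required")
  yrs <- as.integer(names(yearlyValues))
  if (anyNA(yrs)) stop("yearlyValues must be named by calendar year")
  o <- order(yrs)
  yrs <- yrs[o]; vals <- as.numeric(yearlyValues)[o]
  m <- .axisMonths(axis)
  xout <- m$year * 12 + (m$month - 1)      # continuous month index
  xa <- yrs * 12                           # January anchors
  if (length(xa) == 1L)
    return(rep(vals, axis@nSteps))
  stats::approx(xa, vals, xout = xout, rule = 2)$y
}

#' Step yearly categorical codes to a monthly axis
#'
#' Categorical layers (e.g. land use / land cover codes) are never
#' interpolated: each month takes the code of the nearest January anchor
#' (ties resolve to the earlier year).
#'
#' @inheritParams interpolateToMonthly
#' @return integer vector of length `nSteps(axis)`.
#' @export
stepToMonthly <- function(yearlyValues, axis) {
  stopifnot(is(axis, "TimeAxis"))
  if (length(yearlyValues) == 0L)
    stop("at least one yearly anchor is required")
  yrs <- as.integer(names(yearlyValues))
  if (anyNA(yrs)) stop("yearlyValues must be named by calendar year")
  o <- order(yrs)
  yrs <- yrs[o]; vals <- yearlyValues[o]
  m <- .axisMonths(axis)
  xout <- m$year * 12 + (m$month - 1)
  xa <- yrs * 12
  pick <- vapply(xout, function(x) which.min(abs(xa - x)), 0L)
  as.vector(vals[pick])
}
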