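#' @include AllClasses.R rules.R
NULL

#' Moore neighbourhood of a lattice cell
#'
#' All cells within Chebyshev distance `radius` of `(i, j)`, excluding
#' the cell itself and truncated at the grid edges (geographic domains do
#' not wrap around). An interior cell has 8 neighbours at radius 1, an
#' edge cell 5, a corner cell 3.
#'
#' @param i,j 1-based cell index.
#' @param grid a [GridSpec-class].
#' @param radius neighbourhood radius (>= 1), default 1.
#' @return data.frame of neighbour indices with columns `i`, `j`.
#' @examples
#' g <- buildGrid(0, 0, 50, 50)
#' nrow(mooreNeighbors(5, 5, g))  # 8
#' nrow(mooreNeighbors(1, 1, g))  # 3
#' @export
mooreNeighbors <- function(i, j, grid, radius = 1) {
  stopifnot(is(grid, "GridSpec"), radius >= 1)
  if (i < 1 || i > grid@nRows || j < 1 || j > grid@nCols)
    stop("cell index outside the grid")
  off <- expand.grid(di = -radius:radius, dj = -radius:radius)
  off <- off[!(off$di == 0 & off$dj == 0), ]
  ni <- i + off$di; nj <- j + off$dj
  keep <- ni >= 1 & ni <= grid@nRows & nj >= 1 & nj <= grid@nCols
  out <- data.frame(i = ni[keep], j = nj[keep])
  rownames(out) <- NULL
  out
}

## TRUE where the closed Moore neighbourhood (cell itself included)
## contains a confirmed cell: binary dilation by a (2r+1)^2 square
## structuring element, computed with shifted copies on a padded matrix.
.closedNeighborhoodAny <- function(values, radius = 1) {
  nr <- nrow(values); nc <- ncol(values)
  pad <- matrix(0, nr + 2 * radius, nc + 2 * radius)
  pad[radius + seq_len(nr), radius + seq_len(nc)] <- values
  acc <- matrix(0, nr, nc)
  for (di in -radius:radius) for (dj in -radius:radius)
    acc <- acc + pad[radius + di + seq_len(nr), radius + dj + seq_len(nc)]
  acc > 0
}

#' One synchronous update of the resistance automaton
#'
#' The extended update: a cell is confirmed at the next month iff either
#' channel asserts it from the state and drivers of the current month.
#' The diffusion channel requires confirmed resistance already present in
#' the cell's closed Moore neighbourhood (the cell counts as its own
#' neighbour, which is what lets a confirmed cell persist) AND a
#' diffusion rule to hold locally. The emergence channel requires only
#' that an emergence rule holds locally, letting resistance start far
#' from any confirmed cell. A cell where both channels fail is 0 at the
#' next step regardless of its current state — deteriorating driver
#' conditions erase confirmed resistance. The update is synchronous
#' (double-buffered): all decisions read the current state only.
#'
#' @param state a [StateGrid-class].
#' @param driversAtT named list of `nRows x nCols` matrices, one per
#'   driver, holding the current month's values. Conditions on missing
#'   drivers or `NA` cells evaluate `FALSE`.
#' @param ruleset a [RuleSet-class].
#' @param radius Moore-neighbourhood radius, default 1.
#' @return a [StateGrid-class] at `step + 1`.
#' @export
caStep <- function(state, driversAtT, ruleset, radius = 1) {
  stopifnot(is(state, "StateGrid"), is(ruleset, "RuleSet"))
  dims <- dim(state@values)
  for (m in driversAtT)
    if (!identical(dim(m), dims))
      stop("driver slice dimensions do not match the state grid")
  new("StateGrid", grid = state@grid, step = state@step + 1L,
      values = .stepValues(state@values, driversAtT, ruleset, radius))
}

.stepValues <- function(values, driversAtT, ruleset, radius = 1) {
  dims <- dim(values)
  diff_ok <- .ruleListMask(ruleset@diffusionRules, driversAtT, dims)
  emer_ok <- .ruleListMask(ruleset@emergenceRules, driversAtT, dims)
  present <- .closedNeighborhoodAny(values, radius)
  nxt <- (present & diff_ok) | emer_ok
  storage.mode(nxt) <- "double"
  attr(nxt, "n_missing") <-
    attr(diff_ok, "n_missing") + attr(emer_ok, "n_missing")
  nxt
}

#' Run the automaton over a monthly axis
#'
#' Iterates [caStep()] from a seed state across every step of the driver
#' stack's time axis. Fully deterministic: identical inputs give
#' identical sequences. Missing driver values make the affected
#' conditions `FALSE` (never asserting resistance from absent data); a
#' single warning reports how many cell-condition evaluations hit
#' missing data over the whole run.
#'
#' @param seed a [StateGrid-class] at step 1.
#' @param drivers a [DriverStack-class] on the same grid.
#' @param ruleset a [RuleSet-class].
#' @param radius Moore-neighbourhood radius, default 1.
#' @return a [StateSequence-class] of length `nSteps(drivers)` whose
#'   first slice is the seed.
#' @export
caRun <- function(seed, drivers, ruleset, radius = 1) {
  stopifnot(is(seed, "StateGrid"), is(drivers, "DriverStack"),
            is(ruleset, "RuleSet"))
  g <- drivers@grid
  if (!identical(dim(seed@values), c(g@nRows, g@nCols)))
    stop("seed grid does not match the driver stack")
  ns <- drivers@axis@nSteps
  out <- array(0, c(g@nRows, g@nCols, ns))
  out[, , 1] <- seed@values
  cur <- seed@values
  nMissing <- 0
  for (k in seq_len(ns - 1L)) {
    slice <- lapply(drivers@layers, function(a) a[, , k, drop = TRUE])
    cur <- .stepValues(cur, slice, ruleset, radius)
    nMissing <- nMissing + attr(cur, "n_missing")
    out[, , k + 1L] <- cur
  }
  if (nMissing > 0)
    warning(nMissing, " condition evaluation(s) hit missing driver data",
            " (treated as FALSE)")
  new("StateSequence", grid = g, axis = drivers@axis, values = out)
}
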