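#' @import methods
NULL

## Central S4 containers: the spatial lattice, the monthly clock, gridded
## driver stacks, binary resistance-state lattices, observed (rasterized)
## bioassay outcomes, declarative rule sets and validation reports.

#' GridSpec: a regular planar lattice of square cells
#'
#' Describes the spatial domain as `nRows` x `nCols` square cells of side
#' `cellSize` kilometres on a single projected plane. Cell `(i, j)` (both
#' 1-based, `i` increasing with y) covers the half-open square
#' `[originX + (j-1) s, originX + j s) x [originY + (i-1) s, originY + i s)`,
#' so every in-bounds point belongs to exactly one cell.
#'
#' @slot originX,originY planar coordinates of the lower-left corner (km).
#' @slot cellSize cell side length in km (default 5, the resolution at
#'   which national territories are gridded for resistance surveillance).
#' @slot nRows,nCols lattice dimensions.
#' @exportClass GridSpec
setClass("GridSpec",
  representation(originX = "numeric", originY = "numeric",
                 cellSize = "numeric", nRows = "integer", nCols = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
        object@cellSize <= 0)
      msg <- c(msg, "cellSize must be a single positive number")
    if (length(object@nRows) != 1L || object@nRows < 1L)
      msg <- c(msg, "nRows must be >= 1")
    if (length(object@nCols) != 1L || object@nCols < 1L)
      msg <- c(msg, "nCols must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' TimeAxis: consecutive calendar months
#'
#' The model clock: `nSteps` consecutive months starting at
#' `startYear`-`startMonth`. The fixed one-month increment is the time step
#' of the automaton update.
#'
#' @slot startYear,startMonth first month of the axis.
#' @slot nSteps number of monthly steps (>= 1).
#' @exportClass TimeAxis
setClass("TimeAxis",
  representation(startYear = "integer", startMonth = "integer",
                 nSteps = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@startMonth < 1L || object@startMonth > 12L)
      msg <- c(msg, "startMonth must be in 1..12")
    if (object@nSteps < 1L)
      msg <- c(msg, "nSteps must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' StateGrid: the binary confirmed-resistance lattice at one time step
#'
#' Cell value 1 means the vector population of that cell is in the
#' confirmed phenotypic-resistance state (bioassay mortality < 90%);
#' 0 means it is not.
#'
#' @slot grid the [GridSpec-class] the lattice lives on.
#' @slot step 1-based index of the time step the state refers to.
#' @slot values `nRows x nCols` numeric matrix of 0/1.
#' @exportClass StateGrid
setClass("StateGrid",
  representation(grid = "GridSpec", step = "integer", values = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@values),
                   c(object@grid@nRows, object@grid@nCols)))
      msg <- c(msg, "values must be an nRows x nCols matrix")
    if (!all(object@values %in% c(0, 1)))
      msg <- c(msg, "values must be 0 or 1")
    if (object@step < 1L) msg <- c(msg, "step must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' StateSequence: the state lattice over a whole monthly axis
#'
#' @slot grid the [GridSpec-class].
#' @slot axis the [TimeAxis-class]; third array dimension matches `nSteps`.
#' @slot values `nRows x nCols x nSteps` array of 0/1.
#' @exportClass StateSequence
setClass("StateSequence",
  representation(grid = "GridSpec", axis = "TimeAxis", values = "array"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@values)
    if (length(d) != 3L ||
        !identical(d, c(object@grid@nRows, object@grid@nCols,
                        object@axis@nSteps)))
      msg <- c(msg, "values must be an nRows x nCols x nSteps array")
    else if (!all(object@values %in% c(0, 1)))
      msg <- c(msg, "values must be 0 or 1")
    if (is.null(msg)) TRUE else msg
  })

#' DriverStack: time-indexed gridded driver layers
#'
#' Named stack of per-cell, per-month driver surfaces (temperature,
#' precipitation, ITN/IRS coverage, crop fractions, population density,
#' NDVI, elevation, categorical land use / land cover, ...) aligned to one
#' grid and one monthly axis. Continuous layers hold numeric values;
#' categorical layers hold integer codes with a legend.
#'
#' @slot grid the [GridSpec-class].
#' @slot axis the [TimeAxis-class].
#' @slot layers named list of `nRows x nCols x nSteps` arrays.
#' @slot kinds named character, `"continuous"` or `"categorical"` per layer.
#' @slot legends named list; for categorical layers, the integer code set.
#' @exportClass DriverStack
setClass("DriverStack",
  representation(grid = "GridSpec", axis = "TimeAxis", layers = "list",
                 kinds = "character", legends = "list"),
  validity = function(object) {
    msg <- NULL
    nm <- names(object@layers)
    if (length(object@layers) && (is.null(nm) || any(nm == "")))
      msg <- c(msg, "all layers must be named")
    if (!identical(sort(nm), sort(names(object@kinds))))
      msg <- c(msg, "kinds must be named exactly after layers")
    if (!all(object@kinds %in% c("continuous", "categorical")))
      msg <- c(msg, "kinds must be 'continuous' or 'categorical'")
    want <- c(object@grid@nRows, object@grid@nCols, object@axis@nSteps)
    for (l in nm)
      if (!identical(dim(object@layers[[l]]), want)) {
        msg <- c(msg, sprintf("layer '%s' must be nRows x nCols x nSteps", l))
        break
      }
    if (is.null(msg)) TRUE else msg
  })

.validRule <- function(rule) {
  if (!is.list(rule) || is.null(rule$name) || !nzchar(rule$name))
    return("each rule must be a named list with a non-empty 'name'")
  if (!is.list(rule$conditions) || length(rule$conditions) < 1L)
    return(sprintf("rule '%s' must have >= 1 condition", rule$name))
  ops <- c("in_interval", "greater_than", "less_than", "greater_equal",
           "equals_category")
  for (cond in rule$conditions) {
    if (is.null(cond$driver) || !nzchar(cond$driver))
      return(sprintf("rule '%s': condition lacks a driver name", rule$name))
    if (is.null(cond$op) || !cond$op %in% ops)
      return(sprintf("rule '%s': unknown op '%s'", rule$name, cond$op))
    if (cond$op == "in_interval") {
      if (length(cond$bounds) != 2L || cond$bounds[1] > cond$bounds[2])
        return(sprintf("rule '%s': interval bounds must satisfy lower <= upper",
                       rule$name))
    } else if (length(cond$bounds) != 1L || !is.finite(cond$bounds)) {
      return(sprintf("rule '%s': op '%s' needs one finite bound",
                     rule$name, cond$op))
    }
  }
  TRUE
}

#' RuleSet: declarative transition rules for the automaton
#'
#' Two channels of threshold rules over driver values. The diffusion
#' channel gates the neighbourhood spread of confirmed resistance (a cell
#' already confirmed, or adjacent to a confirmed cell, stays/becomes
#' confirmed only where a diffusion rule holds); the emergence channel
#' lets confirmed resistance start in any cell whose conditions permit it,
#' regardless of neighbourhood. Within a rule the conditions are a
#' conjunction; across rules a set is a disjunction.
#'
#' @slot diffusionRules,emergenceRules lists of rules; each rule is a list
#'   with elements `name`, `species`, `insecticide_class` and `conditions`
#'   (a list of `list(driver, op, bounds)` clauses). See [irCondition()].
#' @exportClass RuleSet
setClass("RuleSet",
  representation(diffusionRules = "list", emergenceRules = "list"),
  validity = function(object) {
    msg <- NULL
    for (ch in c("diffusionRules", "emergenceRules")) {
      rules <- slot(object, ch)
      for (rule in rules) {
        v <- .validRule(rule)
        if (!isTRUE(v)) msg <- c(msg, paste0(ch, ": ", v))
      }
      nms <- vapply(rules, function(r) r$name %||% "", "")
      if (anyDuplicated(nms))
        msg <- c(msg, paste0(ch, ": rule names must be unique"))
    }
    if (is.null(msg)) TRUE else msg
  })

#' ObservedGrid: rasterized bioassay outcomes for one year
#'
#' Point susceptibility records of one species x insecticide class x year,
#' aggregated to the lattice. A covered cell (>= 1 record) is
#' confirmed-present when at least one of its records classifies as
#' confirmed resistance; cells without records carry no status and are
#' never evaluated.
#'
#' @slot grid the [GridSpec-class].
#' @slot year calendar year of the records.
#' @slot species,insecticideClass labels the records were filtered to.
#' @slot status data.frame with columns `i`, `j`, `confirmed` (logical),
#'   one row per covered cell.
#' @exportClass ObservedGrid
setClass("ObservedGrid",
  representation(grid = "GridSpec", year = "integer", species = "character",
                 insecticideClass = "character", status = "data.frame"),
  validity = function(object) {
    msg <- NULL
    st <- object@status
    if (!all(c("i", "j", "confirmed") %in% names(st)))
      msg <- c(msg, "status needs columns i, j, confirmed")
    else {
      if (nrow(st) && (any(st$i < 1L | st$i > object@grid@nRows) ||
                       any(st$j < 1L | st$j > object@grid@nCols)))
        msg <- c(msg, "status indices out of grid")
      if (anyDuplicated(st[c("i", "j")]))
        msg <- c(msg, "one status row per covered cell")
    }
    if (is.null(msg)) TRUE else msg
  })

#' AccuracyReport: per-year confusion counts and accuracy
#'
#' Validation summary comparing predicted annual confirmed-resistance
#' grids against observed ones at covered cells only. Accuracy is
#' `(Tp + Tn) / (Tp + Tn + Fp + Fn)`; years with no covered cells are
#' reported as `NA` and excluded from the mean.
#'
#' @slot species,insecticideClass labels of the comparison.
#' @slot perYear data.frame with columns `year`, `tp`, `tn`, `fp`, `fn`,
#'   `n`, `accuracy`.
#' @slot meanAccuracy mean accuracy over years with >= 1 evaluated cell.
#' @exportClass AccuracyReport
setClass("AccuracyReport",
  representation(species = "character", insecticideClass = "character",
                 perYear = "data.frame", meanAccuracy = "numeric"),
  validity = function(object) {
    need <- c("year", "tp", "tn", "fp", "fn", "n", "accuracy")
    if (!all(need %in% names(object@perYear)))
      return("perYear needs columns year, tp, tn, fp, fn, n, accuracy")
    acc <- object@perYear$accuracy
    if (any(!is.na(acc) & (acc < 0 | acc > 1)))
      return("accuracy must lie in [0, 1]")
    TRUE
  })

`%||%` <- function(a, b) if (is.null(a)) b else a
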