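#' @include AllClasses.R
NULL

#' @rdname GridSpec-class
#' @param x a ResistCA object
#' @export
setGeneric("nRows", function(x) standardGeneric("nRows"))
#' @rdname GridSpec-class
#' @export
setGeneric("nCols", function(x) standardGeneric("nCols"))
#' @rdname GridSpec-class
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))
#' @rdname GridSpec-class
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname GridSpec-class
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))
#' @rdname TimeAxis-class
#' @param x a ResistCA object
#' @export
setGeneric("nSteps", function(x) standardGeneric("nSteps"))
#' @rdname TimeAxis-class
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))
#' @rdname StateGrid-class
#' @param x a ResistCA object
#' @export
setGeneric("stateValues", function(x) standardGeneric("stateValues"))
#' @rdname DriverStack-class
#' @param x a [DriverStack-class]
#' @export
setGeneric("driverNames", function(x) standardGeneric("driverNames"))
#' @rdname DriverStack-class
#' @export
setGeneric("driverKinds", function(x) standardGeneric("driverKinds"))
#' @rdname ObservedGrid-class
#' @param x an [ObservedGrid-class]
#' @export
setGeneric("coveredCells", function(x) standardGeneric("coveredCells"))
#' @rdname AccuracyReport-class
#' @param x an [AccuracyReport-class]
#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))
#' @rdname AccuracyReport-class
#' @export
setGeneric("perYear", function(x) standardGeneric("perYear"))

#' @rdname GridSpec-class
setMethod("nRows", "GridSpec", function(x) x@nRows)
#' @rdname GridSpec-class
setMethod("nCols", "GridSpec", function(x) x@nCols)
#' @rdname GridSpec-class
setMethod("cellSize", "GridSpec", function(x) x@cellSize)
#' @rdname GridSpec-class
setMethod("gridOrigin", "GridSpec",
          function(x) c(x = x@originX, y = x@originY))
#' @rdname TimeAxis-class
setMethod("nSteps", "TimeAxis", function(x) x@nSteps)

#' @rdname StateGrid-class
setMethod("gridSpec", "StateGrid", function(x) x@grid)
#' @rdname StateSequence-class
setMethod("gridSpec", "StateSequence", function(x) x@grid)
#' @rdname DriverStack-class
setMethod("gridSpec", "DriverStack", function(x) x@grid)
#' @rdname ObservedGrid-class
setMethod("gridSpec", "ObservedGrid", function(x) x@grid)
#' @rdname StateSequence-class
setMethod("timeAxis", "StateSequence", function(x) x@axis)
#' @rdname DriverStack-class
setMethod("timeAxis", "DriverStack", function(x) x@axis)
#' @rdname StateSequence-class
setMethod("nSteps", "StateSequence", function(x) x@axis@nSteps)
#' @rdname DriverStack-class
setMethod("nSteps", "DriverStack", function(x) x@axis@nSteps)

#' @rdname StateGrid-class
setMethod("stateValues", "StateGrid", function(x) x@values)
#' @rdname StateSequence-class
#' @param x a [StateSequence-class]
setMethod("stateValues", "StateSequence", function(x) x@values)
#' @rdname DriverStack-class
setMethod("driverNames", "DriverStack", function(x) names(x@layers))
#' @rdname DriverStack-class
setMethod("driverKinds", "DriverStack", function(x) x@kinds)
#' @rdname ObservedGrid-class
setMethod("coveredCells", "ObservedGrid",
          function(x) x@status[c("i", "j")])
#' @rdname AccuracyReport-class
setMethod("meanAccuracy", "AccuracyReport", function(x) x@meanAccuracy)
#' @rdname AccuracyReport-class
setMethod("perYear", "AccuracyReport", function(x) x@perYear)

#' Extract one monthly state from a sequence
#'
#' @param x a [StateSequence-class]
#' @param i step index
#' @param j,drop,... unused
#' @return a [StateGrid-class]
#' @export
setMethod("[[", "StateSequence", function(x, i, j, ...) {
  i <- as.integer(i)
  stopifnot(length(i) == 1L, i >= 1L, i <= x@axis@nSteps)
  new("StateGrid", grid = x@grid, step = i,
      values = x@values[, , i, drop = TRUE])
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells of %g km, origin (%g, %g)\n",
              object@nRows, object@nCols, object@cellSize,
              object@originX, object@originY))
})

setMethod("show", "TimeAxis", function(object) {
  m <- .axisMonths(object)
  cat(sprintf("TimeAxis: %d monthly steps, %04d-%02d .. %04d-%02d\n",
              object@nSteps, m$year[1], m$month[1],
              m$year[object@nSteps], m$month[object@nSteps]))
})

setMethod("show", "StateGrid", function(object) {
  cat(sprintf("StateGrid: step %d, %d / %d cells confirmed\n",
              object@step, sum(object@values),
              length(object@values)))
})

setMethod("show", "StateSequence", function(object) {
  cat(sprintf(
    "StateSequence: %d x %d grid, %d steps; confirmed cells %d -> %d\n",
    object@grid@nRows, object@grid@nCols, object@axis@nSteps,
    sum(object@values[, , 1]), sum(object@values[, , object@axis@nSteps])))
})

setMethod("show", "DriverStack", function(object) {
  cat(sprintf("DriverStack: %d layers on a %d x %d grid, %d steps\n",
              length(object@layers), object@grid@nRows, object@grid@nCols,
              object@axis@nSteps))
  if (length(object@layers))
    cat("  ", paste0(names(object@layers), " (",
                     unname(object@kinds[names(object@layers)]), ")",
                     collapse = ", "), "\n", sep = "")
})

setMethod("show", "RuleSet", function(object) {
  cat(sprintf("RuleSet: %d diffusion rule(s), %d emergence rule(s)\n",
              length(object@diffusionRules), length(object@emergenceRules)))
  for (r in object@diffusionRules)
    cat("  diffusion:", r$name, sprintf("(%d condition(s))\n",
                                        length(r$conditions)))
  for (r in object@emergenceRules)
    cat("  emergence:", r$name, sprintf("(%d condition(s))\n",
                                        length(r$conditions)))
})

setMethod("show", "ObservedGrid", function(object) {
  cat(sprintf(
    "ObservedGrid: %s / %s, year %d; %d covered cells (%d confirmed)\n",
    object@species, object@insecticideClass, object@year,
    nrow(object@status), sum(object@status$confirmed)))
})

setMethod("show", "AccuracyReport", function(object) {
  cat(sprintf("AccuracyReport: %s / %s\n", object@species,
              object@insecticideClass))
  print(object@perYear, row.names = FALSE)
  cat(sprintf("Mean accuracy over evaluated years: %s\n",
              ifelse(is.na(object@meanAccuracy), "-",
                     format(round(object@meanAccuracy, 4)))))
})
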