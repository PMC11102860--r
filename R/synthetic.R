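#' @include AllClasses.R ca_engine.R ir_states.R
NULL

#' Declare one synthetic driver layer
#'
#' Continuous layers are smooth low-frequency random surfaces (a seeded
#' sum of plane-wave cosines) scaled into `[min, max]`, optionally with
#' a seasonal sinusoid and cell-level noise, then clipped back to the
#' declared range. `zeroInflation` pushes the lowest fraction of the
#' surface to exactly 0 — crop-fraction layers are zero outside farmed
#' areas, which is what makes threshold rules like "irrigated rice
#' present" spatially selective. Categorical layers are contiguous
#' patches obtained by quantile-binning a smooth surface into `nCodes`
#' integer codes.
#'
#' @param name layer name.
#' @param kind `"continuous"` or `"categorical"`.
#' @param min,max declared range (continuous).
#' @param seasonalAmp amplitude of the 12-month sinusoid, in the layer's
#'   units.
#' @param noiseSd standard deviation of i.i.d. cell-month noise.
#' @param zeroInflation fraction of area clamped to exactly 0.
#' @param static logical; a static layer has no seasonal or noise term.
#' @param nCodes number of categorical codes.
#' @return a driver-spec list for [syntheticScenario()].
#' @export
driverSpec <- function(name, kind = c("continuous", "categorical"),
                       min = 0, max = 1, seasonalAmp = 0, noiseSd = 0,
                       zeroInflation = 0, static = FALSE, nCodes = 5L) {
  kind <- match.arg(kind)
  if (kind == "continuous" && min >= max)
    stop("invalid range for '", name, "': min must be < max")
  if (zeroInflation < 0 || zeroInflation >= 1)
    stop("zeroInflation must lie in [0, 1)")
  list(name = name, kind = kind, min = min, max = max,
       seasonalAmp = seasonalAmp, noiseSd = noiseSd,
       zeroInflation = zeroInflation, static = static,
       nCodes = as.integer(nCodes))
}

#' Default synthetic driver catalogue
#'
#' Emulates the driver families used for resistance modelling —
#' climatic surfaces (temperature, precipitation, relative humidity,
#' NDVI), intervention coverage (ITN/IRS), crop fractions (irrigated
#' rice, vegetables, overall crop farming), population density, static
#' elevation and a categorical land-use/land-cover layer — with ranges
#' a field scientist would call realistic for sub-Saharan study areas.
#' Temperature deliberately spans 12-42 degC so the 15-38 degC rule band
#' actually binds.
#'
#' @return named list of driver specs.
#' @export
defaultDriverSpecs <- function() {
  specs <- list(
    driverSpec("temperature", min = 12, max = 42, seasonalAmp = 4,
               noiseSd = 0.5),
    driverSpec("precipitation", min = 0, max = 300, seasonalAmp = 60,
               noiseSd = 5),
    driverSpec("humidity", min = 20, max = 95, seasonalAmp = 10,
               noiseSd = 1),
    driverSpec("itn_irs_coverage", min = 0, max = 1, noiseSd = 0.01),
    driverSpec("irrigated_rice", min = 0, max = 1, zeroInflation = 0.7,
               static = TRUE),
    driverSpec("vegetables", min = 0, max = 1, zeroInflation = 0.5,
               static = TRUE),
    driverSpec("crop_farming", min = 0, max = 1, zeroInflation = 0.3,
               static = TRUE),
    driverSpec("population_density", min = 0, max = 1000, noiseSd = 5),
    driverSpec("ndvi", min = 0, max = 0.9, seasonalAmp = 0.1,
               noiseSd = 0.01),
    driverSpec("elevation", min = 0, max = 2500, static = TRUE),
    driverSpec("lulc", kind = "categorical", nCodes = 5L))
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Define a synthetic study scenario
#'
#' Bundles everything needed to generate a reproducible gridded study: a
#' lattice, a monthly axis, a planted ground-truth rule set, driver
#' specifications, sampling effort and label noise. Defaults describe
#' the reference scenario used throughout the package's tests: a 30 x 30
#' lattice of 5-km cells, 60 monthly steps from January 2000, the three
#' built-in rules planted as truth, a single central seed cell, and 50
#' bioassay records per year.
#'
#' @param seed integer master seed; every random quantity derives from
#'   it.
#' @param grid a [GridSpec-class].
#' @param axis a [TimeAxis-class].
#' @param plantedRuleset the ground-truth [RuleSet-class].
#' @param driverSpecs named list from [driverSpec()].
#' @param nRecordsPerYear bioassay records sampled each year.
#' @param labelNoise probability in [0, 0.5) that a record's mortality
#'   band is swapped.
#' @param seedCells 2-column matrix (i, j) of initially confirmed cells.
#' @param species,insecticideClass labels stamped on generated records.
#' @return a `SyntheticScenario` (list).
#' @export
syntheticScenario <- function(seed = 1L,
                              grid = buildGrid(0, 0, 150, 150, 5),
                              axis = TimeAxis(2000, 1, 60),
                              plantedRuleset = builtinRuleSet(),
                              driverSpecs = defaultDriverSpecs(),
                              nRecordsPerYear = 50L,
                              labelNoise = 0,
                              seedCells = NULL,
                              species = "gambiae_complex",
                              insecticideClass = "pyrethroid") {
  stopifnot(is(grid, "GridSpec"), is(axis, "TimeAxis"),
            is(plantedRuleset, "RuleSet"))
  if (labelNoise < 0 || labelNoise >= 0.5)
    stop("labelNoise must lie in [0, 0.5)")
  if (nRecordsPerYear > grid@nRows * grid@nCols)
    stop("nRecordsPerYear exceeds the cell count")
  if (is.null(seedCells))
    seedCells <- cbind(i = (grid@nRows + 1L) %/% 2L,
                       j = (grid@nCols + 1L) %/% 2L)
  structure(list(seed = as.integer(seed), grid = grid, axis = axis,
                 plantedRuleset = plantedRuleset,
                 driverSpecs = driverSpecs,
                 nRecordsPerYear = as.integer(nRecordsPerYear),
                 labelNoise = labelNoise, seedCells = seedCells,
                 species = species, insecticideClass = insecticideClass),
            class = "SyntheticScenario")
}

## Smooth [0,1] surface: sum of K random plane-wave cosines over the
## lattice, min-max normalized. Degenerate (constant) draws normalize to
## 0.5.
.smoothSurface <- function(nr, nc, nWaves = 4) {
  x <- matrix(rep(seq_len(nc), each = nr), nr, nc) / nc
  y <- matrix(rep(seq_len(nr), nc), nr, nc) / nr
  f <- matrix(0, nr, nc)
  for (k in seq_len(nWaves)) {
    u <- stats::runif(1, 0.5, 2.5); v <- stats::runif(1, 0.5, 2.5)
    su <- sample(c(-1, 1), 2, replace = TRUE)
    amp <- stats::runif(1, 0.5, 1); phase <- stats::runif(1, 0, 2 * pi)
    f <- f + amp * cos(2 * pi * (su[1] * u * x + su[2] * v * y) + phase)
  }
  rng <- range(f)
  if (rng[2] - rng[1] < .Machine$double.eps) return(f * 0 + 0.5)
  (f - rng[1]) / (rng[2] - rng[1])
}

#' Generate the gridded driver stack of a scenario
#'
#' Fully reproducible from the scenario seed: each layer draws from its
#' own deterministic position in the random stream. Continuous values
#' are clipped to their declared range after adding seasonal and noise
#' terms.
#'
#' @param scenario a [syntheticScenario()].
#' @return a [DriverStack-class].
#' @export
generateDrivers <- function(scenario) {
  stopifnot(inherits(scenario, "SyntheticScenario"))
  g <- scenario$grid; ax <- scenario$axis
  nr <- g@nRows; nc <- g@nCols; ns <- ax@nSteps
  months <- .axisMonths(ax)$month
  layers <- list(); kinds <- character(); legends <- list()
  set.seed(scenario$seed)
  for (spec in scenario$driverSpecs) {
    base <- .smoothSurface(nr, nc)
    if (spec$kind == "categorical") {
      codes <- matrix(cut(base, breaks = stats::quantile(
        base, probs = seq(0, 1, length.out = spec$nCodes + 1)),
        include.lowest = TRUE, labels = FALSE), nr, nc)
      a <- array(rep(as.numeric(codes), ns), c(nr, nc, ns))
      legends[[spec$name]] <- seq_len(spec$nCodes)
    } else {
      if (spec$zeroInflation > 0) {
        cutq <- stats::quantile(base, spec$zeroInflation)
        base <- pmax(0, base - cutq) / (1 - cutq)
      }
      surf <- spec$min + base * (spec$max - spec$min)
      phase <- stats::runif(1, 0, 2 * pi)
      a <- array(0, c(nr, nc, ns))
      for (k in seq_len(ns)) {
        slice <- surf
        if (!spec$static) {
          if (spec$seasonalAmp > 0)
            slice <- slice + spec$seasonalAmp *
              sin(2 * pi * (months[k] - 1) / 12 + phase)
          if (spec$noiseSd > 0)
            slice <- slice + stats::rnorm(nr * nc, 0, spec$noiseSd)
        }
        a[, , k] <- pmin(spec$max, pmax(spec$min, slice))
      }
    }
    layers[[spec$name]] <- a
    kinds[spec$name] <- spec$kind
  }
  new("DriverStack", grid = g, axis = ax, layers = layers, kinds = kinds,
      legends = legends)
}

#' Generate the ground-truth state sequence of a scenario
#'
#' Runs the automaton itself under the planted rule set from the
#' scenario's seed cells, so the truth is by construction a trajectory
#' of the model class.
#'
#' @param drivers a [DriverStack-class] (from [generateDrivers()]).
#' @param plantedRuleset the ground-truth [RuleSet-class].
#' @param seedCells 2-column matrix (i, j) of initially confirmed cells.
#' @param radius Moore-neighbourhood radius.
#' @return a [StateSequence-class].
#' @export
generateTruth <- function(drivers, plantedRuleset, seedCells, radius = 1) {
  stopifnot(is(drivers, "DriverStack"), is(plantedRuleset, "RuleSet"))
  g <- drivers@grid
  v <- matrix(0, g@nRows, g@nCols)
  v[as.matrix(seedCells)] <- 1
  seed <- new("StateGrid", grid = g, step = 1L, values = v)
  caRun(seed, drivers, plantedRuleset, radius)
}

#' Sample georeferenced bioassay records from a truth sequence
#'
#' For each calendar year on the axis, samples `nRecordsPerYear` cells
#' uniformly without replacement and emits one record per cell: cells
#' whose ANNUAL truth (confirmed in >= 1 month of the year) is 1 draw
#' mortality uniformly from [40, 89.9], others from [90, 100], so the
#' WHO classifier recovers the truth exactly; with probability
#' `labelNoise` the bands are swapped. Record coordinates are jittered
#' uniformly inside the cell and dated to a random month of the year.
#'
#' @param truth a [StateSequence-class] aligned to the scenario.
#' @param scenario the [syntheticScenario()].
#' @return records data.frame in the [readRecords()] schema.
#' @export
sampleRecords <- function(truth, scenario) {
  stopifnot(is(truth, "StateSequence"),
            inherits(scenario, "SyntheticScenario"))
  g <- scenario$grid
  if (!identical(dim(truth@values)[1:2], c(g@nRows, g@nCols)))
    stop("truth is not aligned to the scenario grid")
  nCells <- g@nRows * g@nCols
  if (scenario$nRecordsPerYear > nCells)
    stop("nRecordsPerYear exceeds the cell count")
  m <- .axisMonths(scenario$axis)
  set.seed(scenario$seed + 1L)
  out <- list()
  for (y in unique(m$year)) {
    steps <- m$step[m$year == y]
    annual <- apply(truth@values[, , steps, drop = FALSE], c(1, 2),
                    max) > 0
    cells <- sample.int(nCells, scenario$nRecordsPerYear)
    i <- (cells - 1L) %% g@nRows + 1L
    j <- (cells - 1L) %/% g@nRows + 1L
    confirmed <- annual[cbind(i, j)]
    flip <- stats::runif(length(cells)) < scenario$labelNoise
    band <- xor(confirmed, flip)
    mort <- ifelse(band, stats::runif(length(cells), 40, 89.9),
                   stats::runif(length(cells), 90, 100))
    s <- g@cellSize
    out[[length(out) + 1L]] <- data.frame(
      x = g@originX + (j - 1) * s + stats::runif(length(cells), 0, s),
      y = g@originY + (i - 1) * s + stats::runif(length(cells), 0, s),
      year = y,
      month = sample(m$month[m$year == y], length(cells), replace = TRUE),
      species = scenario$species,
      insecticide_class = scenario$insecticideClass,
      mortality_pct = mort,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run a full synthetic study
#'
#' Convenience wrapper: generates drivers, the planted truth, and the
#' sampled records of a scenario in one call.
#'
#' @param scenario a [syntheticScenario()].
#' @return list with `drivers`, `truth`, `records` and the `scenario`.
#' @export
runScenario <- function(scenario) {
  drivers <- generateDrivers(scenario)
  truth <- suppressWarnings(
    generateTruth(drivers, scenario$plantedRuleset, scenario$seedCells))
  records <- sampleRecords(truth, scenario)
  list(drivers = drivers, truth = truth, records = records,
       scenario = scenario)
}
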