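#' @include AllClasses.R
NULL

.IR_CLASSES <- c("pyrethroid", "organochlorine", "carbamate",
                 "organophosphate")

## "2003-07" or "2003-07-15" -> c(year, month); NA NA when unparseable
.parseYearMonth <- function(date) {
  m <- regmatches(date, regexec("^\\s*(\\d{4})-(\\d{1,2})(-\\d{1,2})?\\s*$",
                                as.character(date)))
  t(vapply(m, function(g) {
    if (length(g) < 3L) return(c(NA_integer_, NA_integer_))
    mo <- as.integer(g[3])
    if (is.na(mo) || mo < 1L || mo > 12L) return(c(NA_integer_, NA_integer_))
    c(as.integer(g[2]), mo)
  }, integer(2)))
}

#' Read georeferenced susceptibility-test records
#'
#' Reads a CSV of bioassay records with (at least) the columns `x`, `y`,
#' `date`, `species`, `insecticide_class`, `mortality_pct`. Rows without
#' usable coordinates are dropped (non-georeferenced records are excluded
#' from all downstream analysis) and counted in the `"n_dropped_coords"`
#' attribute; rows with an unparseable date, an unknown insecticide class
#' or mortality outside [0, 100] are rejected with a warning and counted
#' in `"n_rejected"`. Dates are normalized to year-month resolution.
#'
#' @param path CSV file path.
#' @return data.frame with columns `x`, `y`, `year`, `month`, `species`,
#'   `insecticide_class`, `mortality_pct`, plus the count attributes.
#' @export
readRecords <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "date", "species", "insecticide_class",
            "mortality_pct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  df$x <- suppressWarnings(as.numeric(df$x))
  df$y <- suppressWarnings(as.numeric(df$y))
  geo <- is.finite(df$x) & is.finite(df$y)
  nDropped <- sum(!geo)
  df <- df[geo, , drop = FALSE]
  ym <- .parseYearMonth(df$date)
  df$mortality_pct <- suppressWarnings(as.numeric(df$mortality_pct))
  ok <- !is.na(ym[, 1]) &
    df$insecticide_class %in% .IR_CLASSES &
    is.finite(df$mortality_pct) &
    df$mortality_pct >= 0 & df$mortality_pct <= 100
  nRejected <- sum(!ok)
  if (nRejected)
    warning(nRejected,
            " record(s) rejected (bad date, class or mortality)")
  out <- data.frame(x = df$x[ok], y = df$y[ok],
                    year = ym[ok, 1], month = ym[ok, 2],
                    species = df$species[ok],
                    insecticide_class = df$insecticide_class[ok],
                    mortality_pct = df$mortality_pct[ok],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_dropped_coords") <- nDropped
  attr(out, "n_rejected") <- nRejected
  out
}

#' Write susceptibility records to CSV
#'
#' Inverse of [readRecords()]; the `date` column is written as
#' `YYYY-MM`.
#'
#' @param records data.frame in the [readRecords()] schema.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeRecords <- function(records, path) {
  out <- data.frame(x = records$x, y = records$y,
                    date = sprintf("%04d-%02d", records$year,
                                   records$month),
                    species = records$species,
                    insecticide_class = records$insecticide_class,
                    mortality_pct = records$mortality_pct)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read one gridded driver layer from CSV
#'
#' Reads a long-format gridded table with columns `i`, `j`, `t`, `value`
#' and aligns it to the model grid and monthly axis. With
#' `temporal = "monthly"`, `t` is the 1-based step index and every step
#' must be present. With `temporal = "yearly"`, `t` is a calendar year;
#' continuous layers are linearly interpolated between January anchors
#' ([interpolateToMonthly()]) while categorical layers take the nearest
#' anchor's codes ([stepToMonthly()]) — codes are never interpolated.
#'
#' @param path CSV path.
#' @param grid a [GridSpec-class]; the table must cover every cell.
#' @param axis a [TimeAxis-class].
#' @param name layer name.
#' @param kind `"continuous"` or `"categorical"`.
#' @param temporal `"monthly"` or `"yearly"`.
#' @return a [DriverStack-class] holding the single layer (combine with
#'   [c()]-like [stackDrivers()]).
#' @export
readDriverLayer <- function(path, grid, axis, name,
                            kind = c("continuous", "categorical"),
                            temporal = c("monthly", "yearly")) {
  kind <- match.arg(kind); temporal <- match.arg(temporal)
  stopifnot(is(grid, "GridSpec"), is(axis, "TimeAxis"))
  df <- utils::read.csv(path)
  need <- c("i", "j", "t", "value")
  if (!all(need %in% names(df)))
    stop("gridded CSV needs columns i, j, t, value")
  if (any(df$i < 1 | df$i > grid@nRows | df$j < 1 | df$j > grid@nCols))
    stop("cell indices do not match the grid (shape mismatch)")
  nr <- grid@nRows; nc <- grid@nCols; ns <- axis@nSteps
  ts <- sort(unique(df$t))
  perT <- nr * nc
  if (nrow(df) != perT * length(ts) ||
      anyDuplicated(df[c("i", "j", "t")]))
    stop("layer must cover every cell exactly once per time slice")
  slices <- array(NA_real_, c(nr, nc, length(ts)))
  for (k in seq_along(ts)) {
    sl <- df[df$t == ts[k], , drop = FALSE]
    m <- matrix(NA_real_, nr, nc)
    m[cbind(sl$i, sl$j)] <- sl$value
    slices[, , k] <- m
  }
  if (temporal == "monthly") {
    if (!identical(as.integer(ts), seq_len(ns)))
      stop("monthly layer must provide t = 1..nSteps")
    vals <- slices
  } else {
    vals <- array(NA_real_, c(nr, nc, ns))
    interp <- if (kind == "continuous") interpolateToMonthly else stepToMonthly
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      y <- slices[i, j, ]
      names(y) <- ts
      vals[i, j, ] <- interp(y, axis)
    }
  }
  legends <- if (kind == "categorical")
    stats::setNames(list(sort(unique(as.vector(vals)))), name) else list()
  kinds <- stats::setNames(kind, name)
  new("DriverStack", grid = grid, axis = axis,
      layers = stats::setNames(list(vals), name), kinds = kinds,
      legends = legends)
}

#' Write one driver layer as long-format gridded CSV
#'
#' @param drivers a [DriverStack-class].
#' @param name layer to write.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeDriverLayer <- function(drivers, name, path) {
  stopifnot(is(drivers, "DriverStack"), name %in% names(drivers@layers))
  a <- drivers@layers[[name]]
  d <- dim(a)
  idx <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), t = seq_len(d[3]))
  utils::write.csv(data.frame(idx, value = as.vector(a)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Combine driver stacks on the same grid and axis
#'
#' @param ... [DriverStack-class] objects with disjoint layer names.
#' @return a single [DriverStack-class].
#' @export
stackDrivers <- function(...) {
  stacks <- list(...)
  stopifnot(length(stacks) >= 1L,
            all(vapply(stacks, is, TRUE, "DriverStack")))
  g <- stacks[[1]]@grid; ax <- stacks[[1]]@axis
  layers <- list(); kinds <- character(); legends <- list()
  for (s in stacks) {
    layers <- c(layers, s@layers)
    kinds <- c(kinds, s@kinds)
    legends <- c(legends, s@legends)
  }
  new("DriverStack", grid = g, axis = ax, layers = layers, kinds = kinds,
      legends = legends)
}

#' Write a state sequence as a multi-frame TIFF raster
#'
#' One frame per monthly step, values in {0, 1}; the binary lattice
#' round-trips exactly through [readStateRaster()]. Grid geometry and the
#' time axis are not embedded in the file and must travel in the run
#' configuration.
#'
#' @param states a [StateSequence-class].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
writeStateRaster <- function(states, path) {
  stopifnot(is(states, "StateSequence"))
  frames <- lapply(seq_len(states@axis@nSteps),
                   function(k) states@values[, , k, drop = TRUE])
  tiff::writeTIFF(frames, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a state sequence back from a multi-frame TIFF
#'
#' @param path `.tif` path written by [writeStateRaster()].
#' @param grid the [GridSpec-class] the states live on.
#' @param axis the [TimeAxis-class]; frame count must equal `nSteps`.
#' @return a [StateSequence-class].
#' @export
readStateRaster <- function(path, grid, axis) {
  stopifnot(is(grid, "GridSpec"), is(axis, "TimeAxis"))
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  if (length(frames) != axis@nSteps)
    stop("frame count does not match the time axis")
  a <- array(0, c(grid@nRows, grid@nCols, axis@nSteps))
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (!identical(dim(f), c(grid@nRows, grid@nCols)))
      stop("frame dimensions do not match the grid")
    a[, , k] <- round(f)
  }
  new("StateSequence", grid = grid, axis = axis, values = a)
}

#' Write a run configuration (grid, axis, labels) as JSON
#'
#' The configuration travels alongside raster files, which carry neither
#' grid geometry nor the time axis.
#'
#' @param grid a [GridSpec-class].
#' @param axis a [TimeAxis-class].
#' @param species,insecticideClass labels of the model run.
#' @param radius Moore-neighbourhood radius.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeRunConfig <- function(grid, axis, species, insecticideClass, path,
                           radius = 1) {
  stopifnot(is(grid, "GridSpec"), is(axis, "TimeAxis"))
  doc <- list(
    grid = list(origin_x = grid@originX, origin_y = grid@originY,
                cell_size = grid@cellSize, n_rows = grid@nRows,
                n_cols = grid@nCols),
    axis = list(start_year = axis@startYear,
                start_month = axis@startMonth, n_steps = axis@nSteps),
    species = species, insecticide_class = insecticideClass,
    radius = radius)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run configuration
#'
#' @param path JSON path written by [writeRunConfig()].
#' @return list with `grid` ([GridSpec-class]), `axis`
#'   ([TimeAxis-class]), `species`, `insecticideClass`, `radius`.
#' @export
readRunConfig <- function(path) {
  doc <- jsonlite::read_json(path)
  g <- doc$grid
  grid <- new("GridSpec", originX = as.numeric(g$origin_x),
              originY = as.numeric(g$origin_y),
              cellSize = as.numeric(g$cell_size),
              nRows = as.integer(g$n_rows), nCols = as.integer(g$n_cols))
  axis <- TimeAxis(doc$axis$start_year, doc$axis$start_month,
                   doc$axis$n_steps)
  list(grid = grid, axis = axis, species = doc$species,
       insecticideClass = doc$insecticide_class,
       radius = doc$radius %||% 1)
}

.ruleToList <- function(rule) {
  list(name = rule$name, species = rule$species,
       insecticide_class = rule$insecticide_class,
       conditions = lapply(rule$conditions, function(cond)
         list(driver = cond$driver, op = cond$op,
              bounds = as.numeric(cond$bounds))))
}

.ruleFromList <- function(x) {
  conds <- lapply(x$conditions, function(cond)
    irCondition(cond$driver, cond$op, unlist(cond$bounds)))
  irRule(x$name %||% "", conds, x$species %||% "any",
         x$insecticide_class %||% "any")
}

#' Serialize a rule set to JSON
#'
#' The document holds `diffusion_rules` and `emergence_rules` arrays of
#' `{name, species, insecticide_class, conditions:[{driver, op, bounds}]}`
#' objects and round-trips bit-exactly through [readRuleSet()].
#'
#' @param ruleset a [RuleSet-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeRuleSet <- function(ruleset, path) {
  stopifnot(is(ruleset, "RuleSet"))
  doc <- list(diffusion_rules = lapply(ruleset@diffusionRules, .ruleToList),
              emergence_rules = lapply(ruleset@emergenceRules, .ruleToList))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a rule set from JSON
#'
#' @param path JSON path in the [writeRuleSet()] schema.
#' @param drivers optional character vector of known driver names; when
#'   given, a rule referencing an unknown driver is a schema error.
#' @return a [RuleSet-class].
#' @export
readRuleSet <- function(path, drivers = NULL) {
  doc <- jsonlite::read_json(path)
  parse <- function(rules, channel) lapply(rules, function(x) {
    r <- tryCatch(.ruleFromList(x), error = function(e)
      stop(sprintf("%s rule '%s': %s", channel, x$name %||% "?",
                   conditionMessage(e)), call. = FALSE))
    if (!is.null(drivers))
      for (cond in r$conditions)
        if (!cond$driver %in% drivers)
          stop(sprintf("%s rule '%s': unknown driver '%s'", channel,
                       r$name, cond$driver), call. = FALSE)
    r
  })
  RuleSet(diffusionRules = parse(doc$diffusion_rules, "diffusion"),
          emergenceRules = parse(doc$emergence_rules, "emergence"))
}
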