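#' @include AllClasses.R ca_engine.R
NULL

#' Collapse monthly states to an annual prediction
#'
#' A cell is predicted confirmed for a calendar year iff its automaton
#' state is 1 in at least one month of that year — the bridge from the
#' model's monthly clock to annually reported surveillance records.
#'
#' @param states a [StateSequence-class].
#' @param year calendar year; must intersect the sequence's axis.
#' @return logical `nRows x nCols` matrix.
#' @export
annualPrediction <- function(states, year) {
  stopifnot(is(states, "StateSequence"))
  m <- .axisMonths(states@axis)
  steps <- m$step[m$year == year]
  if (!length(steps))
    stop("year ", year, " has no months on the state sequence's axis")
  apply(states@values[, , steps, drop = FALSE], c(1, 2), max) > 0
}

#' Confusion counts at observed cells
#'
#' Compares an annual prediction with the observed grid over the covered
#' cells only — cells with no susceptibility record that year are never
#' evaluated, mirroring record-located surveillance comparison.
#'
#' @param observed an [ObservedGrid-class].
#' @param predicted logical/0-1 `nRows x nCols` matrix (e.g. from
#'   [annualPrediction()]).
#' @return list with counts `tp`, `tn`, `fp`, `fn` and `n` (their sum).
#' @export
confusionCounts <- function(observed, predicted) {
  stopifnot(is(observed, "ObservedGrid"))
  g <- observed@grid
  if (!identical(dim(predicted), c(g@nRows, g@nCols)))
    stop("prediction dimensions do not match the observed grid")
  st <- observed@status
  pred <- as.logical(predicted[cbind(st$i, st$j)])
  obs <- st$confirmed
  list(tp = sum(obs & pred), tn = sum(!obs & !pred),
       fp = sum(!obs & pred), fn = sum(obs & !pred), n = nrow(st))
}

#' Classification accuracy score
#'
#' `(Tp + Tn) / (Tp + Tn + Fp + Fn)`. Undefined (NA) when no cell was
#' evaluated; such years are excluded from annual means.
#'
#' @param counts list with `tp`, `tn`, `fp`, `fn` (from
#'   [confusionCounts()]).
#' @return accuracy in [0, 1], or `NA` for an empty evaluation.
#' @examples
#' accuracyScore(list(tp = 5, tn = 3, fp = 1, fn = 1))  # 0.8
#' @export
accuracyScore <- function(counts) {
  tot <- counts$tp + counts$tn + counts$fp + counts$fn
  if (tot == 0) return(NA_real_)
  (counts$tp + counts$tn) / tot
}

#' Validate a state sequence against observed grids
#'
#' Computes per-year confusion counts and accuracy of the model's annual
#' predictions at observed cells, and their mean over years with at
#' least one evaluated cell (years without records are reported `NA`
#' and excluded from the mean).
#'
#' @param states a [StateSequence-class].
#' @param observed list of [ObservedGrid-class] objects, one per year
#'   (years absent from the list are skipped).
#' @return an [AccuracyReport-class].
#' @export
validateStates <- function(states, observed) {
  stopifnot(is(states, "StateSequence"), length(observed) >= 1L,
            all(vapply(observed, is, TRUE, "ObservedGrid")))
  yrs <- sort(vapply(observed, function(o) o@year, 0L))
  byYear <- stats::setNames(observed,
                            vapply(observed, function(o) o@year, 0L))
  rows <- lapply(yrs, function(y) {
    o <- byYear[[as.character(y)]]
    cc <- confusionCounts(o, annualPrediction(states, y))
    data.frame(year = y, tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn,
               n = cc$n, accuracy = accuracyScore(cc))
  })
  perYear <- do.call(rbind, rows)
  acc <- perYear$accuracy[!is.na(perYear$accuracy)]
  new("AccuracyReport",
      species = observed[[1]]@species,
      insecticideClass = observed[[1]]@insecticideClass,
      perYear = perYear,
      meanAccuracy = if (length(acc)) mean(acc) else NA_real_)
}

#' Write an accuracy report as JSON and per-year CSV
#'
#' The CSV has one row per year with blank accuracy for years without
#' evaluated cells.
#'
#' @param report an [AccuracyReport-class].
#' @param jsonPath output JSON path.
#' @param csvPath optional per-year CSV path.
#' @return `jsonPath`, invisibly.
#' @export
writeAccuracyReport <- function(report, jsonPath, csvPath = NULL) {
  stopifnot(is(report, "AccuracyReport"))
  doc <- list(species = report@species,
              insecticide_class = report@insecticideClass,
              per_year = report@perYear,
              mean_accuracy = report@meanAccuracy)
  jsonlite::write_json(doc, jsonPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  if (!is.null(csvPath)) utils::write.csv(report@perYear, csvPath,
                                          row.names = FALSE, na = "")
  invisible(jsonPath)
}

## Apply one threshold replacement to every same-named rule in both
## channels. part: "lower"/"upper" for intervals, "value" for scalar ops.
.setRuleBound <- function(ruleset, ruleName, condition, part, value) {
  touch <- function(rules) lapply(rules, function(r) {
    if (r$name != ruleName) return(r)
    cond <- r$conditions[[condition]]
    if (cond$op == "in_interval") {
      if (part == "lower") cond$bounds[1] <- value
      else if (part == "upper") cond$bounds[2] <- value
      else stop("part must be 'lower' or 'upper' for an interval")
      if (cond$bounds[1] > cond$bounds[2])
        stop("candidate makes interval lower > upper")
    } else {
      cond$bounds <- value
    }
    r$conditions[[condition]] <- cond
    r
  })
  RuleSet(diffusionRules = touch(ruleset@diffusionRules),
          emergenceRules = touch(ruleset@emergenceRules))
}

#' Calibrate rule thresholds against training observations
#'
#' The fine-tuning loop: an exhaustive grid search over declared
#' candidate values for selected rule thresholds, scoring each candidate
#' rule set by the mean annual accuracy of a fresh automaton run against
#' the training observations, and keeping the best (ties go to the
#' first-encountered maximum in declared iteration order, varying the
#' first target fastest). The returned score always equals
#' [validateStates()] re-run with the returned rule set.
#'
#' @param ruleset starting [RuleSet-class].
#' @param targets named list of targets; each target is a list with
#'   `rule` (rule name), `condition` (1-based condition index), `part`
#'   (`"lower"`/`"upper"` for intervals, `"value"` otherwise) and
#'   `values` (candidate numeric vector in search order). Edits apply to
#'   every same-named rule in both channels.
#' @param seed a [StateGrid-class] starting state for each scoring run.
#' @param drivers a [DriverStack-class].
#' @param observed list of [ObservedGrid-class] training years.
#' @param radius Moore-neighbourhood radius.
#' @return list with `ruleset` (best), `score` (its mean annual
#'   accuracy) and `trace` (data.frame of every combination scored, in
#'   iteration order).
#' @export
calibrateRules <- function(ruleset, targets, seed, drivers, observed,
                           radius = 1) {
  stopifnot(is(ruleset, "RuleSet"), length(targets) >= 1L,
            length(observed) >= 1L)
  for (tg in targets)
    if (!length(tg$values)) stop("empty candidate grid for a target")
  combos <- expand.grid(lapply(targets, `[[`, "values"),
                        KEEP.OUT.ATTRS = FALSE)
  names(combos) <- names(targets)
  scores <- numeric(nrow(combos))
  best <- NULL; bestScore <- -Inf; bestRow <- NA_integer_
  for (row in seq_len(nrow(combos))) {
    rs <- ruleset
    for (t in seq_along(targets)) {
      tg <- targets[[t]]
      rs <- .setRuleBound(rs, tg$rule, tg$condition, tg$part,
                          combos[row, t])
    }
    rep <- validateStates(
      suppressWarnings(caRun(seed, drivers, rs, radius)), observed)
    scores[row] <- rep@meanAccuracy
    if (!is.na(scores[row]) && scores[row] > bestScore) {
      bestScore <- scores[row]; best <- rs; bestRow <- row
    }
  }
  trace <- cbind(combos, score = scores)
  list(ruleset = best, score = bestScore, trace = trace,
       bestIndex = bestRow)
}
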