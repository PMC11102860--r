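mkObserved <- function(grid, year, i, j, confirmed,
                       species = "gambiae_complex",
                       class = "pyrethroid") {
  new("ObservedGrid", grid = grid, year = as.integer(year),
      species = species, insecticideClass = class,
      status = data.frame(i = as.integer(i), j = as.integer(j),
                          confirmed = confirmed))
}

mkStates <- function(grid, axis, fill = 0) {
  new("StateSequence", grid = grid, axis = axis,
      values = array(fill, c(grid@nRows, grid@nCols, axis@nSteps)))
}

test_that("a single confirmed month makes the year predicted confirmed", {
  g <- tinyGrid(3)
  ax <- TimeAxis(2000, 1, 24)
  st <- mkStates(g, ax)
  st@values[2, 2, 3] <- 1                      # March 2000 only
  st@values[, , 24] <- 1                       # December 2001, all cells
  p2000 <- annualPrediction(st, 2000)
  expect_true(p2000[2, 2])
  expect_equal(sum(p2000), 1)
  expect_true(all(annualPrediction(st, 2001)))
  expect_error(annualPrediction(st, 1999), "no months")
})

test_that("confusion counts evaluate covered cells only", {
  g <- buildGrid(0, 0, 50, 50, 5)
  obs <- mkObserved(g, 2000, c(1, 2), c(1, 2), c(TRUE, FALSE))
  pred <- matrix(FALSE, 10, 10)
  cc <- confusionCounts(obs, pred)
  expect_equal(cc$n, 2L)                       # 98 uncovered cells ignored
  expect_equal(cc$fn, 1L)                      # present predicted absent
  expect_equal(cc$tn, 1L)
  pred[1, 1] <- TRUE
  cc2 <- confusionCounts(obs, pred)
  expect_equal(c(cc2$tp, cc2$tn, cc2$fp, cc2$fn), c(1L, 1L, 0L, 0L))
  expect_error(confusionCounts(obs, matrix(FALSE, 3, 3)), "dimensions")
})

test_that("accuracy arithmetic follows (Tp+Tn)/(Tp+Tn+Fp+Fn)", {
  expect_equal(accuracyScore(list(tp = 3, tn = 2, fp = 0, fn = 0)), 1.0)
  expect_equal(accuracyScore(list(tp = 0, tn = 0, fp = 2, fn = 3)), 0.0)
  expect_equal(accuracyScore(list(tp = 5, tn = 3, fp = 1, fn = 1)), 0.8)
  expect_true(is.na(accuracyScore(list(tp = 0, tn = 0, fp = 0, fn = 0))))
  # accuracy is 1 iff no false calls; swapping (Tp,Tn) and (Fp,Fn)
  # simultaneously leaves it unchanged
  set.seed(71)
  for (k in 1:20) {
    c4 <- as.list(stats::setNames(rpois(4, 4), c("tp", "tn", "fp", "fn")))
    a <- accuracyScore(c4)
    if (is.na(a)) next
    expect_true(a >= 0 && a <= 1)
    expect_equal(a == 1, c4$fp == 0 && c4$fn == 0)
    swapped <- list(tp = c4$tn, tn = c4$tp, fp = c4$fn, fn = c4$fp)
    expect_equal(accuracyScore(swapped), a)
  }
})

test_that("years without covered cells are excluded from the mean", {
  g <- tinyGrid(3)
  ax <- TimeAxis(2000, 1, 36)
  st <- mkStates(g, ax)
  st@values[1, 1, ] <- 1
  obs <- list(
    mkObserved(g, 2000, c(1, 2), c(1, 1), c(TRUE, FALSE)),   # both right
    mkObserved(g, 2001, c(1, 3), c(1, 3), c(TRUE, TRUE)),    # one wrong
    mkObserved(g, 2002, integer(), integer(), logical()))    # no coverage
  rep <- validateStates(st, obs)
  py <- perYear(rep)
  expect_equal(py$accuracy[py$year == 2000], 1.0)
  expect_equal(py$accuracy[py$year == 2001], 0.5)
  expect_true(is.na(py$accuracy[py$year == 2002]))
  expect_equal(meanAccuracy(rep), 0.75)        # 2002 excluded
})

test_that("accuracy reports serialize to JSON and per-year CSV", {
  g <- tinyGrid(3)
  ax <- TimeAxis(2000, 1, 24)
  st <- mkStates(g, ax, fill = 1)
  obs <- list(mkObserved(g, 2000, 1, 1, TRUE),
              mkObserved(g, 2001, integer(), integer(), logical()))
  rep <- validateStates(st, obs)
  fj <- withr::local_tempfile(fileext = ".json")
  fc <- withr::local_tempfile(fileext = ".csv")
  writeAccuracyReport(rep, fj, fc)
  doc <- jsonlite::read_json(fj)
  expect_equal(doc$mean_accuracy, 1.0)
  csv <- readLines(fc)
  expect_equal(length(csv), 3L)                 # header + 2 years
  expect_match(csv[3], ",$")                    # blank accuracy for 2001
})

test_that("calibration recovers a planted temperature bound", {
  sc <- syntheticScenario(seed = 13, grid = buildGrid(0, 0, 75, 75, 5),
                          axis = TimeAxis(2000, 1, 36),
                          nRecordsPerYear = 40L)
  res <- runScenario(sc)
  obs <- lapply(sort(unique(res$records$year)), function(y)
    rasterizeRecords(res$records, sc$grid, y, sc$species,
                     sc$insecticideClass))
  seed <- res$truth[[1]]
  # plant the search on the temperature band of both temperature rules
  targets <- list(
    t2 = list(rule = "rice_vegetables_temperature", condition = 3,
              part = "upper", values = c(30, 34, 38, 42)),
    t3 = list(rule = "coverage_vegetables_temperature", condition = 3,
              part = "upper", values = c(30, 34, 38, 42)))
  cal <- calibrateRules(sc$plantedRuleset, targets, seed, res$drivers,
                        obs)
  planted <- validateStates(
    suppressWarnings(caRun(seed, res$drivers, sc$plantedRuleset)), obs)
  expect_gte(cal$score, meanAccuracy(planted))
  # self-consistency: the returned score is the returned rule set's score
  recheck <- validateStates(
    suppressWarnings(caRun(seed, res$drivers, cal$ruleset)), obs)
  expect_equal(cal$score, meanAccuracy(recheck))
  expect_equal(nrow(cal$trace), 16L)
})

test_that("calibration returns a single candidate unchanged and breaks ties
           by iteration order", {
  sc <- syntheticScenario(seed = 19, grid = tinyGrid(6),
                          axis = TimeAxis(2000, 1, 24),
                          nRecordsPerYear = 10L)
  res <- runScenario(sc)
  obs <- lapply(sort(unique(res$records$year)), function(y)
    rasterizeRecords(res$records, sc$grid, y, sc$species,
                     sc$insecticideClass))
  seed <- res$truth[[1]]
  one <- calibrateRules(sc$plantedRuleset,
                        list(t = list(rule = "rice_vegetables_temperature",
                                      condition = 3, part = "upper",
                                      values = 38)),
                        seed, res$drivers, obs)
  expect_equal(nrow(one$trace), 1L)
  expect_equal(one$score,
               meanAccuracy(validateStates(
                 suppressWarnings(caRun(seed, res$drivers,
                                        sc$plantedRuleset)), obs)))
  # candidates far above the data's range all tie: first one returned
  ties <- calibrateRules(sc$plantedRuleset,
                         list(t = list(rule = "rice_vegetables_temperature",
                                       condition = 3, part = "upper",
                                       values = c(100, 200, 300))),
                         seed, res$drivers, obs)
  expect_equal(ties$bestIndex, 1L)
})
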