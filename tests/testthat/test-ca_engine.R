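test_that("Moore neighbourhoods truncate at edges", {
  g <- buildGrid(0, 0, 50, 50, 5)
  expect_equal(nrow(mooreNeighbors(5, 5, g)), 8L)   # interior
  expect_equal(nrow(mooreNeighbors(1, 1, g)), 3L)   # corner
  expect_equal(nrow(mooreNeighbors(1, 6, g)), 5L)   # edge
  nb <- mooreNeighbors(5, 5, g)
  expect_true(all(pmax(abs(nb$i - 5), abs(nb$j - 5)) == 1))
  expect_equal(nrow(mooreNeighbors(5, 5, g, radius = 2)), 24L)
  expect_error(mooreNeighbors(0, 5, g), "outside")
})

test_that("a permissive neighbourhood floods from a central seed in one step", {
  g <- tinyGrid(3)
  drv <- constantStack(g, list(temperature = matrix(25, 3, 3),
                               irrigated_rice = matrix(0.5, 3, 3)))
  rs <- RuleSet(diffusionRules = list(irRule("d", list(
    irCondition("temperature", "in_interval", c(15, 38)),
    irCondition("irrigated_rice", "greater_than", 0)))))
  st <- stateFrom(g, matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3))
  nxt <- caStep(st, lapply(drv@layers, function(a) a[, , 1]), rs)
  expect_equal(sum(stateValues(nxt)), 9)      # all Moore-adjacent to centre
  expect_equal(nxt@step, 2L)
})

test_that("failing diffusion with no emergence erases a confirmed cell", {
  g <- tinyGrid(3)
  rs <- RuleSet(diffusionRules = list(irRule("d", list(
    irCondition("temperature", "in_interval", c(15, 38))))))
  st <- stateFrom(g, matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3))
  hot <- list(temperature = matrix(45, 3, 3))
  nxt <- caStep(st, hot, rs)
  expect_equal(sum(stateValues(nxt)), 0)
})

test_that("the emergence channel ignites an isolated permissive cell", {
  g <- tinyGrid(3)
  rice <- matrix(0, 3, 3); rice[1, 3] <- 0.4
  rs <- RuleSet(emergenceRules = list(irRule("e", list(
    irCondition("irrigated_rice", "greater_than", 0)))))
  st <- stateFrom(g, matrix(0, 3, 3))          # empty lattice
  nxt <- caStep(st, list(irrigated_rice = rice), rs)
  expect_equal(stateValues(nxt)[1, 3], 1)
  expect_equal(sum(stateValues(nxt)), 1)
})

test_that("the engine matches the naive per-cell oracle on random configurations", {
  set.seed(61)
  g <- buildGrid(0, 0, 50, 50, 5)
  mismatches <- 0L
  for (k in 1:100) {
    state <- matrix(rbinom(100, 1, runif(1, 0.1, 0.6)), 10, 10)
    layers <- list(a = matrix(runif(100), 10, 10),
                   b = matrix(runif(100), 10, 10),
                   c = matrix(runif(100), 10, 10))
    rs <- randomRuleSet(names(layers))
    fast <- stateValues(caStep(stateFrom(g, state), layers, rs))
    slow <- naiveStep(state, layers, rs, g)
    mismatches <- mismatches + sum(fast != slow)
  }
  expect_equal(mismatches, 0L)
})

test_that("the update is synchronous and deterministic", {
  set.seed(67)
  g <- buildGrid(0, 0, 40, 40, 5)
  state <- matrix(rbinom(64, 1, 0.3), 8, 8)
  layers <- list(a = matrix(runif(64), 8, 8))
  rs <- randomRuleSet("a")
  a1 <- stateValues(caStep(stateFrom(g, state), layers, rs))
  a2 <- stateValues(caStep(stateFrom(g, state), layers, rs))
  expect_identical(a1, a2)
  # a full run repeated on identical inputs is identical
  drv <- constantStack(g, layers, nSteps = 6)
  r1 <- caRun(stateFrom(g, state), drv, rs)
  r2 <- caRun(stateFrom(g, state), drv, rs)
  expect_identical(stateValues(r1), stateValues(r2))
})

test_that("always-true diffusion grows the confirmed set as a Chebyshev ball", {
  g <- buildGrid(0, 0, 35, 35, 5)              # 7 x 7
  drv <- constantStack(g, list(temperature = matrix(25, 7, 7)),
                       nSteps = 6)
  rs <- RuleSet(diffusionRules = list(alwaysRule()))
  seed <- matrix(0, 7, 7); seed[4, 4] <- 1
  run <- caRun(stateFrom(g, seed), drv, rs)
  cheb <- outer(abs(seq_len(7) - 4), abs(seq_len(7) - 4), pmax)
  for (k in 1:6) {
    expected <- (cheb <= (k - 1)) * 1
    expect_equal(stateValues(run)[, , k], expected)
  }
  # full at step index 4 (3 updates), not before
  expect_equal(sum(stateValues(run)[, , 4]), 49)
  expect_lt(sum(stateValues(run)[, , 3]), 49)
})

test_that("with both channels false the zero state is absorbing from step 2", {
  g <- tinyGrid(4)
  drv <- constantStack(g, list(temperature = matrix(25, 4, 4)),
                       nSteps = 5)
  rs <- RuleSet(diffusionRules = list(neverRule()),
                emergenceRules = list(neverRule()))
  seed <- matrix(rbinom(16, 1, 0.5), 4, 4)
  run <- caRun(stateFrom(g, seed), drv, rs)
  for (k in 2:5) expect_equal(sum(stateValues(run)[, , k]), 0)
})

test_that("a cell with both channels false at t is 0 at t+1 for every
           neighbourhood configuration", {
  # exhaustive over all 2^9 states of a 3x3 lattice: the centre's next
  # state under rule-less dynamics never depends on its neighbours
  g <- tinyGrid(3)
  rs <- RuleSet(diffusionRules = list(neverRule()),
                emergenceRules = list(neverRule()))
  layers <- list(temperature = matrix(25, 3, 3))
  for (code in 0:511) {
    state <- matrix(as.numeric(bitwAnd(bitwShiftR(code, 0:8), 1L)), 3, 3)
    nxt <- stateValues(caStep(stateFrom(g, state), layers, rs))
    expect_equal(sum(nxt), 0)
  }
})

test_that("missing driver layers are conservative and warned about once per run", {
  g <- tinyGrid(3)
  drv <- constantStack(g, list(temperature = matrix(25, 3, 3)),
                       nSteps = 3)
  rs <- RuleSet(diffusionRules = list(irRule("ghost", list(
    irCondition("not_present", "greater_than", 0)))))
  seed <- matrix(1, 3, 3)
  expect_warning(run <- caRun(stateFrom(g, seed), drv, rs),
                 "missing driver")
  expect_equal(sum(stateValues(run)[, , 2]), 0)
})
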