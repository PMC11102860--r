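# Shared fixtures: tiny grids, driver stacks built in code, and an
# independent naive reference implementation of the automaton update
# (per-cell double loop over scalar rule evaluation) used as the oracle
# the vectorized engine must match.

tinyGrid <- function(n = 3, m = n) buildGrid(0, 0, m * 5, n * 5, 5)

# constant-in-time driver stack from named list of matrices
constantStack <- function(grid, mats, nSteps = 2,
                          axis = TimeAxis(2000, 1, nSteps)) {
  layers <- lapply(mats, function(m) {
    a <- array(0, c(nrow(m), ncol(m), axis@nSteps))
    for (k in seq_len(axis@nSteps)) a[, , k] <- m
    a
  })
  kinds <- stats::setNames(rep("continuous", length(mats)), names(mats))
  new("DriverStack", grid = grid, axis = axis, layers = layers,
      kinds = kinds, legends = list())
}

stateFrom <- function(grid, mat, step = 1L)
  new("StateGrid", grid = grid, step = as.integer(step),
      values = matrix(as.numeric(mat), nrow(mat), ncol(mat)))

# rule set satisfied everywhere / nowhere for any stack with a
# "temperature" layer valued in [12, 42]
alwaysRule <- function() irRule("always",
  list(irCondition("temperature", "greater_than", -1e6)))
neverRule <- function() irRule("never",
  list(irCondition("temperature", "greater_than", 1e6)))

# naive reference update: explicit double loop, scalar rule evaluation
naiveStep <- function(stateMat, driversAtT, ruleset, grid, radius = 1) {
  nr <- nrow(stateMat); nc <- ncol(stateMat)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    cellValues <- lapply(driversAtT, function(m) m[i, j])
    nb <- mooreNeighbors(i, j, grid, radius)
    present <- stateMat[i, j] == 1 ||
      any(stateMat[cbind(nb$i, nb$j)] == 1)
    diffuse <- present &&
      evaluateRuleList(ruleset@diffusionRules, cellValues)
    emerge <- evaluateRuleList(ruleset@emergenceRules, cellValues)
    out[i, j] <- as.numeric(diffuse || emerge)
  }
  out
}

# random rule over the given driver names (1-3 conditions, random ops)
randomRule <- function(name, drivers) {
  nCond <- sample(1:3, 1)
  conds <- lapply(seq_len(nCond), function(k) {
    drv <- sample(drivers, 1)
    op <- sample(c("in_interval", "greater_than", "less_than",
                   "greater_equal"), 1)
    if (op == "in_interval") {
      b <- sort(stats::runif(2))
      irCondition(drv, op, b)
    } else irCondition(drv, op, stats::runif(1))
  })
  irRule(name, conds)
}

randomRuleSet <- function(drivers, maxRules = 3) {
  mk <- function(prefix) {
    n <- sample(0:maxRules, 1)
    lapply(seq_len(n), function(k)
      randomRule(paste0(prefix, k), drivers))
  }
  RuleSet(diffusionRules = mk("d"), emergenceRules = mk("e"))
}

# columns that are exactly pairwise uncorrelated in-sample: Helmert
# contrasts are orthogonal and sum to zero
orthogonalDrivers <- function(nDrivers) {
  X <- stats::contr.helmert(nDrivers + 1)
  colnames(X) <- sprintf("drv%02d", seq_len(nDrivers))
  X
}
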