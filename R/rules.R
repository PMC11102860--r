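#' @include AllClasses.R
NULL

#' Build a threshold condition on one driver
#'
#' A condition is a predicate on a single driver value. Intervals are
#' closed on both ends (a temperature band "15 to 38" includes both
#' endpoints); `greater_than` / `less_than` are strict ("surpassing 0.76"
#' excludes 0.76 itself); `equals_category` tests exact code equality for
#' categorical drivers.
#'
#' @param driver driver layer name.
#' @param op one of `"in_interval"`, `"greater_than"`, `"less_than"`,
#'   `"greater_equal"`, `"equals_category"`.
#' @param bounds length-2 numeric `c(lower, upper)` for `in_interval`,
#'   otherwise a single threshold or category code.
#' @return a condition (named list) usable in [irRule()].
#' @examples
#' irCondition("temperature", "in_interval", c(15, 38))
#' irCondition("itn_irs_coverage", "greater_than", 0.76)
#' @export
irCondition <- function(driver, op, bounds) {
  cond <- list(driver = as.character(driver), op = as.character(op),
               bounds = as.numeric(bounds))
  ok <- .validRule(list(name = "tmp", conditions = list(cond)))
  if (!isTRUE(ok)) stop(sub("^rule 'tmp': ", "", ok))
  cond
}

#' Build a transition rule (conjunction of conditions)
#'
#' A rule holds for a cell when ALL its conditions hold for that cell's
#' driver values at the evaluated time step. Rules are specific to a
#' vector species and insecticide class.
#'
#' @param name unique rule label within a rule set.
#' @param conditions list of conditions from [irCondition()]; at least one.
#' @param species vector species label (e.g. `"gambiae_complex"`).
#' @param insecticideClass one of the four classes used in malaria vector
#'   control (`"pyrethroid"`, `"organochlorine"`, `"carbamate"`,
#'   `"organophosphate"`) or `"any"`.
#' @return a rule (named list) usable in [RuleSet()].
#' @export
irRule <- function(name, conditions, species = "any",
                   insecticideClass = "any") {
  rule <- list(name = as.character(name), species = as.character(species),
               insecticide_class = as.character(insecticideClass),
               conditions = conditions)
  ok <- .validRule(rule)
  if (!isTRUE(ok)) stop(ok)
  rule
}

#' Construct a rule set
#'
#' @param diffusionRules rules gating neighbourhood spread.
#' @param emergenceRules rules permitting spontaneous onset in any cell.
#' @return a [RuleSet-class].
#' @export
RuleSet <- function(diffusionRules = list(), emergenceRules = list()) {
  new("RuleSet", diffusionRules = diffusionRules,
      emergenceRules = emergenceRules)
}

#' Evaluate a single condition for one cell
#'
#' A condition on a driver that is absent from `cellValues`, or whose
#' value is missing, evaluates to `FALSE`: absent data never asserts
#' resistance.
#'
#' @param cond condition from [irCondition()].
#' @param cellValues named list/vector of driver values for one cell.
#' @return logical scalar.
#' @examples
#' evaluateCondition(irCondition("temperature", "in_interval", c(15, 38)),
#'                   c(temperature = 25))
#' @export
evaluateCondition <- function(cond, cellValues) {
  idx <- match(cond$driver, names(cellValues))
  if (is.na(idx)) return(FALSE)
  v <- cellValues[[idx]]
  if (is.null(v) || is.na(v)) return(FALSE)
  switch(cond$op,
    in_interval    = v >= cond$bounds[1] && v <= cond$bounds[2],
    greater_than   = v > cond$bounds[1],
    less_than      = v < cond$bounds[1],
    greater_equal  = v >= cond$bounds[1],
    equals_category = v == cond$bounds[1],
    stop("unknown op: ", cond$op))
}

#' Evaluate a rule (conjunction) for one cell
#'
#' @param rule rule from [irRule()].
#' @inheritParams evaluateCondition
#' @return logical scalar; `TRUE` iff every condition holds.
#' @export
evaluateRule <- function(rule, cellValues) {
  for (cond in rule$conditions)
    if (!evaluateCondition(cond, cellValues)) return(FALSE)
  TRUE
}

#' Evaluate a list of rules (disjunction) for one cell
#'
#' @param rules list of rules from [irRule()]; an empty list is `FALSE`
#'   (no rule can ever assert resistance).
#' @inheritParams evaluateCondition
#' @return logical scalar; `TRUE` iff at least one rule holds.
#' @export
evaluateRuleList <- function(rules, cellValues) {
  for (rule in rules)
    if (evaluateRule(rule, cellValues)) return(TRUE)
  FALSE
}

## Vectorized evaluation over whole layers: `layers` is a named list of
## equal-dim numeric matrices (one slice per driver). Missing layers or NA
## values contribute FALSE. Attribute "n_missing" counts cell-condition
## evaluations that hit missing data.
.conditionMask <- function(cond, layers, dims) {
  v <- layers[[cond$driver]]
  if (is.null(v)) {
    m <- matrix(FALSE, dims[1], dims[2])
    attr(m, "n_missing") <- prod(dims)
    return(m)
  }
  m <- switch(cond$op,
    in_interval    = v >= cond$bounds[1] & v <= cond$bounds[2],
    greater_than   = v > cond$bounds[1],
    less_than      = v < cond$bounds[1],
    greater_equal  = v >= cond$bounds[1],
    equals_category = v == cond$bounds[1])
  nm <- sum(is.na(m))
  m[is.na(m)] <- FALSE
  attr(m, "n_missing") <- nm
  m
}

.ruleListMask <- function(rules, layers, dims) {
  out <- matrix(FALSE, dims[1], dims[2])
  missing <- 0L
  for (rule in rules) {
    rm <- matrix(TRUE, dims[1], dims[2])
    for (cond in rule$conditions) {
      cm <- .conditionMask(cond, layers, dims)
      missing <- missing + attr(cm, "n_missing")
      rm <- rm & cm
    }
    out <- out | rm
  }
  attr(out, "n_missing") <- missing
  out
}

#' The built-in example rule set
#'
#' Three driver combinations consistently associated with confirmed
#' resistance, used as defaults and as the planted truth of the synthetic
#' scenarios: (1) any irrigated rice farming; (2) irrigated rice and
#' vegetable farming with temperature in the closed band 15-38 degC;
#' (3) ITN/IRS coverage strictly above 0.76 with vegetable farming and
#' the same temperature band. All three serve both the diffusion and the
#' emergence channel by default.
#'
#' @param species,insecticideClass labels attached to the rules.
#' @return a [RuleSet-class] with the three rules in both channels.
#' @export
builtinRuleSet <- function(species = "gambiae_complex",
                           insecticideClass = "pyrethroid") {
  rules <- list(
    irRule("irrigated_rice",
           list(irCondition("irrigated_rice", "greater_than", 0)),
           species, insecticideClass),
    irRule("rice_vegetables_temperature",
           list(irCondition("irrigated_rice", "greater_than", 0),
                irCondition("vegetables", "greater_than", 0),
                irCondition("temperature", "in_interval", c(15, 38))),
           species, insecticideClass),
    irRule("coverage_vegetables_temperature",
           list(irCondition("itn_irs_coverage", "greater_than", 0.76),
                irCondition("vegetables", "greater_than", 0),
                irCondition("temperature", "in_interval", c(15, 38))),
           species, insecticideClass))
  RuleSet(diffusionRules = rules, emergenceRules = rules)
}
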