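#' @include AllClasses.R
NULL

#' Classify bioassay mortality into WHO resistance states
#'
#' WHO susceptibility-test categories: mortality below 90% within 60
#' minutes of exposure is confirmed resistance; 90% up to (but excluding)
#' 98% is possible resistance; 98-100% is susceptible. The published
#' bands "90 to 97" and "98 to 100" leave (97, 98) unassigned; here
#' possible = [90, 98) so the three states partition [0, 100].
#'
#' @param mortalityPct numeric vector of mortality percentages in [0, 100].
#' @return factor with levels `confirmed`, `possible`, `susceptible`.
#' @examples
#' classifyMortality(c(85, 90, 95, 98, 100))
#' @export
classifyMortality <- function(mortalityPct) {
  if (any(!is.finite(mortalityPct) | mortalityPct < 0 | mortalityPct > 100))
    stop("mortalityPct must lie in [0, 100]")
  cut(mortalityPct, breaks = c(-Inf, 90, 98, Inf), right = FALSE,
      labels = c("confirmed", "possible", "susceptible"))
}

#' Rasterize susceptibility records to an observed state grid
#'
#' Filters the records to one species x insecticide class x year, maps
#' each record to its lattice cell, and marks a covered cell
#' confirmed-present when at least one of its records classifies as
#' confirmed resistance (the conservative surveillance convention).
#' Records falling outside the grid are skipped and counted in the
#' `"n_skipped"` attribute.
#'
#' @param records data.frame in the schema of [readRecords()].
#' @param grid a [GridSpec-class].
#' @param year calendar year to keep.
#' @param species,insecticideClass labels to keep.
#' @return an [ObservedGrid-class].
#' @export
rasterizeRecords <- function(records, grid, year, species,
                             insecticideClass) {
  stopifnot(is(grid, "GridSpec"))
  keep <- records$species == species &
    records$insecticide_class == insecticideClass &
    records$year == year
  rec <- records[keep, , drop = FALSE]
  nskip <- 0L
  status <- data.frame(i = integer(), j = integer(), confirmed = logical())
  if (nrow(rec)) {
    s <- grid@cellSize
    j <- floor((rec$x - grid@originX) / s) + 1
    i <- floor((rec$y - grid@originY) / s) + 1
    inb <- is.finite(i) & is.finite(j) &
      i >= 1 & i <= grid@nRows & j >= 1 & j <= grid@nCols
    nskip <- sum(!inb)
    if (nskip) warning(nskip, " record(s) outside the grid skipped")
    rec <- rec[inb, , drop = FALSE]; i <- i[inb]; j <- j[inb]
    if (nrow(rec)) {
      conf <- classifyMortality(rec$mortality_pct) == "confirmed"
      agg <- stats::aggregate(conf,
                              by = list(i = as.integer(i), j = as.integer(j)),
                              FUN = any)
      status <- data.frame(i = agg$i, j = agg$j, confirmed = agg$x)
      status <- status[order(status$i, status$j), , drop = FALSE]
      rownames(status) <- NULL
    }
  }
  out <- new("ObservedGrid", grid = grid, year = as.integer(year),
             species = species, insecticideClass = insecticideClass,
             status = status)
  attr(out, "n_skipped") <- nskip
  out
}

#' Seed the automaton from the earliest observed year
#'
#' Initial confirmed cells are designated from observation: every cell
#' confirmed-present in the earliest year of the observed sequence gets
#' state 1; all other cells start at 0.
#'
#' @param observed list of [ObservedGrid-class] objects (any order).
#' @return a [StateGrid-class] at step 1.
#' @export
initialSeed <- function(observed) {
  if (length(observed) == 0L)
    stop("at least one observed year is required")
  stopifnot(all(vapply(observed, is, TRUE, "ObservedGrid")))
  yrs <- vapply(observed, function(o) o@year, 0L)
  first <- observed[[which.min(yrs)]]
  v <- matrix(0, first@grid@nRows, first@grid@nCols)
  st <- first@status
  conf <- st[st$confirmed, , drop = FALSE]
  v[cbind(conf$i, conf$j)] <- 1
  new("StateGrid", grid = first@grid, step = 1L, values = v)
}

#' Export an observed grid as a flat table
#'
#' @param observed an [ObservedGrid-class].
#' @param path optional CSV path; when given, the table is also written.
#' @return data.frame with columns `i`, `j`, `year`, `status`.
#' @export
observedToTable <- function(observed, path = NULL) {
  stopifnot(is(observed, "ObservedGrid"))
  out <- data.frame(i = observed@status$i, j = observed@status$j,
                    year = observed@year,
                    status = ifelse(observed@status$confirmed,
                                    "confirmed_present", "confirmed_absent"))
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
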