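#' The ASGO instrument definition
#'
#' Loads the General Assessment of the Hospitalised Patient (ASGO): ten
#' non-medical functions (mental status, movement/ambulation, circulation,
#' breathing, elimination/sphincter control, feeding, sleep/wake, sensory
#' system, self-care ability, prevailing mood), each weighted by the
#' commitment to support needs and described by up to seven ordered
#' modalities. Every modality carries a ranking value equal to the variable
#' weight times its level rank, so the ten weights (which sum to 10) fix the
#' whole scoring grid. Circulation, feeding, elimination and the sensory
#' system permit more than one modality per assessment.
#'
#' The default definition is shipped as a human-readable JSON file in
#' `inst/extdata`; an alternative file with the same schema may be supplied
#' to study modified weightings.
#'
#' @param path Path to a JSON instrument definition. `NULL` (default) loads
#'   the shipped ASGO definition.
#' @return An object of class `asgo_instrument`: a list with elements
#'   `instrument`, `version`, `variables` (named list of variable
#'   definitions, each with `name`, `label`, `weight`, `multi_select` and a
#'   `modalities` data frame with columns `level`, `label`,
#'   `ranking_value`), and `profile_bands`.
#' @examples
#' instr <- asgo_instrument()
#' names(instr$variables)
#' instr$variables$feeding$modalities
#' @export
asgo_instrument <- function(path = NULL) {
  if (is.null(path)) {
    cached <- .asgo_env$instrument
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "asgo_instrument.json", package = "asgo",
                        mustWork = TRUE)
  }
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  vars <- lapply(seq_len(nrow(raw$variables)), function(i) {
    v <- raw$variables[i, ]
    list(name = v$name, label = v$label, weight = v$weight,
         multi_select = v$multi_select,
         modalities = v$modalities[[1]])
  })
  names(vars) <- raw$variables$name
  obj <- structure(
    list(instrument = raw$instrument, version = raw$version,
         variables = vars, profile_bands = raw$profile_bands),
    class = "asgo_instrument")
  validate_instrument(obj)
  if (is.null(.asgo_env$instrument) &&
      identical(path, system.file("extdata", "asgo_instrument.json",
                                  package = "asgo"))) {
    .asgo_env$instrument <- obj
  }
  obj
}

.asgo_env <- new.env(parent = emptyenv())

#' Check an instrument definition for internal consistency
#'
#' Verifies the structural invariants of an ASGO-style definition: exactly
#' ten variables; weights summing to 10; each modality's ranking value equal
#' to weight times level (to one decimal place); ranking values strictly
#' increasing within a variable; levels within 1..7; and the multi-select
#' flag restricted to the four variables that permit it.
#'
#' @param instrument An `asgo_instrument` object.
#' @return The instrument, invisibly; stops with an informative error if an
#'   invariant is violated.
#' @export
validate_instrument <- function(instrument) {
  stopifnot(inherits(instrument, "asgo_instrument"))
  vars <- instrument$variables
  if (length(vars) != 10L)
    stop("instrument must define exactly 10 variables, got ", length(vars))
  w <- vapply(vars, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 10) > 1e-9)
    stop("variable weights must sum to 10, got ", sum(w))
  for (v in vars) {
    m <- v$modalities
    if (any(m$level < 1L | m$level > 7L))
      stop("variable '", v$name, "': levels must lie in 1..7")
    if (any(duplicated(m$level)))
      stop("variable '", v$name, "': duplicated levels")
    bad <- abs(m$ranking_value - round(v$weight * m$level, 1)) > 1e-9
    if (any(bad))
      stop("variable '", v$name, "': ranking value ", m$ranking_value[bad][1],
           " at level ", m$level[bad][1], " is not weight x level")
    if (any(diff(m$ranking_value) <= 0))
      stop("variable '", v$name, "': ranking values must be strictly increasing")
  }
  invisible(instrument)
}

#' @export
print.asgo_instrument <- function(x, ...) {
  cat(x$instrument, "instrument definition (version", x$version, ")\n")
  w <- vapply(x$variables, `[[`, numeric(1), "weight")
  ms <- vapply(x$variables, `[[`, logical(1), "multi_select")
  nm <- vapply(x$variables, `[[`, character(1), "label")
  for (i in seq_along(w))
    cat(sprintf("  %-32s weight %.1f  %s\n", nm[i], w[i],
                if (ms[i]) "[multi-select]" else ""))
  invisible(x)
}

# names of the ten ASGO variables in instrument order
asgo_variable_names <- function(instrument = asgo_instrument()) {
  names(instrument$variables)
}

#' Barthel Index item definitions
#'
#' The ten Barthel Index activities-of-daily-living items with their allowed
#' point values under the original Mahoney--Barthel allocation: 0/5/10/15
#' for chair transfer and walking, 0/5 for bathing and grooming, and 0/5/10
#' for the remaining six items. Item points sum to a 0--100 total where 0 is
#' total dependence and 100 complete independence.
#'
#' @return A named list mapping item name to its vector of allowed points.
#' @examples
#' barthel_items()$walking
#' @export
barthel_items <- function() {
  list(
    feeding    = c(0, 5, 10),
    toilet_use = c(0, 5, 10),
    bathing    = c(0, 5),
    grooming   = c(0, 5),
    dressing   = c(0, 5, 10),
    bowels     = c(0, 5, 10),
    bladder    = c(0, 5, 10),
    transfer   = c(0, 5, 10, 15),
    stairs     = c(0, 5, 10),
    walking    = c(0, 5, 10, 15)
  )
}
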