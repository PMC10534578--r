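#' Construct an ASGO assessment
#'
#' Bundles one patient-timepoint's modality selections. Every one of the ten
#' variables must carry at least one selected level; only the four
#' multi-select variables (circulation, elimination, feeding, sensory
#' system) may carry more than one.
#'
#' @param selections Named list mapping each variable name to an integer
#'   vector of selected levels.
#' @param timepoint `"admission"` or `"discharge"`.
#' @param instrument An `asgo_instrument` the selections are validated
#'   against.
#' @return An object of class `asgo_assessment`.
#' @examples
#' a <- asgo_assessment(all_minimum_selections())
#' score_asgo(a)
#' @export
asgo_assessment <- function(selections,
                            timepoint = c("admission", "discharge"),
                            instrument = asgo_instrument()) {
  timepoint <- match.arg(timepoint)
  vars <- instrument$variables
  missing_vars <- setdiff(names(vars), names(selections))
  if (length(missing_vars))
    stop("no selection for variable(s): ", paste(missing_vars, collapse = ", "))
  unknown <- setdiff(names(selections), names(vars))
  if (length(unknown))
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  for (nm in names(vars)) {
    sel <- selections[[nm]]
    if (!length(sel) || anyNA(sel))
      stop("variable '", nm, "': empty or missing selection")
    sel <- as.integer(sel)
    if (any(duplicated(sel)))
      stop("variable '", nm, "': duplicated levels selected")
    if (!all(sel %in% vars[[nm]]$modalities$level))
      stop("variable '", nm, "': unknown level ",
           paste(setdiff(sel, vars[[nm]]$modalities$level), collapse = ", "))
    if (!vars[[nm]]$multi_select && length(sel) > 1L)
      stop("variable '", nm, "' is single-select but has ",
           length(sel), " selections")
    selections[[nm]] <- sort(sel)
  }
  structure(list(selections = selections[names(vars)], timepoint = timepoint),
            class = "asgo_assessment")
}

#' Convenience selections with every variable at its first modality
#'
#' The all-minimum single-selection assessment is the analytic floor of the
#' ASGO: because the ten weights sum to 10 and each first-level ranking value
#' equals the weight itself, it scores exactly 10.0.
#'
#' @param instrument An `asgo_instrument`.
#' @return A named list of level-1 selections suitable for
#'   [asgo_assessment()].
#' @export
all_minimum_selections <- function(instrument = asgo_instrument()) {
  sel <- lapply(instrument$variables, function(v) min(v$modalities$level))
  sel
}

#' Score an ASGO assessment
#'
#' The raw score is the sum of the selected modalities' ranking values
#' (each already weight x level). For multi-select variables the selected
#' values are combined by summation by default — the scale measures
#' cumulative commitment to support needs — with `combine = "max"` available
#' for sensitivity analysis. The functional-dependence (FD) index is the raw
#' score divided by 10, and the care profile is read off the FD-index bands.
#'
#' @param assessment An `asgo_assessment`.
#' @param instrument The `asgo_instrument` to score against.
#' @param combine How multiple selections on a multi-select variable
#'   contribute: `"sum"` (default) or `"max"`.
#' @return An object of class `asgo_result`: list with `raw_score`,
#'   `fd_index`, `profile`, `per_variable` (named vector of each variable's
#'   contribution) and `timepoint`.
#' @examples
#' sel <- all_minimum_selections()
#' score_asgo(asgo_assessment(sel))$raw_score        # 10.0, the floor
#' sel$feeding <- 7L
#' score_asgo(asgo_assessment(sel))$raw_score        # 10 - 0.6 + 4.2
#' @export
score_asgo <- function(assessment, instrument = asgo_instrument(),
                       combine = c("sum", "max")) {
  stopifnot(inherits(assessment, "asgo_assessment"))
  combine <- match.arg(combine)
  vars <- instrument$variables
  per_var <- vapply(names(vars), function(nm) {
    m <- vars[[nm]]$modalities
    vals <- m$ranking_value[match(assessment$selections[[nm]], m$level)]
    if (combine == "sum") sum(vals) else max(vals)
  }, numeric(1))
  raw <- sum(per_var)
  structure(list(raw_score = raw, fd_index = raw / 10,
                 profile = profile_category(raw / 10),
                 per_variable = per_var,
                 timepoint = assessment$timepoint),
            class = "asgo_result")
}

#' @export
print.asgo_result <- function(x, ...) {
  cat(sprintf("ASGO %s: raw score %.1f, FD index %.2f, %s care\n",
              x$timepoint, x$raw_score, x$fd_index, x$profile))
  invisible(x)
}

#' Care-profile category from the FD index
#'
#' Maps the functional-dependence index (raw ASGO score / 10) onto the four
#' care-intensity bands. Bands are left-closed, right-open so that every
#' index at or above the analytic floor of 1.0 falls in exactly one band:
#' minimum \[1.0, 2.6), medium \[2.6, 3.7), high \[3.7, 4.8), maximum
#' \[4.8, Inf).
#'
#' @param fd_index Numeric vector of FD-index values, each >= 1.
#' @return Character vector with levels `"minimum"`, `"medium"`, `"high"`,
#'   `"maximum"`.
#' @examples
#' profile_category(c(2.0, 3.0, 4.8))
#' @export
profile_category <- function(fd_index) {
  if (any(!is.finite(fd_index)) || any(fd_index < 1.0))
    stop("fd_index must be finite and >= 1.0 (the ASGO floor)")
  cut(fd_index, breaks = c(1.0, 2.6, 3.7, 4.8, Inf), right = FALSE,
      labels = c("minimum", "medium", "high", "maximum")) |> as.character()
}

#' Construct a Barthel Index assessment
#'
#' @param scores Named numeric vector or list with one entry per Barthel
#'   item (see [barthel_items()] for names and allowed point values).
#' @return An object of class `barthel_assessment`.
#' @examples
#' items <- vapply(barthel_items(), max, numeric(1))
#' score_barthel(barthel_assessment(items))   # 100
#' @export
barthel_assessment <- function(scores) {
  items <- barthel_items()
  scores <- unlist(scores)
  missing_items <- setdiff(names(items), names(scores))
  if (length(missing_items))
    stop("missing Barthel item(s): ", paste(missing_items, collapse = ", "))
  unknown <- setdiff(names(scores), names(items))
  if (length(unknown))
    stop("unknown Barthel item(s): ", paste(unknown, collapse = ", "))
  for (nm in names(items)) {
    if (is.na(scores[[nm]]) || !(scores[[nm]] %in% items[[nm]]))
      stop("Barthel item '", nm, "': value ", scores[[nm]],
           " not in allowed set {", paste(items[[nm]], collapse = ", "), "}")
  }
  structure(list(scores = scores[names(items)]), class = "barthel_assessment")
}

#' Total Barthel Index score
#'
#' @param assessment A `barthel_assessment`.
#' @return Integer total in 0..100 (always a multiple of 5).
#' @export
score_barthel <- function(assessment) {
  stopifnot(inherits(assessment, "barthel_assessment"))
  as.integer(sum(assessment$scores))
}

#' Dichotomize a Barthel total at the 60-point cut-off
#'
#' Totals of 60 or more indicate better functional status (independence);
#' totals below 60 indicate worse functional status (dependence).
#'
#' @param total Integer vector of Barthel totals in 0..100.
#' @return A `dependence_status` object (character vector of
#'   `"dependence"`/`"independence"` with `source` and `cutoff` attributes).
#' @examples
#' dichotomize_barthel(c(59, 60))
#' @export
dichotomize_barthel <- function(total) {
  if (any(!is.finite(total)) || any(total < 0 | total > 100))
    stop("Barthel total must lie in [0, 100]")
  dependence_status(ifelse(total >= 60, "independence", "dependence"),
                    source = "barthel", cutoff = 60)
}

#' Classify an ASGO raw score against a dependence cut-off
#'
#' Higher ASGO scores mean greater dependence, so scores at or above the
#' cut-off classify as dependent (ties at the cut-off are dependent).
#'
#' @param raw_score Numeric vector of ASGO raw scores (>= 10).
#' @param cutoff Positive dependence cut-off, e.g. the Youden-optimal value.
#' @return A `dependence_status` object.
#' @examples
#' classify_asgo(c(10, 22.4, 22.5), cutoff = 22.5)
#' @export
classify_asgo <- function(raw_score, cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0)
  if (any(!is.finite(raw_score)) || any(raw_score < 10))
    stop("ASGO raw scores must be finite and >= 10")
  dependence_status(ifelse(raw_score >= cutoff, "dependence", "independence"),
                    source = "asgo", cutoff = cutoff)
}

dependence_status <- function(flag, source, cutoff) {
  structure(flag, source = source, cutoff = cutoff,
            class = "dependence_status")
}

#' @export
print.dependence_status <- function(x, ...) {
  cat(sprintf("dependence status (%s, cut-off %g):\n",
              attr(x, "source"), attr(x, "cutoff")))
  print(unclass(`attributes<-`(x, NULL)))
  invisible(x)
}
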