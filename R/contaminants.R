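#' Define a contaminant
#'
#' A contaminant is identified by name and carries the chronic oral
#' reference dose (RfD, mg per kg body weight per day) used for hazard
#' quotients, plus optional guideline bounds (mg/L) used by
#' [guideline_screen()].
#'
#' @param name Contaminant identifier, e.g. `"fluoride"`.
#' @param rfd Reference dose, mg/kg/day; must be strictly positive.
#' @param guideline_low Optional lower guideline bound, mg/L.
#' @param guideline_high Optional upper guideline bound, mg/L.
#' @return An object of class `contaminant_spec`.
#' @export
#' @examples
#' contaminant_spec("fluoride", rfd = 0.06, guideline_low = 0.5, guideline_high = 1.5)
contaminant_spec <- function(name, rfd, guideline_low = NA_real_, guideline_high = NA_real_) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    stop_validation("`name` must be a single non-empty string.")
  }
  if (!is.numeric(rfd) || length(rfd) != 1 || is.na(rfd) || rfd <= 0) {
    stop_config(sprintf("Reference dose for '%s' must be a single positive number.", name))
  }
  guideline_low <- as.double(guideline_low)
  guideline_high <- as.double(guideline_high)
  if (!is.na(guideline_low) && !is.na(guideline_high) && guideline_low > guideline_high) {
    stop_validation(sprintf(
      "Guideline bounds for '%s' are inverted: low %g > high %g.",
      name, guideline_low, guideline_high
    ))
  }
  structure(
    list(
      name = name,
      rfd = as.double(rfd),
      guideline_low = guideline_low,
      guideline_high = guideline_high
    ),
    class = "contaminant_spec"
  )
}

#' @export
print.contaminant_spec <- function(x, ...) {
  cat(sprintf("<contaminant_spec> %s\n  RfD: %g mg/kg/day\n", x$name, x$rfd))
  if (!is.na(x$guideline_low) || !is.na(x$guideline_high)) {
    cat(sprintf(
      "  guideline: [%s, %s] mg/L\n",
      ifelse(is.na(x$guideline_low), "-", format(x$guideline_low)),
      ifelse(is.na(x$guideline_high), "-", format(x$guideline_high))
    ))
  }
  invisible(x)
}

#' Built-in contaminant definitions
#'
#' The two contaminants of the packaged bottled-water survey with their
#' reference doses (fluoride 0.06, nitrate 1.6 mg/kg/day) and WHO drinking
#' water guidelines (fluoride 0.5-1.5 mg/L; nitrate upper bound 45 mg/L).
#'
#' @return Named list of [contaminant_spec()] objects.
#' @export
#' @examples
#' water_contaminants()$fluoride
water_contaminants <- function() {
  list(
    fluoride = contaminant_spec("fluoride", rfd = 0.06,
                                guideline_low = 0.5, guideline_high = 1.5),
    nitrate = contaminant_spec("nitrate", rfd = 1.6,
                               guideline_high = 45)
  )
}

#' Build an exposure-profile table
#'
#' Each row defines one receptor group for chronic ingestion: daily water
#' intake `ir` (L/day), exposure frequency `ef` (days/year), exposure
#' duration `ed` (years), body weight `bw` (kg) and averaging time `at`
#' (days). The returned tibble carries an `at_consistent` flag recording
#' whether `at == ed * ef` (true for all four default profiles, in which
#' case EDI reduces exactly to `C * ir / bw`).
#'
#' @param groups Data frame with columns `group`, `ir`, `ef`, `ed`, `bw`, `at`.
#' @return A validated tibble of exposure profiles.
#' @seealso [load_fixture()] for the packaged four-group default set.
#' @export
exposure_profiles <- function(groups) {
  required <- c("group", "ir", "ef", "ed", "bw", "at")
  missing <- setdiff(required, names(groups))
  if (length(missing) > 0) {
    stop_schema(sprintf("Exposure table is missing column(s): %s.",
                        paste(missing, collapse = ", ")))
  }
  out <- as_tibble(groups)[required]
  num <- out[c("ir", "ef", "ed", "bw", "at")]
  bad <- !vapply(num, function(v) is.numeric(v) && all(is.finite(v)) && all(v > 0), logical(1))
  if (any(bad)) {
    stop_validation(sprintf("Exposure parameter(s) not strictly positive: %s.",
                            paste(names(num)[bad], collapse = ", ")))
  }
  if (anyDuplicated(out$group)) {
    stop_validation("Exposure group identifiers must be unique.")
  }
  out$at_consistent <- abs(out$at - out$ed * out$ef) < 1e-8 * pmax(out$at, 1)
  out
}
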