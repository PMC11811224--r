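#' Spearman rank correlation with degenerate-input handling
#'
#' Pearson correlation of mid-ranks (ties receive average ranks), i.e. the
#' Spearman coefficient. A zero-variance input cannot be ranked against the
#' output; it is flagged with attribute `degenerate = TRUE` and returns 0.
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return Coefficient in \[-1, 1\]; attribute `degenerate` is `TRUE` when
#'   either vector has zero variance.
#' @export
#' @examples
#' rank_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) stop_validation("`x` and `y` must have equal length.")
  if (length(x) < 3) stop_validation("Need at least 3 paired observations.")
  if (sd(x) == 0 || sd(y) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  structure(cor(x, y, method = "spearman"), degenerate = FALSE)
}

new_sensitivity_report <- function(contributions, group = NA_character_,
                                   contaminant = NA_character_) {
  contributions <- contributions |>
    arrange(desc(.data$contribution)) |>
    mutate(contribution_display = largest_remainder(.data$contribution, digits = 1))
  structure(
    list(
      group = group,
      contaminant = contaminant,
      contributions = contributions,
      ranking = contributions$input
    ),
    class = "sensitivity_report"
  )
}

#' Contribution to variance of simulation inputs
#'
#' Crystal-Ball-style sensitivity: each input's contribution is its squared
#' Spearman rank correlation with the output, normalised over inputs so the
#' percentages sum to 100. Inputs that enter the model inversely (body
#' weight divides the dose) show a negative rank correlation; the sign is
#' reported, the contribution uses the square. Zero-variance inputs
#' contribute 0 and are flagged.
#'
#' @param inputs Named list (or data frame) of equal-length trial vectors.
#' @param output Trial vector of the model output.
#' @return A `sensitivity_report`: tibble of `input`, `rho`, `degenerate`,
#'   `contribution` (full precision, sums to 100), `contribution_display`
#'   (1 decimal, reconciled by largest remainder to sum exactly 100), plus
#'   the descending ranking.
#' @export
#' @examples
#' set.seed(1)
#' a <- rlnorm(1000); b <- rlnorm(1000)
#' contribution_to_variance(list(a = a, b = b), a * b)
contribution_to_variance <- function(inputs, output) {
  inputs <- as.list(inputs)
  if (length(inputs) == 0) stop_validation("Need at least one input vector.")
  if (is.null(names(inputs)) || any(!nzchar(names(inputs)))) {
    stop_validation("Every input vector must be named.")
  }
  lens <- vapply(inputs, length, integer(1))
  if (any(lens != length(output))) {
    stop_validation("All input vectors must match the output length.")
  }
  rho <- map(inputs, rank_correlation, y = output)
  degenerate <- unname(vapply(rho, function(r) isTRUE(attr(r, "degenerate")), logical(1)))
  rho <- unname(vapply(rho, as.double, double(1)))
  if (all(degenerate)) {
    stop_degenerate("All inputs have zero variance; contributions are undefined.")
  }
  contribution <- 100 * rho^2 / sum(rho^2)
  new_sensitivity_report(
    tibble(input = names(inputs), rho = rho, degenerate = degenerate,
           contribution = contribution)
  )
}

#' Sensitivity report for a Monte Carlo scenario
#'
#' Runs [simulate_hq()] capturing the per-input draws (C, IR, BW) and ranks
#' them by contribution to variance of the simulated HQ. At least one
#' marginal must be non-point; point inputs appear with contribution 0.
#'
#' @param scenario A [scenario_spec()].
#' @return A `sensitivity_report` annotated with the scenario's group and
#'   contaminant.
#' @export
#' @examples
#' sc <- default_scenario(
#'   load_fixture("fluoride_table2"),
#'   dplyr::filter(load_fixture("exposure_table1"), group == "infants"),
#'   n_trials = 2000, seed = 7
#' )
#' sensitivity_report(sc)
sensitivity_report <- function(scenario) {
  if (!inherits(scenario, "scenario_spec")) stop_validation("`scenario` must be a scenario_spec.")
  kinds <- c(scenario$c_dist$kind, scenario$ir_dist$kind, scenario$bw_dist$kind)
  if (all(kinds == "point")) {
    stop_degenerate("All scenario inputs are point distributions; sensitivity is undefined.")
  }
  sim <- simulate_hq(scenario)
  report <- contribution_to_variance(as.list(sim$inputs), sim$trials)
  report$group <- scenario$group
  report$contaminant <- scenario$contaminant$name
  report
}

#' @export
print.sensitivity_report <- function(x, ...) {
  header <- sprintf("<sensitivity_report>%s%s\n",
                    if (!is.na(x$contaminant)) paste0(" ", x$contaminant) else "",
                    if (!is.na(x$group)) paste0(" / ", x$group) else "")
  cat(header)
  print(x$contributions, ...)
  invisible(x)
}
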