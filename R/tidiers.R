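#' Tidy a simulation result
#'
#' @param x An `hq_sim` from [simulate_hq()] or [simulate_hi()].
#' @param ... Unused.
#' @return Tibble with one row per trial: `trial`, `value`, plus the
#'   per-input draws when available.
#' @export
tidy.hq_sim <- function(x, ...) {
  out <- tibble(trial = seq_along(x$trials), value = x$trials)
  if (is_tibble(x$inputs)) out <- bind_cols(out, x$inputs)
  out
}

#' Glance at a simulation result
#'
#' @param x An `hq_sim`.
#' @param ... Unused.
#' @return One-row tibble: kind, trial count, mean, SD and the summarised
#'   percentiles.
#' @export
glance.hq_sim <- function(x, ...) {
  tibble(kind = x$kind, n_trials = length(x$trials),
         mean = x$mean, sd = x$sd, !!!as.list(x$percentiles))
}

#' Tidy a deterministic risk table
#'
#' @param x A [risk_table()] result.
#' @param ... Unused.
#' @return The cell tibble (brand x group x contaminant EDI and HQ).
#' @export
tidy.risk_table <- function(x, ...) x$cells

#' Glance at a deterministic risk table
#'
#' @param x A [risk_table()] result.
#' @param ... Unused.
#' @return One-row tibble of cardinalities and overall exceedance counts.
#' @export
glance.risk_table <- function(x, ...) {
  tibble(
    n_brands = length(unique(x$cells$brand)),
    n_groups = length(unique(x$cells$group)),
    n_contaminants = length(unique(x$cells$contaminant)),
    n_hq_gt_1 = sum(x$cells$hq > 1),
    n_hi_gt_1 = sum(x$hi$hi > 1)
  )
}

#' Tidy a sensitivity report
#'
#' @param x A `sensitivity_report`.
#' @param ... Unused.
#' @return The contribution tibble, annotated with group and contaminant.
#' @export
tidy.sensitivity_report <- function(x, ...) {
  mutate(x$contributions, group = x$group, contaminant = x$contaminant, .before = 1)
}

#' Glance at a sensitivity report
#'
#' @param x A `sensitivity_report`.
#' @param ... Unused.
#' @return One-row tibble naming the dominant input and its contribution.
#' @export
glance.sensitivity_report <- function(x, ...) {
  top <- x$contributions[1, ]
  tibble(group = x$group, contaminant = x$contaminant,
         top_input = top$input, top_contribution = top$contribution,
         n_inputs = nrow(x$contributions))
}
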