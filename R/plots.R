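#' Plot a brand panel
#'
#' Measured concentration per brand with replicate-SD error bars and any
#' guideline bounds as dashed lines.
#'
#' @param object A `brand_panel`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.brand_panel <- function(object, ...) {
  spec <- panel_contaminant(object)
  df <- as_tibble(object) |>
    mutate(brand = factor(.data$brand, levels = .data$brand))
  p <- ggplot(df, aes(x = .data$brand, y = .data$measured, fill = .data$water_type)) +
    geom_col() +
    geom_errorbar(aes(ymin = pmax(.data$measured - .data$sd, 0),
                      ymax = .data$measured + .data$sd), width = 0.3) +
    labs(x = NULL, y = sprintf("%s (mg/L)", spec$name), fill = "type") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 60, hjust = 1))
  for (bound in c(spec$guideline_low, spec$guideline_high)) {
    if (!is.na(bound)) p <- p + geom_hline(yintercept = bound, linetype = "dashed")
  }
  p
}

#' Plot a deterministic risk table
#'
#' Stacked per-contaminant HQ bars per brand (the stack height is the
#' hazard index), faceted by age group, with the HQ = 1 concern line.
#'
#' @param object A [risk_table()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.risk_table <- function(object, ...) {
  brands <- unique(object$cells$brand)
  groups <- unique(object$cells$group)
  df <- object$cells |>
    mutate(brand = factor(.data$brand, levels = brands),
           group = factor(.data$group, levels = groups))
  ggplot(df, aes(x = .data$brand, y = .data$hq, fill = .data$contaminant)) +
    geom_col() +
    geom_hline(yintercept = 1, linetype = "dashed") +
    facet_wrap(~group, ncol = 1) +
    labs(x = NULL, y = "hazard quotient (stack = HI)", fill = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 60, hjust = 1))
}

#' Plot a simulated HQ or HI distribution
#'
#' Trial histogram with the mean (solid) and 95th percentile (dashed)
#' marked.
#'
#' @param object An `hq_sim`.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hq_sim <- function(object, bins = 40, ...) {
  df <- tibble(value = object$trials)
  ggplot(df, aes(x = .data$value)) +
    geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    geom_vline(xintercept = object$mean) +
    geom_vline(xintercept = percentile(object, 0.95), linetype = "dashed") +
    labs(x = object$kind, y = "trials") +
    theme_minimal()
}

#' Plot a sensitivity report
#'
#' Contribution-to-variance percentages per input, ordered by rank;
#' negative rank correlations (inverse inputs such as body weight) are
#' shown by bar colour.
#'
#' @param object A `sensitivity_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sensitivity_report <- function(object, ...) {
  df <- object$contributions |>
    mutate(input = factor(.data$input, levels = rev(object$ranking)),
           direction = ifelse(.data$rho < 0, "inverse", "direct"))
  title <- if (!is.na(object$contaminant)) {
    sprintf("Contribution to variance: %s, %s", object$contaminant, object$group)
  } else "Contribution to variance"
  ggplot(df, aes(x = .data$input, y = .data$contribution, fill = .data$direction)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "contribution to variance (%)", fill = NULL, title = title) +
    theme_minimal()
}
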