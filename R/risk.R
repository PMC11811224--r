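#' Estimated daily intake
#'
#' Chronic ingestion dose from drinking water,
#' \deqn{EDI = \frac{C \times IR \times EF \times ED}{BW \times AT},}
#' in mg per kg body weight per day: concentration `C` (mg/L), ingestion
#' rate `IR` (L/day), exposure frequency `EF` (days/year), exposure
#' duration `ED` (years), body weight `BW` (kg) and averaging time `AT`
#' (days). When `AT = ED * EF` (true for all packaged profiles) this is
#' exactly `C * IR / BW`.
#'
#' @param c Concentration(s), mg/L; non-negative.
#' @param profile One exposure profile: a one-row data frame or list with
#'   `ir`, `ef`, `ed`, `bw`, `at`.
#' @return EDI in mg/kg/day, same length as `c`.
#' @export
#' @examples
#' infants <- dplyr::filter(load_fixture("exposure_table1"), group == "infants")
#' edi(0.70, infants)  # 0.70 * 0.7 / 7.5
edi <- function(c, profile) {
  if (any(!is.finite(c)) || any(c < 0)) {
    stop_domain("Concentrations must be finite and non-negative.")
  }
  p <- as.list(profile)
  need <- c("ir", "ef", "ed", "bw", "at")
  if (!all(need %in% names(p))) {
    stop_schema(sprintf("Exposure profile is missing: %s.",
                        paste(setdiff(need, names(p)), collapse = ", ")))
  }
  vals <- vapply(p[need], function(v) as.double(v[[1]]), double(1))
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_validation("All exposure parameters must be strictly positive.")
  }
  c * vals[["ir"]] * vals[["ef"]] * vals[["ed"]] / (vals[["bw"]] * vals[["at"]])
}

#' Hazard quotient
#'
#' Ratio of estimated daily intake to the contaminant's reference dose,
#' `HQ = EDI / RfD`. Values above 1 signal potential non-carcinogenic
#' concern; values at or below 1 are conventionally read as no appreciable
#' risk.
#'
#' @param edi_value EDI value(s), mg/kg/day.
#' @param rfd Reference dose, mg/kg/day; strictly positive.
#' @return Dimensionless hazard quotient(s).
#' @export
#' @examples
#' hazard_quotient(0.042, 0.06)
hazard_quotient <- function(edi_value, rfd) {
  if (!is.numeric(rfd) || length(rfd) != 1 || is.na(rfd) || rfd <= 0) {
    stop_config("Reference dose must be a single positive number.")
  }
  edi_value / rfd
}

#' Hazard index
#'
#' Sum of hazard quotients over co-occurring contaminants for one receptor,
#' `HI = sum(HQ)`. Used as a screening-level measure of additive
#' non-carcinogenic risk from a mixture.
#'
#' @param hqs Numeric vector of hazard quotients (at least one).
#' @return Their arithmetic sum.
#' @export
hazard_index <- function(hqs) {
  if (length(hqs) == 0) stop_empty("Need at least one hazard quotient.")
  if (any(!is.finite(hqs)) || any(hqs < 0)) {
    stop_domain("Hazard quotients must be finite and non-negative.")
  }
  sum(hqs)
}

#' Full deterministic risk table
#'
#' Computes EDI and HQ for every brand x age group x contaminant, and the
#' hazard index HI per brand x group as the sum of that brand's per
#' contaminant HQs. Brands are paired across contaminant panels by brand
#' identifier, never by row position, so HI always combines the same
#' bottle's measurements.
#'
#' @param panels Named list of `brand_panel` objects, one per contaminant,
#'   all covering the same brand set.
#' @param profiles An [exposure_profiles()] tibble.
#' @return A `risk_table` object: list with `cells` (tibble `brand`,
#'   `group`, `contaminant`, `concentration`, `edi`, `hq`) and `hi`
#'   (tibble `brand`, `group`, `hi`).
#' @export
#' @examples
#' rt <- risk_table(
#'   list(fluoride = load_fixture("fluoride_table2"),
#'        nitrate = load_fixture("nitrate_table2")),
#'   load_fixture("exposure_table1")
#' )
#' dplyr::filter(rt$hi, group == "infants", hi > 1)
risk_table <- function(panels, profiles) {
  if (!is.list(panels) || length(panels) == 0) {
    stop_validation("`panels` must be a non-empty list of brand_panel objects.")
  }
  specs <- map(panels, panel_contaminant)
  if (is.null(names(panels)) || any(!nzchar(names(panels)))) {
    names(panels) <- map_chr(specs, "name")
  }
  profiles <- exposure_profiles(profiles)

  brand_sets <- map(panels, "brand")
  all_brands <- brand_sets[[1]]
  for (i in seq_along(brand_sets)[-1]) {
    extra <- setdiff(brand_sets[[i]], all_brands)
    missing <- setdiff(all_brands, brand_sets[[i]])
    if (length(extra) + length(missing) > 0) {
      stop_validation(sprintf(
        "Panels '%s' and '%s' cover different brands (symmetric difference: %s).",
        names(panels)[1], names(panels)[i],
        paste(c(missing, extra), collapse = ", ")
      ))
    }
  }

  # One row per brand x group x contaminant.
  cells <- list_rbind(map(seq_along(panels), function(i) {
    panel <- panels[[i]]
    spec <- specs[[i]]
    list_rbind(map(seq_len(nrow(profiles)), function(g) {
      prof <- profiles[g, ]
      e <- edi(panel$measured, prof)
      tibble(
        brand = panel$brand,
        group = prof$group,
        contaminant = spec$name,
        concentration = panel$measured,
        edi = e,
        hq = hazard_quotient(e, spec$rfd)
      )
    }))
  }))

  hi <- cells |>
    summarise(hi = sum(.data$hq), .by = c("brand", "group"))

  structure(
    list(cells = cells, hi = hi, profiles = profiles,
         contaminants = specs),
    class = "risk_table"
  )
}

#' @export
print.risk_table <- function(x, ...) {
  cat(sprintf("<risk_table> %d brands x %d groups x %d contaminants\n",
              length(unique(x$cells$brand)),
              length(unique(x$cells$group)),
              length(unique(x$cells$contaminant))))
  print(group_summary(x)$hi, ...)
  invisible(x)
}

#' Group-level risk summary
#'
#' Per group and contaminant: arithmetic mean, minimum and maximum of EDI
#' and HQ over brands, and the count of brands with HQ strictly above 1.
#' Per group: the same statistics for HI. Group ordering follows the
#' profile table.
#'
#' @param rt A [risk_table()] result.
#' @return List of two tibbles, `hq` and `hi`, of class `risk_summary`.
#' @export
group_summary <- function(rt) {
  if (!inherits(rt, "risk_table")) stop_validation("`rt` must be a risk_table.")
  if (nrow(rt$cells) == 0) stop_empty("Risk table has no cells.")
  group_levels <- unique(rt$cells$group)
  hq <- rt$cells |>
    mutate(group = factor(.data$group, levels = group_levels)) |>
    summarise(
      edi_mean = mean(.data$edi), edi_min = min(.data$edi), edi_max = max(.data$edi),
      hq_mean = mean(.data$hq), hq_min = min(.data$hq), hq_max = max(.data$hq),
      n_hq_gt_1 = sum(.data$hq > 1),
      .by = c("group", "contaminant")
    ) |>
    arrange(.data$group) |>
    mutate(group = as.character(.data$group))
  hi <- rt$hi |>
    mutate(group = factor(.data$group, levels = group_levels)) |>
    summarise(
      hi_mean = mean(.data$hi), hi_min = min(.data$hi), hi_max = max(.data$hi),
      n_hi_gt_1 = sum(.data$hi > 1),
      .by = "group"
    ) |>
    arrange(.data$group) |>
    mutate(group = as.character(.data$group))
  structure(list(hq = hq, hi = hi), class = "risk_summary")
}

#' @export
print.risk_summary <- function(x, ...) {
  cat("Per-group HQ summary:\n"); print(x$hq, ...)
  cat("Per-group HI summary:\n"); print(x$hi, ...)
  invisible(x)
}
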