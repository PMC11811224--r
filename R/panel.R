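#' Construct a brand concentration panel
#'
#' A brand panel is a tibble with one row per water brand holding the mean
#' measured concentration and its replicate SD (mg/L), the declared label
#' value when one exists, and a free-text `label_note` preserving labels
#' that are printed as bounds (e.g. `"< 2"`) and therefore carry no usable
#' number. The contaminant definition travels with the panel as an
#' attribute.
#'
#' @param data Data frame with columns `brand`, `water_type`, `labeled`,
#'   `label_note`, `measured`, `sd` (missing `label_note` is filled with NA).
#' @param contaminant A [contaminant_spec()].
#' @return A `brand_panel` tibble.
#' @export
brand_panel <- function(data, contaminant) {
  if (!inherits(contaminant, "contaminant_spec")) {
    stop_validation("`contaminant` must be a contaminant_spec object.")
  }
  data <- as_tibble(data)
  if (!"label_note" %in% names(data)) data$label_note <- NA_character_
  required <- c("brand", "water_type", "labeled", "label_note", "measured", "sd")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    stop_schema(sprintf("Panel is missing column(s): %s.", paste(missing, collapse = ", ")))
  }
  out <- data[required]
  out$brand <- as.character(out$brand)
  out$water_type <- as.character(out$water_type)
  out$labeled <- as.double(out$labeled)
  out$measured <- as.double(out$measured)
  out$sd <- as.double(out$sd)
  dup <- unique(out$brand[duplicated(out$brand)])
  if (length(dup) > 0) {
    stop_validation(sprintf("Duplicate brand id(s): %s.", paste(dup, collapse = ", ")))
  }
  bad_type <- setdiff(unique(out$water_type), c("DW", "MW"))
  if (length(bad_type) > 0) {
    stop_validation(sprintf("Unknown water type(s): %s (expected DW or MW).",
                            paste(bad_type, collapse = ", ")))
  }
  for (col in c("measured", "sd")) {
    neg <- which(!is.na(out[[col]]) & out[[col]] < 0)
    if (length(neg) > 0) {
      stop_validation(sprintf("Negative %s value in row %d (brand %s).",
                              col, neg[1], out$brand[neg[1]]))
    }
    if (anyNA(out[[col]])) {
      stop_validation(sprintf("Missing %s value in row %d.", col, which(is.na(out[[col]]))[1]))
    }
  }
  structure(out, contaminant = contaminant,
            class = c("brand_panel", class(tibble())))
}

#' Extract the contaminant definition of a panel
#'
#' @param panel A `brand_panel`.
#' @return The panel's [contaminant_spec()].
#' @export
panel_contaminant <- function(panel) {
  spec <- attr(panel, "contaminant", exact = TRUE)
  if (is.null(spec)) stop_validation("Object carries no contaminant attribute; is it a brand_panel?")
  spec
}

# Parse raw label cells as printed: numbers pass through; "NL" (any case)
# and empty cells mean the bottle carried no declared value; bound strings
# ("< 2", "> 0.1") are unusable numerically and are kept verbatim in
# label_note.
parse_label <- function(raw) {
  raw <- trimws(as.character(raw))
  labeled <- rep(NA_real_, length(raw))
  note <- rep(NA_character_, length(raw))
  for (i in seq_along(raw)) {
    cell <- raw[i]
    if (is.na(cell) || cell == "" || toupper(cell) == "NL") next
    if (grepl("^[<>]", cell)) {
      note[i] <- cell
      next
    }
    value <- suppressWarnings(as.numeric(cell))
    if (is.na(value)) {
      stop_schema(sprintf("Unparseable label cell '%s' in row %d.", cell, i))
    }
    labeled[i] <- value
  }
  list(labeled = labeled, note = note)
}

#' Read a brand panel from a delimited file
#'
#' Expects a comma-delimited UTF-8 file with a header row naming at least
#' `brand`, `water_type`, `labeled`, `measured`, `sd`. Label cells may hold
#' a number, `NL`/empty (unlabeled) or a bound string such as `< 2`, which
#' is preserved in `label_note` but never used numerically.
#'
#' @param path File path.
#' @param contaminant A [contaminant_spec()] describing what the file measures.
#' @return A `brand_panel` tibble; row order follows the file.
#' @export
#' @examples
#' path <- system.file("extdata", "table2_fluoride.csv", package = "watrisk")
#' read_panel(path, water_contaminants()$fluoride)
read_panel <- function(path, contaminant) {
  if (!file.exists(path)) stop_validation(sprintf("File not found: %s.", path))
  raw <- read_csv(path, col_types = cols(.default = col_character()),
                  progress = FALSE)
  required <- c("brand", "water_type", "labeled", "measured", "sd")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop_schema(sprintf("Panel file %s is missing required column(s): %s.",
                        basename(path), paste(missing, collapse = ", ")))
  }
  lab <- parse_label(raw$labeled)
  to_num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & trimws(raw[[col]]) != "")
    if (length(bad) > 0) {
      stop_schema(sprintf("Unparseable %s value '%s' in row %d of %s.",
                          col, raw[[col]][bad[1]], bad[1], basename(path)))
    }
    v
  }
  brand_panel(
    tibble(
      brand = raw$brand,
      water_type = raw$water_type,
      labeled = lab$labeled,
      label_note = lab$note,
      measured = to_num("measured"),
      sd = to_num("sd")
    ),
    contaminant
  )
}

#' Write a brand panel to a delimited file
#'
#' Inverse of [read_panel()]: numeric labels are written at full precision,
#' unlabeled brands as `NL`, and bound labels as their preserved
#' `label_note` string, so a write/read round trip reproduces the panel.
#'
#' @param panel A `brand_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  spec <- panel_contaminant(panel)
  fmt <- function(x) sprintf("%.17g", x)
  label_out <- ifelse(
    !is.na(panel$label_note), panel$label_note,
    ifelse(is.na(panel$labeled), "NL", fmt(panel$labeled))
  )
  out <- tibble(
    brand = panel$brand,
    water_type = panel$water_type,
    labeled = label_out,
    measured = fmt(panel$measured),
    sd = fmt(panel$sd)
  )
  write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Summarise a concentration panel
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator), minimum
#' and maximum of the measured concentrations, in mg/L. With a single
#' record the sample SD is undefined and reported as `NA`.
#'
#' @param panel A `brand_panel`.
#' @return One-row tibble: `contaminant`, `n`, `mean`, `sd`, `min`, `max`.
#' @export
#' @examples
#' load_fixture("fluoride_table2") |> panel_summary()
panel_summary <- function(panel) {
  spec <- panel_contaminant(panel)
  if (nrow(panel) == 0) {
    stop_empty(sprintf("Panel for '%s' has no records to summarise.", spec$name))
  }
  tibble(
    contaminant = spec$name,
    n = nrow(panel),
    mean = mean(panel$measured),
    sd = if (nrow(panel) > 1) sd(panel$measured) else NA_real_,
    min = min(panel$measured),
    max = max(panel$measured)
  )
}

#' Screen a panel against guideline bounds
#'
#' Assigns every brand exactly one range flag — `below_low`, `within` or
#' `above_high` — relative to the contaminant's guideline bounds (bounds
#' inclusive on the `within` side; a one-sided guideline leaves the absent
#' side unflaggable). Independently flags brands whose bottle declared no
#' label value at all (`NL`; bound-style labels such as `"< 2"` count as
#' labeled).
#'
#' @param panel A `brand_panel` whose contaminant has at least one
#'   guideline bound.
#' @return Tibble with one row per brand (`brand`, `water_type`,
#'   `measured`, `labeled`, `unlabeled`, `flag`) carrying a `counts`
#'   attribute: a tibble of per-flag counts plus the unlabeled count.
#' @export
#' @examples
#' scr <- guideline_screen(load_fixture("fluoride_table2"))
#' attr(scr, "counts")
guideline_screen <- function(panel) {
  spec <- panel_contaminant(panel)
  lo <- spec$guideline_low
  hi <- spec$guideline_high
  if (is.na(lo) && is.na(hi)) {
    stop_config(sprintf("Contaminant '%s' has no guideline bounds to screen against.", spec$name))
  }
  flag <- rep("within", nrow(panel))
  if (!is.na(lo)) flag[panel$measured < lo] <- "below_low"
  if (!is.na(hi)) flag[panel$measured > hi] <- "above_high"
  out <- tibble(
    brand = panel$brand,
    water_type = panel$water_type,
    measured = panel$measured,
    labeled = panel$labeled,
    unlabeled = is.na(panel$labeled) & is.na(panel$label_note),
    flag = factor(flag, levels = c("below_low", "within", "above_high"))
  )
  counts <- tibble(
    contaminant = spec$name,
    below_low = sum(out$flag == "below_low"),
    within = sum(out$flag == "within"),
    above_high = sum(out$flag == "above_high"),
    unlabeled = sum(out$unlabeled)
  )
  attr(out, "counts") <- counts
  attr(out, "contaminant") <- spec
  out
}

#' Load a packaged fixture
#'
#' Packaged study data: the 22-brand measured fluoride and nitrate panels
#' (with declared label values as printed, including `NL` and bound-style
#' entries) and the four-age-group exposure parameter set.
#'
#' @param name One of `"fluoride_table2"`, `"nitrate_table2"`,
#'   `"exposure_table1"`.
#' @return A `brand_panel` for the concentration fixtures; an
#'   [exposure_profiles()] tibble for the exposure fixture.
#' @export
#' @examples
#' load_fixture("exposure_table1")
load_fixture <- function(name) {
  file_of <- c(
    fluoride_table2 = "table2_fluoride.csv",
    nitrate_table2 = "table2_nitrate.csv",
    exposure_table1 = "table1_exposure.csv"
  )
  if (!is.character(name) || length(name) != 1 || !name %in% names(file_of)) {
    stop_lookup(sprintf("Unknown fixture '%s'; choose one of: %s.",
                        paste(name, collapse = ", "),
                        paste(names(file_of), collapse = ", ")))
  }
  path <- system.file("extdata", file_of[[name]], package = "watrisk", mustWork = TRUE)
  if (name == "exposure_table1") {
    raw <- read_csv(path, col_types = cols(group = col_character(), .default = col_double()),
                    progress = FALSE)
    return(exposure_profiles(raw))
  }
  spec <- switch(name,
    fluoride_table2 = water_contaminants()$fluoride,
    nitrate_table2 = water_contaminants()$nitrate
  )
  read_panel(path, spec)
}
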