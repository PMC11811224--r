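# Independent oracles kept deliberately naive: loops and two-pass formulas,
# no reuse of package internals beyond constructors.

brute_mean_sd <- function(x) {
  n <- length(x)
  m <- 0
  for (v in x) m <- m + v / n
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  list(mean = m, sd = if (n > 1) sqrt(ss / (n - 1)) else NA_real_)
}

# Cell-by-cell risk table via nested loops over data frames of raw numbers.
brute_risk_cells <- function(conc_by_contaminant, rfds, profiles) {
  rows <- list()
  for (cont in names(conc_by_contaminant)) {
    conc <- conc_by_contaminant[[cont]]
    for (g in seq_len(nrow(profiles))) {
      p <- profiles[g, ]
      for (b in seq_along(conc$measured)) {
        e <- conc$measured[b] * p$ir * p$ef * p$ed / (p$bw * p$at)
        rows[[length(rows) + 1]] <- data.frame(
          brand = conc$brand[b], group = p$group, contaminant = cont,
          edi = e, hq = e / rfds[[cont]]
        )
      }
    }
  }
  do.call(rbind, rows)
}

# Percentile by the explicit rank formula 1 + (n - 1) * q.
brute_percentile <- function(x, q) {
  s <- sort(x)
  r <- 1 + (length(s) - 1) * q
  lo <- floor(r)
  hi <- ceiling(r)
  s[lo] + (r - lo) * (s[hi] - s[lo])
}

# E[1/X] for a (possibly truncated) normal spec, by numeric integration.
trunc_norm_inv_mean <- function(spec) {
  stopifnot(spec$kind == "normal")
  lo <- if (is.na(spec$lower)) -Inf else spec$lower
  hi <- if (is.na(spec$upper)) Inf else spec$upper
  dens <- function(x) dnorm(x, spec$p1, spec$p2)
  mass <- integrate(dens, lo, hi)$value
  integrate(function(x) dens(x) / x, lo, hi)$value / mass
}

# Small panel straight from vectors.
make_panel <- function(measured, contaminant = water_contaminants()$fluoride,
                       labeled = NA_real_, sd = 0.01, brands = NULL) {
  n <- length(measured)
  brand_panel(
    tibble::tibble(
      brand = brands %||% paste0("B", seq_len(n)),
      water_type = "DW",
      labeled = rep_len(labeled, n),
      label_note = NA_character_,
      measured = measured,
      sd = rep_len(sd, n)
    ),
    contaminant
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fixture_panels <- function() {
  list(fluoride = load_fixture("fluoride_table2"),
       nitrate = load_fixture("nitrate_table2"))
}

infants_profile <- function() {
  dplyr::filter(load_fixture("exposure_table1"), group == "infants")
}
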