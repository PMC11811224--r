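#' Ground truth for a synthetic concentration panel
#'
#' Parameters of the generating process for [generate_panel()]: a
#' lognormal concentration law (log-mean `p1`, log-SD `p2`), a detection
#' floor below which measurements are censored up, and a probability that
#' a brand ships with no declared label value. The defaults emulate the
#' packaged fluoride survey: 22 right-skewed brand means around 0.3 mg/L
#' with 8 of 22 brands unlabeled.
#'
#' @param p1 Log-mean of the generating lognormal (default -1.3).
#' @param p2 Log-SD, `>= 0` (default 0.85).
#' @param n_brands Number of brands (default 22).
#' @param floor Detection floor, mg/L (default 0.005).
#' @param label_missing_rate Probability a brand is unlabeled (default 8/22).
#' @param seed Integer seed making the panel reproducible.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(p1 = -1.3, p2 = 0.85, n_brands = 22,
                         floor = 0.005, label_missing_rate = 8 / 22,
                         seed = 1L) {
  if (!is.finite(p2) || p2 < 0) stop_validation("`p2` must be non-negative.")
  if (!is.finite(n_brands) || n_brands < 1) stop_validation("`n_brands` must be >= 1.")
  if (!is.finite(label_missing_rate) || label_missing_rate < 0 || label_missing_rate > 1) {
    stop_validation("`label_missing_rate` must lie in [0, 1].")
  }
  if (!is.finite(floor) || floor <= 0) stop_validation("`floor` must be positive.")
  structure(
    list(p1 = as.double(p1), p2 = as.double(p2), n_brands = as.integer(n_brands),
         floor = as.double(floor), label_missing_rate = as.double(label_missing_rate),
         seed = as.integer(seed)),
    class = "ground_truth"
  )
}

#' Generate a synthetic brand panel with known ground truth
#'
#' Draws brand mean concentrations from `lognormal(p1, p2)` and censors
#' them up to the detection floor; replicate SDs are `|N(0, 0.05 * mean)|`
#' (5% relative replicate noise); each brand carries a declared label with
#' probability `1 - label_missing_rate`, drawn as
#' `measured * lognormal(0, 0.2)` to emulate label/measurement
#' discrepancy. Water types are DW/MW at the packaged survey's 14:8 ratio.
#' Fully reproducible from `truth$seed`.
#'
#' @param truth A [ground_truth()].
#' @param contaminant A [contaminant_spec()] (defaults to the built-in
#'   fluoride definition).
#' @return A `brand_panel` carrying `truth` as attribute `ground_truth`.
#' @export
#' @examples
#' generate_panel(ground_truth(seed = 42))
generate_panel <- function(truth, contaminant = water_contaminants()$fluoride) {
  if (!inherits(truth, "ground_truth")) stop_validation("`truth` must be a ground_truth.")
  n <- truth$n_brands
  set.seed(derive_seed(truth$seed, "panel", contaminant$name))
  measured <- pmax(rlnorm(n, truth$p1, truth$p2), truth$floor)
  sd_rep <- abs(rnorm(n, 0, 0.05 * measured))
  has_label <- runif(n) >= truth$label_missing_rate
  labeled <- ifelse(has_label, measured * rlnorm(n, 0, 0.2), NA_real_)
  water_type <- sample(c("DW", "MW"), n, replace = TRUE, prob = c(14, 8) / 22)
  panel <- brand_panel(
    tibble(
      brand = paste0("B", seq_len(n)),
      water_type = water_type,
      labeled = labeled,
      label_note = NA_character_,
      measured = measured,
      sd = sd_rep
    ),
    contaminant
  )
  attr(panel, "ground_truth") <- truth
  panel
}
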