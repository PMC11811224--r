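# Classed conditions: every error the package raises carries a subclass of
# "watrisk_error" so callers (and the pipeline driver) can branch on the
# failure kind rather than on message text.
abort_watrisk <- function(message, class, ...) {
  abort(message, class = c(class, "watrisk_error"), ...)
}

stop_schema     <- function(msg, ...) abort_watrisk(msg, "watrisk_schema_error", ...)
stop_validation <- function(msg, ...) abort_watrisk(msg, "watrisk_validation_error", ...)
stop_domain     <- function(msg, ...) abort_watrisk(msg, "watrisk_domain_error", ...)
stop_config     <- function(msg, ...) abort_watrisk(msg, "watrisk_config_error", ...)
stop_empty      <- function(msg, ...) abort_watrisk(msg, "watrisk_empty_error", ...)
stop_fit        <- function(msg, ...) abort_watrisk(msg, "watrisk_fit_error", ...)
stop_sampling   <- function(msg, ...) abort_watrisk(msg, "watrisk_sampling_error", ...)
stop_degenerate <- function(msg, ...) abort_watrisk(msg, "watrisk_degenerate_error", ...)
stop_lookup     <- function(msg, ...) abort_watrisk(msg, "watrisk_lookup_error", ...)

#' Round half away from zero
#'
#' Display rounding used in reports: halves round up (`0.125 -> 0.13`),
#' unlike [base::round()]'s round-half-even. Internal computation always
#' keeps full precision; this is applied only when printing report tables.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_up(c(0.125, 0.635), 2)
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Deterministic sub-stream seeds: hash the root seed together with string
# tags (variable name, group, contaminant) into [1, 2^31 - 2]. Keeps the
# IR/BW streams identical across contaminants for shared-draw HI while the
# concentration stream differs per contaminant.
derive_seed <- function(seed, ...) {
  tags <- paste(c(...), collapse = "\r")
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (code in utf8ToInt(tags)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h %% (m - 2L) + 1L)
}

# Largest-remainder rounding: percentages summing to 100 keep summing to
# exactly 100 after rounding to `digits` decimals.
largest_remainder <- function(p, digits = 1) {
  if (length(p) == 0) return(numeric(0))
  scale <- 10^digits
  units <- p * scale
  base <- floor(units)
  deficit <- round(100 * scale - sum(base))
  extra <- integer(length(p))
  if (deficit > 0) {
    take <- order(units - base, decreasing = TRUE)[seq_len(deficit)]
    extra[take] <- 1L
  }
  (base + extra) / scale
}
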