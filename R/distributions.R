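#' Specify a marginal distribution
#'
#' Marginals used by the Monte Carlo engine: `lognormal` (p1 = log-mean,
#' p2 = log-SD), `normal` (p1 = mean, p2 = SD) or `point` (p1 = the value,
#' p2 = 0). Optional truncation bounds restrict the support; sampling
#' redraws values outside `[lower, upper]` (bounds inclusive).
#'
#' @param kind `"lognormal"`, `"normal"` or `"point"`.
#' @param p1 Location-like parameter.
#' @param p2 Scale-like parameter, `>= 0`.
#' @param lower,upper Optional truncation bounds, `lower < upper`.
#' @return A `dist_spec` object.
#' @export
#' @examples
#' dist_normal(7.5, 1.125, lower = 1.5)
dist_spec <- function(kind = c("lognormal", "normal", "point"),
                      p1, p2 = 0, lower = NA_real_, upper = NA_real_) {
  kind <- match.arg(kind)
  p1 <- as.double(p1); p2 <- as.double(p2)
  lower <- as.double(lower); upper <- as.double(upper)
  if (length(p1) != 1 || !is.finite(p1)) stop_validation("`p1` must be a single finite number.")
  if (length(p2) != 1 || !is.finite(p2) || p2 < 0) {
    stop_validation("`p2` must be a single non-negative number.")
  }
  if (kind == "point" && p2 != 0) stop_validation("A point distribution has p2 = 0.")
  if (!is.na(lower) && !is.na(upper) && lower >= upper) {
    stop_validation(sprintf("Truncation bounds inverted: lower %g >= upper %g.", lower, upper))
  }
  if (kind == "lognormal" && !is.na(upper) && upper <= 0) {
    stop_validation("Lognormal support is strictly positive; upper bound must be > 0.")
  }
  structure(list(kind = kind, p1 = p1, p2 = p2, lower = lower, upper = upper),
            class = "dist_spec")
}

#' @rdname dist_spec
#' @param meanlog,sdlog Lognormal log-scale parameters.
#' @export
dist_lognormal <- function(meanlog, sdlog, lower = NA_real_, upper = NA_real_) {
  dist_spec("lognormal", meanlog, sdlog, lower, upper)
}

#' @rdname dist_spec
#' @param mean,sd Normal mean and standard deviation.
#' @export
dist_normal <- function(mean, sd, lower = NA_real_, upper = NA_real_) {
  dist_spec("normal", mean, sd, lower, upper)
}

#' @rdname dist_spec
#' @param value The constant a point distribution always returns.
#' @export
dist_point <- function(value) {
  dist_spec("point", value, 0)
}

#' @export
print.dist_spec <- function(x, ...) {
  bounds <- if (!is.na(x$lower) || !is.na(x$upper)) {
    sprintf(" truncated to [%s, %s]",
            ifelse(is.na(x$lower), "-Inf", format(x$lower)),
            ifelse(is.na(x$upper), "Inf", format(x$upper)))
  } else ""
  cat(sprintf("<dist_spec> %s(p1 = %g, p2 = %g)%s\n", x$kind, x$p1, x$p2, bounds))
  invisible(x)
}

#' Mean of a distribution specification
#'
#' Closed-form expectation for untruncated specs (`exp(p1 + p2^2/2)` for
#' lognormal, `p1` for normal and point); numeric integration over the
#' truncated density otherwise.
#'
#' @param spec A [dist_spec()].
#' @return The distribution mean.
#' @export
dist_mean <- function(spec) {
  lo <- if (is.na(spec$lower)) -Inf else spec$lower
  hi <- if (is.na(spec$upper)) Inf else spec$upper
  if (spec$kind == "point") return(spec$p1)
  if (spec$kind == "lognormal" && lo <= 0 && !is.finite(hi)) {
    return(exp(spec$p1 + spec$p2^2 / 2))
  }
  if (spec$kind == "normal" && !is.finite(lo) && !is.finite(hi)) return(spec$p1)
  dens <- function(x) {
    switch(spec$kind,
      normal = dnorm(x, spec$p1, spec$p2),
      lognormal = stats::dlnorm(x, spec$p1, spec$p2)
    )
  }
  mass <- integrate(dens, max(lo, if (spec$kind == "lognormal") 0 else -Inf), hi)$value
  integrate(function(x) x * dens(x), max(lo, if (spec$kind == "lognormal") 0 else -Inf),
            hi)$value / mass
}

#' Fit a lognormal distribution by log moments
#'
#' Parameterises concentrations as lognormal with `p1` the mean of the
#' natural logs and `p2` their sample standard deviation (n - 1
#' denominator). Values below the detection floor are clamped up to the
#' floor before logging — the detection-limit convention that keeps
#' near-zero readings from dominating the log scale — and the number of
#' clamped values is reported as attribute `n_clamped`.
#'
#' @param values Positive concentrations, mg/L.
#' @param floor Detection floor, mg/L (default 0.005).
#' @return A lognormal [dist_spec()] with attributes `n_clamped` and `n`.
#' @export
#' @examples
#' fit_lognormal(load_fixture("fluoride_table2")$measured)
fit_lognormal <- function(values, floor = 0.005) {
  if (!is.numeric(floor) || length(floor) != 1 || !is.finite(floor) || floor <= 0) {
    stop_config("`floor` must be a single positive number.")
  }
  values <- values[is.finite(values)]
  if (any(values < 0)) stop_domain("Concentrations must be non-negative.")
  if (length(values) < 2) stop_fit("Need at least 2 usable values to fit a lognormal.")
  n_clamped <- sum(values < floor)
  logs <- log(pmax(values, floor))
  spec <- dist_lognormal(mean(logs), sd(logs))
  attr(spec, "n_clamped") <- n_clamped
  attr(spec, "n") <- length(values)
  spec
}

#' Draw from a distribution specification
#'
#' Point specs return a constant vector; normal and lognormal specs draw
#' from the named distribution. Truncation is enforced by rejection:
#' out-of-bounds values are redrawn until `n` in-bounds values (bounds
#' inclusive) are collected. If fewer than 0.01% of a probe batch of
#' draws land in bounds, the truncation interval is treated as carrying
#' negligible mass and sampling errors out.
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws, `>= 1`.
#' @param seed Optional integer; when given, seeds the RNG so the draw is
#'   reproducible.
#' @return Numeric vector of length `n`.
#' @export
#' @examples
#' sample_dist(dist_point(2.5), 4)
sample_dist <- function(spec, n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    stop_validation("`n` must be a single count >= 1.")
  }
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (spec$kind == "point") {
    value <- spec$p1
    if (!is.na(spec$lower) && value < spec$lower ||
        !is.na(spec$upper) && value > spec$upper) {
      stop_sampling("Point value lies outside its truncation bounds.")
    }
    return(rep(value, n))
  }
  draw <- switch(spec$kind,
    normal = function(m) rnorm(m, spec$p1, spec$p2),
    lognormal = function(m) rlnorm(m, spec$p1, spec$p2)
  )
  lo <- if (is.na(spec$lower)) -Inf else spec$lower
  hi <- if (is.na(spec$upper)) Inf else spec$upper
  out <- numeric(0)
  probe <- max(n, 1000L)
  first <- draw(probe)
  keep <- first[first >= lo & first <= hi]
  if (length(keep) / probe < 1e-4) {
    stop_sampling(sprintf(
      "Truncation interval [%g, %g] carries negligible mass (acceptance %.2g%% over %d probe draws).",
      lo, hi, 100 * length(keep) / probe, probe
    ))
  }
  out <- keep[seq_len(min(n, length(keep)))]
  while (length(out) < n) {
    batch <- draw(probe)
    batch <- batch[batch >= lo & batch <= hi]
    out <- c(out, batch[seq_len(min(n - length(out), length(batch)))])
  }
  out
}
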