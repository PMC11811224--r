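point_scenario <- function(c0 = 0.45, group = "infants",
                           ir = 0.7, bw = 7.5, ef = 365, ed = 1.5, at = 547.5,
                           n_trials = 50, seed = 1) {
  scenario_spec(
    contaminant = water_contaminants()$fluoride,
    group = group,
    c_dist = dist_point(c0), ir_dist = dist_point(ir), bw_dist = dist_point(bw),
    ef = ef, ed = ed, at = at, n_trials = n_trials, seed = seed
  )
}

test_that("all-point scenarios collapse to the deterministic engine exactly", {
  sim <- simulate_hq(point_scenario())
  det <- hazard_quotient(edi(0.45, infants_profile()), 0.06)
  expect_identical(unique(sim$trials), det)
  expect_equal(det, 0.70, tolerance = 1e-12)
  expect_equal(sim$sd, 0)
  expect_identical(percentile(sim, 0.95), det)
  expect_identical(unname(sim$percentiles), rep(det, 3))
})

test_that("simulated HQ mean matches the lognormal closed form", {
  sc <- scenario_spec(
    contaminant = water_contaminants()$fluoride, group = "infants",
    c_dist = dist_lognormal(-1.2, 0.5),
    ir_dist = dist_point(0.7), bw_dist = dist_point(7.5),
    ef = 365, ed = 1.5, at = 547.5, n_trials = 20000, seed = 11
  )
  sim <- simulate_hq(sc)
  expected <- exp(-1.2 + 0.5^2 / 2) * 0.7 / (7.5 * 0.06)
  mc_se <- sim$sd / sqrt(length(sim$trials))
  expect_lt(abs(sim$mean - expected), 3 * mc_se)
})

test_that("identical scenarios reproduce bitwise-identical results", {
  sc <- default_scenario(load_fixture("fluoride_table2"), infants_profile(),
                         n_trials = 2000, seed = 99)
  s1 <- simulate_hq(sc)
  s2 <- simulate_hq(sc)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$inputs, s2$inputs)
})

test_that("simulate_hi shares person draws and sums HQ trials exactly", {
  profs <- load_fixture("exposure_table1")
  inf <- profs[profs$group == "infants", ]
  scs <- list(
    default_scenario(load_fixture("fluoride_table2"), inf, n_trials = 3000, seed = 7),
    default_scenario(load_fixture("nitrate_table2"), inf, n_trials = 3000, seed = 7)
  )
  hi <- simulate_hi(scs)
  # one person per trial: identical IR and BW streams across contaminants
  expect_identical(hi$components[[1]]$inputs$IR, hi$components[[2]]$inputs$IR)
  expect_identical(hi$components[[1]]$inputs$BW, hi$components[[2]]$inputs$BW)
  # concentrations drawn independently
  expect_false(identical(hi$components[[1]]$inputs$C, hi$components[[2]]$inputs$C))
  # HI is the elementwise sum of the component HQ vectors
  expect_identical(hi$trials, hi$components[[1]]$trials + hi$components[[2]]$trials)
})

test_that("point-valued simulate_hi equals the deterministic HI", {
  f <- point_scenario(c0 = 0.45)
  n <- point_scenario(c0 = 2.91)
  n$contaminant <- water_contaminants()$nitrate
  hi <- simulate_hi(list(f, n))
  inf <- infants_profile()
  det <- hazard_index(c(hazard_quotient(edi(0.45, inf), 0.06),
                        hazard_quotient(edi(2.91, inf), 1.6)))
  expect_equal(unique(hi$trials), det, tolerance = 1e-12)
})

test_that("two identical lognormal scenarios double the HQ mean", {
  base <- scenario_spec(
    contaminant = water_contaminants()$fluoride, group = "infants",
    c_dist = dist_lognormal(-1.2, 0.5),
    ir_dist = dist_point(0.7), bw_dist = dist_point(7.5),
    ef = 365, ed = 1.5, at = 547.5, n_trials = 20000, seed = 21
  )
  other <- base
  other$contaminant <- contaminant_spec("fluoride_b", rfd = 0.06)
  hi <- simulate_hi(list(base, other))
  single <- simulate_hq(base)
  mc_se <- hi$sd / sqrt(length(hi$trials))
  expect_lt(abs(hi$mean - 2 * single$mean), 3 * mc_se)
})

test_that("simulate_hi validates group and stream agreement", {
  a <- point_scenario(group = "infants")
  b <- point_scenario(group = "adults")
  expect_error(simulate_hi(list(a, b)), class = "watrisk_validation_error")
  c2 <- point_scenario()
  c2$ir_dist <- dist_lognormal(log(0.7), 0.25)
  expect_error(simulate_hi(list(point_scenario(), c2)),
               class = "watrisk_validation_error")
})

test_that("percentile uses the 1 + (n-1)q interpolation convention", {
  expect_equal(percentile(c(1, 2, 3, 4, 5), 0.5), 3)
  expect_equal(percentile(c(1, 2, 3, 4), 0.95), 3.85)
  expect_equal(percentile(rep(2.2, 10), 0.3), 2.2)
  expect_error(percentile(1:5, 0), class = "watrisk_domain_error")
  expect_error(percentile(1:5, 1.2), class = "watrisk_domain_error")

  set.seed(31)
  for (i in 1:5) {
    x <- rlnorm(50 + i)
    qs <- runif(4, 0.01, 0.99)
    for (q in qs) expect_equal(percentile(x, q), brute_percentile(x, q))
    sorted_q <- sort(qs)
    vals <- vapply(sorted_q, function(q) percentile(x, q), double(1))
    expect_true(all(diff(vals) >= 0))  # monotone in q
  }
})

test_that("default infant scenarios put the 95th percentile highest", {
  profs <- load_fixture("exposure_table1")
  p95 <- vapply(seq_len(nrow(profs)), function(g) {
    sim <- simulate_hq(default_scenario(load_fixture("fluoride_table2"),
                                        profs[g, ], n_trials = 4000, seed = 13))
    percentile(sim, 0.95)
  }, double(1))
  expect_equal(which.max(p95), 1L)  # infants
})
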