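test_that("edi reproduces hand arithmetic and degenerate inputs", {
  inf <- infants_profile()
  # B15 fluoride for infants: 0.70 * 0.7 / 7.5 since AT = ED * EF
  expect_equal(edi(0.70, inf), 0.70 * 0.7 / 7.5, tolerance = 1e-12)
  expect_equal(edi(0, inf), 0)
  expect_error(edi(-0.1, inf), class = "watrisk_domain_error")
  expect_error(edi(0.5, list(ir = 1, ef = 365)), class = "watrisk_schema_error")
  expect_error(edi(0.5, list(ir = 1, ef = 365, ed = 1, bw = -5, at = 365)),
               class = "watrisk_validation_error")
})

test_that("edi is linear in concentration and AT-consistent for all profiles", {
  profs <- load_fixture("exposure_table1")
  for (g in seq_len(nrow(profs))) {
    p <- profs[g, ]
    expect_equal(edi(0.64, p), 0.64 * p$ir / p$bw, tolerance = 1e-14)
    for (c0 in c(0.01, 0.32, 4.96)) {
      expect_equal(edi(2 * c0, p), 2 * edi(c0, p), tolerance = 1e-14)
    }
  }
})

test_that("hazard_quotient matches printed cells and guards its inputs", {
  inf <- infants_profile()
  expect_equal(round_half_up(hazard_quotient(edi(0.45, inf), 0.06)), 0.70)
  expect_equal(round_half_up(hazard_quotient(edi(0.70, inf), 0.06)), 1.09)
  expect_equal(hazard_quotient(0.06, 0.06), 1)
  expect_error(hazard_quotient(0.1, 0), class = "watrisk_config_error")
  expect_error(hazard_quotient(0.1, -1), class = "watrisk_config_error")
})

test_that("hazard_index sums hazard quotients", {
  expect_equal(hazard_index(c(0, 0)), 0)
  expect_equal(hazard_index(0.5), 0.5)
  inf <- infants_profile()
  hq_f <- hazard_quotient(edi(0.71, inf), 0.06)
  hq_n <- hazard_quotient(edi(2.78, inf), 1.6)
  expect_equal(hazard_index(c(hq_f, hq_n)), 1.266611, tolerance = 1e-6)
  expect_error(hazard_index(numeric(0)), class = "watrisk_empty_error")
})

test_that("risk_table has full cardinality and pairs HI by brand id", {
  rt <- risk_table(fixture_panels(), load_fixture("exposure_table1"))
  expect_equal(nrow(rt$cells), 22 * 4 * 2)
  expect_equal(nrow(rt$hi), 22 * 4)

  inf_f <- dplyr::filter(rt$cells, group == "infants", contaminant == "fluoride")
  expect_setequal(inf_f$brand[inf_f$hq > 1], c("B3", "B15"))

  # HI additivity: every HI cell equals the sum of its HQ cells exactly
  check <- rt$cells |>
    dplyr::summarise(s = sum(hq), .by = c(brand, group)) |>
    dplyr::left_join(rt$hi, by = c("brand", "group"))
  expect_identical(check$s, check$hi)

  # pairing is by brand id even when panels arrive in different row orders
  shuffled <- fixture_panels()
  reordered <- shuffled$nitrate[rev(seq_len(nrow(shuffled$nitrate))), ]
  attr(reordered, "contaminant") <- panel_contaminant(shuffled$nitrate)
  class(reordered) <- class(shuffled$nitrate)
  rt2 <- risk_table(list(fluoride = shuffled$fluoride, nitrate = reordered),
                    load_fixture("exposure_table1"))
  expect_equal(
    dplyr::arrange(rt$hi, brand, group),
    dplyr::arrange(rt2$hi, brand, group)
  )
})

test_that("mismatched brand sets fail with the symmetric difference", {
  p1 <- make_panel(c(0.1, 0.2), brands = c("B1", "B2"))
  p2 <- make_panel(c(0.3, 0.4), contaminant = water_contaminants()$nitrate,
                   brands = c("B2", "B9"))
  err <- expect_error(
    risk_table(list(fluoride = p1, nitrate = p2), load_fixture("exposure_table1")),
    class = "watrisk_validation_error"
  )
  expect_match(conditionMessage(err), "B1")
  expect_match(conditionMessage(err), "B9")
})

test_that("HQ ordering over groups follows ingestion rate per body weight", {
  profs <- load_fixture("exposure_table1")
  for (c0 in c(0.05, 0.32, 0.71, 4.96)) {
    hqs <- vapply(seq_len(nrow(profs)), function(g) {
      hazard_quotient(edi(c0, profs[g, ]), 0.06)
    }, double(1))
    expect_true(all(diff(hqs) < 0))  # infants > children > teenagers > adults
  }
})

test_that("risk_table matches a brute-force loop oracle cell for cell", {
  profs <- load_fixture("exposure_table1")
  for (seed in c(5, 6)) {
    fl <- generate_panel(ground_truth(n_brands = 9, seed = seed))
    nt <- generate_panel(ground_truth(p1 = 0.6, p2 = 0.7, n_brands = 9, seed = seed + 100),
                         contaminant = water_contaminants()$nitrate)
    rt <- risk_table(list(fluoride = fl, nitrate = nt), profs)
    oracle <- brute_risk_cells(
      list(fluoride = fl, nitrate = nt),
      rfds = c(fluoride = 0.06, nitrate = 1.6),
      profiles = profs
    )
    joined <- dplyr::inner_join(
      rt$cells, oracle,
      by = c("brand", "group", "contaminant"), suffix = c("", "_oracle")
    )
    expect_equal(nrow(joined), nrow(rt$cells))
    expect_equal(joined$edi, joined$edi_oracle, tolerance = 1e-12)
    expect_equal(joined$hq, joined$hq_oracle, tolerance = 1e-12)
  }
})

test_that("group_summary collapses correctly for a single-brand panel", {
  profs <- load_fixture("exposure_table1")
  rt <- risk_table(
    list(fluoride = make_panel(0.45),
         nitrate = make_panel(2.91, contaminant = water_contaminants()$nitrate)),
    profs
  )
  gs <- group_summary(rt)
  expect_equal(gs$hq$hq_mean, gs$hq$hq_min)
  expect_equal(gs$hq$hq_mean, gs$hq$hq_max)
  expect_equal(gs$hi$hi_mean, gs$hi$hi_max)
  expect_equal(gs$hq$group[1:2], c("infants", "infants"))  # profile order kept
})
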