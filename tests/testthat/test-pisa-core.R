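test_that("coefficient table matches the published values (checksum + spot checks)", {
  tab <- pisa_coefficients()
  expect_equal(nrow(tab), 14)
  expect_equal(sum(tab$slope), 313.26, tolerance = 1e-12)
  mxci <- tab[tab$jaw == "maxilla" & tab$tooth_class == "central_incisor", ]
  expect_equal(mxci$slope, 16.96)
  expect_equal(mxci$a1, 12.3905)
  expect_equal(mxci$a6, -0.0003083)
  expect_true(all(tab$slope > 0))
})

test_that("worked PESA examples evaluate correctly", {
  expect_equal(pesa_area("maxilla", "central_incisor", 5, "japanese"), 84.8)
  expect_equal(round_half_up(pesa_area("maxilla", "central_incisor", 5, "original"), 1), 88.9)
  expect_equal(pesa_area("maxilla", "first_molar", 4, "japanese"), 153.32)
  expect_equal(pesa_area("maxilla", "central_incisor", 1, "original"),
               13.0652, tolerance = 1e-3 / 13)
  # no intercept: zero depth gives zero area for every type and version
  tt <- tooth_types()
  for (v in c("japanese", "original")) {
    expect_equal(pesa_area(tt$jaw, tt$tooth_class, rep(0, 14), v), rep(0, 14))
  }
  expect_error(pesa_area("maxilla", "central_incisor", -1, "japanese"),
               class = "pisacalc_negative_ppd")
  expect_error(pesa_area("maxilla", "third_molar", 3, "japanese"),
               class = "pisacalc_unregistered_tooth")
  expect_warning(pesa_area("maxilla", "canine", 12, "japanese"), "extrapolated")
})

test_that("japanese version is homogeneous in depth", {
  tt <- tooth_types()
  withr::with_seed(21, {
    for (i in 1:10) {
      x <- stats::runif(1, 0, 10)
      lam <- stats::runif(1, 0, 10 / max(x, 1))
      base <- pesa_area(tt$jaw, tt$tooth_class, rep(x, 14), "japanese")
      scaled <- pesa_area(tt$jaw, tt$tooth_class, rep(lam * x, 14), "japanese")
      expect_equal(scaled, lam * base, tolerance = 1e-12)
    }
  })
})

test_that("term-by-term polynomial evaluation agrees with the package evaluator", {
  tab <- pisa_coefficients()
  for (i in seq_len(nrow(tab))) {
    for (x in seq(0.5, 10, by = 0.5)) {
      expect_equal(
        pesa_area(tab$jaw[i], tab$tooth_class[i], x, "original"),
        naive_poly_pesa(tab[i, ], x),
        tolerance = 1e-9
      )
    }
  }
})

test_that("tooth_pisa is the bleeding-weighted area with valid bounds", {
  expect_equal(tooth_pisa(84.8, 1), 84.8)
  expect_equal(tooth_pisa(84.8, 0), 0)
  expect_equal(tooth_pisa(84.8, 2 / 6), 28.2667, tolerance = 1e-3 / 28)
  expect_error(tooth_pisa(-1, 0.5), class = "pisacalc_bad_pesa")
  expect_error(tooth_pisa(10, 1.2), class = "pisacalc_bad_bop_frac")
})

test_that("chart_areas reproduces whole-mouth totals and composes per tooth", {
  tot <- chart_totals(chart_areas(uniform_chart(3), "japanese"))
  expect_equal(round_half_up(tot$total_pisa, 1), 1879.6)

  empty <- uniform_chart(3)[0, ]
  res <- chart_areas(empty, "both")
  expect_equal(nrow(res), 0)
  expect_equal(nrow(chart_totals(res)), 0)

  one <- uniform_chart(5)[uniform_chart(5)$tooth == 11, ]
  one[paste0("bop_", c("mb", "b", "db", "dl", "l", "ml"))] <- 0
  r1 <- chart_areas(one, "japanese")
  expect_equal(r1$pesa, 84.8)
  expect_equal(r1$pisa, 0)
})

test_that("0 <= PISA <= PESA, equality exactly under full bleeding", {
  withr::with_seed(22, {
    for (i in 1:10) {
      ch <- random_chart(n_teeth = 10)
      res <- chart_areas(ch, "both")
      expect_true(all(res$pisa >= 0))
      expect_true(all(res$pisa <= res$pesa + 1e-12))
      full <- dplyr::near(res$bop_frac, 1)
      expect_equal(res$pisa[full], res$pesa[full])
    }
  })
})

test_that("mirror teeth with identical measurements score identically", {
  ch <- uniform_chart(4)
  res <- chart_areas(ch, "both")
  by_type <- res |>
    dplyr::group_by(version, jaw, tooth_class) |>
    dplyr::summarise(n = dplyr::n_distinct(round(pesa, 12)), .groups = "drop")
  expect_true(all(by_type$n == 1))
})

test_that("totals are additive over any partition of the teeth", {
  withr::with_seed(23, {
    ch <- random_chart(n_teeth = 16)
    whole <- chart_totals(chart_areas(ch, "both"))
    split_at <- sample(2:15, 1)
    part1 <- chart_totals(chart_areas(ch[1:split_at, ], "both"))
    part2 <- chart_totals(chart_areas(ch[(split_at + 1):16, ], "both"))
    merged <- dplyr::bind_rows(part1, part2) |>
      dplyr::group_by(subject_id, version) |>
      dplyr::summarise(total_pesa = sum(total_pesa), total_pisa = sum(total_pisa),
                       .groups = "drop")
    expect_equal(whole$total_pesa, merged$total_pesa)
    expect_equal(whole$total_pisa, merged$total_pisa)
  })
})

test_that("third-molar policies behave per contract", {
  ch <- uniform_chart(3)
  ch_m3 <- dplyr::bind_rows(ch, dplyr::mutate(ch[1:2, ], tooth = c(18L, 38L)))

  res <- chart_areas(ch_m3, "japanese", third_molar_policy = "exclude")
  expect_setequal(attr(res, "skipped_teeth"), c(18L, 38L))
  expect_equal(chart_totals(res)$total_pisa,
               chart_totals(chart_areas(ch, "japanese"))$total_pisa)

  expect_error(chart_areas(ch_m3, "japanese", third_molar_policy = "error"),
               "18", class = "pisacalc_third_molar")
  expect_error(chart_areas(ch_m3, "japanese", third_molar_policy = "use_registered"),
               class = "pisacalc_unregistered_tooth")

  zeros <- tibble::tibble(jaw = c("maxilla", "mandible"), slope = c(1, 1),
                          a1 = 0, a2 = 0, a3 = 0, a4 = 0, a5 = 0, a6 = 0)
  ext <- register_third_molar_coefficients(zeros)
  res0 <- chart_areas(ch_m3, "original", third_molar_policy = "use_registered",
                      coef_table = ext)
  m3 <- res0[res0$tooth_class == "third_molar", ]
  expect_equal(nrow(m3), 2)
  expect_equal(m3$pesa, c(0, 0))
  expect_equal(chart_totals(res0)$total_pisa,
               chart_totals(chart_areas(ch, "original"))$total_pisa)

  expect_error(register_third_molar_coefficients(zeros[1, ]),
               class = "pisacalc_partial_registration")
})

test_that("monotonicity scan flags only the known original-version dip", {
  viol <- check_pesa_monotonicity()
  expect_true(all(viol$version == "original"))
  expect_true(all(viol$jaw == "mandible" & viol$tooth_class == "second_molar"))
  expect_true(all(viol$x_lo >= 1.1 & viol$x_hi <= 1.5))
})
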