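test_that("signed-rank test matches hand-enumerated exact cases", {
  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))
  expect_true(res$exact)
  expect_equal(res$p_value, 2 / 32)

  expect_error(wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3)),
               class = "pisacalc_degenerate_pairs")

  # antisymmetric pairs sit at the null centre
  res2 <- wilcoxon_signed_rank(c(1, 2), c(2, 1))
  expect_equal(res2$p_value, 1)

  # zero differences are dropped before ranking
  res3 <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 7), c(2, 4, 6, 8, 10, 7))
  expect_equal(res3$n, 5)
  expect_equal(res3$p_value, 2 / 32)
})

test_that("exact path agrees with full 2^n enumeration on random tie-free pairs", {
  withr::with_seed(41, {
    for (i in 1:60) {
      n <- sample(3:12, 1)
      d <- round(stats::rnorm(n, sd = 3), 6)
      d <- d[d != 0]
      if (length(d) < 3 || anyDuplicated(abs(d))) next
      res <- wilcoxon_signed_rank(d, rep(0, length(d)))
      expect_true(res$exact)
      expect_equal(res$p_value, enumerate_signed_rank_p(d), tolerance = 1e-12)
    }
  })
})

test_that("large or tied samples switch to the corrected normal approximation", {
  withr::with_seed(42, {
    d <- round(stats::rnorm(40), 1)  # ties virtually certain
    res <- wilcoxon_signed_rank(d, rep(0, length(d)))
    expect_false(res$exact)
    expect_gte(res$p_value, 0); expect_lte(res$p_value, 1)
  })
  # ties force the approximation even for small n
  res2 <- wilcoxon_signed_rank(c(3, 4, 6), c(2, 3, 4))
  expect_false(res2$exact)
})

test_that("spearman rho equals midrank product-moment correlation", {
  expect_equal(spearman_assoc(1:6, (1:6)^2)$rho, 1)
  expect_equal(spearman_assoc(1:6, -(1:6))$rho, -1)
  expect_equal(spearman_assoc(1:4, c(1, 3, 2, 4))$rho, 0.8)

  withr::with_seed(43, {
    for (i in 1:20) {
      n <- sample(5:40, 1)
      x <- sample(round(stats::rnorm(n), 1))  # ties likely
      y <- sample(round(stats::rnorm(n), 1))
      got <- spearman_assoc(x, y)
      expect_equal(got$rho, stats::cor(rank(x), rank(y)), tolerance = 1e-12)
      # cross-check against the standard implementation's estimate
      expect_equal(got$rho,
                   unname(suppressWarnings(
                     stats::cor.test(x, y, method = "spearman")$estimate)),
                   tolerance = 1e-12)
    }
  })

  expect_warning(res <- spearman_assoc(rep(1, 5), 1:5), "undefined")
  expect_true(res$undefined)
  expect_error(spearman_assoc(1:5, 1:4), class = "pisacalc_bad_pairs")
})

test_that("standardised regression matches a closed-form normal-equations solve", {
  withr::with_seed(44, {
    dat <- tibble::tibble(
      bmi = c(21.3, 24.9, 19.8, 27.2, 23.1, 22.0),
      age = c(55, 61, 72, 48, 66, 70),
      sex01 = c(0, 1, 0, 1, 1, 0)
    )
    dat$y <- 3 + 2 * dat$bmi - 0.5 * dat$age + 4 * dat$sex01 + c(0.3, -0.2, 0.1, 0.4, -0.5, 0.1)
    got <- standardized_regression(dat, "y", c("bmi", "age", "sex01"))
    X <- cbind(1, as.matrix(dat[c("bmi", "age", "sex01")]))
    b <- solve(t(X) %*% X, t(X) %*% dat$y)[-1]
    expect_equal(got$estimate, unname(b), tolerance = 1e-8)
    sds <- apply(dat[c("bmi", "age", "sex01")], 2, sd)
    expect_equal(got$std_estimate, unname(b * sds / sd(dat$y)), tolerance = 1e-8)
  })
})

test_that("standardised regression recovers identity and null relations", {
  withr::with_seed(45, {
    n <- 400
    dat <- tibble::tibble(bmi = stats::rnorm(n, 23, 3), age = stats::rnorm(n, 65, 10),
                          sex01 = stats::rbinom(n, 1, 0.5))
    dat$y <- dat$bmi
    # outcome copies a predictor exactly; lm warns about the perfect fit
    got <- suppressWarnings(standardized_regression(dat, "y", c("bmi", "age", "sex01")))
    expect_equal(got$std_estimate[got$term == "bmi"], 1, tolerance = 1e-8)
    expect_equal(got$std_estimate[got$term != "bmi"], c(0, 0), tolerance = 1e-8)

    dat$y2 <- stats::rnorm(n)
    got2 <- standardized_regression(dat, "y2", c("bmi", "age", "sex01"))
    expect_true(all(abs(got2$std_estimate) < 0.15))

    dat$bmi2 <- 2 * dat$bmi
    expect_error(standardized_regression(dat, "y", c("bmi", "bmi2")),
                 class = "pisacalc_collinear")
  })
})

test_that("the full paired analysis runs and reports the expected direction", {
  co <- generate_cohort(cohort_config(n_subjects = 60, seed = 8))
  rep <- run_phase3(co)
  cmp <- generics::tidy(rep)
  jp_pesa <- cmp$median[cmp$variable == "PESA" & cmp$version == "japanese"]
  og_pesa <- cmp$median[cmp$variable == "PESA" & cmp$version == "original"]
  expect_gt(jp_pesa, og_pesa)
  expect_lt(cmp$p_value[cmp$variable == "PESA"][1], 0.01)
  expect_true(all(cmp$q25 <= cmp$median & cmp$median <= cmp$q75))

  assoc <- generics::tidy(rep, which = "associations")
  expect_equal(nrow(assoc), 2)
  expect_true(all(abs(assoc$spearman_rho) <= 1))

  gl <- generics::glance(rep)
  expect_equal(gl$n_subjects, 60)
  expect_output(print(rep), "Paired version comparison")
})

test_that("the paired analysis refuses cohorts without scoreable mouths", {
  ch <- uniform_chart(2, subject_id = "A")
  co <- manual_cohort(ch, tibble::tibble(subject_id = c("A", "B"),
                                         age = 60, sex = "female", bmi = 22,
                                         n_teeth = c(28L, 0L)))
  expect_error(suppressMessages(run_phase3(co)), class = "pisacalc_bad_cohort")
})
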