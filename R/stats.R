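# Paired comparison and association statistics for the two formula versions.

#' Wilcoxon signed-rank test with fixed conventions
#'
#' Paired two-sided test of `a` vs `b`. Conventions (documented because
#' software differs): zero differences are dropped; ranks of |differences|
#' use midranks for ties; the exact null distribution is used when at most
#' 25 nonzero pairs remain and the absolute differences are tie-free,
#' otherwise the normal approximation with tie correction and continuity
#' correction.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @return A one-row tibble: `statistic` (rank sum of positive differences),
#'   `p_value`, `n` (nonzero pairs), `exact` (logical).
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) {
    abort_pisa("wilcoxon_signed_rank(): a and b must have equal length.",
               "pisacalc_bad_pairs")
  }
  d <- a - b
  d <- d[!is.na(d) & d != 0]
  if (!length(d)) {
    abort_pisa("wilcoxon_signed_rank(): all paired differences are zero; the test is undefined.",
               "pisacalc_degenerate_pairs")
  }
  n <- length(d)
  ties <- anyDuplicated(abs(d)) > 0
  exact <- n <= 25 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = exact, correct = TRUE)
  )
  tibble::tibble(statistic = unname(res$statistic),
                 p_value = res$p.value, n = n, exact = exact)
}

#' Spearman rank correlation (midranks, t approximation)
#'
#' rho is the product-moment correlation of the midrank-transformed data;
#' the two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom,
#' which is approximate in small samples.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A one-row tibble: `rho`, `p_value`, `n`, `undefined` (TRUE when a
#'   rank vector is constant, where rho does not exist).
#' @export
#' @examples
#' spearman_assoc(1:4, c(1, 3, 2, 4))
spearman_assoc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort_pisa("spearman_assoc(): x and y must have equal length >= 3.",
               "pisacalc_bad_pairs")
  }
  rx <- rank(x)
  ry <- rank(y)
  n <- length(x)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("spearman_assoc(): constant ranks; rho is undefined.", call. = FALSE)
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = n,
                          undefined = TRUE))
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(rho = rho, p_value = p, n = n, undefined = FALSE)
}

#' Standardised multiple regression
#'
#' Ordinary least squares of `outcome` on the named predictors (raw scale),
#' reporting both raw and standardised coefficients. Standardisation follows
#' the common statistics-package convention `beta_j = b_j * sd(x_j) /
#' sd(y)` with sample SDs, applied to binary predictors too.
#'
#' @param data A data frame.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor column names; binary
#'   factors must already be coded 0/1.
#' @return A tibble, one row per predictor: `term`, `estimate` (raw),
#'   `std_estimate`, `p_value`.
#' @export
standardized_regression <- function(data, outcome, predictors) {
  if (nrow(data) <= length(predictors) + 1) {
    abort_pisa("standardized_regression(): need n > number of predictors + 1.",
               "pisacalc_bad_pairs")
  }
  x <- as.matrix(data[predictors])
  if (!is.numeric(x)) {
    abort_pisa("standardized_regression(): predictors must be numeric (code sex as 0/1).",
               "pisacalc_bad_pairs")
  }
  kap <- kappa(cbind(1, scale(x)), exact = TRUE)
  if (!is.finite(kap) || kap > 1e8) {
    abort_pisa(sprintf("standardized_regression(): predictors are collinear (%s).",
                       paste(predictors, collapse = ", ")),
               "pisacalc_collinear")
  }
  fml <- stats::reformulate(predictors, response = outcome)
  fit <- stats::lm(fml, data = data)
  co <- summary(fit)$coefficients[predictors, , drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  tibble::tibble(
    term = predictors,
    estimate = unname(co[, "Estimate"]),
    std_estimate = unname(co[, "Estimate"] * sds) / stats::sd(data[[outcome]]),
    p_value = unname(co[, "Pr(>|t|)"])
  )
}

#' Paired version comparison and BMI associations on a cohort
#'
#' The full validation analysis: per-subject whole-mouth PESA and PISA are
#' computed under both formula versions on identical charts; the versions
#' are compared with the paired Wilcoxon signed-rank test (PESA and PISA
#' separately); and each version's PISA is related to BMI by Spearman
#' correlation and by standardised OLS adjusting for age and sex.
#'
#' @param cohort A `pisa_cohort` (or anything [cohort_charts()] accepts with
#'   `age`, `sex`, `bmi` columns). Subjects without teeth are dropped with a
#'   message; at least 3 toothed subjects are required.
#' @param coef_table Coefficient table.
#' @return A `pisa_phase3` object: list with `subjects` (per-subject totals,
#'   both versions, plus covariates), `comparison` (one row per variable and
#'   version: median, quartiles, Wilcoxon statistic and p), and
#'   `associations` (per version: Spearman rho/p and adjusted standardised
#'   beta/p for BMI). [generics::tidy()] and [generics::glance()] methods
#'   are provided.
#' @export
run_phase3 <- function(cohort, coef_table = pisa_coefficients()) {
  charts <- cohort_charts(cohort)
  cov <- tibble::as_tibble(cohort)
  toothed <- unique(charts$subject_id)
  dropped <- setdiff(cov$subject_id, toothed)
  if (length(dropped)) {
    message(sprintf("Dropping %d edentulous subject(s).", length(dropped)))
    cov <- cov[cov$subject_id %in% toothed, ]
  }
  if (nrow(cov) < 3) {
    abort_pisa("run_phase3(): need at least 3 subjects with at least one tooth.",
               "pisacalc_bad_cohort")
  }
  totals <- chart_areas(charts, version = "both", coef_table = coef_table) |>
    chart_totals()
  wide <- totals |>
    tidyr::pivot_wider(id_cols = "subject_id", names_from = "version",
                       values_from = c("total_pesa", "total_pisa")) |>
    dplyr::inner_join(cov[c("subject_id", "age", "sex", "bmi")], by = "subject_id")
  wide$sex01 <- as.integer(wide$sex == "male")

  q3 <- function(x) stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE)
  comparison <- purrr::map_dfr(c("pesa", "pisa"), function(var) {
    jp <- wide[[paste0("total_", var, "_japanese")]]
    og <- wide[[paste0("total_", var, "_original")]]
    wt <- wilcoxon_signed_rank(jp, og)
    purrr::map_dfr(
      list(japanese = jp, original = og),
      function(v) {
        q <- q3(v)
        tibble::tibble(median = q[1], q25 = q[2], q75 = q[3])
      },
      .id = "version"
    ) |>
      dplyr::mutate(variable = toupper(var), statistic = wt$statistic,
                    p_value = wt$p_value, .before = 1)
  })

  associations <- purrr::map_dfr(VERSIONS, function(v) {
    pisa <- wide[[paste0("total_pisa_", v)]]
    sp <- spearman_assoc(pisa, wide$bmi)
    dat <- tibble::tibble(pisa = pisa, bmi = wide$bmi, age = wide$age,
                          sex01 = wide$sex01)
    reg <- standardized_regression(dat, "pisa", c("bmi", "age", "sex01"))
    bmi_row <- reg[reg$term == "bmi", ]
    tibble::tibble(version = v, spearman_rho = sp$rho, spearman_p = sp$p_value,
                   std_beta_bmi = bmi_row$std_estimate, beta_p = bmi_row$p_value,
                   regression = list(reg))
  })

  structure(list(subjects = wide, comparison = comparison,
                 associations = associations, n = nrow(wide)),
            class = "pisa_phase3")
}

#' @export
print.pisa_phase3 <- function(x, ...) {
  cat(sprintf("Paired version comparison on %d subjects\n\n", x$n))
  print(x$comparison)
  cat("\nAssociations of PISA with BMI (Spearman; OLS adjusted for age, sex):\n")
  print(dplyr::select(x$associations, -"regression"))
  invisible(x)
}

#' Tidy a version-comparison result
#'
#' @param x A `pisa_phase3` object.
#' @param which `"comparison"` (default) or `"associations"`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.pisa_phase3 <- function(x, which = c("comparison", "associations"), ...) {
  which <- rlang::arg_match(which)
  if (which == "comparison") x$comparison
  else dplyr::select(x$associations, -"regression")
}

#' One-row summary of a version-comparison result
#'
#' @param x A `pisa_phase3` object.
#' @param ... Unused.
#' @return A one-row tibble with subject count and headline p-values.
#' @exportS3Method generics::glance
glance.pisa_phase3 <- function(x, ...) {
  cmp <- x$comparison
  tibble::tibble(
    n_subjects = x$n,
    pesa_p = cmp$p_value[cmp$variable == "PESA"][1],
    pisa_p = cmp$p_value[cmp$variable == "PISA"][1],
    spearman_rho_japanese = x$associations$spearman_rho[
      x$associations$version == "japanese"],
    spearman_rho_original = x$associations$spearman_rho[
      x$associations$version == "original"]
  )
}
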