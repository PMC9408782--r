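# Synthetic cross-sectional cohort generator.
#
# Stands in for non-public clinical charting data: subjects carry age, sex,
# BMI and a full-mouth six-site chart whose marginal summaries (median/IQR of
# age, BMI, tooth count, mean probing depth, bleeding percentage) are
# calibrated to published cross-sectional targets. Every distributional form
# here is an explicit modelling choice of this package, not an estimate of
# the clinical joint distribution; see the methods vignette.

# ---- quantile-matching fitters (deterministic, run once per config) --------

fit_lognormal_q <- function(q25, q50, q75) {
  z <- stats::qnorm(c(0.25, 0.5, 0.75))
  y <- log(c(q25, q50, q75))
  sdlog <- stats::cov(z, y) / stats::var(z)   # least-squares line through the 3 log-quantiles
  list(meanlog = mean(y), sdlog = sdlog)
}

fit_truncnorm_q <- function(q25, q50, q75, lower, upper) {
  qtn <- function(p, mu, sigma) {
    flo <- stats::pnorm(lower, mu, sigma)
    fhi <- stats::pnorm(upper, mu, sigma)
    stats::qnorm(flo + p * (fhi - flo), mu, sigma)
  }
  obj <- function(par) {
    q <- qtn(c(0.25, 0.5, 0.75), par[1], exp(par[2]))
    sum((q - c(q25, q50, q75))^2)
  }
  fit <- stats::optim(c(q50, log((q75 - q25) / 1.349)), obj, method = "Nelder-Mead")
  list(mu = fit$par[1], sigma = exp(fit$par[2]), lower = lower, upper = upper)
}

fit_shifted_gamma_q <- function(q25, q50, q75, shift) {
  obj <- function(par) {
    q <- shift + stats::qgamma(c(0.25, 0.5, 0.75), exp(par[1]), exp(par[2]))
    sum((q - c(q25, q50, q75))^2)
  }
  fit <- stats::optim(c(log(4), log(4 / (q50 - shift))), obj, method = "Nelder-Mead")
  list(shape = exp(fit$par[1]), rate = exp(fit$par[2]), shift = shift)
}

fit_beta_q <- function(q25, q50, q75) {
  obj <- function(par) {
    q <- stats::qbeta(c(0.25, 0.5, 0.75), exp(par[1]), exp(par[2]))
    sum((q - c(q25, q50, q75))^2)
  }
  fit <- stats::optim(c(log(2), log(2 * (1 - q50) / q50)), obj, method = "Nelder-Mead")
  list(shape1 = exp(fit$par[1]), shape2 = exp(fit$par[2]))
}

bbinom_cdf <- function(size, shape1, shape2) {
  k <- 0:size
  lp <- lchoose(size, k) + lbeta(k + shape1, size - k + shape2) - lbeta(shape1, shape2)
  cumsum(exp(lp))
}

fit_betabinom_q <- function(q25, q50, q75, size) {
  # interpolated discrete quantiles so Nelder-Mead sees a usable surface
  qbb <- function(p, shape1, shape2) {
    cdf <- bbinom_cdf(size, shape1, shape2)
    stats::approx(c(0, cdf), c(-0.5, 0:size + 0.5), xout = p, rule = 2,
                  ties = "ordered")$y
  }
  obj <- function(par) {
    q <- qbb(c(0.25, 0.5, 0.75), exp(par[1]), exp(par[2]))
    sum((q - c(q25, q50, q75))^2)
  }
  mu0 <- q50 / size
  fit <- stats::optim(c(log(5 * mu0 / (1 - mu0)), log(5)), obj, method = "Nelder-Mead")
  list(shape1 = exp(fit$par[1]), shape2 = exp(fit$par[2]), size = size)
}

# ---- configuration ---------------------------------------------------------

#' Configure the synthetic cohort generator
#'
#' Defaults encode the published cross-sectional targets: 210 subjects
#' (70 male / 140 female), age median 70 (IQR 61-76) years, BMI median 22.9
#' (20.4-25.0) kg/m^2, 25 (21-27) teeth present, subject mean probing depth
#' 2.29 (2.08-2.50) mm, bleeding at 13.4 (8.0-23.3) percent of sites.
#' Distribution families and the BMI-inflammation coupling are this
#' package's own stand-ins (see the methods vignette); the marginal
#' parameters are fitted to the quartile targets at configuration time by
#' least squares on the quantile function.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   config including this seed.
#' @param age_q,bmi_q,teeth_q,mean_ppd_q,bop_pct_q Numeric `c(q25, median,
#'   q75)` targets for the five summaries.
#' @param male_frac Fraction of male subjects (assigned exactly, up to
#'   rounding).
#' @param bmi_inflammation_effect Standardised logit-scale shift of a
#'   subject's bleeding propensity per SD of BMI (>= 0). The default (0.21)
#'   was calibrated once, at large n, so that Spearman's rho between
#'   whole-mouth PISA and BMI is about 0.19, the strength reported for the
#'   clinical data.
#' @return A `pisa_cohort_config` list with the targets and fitted
#'   distribution parameters.
#' @export
cohort_config <- function(n_subjects = 210,
                          seed = 1L,
                          age_q = c(61, 70, 76),
                          bmi_q = c(20.4, 22.9, 25.0),
                          teeth_q = c(21, 25, 27),
                          mean_ppd_q = c(2.08, 2.29, 2.50),
                          bop_pct_q = c(8.0, 13.4, 23.3),
                          male_frac = 70 / 210,
                          bmi_inflammation_effect = 0.21) {
  if (n_subjects < 2) abort_pisa("n_subjects must be >= 2.", "pisacalc_bad_config")
  if (bmi_inflammation_effect < 0) {
    abort_pisa("bmi_inflammation_effect must be >= 0.", "pisacalc_bad_config")
  }
  for (q in list(age_q, bmi_q, teeth_q, mean_ppd_q, bop_pct_q)) {
    if (length(q) != 3 || is.unsorted(q, strictly = FALSE)) {
      abort_pisa("Quartile targets must be c(q25, median, q75), ordered.",
                 "pisacalc_bad_config")
    }
  }
  if (age_q[1] < 40 || age_q[3] > 95) {
    abort_pisa("Age targets must lie inside the [40, 95] support.", "pisacalc_bad_config")
  }
  if (mean_ppd_q[1] < 1) {
    abort_pisa("Mean-PPD targets must be >= the 1 mm floor.", "pisacalc_bad_config")
  }
  if (bop_pct_q[1] < 0 || bop_pct_q[3] > 100) {
    abort_pisa("BOP%% targets must lie in [0, 100].", "pisacalc_bad_config")
  }
  if (teeth_q[3] > 28) {
    abort_pisa("Tooth-count targets cannot exceed the 28 modelled positions.",
               "pisacalc_bad_config")
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    seed = as.integer(seed),
    targets = list(age = age_q, bmi = bmi_q, teeth = teeth_q,
                   mean_ppd = mean_ppd_q, bop_pct = bop_pct_q),
    male_frac = male_frac,
    bmi_inflammation_effect = bmi_inflammation_effect,
    site_bop_depth_coef = 0.25,   # logit uplift per mm a site is deeper than its mouth's mean
    site_noise = list(shape = 2, rate = 2),  # centred gamma site noise, sd ~0.71 mm
    fits = list(
      age = fit_truncnorm_q(age_q[1], age_q[2], age_q[3], 40, 95),
      bmi = fit_lognormal_q(bmi_q[1], bmi_q[2], bmi_q[3]),
      teeth = fit_betabinom_q(teeth_q[1], teeth_q[2], teeth_q[3], 28),
      mean_ppd = fit_shifted_gamma_q(mean_ppd_q[1], mean_ppd_q[2], mean_ppd_q[3], 1),
      bop = fit_beta_q(bop_pct_q[1] / 100, bop_pct_q[2] / 100, bop_pct_q[3] / 100)
    )
  ), class = "pisa_cohort_config")
}

# ---- generation ------------------------------------------------------------

#' Generate a synthetic cohort
#'
#' Draws subjects and full-mouth charts under the configured generative
#' model: truncated-normal age, log-normal BMI, beta-binomial tooth count
#' over the 28 non-third-molar positions (positions dropped at random),
#' shifted-gamma subject mean depth with centred gamma site noise rounded to
#' integer mm and clamped to \[1, 10\], and a beta bleeding propensity
#' shifted on the logit scale by `bmi_inflammation_effect` x standardised
#' BMI, with a small extra logit uplift at deeper sites. Third molars are
#' never generated.
#'
#' @param config A [cohort_config()].
#' @return A tibble of class `pisa_cohort` with columns `subject_id`, `age`,
#'   `sex`, `bmi`, `n_teeth`, plus attributes `charts` (one combined wide
#'   chart for all subjects) and `config`. The result is byte-identical for
#'   identical configs.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 25, seed = 7))
#' cohort_summary(cohort)
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "pisa_cohort_config"))
  n <- config$n_subjects
  f <- config$fits
  withr::with_seed(config$seed, {
    # covariates
    flo <- stats::pnorm(f$age$lower, f$age$mu, f$age$sigma)
    fhi <- stats::pnorm(f$age$upper, f$age$mu, f$age$sigma)
    age <- stats::qnorm(flo + stats::runif(n) * (fhi - flo), f$age$mu, f$age$sigma)
    bmi <- stats::rlnorm(n, f$bmi$meanlog, f$bmi$sdlog)
    n_male <- round(n * config$male_frac)
    sex <- sample(rep(c("male", "female"), c(n_male, n - n_male)))

    # dentition: how many and which of the 28 positions
    p_keep <- stats::rbeta(n, f$teeth$shape1, f$teeth$shape2)
    n_teeth <- stats::rbinom(n, f$teeth$size, p_keep)
    n_teeth <- pmax(n_teeth, 1L)  # an edentulous mouth has no chart row
    positions <- as.integer(outer(c(10L, 20L, 30L, 40L), 1:7, `+`))
    teeth <- lapply(n_teeth, function(k) sort(sample(positions, k)))

    # depths: subject mean + centred gamma site noise, integer mm in [1, 10]
    subj_mean <- f$mean_ppd$shift +
      stats::rgamma(n, f$mean_ppd$shape, f$mean_ppd$rate)
    idx <- rep.int(seq_len(n), n_teeth)
    n_sites <- length(idx) * 6L
    noise <- stats::rgamma(n_sites, config$site_noise$shape, config$site_noise$rate) -
      config$site_noise$shape / config$site_noise$rate
    ppd <- matrix(pmin(pmax(round(subj_mean[idx] + noise), 1), 10),
                  ncol = 6)

    # bleeding: beta propensity, logit-shifted by standardised BMI and depth
    prop <- stats::rbeta(n, f$bop$shape1, f$bop$shape2)
    z_bmi <- as.numeric(scale(bmi))
    lodds <- stats::qlogis(pmin(pmax(prop, 1e-12), 1 - 1e-12)) +
      config$bmi_inflammation_effect * z_bmi
    p_site <- stats::plogis(lodds[idx] +
                              config$site_bop_depth_coef * (ppd - subj_mean[idx]))
    bop <- matrix(as.double(stats::rbinom(n_sites, 1, p_site)), ncol = 6)

    subject_id <- sprintf("S%04d", seq_len(n))
    charts <- tibble::tibble(subject_id = subject_id[idx],
                             tooth = unlist(teeth))
    for (j in seq_along(PPD_COLS)) charts[[PPD_COLS[j]]] <- ppd[, j]
    for (j in seq_along(BOP_COLS)) charts[[BOP_COLS[j]]] <- bop[, j]

    out <- tibble::tibble(subject_id = subject_id, age = age, sex = sex,
                          bmi = bmi, n_teeth = n_teeth)
    attr(out, "charts") <- charts
    attr(out, "config") <- config
    class(out) <- c("pisa_cohort", class(out))
    out
  })
}

#' Combined chart of a cohort
#'
#' @param cohort A `pisa_cohort`.
#' @return The combined wide chart tibble (all subjects, one row per tooth).
#' @export
cohort_charts <- function(cohort) {
  stopifnot(inherits(cohort, "pisa_cohort"))
  attr(cohort, "charts")
}

#' Cohort summary table
#'
#' Median and quartiles (linear-interpolation convention, `stats::quantile`
#' type 7) of the five calibrated summaries. Subject mean PPD averages over
#' all measured sites; BOP% is the percentage of flagged sites that bleed.
#'
#' @param cohort A `pisa_cohort`, or any data frame with the covariate
#'   columns plus a chart retrievable via [cohort_charts()].
#' @return A tibble: `variable`, `median`, `q25`, `q75`.
#' @export
cohort_summary <- function(cohort) {
  if (nrow(cohort) == 0) abort_pisa("Empty cohort.", "pisacalc_bad_cohort")
  charts <- cohort_charts(cohort)
  ppd <- as.matrix(charts[PPD_COLS])
  bop <- as.matrix(charts[BOP_COLS])
  per_subj <- tibble::tibble(
    subject_id = charts$subject_id,
    ppd_sum = rowSums(ppd, na.rm = TRUE),
    ppd_n = rowSums(!is.na(ppd)),
    bop_sum = rowSums(bop, na.rm = TRUE),
    bop_n = rowSums(!is.na(bop))
  ) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      mean_ppd = sum(.data$ppd_sum) / sum(.data$ppd_n),
      bop_pct = 100 * sum(.data$bop_sum) / sum(.data$bop_n),
      .groups = "drop"
    )
  dat <- dplyr::left_join(tibble::as_tibble(cohort), per_subj, by = "subject_id")
  q3 <- function(x) stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  vars <- c(age = "age", bmi = "bmi", n_teeth = "n_teeth",
            mean_ppd = "mean_ppd", bop_pct = "bop_pct")
  purrr::map_dfr(names(vars), function(v) {
    q <- q3(dat[[vars[[v]]]])
    tibble::tibble(variable = v, median = q[1], q25 = q[2], q75 = q[3])
  })
}

#' Write a cohort to a directory
#'
#' One chart file per subject (canonical wide format) under `charts/`, plus
#' a `covariates.csv` with `subject_id`, `age`, `sex`, `bmi`.
#'
#' @param cohort A `pisa_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "charts"), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tibble::as_tibble(cohort)[c("subject_id", "age", "sex", "bmi")],
                   file.path(dir, "covariates.csv"), progress = FALSE)
  charts <- cohort_charts(cohort)
  for (id in unique(charts$subject_id)) {
    write_chart(charts[charts$subject_id == id, ],
                file.path(dir, "charts", paste0(id, ".csv")))
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `covariates.csv` and `charts/`.
#' @return A `pisa_cohort` tibble (without a generator config attribute).
#' @export
read_cohort <- function(dir) {
  cov_path <- file.path(dir, "covariates.csv")
  if (!file.exists(cov_path)) {
    abort_pisa(sprintf("No covariates.csv in %s", dir), "pisacalc_io_error")
  }
  cov <- readr::read_csv(cov_path, show_col_types = FALSE, progress = FALSE)
  files <- list.files(file.path(dir, "charts"), pattern = "\\.csv$",
                      full.names = TRUE)
  charts <- dplyr::bind_rows(lapply(files, read_chart))
  cov$n_teeth <- as.integer(table(factor(charts$subject_id,
                                         levels = cov$subject_id)))
  out <- tibble::as_tibble(cov)
  attr(out, "charts") <- charts
  class(out) <- c("pisa_cohort", class(out))
  out
}
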