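# PESA / PISA computation per tooth and per chart.

VERSIONS <- c("japanese", "original")

# Horner evaluation of a1*x + ... + a6*x^6 (no intercept)
eval_pesa_poly <- function(a, x) {
  # a: matrix n x 6 aligned with x
  acc <- a[, 6]
  for (k in 5:1) acc <- acc * x + a[, k]
  unname(acc * x)
}

#' Periodontal epithelial surface area of one tooth type
#'
#' Evaluates the PESA formula for a tooth type at a mean probing depth, under
#' either version. Vectorised over `jaw`/`tooth_class`/`ppd`.
#'
#' The formulas are evidenced on depths of 0-10 mm; deeper values are still
#' computed (the Japanese version is linear, the original a degree-6
#' polynomial) but a warning flags the extrapolation.
#'
#' @param jaw `"maxilla"` or `"mandible"`.
#' @param tooth_class One of the eight tooth classes (see [tooth_types()]).
#' @param ppd Mean probing depth in mm, >= 0.
#' @param version `"japanese"` (linear slope) or `"original"` (polynomial).
#' @param coef_table Coefficient table; default [pisa_coefficients()].
#' @return PESA in mm^2.
#' @export
#' @examples
#' pesa_area("maxilla", "central_incisor", 5, "japanese")  # 84.8
#' pesa_area("maxilla", "central_incisor", 5, "original")  # ~88.87
pesa_area <- function(jaw, tooth_class, ppd, version,
                      coef_table = pisa_coefficients()) {
  version <- rlang::arg_match(version, VERSIONS)
  if (any(is.na(ppd)) || any(ppd < 0)) {
    abort_pisa("pesa_area(): probing depth must be non-negative.",
               "pisacalc_negative_ppd")
  }
  key <- tibble::tibble(jaw = jaw, tooth_class = tooth_class, ppd = ppd)
  m <- dplyr::left_join(key, coef_table, by = c("jaw", "tooth_class"))
  if (anyNA(m$slope)) {
    miss <- unique(paste(m$jaw, m$tooth_class)[is.na(m$slope)])
    abort_pisa(sprintf("No coefficients registered for: %s",
                       paste(miss, collapse = "; ")),
               "pisacalc_unregistered_tooth")
  }
  if (any(ppd > 10)) {
    warning("pesa_area(): depth(s) above 10 mm lie outside the evidenced range; values are extrapolated.",
            call. = FALSE)
  }
  if (version == "japanese") {
    m$slope * m$ppd
  } else {
    eval_pesa_poly(as.matrix(m[paste0("a", 1:6)]), m$ppd)
  }
}

#' Inflamed surface area of one tooth
#'
#' PISA is the epithelial surface weighted by the fraction of bleeding sites.
#'
#' @param pesa PESA in mm^2, >= 0.
#' @param bop_frac Fraction of BOP-positive sites in \[0, 1\].
#' @return PISA in mm^2.
#' @export
#' @examples
#' tooth_pisa(84.8, 2 / 6)
tooth_pisa <- function(pesa, bop_frac) {
  if (any(pesa < 0, na.rm = TRUE)) {
    abort_pisa("tooth_pisa(): PESA must be non-negative.", "pisacalc_bad_pesa")
  }
  if (any(bop_frac < 0 | bop_frac > 1, na.rm = TRUE)) {
    abort_pisa("tooth_pisa(): BOP fraction must lie in [0, 1].", "pisacalc_bad_bop_frac")
  }
  pesa * bop_frac
}

#' Per-tooth and whole-chart surface areas
#'
#' The full charting pipeline: per tooth, the mean probing depth enters the
#' version's PESA formula and the result is weighted by the tooth's bleeding
#' fraction to give PISA; chart totals are sums over teeth.
#'
#' @param chart A wide chart (see [validate_chart()]); may hold several
#'   subjects.
#' @param version `"japanese"`, `"original"`, or `"both"` (stacked results,
#'   one set of rows per version). There is no default: the choice of formula
#'   system is always explicit.
#' @param third_molar_policy What to do with position-8 teeth: `"exclude"`
#'   (default; skipped and reported via the `skipped_teeth` attribute),
#'   `"error"`, or `"use_registered"` (requires a `coef_table` extended by
#'   [register_third_molar_coefficients()]).
#' @param coef_table Coefficient table; default [pisa_coefficients()].
#' @return A tibble of class `pisa_areas`: one row per tooth and version with
#'   `subject_id`, `tooth`, `jaw`, `tooth_class`, `side`, `n_sites`,
#'   `mean_ppd`, `bop_frac`, `version`, `pesa`, `pisa`, `extrapolated`.
#'   Attribute `skipped_teeth` lists excluded third molars.
#' @export
#' @examples
#' chart_areas(uniform_chart(3), version = "both") |> chart_totals()
chart_areas <- function(chart, version,
                        third_molar_policy = c("exclude", "error", "use_registered"),
                        coef_table = pisa_coefficients()) {
  versions <- if (identical(version, "both")) VERSIONS else rlang::arg_match(version, VERSIONS)
  third_molar_policy <- rlang::arg_match(third_molar_policy)

  s <- chart_site_summary(chart)
  if (any(is.na(s$bop_frac))) {
    abort_pisa("chart_areas(): tooth with measured depth but no BOP flag; PISA is undefined.",
               "pisacalc_all_missing")
  }
  skipped <- integer(0)
  m3 <- s$tooth_class == "third_molar"
  if (any(m3)) {
    if (third_molar_policy == "error") {
      abort_pisa(sprintf("Third molar(s) present: %s",
                         paste(s$tooth[m3], collapse = ", ")),
                 "pisacalc_third_molar")
    }
    if (third_molar_policy == "exclude") {
      skipped <- s$tooth[m3]
      s <- s[!m3, ]
    } else if (!any(coef_table$tooth_class == "third_molar")) {
      abort_pisa("third_molar_policy = \"use_registered\" but no third-molar coefficients are registered.",
                 "pisacalc_unregistered_tooth")
    }
  }

  out <- purrr::map_dfr(versions, function(v) {
    res <- s
    res$version <- v
    res$pesa <- if (nrow(s)) {
      pesa_area(s$jaw, s$tooth_class, s$mean_ppd, v, coef_table)
    } else double(0)
    res$pisa <- res$pesa * res$bop_frac
    res$extrapolated <- res$mean_ppd > 10
    res
  })
  out <- out[setdiff(names(out), "bop_sites")]
  attr(out, "skipped_teeth") <- skipped
  class(out) <- c("pisa_areas", class(out))
  out
}

#' Chart totals
#'
#' Sums per-tooth areas to whole-mouth totals per subject and version.
#'
#' @param areas A `pisa_areas` tibble from [chart_areas()].
#' @return A tibble: `subject_id`, `version`, `n_teeth`, `total_pesa`,
#'   `total_pisa` (mm^2).
#' @export
chart_totals <- function(areas) {
  areas |>
    dplyr::group_by(.data$subject_id, .data$version) |>
    dplyr::summarise(
      n_teeth = dplyr::n(),
      total_pesa = sum(.data$pesa),
      total_pisa = sum(.data$pisa),
      .groups = "drop"
    )
}

#' Numerical monotonicity check of the PESA formulas
#'
#' PESA should increase with probing depth. The Japanese version is linear
#' with positive slope, so it always does; the original degree-6 polynomials
#' are only guaranteed empirically. This check scans a fine depth grid and
#' reports every interval on which a formula decreases, rather than hiding
#' or clamping it. (With the shipped table the original-version mandibular
#' second molar dips slightly around 1.2-1.4 mm.)
#'
#' @param from,to,by Depth grid in mm (default 1 to 10 by 0.1).
#' @param coef_table Coefficient table.
#' @return Tibble of violations: `version`, `jaw`, `tooth_class`, `x_lo`,
#'   `x_hi`, `drop` (area decrease in mm^2). Zero rows = monotone everywhere.
#' @export
check_pesa_monotonicity <- function(from = 1, to = 10, by = 0.1,
                                    coef_table = pisa_coefficients()) {
  grid <- seq(from, to, by = by)
  tt <- coef_table[c("jaw", "tooth_class")]
  purrr::map_dfr(VERSIONS, function(v) {
    purrr::map_dfr(seq_len(nrow(tt)), function(i) {
      vals <- pesa_area(tt$jaw[i], tt$tooth_class[i], grid, v, coef_table)
      d <- diff(vals)
      bad <- which(d <= 0)
      if (!length(bad)) return(NULL)
      tibble::tibble(
        version = v, jaw = tt$jaw[i], tooth_class = tt$tooth_class[i],
        x_lo = grid[bad], x_hi = grid[bad + 1], drop = -d[bad]
      )
    })
  })
}
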