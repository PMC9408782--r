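# Published PESA formula coefficients for the 14 non-third-molar tooth types.
#
# Japanese version: PESA = slope * mean PPD (mm^2 per mm), one slope per type,
# derived from attachment-level measurements on extracted teeth of Japanese
# patients. Original version: PESA = a1*x + a2*x^2 + ... + a6*x^6 with x the
# mean PPD in mm. Neither version has an intercept, so PESA(0) = 0.
#
# Transcription note: in the published table the maxillary lateral incisor's
# original-version a5 appears as 0.05890, a misplaced decimal point. That
# value would drive the tooth's PESA to ~5500 mm^2 at 10 mm (an order of
# magnitude above every neighbouring tooth) and contradicts the published
# whole-mouth totals, the 5-6 mm crossover and the per-tooth curves, all of
# which are restored exactly by 0.00589. The corrected value is stored here;
# see the methods vignette.

pisa_coef_data <- function() {
  tt <- tooth_types(scoreable_only = TRUE)
  tibble::tibble(
    jaw = tt$jaw,
    tooth_class = tt$tooth_class,
    slope = c(16.96, 17.54, 20.52, 20.90, 19.98, 38.33, 31.10,
              12.70, 15.91, 20.13, 19.32, 18.04, 34.27, 27.56),
    a1 = c(12.3905, 18.7571, 16.5369, 21.8618, 39.2681, 16.8835, 25.4265,
           21.4600, 16.4395, 24.6992, 24.6866, 13.1705, 19.1229, 46.6148),
    a2 = c(0.1374, -1.6471, 1.6010, -2.3031, -7.3113, -0.5688, 4.6241,
           -6.6888, -1.0337, -3.5868, -4.8531, 5.0958, -12.2566, -43.1558),
    a3 = c(0.6717, 0.5258, -0.2494, 0.5330, 1.2340, 1.5433, -3.0787,
           2.4638, 0.4146, 0.6903, 1.3992, -1.0989, 5.5750, 16.7577),
    a4 = c(-0.14536, -0.07900, 0.01087, -0.04075, -0.12192, -0.06519, 0.95774,
           -0.39094, -0.05711, -0.05799, -0.18028, 0.10864, -0.78145, -2.48858),
    a5 = c(0.01126, 0.00589, 0.00021, 0.00062, 0.00626, -0.01454, -0.10923,
           0.02743, 0.00257, 0.00189, 0.01037, -0.00559, 0.04566, 0.16174),
    a6 = c(-0.0003083, -0.0001855, -0.0000182, 0.0000199, -0.0001260,
           0.0009019, 0.0040876, -0.0007116, -0.0000211, -0.0000142,
           -0.0002229, 0.0001179, -0.0009711, -0.0038873)
  )
}

#' PESA formula coefficient table
#'
#' One row per scoreable tooth type with the Japanese-version slope (mm^2 of
#' epithelial surface per mm of probing depth) and the original-version
#' polynomial coefficients `a1`..`a6`. Third molars are absent by default;
#' add them with [register_third_molar_coefficients()].
#'
#' The stored values are the published ones, with a single documented
#' decimal-point correction (maxillary lateral incisor `a5` = 0.00589); the
#' as-printed 0.05890 is inconsistent with the published whole-mouth totals
#' and per-tooth curves. See the methods vignette.
#'
#' @return A tibble with columns `jaw`, `tooth_class`, `slope`, `a1`..`a6`.
#' @export
#' @examples
#' pisa_coefficients()
pisa_coefficients <- function() {
  pisa_coef_data()
}

#' Register third-molar coefficients
#'
#' The shipped table deliberately omits third molars (their coefficients are
#' published elsewhere). Callers holding those coefficients can extend the
#' table; both jaws must be supplied together so a chart cannot be scored
#' with a half-registered dentition.
#'
#' @param coeffs A data frame with columns `jaw` (both `"maxilla"` and
#'   `"mandible"` present), `slope`, `a1`..`a6` for the third molars.
#' @param table Coefficient table to extend (default [pisa_coefficients()]).
#' @return The extended coefficient table.
#' @export
#' @examples
#' zeros <- tibble::tibble(jaw = c("maxilla", "mandible"), slope = c(1, 1),
#'   a1 = 0, a2 = 0, a3 = 0, a4 = 0, a5 = 0, a6 = 0)
#' register_third_molar_coefficients(zeros)
register_third_molar_coefficients <- function(coeffs, table = pisa_coefficients()) {
  coeffs <- tibble::as_tibble(coeffs)
  needed <- c("jaw", "slope", paste0("a", 1:6))
  missing_cols <- setdiff(needed, names(coeffs))
  if (length(missing_cols)) {
    abort_pisa(sprintf("Third-molar coefficients missing column(s): %s",
                       paste(missing_cols, collapse = ", ")),
               "pisacalc_bad_coefficients")
  }
  if (!setequal(coeffs$jaw, c("maxilla", "mandible")) ||
      nrow(coeffs) != 2) {
    abort_pisa("Third-molar coefficients must be registered for both jaws (one row each).",
               "pisacalc_partial_registration")
  }
  coeffs$tooth_class <- "third_molar"
  dplyr::bind_rows(table, coeffs[c("jaw", "tooth_class", needed[-1])])
}
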