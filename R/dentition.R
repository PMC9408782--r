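# Dentition model: FDI tooth codes, tooth types, six-site charts.
#
# A chart is an ordinary tibble in "wide" shape, one row per present tooth:
#   subject_id (optional), tooth (FDI integer),
#   ppd_mb, ppd_b, ppd_db, ppd_dl, ppd_l, ppd_ml   (depths, mm; NA = missing)
#   bop_mb, bop_b, bop_db, bop_dl, bop_l, bop_ml   (0/1/NA)
# Sites run mesiobuccal, buccal, distobuccal, distolingual, lingual,
# mesiolingual. Absent teeth are simply absent rows.

SITE_NAMES <- c("mb", "b", "db", "dl", "l", "ml")
PPD_COLS <- paste0("ppd_", SITE_NAMES)
BOP_COLS <- paste0("bop_", SITE_NAMES)
CHART_COLS <- c("tooth", PPD_COLS, BOP_COLS)

TOOTH_CLASSES <- c(
  "central_incisor", "lateral_incisor", "canine", "first_premolar",
  "second_premolar", "first_molar", "second_molar", "third_molar"
)

#' Enumerate tooth types
#'
#' The 16 jaw-by-class combinations of the permanent dentition. Third molars
#' exist as types but are not scoreable by default: the shipped coefficient
#' table covers the 14 non-third-molar types only (see
#' [register_third_molar_coefficients()]).
#'
#' @param scoreable_only If `TRUE` (default) drop the two third-molar types.
#' @return A tibble with columns `jaw`, `tooth_class`, `scoreable`.
#' @export
#' @examples
#' tooth_types()
tooth_types <- function(scoreable_only = TRUE) {
  out <- tidyr::expand_grid(
    jaw = c("maxilla", "mandible"),
    tooth_class = TOOTH_CLASSES
  )
  out$scoreable <- out$tooth_class != "third_molar"
  if (scoreable_only) out <- out[out$scoreable, ]
  tibble::as_tibble(out)
}

#' Decode FDI tooth codes
#'
#' Maps two-digit FDI codes (quadrants 1-4, positions 1-8) to jaw, tooth
#' class and side. Mirror teeth (e.g. 16 and 26) share a tooth type.
#'
#' @param tooth Integer vector of FDI codes.
#' @return A tibble with columns `tooth`, `jaw`, `tooth_class`, `side`.
#' @export
#' @examples
#' fdi_decode(c(11, 37))
fdi_decode <- function(tooth) {
  tooth <- as.integer(tooth)
  quadrant <- tooth %/% 10L
  position <- tooth %% 10L
  bad <- is.na(tooth) | quadrant < 1L | quadrant > 4L | position < 1L | position > 8L
  if (any(bad)) {
    abort_pisa(
      sprintf("Invalid FDI tooth code(s): %s",
              paste(unique(tooth[bad]), collapse = ", ")),
      "pisacalc_invalid_fdi"
    )
  }
  tibble::tibble(
    tooth = tooth,
    jaw = ifelse(quadrant <= 2L, "maxilla", "mandible"),
    tooth_class = TOOTH_CLASSES[position],
    side = ifelse(quadrant %in% c(1L, 4L), "right", "left")
  )
}

#' Mean probing depth of one tooth
#'
#' Arithmetic mean of the measured (non-missing) site depths. The denominator
#' is the number of measured sites, so partially charted teeth degrade
#' gracefully.
#'
#' @param ppd Numeric vector of site depths in mm (`NA` = unmeasured).
#' @return Mean depth in mm.
#' @export
#' @examples
#' mean_ppd(c(3, 3, 3, NA, 3, 3))
mean_ppd <- function(ppd) {
  if (all(is.na(ppd))) {
    abort_pisa("mean_ppd(): all sites missing; an unmeasured tooth must be omitted from the chart.",
               "pisacalc_all_missing")
  }
  if (any(ppd < 0, na.rm = TRUE)) {
    abort_pisa("mean_ppd(): negative probing depth.", "pisacalc_negative_ppd")
  }
  mean(ppd, na.rm = TRUE)
}

#' Fraction of bleeding sites of one tooth
#'
#' Number of BOP-positive sites over the number of sites with a recorded BOP
#' flag.
#'
#' @param bop Vector of 0/1 flags (`NA` = unmeasured).
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' bop_fraction(c(1, 1, 0, 0, 0, 0))
bop_fraction <- function(bop) {
  if (all(is.na(bop))) {
    abort_pisa("bop_fraction(): all BOP flags missing.", "pisacalc_all_missing")
  }
  if (!all(bop %in% c(0, 1) | is.na(bop))) {
    abort_pisa("bop_fraction(): BOP flags must be 0, 1 or NA.", "pisacalc_invalid_bop")
  }
  sum(bop, na.rm = TRUE) / sum(!is.na(bop))
}

#' Validate a periodontal chart
#'
#' Checks the wide chart contract: required columns, valid FDI codes, no
#' duplicated tooth within a subject, at most 32 teeth per subject, depths in
#' \[0, 15\] mm, BOP flags in \{0, 1, NA\}, no BOP flag on a site whose depth
#' is unmeasured, and at least one measured depth per tooth row.
#'
#' @param chart A wide chart data frame (see package-level docs for columns).
#' @return The chart, invisibly coerced to a tibble, if valid; otherwise an
#'   error naming the offending rows.
#' @export
validate_chart <- function(chart) {
  chart <- tibble::as_tibble(chart)
  missing_cols <- setdiff(CHART_COLS, names(chart))
  if (length(missing_cols)) {
    abort_pisa(sprintf("Chart is missing column(s): %s",
                       paste(missing_cols, collapse = ", ")),
               "pisacalc_bad_columns")
  }
  if (!"subject_id" %in% names(chart)) chart$subject_id <- "subject"
  if (nrow(chart) == 0) return(invisible(chart))

  fdi_decode(chart$tooth)  # validates codes

  dup <- duplicated(chart[c("subject_id", "tooth")])
  if (any(dup)) {
    abort_pisa(sprintf("Duplicate tooth row(s) at row %s (tooth %s).",
                       paste(which(dup), collapse = ", "),
                       paste(chart$tooth[dup], collapse = ", ")),
               "pisacalc_duplicate_tooth")
  }
  n_teeth <- table(chart$subject_id)
  if (any(n_teeth > 32)) {
    abort_pisa("A subject has more than 32 teeth.", "pisacalc_too_many_teeth")
  }

  ppd <- as.matrix(chart[PPD_COLS])
  bop <- as.matrix(chart[BOP_COLS])
  if (!is.numeric(ppd)) abort_pisa("PPD columns must be numeric.", "pisacalc_bad_ppd")
  if (any(ppd < 0 | ppd > 15, na.rm = TRUE)) {
    abort_pisa("PPD values must lie in [0, 15] mm.", "pisacalc_bad_ppd")
  }
  if (!all(bop %in% c(0, 1) | is.na(bop))) {
    abort_pisa("BOP values must be 0, 1 or missing.", "pisacalc_invalid_bop")
  }
  orphan <- is.na(ppd) & !is.na(bop)
  if (any(orphan)) {
    abort_pisa(sprintf("BOP recorded on unmeasured site(s) at row %s.",
                       paste(which(rowSums(orphan) > 0), collapse = ", ")),
               "pisacalc_orphan_bop")
  }
  empty <- rowSums(!is.na(ppd)) == 0
  if (any(empty)) {
    abort_pisa(sprintf("Row %s has no measured site; omit absent teeth instead.",
                       paste(which(empty), collapse = ", ")),
               "pisacalc_all_missing")
  }
  invisible(chart)
}

#' Per-tooth site summary
#'
#' Collapses the six-site chart to one row per tooth with the two quantities
#' the area formulas consume: mean probing depth and bleeding fraction.
#'
#' @param chart A valid wide chart.
#' @return A tibble: `subject_id`, `tooth`, `jaw`, `tooth_class`, `side`,
#'   `n_sites` (measured depths), `mean_ppd` (mm), `bop_sites` (flagged
#'   sites), `bop_frac`.
#' @export
#' @examples
#' chart_site_summary(uniform_chart(3))
chart_site_summary <- function(chart) {
  chart <- validate_chart(chart)
  if (nrow(chart) == 0) {
    return(tibble::tibble(
      subject_id = character(), tooth = integer(), jaw = character(),
      tooth_class = character(), side = character(), n_sites = integer(),
      mean_ppd = double(), bop_sites = integer(), bop_frac = double()
    ))
  }
  ppd <- as.matrix(chart[PPD_COLS])
  bop <- as.matrix(chart[BOP_COLS])
  dplyr::bind_cols(
    chart["subject_id"],
    fdi_decode(chart$tooth),
    tibble::tibble(
      n_sites = rowSums(!is.na(ppd)),
      mean_ppd = rowMeans(ppd, na.rm = TRUE),
      bop_sites = rowSums(!is.na(bop)),
      bop_frac = ifelse(rowSums(!is.na(bop)) > 0,
                        rowSums(bop == 1, na.rm = TRUE) / rowSums(!is.na(bop)),
                        NA_real_)
    )
  )
}
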