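# Chart and result I/O.
#
# Canonical on-disk form mirrors the charting-spreadsheet workflow: one row
# per tooth with a mandatory header. Wide columns:
#   tooth, ppd_mb, ppd_b, ppd_db, ppd_dl, ppd_l, ppd_ml,
#          bop_mb, bop_b, bop_db, bop_dl, bop_l, bop_ml
# (optionally preceded by subject_id). A long layout (tooth, site, ppd, bop;
# one row per site) is accepted on input. Missing = empty cell or "NA".
# Decimal separator is always the point, independent of locale.

RESULTS_SCHEMA <- "pisacalc/1"

parse_numeric_strict <- function(x, what) {
  x[x %in% c("", "NA")] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    abort_pisa(sprintf("Non-numeric %s value(s): %s (row %s)", what,
                       paste(unique(x[bad]), collapse = ", "),
                       paste(which(bad), collapse = ", ")),
               "pisacalc_parse_error")
  }
  out
}

#' Read a periodontal chart file
#'
#' @param path Path to a delimited text file with a mandatory header.
#' @param layout `"wide"` (default, one row per tooth) or `"long"` (one row
#'   per tooth-site with columns `tooth`, `site`, `ppd`, `bop`; `site` uses
#'   the tokens mb, b, db, dl, l, ml).
#' @param delim Field delimiter (default `","`).
#' @return A validated wide chart tibble.
#' @export
read_chart <- function(path, layout = c("wide", "long"), delim = ",") {
  layout <- rlang::arg_match(layout)
  if (!file.exists(path)) {
    abort_pisa(sprintf("Chart file not found: %s", path), "pisacalc_io_error")
  }
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    locale = readr::locale(decimal_mark = "."), na = character(), progress = FALSE
  )
  if (layout == "long") {
    needed <- c("tooth", "site", "ppd", "bop")
    if (!all(needed %in% names(raw))) {
      abort_pisa("Long chart layout requires columns tooth, site, ppd, bop.",
                 "pisacalc_bad_columns")
    }
    if (!all(raw$site %in% SITE_NAMES)) {
      abort_pisa(sprintf("Unknown site token(s): %s",
                         paste(setdiff(unique(raw$site), SITE_NAMES), collapse = ", ")),
                 "pisacalc_bad_columns")
    }
    raw <- raw |>
      tidyr::pivot_wider(names_from = "site", values_from = c("ppd", "bop"),
                         names_sep = "_")
    missing_cols <- setdiff(CHART_COLS[-1], names(raw))
    for (cc in missing_cols) raw[[cc]] <- NA_character_
  }
  missing_cols <- setdiff(CHART_COLS, names(raw))
  if (length(missing_cols)) {
    abort_pisa(sprintf("Chart file is missing column(s): %s",
                       paste(missing_cols, collapse = ", ")),
               "pisacalc_bad_columns")
  }
  chart <- tibble::tibble(tooth = as.integer(parse_numeric_strict(raw$tooth, "tooth")))
  if ("subject_id" %in% names(raw)) chart$subject_id <- raw$subject_id
  for (cc in PPD_COLS) chart[[cc]] <- parse_numeric_strict(raw[[cc]], cc)
  for (cc in BOP_COLS) {
    v <- parse_numeric_strict(raw[[cc]], cc)
    if (!all(v %in% c(0, 1) | is.na(v))) {
      abort_pisa(sprintf("%s: BOP values must be 0, 1 or empty.", cc),
                 "pisacalc_invalid_bop")
    }
    chart[[cc]] <- v
  }
  chart <- chart[c(intersect("subject_id", names(chart)), CHART_COLS)]
  validate_chart(chart)
  chart
}

#' Write a periodontal chart file
#'
#' Writes the canonical wide layout; missing values become empty cells so
#' that [read_chart()] round-trips the chart exactly.
#'
#' @param chart A valid wide chart.
#' @param path Output path.
#' @param delim Field delimiter (default `","`).
#' @return `path`, invisibly.
#' @export
write_chart <- function(chart, path, delim = ",") {
  chart <- validate_chart(chart)
  cols <- c(intersect("subject_id", names(chart)), CHART_COLS)
  readr::write_delim(chart[cols], path, delim = delim, na = "", progress = FALSE)
  invisible(path)
}

#' Write a results table
#'
#' Two formats: `"csv"` prints areas at the 1-decimal reporting precision and,
#' for per-tooth area results, appends one totals row per subject and
#' version; `"json"` is a structured-text export carrying full precision, the
#' result type and a schema version string.
#'
#' @param result A `pisa_areas`, `pisa_sweep`, other tibble, or
#'   `pisa_phase3` object.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, format = c("csv", "json")) {
  format <- rlang::arg_match(format)
  if (format == "json") {
    payload <- list(
      schema = RESULTS_SCHEMA,
      type = class(result)[1],
      data = if (inherits(result, "pisa_phase3")) unclass(result) else result
    )
    jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                         dataframe = "rows", na = "null")
    return(invisible(path))
  }
  if (inherits(result, "pisa_phase3")) {
    result <- generics::tidy(result)
  }
  tab <- tibble::as_tibble(result)
  if (inherits(result, "pisa_areas")) {
    totals <- chart_totals(result)
    tot_rows <- tibble::tibble(
      subject_id = totals$subject_id, tooth = NA_integer_,
      jaw = NA_character_, tooth_class = "TOTAL", side = NA_character_,
      n_sites = NA_real_, mean_ppd = NA_real_, bop_frac = NA_real_,
      version = totals$version, pesa = totals$total_pesa,
      pisa = totals$total_pisa, extrapolated = NA
    )
    tab <- dplyr::bind_rows(tab, tot_rows)
  }
  num <- vapply(tab, is.numeric, logical(1)) & names(tab) %in% c("pesa", "pisa", "area_mm2")
  tab[num] <- lapply(tab[num], round_half_up, digits = 1)
  readr::write_csv(tab, path, na = "", progress = FALSE)
  invisible(path)
}
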