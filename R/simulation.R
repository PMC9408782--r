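# Uniform-depth simulation comparing the two formula versions.
#
# The experiment: every one of the 28 non-third-molar teeth probed at the
# same depth at all six sites, every site bleeding, so PISA = PESA and the
# two versions can be compared per tooth type and for the whole mouth over a
# depth grid.

#' Uniform full-mouth chart
#'
#' A 28-tooth chart (third molars absent) with every site at the same depth
#' and every site BOP-positive.
#'
#' @param ppd Probing depth in mm (>= 0) applied to all sites.
#' @param subject_id Subject label (default encodes the depth).
#' @return A wide chart tibble.
#' @export
#' @examples
#' uniform_chart(3)
uniform_chart <- function(ppd, subject_id = sprintf("uniform_%gmm", ppd)) {
  stopifnot(length(ppd) == 1, ppd >= 0)
  teeth <- as.integer(outer(c(10L, 20L, 30L, 40L), 1:7, `+`))
  chart <- tibble::tibble(subject_id = subject_id, tooth = teeth)
  for (cc in PPD_COLS) chart[[cc]] <- ppd
  for (cc in BOP_COLS) chart[[cc]] <- 1
  chart
}

#' Depth sweep of both versions
#'
#' Evaluates both formula versions over a grid of uniform probing depths,
#' with all sites bleeding. Per tooth type the reported area is for a single
#' tooth; the whole-mouth `total` scope counts both sides (2 x 14 teeth).
#'
#' @param ppd Depth grid in mm (default the integers 1-10).
#' @param coef_table Coefficient table.
#' @return A tidy tibble of class `pisa_sweep`: `ppd`, `version`, `scope`
#'   (`"tooth_type"` or `"total"`), `jaw`, `tooth_class` (NA for totals),
#'   `area_mm2`. With full bleeding PISA equals PESA, so one area column
#'   serves for both.
#' @export
#' @examples
#' sw <- pisa_sweep()
#' crossover(sw)
pisa_sweep <- function(ppd = 1:10, coef_table = pisa_coefficients()) {
  stopifnot(all(ppd >= 0))
  tt <- coef_table[coef_table$tooth_class != "third_molar", c("jaw", "tooth_class")]
  per_tooth <- tidyr::expand_grid(ppd = ppd, version = VERSIONS, tt)
  per_tooth$area_mm2 <- pesa_area(per_tooth$jaw, per_tooth$tooth_class,
                                  per_tooth$ppd, "japanese", coef_table) * NA
  for (v in VERSIONS) {
    i <- per_tooth$version == v
    per_tooth$area_mm2[i] <- pesa_area(per_tooth$jaw[i], per_tooth$tooth_class[i],
                                       per_tooth$ppd[i], v, coef_table)
  }
  per_tooth$scope <- "tooth_type"
  totals <- per_tooth |>
    dplyr::group_by(.data$ppd, .data$version) |>
    dplyr::summarise(area_mm2 = 2 * sum(.data$area_mm2), .groups = "drop") |>
    dplyr::mutate(scope = "total", jaw = NA_character_, tooth_class = NA_character_)
  out <- dplyr::bind_rows(per_tooth, totals)[
    , c("ppd", "version", "scope", "jaw", "tooth_class", "area_mm2")]
  class(out) <- c("pisa_sweep", class(out))
  out
}

sweep_total_diff <- function(sweep) {
  sweep |>
    dplyr::filter(.data$scope == "total") |>
    dplyr::select("ppd", "version", "area_mm2") |>
    tidyr::pivot_wider(names_from = "version", values_from = "area_mm2") |>
    dplyr::arrange(.data$ppd) |>
    dplyr::mutate(diff = .data$japanese - .data$original)
}

#' Locate crossovers between the versions' whole-mouth totals
#'
#' Scans consecutive grid points of the whole-mouth totals for a sign change
#' of (Japanese - original). A strict sign change between two grid points
#' yields the interval between them; an exact zero at a grid point flanked by
#' opposite signs yields the degenerate interval (x, x). An identically zero
#' difference yields no crossover.
#'
#' @param sweep A `pisa_sweep` result with at least two grid points.
#' @return A tibble with columns `lower`, `upper` (mm); zero rows if the
#'   versions never cross on the grid.
#' @export
crossover <- function(sweep) {
  w <- sweep_total_diff(sweep)
  if (nrow(w) < 2) {
    abort_pisa("crossover(): need at least two grid points.", "pisacalc_bad_grid")
  }
  d <- w$diff
  x <- w$ppd
  out <- tibble::tibble(lower = double(), upper = double())
  s <- sign(d)
  for (i in seq_len(length(d) - 1)) {
    if (s[i] * s[i + 1] < 0) {
      out <- dplyr::bind_rows(out, tibble::tibble(lower = x[i], upper = x[i + 1]))
    }
  }
  zero <- which(s == 0)
  for (i in zero) {
    prev_s <- if (any(s[seq_len(i - 1)] != 0)) s[max(which(s[seq_len(i - 1)] != 0))] else 0
    rest <- if (i < length(s)) s[(i + 1):length(s)] else integer(0)
    next_s <- if (any(rest != 0)) rest[which(rest != 0)[1]] else 0
    if (prev_s * next_s < 0) {
      out <- dplyr::bind_rows(out, tibble::tibble(lower = x[i], upper = x[i]))
    }
  }
  dplyr::arrange(out, .data$lower)
}

#' Whole-mouth ratio of the Japanese to the original version
#'
#' @param sweep A `pisa_sweep` result.
#' @return A tibble: `ppd`, `japanese`, `original`, `ratio`, `undefined`
#'   (TRUE where the original total is zero; `ratio` is NA there rather than
#'   an infinity).
#' @export
version_ratio <- function(sweep) {
  w <- sweep_total_diff(sweep)
  w$undefined <- w$original == 0
  w$ratio <- ifelse(w$undefined, NA_real_, w$japanese / w$original)
  w[c("ppd", "japanese", "original", "ratio", "undefined")]
}

#' Plot a depth sweep
#'
#' Whole-mouth totals by version, and optionally the per-tooth-type curves
#' facetted by jaw and class.
#'
#' @param object A `pisa_sweep` result.
#' @param scope `"total"` (default) or `"tooth_type"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pisa_sweep <- function(object, scope = c("total", "tooth_type"), ...) {
  scope <- rlang::arg_match(scope)
  dat <- dplyr::filter(tibble::as_tibble(object), .data$scope == !!scope)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$ppd, y = .data$area_mm2,
                                         colour = .data$version)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Probing pocket depth (mm)",
                  y = expression(PISA ~ (mm^2)), colour = "Version")
  if (scope == "tooth_type") {
    p <- p + ggplot2::facet_wrap(~ jaw + tooth_class, scales = "free_y")
  }
  p
}
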