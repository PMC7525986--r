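# Gene presence/absence from per-base coverage.
#
# The statistic is the fraction of a gene's bases covered by at least one
# read ("non-zero-coverage bases"). A gene is called absent when that
# fraction falls strictly below the threshold (default 0.10, i.e. at least
# 90% zero-covered bases). Depth >= 1 counts as covered regardless of
# mapping quality; any MQ filtering belongs upstream of the depth table.

#' Fraction of positions covered by at least one read
#'
#' @param depth Non-negative integer vector of per-base depths.
#' @return Exact fraction in `[0, 1]`.
#' @export
nonzero_coverage_fraction <- function(depth) {
  if (length(depth) == 0L) stop("empty depth vector", call. = FALSE)
  if (any(depth < 0)) stop("negative depth", call. = FALSE)
  sum(depth >= 1) / length(depth)
}

#' Call gene presence/absence from a coverage fraction
#'
#' Absent iff `fraction < threshold` (strict inequality, so a gene at
#' exactly the threshold is called present).
#'
#' @param fraction Non-zero-coverage fraction(s) in `[0, 1]`.
#' @param threshold Absence threshold, default 0.10.
#' @return Tibble with columns `nonzero_fraction`, `threshold`, `call`.
#' @export
call_presence <- function(fraction, threshold = 0.10) {
  if (any(fraction < 0 | fraction > 1)) {
    stop("fraction must be in [0, 1]", call. = FALSE)
  }
  tibble::tibble(
    nonzero_fraction = fraction,
    threshold = threshold,
    call = ifelse(fraction < threshold, "absent", "present")
  )
}

#' Presence/absence report over a depth table
#'
#' One row per (sample, gene): the non-zero-coverage fraction, the
#' integer percentage (rounded half-up, as printed in reports) and the
#' presence call.
#'
#' @param depth_tbl Tibble from [read_depth_table()] or
#'   [simulate_depth_track()]; columns `gene`, `depth`, optionally `sample`.
#' @param threshold Absence threshold, default 0.10.
#' @return Tibble with columns `sample` (if present), `gene`,
#'   `nonzero_fraction`, `percent`, `call`.
#' @export
presence_report <- function(depth_tbl, threshold = 0.10) {
  depth_tbl <- tibble::as_tibble(depth_tbl)
  keys <- intersect(c("sample", "gene"), names(depth_tbl))
  out <- depth_tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      nonzero_fraction = nonzero_coverage_fraction(.data$depth),
      .groups = "drop"
    )
  out$percent <- round_half_up(100 * out$nonzero_fraction)
  out$call <- ifelse(out$nonzero_fraction < threshold, "absent", "present")
  out
}

# round-half-up to integer (reports print integer percentages; the rounding
# convention is round-half-up, documented in the vignette)
round_half_up <- function(x) floor(x + 0.5)

#' Render a wide presence table (genomes x genes)
#'
#' @param report Output of [presence_report()] with a `sample` column.
#' @return Wide tibble, one row per sample, integer-percent cells.
#' @export
presence_wide <- function(report) {
  stopifnot("sample" %in% names(report))
  tidyr::pivot_wider(
    report[, c("sample", "gene", "percent")],
    names_from = "gene", values_from = "percent"
  )
}
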