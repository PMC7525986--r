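# ggplot2 visualisations for the main result types.

#' Plot site-wise selection calls
#'
#' Per-method calls along the codon axis, with ABS positions shaded and
#' consensus calls drawn as triangles.
#'
#' @param object A `site_consensus` table from [consensus_sites()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.site_consensus <- function(object, ...) {
  long <- object |>
    dplyr::select(dplyr::all_of("codon"), dplyr::starts_with("class_")) |>
    tidyr::pivot_longer(dplyr::starts_with("class_"),
      names_to = "method", values_to = "class",
      names_prefix = "class_"
    )
  abs_df <- object[object$is_abs, "codon", drop = FALSE]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$codon, y = .data$method)) +
    ggplot2::geom_vline(
      data = abs_df, ggplot2::aes(xintercept = .data$codon),
      colour = "grey85", linewidth = 1.5
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class), size = 2) +
    ggplot2::geom_point(
      data = dplyr::mutate(
        object[object$consensus != "none", c("codon", "consensus")],
        method = "consensus"
      ),
      ggplot2::aes(colour = .data$consensus), shape = 17, size = 3
    ) +
    ggplot2::scale_colour_manual(
      values = c(positive = "#d55e00", negative = "#0072b2", none = "grey70"),
      name = "call"
    ) +
    ggplot2::labs(
      x = "codon position", y = NULL,
      title = "Site-wise selection calls (ABS positions shaded)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a recombination scan trace
#'
#' Per-candidate two-partition cAIC against the single-tree cAIC line.
#'
#' @param object An `sbp_scan` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sbp_scan <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$breakpoint, y = .data$caic)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(
      yintercept = object$caic_single,
      linetype = "dashed", colour = "#d55e00"
    ) +
    ggplot2::annotate("text",
      x = min(object$trace$breakpoint), y = object$caic_single,
      label = "single tree", vjust = -0.5, hjust = 0, size = 3, colour = "#d55e00"
    ) +
    ggplot2::labs(
      x = "breakpoint (codon boundary)", y = "cAIC",
      title = sprintf("Single-breakpoint scan (delta cAIC = %.1f)", object$delta_caic)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a per-base depth track with the presence threshold
#'
#' @param depth_tbl Tibble with `gene`, `pos`, `depth`.
#' @param threshold Presence threshold annotated in the subtitle.
#' @return A ggplot object.
#' @export
plot_depth_track <- function(depth_tbl, threshold = 0.10) {
  frac <- depth_tbl |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(f = mean(.data$depth >= 1), .groups = "drop")
  lab <- paste0(
    frac$gene, " (", round_half_up(100 * frac$f), "% non-zero)"
  )
  names(lab) <- frac$gene
  ggplot2::ggplot(depth_tbl, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_area(fill = "#0072b2", alpha = 0.7) +
    ggplot2::facet_wrap(~gene,
      scales = "free", ncol = 1,
      labeller = ggplot2::labeller(gene = lab)
    ) +
    ggplot2::labs(
      x = "position (bp)", y = "depth",
      subtitle = paste0(
        "absence called below ",
        round_half_up(100 * threshold), "% non-zero-coverage bases"
      )
    ) +
    ggplot2::theme_minimal()
}
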