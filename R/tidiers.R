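# broom-style accessors and ggplot2 views of screen results.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a screen result
#'
#' One row per candidate locus with the scalar annotation columns (list
#' columns and the full polyprotein string are dropped; they remain on
#' `x$candidates`).
#'
#' @param x An `eve_screen` from [run_screen()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.eve_screen <- function(x, ...) {
  x$candidates |>
    select(-dplyr::any_of(c("gc_sequons", "polyprotein")))
}

#' One-row summary of a screen
#'
#' @param x An `eve_screen`.
#' @param ... Unused.
#' @return Tibble with locus and verdict counts.
#' @export
glance.eve_screen <- function(x, ...) {
  v <- x$candidates$verdict
  tibble(
    n_hits = nrow(x$hits),
    n_loci = nrow(x$candidates),
    n_intact = sum(v == "intact_EVE_phlebovirus_env"),
    n_complete_other = sum(v == "complete_polyprotein_other_env"),
    n_incomplete = sum(v == "incomplete"),
    n_rejected = sum(v == "rejected")
  )
}

#' Element map of a screen result
#'
#' Elements as horizontal segments per contig, LTRs as ticks, colored by
#' verdict.
#'
#' @param object An `eve_screen`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eve_screen <- function(object, ...) {
  cands <- object$candidates |>
    mutate(y = factor(.data$contig),
           xs = ifelse(is.na(.data$element_start), .data$locus_start,
                       .data$element_start),
           xe = ifelse(is.na(.data$element_end), .data$locus_end,
                       .data$element_end))
  p <- ggplot2::ggplot(cands) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$xs / 1000, xend = .data$xe / 1000,
                   y = .data$y, yend = .data$y, color = .data$verdict),
      linewidth = 3, lineend = "butt") +
    ggplot2::labs(x = "position (kb)", y = NULL, color = "verdict") +
    ggplot2::theme_minimal()
  ltrs <- cands |> filter(!is.na(.data$ltr5_start))
  if (nrow(ltrs)) {
    p <- p + ggplot2::geom_point(
      data = tidyr::pivot_longer(
        ltrs |> select("y", "ltr5_start", "ltr3_start"),
        cols = c("ltr5_start", "ltr3_start"), values_to = "x"),
      ggplot2::aes(x = .data$x / 1000, y = .data$y), shape = "|", size = 4)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Hydropathy profile plot with TM calls
#'
#' @param protein Amino-acid string.
#' @param window,threshold,min_len Passed to the profile and TM caller.
#' @return A ggplot of the sliding-window profile with the threshold line
#'   and predicted TM segments shaded.
#' @export
plot_hydropathy <- function(protein, window = 19, threshold = 1.6,
                            min_len = 17) {
  prof <- hydropathy_profile(protein, window)
  tm <- predict_tm_segments(prof, threshold = threshold, min_len = min_len)
  p <- ggplot2::ggplot(prof, ggplot2::aes(x = .data$position,
                                          y = .data$hydropathy)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "residue", y = "mean hydropathy (Kyte-Doolittle)") +
    ggplot2::theme_minimal()
  if (nrow(tm)) {
    p <- p + ggplot2::geom_rect(
      data = tm, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      alpha = 0.15, fill = "steelblue")
  }
  p
}
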