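#' @importFrom ggplot2 ggplot aes geom_raster geom_line geom_point geom_col
#'   geom_vline scale_fill_viridis_c labs theme_minimal autoplot
#'   scale_y_log10 scale_x_log10 facet_wrap geom_tile
NULL

#' Plot a contact map
#'
#' Log-scaled heatmap of one chromosome's values (raw, balanced or O/E).
#'
#' @param object A [contact_map()].
#' @param chrom Chromosome to draw (default first).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.contact_map <- function(object, chrom = NULL, ...) {
  chrom <- chrom %||% object$grid$chroms[1]
  v <- map_values(object, chrom)
  res <- object$grid$resolution
  df <- tibble(x = (as.vector(col(v)) - 0.5) * res / 1e6,
               y = (as.vector(row(v)) - 0.5) * res / 1e6,
               value = as.vector(v))
  ggplot(df, aes(.data$x, .data$y, fill = log10(.data$value + 1e-9))) +
    geom_raster() +
    scale_fill_viridis_c(name = "log10 signal") +
    labs(x = paste0(chrom, " (Mb)"), y = NULL,
         title = sprintf("%s map, %s", object$kind, chrom)) +
    theme_minimal()
}

#' Plot a separation-score track
#'
#' @param object A [tad_separation_score()] track.
#' @param boundaries Optional `boundary_set` to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.separation_track <- function(object, boundaries = NULL, ...) {
  p <- ggplot(object, aes(.data$pos / 1e6, .data$score)) +
    geom_line(na.rm = TRUE) +
    facet_wrap(~chrom, scales = "free_x") +
    labs(x = "position (Mb)", y = "TAD-separation score") +
    theme_minimal()
  if (!is.null(boundaries) && nrow(boundaries) > 0)
    p <- p + geom_vline(data = boundaries,
                        aes(xintercept = .data$pos / 1e6),
                        linetype = "dashed", colour = "red")
  p
}

#' Plot a distance-decay profile
#'
#' Log-log expected contact vs distance with the fitted exponent in the
#' title.
#'
#' @param object A `decay_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decay_profile <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), .data$distance > 0,
                      !is.na(.data$expected), .data$expected > 0)
  ggplot(df, aes(.data$distance, .data$expected)) +
    geom_line() +
    scale_x_log10() + scale_y_log10() +
    labs(x = "distance (bins)", y = "expected balanced contact",
         title = sprintf("distance decay (alpha = %.2f)", attr(object, "alpha"))) +
    theme_minimal()
}

#' Plot a Hi-C boundary metaplot
#'
#' @param object A `hic_metaplot`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hic_metaplot <- function(object, ...) {
  df <- tidy.hic_metaplot(object)
  ggplot(df, aes(.data$offset_col, .data$offset_row, fill = .data$mean_oe)) +
    geom_tile() +
    scale_fill_viridis_c(name = "mean O/E") +
    labs(x = "offset (bins)", y = "offset (bins)",
         title = sprintf("mean contacts around %d boundaries",
                         object$n_boundaries)) +
    theme_minimal()
}

#' Plot an RNA boundary metaplot
#'
#' Forward and reverse mean track signal around boundaries; at convergent
#' boundaries the forward strand dominates upstream and the reverse strand
#' downstream.
#'
#' @param profile A [rna_boundary_metaplot()] tibble.
#' @return A ggplot.
#' @export
plot_rna_metaplot <- function(profile) {
  df <- tidyr::pivot_longer(profile, c("forward", "reverse"),
                            names_to = "strand", values_to = "signal")
  ggplot(df, aes(.data$offset / 1e3, .data$signal, colour = .data$strand)) +
    geom_line() +
    geom_vline(xintercept = 0, linetype = "dashed") +
    labs(x = "offset from boundary (kb)", y = "mean summed TPM") +
    theme_minimal()
}

#' Plot a condition trend
#'
#' Mean boundary strength per condition in dose order.
#'
#' @param object A `condition_trend`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.condition_trend <- function(object, ...) {
  ggplot(object$summary, aes(.data$dose_rank, .data$mean_strength)) +
    geom_line() + geom_point() +
    labs(x = "dose rank", y = "mean boundary strength",
         title = sprintf("insulation vs dose (rho = %.2f, p = %.3g)",
                         object$rho, object$p_value)) +
    theme_minimal()
}
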