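#' Plot a circuit trajectory
#'
#' Time courses of the requested species, faceted on free y scales.
#'
#' @param object A `circuit_trajectory`.
#' @param species Character vector of species to show; default Hes mRNA,
#'   homodimer and proneural mRNA/activity.
#' @param post_transient_only Drop the transient span? Default `TRUE`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.circuit_trajectory <- function(object,
                                        species = c("m", "p2", "ma", "a2"),
                                        post_transient_only = TRUE, ...) {
  dat <- if (post_transient_only) post_transient(object) else object
  long <- tidy(dat) |>
    dplyr::filter(.data$species %in% !!species) |>
    dplyr::mutate(species = factor(.data$species, levels = !!species))
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$species), scales = "free_y",
                        ncol = 1) +
    ggplot2::labs(x = "time (min)", y = "molecules per cell") +
    ggplot2::theme_minimal()
}

#' Plot a phase diagram
#'
#' Heat map over the two swept parameters. `fill = "fate"` shows the
#' three-way qNSC/aNSC/Diff partition; `fill = "period"` or
#' `"mean_proneural"` show the underlying continuous summaries
#' (non-oscillatory cells are blank on the period map).
#'
#' @param object A `phase_diagram` from [sweep_2d()].
#' @param fill One of `"fate"`, `"period"`, `"mean_proneural"`,
#'   `"temporal_mean"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_diagram <- function(object, fill = c("fate", "period",
                                                    "mean_proneural",
                                                    "temporal_mean"), ...) {
  fill <- match.arg(fill)
  ax <- attr(object, "axes")
  p <- ggplot2::ggplot(object, ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]])) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data[[fill]])) +
    ggplot2::labs(x = ax[1], y = ax[2]) +
    ggplot2::theme_minimal()
  if (fill == "fate") {
    p <- p + ggplot2::scale_fill_manual(values = c(
      qNSC = "#2166ac", aNSC = "#92c5de", Diff = "#b2182b"), drop = FALSE)
  } else {
    p <- p + ggplot2::scale_fill_viridis_c(na.value = "white")
  }
  p
}

#' Plot a Notch dose-response table
#'
#' Envelope (max/min) and temporal-mean curves of one species against the
#' Notch input, the standard summary of a one-dimensional dose sweep.
#'
#' @param dose A tibble from [notch_dose_response()].
#' @param species `"m"` (Hes mRNA) or `"ma"` (proneural mRNA).
#' @return A ggplot object.
#' @export
plot_dose_response <- function(dose, species = "m") {
  dat <- dplyr::filter(dose, .data$species == !!species)
  ggplot2::ggplot(dat, ggplot2::aes(.data$I)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$env_min,
                                      ymax = .data$env_max),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$temporal_mean),
                       linetype = "dashed") +
    ggplot2::labs(x = "Notch input I (molecules)",
                  y = paste0(species, " (molecules)")) +
    ggplot2::theme_minimal()
}

#' Plot cells on Hes/Id score axes
#'
#' The subpopulation scatter: each cell at its (ID-panel, Hes-panel) score
#' with the classification threshold drawn on both axes.
#'
#' @param annotations A `cell_annotation` from [classify_cells()].
#' @param expressed_threshold Threshold to draw. Default 1.
#' @return A ggplot object.
#' @export
plot_subpopulations <- function(annotations, expressed_threshold = 1) {
  ggplot2::ggplot(annotations,
                  ggplot2::aes(.data$id_score, .data$hes_score,
                               colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = expressed_threshold, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = expressed_threshold, linetype = "dotted") +
    ggplot2::labs(x = "ID panel score (log2)", y = "Hes panel score (log2)") +
    ggplot2::theme_minimal()
}

#' Plot a PCA embedding
#'
#' @param object A `cell_pca` from [pca_embed()].
#' @param colour Optional per-cell vector (e.g. a panel score or label) to
#'   colour by.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cell_pca <- function(object, colour = NULL, ...) {
  ev <- attr(object, "explained_variance")
  dat <- as_tibble(object)
  if (!is.null(colour)) dat$colour <- colour
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * ev[2])) +
    ggplot2::theme_minimal()
  if (is.null(colour)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour)) +
      ggplot2::labs(colour = NULL)
  }
}
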