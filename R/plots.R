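#' Plot the DEG / FDEG burst over time
#'
#' Area chart of per-time-point DEG and first-DE (FDEG) counts, up- and
#' down-regulated genes stacked separately.
#'
#' @param object a `wound_de`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot wound_de
#' @export
autoplot.wound_de <- function(object, ...) {
  b <- burst_summary(object)
  long <- tidyr::pivot_longer(
    b[, c("time_min", "n_deg_up", "n_deg_down", "n_fdeg_up", "n_fdeg_down")],
    -"time_min", names_to = "series", values_to = "n")
  long$what <- ifelse(grepl("fdeg", long$series), "FDEG", "DEG")
  long$direction <- ifelse(grepl("up$", long$series), "up", "down")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_min, .data$n,
                                     fill = .data$direction)) +
    ggplot2::geom_area(alpha = 0.7, position = "identity") +
    ggplot2::facet_wrap(~what, ncol = 1, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(up = "#c0392b", down = "#1e8449")) +
    ggplot2::labs(x = "minutes after wounding", y = "genes",
                  title = "Differential-expression burst") +
    ggplot2::theme_minimal()
}

#' Plot fuzzy-cluster mean trajectories
#'
#' @param object a `wound_fuzzy` from [cluster_trajectories()].
#' @param ... unused.
#' @return A ggplot of the unstandardized mean log2 fold-change trajectory
#'   per cluster, coloured by direction.
#' @method autoplot wound_fuzzy
#' @export
autoplot.wound_fuzzy <- function(object, ...) {
  if (is.null(object$mean_trajectories)) {
    abort("autoplot needs the trajectories from cluster_trajectories().")
  }
  traj <- as_tibble(object$mean_trajectories, rownames = "cluster")
  long <- tidyr::pivot_longer(traj, -"cluster", names_to = "time_min",
                              values_to = "log2fc")
  long$time_min <- as.numeric(long$time_min)
  long$direction <- unname(object$directions[long$cluster])
  ggplot2::ggplot(long, ggplot2::aes(.data$time_min, .data$log2fc,
                                     colour = .data$direction)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#1e8449")) +
    ggplot2::labs(x = "minutes after wounding", y = "mean log2 fold change",
                  title = "Temporal expression clusters") +
    ggplot2::theme_minimal()
}

#' Plot the inferred transcriptional phases
#'
#' @param object a `wound_chronology`.
#' @param ... unused.
#' @return A ggplot showing each gene set's contiguous phase intervals.
#' @method autoplot wound_chronology
#' @export
autoplot.wound_chronology <- function(object, ...) {
  ph <- purrr::map_dfr(names(object$phases), function(s) {
    dplyr::mutate(object$phases[[s]], set = s, .before = 1)
  })
  ph$end_plot <- ifelse(ph$end_min == ph$start_min,
                        ph$start_min + 1, ph$end_min)
  ggplot2::ggplot(ph, ggplot2::aes(xmin = .data$start_min,
                                   xmax = .data$end_plot,
                                   ymin = as.numeric(factor(.data$set)) - 0.4,
                                   ymax = as.numeric(factor(.data$set)) + 0.4,
                                   fill = .data$label)) +
    ggplot2::geom_rect(colour = "white") +
    ggplot2::scale_y_continuous(breaks = seq_along(unique(ph$set)),
                                labels = sort(unique(ph$set))) +
    ggplot2::labs(x = "minutes after wounding", y = NULL, fill = "phase",
                  title = "Transcriptional phases") +
    ggplot2::theme_minimal()
}

#' Plot module-volatile correlations
#'
#' @param object a `wound_network` with a module-trait table.
#' @param ... unused.
#' @return A ggplot heat map of Pearson r per (module, metabolite);
#'   significant pairs (p < 0.05) are starred.
#' @method autoplot wound_network
#' @export
autoplot.wound_network <- function(object, ...) {
  mt <- object$module_trait
  if (is.null(mt)) abort("No module-trait correlations in this network.")
  ggplot2::ggplot(mt, ggplot2::aes(.data$metabolite, .data$module,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$significant, "*", "")),
                       size = 5) +
    ggplot2::scale_fill_gradient2(low = "#2471a3", mid = "white",
                                  high = "#c0392b", limits = c(-1, 1)) +
    ggplot2::labs(title = "Module-volatile correlation", x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot PCA sample scores
#'
#' @param object a `wound_pca`.
#' @param samples optional sample sheet to colour by group.
#' @param ... unused.
#' @return A ggplot of the first two principal components.
#' @method autoplot wound_pca
#' @export
autoplot.wound_pca <- function(object, samples = NULL, ...) {
  sc <- object$scores
  if (!is.null(samples)) {
    sc <- dplyr::left_join(sc, samples, by = "sample_id")
    pl <- ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2,
                                           colour = .data$group,
                                           size = .data$time_min))
  } else {
    pl <- ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2))
  }
  pl + ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2]),
      title = "Sample principal components") +
    ggplot2::theme_minimal()
}
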