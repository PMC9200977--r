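## Optional figures (ggplot2, Suggests).

#' Plot per-parameter AUC-ROC panels
#'
#' Mean out-of-bag AUC-ROC per PLR parameter with SD error bars, one panel
#' per eye, points coloured by condition, dashed reference line at
#' AUC = 0.7.
#'
#' @param results the `results` data.frame from [runPipeline()]
#' @param conditions conditions to show
#' @return a ggplot object
#' @export
plotAUCPanel <- function(results, conditions = c("dim_red", "dim_blue")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- results[results$condition %in% conditions, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter, y = .data$auc_mean,
                                   colour = .data$condition)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.5)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$auc_mean - .data$auc_sd,
                   ymax = .data$auc_mean + .data$auc_sd),
      width = 0.3, position = ggplot2::position_dodge(0.5)) +
    ggplot2::geom_hline(yintercept = 0.7, linetype = "dashed") +
    ggplot2::facet_wrap(~eye) +
    ggplot2::scale_colour_manual(
      values = c(dim_red = "#c0392b", dim_blue = "#2980b9",
                 bright_red = "#e74c3c", bright_blue = "#3498db")) +
    ggplot2::labs(x = "PLR parameter", y = "out-of-bag AUC-ROC") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Plot a visual-field weight map
#'
#' Bootstrap-averaged per-target model weights on the 24-2 grid layout.
#'
#' @param map weight map (from [weightMap()]) over the 54 dim-light
#'   targets
#' @param eye which eye's grid to draw
#' @return a ggplot object
#' @export
plotWeightMap <- function(map, eye = c("right", "left")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  eye <- match.arg(eye)
  g <- makeGrid(eye)
  targ <- as.integer(sub("^T", "", names(map)))
  g$weight <- map[match(g$index, targ)]
  ggplot2::ggplot(g, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data$weight)) +
    ggplot2::geom_tile(width = 5, height = 5, colour = "grey40") +
    ggplot2::scale_fill_gradient(low = "white", high = "#1a237e") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "visual field x (deg)", y = "visual field y (deg)",
                  title = paste(eye, "eye")) +
    ggplot2::theme_minimal()
}
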