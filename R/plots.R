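# ggplot2 visualisations for the main result types.

#' Plot a decision curve
#'
#' @param object A `hab_decision_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hab_decision_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
    cols = c("model", "treat_all", "treat_none"),
    names_to = "strategy", values_to = "net_benefit"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$threshold, y = .data$net_benefit,
    colour = .data$strategy
  )) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.05, NA)) +
    ggplot2::labs(
      x = "threshold probability", y = "net benefit",
      title = "Decision-curve analysis"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a calibration curve
#'
#' @param object A `hab_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hab_calibration <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$mean_predicted, y = .data$observed_rate)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "mean predicted probability", y = "observed event rate",
      subtitle = sprintf(
        "recalibration intercept %.2f, slope %.2f",
        attr(object, "intercept"), attr(object, "slope")
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve for an evaluation report
#'
#' @param object A `hab_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hab_eval <- function(object, ...) {
  if (is.na(object$auc)) stop("AUC undefined for this evaluation", call. = FALSE)
  y <- object$labels
  s <- object$scores
  cuts <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
  pts <- tibble::tibble(
    tpr = vapply(cuts, function(t) mean(s[y == 1] >= t), numeric(1)),
    fpr = vapply(cuts, function(t) mean(s[y == 0] >= t), numeric(1))
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf(
        "%s: AUC %.3f (95%% CI %.3f-%.3f)",
        object$model_id, object$auc, object$auc_ci[1], object$auc_ci[2]
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot habitat composition fractions
#'
#' @param composition Tibble from [habitat_composition()], optionally with a
#'   `timepoint` column for paired display.
#' @return A ggplot object.
#' @export
plot_habitat_composition <- function(composition) {
  p <- ggplot2::ggplot(composition, ggplot2::aes(
    x = factor(.data$habitat), y = .data$fraction,
    fill = factor(.data$habitat)
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", name = "habitat") +
    ggplot2::labs(
      x = "habitat (1 = highest enhancement)",
      y = "volume fraction"
    ) +
    ggplot2::theme_minimal()
  if ("timepoint" %in% names(composition)) {
    p <- p + ggplot2::facet_wrap(~timepoint)
  }
  p
}

#' Plot an axial slice of a habitat map
#'
#' @param map A `hab_map`.
#' @param slice Axial slice index (middle slice by default).
#' @return A ggplot object.
#' @export
plot_habitat_slice <- function(map, slice = NULL) {
  d <- dim(map$labels)
  if (is.null(slice)) {
    zs <- apply(map$labels > 0, 3, sum)
    slice <- which.max(zs)
  }
  m <- map$labels[, , slice]
  df <- tibble::tibble(
    x = as.vector(row(m)), y = as.vector(col(m)),
    habitat = factor(ifelse(as.vector(m) == 0, NA, as.vector(m)))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$habitat)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", na.value = "grey95") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("habitat map, slice %d", slice)) +
    ggplot2::theme_void()
}

#' Heatmap of feature-immune Spearman correlations
#'
#' @param object A `hab_immune_cor`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hab_immune_cor <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$feature, y = .data$cell_type, fill = .data$rho)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
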