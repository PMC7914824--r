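# ggplot2 views of recordings, importance rankings and evaluation reports.

#' @export
autoplot.pcg_recording <- function(object, seg = NULL, ...) {
  t <- (seq_along(object$samples) - 1L) / object$rate
  df <- tibble::tibble(time = t, amplitude = object$samples)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "amplitude",
                  title = sprintf("Patient %s, auscultation point %d",
                                  object$patient_id, object$point_id))
  if (!is.null(seg)) {
    shade <- tibble::tibble(
      xmin = c(seg$s1_start, seg$s2_start) / object$rate,
      xmax = c(seg$m1_start, seg$m2_start) / object$rate,
      phase = rep(c("S1", "S2"), each = nrow(seg)))
    p <- p + ggplot2::geom_rect(
      data = shade, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf, fill = .data$phase),
      alpha = 0.2)
  }
  p
}

#' Plot a gain-importance ranking
#'
#' @param ranking Tibble from [gain_importance()].
#' @param n Number of top features to show.
#' @return A ggplot object.
#' @export
plot_importance <- function(ranking, n = 15) {
  top <- head(ranking, n)
  top$feature <- factor(top$feature, levels = rev(top$feature))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$gain, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cumulative split gain", y = NULL,
                  title = sprintf("Top-%d features by gain", nrow(top)))
}

#' @export
autoplot.pcg_eval <- function(object, ...) {
  pp <- object$patient_probs
  y <- as_binary_label(factor(pp$label, levels = unique(c("healthy", pp$label))))
  ord <- order(pp$prob, decreasing = TRUE)
  tpr <- cumsum(y[ord] == 1) / sum(y == 1)
  fpr <- cumsum(y[ord] == 0) / sum(y == 0)
  roc <- tibble::tibble(fpr = c(0, fpr), tpr = c(0, tpr))
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("Patient-level ROC, test AUC %.3f", object$test_auc))
}
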