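#' Deviance / rank scatterplots of the batch-bias diagnostic
#'
#' The canonical diagnostic view: per-gene deviance without the batch
#' covariate (x) against deviance with it (y), or the same for deviance
#' ranks. Points are coloured by binned nSD of RCD (deviance view) or RD
#' (rank view); the identity line marks "batch changes nothing"; flagged
#' genes fall below it (deviance view) and are labelled.
#'
#' @param bias an `svg_bias` object from [detect_bias()].
#' @param batch_var batch variable to plot; default the first one present.
#' @param type `"deviance"` or `"rank"`.
#' @param label_flagged label flagged genes with their IDs (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_deviance_scatter <- function(bias, batch_var = NULL,
                                  type = c("deviance", "rank"),
                                  label_flagged = TRUE) {
  stopifnot(inherits(bias, "svg_bias"))
  type <- match.arg(type)
  batch_var <- batch_var %||% names(bias$flagged)[1L]
  tbl <- dplyr::filter(bias$table, .data$batch_var == !!batch_var)
  if (nrow(tbl) == 0L) {
    stop("batch variable `", batch_var, "` not present in the bias table",
         call. = FALSE)
  }

  if (type == "deviance") {
    tbl$.x <- tbl$d_default
    tbl$.y <- tbl$d_batch
    tbl$.stat <- tbl$nsd_rcd
    labs <- ggplot2::labs(
      x = "deviance, no covariate", y = paste0("deviance, ", batch_var),
      colour = "nSD(RCD)",
      title = paste0("Change in binomial deviance: ", batch_var))
  } else {
    tbl$.x <- tbl$r_default
    tbl$.y <- tbl$r_batch
    tbl$.stat <- tbl$nsd_rd
    labs <- ggplot2::labs(
      x = "rank, no covariate", y = paste0("rank, ", batch_var),
      colour = "nSD(RD)",
      title = paste0("Change in deviance rank: ", batch_var))
  }
  tbl$.bin <- cut(pmin(tbl$.stat, 1e6),   # bin Inf sentinels with the top
                  breaks = c(-Inf, 1, 2, 3, Inf),
                  labels = c("< 1", "1–2", "2–3", "> 3"))

  p <- ggplot2::ggplot(tbl, ggplot2::aes(.data$.x, .data$.y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$.bin), size = 1.2,
                        alpha = 0.8) +
    ggplot2::scale_colour_manual(
      values = c("< 1" = "grey65", "1–2" = "#9ecae1",
                 "2–3" = "#fd8d3c", "> 3" = "#de2d26"),
      drop = FALSE) +
    labs +
    ggplot2::theme_bw()
  if (label_flagged && any(tbl$flagged)) {
    p <- p + ggplot2::geom_text(
      data = dplyr::filter(tbl, .data$flagged),
      ggplot2::aes(label = .data$gene_id),
      size = 2.6, hjust = -0.1, vjust = -0.4, check_overlap = TRUE)
  }
  p
}

#' @describeIn detect_bias deviance or rank scatterplot; see
#'   [plot_deviance_scatter()].
#' @param object an `svg_bias` object.
#' @inheritParams plot_deviance_scatter
#' @exportS3Method ggplot2::autoplot
autoplot.svg_bias <- function(object, batch_var = NULL,
                              type = c("deviance", "rank"), ...) {
  plot_deviance_scatter(object, batch_var = batch_var, type = type, ...)
}
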