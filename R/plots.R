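#' Volcano plot of a differential-expression result
#'
#' @param de An `igc_de` result from [nb_wald_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, ...) {
  dat <- tidy(de) |>
    dplyr::filter(!is.na(.data$p_adj)) |>
    dplyr::mutate(neglog10 = -log10(pmax(.data$p_adj, 1e-300)))
  ggplot2::ggplot(dat, ggplot2::aes(.data$log2fc, .data$neglog10,
                                    color = .data$call)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_color_manual(values = c(up = "#c0392b", down = "#2471a3",
                                           ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change (tumor / normal)",
                  y = "-log10 adjusted p", color = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.igc_de <- function(object, ...) plot_volcano(object, ...)

#' @export
autoplot.roc_result <- function(object, ...) {
  pos <- object$data$value[object$data$label == "tumor"]
  neg <- object$data$value[object$data$label != "tumor"]
  if (object$orientation == "flipped") {
    pos <- -pos; neg <- -neg
  }
  thr <- sort(unique(c(-Inf, object$data$value, Inf)), decreasing = TRUE)
  curve <- tibble::tibble(
    fpr = vapply(thr, function(t) mean(neg >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(pos >= t), numeric(1))
  )
  ggplot2::ggplot(curve, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", color = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("AUC = %.3f (%s)", object$auc, object$band)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.survival_comparison <- function(object, ...) {
  dat <- tidy(object)
  # prepend t = 0, S = 1 per group so curves start at the origin
  origins <- dplyr::distinct(dat, .data$group) |>
    dplyr::mutate(time = 0, surv = 1)
  dat <- dplyr::bind_rows(origins, dat[c("group", "time", "surv")])
  subtitle <- if (isTRUE(object$degenerate)) {
    "no events observed"
  } else {
    sprintf("log-rank p = %.4g", object$p_value)
  }
  ggplot2::ggplot(dat, ggplot2::aes(.data$time, .data$surv,
                                    color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability",
                  color = "Expression", subtitle = subtitle) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.regulatory_circuit <- function(object, ...) {
  edges <- object$edges
  if (nrow(edges) == 0L) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = sprintf("%s (empty)", object$circuit_type)))
  }
  mirnas <- sort(unique(edges$mirna_id))
  genes <- sort(unique(edges$gene_id))
  pos <- function(ids) seq(0, 1, length.out = max(length(ids), 2))[seq_along(ids)]
  nodes <- dplyr::bind_rows(
    tibble::tibble(id = mirnas, x = 0, y = pos(mirnas), side = "miRNA"),
    tibble::tibble(id = genes, x = 1, y = pos(genes), side = "gene"))
  seg <- edges |>
    dplyr::mutate(y0 = nodes$y[match(.data$mirna_id, nodes$id)],
                  y1 = nodes$y[match(.data$gene_id, nodes$id)])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = 0, xend = 1,
                                       y = .data$y0, yend = .data$y1),
                          color = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(.data$x, .data$y, shape = .data$side),
                        size = 2) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y, label = .data$id,
                                    hjust = ifelse(.data$x == 0, 1.1, -0.1)),
                       size = 2.5) +
    ggplot2::scale_x_continuous(limits = c(-0.5, 1.5)) +
    ggplot2::labs(title = object$circuit_type) +
    ggplot2::theme_void()
}

#' @export
autoplot.enrichment_result <- function(object, top = 15, ...) {
  dat <- utils::head(object, top) |>
    dplyr::mutate(set_id = stats::reorder(.data$set_id,
                                          -log10(pmax(.data$p_adj, 1e-300))))
  ggplot2::ggplot(dat, ggplot2::aes(-log10(pmax(.data$p_adj, 1e-300)),
                                    .data$set_id, fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "-log10 adjusted p", y = NULL, fill = "p_adj <= alpha") +
    ggplot2::theme_minimal()
}
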