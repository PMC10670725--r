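#' Tidiers for pipeline result objects
#'
#' `tidy()` returns the per-element detail of a result as a tibble;
#' `glance()` returns a one-row summary.
#'
#' @param x A result object (`igc_de`, `roc_result`,
#'   `survival_comparison`, `correlation_result`, `km_curve`,
#'   `regulatory_circuit`, or `igc_pipeline`).
#' @param ... Unused.
#' @name mircircuit-tidiers
NULL

#' @rdname mircircuit-tidiers
#' @export
tidy.igc_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "igc_de")
  tibble::as_tibble(out)
}

#' @rdname mircircuit-tidiers
#' @export
glance.igc_de <- function(x, ...) {
  tibble::tibble(
    kind = attr(x, "kind"),
    n_features = nrow(x),
    n_tested = sum(!is.na(x$p_value)),
    n_up = sum(x$call == "up"),
    n_down = sum(x$call == "down"),
    alpha = attr(x, "alpha"),
    lfc_threshold = attr(x, "lfc_threshold")
  )
}

#' @rdname mircircuit-tidiers
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, band = x$band, orientation = x$orientation,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname mircircuit-tidiers
#' @export
tidy.km_curve <- function(x, ...) x$table

#' @rdname mircircuit-tidiers
#' @export
tidy.survival_comparison <- function(x, ...) {
  purrr::imap_dfr(x$km, function(km, grp) {
    dplyr::mutate(km$table, group = grp, .before = 1)
  })
}

#' @rdname mircircuit-tidiers
#' @export
glance.survival_comparison <- function(x, ...) {
  tibble::tibble(logrank_stat = x$logrank_stat, p_value = x$p_value,
                 n_low = x$n[1], n_high = x$n[2],
                 n_events = x$n_events, degenerate = x$degenerate)
}

#' @rdname mircircuit-tidiers
#' @export
glance.correlation_result <- function(x, ...) {
  tibble::tibble(r = x$r, p_value = x$p_value, n = x$n,
                 inverse_significant = x$inverse_significant)
}

#' @rdname mircircuit-tidiers
#' @export
tidy.regulatory_circuit <- function(x, ...) {
  dplyr::mutate(x$edges, circuit_type = x$circuit_type,
                mirna_direction = x$mirna_direction,
                gene_mrna_direction = x$gene_mrna_direction,
                gene_protein_direction = x$gene_protein_direction)
}

#' @rdname mircircuit-tidiers
#' @export
glance.regulatory_circuit <- function(x, ...) circuit_summary(x)

#' @rdname mircircuit-tidiers
#' @export
glance.igc_pipeline <- function(x, ...) {
  s <- x$summaries
  tibble::tibble(
    n_deg = x$manifest$row_counts$deg_up + x$manifest$row_counts$deg_down,
    n_dem = x$manifest$row_counts$dem_up + x$manifest$row_counts$dem_down,
    rrc1_edges = s$n_edges[s$circuit_type == "RRC1"],
    rrc2_edges = s$n_edges[s$circuit_type == "RRC2"],
    irc_edges = s$n_edges[s$circuit_type == "IRC"]
  )
}
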