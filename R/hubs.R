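#' Target-side hubs by maximal clique centrality
#'
#' Scores every target gene of a circuit by maximal clique centrality on
#' the circuit's undirected bipartite graph and returns the top `k`,
#' ranked by score descending with a deterministic lexicographic tie-break
#' on gene ID. On a bipartite circuit the MCC score equals the number of
#' distinct regulators, so the score and regulator-count columns agree by
#' construction.
#'
#' @param circuit A `regulatory_circuit`, or a tibble of edges with columns
#'   `mirna_id` and `gene_id`.
#' @param k Number of hubs to return (default 5).
#' @return A tibble of class `hub_result` with columns `gene_id`,
#'   `mcc_score`, `n_regulators`, plus `circuit_type` and `direction` when
#'   available.
#' @examples
#' edges <- tibble::tibble(mirna_id = c("m1", "m2", "m2"),
#'                         gene_id = c("A", "A", "B"))
#' select_target_hubs(edges, k = 2)
#' @export
select_target_hubs <- function(circuit, k = 5) {
  if (k <= 0) stop("`k` must be positive", call. = FALSE)
  edges <- circuit_edges(circuit)
  if (nrow(edges) == 0L)
    return(empty_hub_tbl(c("gene_id", "mcc_score", "n_regulators")))
  scores <- mcc_score(edges[c("mirna_id", "gene_id")])
  genes <- unique(edges$gene_id)
  n_reg <- edges |>
    dplyr::distinct(.data$mirna_id, .data$gene_id) |>
    dplyr::count(.data$gene_id, name = "n_regulators")
  out <- scores |>
    dplyr::filter(.data$node %in% genes) |>
    dplyr::rename(gene_id = "node", mcc_score = "mcc") |>
    dplyr::left_join(n_reg, by = "gene_id") |>
    dplyr::arrange(dplyr::desc(.data$mcc_score), .data$gene_id) |>
    utils::head(k)
  annotate_hubs(out, circuit,
                direction = function(circ)
                  paste(circ$gene_mrna_direction, circ$gene_protein_direction,
                        sep = "/"))
}

#' Regulator-side hubs by out-degree with tie expansion
#'
#' Ranks regulators (miRNAs) by the number of distinct targets. The
#' returned set is the top `k` expanded to include every regulator tied
#' with the k-th out-degree, so more than `k` hubs may be reported.
#' Coverage is the out-degree as a percentage of the circuit's distinct
#' target count, rounded to one decimal.
#'
#' @inheritParams select_target_hubs
#' @return A tibble of class `hub_result` with columns `mirna_id`,
#'   `out_degree`, `coverage_pct`, plus `circuit_type` and `direction` when
#'   available.
#' @examples
#' edges <- tibble::tibble(mirna_id = c("m1", "m1", "m2"),
#'                         gene_id = c("A", "B", "A"))
#' select_regulator_hubs(edges, k = 1)
#' @export
select_regulator_hubs <- function(circuit, k = 5) {
  if (k <= 0) stop("`k` must be positive", call. = FALSE)
  edges <- circuit_edges(circuit)
  if (nrow(edges) == 0L)
    return(empty_hub_tbl(c("mirna_id", "out_degree", "coverage_pct")))
  n_targets <- dplyr::n_distinct(edges$gene_id)
  deg <- edges |>
    dplyr::distinct(.data$mirna_id, .data$gene_id) |>
    dplyr::count(.data$mirna_id, name = "out_degree") |>
    dplyr::arrange(dplyr::desc(.data$out_degree), .data$mirna_id)
  cutoff <- deg$out_degree[min(k, nrow(deg))]
  out <- deg |>
    dplyr::filter(.data$out_degree >= cutoff) |>
    dplyr::mutate(coverage_pct = round(100 * .data$out_degree / n_targets, 1))
  annotate_hubs(out, circuit, direction = function(circ) circ$mirna_direction)
}

circuit_edges <- function(circuit) {
  if (inherits(circuit, "regulatory_circuit")) return(circuit$edges)
  stopifnot(all(c("mirna_id", "gene_id") %in% names(circuit)))
  tibble::as_tibble(circuit)
}

annotate_hubs <- function(out, circuit, direction) {
  if (inherits(circuit, "regulatory_circuit")) {
    out$circuit_type <- circuit$circuit_type
    out$direction <- direction(circuit)
  }
  class(out) <- c("hub_result", class(out))
  out
}

empty_hub_tbl <- function(cols) {
  out <- tibble::as_tibble(stats::setNames(
    list(character(), numeric(), numeric()), cols))
  class(out) <- c("hub_result", class(out))
  out
}

#' Hub tables for every circuit in a set
#'
#' @param circuits A `circuit_set` from [assemble_circuits()].
#' @param k Hub count per circuit and side (default 5; the regulator side's
#'   tie expansion may return more).
#' @return A list with tibbles `target_hubs` and `regulator_hubs` stacking
#'   all circuits.
#' @export
find_hubs <- function(circuits, k = 5) {
  stopifnot(inherits(circuits, "circuit_set"))
  out <- list(
    target_hubs = purrr::map_dfr(circuits, select_target_hubs, k = k),
    regulator_hubs = purrr::map_dfr(circuits, select_regulator_hubs, k = k)
  )
  attr(out, "edges") <- purrr::map_dfr(circuits, `[[`, "edges")
  out
}
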