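#' Filter a miRNA-target interaction table to validated support
#'
#' Drops rows whose `support_type` contains "negative" (case-insensitive
#' substring match, mirroring the refuted-interaction annotation used by
#' curated target databases) and collapses duplicate (miRNA, gene) pairs to
#' a single edge. IDs are harmonized first: gene symbols uppercased, miRNA
#' IDs lowercased, with an optional alias table applied before matching.
#'
#' @param interactions Tibble with columns `mirna_id`, `gene_id`,
#'   `support_type`, and optionally `database`.
#' @param aliases Optional alias tibble with columns `from`, `to`; IDs equal
#'   to `from` (after case harmonization) are replaced by `to`. Use this to
#'   map e.g. precursor to mature miRNA names — no mapping is guessed.
#'
#' @return The filtered, deduplicated interaction tibble.
#' @examples
#' tab <- tibble::tibble(
#'   mirna_id = c("hsa-miR-1", "hsa-miR-1", "hsa-miR-2"),
#'   gene_id = c("Cfl2", "CFL2", "PCNA"),
#'   support_type = c("Functional MTI", "Functional MTI", "Negative"))
#' filter_validated(tab)
#' @export
filter_validated <- function(interactions, aliases = NULL) {
  stopifnot(all(c("mirna_id", "gene_id", "support_type") %in%
                  names(interactions)))
  if (nrow(interactions) == 0L) return(tibble::as_tibble(interactions))
  interactions |>
    dplyr::mutate(mirna_id = harmonize_mirna(.data$mirna_id, aliases),
                  gene_id = harmonize_gene(.data$gene_id, aliases)) |>
    dplyr::filter(!grepl("negative", .data$support_type, ignore.case = TRUE)) |>
    dplyr::distinct(.data$mirna_id, .data$gene_id, .keep_all = TRUE)
}

harmonize_gene <- function(x, aliases = NULL) {
  x <- toupper(trimws(x))
  apply_aliases(x, aliases)
}

harmonize_mirna <- function(x, aliases = NULL) {
  x <- tolower(trimws(x))
  apply_aliases(x, aliases)
}

apply_aliases <- function(x, aliases) {
  if (is.null(aliases)) return(x)
  stopifnot(all(c("from", "to") %in% names(aliases)))
  hit <- match(x, aliases$from)
  ifelse(is.na(hit), x, aliases$to[hit])
}

#' Validate and harmonize a protein differential-expression table
#'
#' @param proteins Tibble with columns `gene_id` and `direction`
#'   (`"up"`/`"down"`). Duplicate rows for a gene are tolerated only if they
#'   agree in direction; conflicting duplicates are an error rather than
#'   being resolved silently.
#' @param aliases Optional alias table as in [filter_validated()].
#' @return A deduplicated tibble with harmonized gene symbols.
#' @export
validate_protein_table <- function(proteins, aliases = NULL) {
  stopifnot(all(c("gene_id", "direction") %in% names(proteins)))
  if (!all(proteins$direction %in% c("up", "down")))
    stop('protein `direction` must be "up" or "down"', call. = FALSE)
  out <- proteins |>
    dplyr::mutate(gene_id = harmonize_gene(.data$gene_id, aliases)) |>
    dplyr::distinct(.data$gene_id, .data$direction)
  dup <- out$gene_id[duplicated(out$gene_id)]
  if (length(dup) > 0)
    stop("conflicting protein directions for: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  out
}

#' Directional overlap groups between DE genes and DE proteins
#'
#' Intersects the up/down differentially expressed gene sets with the
#' up/down protein sets, yielding the four pairwise-disjoint groups that
#' seed circuit assembly: concordant down/down (degradation candidates),
#' concordant up/up (induction candidates), mRNA-up/protein-down
#' (translational-repression candidates), and mRNA-down/protein-up (excluded
#' from circuits downstream as mechanistically unexplained).
#'
#' @param degs A `directional_sets` object for genes from
#'   [call_differential()] (or a list with `up` and `down` character
#'   vectors).
#' @param proteins Protein table (`gene_id`, `direction`), validated via
#'   [validate_protein_table()].
#' @param aliases Optional alias table.
#' @return A list of class `overlap_groups` with character-vector elements
#'   `down_down`, `up_up`, `up_down`, `down_up`.
#' @examples
#' degs <- list(up = c("A", "B"), down = c("C", "D"))
#' prot <- tibble::tibble(gene_id = c("B", "C"), direction = c("down", "down"))
#' build_overlap_groups(degs, prot)
#' @export
build_overlap_groups <- function(degs, proteins, aliases = NULL) {
  proteins <- validate_protein_table(proteins, aliases)
  deg_up <- harmonize_gene(degs$up, aliases)
  deg_down <- harmonize_gene(degs$down, aliases)
  prot_up <- proteins$gene_id[proteins$direction == "up"]
  prot_down <- proteins$gene_id[proteins$direction == "down"]
  structure(
    list(down_down = sort(intersect(deg_down, prot_down)),
         up_up = sort(intersect(deg_up, prot_up)),
         up_down = sort(intersect(deg_up, prot_down)),
         down_up = sort(intersect(deg_down, prot_up))),
    class = "overlap_groups"
  )
}

#' @export
print.overlap_groups <- function(x, ...) {
  cat(sprintf(paste0("<overlap_groups> down/down: %d; up/up: %d; ",
                     "mRNA-up/protein-down: %d; mRNA-down/protein-up: %d\n"),
              length(x$down_down), length(x$up_up),
              length(x$up_down), length(x$down_up)))
  invisible(x)
}

#' Assemble the three mechanism-typed regulatory circuits
#'
#' Applies the classical miRNA regulatory logic to the validated interaction
#' table:
#' * `RRC1` (repression by degradation): up-regulated miRNAs targeting genes
#'   down at both mRNA and protein level;
#' * `RRC2` (translational repression): up-regulated miRNAs targeting genes
#'   up at mRNA but down at protein level;
#' * `IRC` (induction by release): down-regulated miRNAs whose targets are
#'   up at both mRNA and protein level.
#'
#' Genes down at mRNA but up at protein level match no miRNA mechanism and
#' deliberately form no fourth circuit. Nodes without a surviving edge are
#' dropped.
#'
#' @param dems A `directional_sets` object for miRNAs (or list with `up`,
#'   `down`).
#' @param groups An `overlap_groups` object from [build_overlap_groups()].
#' @param validated A filtered interaction table from [filter_validated()].
#' @param aliases Optional alias table.
#' @return A named list of class `circuit_set` with `regulatory_circuit`
#'   elements `RRC1`, `RRC2`, `IRC` (possibly empty).
#' @export
assemble_circuits <- function(dems, groups, validated, aliases = NULL) {
  mir_up <- harmonize_mirna(dems$up, aliases)
  mir_down <- harmonize_mirna(dems$down, aliases)
  edges <- validated |>
    dplyr::select("mirna_id", "gene_id") |>
    dplyr::distinct()

  make <- function(type, mirnas, genes, mrna_dir, prot_dir, mir_dir) {
    sub <- edges |>
      dplyr::filter(.data$mirna_id %in% mirnas, .data$gene_id %in% genes) |>
      dplyr::arrange(.data$mirna_id, .data$gene_id)
    regulatory_circuit(type, sub,
                       mirna_direction = mir_dir,
                       gene_mrna_direction = mrna_dir,
                       gene_protein_direction = prot_dir)
  }
  structure(
    list(RRC1 = make("RRC1", mir_up, groups$down_down, "down", "down", "up"),
         RRC2 = make("RRC2", mir_up, groups$up_down, "up", "down", "up"),
         IRC = make("IRC", mir_down, groups$up_up, "up", "up", "down")),
    class = "circuit_set"
  )
}

#' Construct a regulatory circuit object
#'
#' @param circuit_type `"RRC1"`, `"RRC2"`, or `"IRC"`.
#' @param edges Tibble with columns `mirna_id`, `gene_id`.
#' @param mirna_direction,gene_mrna_direction,gene_protein_direction The
#'   direction (`"up"`/`"down"`) shared by all nodes of that layer in this
#'   circuit type.
#' @return An object of class `regulatory_circuit`.
#' @export
regulatory_circuit <- function(circuit_type, edges,
                               mirna_direction, gene_mrna_direction,
                               gene_protein_direction) {
  circuit_type <- match.arg(circuit_type, c("RRC1", "RRC2", "IRC"))
  stopifnot(all(c("mirna_id", "gene_id") %in% names(edges)))
  edges <- tibble::as_tibble(edges[c("mirna_id", "gene_id")])
  structure(
    list(circuit_type = circuit_type,
         edges = edges,
         mirnas = sort(unique(edges$mirna_id)),
         genes = sort(unique(edges$gene_id)),
         mirna_direction = mirna_direction,
         gene_mrna_direction = gene_mrna_direction,
         gene_protein_direction = gene_protein_direction),
    class = "regulatory_circuit"
  )
}

#' @export
print.regulatory_circuit <- function(x, ...) {
  cat(sprintf(
    "<regulatory_circuit> %s: %d edges, %d miRNAs (%s) -> %d genes (mRNA %s / protein %s)\n",
    x$circuit_type, nrow(x$edges), length(x$mirnas), x$mirna_direction,
    length(x$genes), x$gene_mrna_direction, x$gene_protein_direction))
  invisible(x)
}

#' Summarize one circuit or a circuit set
#'
#' @param circuit A `regulatory_circuit` or `circuit_set`.
#' @return A tibble with columns `circuit_type`, `n_edges`, `n_mirnas`,
#'   `n_genes`, counting only nodes incident to at least one edge.
#' @examples
#' rc <- regulatory_circuit("RRC1",
#'   tibble::tibble(mirna_id = "hsa-mir-1", gene_id = c("A", "B")),
#'   "up", "down", "down")
#' circuit_summary(rc)
#' @export
circuit_summary <- function(circuit) {
  if (inherits(circuit, "circuit_set"))
    return(purrr::map_dfr(circuit, circuit_summary))
  stopifnot(inherits(circuit, "regulatory_circuit"))
  tibble::tibble(circuit_type = circuit$circuit_type,
                 n_edges = nrow(circuit$edges),
                 n_mirnas = dplyr::n_distinct(circuit$edges$mirna_id),
                 n_genes = dplyr::n_distinct(circuit$edges$gene_id))
}
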