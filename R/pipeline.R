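#' Run the full regulatory-circuit pipeline
#'
#' Executes the analysis end to end: differential expression of mRNAs and
#' miRNAs, directional DEG/DEP overlap, circuit assembly from validated
#' interactions, hub detection for each circuit, optional enrichment of the
#' circuit gene sets, and clinical association of the top hub pair (ROC,
#' quartile-stratified log-rank survival, T-stage tests, regulator-target
#' correlation). Any stage failure is rethrown with the stage name.
#'
#' @param mrna,mirna [count_matrix()] objects.
#' @param proteins Protein table (`gene_id`, `direction`).
#' @param interactions Interaction table (`mirna_id`, `gene_id`,
#'   `support_type`, ...).
#' @param clinical Optional clinical table (`sample_id`, `t_stage`,
#'   `os_time`, `os_event`); clinical associations are skipped when absent.
#' @param collections Optional named list of [set_collection()] objects for
#'   enrichment of the pooled circuit gene set.
#' @param alpha Adjusted-p significance level for every stage.
#' @param gene_lfc,mirna_lfc Log2-fold-change thresholds for DEG and DEM
#'   calls (defaults 1 and 0).
#' @param hub_k Hubs per circuit and side.
#' @param aliases Optional ID alias table.
#' @param outdir When non-NULL, every intermediate table is written there
#'   as TSV (plus SIF edge lists and a JSON run manifest).
#' @return A list of class `igc_pipeline` with elements `de_mrna`,
#'   `de_mirna`, `overlap`, `circuits`, `summaries`, `hubs`, `enrichment`,
#'   `clinical_assoc`, and `manifest`.
#' @examples
#' sim <- simulate_igc_study(sim_config(n_genes = 150, n_mirnas = 40,
#'                                      n_tumor = 20, n_normal = 8,
#'                                      n_true_edges = 30, n_decoy_edges = 10))
#' res <- run_pipeline(sim$mrna, sim$mirna, sim$proteins, sim$interactions)
#' res$summaries
#' @export
run_pipeline <- function(mrna, mirna, proteins, interactions,
                         clinical = NULL, collections = NULL,
                         alpha = 0.05, gene_lfc = 1, mirna_lfc = 0,
                         hub_k = 5, aliases = NULL, outdir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  de_mrna <- stage("de_mrna",
                   nb_wald_test(mrna, alpha = alpha, lfc_threshold = gene_lfc))
  de_mirna <- stage("de_mirna",
                    nb_wald_test(mirna, alpha = alpha, lfc_threshold = mirna_lfc))
  degs <- call_differential(de_mrna)
  dems <- call_differential(de_mirna)

  validated <- stage("filter_interactions",
                     filter_validated(interactions, aliases))
  overlap <- stage("overlap", build_overlap_groups(degs, proteins, aliases))
  circuits <- stage("circuits",
                    assemble_circuits(dems, overlap, validated, aliases))
  summaries <- circuit_summary(circuits)
  hubs <- stage("hubs", find_hubs(circuits, k = hub_k))

  enrichment <- NULL
  if (!is.null(collections)) {
    circuit_genes <- unique(unlist(lapply(circuits, `[[`, "genes")))
    enrichment <- stage("enrich", purrr::map(
      collections, function(col) ora_test(circuit_genes, col, alpha = alpha)))
  }

  clinical_assoc <- NULL
  if (!is.null(clinical)) {
    clinical_assoc <- stage("clinical",
                            hub_clinical_association(mrna, mirna, hubs,
                                                     clinical, alpha = alpha))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("miRcircuit")),
    config_hash = rlang::hash(list(alpha = alpha, gene_lfc = gene_lfc,
                                   mirna_lfc = mirna_lfc, hub_k = hub_k)),
    thresholds = list(alpha = alpha, gene_lfc = gene_lfc,
                      mirna_lfc = mirna_lfc, hub_k = hub_k),
    row_counts = list(
      de_mrna = nrow(de_mrna), de_mirna = nrow(de_mirna),
      validated_interactions = nrow(validated),
      deg_up = length(degs$up), deg_down = length(degs$down),
      dem_up = length(dems$up), dem_down = length(dems$down),
      circuit_edges = stats::setNames(summaries$n_edges,
                                      summaries$circuit_type)
    )
  )

  res <- structure(
    list(de_mrna = de_mrna, de_mirna = de_mirna, overlap = overlap,
         circuits = circuits, summaries = summaries, hubs = hubs,
         enrichment = enrichment, clinical_assoc = clinical_assoc,
         manifest = manifest),
    class = "igc_pipeline"
  )
  if (!is.null(outdir)) write_pipeline_results(res, outdir)
  res
}

#' Clinical association of the top hub pair
#'
#' For the highest-MCC target gene: ROC AUC for tumor-vs-normal, T-stage
#' Kruskal-Wallis with pairwise Mann-Whitney tests, and a log-rank
#' comparison of the lower- versus upper-quartile expression groups. For
#' its top regulator: ROC AUC and the Pearson inverse-correlation test of
#' the regulator-target pair across tumor samples.
#'
#' @param mrna,mirna [count_matrix()] objects.
#' @param hubs Hub tables from [find_hubs()].
#' @param clinical Clinical table (`sample_id`, `t_stage`, `os_time`,
#'   `os_event`).
#' @param alpha Significance level.
#' @return A list with `gene`, `mirna`, `roc_gene`, `roc_mirna`,
#'   `t_stage`, `survival`, `correlation` (elements NULL when the hub
#'   tables are empty).
#' @export
hub_clinical_association <- function(mrna, mirna, hubs, clinical,
                                     alpha = 0.05) {
  if (nrow(hubs$target_hubs) == 0L) return(NULL)
  expr_g <- vst_like_transform(mrna)
  gene <- hubs$target_hubs$gene_id[1]

  roc_gene <- roc_auc(expr_g[gene, ], mrna$condition)

  tumor_ids <- colnames(expr_g)[mrna$condition == "tumor"]
  tumor_ids <- intersect(tumor_ids, clinical$sample_id)
  gx <- expr_g[gene, tumor_ids]
  clin <- clinical[match(tumor_ids, clinical$sample_id), ]

  tstage <- t_stage_association(gx, clin$t_stage)

  groups <- quartile_stratify(gx, tumor_ids)
  surv_of <- function(ids) {
    rows <- clin[match(ids, clin$sample_id), ]
    keep <- !is.na(rows$os_time) & !is.na(rows$os_event)
    list(times = rows$os_time[keep], events = rows$os_event[keep])
  }
  survival_cmp <- logrank_test(surv_of(groups$low), surv_of(groups$high))

  mirna_hub <- NULL; roc_mirna <- NULL; correlation <- NULL
  if (nrow(hubs$regulator_hubs) > 0L) {
    # prefer the highest-ranked regulator that actually targets the top gene
    regulators <- attr(hubs, "edges")
    mirna_hub <- if (!is.null(regulators)) {
      cand <- regulators$mirna_id[regulators$gene_id == gene]
      ranked <- hubs$regulator_hubs$mirna_id
      c(intersect(ranked, cand), cand, ranked)[1]
    } else {
      hubs$regulator_hubs$mirna_id[1]
    }
    expr_m <- vst_like_transform(mirna)
    if (mirna_hub %in% rownames(expr_m)) {
      roc_mirna <- roc_auc(expr_m[mirna_hub, ], mirna$condition)
      shared <- intersect(tumor_ids, colnames(expr_m))
      if (length(shared) >= 3L) {
        correlation <- pearson_inverse(expr_m[mirna_hub, shared],
                                       expr_g[gene, shared], alpha = alpha)
      }
    }
  }

  list(gene = gene, mirna = mirna_hub, roc_gene = roc_gene,
       roc_mirna = roc_mirna, t_stage = tstage, survival = survival_cmp,
       correlation = correlation)
}

#' Write all pipeline result tables to a directory
#'
#' @param res An `igc_pipeline` object.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_results <- function(res, outdir) {
  stopifnot(inherits(res, "igc_pipeline"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  write_table_tsv(tibble::as_tibble(res$de_mrna), p("de_mrna.tsv"))
  write_table_tsv(tibble::as_tibble(res$de_mirna), p("de_mirna.tsv"))
  overlap_tab <- purrr::imap_dfr(unclass(res$overlap), function(genes, grp) {
    tibble::tibble(group = grp, gene_id = genes)
  })
  write_table_tsv(overlap_tab, p("overlap_groups.tsv"))
  write_table_tsv(res$summaries, p("circuit_summary.tsv"))
  for (nm in names(res$circuits)) {
    write_table_tsv(res$circuits[[nm]]$edges,
                    p(sprintf("circuit_%s.tsv", nm)))
    write_circuit_sif(res$circuits[[nm]], p(sprintf("circuit_%s.sif", nm)))
  }
  write_table_tsv(res$hubs$target_hubs, p("target_hubs.tsv"))
  write_table_tsv(res$hubs$regulator_hubs, p("regulator_hubs.tsv"))
  if (!is.null(res$enrichment)) {
    for (nm in names(res$enrichment))
      write_table_tsv(res$enrichment[[nm]],
                      p(sprintf("enrichment_%s.tsv", nm)))
  }
  jsonlite::write_json(res$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.igc_pipeline <- function(x, ...) {
  cat("<igc_pipeline>\n")
  cat(sprintf("  DEGs: %d up, %d down; DEMs: %d up, %d down\n",
              x$manifest$row_counts$deg_up, x$manifest$row_counts$deg_down,
              x$manifest$row_counts$dem_up, x$manifest$row_counts$dem_down))
  s <- x$summaries
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s: %d edges (%d miRNAs -> %d genes)\n",
                s$circuit_type[i], s$n_edges[i], s$n_mirnas[i], s$n_genes[i]))
  invisible(x)
}
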