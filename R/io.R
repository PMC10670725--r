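#' Read and write pipeline tables
#'
#' All pipeline tables share one TSV dialect: tab-separated, UTF-8, `#`
#' comment lines, and `.` for missing values. `read_table_tsv()` validates
#' the header against a required schema and errors naming any missing or
#' unexpected columns; `write_table_tsv()` is its inverse, so a write
#' followed by a read is the identity on the table.
#'
#' @param path File path.
#' @param required Character vector of required column names; when given,
#'   the file must contain exactly these columns.
#' @return `read_table_tsv()`: a tibble.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_table_tsv(tibble::tibble(a = 1, b = "x"), f)
#' read_table_tsv(f, required = c("a", "b"))
#' @export
read_table_tsv <- function(path, required = NULL) {
  tab <- readr::read_tsv(path, comment = "#", na = ".",
                         show_col_types = FALSE, progress = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(tab))
    extra <- setdiff(names(tab), required)
    if (length(missing) > 0 || length(extra) > 0)
      stop(sprintf("schema mismatch in %s:%s%s", path,
                   if (length(missing)) paste0(" missing column(s) ",
                                               paste(missing, collapse = ", ")) else "",
                   if (length(extra)) paste0(" unexpected column(s) ",
                                             paste(extra, collapse = ", ")) else ""),
           call. = FALSE)
    tab <- tab[required]
  }
  tab
}

#' @rdname read_table_tsv
#' @param tab A data frame to write.
#' @return `write_table_tsv()`: `path`, invisibly.
#' @export
write_table_tsv <- function(tab, path) {
  readr::write_tsv(tab, path, na = ".", progress = FALSE)
  invisible(path)
}

#' Read a count matrix and its sample sheet
#'
#' The counts TSV has features in rows (first column = feature ID) and
#' samples in columns; the sample sheet has columns `sample_id` and
#' `condition` (`"tumor"`/`"normal"`).
#'
#' @param counts_path,samples_path File paths.
#' @param kind `"mRNA"` or `"miRNA"`.
#' @return A [count_matrix()].
#' @export
read_counts_tsv <- function(counts_path, samples_path,
                            kind = c("mRNA", "miRNA")) {
  kind <- match.arg(kind)
  raw <- read_table_tsv(counts_path)
  samples <- read_table_tsv(samples_path,
                            required = c("sample_id", "condition"))
  m <- as.matrix(raw[-1])
  rownames(m) <- raw[[1]]
  missing <- setdiff(colnames(m), samples$sample_id)
  if (length(missing) > 0)
    stop("samples absent from sample sheet: ",
         paste(missing, collapse = ", "), call. = FALSE)
  cond <- samples$condition[match(colnames(m), samples$sample_id)]
  count_matrix(m, cond, kind)
}

#' Write a count matrix and sample sheet
#'
#' @param counts A [count_matrix()].
#' @param counts_path,samples_path Output paths.
#' @return `counts_path`, invisibly.
#' @export
write_counts_tsv <- function(counts, counts_path, samples_path) {
  tab <- tibble::as_tibble(counts$counts, rownames = "feature_id")
  write_table_tsv(tab, counts_path)
  write_table_tsv(tibble::tibble(sample_id = colnames(counts$counts),
                                 condition = counts$condition),
                  samples_path)
  invisible(counts_path)
}

#' Write a circuit edge list in SIF dialect
#'
#' One line per edge: `mirna <tab> represses <tab> gene` (for the inductive
#' circuit the relation is `fails_to_repress`).
#'
#' @param circuit A `regulatory_circuit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_circuit_sif <- function(circuit, path) {
  stopifnot(inherits(circuit, "regulatory_circuit"))
  relation <- if (circuit$circuit_type == "IRC") "fails_to_repress" else "represses"
  lines <- sprintf("%s\t%s\t%s", circuit$edges$mirna_id, relation,
                   circuit$edges$gene_id)
  writeLines(lines, path)
  invisible(path)
}

#' Write every table of a simulated study to a directory
#'
#' Produces the TSV inputs the pipeline readers expect (counts + sample
#' sheets, protein table, interaction table, clinical table) plus
#' planted-truth sidecar tables for recovery testing.
#'
#' @param sim An `igc_simulation` from [simulate_igc_study()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_sim_data <- function(sim, outdir) {
  stopifnot(inherits(sim, "igc_simulation"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  write_counts_tsv(sim$mrna, p("mrna_counts.tsv"), p("mrna_samples.tsv"))
  write_counts_tsv(sim$mirna, p("mirna_counts.tsv"), p("mirna_samples.tsv"))
  write_table_tsv(sim$proteins, p("proteins.tsv"))
  write_table_tsv(sim$interactions, p("interactions.tsv"))
  write_table_tsv(sim$clinical, p("clinical.tsv"))
  write_table_tsv(sim$truth$de_genes, p("truth_de_genes.tsv"))
  write_table_tsv(sim$truth$de_mirnas, p("truth_de_mirnas.tsv"))
  write_table_tsv(sim$truth$true_edges, p("truth_edges.tsv"))
  write_table_tsv(sim$truth$hazard_genes, p("truth_hazard_genes.tsv"))
  invisible(outdir)
}
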