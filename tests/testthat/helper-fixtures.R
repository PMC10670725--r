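# Small deterministic fixtures shared across test files.

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 120, n_mirnas = 30, n_tumor = 12, n_normal = 6,
         n_true_edges = 20, n_decoy_edges = 10, seed = 42L),
    list(...))
  do.call(sim_config, args)
}

toy_count_matrix <- function(counts, condition = NULL, kind = "mRNA") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("G%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%02d", seq_len(ncol(counts)))
  if (is.null(condition))
    condition <- rep(c("tumor", "normal"), length.out = ncol(counts))
  count_matrix(counts, condition, kind)
}

# Exhaustive maximal-clique enumeration by subset checking (oracle).
brute_force_cliques <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  from <- as.character(edges[[1]]); to <- as.character(edges[[2]])
  labels <- sort(unique(c(from, to, as.character(nodes))))
  n <- length(labels)
  adj <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  for (i in seq_along(from)) {
    adj[from[i], to[i]] <- TRUE
    adj[to[i], from[i]] <- TRUE
  }
  diag(adj) <- FALSE
  subsets <- lapply(seq_len(2^n) - 1L, function(mask) {
    labels[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
  })
  is_clique <- vapply(subsets, function(s) {
    if (length(s) < 2) return(length(s) == 1)
    all(adj[s, s][upper.tri(matrix(0, length(s), length(s)))])
  }, logical(1))
  cliques <- subsets[is_clique]
  maximal <- vapply(seq_along(cliques), function(i) {
    !any(vapply(cliques[-i], function(other)
      all(cliques[[i]] %in% other), logical(1)))
  }, logical(1))
  out <- lapply(cliques[maximal], sort)
  out[order(vapply(out, paste, character(1), collapse = "\r"))]
}

random_graph_edges <- function(n_nodes, p = 0.4) {
  labels <- letters[seq_len(n_nodes)]
  pairs <- t(utils::combn(labels, 2))
  keep <- stats::runif(nrow(pairs)) < p
  data.frame(from = pairs[keep, 1], to = pairs[keep, 2])
}

# Brute-force circuit assembly: apply each direction rule row by row.
brute_force_circuits <- function(mir_up, mir_down, g_dd, g_ud, g_uu, validated) {
  pick <- function(mirnas, genes) {
    rows <- validated[validated$mirna_id %in% mirnas &
                        validated$gene_id %in% genes, c("mirna_id", "gene_id")]
    rows <- unique(rows)
    rows[order(rows$mirna_id, rows$gene_id), ]
  }
  list(RRC1 = pick(mir_up, g_dd), RRC2 = pick(mir_up, g_ud),
       IRC = pick(mir_down, g_uu))
}
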