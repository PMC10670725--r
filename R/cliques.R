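#' Enumerate all maximal cliques of an undirected graph
#'
#' Bron-Kerbosch enumeration with pivoting on the vertex of the union of the
#' candidate and excluded sets that covers the most candidates. Every
#' maximal clique (including singletons for isolated vertices) is returned
#' exactly once.
#'
#' @param edges A two-column data frame (or matrix) of undirected edges;
#'   self-loops are ignored.
#' @param nodes Optional character vector of vertex IDs; defaults to the
#'   vertices appearing in `edges`, but may add isolated vertices.
#' @return A list of character vectors, each a maximal clique, vertices
#'   sorted within a clique and cliques in a deterministic order.
#' @examples
#' maximal_cliques(data.frame(from = c("a", "b"), to = c("b", "c")))
#' @export
maximal_cliques <- function(edges, nodes = NULL) {
  adj <- build_adjacency(edges, nodes)
  n <- length(adj$labels)
  out <- vector("list", 0L)
  if (n == 0L) return(out)

  neighbors <- adj$neighbors  # list of integer vectors, sorted
  bk <- function(r, p, x) {
    if (length(p) == 0L && length(x) == 0L) {
      out[[length(out) + 1L]] <<- r
      return(invisible())
    }
    # pivot: vertex of P ∪ X with the most neighbors inside P
    px <- c(p, x)
    cover <- vapply(px, function(u) length(intersect(neighbors[[u]], p)),
                    integer(1))
    pivot <- px[which.max(cover)]
    for (v in setdiff(p, neighbors[[pivot]])) {
      nv <- neighbors[[v]]
      bk(c(r, v), intersect(p, nv), intersect(x, nv))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  cliques <- lapply(out, function(idx) sort(adj$labels[idx]))
  cliques[order(vapply(cliques, function(cl) paste(cl, collapse = "\r"),
                       character(1)))]
}

build_adjacency <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2L) stop("`edges` needs two columns", call. = FALSE)
  from <- as.character(edges[[1]])
  to <- as.character(edges[[2]])
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  labels <- sort(unique(c(from, to, as.character(nodes %||% character(0)))))
  i <- match(from, labels); j <- match(to, labels)
  neighbors <- vector("list", length(labels))
  for (k in seq_along(labels)) neighbors[[k]] <- integer(0)
  if (length(i) > 0) {
    pairs <- unique(data.frame(a = pmin(i, j), b = pmax(i, j)))
    for (r in seq_len(nrow(pairs))) {
      a <- pairs$a[r]; b <- pairs$b[r]
      neighbors[[a]] <- c(neighbors[[a]], b)
      neighbors[[b]] <- c(neighbors[[b]], a)
    }
    neighbors <- lapply(neighbors, function(v) sort(unique(v)))
  }
  list(labels = labels, neighbors = neighbors)
}

#' Maximal clique centrality of graph nodes
#'
#' `MCC(v) = sum over maximal cliques C containing v of (|C| - 1)!`.
#' Isolated nodes score 0 by convention, which keeps the identity
#' `MCC(v) = degree(v)` exact on bipartite graphs (where every maximal
#' clique is a single edge).
#'
#' @inheritParams maximal_cliques
#' @param node Optional single vertex ID; when supplied, returns its score
#'   as a scalar (unknown vertices are an error).
#' @return A tibble (`node`, `mcc`) for all vertices, or a scalar when
#'   `node` is given.
#' @examples
#' mcc_score(data.frame(from = c("a", "b"), to = c("b", "c")), node = "b")
#' @export
mcc_score <- function(edges, nodes = NULL, node = NULL) {
  cliques <- maximal_cliques(edges, nodes)
  labels <- sort(unique(unlist(c(
    lapply(cliques, identity), as.character(nodes %||% character(0))))))
  scores <- stats::setNames(numeric(length(labels)), labels)
  for (cl in cliques) {
    if (length(cl) < 2L) next  # singleton = isolated node, scores 0
    scores[cl] <- scores[cl] + factorial(length(cl) - 1L)
  }
  if (!is.null(node)) {
    if (!node %in% labels) stop(sprintf("unknown node '%s'", node), call. = FALSE)
    return(unname(scores[[node]]))
  }
  tibble::tibble(node = labels, mcc = unname(scores))
}
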