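#' Build an annotation set collection for over-representation analysis
#'
#' @param sets Named list of character vectors (set ID -> member IDs).
#' @param background Character vector: the universe against which
#'   enrichment is judged. Every set must be a nonempty subset of it.
#'   In this pipeline the conventional background is all features tested
#'   for differential expression, not the whole genome.
#' @param category Label for the collection (e.g. `"pathway"`,
#'   `"miRNA-family"`); adjustment is always performed within one category.
#' @return A list of class `set_collection`.
#' @examples
#' col <- set_collection(list(s1 = c("A", "B")), background = c("A", "B", "C"))
#' col$category
#' @export
set_collection <- function(sets, background, category = "pathway") {
  stopifnot(is.list(sets), length(names(sets)) == length(sets))
  background <- unique(as.character(background))
  if (length(background) == 0L) stop("empty background", call. = FALSE)
  sets <- lapply(sets, function(s) unique(as.character(s)))
  bad <- names(sets)[vapply(sets, length, integer(1)) == 0L]
  if (length(bad) > 0)
    stop("empty sets: ", paste(bad, collapse = ", "), call. = FALSE)
  outside <- names(sets)[!vapply(sets, function(s) all(s %in% background),
                                 logical(1))]
  if (length(outside) > 0)
    stop("sets with members outside the background: ",
         paste(outside, collapse = ", "), call. = FALSE)
  structure(list(sets = sets, background = background, category = category),
            class = "set_collection")
}

#' Hypergeometric over-representation test
#'
#' For each annotated set, tests whether the query is enriched for its
#' members: with background size `N`, set size `K`, query size `n` (after
#' restriction to the background), and overlap `k`, the p-value is the
#' hypergeometric upper tail `P(X >= k)`. P-values are Benjamini-Hochberg
#' adjusted across the sets of this collection only (per-category
#' adjustment). Query IDs outside the background are dropped with a
#' message; a query entirely outside the background is an error, since it
#' usually signals an ID-space mismatch.
#'
#' @param query Character vector of feature IDs.
#' @param collection A [set_collection()].
#' @param alpha Significance level for the `significant` flag.
#' @return A tibble of class `enrichment_result`, one row per set, sorted
#'   by `p_adj` then `p_value`, with columns `set_id`, `k`, `K`, `n`, `N`,
#'   `p_value`, `p_adj`, `significant`, `category`.
#' @examples
#' col <- set_collection(list(s1 = c("A", "B", "C")), background = LETTERS[1:10])
#' ora_test(c("A", "B"), col)
#' @export
ora_test <- function(query, collection, alpha = 0.05) {
  stopifnot(inherits(collection, "set_collection"))
  query <- unique(as.character(query))
  inside <- query[query %in% collection$background]
  if (length(inside) == 0L)
    stop(paste("no query ID is in the collection background -",
               "the query and collection appear to use different ID spaces"),
         call. = FALSE)
  dropped <- length(query) - length(inside)
  if (dropped > 0)
    message(sprintf("ora_test: dropped %d query ID(s) outside the background",
                    dropped))
  N <- length(collection$background)
  n <- length(inside)
  rows <- purrr::imap_dfr(collection$sets, function(members, set_id) {
    K <- length(members)
    k <- length(intersect(inside, members))
    tibble::tibble(set_id = set_id, k = k, K = K, n = n, N = N,
                   p_value = stats::phyper(k - 1, K, N - K, n,
                                           lower.tail = FALSE))
  })
  rows |>
    dplyr::mutate(p_adj = bh_adjust(.data$p_value),
                  significant = .data$p_adj <= alpha,
                  category = collection$category) |>
    dplyr::arrange(.data$p_adj, .data$p_value, .data$set_id) |>
    structure(class = c("enrichment_result", class(rows)))
}

#' Read or write GMT set collections
#'
#' GMT is the tab-separated gene-set exchange format: one set per line as
#' `set_id <tab> description <tab> member1 <tab> member2 ...`.
#'
#' @param path File path.
#' @return `read_gmt()`: a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(
    lapply(fields, function(f) unique(f[-(1:2)])),
    vapply(fields, `[[`, character(1), 1L)
  )
}

#' @rdname read_gmt
#' @param sets Named list of character vectors to write.
#' @param descriptions Optional character vector of set descriptions.
#' @return `write_gmt()`: the path, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
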