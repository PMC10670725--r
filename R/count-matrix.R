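#' Construct a count matrix with sample conditions
#'
#' The container used throughout the differential-expression stage: an
#' integer feature-by-sample matrix plus a tumor/normal condition label per
#' sample and a feature kind (`"mRNA"` or `"miRNA"`).
#'
#' @param counts Nonnegative integer matrix, features in rows, samples in
#'   columns; dimnames give feature and sample IDs.
#' @param condition Character or factor of length `ncol(counts)` with values
#'   `"tumor"` or `"normal"`.
#' @param kind `"mRNA"` or `"miRNA"`.
#'
#' @return An object of class `count_matrix`.
#' @examples
#' m <- matrix(rpois(12, 10), nrow = 3,
#'             dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' cm <- count_matrix(m, c("tumor", "tumor", "normal", "normal"), "mRNA")
#' dim(cm$counts)
#' @export
count_matrix <- function(counts, condition, kind = c("mRNA", "miRNA")) {
  kind <- match.arg(kind)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have feature (row) and sample (column) names", call. = FALSE)
  if (anyDuplicated(rownames(counts))) stop("duplicate feature IDs", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("duplicate sample IDs", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must be nonnegative integers", call. = FALSE)
  condition <- as.character(condition)
  if (length(condition) != ncol(counts))
    stop("`condition` must have one label per sample", call. = FALSE)
  if (!all(condition %in% c("tumor", "normal")))
    stop('`condition` values must be "tumor" or "normal"', call. = FALSE)
  if (length(unique(condition)) < 2L)
    stop("both tumor and normal samples must be present", call. = FALSE)
  structure(
    list(counts = counts, condition = condition, kind = kind),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %s: %d features x %d samples (%d tumor, %d normal)\n",
              x$kind, nrow(x$counts), ncol(x$counts),
              sum(x$condition == "tumor"), sum(x$condition == "normal")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Tidy a count matrix into long format
#'
#' @param x A [count_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `feature_id`, `sample_id`, `condition`,
#'   `count`.
#' @export
tidy.count_matrix <- function(x, ...) {
  tibble::as_tibble(x$counts, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "sample_id",
                        values_to = "count") |>
    dplyr::mutate(condition = x$condition[match(.data$sample_id,
                                                colnames(x$counts))],
                  .before = "count")
}
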