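#' Median-of-ratios size factors
#'
#' Library-size normalization in the style used for bulk RNA-seq count
#' models: each sample's factor is the median, over features expressed in
#' every sample, of the ratio between the sample's count and the feature's
#' geometric mean across samples.
#'
#' @param counts A [count_matrix()].
#' @param pseudo_reference If `TRUE`, features with zeros are retained by
#'   computing the geometric mean over positive counts only (useful for very
#'   sparse matrices). Default `FALSE`, the classical estimator.
#'
#' @return Named numeric vector of positive per-sample factors.
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), nrow = 3,
#'             dimnames = list(paste0("G", 1:3), c("S1", "S2")))
#' cm <- count_matrix(m, c("tumor", "normal"), "mRNA")
#' estimate_size_factors(cm)  # S2 is a doubled S1: factors in ratio 2
#' @export
estimate_size_factors <- function(counts, pseudo_reference = FALSE) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$counts
  logc <- log(m)
  if (pseudo_reference) {
    log_geo <- apply(logc, 1L, function(r) {
      pos <- is.finite(r)
      if (any(pos)) mean(r[pos]) else -Inf
    })
    usable <- is.finite(log_geo) & rowSums(m > 0) > 0
  } else {
    log_geo <- rowMeans(logc)
    usable <- is.finite(log_geo)
  }
  if (!any(usable))
    stop(paste("no feature has positive counts in every sample;",
               "rerun with `pseudo_reference = TRUE` to use a",
               "positive-count geometric-mean reference"), call. = FALSE)
  sf <- apply(logc[usable, , drop = FALSE], 2L, function(col) {
    ratio <- col - log_geo[usable]
    exp(stats::median(ratio[is.finite(ratio)]))
  })
  names(sf) <- colnames(m)
  sf
}

#' Negative-binomial Wald test for tumor-vs-normal differential expression
#'
#' A deliberately transparent NB test: counts are normalized by
#' median-of-ratios size factors, per-feature dispersion is estimated by
#' method of moments (`alpha = (var - mu * c) / mu^2`, pooled across the two
#' groups and floored at 0), the log2 fold change is
#' `log2((mean_tumor + eps) / (mean_normal + eps))` with pseudo-count
#' `eps = 0.5`, its standard error follows from the delta method under
#' `var = mu + alpha * mu^2`, and the Wald z statistic is referred to the
#' standard normal. Tumor is always the numerator of the fold change.
#' Features with zero counts in every sample are excluded from testing and
#' from the Benjamini-Hochberg denominator.
#'
#' @param counts A [count_matrix()].
#' @param sf Size factors; computed from `counts` when omitted.
#' @param lfc_pseudocount Pseudo-count `eps` added to both group means.
#' @param alpha Significance level for the differential call.
#' @param lfc_threshold Absolute log2-fold-change threshold for the call.
#'   Defaults to the conventional cutoffs per feature kind: genes are called
#'   at `|log2FC| >= 1`, miRNAs at `|log2FC| > 0`, both at adjusted p <= alpha.
#'
#' @return An object of class `igc_de`: a tibble with columns `feature_id`,
#'   `base_mean`, `log2fc`, `se`, `stat`, `p_value`, `p_adj`, `call`
#'   (`"up"`/`"down"`/`"ns"`), carrying `kind` and the thresholds as
#'   attributes.
#' @examples
#' sim <- generate_counts(sim_config(n_genes = 100, n_mirnas = 20,
#'                                   n_tumor = 10, n_normal = 10), "mRNA")
#' de <- nb_wald_test(sim$counts)
#' head(de)
#' @export
nb_wald_test <- function(counts, sf = estimate_size_factors(counts),
                         lfc_pseudocount = 0.5, alpha = 0.05,
                         lfc_threshold = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  cond <- counts$condition
  if (sum(cond == "tumor") < 2L || sum(cond == "normal") < 2L)
    stop("both groups need at least 2 samples", call. = FALSE)
  m <- counts$counts
  norm <- sweep(m, 2L, sf[colnames(m)], "/")
  tum <- norm[, cond == "tumor", drop = FALSE]
  nor <- norm[, cond == "normal", drop = FALSE]
  n_t <- ncol(tum); n_n <- ncol(nor)
  inv_sf_t <- 1 / sf[colnames(m)][cond == "tumor"]
  inv_sf_n <- 1 / sf[colnames(m)][cond == "normal"]

  mean_t <- rowMeans(tum)
  mean_n <- rowMeans(nor)
  var_t <- apply(tum, 1L, stats::var)
  var_n <- apply(nor, 1L, stats::var)

  # Method-of-moments dispersion: on the normalized scale,
  # Var(K/s) = mu/s + alpha*mu^2, so E[sample var] ~ mu*mean(1/s) + alpha*mu^2.
  mom <- function(v, mu, c_inv) ifelse(mu > 0, (v - mu * c_inv) / mu^2, NA_real_)
  a_t <- mom(var_t, mean_t, mean(inv_sf_t))
  a_n <- mom(var_n, mean_n, mean(inv_sf_n))
  w_t <- ifelse(is.na(a_t), 0, n_t - 1)
  w_n <- ifelse(is.na(a_n), 0, n_n - 1)
  disp <- (dplyr::coalesce(a_t, 0) * w_t + dplyr::coalesce(a_n, 0) * w_n) /
    pmax(w_t + w_n, 1)
  disp <- pmax(disp, 0)

  eps <- lfc_pseudocount
  log2fc <- log2((mean_t + eps) / (mean_n + eps))

  # Delta method: Var(mean_g) = mu*mean(1/s)/n + alpha*mu^2/n per group,
  # then Var(log2(mean + eps)) = Var(mean) / ((mean + eps)^2 * ln2^2).
  v_mt <- (mean_t * mean(inv_sf_t) + disp * mean_t^2) / n_t
  v_mn <- (mean_n * mean(inv_sf_n) + disp * mean_n^2) / n_n
  se <- sqrt(v_mt / (mean_t + eps)^2 + v_mn / (mean_n + eps)^2) / log(2)

  tested <- rowSums(m) > 0
  stat <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * stats::pnorm(-abs(stat))
  p[!tested] <- NA_real_
  stat[!tested] <- NA_real_
  se[!tested] <- NA_real_
  p_adj <- rep(NA_real_, length(p))
  p_adj[tested] <- bh_adjust(p[tested])

  kind <- counts$kind
  if (is.null(lfc_threshold)) lfc_threshold <- if (kind == "mRNA") 1 else 0
  res <- tibble::tibble(
    feature_id = rownames(m),
    base_mean = (mean_t * n_t + mean_n * n_n) / (n_t + n_n),
    log2fc = log2fc, se = se, stat = stat,
    p_value = p, p_adj = p_adj
  )
  res$call <- de_call(res$log2fc, res$p_adj, kind, alpha, lfc_threshold)
  structure(res, class = c("igc_de", class(res)),
            kind = kind, alpha = alpha, lfc_threshold = lfc_threshold)
}

# Directional call with kind-specific threshold semantics: genes use
# |log2FC| >= threshold (>= 1 by convention); miRNAs use a strict
# |log2FC| > threshold (> 0), so any significant nonzero change counts.
de_call <- function(log2fc, p_adj, kind, alpha, lfc_threshold) {
  meets_lfc <- if (kind == "mRNA") {
    abs(log2fc) >= lfc_threshold
  } else {
    abs(log2fc) > lfc_threshold
  }
  sig <- !is.na(p_adj) & p_adj <= alpha & meets_lfc
  dplyr::case_when(sig & log2fc > 0 ~ "up",
                   sig & log2fc < 0 ~ "down",
                   .default = "ns")
}

#' Extract directional feature sets from a differential result
#'
#' Applies the standard selection rules: genes are differentially expressed
#' at adjusted p <= `alpha` and `|log2FC| >= lfc_threshold` (default 1);
#' miRNAs at adjusted p <= `alpha` and `|log2FC| > lfc_threshold`
#' (default 0, i.e. any significant change).
#'
#' @param result An `igc_de` tibble from [nb_wald_test()].
#' @param kind `"mRNA"` or `"miRNA"`; defaults to the result's own kind.
#' @param alpha,lfc_threshold Override the thresholds stored in `result`.
#'
#' @return A list of class `directional_sets` with character vectors `up`
#'   and `down` and the `kind`.
#' @examples
#' de <- tibble::tibble(feature_id = c("A", "B"), log2fc = c(2, -0.5),
#'                      p_adj = c(0.01, 0.2))
#' call_differential(de, kind = "mRNA")$up
#' @export
call_differential <- function(result, kind = NULL, alpha = NULL,
                              lfc_threshold = NULL) {
  kind <- kind %||% attr(result, "kind") %||% "mRNA"
  kind <- match.arg(kind, c("mRNA", "miRNA"))
  alpha <- alpha %||% attr(result, "alpha") %||% 0.05
  lfc_threshold <- lfc_threshold %||% attr(result, "lfc_threshold") %||%
    (if (kind == "mRNA") 1 else 0)
  call <- de_call(result$log2fc, result$p_adj, kind, alpha, lfc_threshold)
  structure(
    list(up = result$feature_id[call == "up"],
         down = result$feature_id[call == "down"],
         kind = kind),
    class = "directional_sets"
  )
}

#' @export
print.directional_sets <- function(x, ...) {
  cat(sprintf("<directional_sets> %s: %d up, %d down\n",
              x$kind, length(x$up), length(x$down)))
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classical FDR control: sorted p-values are scaled by `m / rank` and a
#' running minimum from the largest rank downward enforces monotonicity;
#' results are clipped to 1. `NA` values are passed through and do not count
#' toward `m`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(out)
  o <- order(p[ok])
  sorted <- p[ok][o]
  adj <- pmin(1, rev(cummin(rev(sorted * m / seq_len(m)))))
  out[ok[o]] <- adj
  out
}

#' Log2 normalized-count transform
#'
#' `x = log2(count / size_factor + 1)`: a monotone, variance-damping
#' transform of normalized counts used for quartile stratification, ROC
#' analysis, and correlation, where only the ordering and rough scale of
#' expression matter.
#'
#' @param counts A [count_matrix()].
#' @param sf Size factors; computed from `counts` when omitted.
#' @return A numeric matrix with the same dimnames as the counts.
#' @examples
#' m <- matrix(c(0L, 7L, 3L, 1L), 2, dimnames = list(c("A", "B"), c("S1", "S2")))
#' cm <- count_matrix(m, c("tumor", "normal"), "mRNA")
#' vst_like_transform(cm, sf = c(S1 = 1, S2 = 1))
#' @export
vst_like_transform <- function(counts, sf = estimate_size_factors(counts)) {
  stopifnot(inherits(counts, "count_matrix"))
  log2(sweep(counts$counts, 2L, sf[colnames(counts$counts)], "/") + 1)
}
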