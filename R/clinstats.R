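#' ROC AUC of a single marker for tumor-vs-normal discrimination
#'
#' The AUC is computed from the rank statistic (Mann-Whitney form, ties get
#' half credit): the probability that a randomly chosen tumor sample's value
#' exceeds a randomly chosen normal sample's value. Markers that run the
#' "wrong way" (AUC < 0.5, e.g. down-regulated genes) are flipped so the
#' reported AUC is always >= 0.5, and the flip is recorded. The qualitative
#' band follows the conventional cutpoints: 0.9-1 excellent, 0.8-0.9 good,
#' 0.7-0.8 fair, 0.6-0.7 poor, 0.5-0.6 failure.
#'
#' @param values Numeric marker values (e.g. transformed expression).
#' @param labels Class labels, same length as `values`.
#' @param positive The label treated as positive class (default `"tumor"`).
#' @return An object of class `roc_result`: list with `auc`, `orientation`
#'   (`"as-is"`/`"flipped"`), `n_pos`, `n_neg`, `band`, and the input data
#'   for plotting.
#' @examples
#' roc_auc(c(5, 6, 7, 1, 2), c("tumor", "tumor", "tumor", "normal", "normal"))
#' @export
roc_auc <- function(values, labels, positive = "tumor") {
  stopifnot(length(values) == length(labels))
  pos <- values[labels == positive]
  neg <- values[labels != positive]
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  orientation <- "as-is"
  if (auc < 0.5) {
    auc <- 1 - auc
    orientation <- "flipped"
  }
  structure(
    list(auc = auc, orientation = orientation,
         n_pos = length(pos), n_neg = length(neg),
         band = auc_band(auc),
         data = tibble::tibble(value = values, label = labels)),
    class = "roc_result"
  )
}

auc_band <- function(auc) {
  dplyr::case_when(auc >= 0.9 ~ "excellent",
                   auc >= 0.8 ~ "good",
                   auc >= 0.7 ~ "fair",
                   auc >= 0.6 ~ "poor",
                   .default = "failure")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%s, %s); %d positive vs %d negative\n",
              x$auc, x$band, x$orientation, x$n_pos, x$n_neg))
  invisible(x)
}

#' Lower- and upper-quartile expression groups
#'
#' Splits samples into the `floor(n/4)` lowest and `floor(n/4)` highest by
#' expression, the conventional design for quartile-stratified survival
#' comparison (180 patients give two groups of 45). Ties at a boundary are
#' broken deterministically by sample ID.
#'
#' @param values Named numeric vector of expression values (names = sample
#'   IDs), or unnamed with `ids` supplied.
#' @param ids Sample IDs, defaulting to `names(values)`.
#' @return A list with character vectors `low` and `high` (disjoint).
#' @examples
#' quartile_stratify(stats::setNames(1:8, paste0("S", 1:8)))
#' @export
quartile_stratify <- function(values, ids = names(values)) {
  n <- length(values)
  if (n < 4L) stop("need at least 4 samples to form quartile groups",
                   call. = FALSE)
  if (is.null(ids)) stop("sample IDs are required", call. = FALSE)
  ord <- order(values, ids)
  q <- floor(n / 4)
  list(low = ids[ord[seq_len(q)]],
       high = ids[ord[seq.int(n - q + 1L, n)]])
}

#' Kaplan-Meier product-limit survival curve
#'
#' @param times Nonnegative follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return An object of class `km_curve`: a tibble (`time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`) plus a right-continuous step function
#'   accessible via `km_survival()`.
#' @examples
#' km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
#' km_survival(km)(2)  # 1/3 after the second of three events
#' @export
km_estimate <- function(times, events) {
  if (any(times < 0)) stop("negative survival time", call. = FALSE)
  stopifnot(length(times) == length(events), all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  tab <- tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                        n_event = fit$n.event, n_censor = fit$n.censor,
                        surv = fit$surv)
  drops <- tab[tab$n_event > 0, ]
  step <- if (nrow(drops) > 0) {
    stats::stepfun(drops$time, c(1, drops$surv), right = FALSE)
  } else {
    function(t) rep(1, length(t))
  }
  structure(list(table = tab, step = step, n = length(times),
                 n_events = sum(events)),
            class = "km_curve")
}

#' @rdname km_estimate
#' @param km A `km_curve`.
#' @return `km_survival()`: the survival step function `S(t)`.
#' @export
km_survival <- function(km) {
  stopifnot(inherits(km, "km_curve"))
  km$step
}

#' Two-group log-rank test with Kaplan-Meier curves
#'
#' Standard (rho = 0) log-rank comparison of two survival experiences:
#' observed minus hypergeometric-expected events at each distinct event
#' time, with the 1-df chi-square reference for the p-value. When neither
#' group has any event the statistic is undefined and the result is
#' flagged instead of erroring.
#'
#' @param group_a,group_b Each a list or data frame with elements/columns
#'   `times` and `events`.
#' @param labels Length-2 character vector naming the groups (default
#'   `c("low", "high")`).
#' @return An object of class `survival_comparison`: `km` (named list of
#'   [km_estimate()] curves), `logrank_stat`, `p_value`, `n` (group sizes),
#'   `n_events`, and `degenerate` (TRUE when no events occurred).
#' @examples
#' a <- list(times = c(2, 4, 6), events = c(1, 1, 0))
#' b <- list(times = c(1, 2, 3), events = c(1, 1, 1))
#' logrank_test(a, b)$p_value
#' @export
logrank_test <- function(group_a, group_b, labels = c("low", "high")) {
  ga <- as.list(group_a); gb <- as.list(group_b)
  stopifnot(length(ga$times) > 0, length(gb$times) > 0)
  km <- stats::setNames(
    list(km_estimate(ga$times, ga$events), km_estimate(gb$times, gb$events)),
    labels)
  n_events <- sum(ga$events) + sum(gb$events)
  if (n_events == 0) {
    return(structure(
      list(km = km, logrank_stat = NA_real_, p_value = NA_real_,
           n = c(length(ga$times), length(gb$times)),
           n_events = 0L, degenerate = TRUE),
      class = "survival_comparison"))
  }
  time <- c(ga$times, gb$times)
  event <- c(ga$events, gb$events)
  grp <- rep(labels, c(length(ga$times), length(gb$times)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, rho = 0)
  structure(
    list(km = km, logrank_stat = unname(sd$chisq),
         p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
         n = c(length(ga$times), length(gb$times)),
         n_events = n_events, degenerate = FALSE),
    class = "survival_comparison"
  )
}

#' @export
print.survival_comparison <- function(x, ...) {
  if (x$degenerate) {
    cat("<survival_comparison> no events in either group; log-rank undefined\n")
  } else {
    cat(sprintf("<survival_comparison> log-rank chi-sq = %.3f, p = %.4g (n = %d vs %d, %d events)\n",
                x$logrank_stat, x$p_value, x$n[1], x$n[2], x$n_events))
  }
  invisible(x)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic referred to chi-square with (groups - 1)
#' degrees of freedom. The degenerate case where every observation shares
#' one value is reported as H = 0, p = 1.
#'
#' @param values Numeric observations.
#' @param groups Group labels (at least 2 distinct groups, each nonempty).
#' @return A tibble with `statistic`, `df`, `p_value`, `n_groups`.
#' @examples
#' kruskal_wallis(c(1, 2, 7, 8, 15, 16), rep(c("a", "b", "c"), each = 2))
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (stats::var(values) == 0) {
    return(tibble::tibble(statistic = 0, df = nlevels(groups) - 1L,
                          p_value = 1, n_groups = nlevels(groups)))
  }
  kt <- stats::kruskal.test(values, groups)
  tibble::tibble(statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p_value = kt$p.value,
                 n_groups = nlevels(groups))
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact enumeration when the combined sample size is <= 12 and no ties are
#' present; otherwise the tie-corrected normal approximation with
#' continuity correction. Two-sided throughout.
#'
#' @param values_a,values_b Numeric samples (both nonempty).
#' @return A tibble with `u` (the U statistic for sample a), `p_value`,
#'   `exact` (whether exact enumeration was used).
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # exact p = 1/3
#' @export
mann_whitney <- function(values_a, values_b) {
  stopifnot(length(values_a) > 0, length(values_b) > 0)
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- (length(values_a) + length(values_b) <= 12L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = exact, correct = TRUE)
  )
  tibble::tibble(u = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Pearson correlation with the inverse-regulation significance rule
#'
#' Computes the sample Pearson correlation and its two-sided t-test
#' p-value, and flags a regulator-target pair as a significant inverse
#' correlation when `p <= alpha` and `r <= r_threshold` (defaults 0.05 and
#' -0.3), the convention for calling a miRNA-target pair inversely
#' co-expressed.
#'
#' @param x,y Numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @param alpha Significance level.
#' @param r_threshold Correlation ceiling for the inverse call.
#' @return An object of class `correlation_result`: list with `r`,
#'   `p_value`, `n`, `inverse_significant`.
#' @examples
#' pearson_inverse(1:10, -2 * (1:10) + rnorm(10, sd = 0.1))
#' @export
pearson_inverse <- function(x, y, alpha = 0.05, r_threshold = -0.3) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in `x` or `y`", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  p <- if (abs(r) == 1) 0 else ct$p.value  # exact linearity
  structure(
    list(r = r, p_value = p, n = length(x),
         inverse_significant = (p <= alpha && r <= r_threshold)),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.3f, p = %.4g (n = %d)%s\n",
              x$r, x$p_value, x$n,
              if (x$inverse_significant) " [significant inverse]" else ""))
  invisible(x)
}

#' T-stage association of a marker: Kruskal-Wallis plus pairwise tests
#'
#' Runs a Kruskal-Wallis test of the marker across T stages and all
#' pairwise Mann-Whitney comparisons. Samples missing the stage are
#' dropped with a message. Pairwise p-values are unadjusted by default;
#' `adjust = TRUE` applies Benjamini-Hochberg over the pairwise family.
#'
#' @param values Named numeric vector of marker values (names = sample IDs).
#' @param stages Character vector of T stages (`"T1"`-`"T4"`, `NA` allowed),
#'   aligned with `values`.
#' @param adjust Apply BH over the pairwise p-values.
#' @return A list with `kw` (tibble from [kruskal_wallis()]), `pairwise`
#'   (tibble: `stage_a`, `stage_b`, `u`, `p_value`), and `n_dropped`.
#' @export
t_stage_association <- function(values, stages, adjust = FALSE) {
  stopifnot(length(values) == length(stages))
  keep <- !is.na(stages)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("t_stage_association: dropped %d sample(s) missing T stage",
                    n_dropped))
  values <- values[keep]; stages <- stages[keep]
  lev <- sort(unique(stages))
  if (length(lev) < 2L) stop("need at least 2 observed stages", call. = FALSE)
  kw <- kruskal_wallis(values, stages)
  pairs <- utils::combn(lev, 2L)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    mw <- mann_whitney(values[stages == a], values[stages == b])
    tibble::tibble(stage_a = a, stage_b = b, u = mw$u, p_value = mw$p_value)
  })
  if (adjust) pairwise$p_adj <- bh_adjust(pairwise$p_value)
  list(kw = kw, pairwise = pairwise, n_dropped = n_dropped)
}
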