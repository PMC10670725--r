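test_that("AUC hits its boundary cases and bands", {
  sep <- roc_auc(c(5, 6, 7, 1, 2), c("tumor", "tumor", "tumor",
                                     "normal", "normal"))
  expect_equal(sep$auc, 1)
  expect_equal(sep$band, "excellent")

  ties <- roc_auc(rep(3, 10), rep(c("tumor", "normal"), 5))
  expect_equal(ties$auc, 0.5)
  expect_equal(ties$band, "failure")

  # 3 of 4 tumor/normal pairs correctly ordered: AUC = 0.75 -> "fair"
  expect_equal(roc_auc(c(2, 4, 1, 3),
                       c("tumor", "tumor", "normal", "normal"))$band, "fair")
  expect_error(roc_auc(1:3, rep("tumor", 3)), "both classes")
})

test_that("AUC equals brute-force pair counting and flips orientation", {
  set.seed(50)
  for (rep in 1:10) {
    n_pos <- sample(3:30, 1); n_neg <- sample(3:30, 1)
    pos <- sample(1:15, n_pos, replace = TRUE)
    neg <- sample(1:15, n_neg, replace = TRUE)
    res <- roc_auc(c(pos, neg), rep(c("tumor", "normal"), c(n_pos, n_neg)))
    wins <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
    raw <- mean(wins)
    expect_equal(res$auc, max(raw, 1 - raw))
    expect_equal(res$orientation, if (raw < 0.5) "flipped" else "as-is")
    expect_gte(res$auc, 0.5)
  }
})

test_that("quartile groups take floor(n/4) from each end, disjointly", {
  v <- setNames(c(4, 1, 3, 2, 8, 6, 5, 7), paste0("S", 1:8))
  g <- quartile_stratify(v)
  expect_equal(g$low, c("S2", "S4"))     # values 1, 2
  expect_equal(g$high, c("S8", "S5"))    # values 7, 8 in ascending order
  expect_length(intersect(g$low, g$high), 0)
  expect_error(quartile_stratify(setNames(1:3, letters[1:3])), "at least 4")

  # 180 samples -> 45 per group
  v180 <- setNames(rnorm(180), sprintf("P%03d", 1:180))
  g180 <- quartile_stratify(v180)
  expect_length(g180$low, 45)
  expect_length(g180$high, 45)

  # boundary ties break deterministically by sample ID
  tied <- setNames(c(1, 2, 2, 3), c("d", "c", "b", "a"))
  expect_equal(quartile_stratify(tied)$low, "d")
  expect_equal(quartile_stratify(tied)$high, "a")
})

test_that("Kaplan-Meier estimator matches hand product-limit computation", {
  none <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_equal(km_survival(none)(c(0, 3, 10)), rep(1, 3))

  all_ev <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  s <- km_survival(all_ev)
  expect_equal(s(1), 2 / 3)
  expect_equal(s(2), 1 / 3)
  expect_equal(s(3), 0)
  expect_equal(s(0.5), 1)

  one <- km_estimate(c(2, 3, 4, 5), c(1, 0, 0, 0))
  expect_equal(km_survival(one)(2), 3 / 4)

  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")

  # censoring before an event shrinks the risk set first
  km <- km_estimate(c(1, 2, 3, 4), c(1, 0, 1, 0))
  expect_equal(km_survival(km)(3), (3 / 4) * (1 / 2))
})

test_that("KM reproduces the empirical survival function without censoring", {
  set.seed(51)
  times <- rexp(40, 0.1)
  km <- km_estimate(times, rep(1, 40))
  s <- km_survival(km)
  for (t in quantile(times, c(0.2, 0.5, 0.8)))
    expect_equal(s(t), mean(times > t))
})

test_that("log-rank test: identity, symmetry, and a hand-worked table", {
  a <- list(times = c(1, 3, 5), events = c(1, 1, 0))
  expect_equal(logrank_test(a, a)$logrank_stat, 0)
  expect_equal(logrank_test(a, a)$p_value, 1)

  b <- list(times = c(2, 4, 6), events = c(1, 1, 1))
  expect_equal(logrank_test(a, b)$logrank_stat,
               logrank_test(b, a)$logrank_stat)

  # hand O/E table: groups {1+,2} vs {1,2+} with distinct event times
  g1 <- list(times = c(1, 2), events = c(0, 1))
  g2 <- list(times = c(1, 2), events = c(1, 0))
  # t=1: 4 at risk (2 per group), 1 event in g2 -> E1 = 0.5, V = 0.25
  # t=2: 2 at risk (1 per group), 1 event in g1 -> E1 = 0.5, V = 0.25
  # O1 - E1 = 1 - 1 = 0 -> statistic 0
  expect_equal(logrank_test(g1, g2)$logrank_stat, 0)

  # all-censored input is flagged, not an error
  cens <- list(times = c(1, 2), events = c(0, 0))
  res <- logrank_test(cens, cens)
  expect_true(res$degenerate)
  expect_true(is.na(res$p_value))
})

test_that("log-rank p approximates a permutation reference", {
  set.seed(52)
  times <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  events <- rep(1, 10)
  grp <- rep(c(0, 1), 5)
  stat_of <- function(g) {
    logrank_test(list(times = times[g == 0], events = events[g == 0]),
                 list(times = times[g == 1], events = events[g == 1]))$logrank_stat
  }
  obs <- stat_of(grp)
  perm <- replicate(400, stat_of(sample(grp)))
  p_perm <- mean(perm >= obs - 1e-12)
  p_chisq <- logrank_test(list(times = times[grp == 0], events = events[grp == 0]),
                          list(times = times[grp == 1],
                               events = events[grp == 1]))$p_value
  expect_lt(abs(p_perm - p_chisq), 0.12)
})

test_that("Kruskal-Wallis separates non-overlapping groups and handles ties", {
  vals <- c(1, 2, 3, 4, 11, 12, 13, 14, 21, 22, 23, 24)
  grp <- rep(c("a", "b", "c"), each = 4)
  res <- kruskal_wallis(vals, grp)
  # non-overlapping ranks maximize H for this configuration:
  # H = 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2 with rank means 2.5, 6.5, 10.5
  h_max <- 12 / (12 * 13) * 4 * ((2.5 - 6.5)^2 + 0 + (10.5 - 6.5)^2)
  expect_equal(res$statistic, h_max)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$statistic, unname(kruskal.test(vals, factor(grp))$statistic))

  flat <- kruskal_wallis(rep(5, 9), rep(c("a", "b", "c"), 3))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(kruskal_wallis(1:4, rep("a", 4)), "at least 2")
})

test_that("Kruskal-Wallis p-values are near-uniform under the null", {
  set.seed(53)
  pvals <- replicate(200, {
    kruskal_wallis(rnorm(30), rep(c("a", "b", "c"), each = 10))$p_value
  })
  expect_lt(abs(mean(pvals <= 0.05) - 0.05), 0.04)
  expect_gt(mean(pvals > 0.5), 0.35)
})

test_that("Mann-Whitney: exact enumeration, symmetry, and U conservation", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_true(res$exact)
  expect_equal(res$p_value, 1 / 3)   # 2 / C(4,2)
  expect_equal(unname(res$u), 0)

  # perfectly interleaved samples: U at its central value, exact p = 1
  sym <- mann_whitney(c(1, 4, 5, 8), c(2, 3, 6, 7))
  expect_true(sym$exact)
  expect_equal(sym$p_value, 1)

  set.seed(54)
  for (rep in 1:10) {
    a <- sample(1:100, 6); b <- sample(101:200, 5)
    ua <- mann_whitney(a, b)$u
    ub <- mann_whitney(b, a)$u
    expect_equal(unname(ua + ub), length(a) * length(b))
  }
})

test_that("Pearson inverse-correlation rule follows both gates", {
  x <- 1:10
  perfect <- pearson_inverse(x, -2 * x + 1)
  expect_equal(perfect$r, -1)
  expect_true(perfect$inverse_significant)

  # construct data with sample correlation exactly -0.25: significant at
  # n = 500 but failing the R <= -0.3 gate
  set.seed(55)
  n <- 500
  xs <- as.numeric(scale(rnorm(n)))
  e <- residuals(lm(rnorm(n) ~ xs))
  es <- as.numeric(scale(e))
  y <- -0.25 * xs + sqrt(1 - 0.25^2) * es
  weak <- pearson_inverse(xs, y)
  expect_equal(weak$r, -0.25, tolerance = 1e-10)
  expect_lte(weak$p_value, 0.05)
  expect_false(weak$inverse_significant)

  expect_error(pearson_inverse(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_inverse(1:2, 2:1), "at least 3")
})

test_that("null pairs are rarely called inverse-significant", {
  set.seed(56)
  calls <- replicate(300, {
    pearson_inverse(rnorm(50), rnorm(50))$inverse_significant
  })
  expect_lte(mean(calls), 0.05)  # one-sided half of alpha, plus margin
})

test_that("the quartile log-rank detects the generator's default hazard effect", {
  detected <- vapply(1:25, function(s) {
    cfg <- sim_config(n_genes = 30, n_mirnas = 5, n_tumor = 100, n_normal = 2,
                      frac_de_genes = 0.2, frac_de_mirnas = 0.4,
                      n_true_edges = 5, n_decoy_edges = 0,
                      seed = 9000L + s)  # default hub_hazard_lfc
    sim <- simulate_igc_study(cfg)
    g <- sim$truth$hazard_genes$gene_id[1]
    expr <- vst_like_transform(sim$mrna)
    tumor <- colnames(expr)[sim$mrna$condition == "tumor"]
    grp <- quartile_stratify(expr[g, tumor], tumor)
    clin <- sim$clinical
    lo <- clin[match(grp$low, clin$sample_id), ]
    hi <- clin[match(grp$high, clin$sample_id), ]
    logrank_test(list(times = lo$os_time, events = lo$os_event),
                 list(times = hi$os_time, events = hi$os_event))$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(detected), 0.8)
})

test_that("T-stage association drops missing stages and reports all pairs", {
  set.seed(57)
  vals <- setNames(rnorm(40), paste0("S", 1:40))
  stages <- sample(c("T1", "T2", "T3", "T4"), 40, replace = TRUE)
  stages[1:3] <- NA
  expect_message(res <- t_stage_association(vals, stages), "dropped 3")
  expect_equal(nrow(res$pairwise), choose(4, 2))
  expect_equal(res$n_dropped, 3)
  adj <- suppressMessages(t_stage_association(vals, stages, adjust = TRUE))
  expect_true(all(adj$pairwise$p_adj >= adj$pairwise$p_value))
})
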