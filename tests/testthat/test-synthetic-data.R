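test_that("fixed seed gives identical simulations; config is validated", {
  cfg <- small_config(seed = 1L)
  a <- simulate_igc_study(cfg)
  b <- simulate_igc_study(cfg)
  expect_identical(a$mrna$counts, b$mrna$counts)
  expect_identical(a$mirna$counts, b$mirna$counts)
  expect_identical(a$interactions, b$interactions)
  expect_identical(a$clinical, b$clinical)

  expect_error(sim_config(n_tumor = 1), "replication")
  expect_error(sim_config(frac_de_genes = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(dispersion = -0.1), ">= 0")
})

test_that("planted truth records exactly the configured effects", {
  cfg <- small_config(n_genes = 500, frac_de_genes = 0.1)
  sim <- generate_counts(cfg, "mRNA")
  expect_equal(nrow(sim$truth), 50)
  expect_true(all(abs(sim$truth$log2fc) == cfg$lfc_magnitude))
  expect_false(anyDuplicated(sim$truth$feature_id) > 0)

  none <- generate_counts(small_config(frac_de_genes = 0), "mRNA")
  expect_equal(nrow(none$truth), 0)
})

test_that("simulated counts match negative-binomial moments", {
  cfg <- sim_config(n_genes = 2, n_mirnas = 2, n_tumor = 5000, n_normal = 5000,
                    frac_de_genes = 0, dispersion = 0.2,
                    base_mean_range = c(100, 100), seed = 3L)
  sim <- generate_counts(cfg, "mRNA")
  sf <- sim$size_factors
  # normalized counts have mean mu and var ~ mu*mean(1/sf) + alpha*mu^2
  norm <- sweep(sim$counts$counts, 2, sf, "/")
  for (f in 1:2) {
    mu_hat <- mean(norm[f, ])
    expect_lt(abs(mu_hat - 100) / 100, 0.05)
    v_expected <- 100 * mean(1 / sf) + 0.2 * 100^2
    expect_lt(abs(var(norm[f, ]) - v_expected) / v_expected, 0.05)
  }
})

test_that("interaction table has planted composition and referential integrity", {
  cfg <- small_config(n_true_edges = 40, n_decoy_edges = 0, frac_negative = 0.1)
  sim <- simulate_igc_study(cfg)
  tab <- sim$interactions
  n_neg <- sum(grepl("negative", tab$support_type, ignore.case = TRUE))
  expect_equal(n_neg, round(0.1 * 40))
  expect_equal(nrow(tab), 40 + n_neg)

  expect_true(all(tab$mirna_id %in% sim$truth$all_mirnas))
  expect_true(all(tab$gene_id %in% sim$truth$all_genes))

  # true edges only connect planted DE features, recorded exactly once
  edges <- sim$truth$true_edges
  expect_equal(nrow(edges), 40)
  expect_false(anyDuplicated(paste(edges$mirna_id, edges$gene_id)) > 0)
  expect_true(all(edges$mirna_id %in% sim$truth$de_mirnas$feature_id))
  expect_true(all(edges$gene_id %in% sim$truth$de_genes$feature_id))

  # decoys sit strictly among non-DE features
  cfg2 <- small_config(n_true_edges = 0, n_decoy_edges = 25, frac_negative = 0)
  sim2 <- simulate_igc_study(cfg2)
  expect_false(any(sim2$interactions$mirna_id %in% sim2$truth$de_mirnas$feature_id))
  expect_false(any(sim2$interactions$gene_id %in% sim2$truth$de_genes$feature_id))

  # a 10% negative fraction of 100 edges yields 10 negative rows
  cfg3 <- small_config(n_genes = 400, n_mirnas = 80, n_true_edges = 60,
                       n_decoy_edges = 40, frac_negative = 0.1)
  sim3 <- simulate_igc_study(cfg3)
  expect_equal(sum(sim3$interactions$support_type == "negative"), 10)
})

test_that("clinical table covers every tumor sample with valid fields", {
  sim <- simulate_igc_study(small_config())
  clin <- sim$clinical
  tumor_ids <- colnames(sim$mrna$counts)[sim$mrna$condition == "tumor"]
  expect_setequal(clin$sample_id, tumor_ids)
  expect_true(all(is.na(clin$t_stage) |
                    clin$t_stage %in% c("T1", "T2", "T3", "T4")))
  expect_true(all(clin$os_time >= 0))
  expect_true(all(clin$os_event %in% c(0, 1)))
  expect_error(
    generate_clinical(small_config(), sim$mrna,
                      list(hazard_genes = tibble::tibble())),
    "hazard_genes")
})

test_that("planted hazard shortens survival of the high-expression quartile", {
  # strong positive hazard coefficient: high expression of the designated
  # gene should give shorter median survival in nearly all replicates
  worse <- vapply(1:60, function(s) {
    cfg <- sim_config(n_genes = 30, n_mirnas = 5, n_tumor = 60, n_normal = 2,
                      frac_de_genes = 0.2, frac_de_mirnas = 0.4,
                      n_true_edges = 5, n_decoy_edges = 0,
                      hub_hazard_lfc = 1.5, dropout_rate = 0,
                      censoring_horizon = Inf, seed = 1000L + s)
    sim <- simulate_igc_study(cfg)
    g <- sim$truth$hazard_genes$gene_id[1]
    expr <- vst_like_transform(sim$mrna)
    tumor <- colnames(expr)[sim$mrna$condition == "tumor"]
    grp <- quartile_stratify(expr[g, tumor], tumor)
    clin <- sim$clinical
    median(clin$os_time[clin$sample_id %in% grp$high]) <
      median(clin$os_time[clin$sample_id %in% grp$low])
  }, logical(1))
  expect_gte(mean(worse), 0.95)
})

test_that("zero hazard coefficient gives a null quartile log-rank test", {
  pvals <- vapply(1:40, function(s) {
    cfg <- sim_config(n_genes = 20, n_mirnas = 5, n_tumor = 48, n_normal = 2,
                      frac_de_genes = 0, frac_de_mirnas = 0,
                      n_true_edges = 0, n_decoy_edges = 0,
                      hub_hazard_lfc = 0, dropout_rate = 0,
                      censoring_horizon = Inf, seed = 5000L + s)
    mrna <- generate_counts(cfg, "mRNA")
    clin <- generate_clinical(cfg, mrna$counts,
                              list(hazard_genes = tibble::tibble()))
    expr <- vst_like_transform(mrna$counts)
    tumor <- colnames(expr)[mrna$counts$condition == "tumor"]
    grp <- quartile_stratify(expr[1, tumor], tumor)
    a <- clin[match(grp$low, clin$sample_id), ]
    b <- clin[match(grp$high, clin$sample_id), ]
    logrank_test(list(times = a$os_time, events = a$os_event),
                 list(times = b$os_time, events = b$os_event))$p_value
  }, numeric(1))
  # null: rejection near the nominal 5% rate (binomial slack for 40 draws)
  expect_lte(mean(pvals <= 0.05), 0.2)
  expect_gt(mean(pvals > 0.3), 0.4)
})
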