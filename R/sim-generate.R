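#' Simulate a tumor/normal count matrix with planted fold changes
#'
#' Draws negative-binomial counts `NB(mu, alpha)` with
#' `var = mu + alpha * mu^2`. For each feature the log2 mean is a baseline
#' (log-uniform over `config$base_mean_range`) plus, for the planted
#' differentially expressed fraction, a tumor-only shift of
#' `+/- lfc_magnitude` log2 units. Sample-specific size factors are drawn
#' log-uniformly in `[0.5, 2]` so that library-size normalization downstream
#' is nontrivial.
#'
#' @param config A [sim_config()].
#' @param kind `"mRNA"` or `"miRNA"`; selects the feature universe size, ID
#'   style, and planted DE fraction.
#'
#' @return A list with elements `counts` (a [count_matrix()]), `truth`
#'   (tibble of planted effects: `feature_id`, `log2fc`), and `size_factors`
#'   (the true per-sample scale factors).
#' @examples
#' sim <- generate_counts(sim_config(n_genes = 50, n_mirnas = 10,
#'                                   n_tumor = 6, n_normal = 4), "mRNA")
#' sim$truth
#' @export
generate_counts <- function(config, kind = c("mRNA", "miRNA")) {
  kind <- match.arg(kind)
  validate_sim_config(config)
  set.seed(sim_seed(config, kind))

  n_feat <- if (kind == "mRNA") config$n_genes else config$n_mirnas
  frac_de <- if (kind == "mRNA") config$frac_de_genes else config$frac_de_mirnas
  feature_ids <- if (kind == "mRNA") {
    sprintf("GENE%04d", seq_len(n_feat))
  } else {
    sprintf("hsa-mir-%04d", seq_len(n_feat))
  }
  sample_ids <- c(sprintf("TUMOR%03d", seq_len(config$n_tumor)),
                  sprintf("NORMAL%03d", seq_len(config$n_normal)))
  condition <- rep(c("tumor", "normal"), c(config$n_tumor, config$n_normal))
  n_samp <- length(sample_ids)

  base_mean <- exp(stats::runif(n_feat,
                                log(config$base_mean_range[1]),
                                log(config$base_mean_range[2])))
  size_factors <- exp(stats::runif(n_samp, log(0.5), log(2)))
  names(size_factors) <- sample_ids

  n_de <- round(frac_de * n_feat)
  de_idx <- if (n_de > 0) sort(sample.int(n_feat, n_de)) else integer(0)
  lfc <- numeric(n_feat)
  if (n_de > 0)
    lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) * config$lfc_magnitude

  # mu[f, s] = size_factor_s * base_f * 2^(lfc_f * 1[tumor])
  is_tumor <- as.numeric(condition == "tumor")
  mu <- (base_mean * 2^(outer(lfc, is_tumor))) *
    rep(size_factors, each = n_feat)
  counts <- if (config$dispersion > 0) {
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
  } else {
    stats::rpois(length(mu), lambda = mu)
  }
  counts <- matrix(counts, nrow = n_feat,
                   dimnames = list(feature_ids, sample_ids))

  list(
    counts = count_matrix(counts, condition, kind),
    truth = tibble::tibble(feature_id = feature_ids[de_idx],
                           log2fc = lfc[de_idx]),
    size_factors = size_factors
  )
}

#' Simulate a protein differential-expression table
#'
#' Each planted DE gene is detected at the protein level with probability
#' `frac_protein_detected`; a detected protein's direction agrees with its
#' mRNA direction with probability `frac_protein_concordant` and is flipped
#' otherwise (emulating translational repression and inverse regulation).
#'
#' @param config A [sim_config()].
#' @param gene_truth Tibble of planted gene effects from
#'   [generate_counts()] (`feature_id`, `log2fc`).
#'
#' @return A tibble with columns `gene_id`, `direction` (`"up"`/`"down"`).
#' @export
generate_proteins <- function(config, gene_truth) {
  validate_sim_config(config)
  set.seed(sim_seed(config, "proteins"))
  if (nrow(gene_truth) == 0L)
    return(tibble::tibble(gene_id = character(), direction = character()))
  detected <- stats::runif(nrow(gene_truth)) < config$frac_protein_detected
  tab <- gene_truth[detected, , drop = FALSE]
  if (nrow(tab) == 0L)
    return(tibble::tibble(gene_id = character(), direction = character()))
  mrna_dir <- ifelse(tab$log2fc > 0, "up", "down")
  concord <- stats::runif(nrow(tab)) < config$frac_protein_concordant
  direction <- ifelse(concord, mrna_dir,
                      ifelse(mrna_dir == "up", "down", "up"))
  tibble::tibble(gene_id = tab$feature_id, direction = direction)
}

#' Simulate a validated miRNA-target interaction table
#'
#' Plants `n_true_edges` edges between DE miRNAs and DE genes (support type
#' `"validated"`), adds `n_decoy_edges` decoy edges among non-DE features,
#' and appends a `frac_negative` fraction of rows labelled `"negative"`
#' support, emulating refuted database entries that downstream filtering
#' must drop.
#'
#' @param config A [sim_config()].
#' @param truth A list with tibbles `de_genes` and `de_mirnas`
#'   (`feature_id`, `log2fc`) as produced by [generate_counts()], plus
#'   character vectors `all_genes` and `all_mirnas` giving the simulated
#'   universe.
#'
#' @return A tibble with columns `mirna_id`, `gene_id`, `support_type`,
#'   `database`, carrying the planted edges as the attribute `"true_edges"`.
#' @export
generate_interactions <- function(config, truth) {
  validate_sim_config(config)
  set.seed(sim_seed(config, "interactions"))
  stopifnot(is.list(truth),
            all(c("de_genes", "de_mirnas", "all_genes", "all_mirnas") %in% names(truth)))
  databases <- c("miRecords", "miRTarBase", "TarBase")

  sample_pairs <- function(mirnas, genes, n) {
    total <- length(mirnas) * length(genes)
    if (n > total)
      stop(sprintf("cannot draw %d distinct edges from a %d x %d universe",
                   n, length(mirnas), length(genes)), call. = FALSE)
    idx <- sample.int(total, n)
    tibble::tibble(mirna_id = mirnas[((idx - 1L) %% length(mirnas)) + 1L],
                   gene_id = genes[((idx - 1L) %/% length(mirnas)) + 1L])
  }

  true_edges <- if (config$n_true_edges > 0) {
    sample_pairs(truth$de_mirnas$feature_id, truth$de_genes$feature_id,
                 config$n_true_edges)
  } else {
    tibble::tibble(mirna_id = character(), gene_id = character())
  }

  non_de_mirnas <- setdiff(truth$all_mirnas, truth$de_mirnas$feature_id)
  non_de_genes <- setdiff(truth$all_genes, truth$de_genes$feature_id)
  decoy_edges <- if (config$n_decoy_edges > 0) {
    sample_pairs(non_de_mirnas, non_de_genes, config$n_decoy_edges)
  } else {
    tibble::tibble(mirna_id = character(), gene_id = character())
  }

  validated <- dplyr::bind_rows(true_edges, decoy_edges) |>
    dplyr::mutate(support_type = "validated",
                  database = sample(databases, dplyr::n(), replace = TRUE))

  n_neg <- round(config$frac_negative * nrow(validated))
  negative <- if (n_neg > 0) {
    sample_pairs(truth$all_mirnas, truth$all_genes, n_neg) |>
      dplyr::mutate(support_type = "negative",
                    database = sample(databases, dplyr::n(), replace = TRUE))
  } else {
    NULL
  }

  out <- dplyr::bind_rows(validated, negative)
  attr(out, "true_edges") <- true_edges
  out
}

#' Simulate clinical annotation for the tumor samples
#'
#' T stage is drawn per tumor sample from a categorical distribution whose
#' probabilities are monotonically shifted toward higher stages as the
#' designated gene's expression quartile increases (strength
#' `t_stage_shift`). Overall-survival times are exponential with log-hazard
#' `log(baseline) + sum(beta_g * z_g)` over the hazard genes (`z` =
#' standardized log2 normalized expression); censoring combines an
#' administrative horizon with independent exponential dropout.
#'
#' @param config A [sim_config()].
#' @param counts The mRNA [count_matrix()] (tumor samples are read from it).
#' @param truth A list with element `hazard_genes`, a tibble
#'   (`gene_id`, `coef`) of log-hazard coefficients per standard deviation
#'   of expression; may be empty only when `config$hub_hazard_lfc == 0`.
#'
#' @return A tibble with columns `sample_id`, `t_stage` (`"T1"`–`"T4"`,
#'   possibly `NA`), `os_time`, `os_event`.
#' @export
generate_clinical <- function(config, counts, truth) {
  validate_sim_config(config)
  stopifnot(inherits(counts, "count_matrix"))
  hazard_genes <- truth$hazard_genes
  if ((is.null(hazard_genes) || nrow(hazard_genes) == 0L) &&
      config$hub_hazard_lfc != 0)
    stop("`truth$hazard_genes` is empty but `hub_hazard_lfc` is nonzero",
         call. = FALSE)
  set.seed(sim_seed(config, "clinical"))

  tumor_ids <- colnames(counts$counts)[counts$condition == "tumor"]
  if (length(tumor_ids) == 0L) stop("no tumor samples present", call. = FALSE)
  n <- length(tumor_ids)

  sf <- estimate_size_factors(counts)
  expr <- vst_like_transform(counts, sf)[, tumor_ids, drop = FALSE]

  # T stage: baseline frequencies typical of a resected gastric cancer
  # cohort, tilted by the designated gene's expression quartile.
  stage_gene <- if (!is.null(hazard_genes) && nrow(hazard_genes) > 0) {
    hazard_genes$gene_id[1]
  } else {
    rownames(expr)[1]
  }
  base_probs <- c(T1 = 0.06, T2 = 0.29, T3 = 0.40, T4 = 0.25)
  quart <- quartile_of(expr[stage_gene, ], tumor_ids)
  t_stage <- vapply(quart, function(q) {
    w <- base_probs * exp(config$t_stage_shift * (q - 2.5) * (1:4 - 2.5))
    sample(names(base_probs), 1L, prob = w / sum(w))
  }, character(1))
  t_stage[stats::runif(n) < config$t_stage_missing] <- NA_character_

  log_hazard <- rep(log(config$survival_baseline_hazard), n)
  if (!is.null(hazard_genes) && nrow(hazard_genes) > 0 &&
      config$hub_hazard_lfc != 0) {
    for (i in seq_len(nrow(hazard_genes))) {
      g <- hazard_genes$gene_id[i]
      if (!g %in% rownames(expr))
        stop(sprintf("hazard gene %s not in the count matrix", g), call. = FALSE)
      z <- as.numeric(scale(expr[g, ]))
      if (any(is.na(z))) z[] <- 0  # constant expression carries no signal
      log_hazard <- log_hazard + hazard_genes$coef[i] * z
    }
  }
  event_time <- stats::rexp(n, rate = exp(log_hazard))
  dropout <- if (config$dropout_rate > 0) {
    stats::rexp(n, rate = config$dropout_rate)
  } else {
    rep(Inf, n)
  }
  censor_time <- pmin(dropout, config$censoring_horizon)

  tibble::tibble(
    sample_id = tumor_ids,
    t_stage = t_stage,
    os_time = pmin(event_time, censor_time),
    os_event = as.integer(event_time <= censor_time)
  )
}

# Expression quartile (1-4) with deterministic sample-ID tie-break.
quartile_of <- function(values, ids) {
  ord <- order(values, ids)
  q <- integer(length(values))
  q[ord] <- ceiling(seq_along(values) / (length(values) / 4))
  pmin(q, 4L)
}

#' Simulate a complete multi-omics study with ground truth
#'
#' Runs every generator under a single seed and assembles a planted-truth
#' record for recovery testing: DE features, true regulatory edges, protein
#' directions, and hazard coefficients. The designated hazard gene is the
#' first planted down-regulated gene that participates in a true edge from
#' an up-regulated miRNA (falling back to the first DE gene), so the
#' survival signal sits on a gene that the circuit stage can recover.
#'
#' @param config A [sim_config()].
#'
#' @return A list of class `igc_simulation` with elements `mrna`, `mirna`
#'   (each a [count_matrix()]), `proteins`, `interactions`, `clinical`
#'   (tibbles), and `truth` (list: `de_genes`, `de_mirnas`, `true_edges`,
#'   `protein_directions`, `hazard_genes`, `all_genes`, `all_mirnas`).
#' @examples
#' sim <- simulate_igc_study(sim_config(n_genes = 100, n_mirnas = 30,
#'                                      n_tumor = 12, n_normal = 6,
#'                                      n_true_edges = 20, n_decoy_edges = 10))
#' names(sim)
#' @export
simulate_igc_study <- function(config = sim_config()) {
  mrna <- generate_counts(config, "mRNA")
  mirna <- generate_counts(config, "miRNA")
  proteins <- generate_proteins(config, mrna$truth)

  truth <- list(
    de_genes = mrna$truth,
    de_mirnas = mirna$truth,
    all_genes = rownames(mrna$counts$counts),
    all_mirnas = rownames(mirna$counts$counts)
  )
  interactions <- generate_interactions(config, truth)
  truth$true_edges <- attr(interactions, "true_edges")
  truth$protein_directions <- proteins

  hazard_gene <- character(0)
  if (config$hub_hazard_lfc != 0) {
    down_genes <- truth$de_genes$feature_id[truth$de_genes$log2fc < 0]
    up_mirnas <- truth$de_mirnas$feature_id[truth$de_mirnas$log2fc > 0]
    cand <- truth$true_edges |>
      dplyr::filter(.data$mirna_id %in% up_mirnas,
                    .data$gene_id %in% down_genes) |>
      dplyr::pull("gene_id")
    hazard_gene <- if (length(cand) > 0) {
      sort(cand)[1]
    } else if (nrow(truth$de_genes) > 0) {
      truth$de_genes$feature_id[1]
    } else {
      truth$all_genes[1]  # null simulations: designate an arbitrary gene
    }
  }
  truth$hazard_genes <- tibble::tibble(
    gene_id = hazard_gene,
    coef = rep(config$hub_hazard_lfc, length(hazard_gene))
  )

  clinical <- generate_clinical(config, mrna$counts, truth)

  structure(
    list(mrna = mrna$counts, mirna = mirna$counts, proteins = proteins,
         interactions = interactions, clinical = clinical, truth = truth,
         config = config),
    class = "igc_simulation"
  )
}

#' @export
print.igc_simulation <- function(x, ...) {
  cat(sprintf(paste0(
    "<igc_simulation> %d genes x %d samples; %d miRNAs; %d protein rows;\n",
    "  %d interaction rows (%d planted true edges); %d clinical records\n"),
    nrow(x$mrna$counts), ncol(x$mrna$counts), nrow(x$mirna$counts),
    nrow(x$proteins), nrow(x$interactions), nrow(x$truth$true_edges),
    nrow(x$clinical)))
  invisible(x)
}
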