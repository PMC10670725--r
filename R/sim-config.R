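#' Simulation configuration for a synthetic tumor/normal multi-omics study
#'
#' Bundles every knob of the synthetic data generator into a validated list.
#' Defaults emulate the TCGA-style intestinal gastric cancer cohort the
#' pipeline was designed around: 180 tumor and 18 adjacent-normal samples,
#' roughly a quarter of genes and miRNAs differentially expressed, bulk
#' RNA-seq-like negative-binomial dispersion, and survival times on a scale
#' of months.
#'
#' @param n_genes,n_mirnas Number of simulated genes and miRNAs.
#' @param n_tumor,n_normal Number of tumor and adjacent-normal samples
#'   (each must be at least 2 so differential expression has replication).
#' @param frac_de_genes,frac_de_mirnas Fraction of features with a planted
#'   tumor-vs-normal effect, in `[0, 1]`.
#' @param lfc_magnitude Absolute planted log2 fold change for differentially
#'   expressed features (sign is random per feature).
#' @param dispersion Negative-binomial dispersion `alpha` >= 0, in the
#'   mean/dispersion parameterization `var = mu + alpha * mu^2`. Zero gives
#'   Poisson counts.
#' @param base_mean_range Two positive numbers; baseline per-feature means are
#'   drawn log-uniformly over this interval.
#' @param n_true_edges Number of planted (DE miRNA, DE gene) regulatory edges.
#' @param n_decoy_edges Number of decoy edges among non-DE features.
#' @param frac_negative Fraction (of true + decoy edges) of additional rows
#'   labelled with "negative" support type, emulating refuted interactions.
#' @param frac_protein_detected Probability that a DE gene appears in the
#'   protein differential-expression table.
#' @param frac_protein_concordant Probability that a detected protein's
#'   direction agrees with its mRNA direction (discordant proteins emulate
#'   translational repression).
#' @param survival_baseline_hazard Baseline hazard, events per time unit
#'   (months by convention).
#' @param hub_hazard_lfc Log-hazard change per standard deviation of
#'   expression for the designated hazard gene(s); 0 disables the planted
#'   survival signal.
#' @param censoring_horizon Administrative censoring time.
#' @param dropout_rate Rate of an independent exponential dropout process.
#' @param t_stage_shift Strength of the monotone link between the designated
#'   gene's expression quartile and pathologic T stage (0 = no association).
#' @param t_stage_missing Probability a tumor sample is missing its T stage.
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 200, n_mirnas = 40, n_tumor = 20, n_normal = 10)
#' cfg$frac_de_genes
#' @export
sim_config <- function(n_genes = 2000,
                       n_mirnas = 300,
                       n_tumor = 180,
                       n_normal = 18,
                       frac_de_genes = 0.25,
                       frac_de_mirnas = 0.23,
                       lfc_magnitude = 2,
                       dispersion = 0.1,
                       base_mean_range = c(20, 2000),
                       n_true_edges = 150,
                       n_decoy_edges = 150,
                       frac_negative = 0.1,
                       frac_protein_detected = 0.6,
                       frac_protein_concordant = 0.8,
                       survival_baseline_hazard = 0.015,
                       hub_hazard_lfc = 0.75,
                       censoring_horizon = 120,
                       dropout_rate = 0.005,
                       t_stage_shift = 0.4,
                       t_stage_missing = 1 / 30,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
    n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
    frac_de_genes = frac_de_genes, frac_de_mirnas = frac_de_mirnas,
    lfc_magnitude = lfc_magnitude, dispersion = dispersion,
    base_mean_range = as.numeric(base_mean_range),
    n_true_edges = as.integer(n_true_edges),
    n_decoy_edges = as.integer(n_decoy_edges),
    frac_negative = frac_negative,
    frac_protein_detected = frac_protein_detected,
    frac_protein_concordant = frac_protein_concordant,
    survival_baseline_hazard = survival_baseline_hazard,
    hub_hazard_lfc = hub_hazard_lfc,
    censoring_horizon = censoring_horizon,
    dropout_rate = dropout_rate,
    t_stage_shift = t_stage_shift,
    t_stage_missing = t_stage_missing,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_if <- function(bad, msg) if (bad) stop(msg, call. = FALSE)
  counts <- c("n_genes", "n_mirnas", "n_tumor", "n_normal")
  for (f in counts) stop_if(is.na(cfg[[f]]) || cfg[[f]] < 1L,
                            sprintf("`%s` must be a positive count", f))
  stop_if(cfg$n_tumor < 2L || cfg$n_normal < 2L,
          "`n_tumor` and `n_normal` must each be >= 2 (differential expression needs replication)")
  props <- c("frac_de_genes", "frac_de_mirnas", "frac_negative",
             "frac_protein_detected", "frac_protein_concordant",
             "t_stage_missing")
  for (f in props) stop_if(cfg[[f]] < 0 || cfg[[f]] > 1,
                           sprintf("`%s` must lie in [0, 1]", f))
  stop_if(cfg$dispersion < 0, "`dispersion` must be >= 0")
  stop_if(length(cfg$base_mean_range) != 2L || any(cfg$base_mean_range <= 0) ||
            diff(cfg$base_mean_range) < 0,
          "`base_mean_range` must be a positive, nondecreasing interval")
  stop_if(cfg$n_true_edges < 0L || cfg$n_decoy_edges < 0L,
          "edge counts must be nonnegative")
  stop_if(cfg$survival_baseline_hazard <= 0, "`survival_baseline_hazard` must be > 0")
  stop_if(cfg$censoring_horizon <= 0, "`censoring_horizon` must be > 0")
  stop_if(cfg$dropout_rate < 0, "`dropout_rate` must be >= 0")
  stop_if(is.na(cfg$seed), "`seed` must be an integer")
  invisible(cfg)
}

# Stage-specific RNG offsets so each generator draws from its own
# deterministic stream derived from the single top-level seed.
sim_seed <- function(cfg, stage) {
  offset <- c(mRNA = 0L, miRNA = 1L, proteins = 2L,
              interactions = 3L, clinical = 4L)[[stage]]
  (cfg$seed + offset) %% .Machine$integer.max
}
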