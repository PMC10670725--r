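# miRcircuit

Integrative miRNA–mRNA–protein regulatory-circuit analysis for tumor
versus adjacent-normal cohorts, written for systems-biology researchers
who want to move from three differential-expression lists to a small set
of mechanism-typed regulatory circuits and clinically characterized hub
molecules.

## The method

Post-transcriptional regulation by miRNAs leaves two distinct molecular
signatures. With near-perfect target complementarity the transcript is
degraded, so the target falls at both the mRNA and the protein level;
with partial complementarity translation is repressed, so only the
protein falls while the transcript may even rise. `miRcircuit`
operationalizes this logic over three omics layers:

1. **Differential expression.** Counts are normalized by median-of-ratios
   size factors and tested feature by feature with a negative-binomial
   Wald test (`var = μ + αμ²`, method-of-moments dispersion, pseudo-count
   ε = 0.5, tumor in the numerator). Genes are called at BH-adjusted
   p ≤ 0.05 and |log2FC| ≥ 1; miRNAs at adjusted p ≤ 0.05 and |log2FC| > 0.
2. **Directional overlap.** DEGs are intersected with a protein
   differential-expression table into four disjoint groups:
   mRNA↓/protein↓, mRNA↑/protein↑, mRNA↑/protein↓, and mRNA↓/protein↑.
3. **Circuit assembly.** Validated miRNA→gene interactions (rows with
   "negative" support are removed) are typed by mechanism:
   - **RRC1** (repression by degradation): miRNA↑ → gene mRNA↓/protein↓;
   - **RRC2** (translational repression): miRNA↑ → gene mRNA↑/protein↓;
   - **IRC** (induction by release): miRNA↓ → gene mRNA↑/protein↑.
   The mRNA↓/protein↑ group matches no miRNA mechanism and deliberately
   forms no circuit.
4. **Hubs.** Target genes are ranked by maximal clique centrality,
   `MCC(v) = Σ_{maximal cliques C ∋ v} (|C|−1)!`, computed from an
   authored Bron–Kerbosch enumeration with pivoting (on a bipartite
   circuit MCC reduces exactly to the number of regulators); miRNAs are
   ranked by out-degree with all ties at the cutoff included, and
   coverage is reported as the percentage of the circuit's distinct
   targets.
5. **Enrichment.** Hypergeometric over-representation of circuit gene or
   miRNA sets against user-supplied GMT collections, BH-adjusted within
   each category.
6. **Clinical association.** Per-marker ROC AUC via the rank statistic
   (flipped to ≥ 0.5 with the orientation recorded, banded
   excellent/good/fair/poor/failure at 0.9/0.8/0.7/0.6), Kruskal–Wallis
   plus pairwise Mann–Whitney across pathologic T stages,
   quartile-stratified Kaplan–Meier curves compared by log-rank, and
   Pearson correlation of regulator–target pairs with the inverse-
   regulation call at p ≤ 0.05 and R ≤ −0.3.

A synthetic-data module simulates all four inputs — NB counts with
planted fold changes, a protein direction table, an interaction table
with planted true edges, decoys, and refuted rows, and clinical data with
expression-linked T stage and proportional-hazards survival — together
with a complete ground-truth record, so the whole pipeline can be
validated by recovery of planted effects.

## Worked example

```r
library(miRcircuit)

cfg <- sim_config(n_genes = 500, n_mirnas = 100, n_tumor = 60, n_normal = 15,
                  n_true_edges = 80, n_decoy_edges = 40, seed = 11)
sim <- simulate_igc_study(cfg)
res <- run_pipeline(sim$mrna, sim$mirna, sim$proteins, sim$interactions,
                    clinical = sim$clinical)
res
#> <igc_pipeline>
#>   DEGs: 58 up, 67 down; DEMs: 11 up, 14 down
#>   RRC1: 7 edges (4 miRNAs -> 6 genes)
#>   RRC2: 2 edges (2 miRNAs -> 1 genes)
#>   IRC: 10 edges (8 miRNAs -> 8 genes)
```

125 of the 500 genes are called differentially expressed (the generator
planted 125 at |log2FC| = 2), and the validated interactions split into
the three mechanism-typed circuits. Hubs:

```r
head(res$hubs$target_hubs, 3)
#>   gene_id  mcc_score n_regulators circuit_type direction
#> 1 GENE0486         2            2 RRC1         down/down
#> 2 GENE0115         1            1 RRC1         down/down
#> 3 GENE0189         1            1 RRC1         down/down

head(res$hubs$regulator_hubs, 2)
#>   mirna_id     out_degree coverage_pct circuit_type direction
#> 1 hsa-mir-0040          2         33.3 RRC1         up
#> 2 hsa-mir-0047          2         33.3 RRC1         up
```

`GENE0486` is repressed by two up-regulated miRNAs (MCC score 2 =
regulator count, as always on bipartite circuits); `hsa-mir-0040`
targets 2 of RRC1's 6 genes, i.e. 33.3% coverage. The top hub separates
tumors from normals almost perfectly:

```r
res$clinical_assoc$roc_gene
#> <roc_result> AUC = 0.9989 (excellent, flipped); 60 positive vs 15 negative
```

("flipped" records that the gene is down-regulated, so low expression
marks tumors.) `glance()`, `tidy()`, and `autoplot()` methods are
provided for every result type (volcano, ROC, Kaplan–Meier, circuit, and
enrichment plots).

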