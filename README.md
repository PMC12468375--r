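# consensusDR

Stage-specific consensus drug repurposing with structural and synergy
analysis.

Transcriptomic signature-reversal repurposing asks which known drugs push
a disease's gene-expression signature back toward normal. Tools built on
perturbation compendia (Connectivity-Map-style services) each return a
ranked list of candidate "reverser" drugs for a given up/down gene
signature, but different tools — and different patient cohorts — rarely
agree. `consensusDR` implements the full analysis chain needed to turn
several such ranked lists, across several datasets and disease stages,
into a single defensible shortlist per stage, and to characterise that
shortlist chemically and therapeutically. It was built with the
monoclonal gammopathy → smouldering myeloma → multiple myeloma
progression in mind (stages are labels, so any staged disease works).

The package covers, as composable functions:

* **Signatures** — quantile normalisation, empirical-Bayes moderated-t
  differential expression, probe-to-symbol collapsing, and symmetric
  top-150 up / top-150 down signature extraction at adjusted p < 0.05.
* **Consensus ranking** (the core) — two-level weighted rank
  aggregation. For item *i*,

  `Score_i = w1 * R_i + w2 * A_i`, with `w1 = 0.7`, `w2 = 0.3`,

  where `R_i` is the mean normalised rank value over the sources that
  report the item (rank *r* in a *K*-item list contributes
  `(K - r + 1) / K`, so rank 1 → 1) and `A_i` is the fraction of sources
  reporting it. The same formula aggregates tools within a dataset and
  then datasets within a stage; drugs scoring ≥ 0.75 form the stage
  shortlist. Pathways are aggregated identically, ranked by adjusted
  p-value within each dataset.
* **Enrichment** — hypergeometric over-representation analysis of DEG
  sets and of drug-target gene sets against a measured-gene universe,
  with Benjamini–Hochberg adjustment.
* **Structural similarity** — OpenBabel path fingerprints from SMILES,
  Tanimoto matrices, cross-set screening at 80% similarity, and
  complete-linkage clustering cut at Soergel distance 0.15
  (≈ 87% Tanimoto under the `T = 1/(1+d)` threshold convention).
* **Synergy** — ZIP, Loewe, HSA and Bliss reference models scored from
  raw dose–response matrices, with strict `>+5` (moderate) / `>+10`
  (strong) classification, per-model top lists and the cross-model
  intersection.
* **Synthetic data** — seeded generators for every input type with
  planted ground truth (JSON sidecars), so the whole pipeline is testable
  end to end with known answers.

## Worked example

Aggregate three tools × four datasets of ranked drug lists, in which 25
planted true reversers out of 300 drugs win pairwise rank contests with
probability 0.9:

```r
library(consensusDR)

universe <- sprintf("drug%03d", 1:300)
truth <- planted_tool_truth(universe[1:25], n_tools = 3, n_datasets = 4,
                            top_k = 50, rank_advantage = 0.9)
tool_lists <- gen_tool_outputs(universe, truth, seed = 1, stage = "MM")

per_dataset <- lapply(tool_lists, function(tools)
  aggregate_within_dataset(lapply(tools, truncate_top_k, k = 50)))
consensus <- aggregate_across_datasets(per_dataset, stage = "MM")
head(consensus, 5)
#>   item_id         R A     score n_sources
#> 1 drug014 0.9499985 1 0.9649989         4
#> 2 drug018 0.9339025 1 0.9537318         4
#> 3 drug012 0.9295624 1 0.9506937         4
#> 4 drug007 0.9248537 1 0.9473976         4
#> 5 drug025 0.9103497 1 0.9372448         4

shortlist <- retain_threshold(consensus, threshold = 0.75)
nrow(shortlist)
#> [1] 23
mean(shortlist$item_id %in% truth$true_reversers)
#> [1] 1
```

Every drug in the head of the list is a planted reverser (`drug001`–
`drug025`); each appears in all four datasets (`A = 1`) with near-top
average rank, and the 0.75 retention rule returns a 23-drug shortlist
that is 100% planted reversers. `run_pipeline(default_config())` chains
this with simulation, differential expression, enrichment, clustering
and synergy scoring, writing per-stage CSVs and a manifest whose output
hashes are reproducible for a fixed configuration.

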