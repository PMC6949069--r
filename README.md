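# riskmod

Identification of disease **risk modules** from paired tumor/normal
expression data and a seed-gene-centered protein-interaction network.

Known disease genes ("seed genes", here defined as genes catalogued in at
least two independent disease-gene databases) anchor a subnetwork of the
interactome. `riskmod` searches that subnetwork for modules — connected
gene sets containing both seed and non-seed genes — whose expression
behaviour marks them as disease-associated, and validates them by
classification. The pipeline has four stages:

1. **Differential screening.** Genes are screened for mean shifts with a
   paired SAM-style moderated statistic
   `d = z̄ / (se(z̄) + s₀)` on within-pair differences `z = tumor − normal`
   (FDR < 0.05 and |log₂FC| > 1), and for variance shifts with
   `V = |S²_normal − S²_tumor|` tested against a label-permutation null
   (FDR-adjusted empirical p < 0.05). DEGs ∪ DEVGs are the differential
   genes.
2. **Primary modules.** Cliques of 5–8 genes containing at least one seed
   and one differential gene are mined from the seed-centered network and
   iteratively merged whenever the Simpson overlap of their *seed* sets
   `S(A,B) = |A∩B| / min(|A|,|B|)` exceeds 0.8.
3. **Candidate modules.** Within each primary module every non-seed gene
   y is scored by `Σₓ MI(x,y)` (Kraskov k-NN mutual information, k = 3)
   and by the mean |Pearson correlation| with the seed genes x; genes
   jointly maximal under Pareto dominance are retained. Modules reduced
   to seeds only are dropped.
4. **Risk modules.** Each candidate M is scored three ways:
   - MRF module score
     `W(M) = (1/m) Σ_{i∈C1} f_i − (1/k) Σ_{(u,v)∈E(M), u,v∈C2}
     (f_u/d_u − f_v/d_v)² · MI(u,v)`
     with `f` the absolute paired t statistic, `d` the network degree,
     `m` the gene count and `k` the edge count of M;
   - functional consistency `F(M)`, the mean Jaccard index of annotation
     sets over (seed, non-seed) pairs;
   - correlation rewiring `ΔPCC(M) = Σ_pairs |PCC_tumor − PCC_normal|`.

   Each score is compared with 1,000 (configurable) random modules of the
   same gene and seed composition; candidates significant in **all
   three** permutation tests (p < 0.05) are risk modules. A linear-SVM
   LOOCV AUC against size-matched random feature sets validates them.

A ground-truth synthetic-data generator (paired expression with planted
mean/variance/correlation structure, a seed-centered network with planted
near-cliques, and annotation sets with planted overlap) makes every stage
testable offline.

## Worked example

```r
library(riskmod)

study  <- simulate_study(simulation_config(rng_seed = 1))
config <- pipeline_config(n_random = 200, rng_seed = 1)
res <- run_pipeline(study$expr, study$network, study$seeds,
                    study$annotations, config)
risk_summary(res$reports)
```

```
    label          W         F      dPCC         p_W         p_F      p_dPCC is_risk
1 M1.cand 2.82377717 0.6777778 20.628651 0.004975124 0.004975124 0.004975124    TRUE
2 M2.cand 2.81189824 0.8333333 19.367247 0.004975124 0.004975124 0.004975124    TRUE
3 M3.cand 0.20448883 0.0000000  4.341935 0.522388060 1.000000000 0.144278607   FALSE
4 M4.cand 0.05535529 0.0000000  5.032805 0.845771144 1.000000000 0.462686567   FALSE
```

The two modules carrying the planted coherent signal are significant in
all three scores (p = 1/201 against 200 random modules each); the
variance-inflated decoy module and a background module fail. The
recovered risk modules overlap the planted 16-gene module at Jaccard
0.688, and classification with their genes separates tumor from normal
samples with a LOOCV AUC of 0.977.

The same chain is available from a shell via the thin CLI:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "riskmod.R", package = "riskmod"))')
Rscript $CLI simulate   --out fx --seed-rng 3
Rscript $CLI screen     --expr fx/expression.tsv --samples fx/samples.tsv --seed-rng 3 --out diff.tsv
Rscript $CLI mine       --network fx/network.tsv --seeds fx/seeds.txt --diff diff.tsv --out primary.json
Rscript $CLI candidates --modules primary.json --expr fx/expression.tsv --samples fx/samples.tsv --out cands.json
Rscript $CLI score      --modules cands.json --expr fx/expression.tsv --samples fx/samples.tsv \
                        --gmt fx/annotations.gmt --network fx/network.tsv --seeds fx/seeds.txt \
                        --n-random 200 --seed-rng 3 --out reports.json
Rscript $CLI validate   --modules cands.json --expr fx/expression.tsv --samples fx/samples.tsv \
                        --network fx/network.tsv --baseline 50 --seed-rng 3 --out val.json
```

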