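# slnpm

Linear neighborhood propagation for lncRNA–miRNA interaction prediction.

Long non-coding RNAs (lncRNAs) regulate microRNAs (miRNAs) by acting as
decoys or sponges, and mapping which lncRNA binds which miRNA is central to
understanding lncRNA function in disease. Experimentally verified
interactions cover only a small corner of the possible pairs, so this
package ranks all unobserved lncRNA–miRNA pairs by how likely they are to
interact, using nothing beyond the known interaction list and the
transcript sequences — the two inputs that are available for essentially
every entity. It is aimed at computational biologists triaging candidate
interactions for validation, and at methods researchers who need a clean,
tested reference implementation of neighborhood-based label propagation on
bipartite networks.

## Method

Entities are embedded two ways: as 1024-dimensional 5-mer frequency
vectors computed from their sequences, and as binary interaction profiles
(rows/columns of the interaction matrix *Y* ∈ {0,1}<sup>l×m</sup>). On
each representation a **linear neighborhood similarity** (LNS) *W* is
learned by reconstructing every entity from its nearest neighbors:

    min_W  ½‖X − (C∘W)X‖²_F + (μ/2)Σᵢ‖(C∘W)e‖²₂   s.t. (C∘W)e = e, W ≥ 0

where *C* marks the *K*(n−1) nearest neighbors by Euclidean distance. Each
row of *W* lies on the probability simplex over its neighborhood; the
package solves the row subproblems exactly by monotone accelerated
projected gradient descent.

Entities with no known interaction have empty profiles, so two cold-start
strategies combine the information sources:

* **SC** (similarity combination): use the interaction-profile similarity
  row where it exists, substitute the sequence-similarity row where it
  does not.
* **PC** (profile complementation): rebuild the missing profile as the
  similarity-weighted average of the profiles of the *k* nearest
  interacting sequence neighbors, then learn similarities from the
  completed matrix.

Scores come from label propagation on the two similarity graphs,
*F ← αSF + (1−α)Y*, whose fixed point is (1−α)(I−αS)⁻¹Y, and the final
prediction is the fusion *P = βP^l + (1−β)P^m*. Defaults are K = 80%
(90% for PC), α = 0.4, β = 0.25.

Because no external database is bundled, the package ships a synthetic
generator (`simulate_network()`) that plants group structure jointly in
sequences (group-specific first-order nucleotide chains) and interactions
(dense within groups, sparse across), plus the full evaluation protocol:
repeated 5-fold cross-validation, AUPR/AUC/REC/SP/PR/ACC/F1, top-k recall
and a parameter grid search.

## Worked example

```r
library(slnpm)

sim   <- simulate_network(simulation_config(n_lnc = 60, n_mir = 30, seed = 7))
X_lnc <- kmer_features(sim$lnc_seqs)   # 60 x 1024 5-mer frequencies
X_mir <- kmer_features(sim$mir_seqs)

# mask 10% of entities entirely (cold start), predict with SLNPM-SC
hold <- holdout_cold_start(sim$Y, 0.1, seed = 8)
P    <- slnpm_sc(hold$Y_train, X_lnc, X_mir)
top  <- write_predictions(P, tempfile(), Y_known = hold$Y_train, mask_known = TRUE)
head(top, 5)
#>   lncRNA_id miRNA_id score known
#> 1    lnc054   mir026 0.271     0
#> 2    lnc002   mir006 0.235     0
#> 3    lnc001   mir013 0.232     0
#> 4    lnc045   mir001 0.225     0
#> 5    lnc009   mir005 0.224     0

cross_validate(sim$Y, X_lnc, X_mir, method = "sc", n_runs = 2, n_folds = 5, seed = 1)
#> Cross-validated SC model over 10 fold evaluations
#>   aupr    auc    rec     sp     pr    acc     f1
#> 0.0930 0.7456 0.1188 0.9706 0.1188 0.9432 0.1188
```

The score column ranks candidate pairs: on this small planted network the
model retrieves held-out interactions with AUC ≈ 0.75 while calling only
~12% of a fold's candidates positive at the rank cutoff, and the masked
(cold-start) lncRNAs — invisible to any profile-only model — reach a
median per-entity AUC of 0.77 from their sequence neighbors alone.

A command-line interface with the same functionality is installed as
`exec/slnpm` (subcommands `simulate`, `features`, `similarity`, `predict`,
`evaluate`, `grid`).

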