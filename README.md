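# lncmir

Link prediction for lncRNA–miRNA interactions from sequence and network
topology.

Long noncoding RNAs (lncRNAs) regulate gene expression in part by acting as
competing endogenous RNAs: they carry miRNA response elements and sponge
miRNAs away from their mRNA targets. Experimentally verified lncRNA–miRNA
pairs are scarce, so computational ranking of candidate pairs is a standard
step before wet-lab validation. `lncmir` implements a deep link-prediction
pipeline for this problem as a tested R library plus a command-line
interface, together with the evaluation machinery the field expects
(5-fold cross-validation, cold-start "blind" splits, label-noise robustness)
and a synthetic-data generator so every stage runs without downloads.

## The model

Each side of a candidate pair gets two embeddings — a *biological* one from
sequence/structure and a *topological* one from the known interaction graph —
which are fused and scored by an MLP trained end to end with
binary cross-entropy (Adam, learning rate 1e-4, up to 200 epochs, best
validation checkpoint kept).

**lncRNA encoder.** A sequence of length *L* is segmented into overlapping
k-mers (*L* − *k* + 1 tokens) at several scales (default k = 3, 9, 15). Each
scale is embedded by a PV-DM paragraph-vector model trained with negative
sampling: the hidden state at position *t* is the mean of the document
vector and the 2*c* surrounding word vectors,

    h_t = (E_doc + Σ_{−c ≤ j ≤ c, j ≠ 0} w_{t+j}) / (2c + 1),

and the target k-mer is predicted by a softmax over the k-mer vocabulary.
The per-scale document vectors are stacked into H and fused by scaled
dot-product self-attention, `E_M = mean(softmax(QKᵀ/√d) V)` with
Q = H·W_Q, K = H·W_K, V = H·W_V.

**miRNA encoder.** The secondary-structure contact map (from dot-bracket
strings or thresholded probability matrices; a synthetic hairpin generator
is bundled) defines a graph over nucleotides. Node features (one-hot
nucleotides, or externally supplied per-nucleotide embeddings from an RNA
language model) are propagated through a degree-normalized GCN,

    H^{p+1} = σ(D̃^{−1/2} (A + I) D̃^{−1/2} H^p W_p),

and mean-pooled into `E_M_mi`.

**Interaction encoder (globally enhanced GCN).** Known pairs form a sparse
bipartite graph. Each layer first runs the normalized GCN rule on the
block-symmetrized adjacency, then two virtual hub nodes gather the
per-type means,

    h_g_lnc = (1/N) Σ_u h_u,   h_g_mi = (1/M) Σ_v h_v,

and broadcast a learned transform back additively to every node of their
type (`h ← h + σ(h_g B_type)`), so even isolated nodes have a whole-graph
receptive field — the property that matters on very sparse interaction
maps. Setting the broadcast weights to zero recovers a vanilla GCN exactly,
which is also the `vanilla_gcn` ablation; `none` and `only` ablations drop
the topological or the biological embeddings respectively.

## Worked example

Simulate the "small" planted benchmark (60 lncRNAs × 80 miRNAs, rank-4
latent structure, 5% density), check that a rank-4 ALS factorization can
recover the held-out fold (so the benchmark is learnable), then train the
full model on fold 1 and evaluate. Runs in about two minutes on one CPU.

```r
library(lncmir)

dir <- file.path(tempdir(), "demo_small")
bundle <- make_fixture_bundle(dir, scale = "small", seed = 1)
tab <- bundle$table
folds <- make_cv_folds(tab, k = 5, seed = 1)
fold1 <- split_fold_pairs(folds, tab, fold = 1)

oracle <- als_link_oracle(fold1$train, tab$lnc_ids, tab$mi_ids, rank = 4)
compute_metrics(oracle$score(fold1$val), fold1$val$label)$AUC
#> [1] 0.8898765

sel_idx <- seq(1, nrow(fold1$train), by = 10)   # internal selection split
model <- train_model(run_config(seed = 1),
                     list(lnc_seqs = bundle$lnc_seqs,
                          mi_seqs = bundle$mi_seqs, cmaps = bundle$cmaps,
                          train = fold1$train[-sel_idx, ],
                          val = fold1$train[sel_idx, ]))
compute_metrics(predict_pairs(model, fold1$val), fold1$val$label)
#> metrics (n_pos=45, n_neg=45, threshold=0.50)
#>   F1    0.7957
#>   AUC   0.8622
#>   AUPR  0.8639
#>   NDCG  0.9661
#>   Pre   0.7708
#>   Rec   0.8222
```

The model's held-out AUC (0.862) tracks the ALS recoverability ceiling
estimate (0.890): the planted low-rank structure is being learned from the
graph, since the synthetic sequences carry no interaction signal by design.
Ranked candidate lists for specific lncRNAs come from `predict_ranked()`.

## Command line

Every step is also a CLI subcommand (`simulate`, `pretrain-lnc`, `split`,
`train`, `evaluate`, `predict`), each writing a `manifest.json` with the
seed, config hash and input fingerprints; identical invocations produce
byte-identical outputs.

```sh
Rscript -e 'lncmir::run_cli(commandArgs(TRUE))' simulate --scale tiny --seed 1 --out bundle
Rscript -e 'lncmir::run_cli(commandArgs(TRUE))' split --interactions bundle/interactions.tsv \
    --mode blind_lnc --folds 5 --seed 1 --out splits
```

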