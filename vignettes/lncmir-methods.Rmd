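---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the model implemented by `lncmir`, the choices made
where the design was genuinely open, the synthetic data the tests rely on,
and what a green test suite does and does not establish.

## 1. Problem and model

Given a set of lncRNAs, a set of miRNAs and a sparse list of experimentally
verified interactions, the task is to rank unobserved (lncRNA, miRNA) pairs
by interaction probability. The model combines three encoders and a scoring
head, trained jointly by full-batch Adam on binary cross-entropy with
logits.

**Multiscale lncRNA encoder.** Sequences are tokenized into overlapping
k-mers at several window sizes (default `k_values = c(3, 9, 15)`): a single
scale either misses short motifs or dilutes long-range composition, and the
scales are deliberately redundant. Each scale gets its own PV-DM
paragraph-vector model: the hidden state at a position is the arithmetic
mean of the document vector and the surrounding word vectors within a
window of half-width `c`, and a softmax over the k-mer vocabulary predicts
the target token; training maximizes the log-likelihood with negative
sampling (noise distribution: unigram frequency to the 0.75 power, the
conventional choice, unstated in the source literature). The per-scale
document vectors are stacked and fused by single-head scaled dot-product
self-attention followed by mean pooling. Scales carry no order, so there is
no positional encoding, and the fused vector is invariant to scale
permutation (tested).

Two deliberate deviations from the textbook formulas:

* *Edge windows.* At sequence boundaries the context window is truncated
  and the hidden mean divides by the actual vector count + 1 rather than
  `2c + 1`; dividing by the nominal count would bias edge positions toward
  zero.
* *Unseen documents.* Sequences outside the training corpus are embedded by
  optimizing a fresh document vector against frozen word/context tables
  (`infer_doc_vector`). A document whose k-mers are all out-of-vocabulary
  (routine at k = 15 for unrelated sequences) carries no information; the
  stack builder then uses the seeded random initialization that a zero-step
  inference returns. The operation itself errors in that case, per its
  contract.

**miRNA encoder.** miRNAs are short and structure-driven, so the encoder
works on the secondary-structure contact graph: nodes are nucleotides,
edges are predicted contacts. Contact maps come from dot-bracket strings
(single bracket family; pseudoknots rejected) or from numeric probability
matrices thresholded at 0.5 by default — the literature encodes contacts as
a binary matrix but never states the threshold; 0.5 is the neutral choice,
and the max-symmetrization `max(A, Aᵀ)` resolves asymmetric predictor
output. Node features are either one-hot nucleotides (the bundled
fallback, and the `onehot_mi` ablation) or an externally supplied L×d
matrix standing in for an RNA language model, which is out of scope as a
dependency. Two ReLU GCN layers (`σ(D̃^{-1/2}(A+I)D̃^{-1/2}HW)`) and mean
pooling produce one vector per miRNA. Two layers at width 64 is the
conventional sparse-graph configuration; depth/width were not stated.

**Globally enhanced interaction GCN.** The known interactions form a
bipartite graph that is extremely sparse, so plain message passing reaches
few nodes. Each GE-GCN layer therefore runs (i) normalized local
propagation on the block-symmetrized adjacency, (ii) a gather step in which
one virtual hub per node type averages all feature vectors of its type, and
(iii) a broadcast/update step returning hub information to every node.
The gather step is exactly the per-type arithmetic mean. The broadcast
arithmetic is not specified in the source literature; this package uses the
additive residual form `h ← h + σ(h_hub B_type)` with a learnable per-type
matrix because it (a) reduces *exactly* to a vanilla GCN when `B_type = 0`,
matching the `vanilla_gcn` ablation and giving a machine-checkable identity
(tested: identical per-epoch loss traces with broadcast weights zeroed and
frozen), and (b) remains well-posed on graphs with isolated nodes. Hub
states are recomputed in every layer. Initial node states are free
learnable embeddings: nothing in the source ties them to the feature
encoders, and independence keeps the `only` ablation meaningful.

The interaction graph spans the full entity universe: entities without
training edges sit isolated and receive information only through the hub
broadcast. Entities entirely unknown at training time (independent test
sets) are represented at prediction time by the trained per-type mean
embedding — the least-assumption fallback; predictions for such entities
lean on the sequence/structure side.

**Scoring head.** Per side, the biological and topological embeddings are
projected to a common width, averaged, and the two halves concatenated;
a `[2d, d, 1]` MLP with ReLU and dropout 0.2 produces the logit. The
published description says only "multilayer perceptron"; one hidden layer
of width d is the smallest faithful reading.

## 2. Training protocol and tunables

| parameter | default | meaning / why |
|---|---|---|
| `lr` | 1e-4 | Adam learning rate (published value) |
| `max_epochs` | 200 | epoch budget; the best validation-AUC checkpoint is kept, since "up to N epochs" implies early selection without stating a rule |
| `embed_dim` | 64 | shared width of all embeddings |
| `window` (c) | 5 | PV-DM context half-window (unstated; conventional) |
| `n_negative` | 5 | PV-DM negative samples (unstated; conventional) |
| `pvdm_epochs` | 30 | PV-DM pretraining epochs (desk-scale minutes) |
| `neg_ratio` | 1.0 | training negatives per positive; the published metrics look balanced but the protocol is unstated |
| `dropout` | 0.2 | MLP regularization |
| `threshold` | 0.5 | probability cutoff for F1/Pre/Rec (unstated; standard) |
| `leak_free_pvdm` | TRUE | PV-DM trains only on training-split sequences; unseen sequences are embedded with frozen tables. Whether the original pretraining included test sequences is unknown; the leak-free default is the defensible one, and the flag exists because the alternative is cheap to switch on |

Negative pairs are sampled uniformly from the complement of *all* known
positives (not merely the fold's), so a sampled negative can never be a
held-out positive. Sampling is rejection sampling under a derived seed —
deterministic, and disjoint across folds.

Training is full-batch: at desk scale (hundreds of pairs) every epoch is
one Adam step, and the expensive part of an epoch is the entity forward
pass, which minibatching would multiply, not amortize. All gradients are
hand-derived per component; the test suite checks every parameter block
against central finite differences in all ablation modes. Dropout masks,
parameter initialization and PV-DM SGD all draw from seeds derived from the
single run seed, making end-to-end runs bit-reproducible; ablation modes
initialize every parameter block in the same order so that RNG streams
align across variants (this is what makes the clamped-equivalence identity
exact).

Degenerate inputs: a non-finite loss aborts with the epoch and learning
rate in the message; empty training splits, single-class metric inputs and
infeasible negative-sampling requests error early with specific messages.
Ranking ties are broken lexicographically by (lnc_id, mi_id); AUC uses
average ranks; NDCG uses a stable sort, so exact ties keep input order.

## 3. Evaluation machinery

* **Standard CV**: positive pairs shuffled into k near-equal folds (sizes
  differ by ≤ 1); per-fold negatives at `neg_ratio`.
* **Blind (cold-start) splits**: *entities* of the blinded type are
  partitioned; a fold's validation pairs are those whose blinded entity is
  in the fold, everything else trains. In `blind_both`, a validation pair
  needs both entities blinded in the same fold, and mixed pairs (exactly
  one blinded entity) are dropped from that fold entirely — the source
  wording ("removes overlap on both sides") is ambiguous, and dropping
  enforces a strict cold start. The leak-freedom invariant (no blinded
  validation entity appears in any training pair) is asserted
  programmatically over random tables.
* **Independent**: train on one interaction table, evaluate on an external
  one (half validation, half test).
* **Metrics**: AUC as the Mann–Whitney rank statistic with average-rank
  ties; AUPR by step-wise precision–recall integration over all unique
  thresholds; NDCG with binary gains and `1/log2(rank+1)` discount on the
  single globally ranked list, normalized by the ideal ranking — the
  simplest consistent reading of an otherwise undefined NDCG variant.
  Metrics are computed per fold and reported as mean ± sd (pooled vs
  averaged was unstated; averaging is standard practice). All three ranking
  metrics are verified against quadratic/exhaustive reference
  implementations to 1e-9.
* **Label-noise protocol**: `inject_label_noise(pairs, r)` picks
  `floor(r · min(P, Q))` positives and equally many negatives uniformly and
  swaps their labels, conserving class counts; `r = 0` is the identity.
  Model selection inside each fold carves 10% of the training pairs into an
  internal validation set — the evaluation fold itself is never used for
  checkpoint selection.

## 4. Synthetic data: what it emulates and what it does not

The generator produces (i) uniform random RNA sequences with uniform
lengths, (ii) single-stem hairpin contact maps (position i paired with
L−1−i for the first `stem` positions), and (iii) a planted low-rank
bipartite interaction graph: latent factors `u_i, v_j`, connection
probability `sigmoid(gain · u_iᵀv_j + intercept + noise)`, with the
intercept calibrated by bisection so the expected density matches the
target within 0.005.

The default factor distribution is *archetype-structured*: each entity's
factor is a scaled copy of one of r orthogonal archetypes plus isotropic
spread (0.35). This was a deliberate design decision, made after
measurement, and it deserves its rationale spelled out. With plain
standard-normal factors at the default sparsity (60×80 grid, 5% density,
rank 4), the true planted probabilities separate held-out pairs almost
perfectly (AUC ≈ 0.99), but *no* rank-4 factorization fitted to ~4 observed
edges per entity recovers them (ALS plateaus near AUC 0.7): the benchmark
would be informative in principle yet unlearnable in practice, defeating
its purpose as a recoverability control. Archetype structure concentrates
edges within latent modules — which is also the more biologically plausible
shape for ceRNA networks, where families of lncRNAs share response elements
for families of miRNAs — and makes the benchmark recoverable by the rank-r
ALS oracle. `factor_model = "gaussian"` retains the diffuse variant.

The recoverability oracle itself (`als_link_oracle`) is implicit-feedback
weighted ALS on a pseudo-logit scale: observed pairs regress to ±2 with
weight 1, unobserved cells to 0 with weight 0.1, ridge 0.5, spectral
(truncated SVD) initialization, 30 sweeps. It is deterministic and shares
no code with the model it benchmarks.

What a green suite establishes: the formulas are implemented as printed
(against brute-force oracles), the cold-start machinery is leak-free, the
trainer optimizes what it claims (gradient checks, memorization, loss
descent), and the full model extracts plantable topological signal at least
as well as a matrix-factorization oracle minus a small margin. What it does
*not* establish: performance on real curated interaction data, the value of
real RNA-language-model features over one-hot (synthetic sequences carry no
interaction signal by construction), or realistic secondary-structure
effects (hairpins are deliberately simplistic topology variety, nothing
more).

## 5. Known limitations

* The broadcast/update arithmetic of the globally enhanced layer is an
  interpretation (the additive residual form above); other reasonable forms
  (gated, concatenative) exist and would not reduce to the vanilla-GCN
  ablation as cleanly.
* PV-DM hyperparameters (d, c, epochs, negatives) were not published;
  defaults are conventional rather than tuned.
* Entities unknown at training time are scored through sequence features
  plus a per-type mean topology embedding; with `interaction_mode = "only"`
  such entities cannot be scored at all.
* The CLI stores model checkpoints as RDS (an R serialization), not a
  portable archive format.
* Full-batch training holds all entity embeddings and the dense
  (N+M)×(N+M) normalized adjacency in memory; fine for thousands of
  entities, not for hundreds of thousands.
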