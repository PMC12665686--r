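---
title: "Methods: masked-expression pre-training and LSH-attention classification of single cells"
author: "screformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: masked-expression pre-training and LSH-attention classification of single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Cell-type annotation from scRNA-seq assigns each cell, described by a
vector of transcript counts over tens of thousands of genes, to a class in
a hierarchical taxonomy; here only the first (major-category) tier is
classified, and the deeper levels are carried along by downward label
propagation. The dimensionality is the obstacle: standard Transformer
self-attention is quadratic in sequence length, so a sequence of ~17,000
genes is infeasible, and the usual escape — highly-variable-gene selection
or dimensionality reduction — discards gene-gene relationships before the
model ever sees them.

`screformer` implements the alternative this package is built around: a
BERT-style two-stage procedure whose encoder is a *Reformer*, so the full
filtered gene sequence can be attended to.

1. **Tokenization.** Each cell is a fixed-order sequence over the gene
   vocabulary (genes expressed somewhere in the data and present in the
   gene-embedding table). Each gene's continuous expression is discretized
   into B bins; bin 0 is reserved for exactly-zero expression. The
   per-gene input vector is a sum of three components: a gene-identity
   embedding (optionally initialized from a Gene2vec-style co-expression
   embedding), a learnable bin embedding, and the standard sinusoidal
   positional encoding.
2. **Encoder.** `nLayers` reversible blocks, each coupling a multi-head
   LSH-attention sublayer F and a feed-forward sublayer G as
   `y1 = x1 + F(x2); y2 = x2 + G(y1)` with pre-layer-norm inside F and G.
   LSH attention hashes (shared-QK) query vectors with angular locality
   sensitive hashing, sorts positions by bucket, cuts the sorted order
   into chunks of `ceiling(L / nBuckets)` and lets each position attend
   within its chunk and to the preceding chunk. Keys are the
   row-normalized queries, which is what makes bucket membership
   consistent between queries and keys.
3. **Pre-training.** A masked-expression objective: 15% of the *expressed*
   (nonzero-bin) genes of each cell are selected; 90% of the selected
   positions are shown as a reserved MASK token and the rest are left
   unchanged. A linear head predicts the original bin from the encoder
   feature at each masked position; the loss is the summed cross-entropy
   over masked positions.
4. **Fine-tuning.** A classification head — a per-gene 1-D convolution
   (kernel size 1 over the feature axis), pooling over genes
   (concatenated mean- and max-pooling), and a three-layer perceptron —
   maps per-gene features to class probabilities; every weight in the
   model, embeddings included, is updated under the summed
   classification cross-entropy.
5. **Interpretation.** A sampling (permutation) Shapley estimator
   attributes a chosen class's pre-softmax logit to individual genes,
   replacing "switched-off" genes by the corresponding bin of a random
   background cell; genes are ranked by mean absolute attribution.

# Parameters that matter

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `nBins` | 7 | expression bins incl. the zero bin; small enough that every bin stays populated on sparse counts |
| `transform` | `log1p` | variance-stabilizing transform before quantile binning |
| `dModel` | 200 | feature width; equals the published gene-embedding width |
| `nLayers` | 6 | reversible blocks (published depth) |
| `nHeads` | 10 | attention heads (published) |
| `nBuckets` | 64 | LSH buckets (published); 1 recovers exact full attention |
| `nHashRounds` | 4 | hash rounds unioned into candidate sets; 1 activates the fast block-sparse path |
| `maskProb` | 0.15 | masking rate over expressed genes (published) |
| `replaceProb` | 0.9 | MASK-token share among selected positions (published) |
| fine-tune protocol | max 3 epochs, patience 1, AdamW, linear schedule, 10% warm-up | published protocol |
| `dropout` | 0.1 | classification-head dropout; see the desk-scale note below |

The published optimizer settings (batch 6, learning rate 1e-4, gradient
accumulation 60, seed 2022) are the argument defaults of
`finetuneReformer()`. At the desk scale of the bundled experiments
(hundreds to thousands of cells, feature widths 16-32) those values are
conservative: one epoch there is ~10^5 optimizer steps, while at desk
scale it is a few dozen, so the experiments in the tests and the
acceptance script use batch 4 (fine-tuning), learning rate 1e-3 to
3e-3, and up to ten epochs, which reach good optima in minutes on one
CPU. With 16-32 pooled channels, multiplicative dropout
noise is large relative to the class signal, so the desk-scale
configurations set `dropout = 0`; at the published width (200 channels,
512-unit hidden layers) the default 0.1 is appropriate.

# Numerical and design choices

**Bin edges.** Edges are the upper quantile boundaries of the transformed
*nonzero* training values at probabilities `1/(B-1), ..., 1`; a positive
value maps to `min(B-1, 1 + #{edges < t(v)})`. This spreads nonzero mass
nearly uniformly over bins `1..B-1`, keeps the zero bin pure, is monotone,
and clamps unseen larger values into the top bin. Edges are frozen after
fitting and serialized with the model, so inference always uses
training-time edges. Binning is global by default (one edge set for all
genes); per-gene edges are available behind `perGene = TRUE` for data
whose dynamic range differs strongly between genes.

**Masked-dense evaluation of LSH attention.** The candidate sets are
built exactly as in the chunked Reformer scheme, but the restricted
softmax is evaluated as a dense score matrix plus a 0/-Inf mask when
hash rounds are unioned (the union-then-softmax reading: one softmax over
the union of per-round candidate sets). With a single hash round the
implementation switches to a genuinely block-sparse path that computes
only the per-chunk score blocks; both paths are exercised against each
other and against brute-force restricted softmax in the tests. At the
sequence lengths this package targets the two evaluations are
numerically identical.

**Self-attention.** The original Reformer forbids a position attending to
itself (under shared-QK the self-score is always maximal). Here the
default *allows* self-attention, because the package treats
"`nBuckets = 1` equals full attention exactly" as a load-bearing
invariant — it is the oracle the LSH implementation is tested against.
The exclude-self convention is available via `allowSelf = FALSE`.

**Reversible stack.** The two half-states are initialized to the same
embedding matrix and the encoder output is their mean, so a zero-layer
encoder returns exactly the input embeddings. The backward pass
recomputes activations from the outputs layer by layer (`x2 = y2 - G(y1)`,
`x1 = y1 - F(x2)`); the discrete hash/bucket decisions are cached from the
forward pass, so recomputation changes no candidate set. Training loops
use the stored-activation mode (identical numbers, fewer forward passes);
the equivalence of the two modes is asserted to 1e-4 relative error in
the acceptance suite and holds to machine precision in practice.

**Hash rotations.** Angular LSH projects onto seeded Gaussian matrices;
when the head dimension allows (`d_k >= nBuckets/2`) the columns are
orthonormalized, which makes bucket occupancy exactly uniform for
isotropic inputs and improves bucket balance generally. Rotations are a
fixed architectural constant (hash seed 1 everywhere), so training and
inference always agree on bucket assignments.

**Loss scaling.** The exported losses sum over cells and masked genes, so
the closed forms hold exactly (uniform reconstruction = masked count x
log B; uniform classification = m x log C). The optimizer minimizes the
per-masked-token (resp. per-cell) mean — the same objective up to the
learning-rate scale — so the learning rate does not depend on batch size.
Training histories record per-token means, directly comparable to log B.

**Head pooling and standardization.** Pooling conv features over
hundreds of genes produces channels that are near-constant offsets plus
a small cell-specific part, and a pure mean dilutes a sparse marker
module (10 of 300 genes) thirty-fold. Two measures keep the head
trainable in few epochs: the pooled vector concatenates mean-pooling
(module-wide signal) with max-pooling (sparse-marker detection), and a
frozen per-channel standardization (mean/SD fitted once, on up to 160
training cells, with the initial weights) is applied before the MLP.
Without these the head spends many epochs in a plateau predicting class
priors; with them, discriminative learning starts immediately. The
statistics are constants thereafter (any later drift is an affine change
the MLP absorbs).

**Activation.** ReLU in the feed-forward and head layers (the original
Transformer choice); cheap exact gradients matter in a hand-written
engine.

**Degenerate inputs.** All-zero cells yield an empty mask set with a
warning; a constant nonzero matrix puts all values in one bin; zero
vectors hash by the argmax-first convention; probabilities are clamped at
1e-12 in the losses with a warning; ties in `predict` break to the lowest
class index.

# What the synthetic generator emulates — and what it does not

`simulateCells()` draws gamma-Poisson (negative binomial) counts with a
single dispersion parameter, plants one disjoint marker module per cell
type whose mean is multiplied by `foldChange` in cells of that type,
applies independent dropout zeroing, builds a nested 4-level label tree
with downward propagation, and generates a matching embedding table in
which co-module genes share a latent direction (expected within-module
cosine `withinSim`, near-zero between modules).

The default fixture is 2,000 cells x 300 genes, 5 types with 10 markers
each, fold change 6, base mean 2, dispersion 0.5, dropout 0.3, and mildly
imbalanced type proportions (1/3 majority class). These are the study
conditions of every end-to-end experiment in the package; the ablation
grid uses a reduced 500-cell x 120-gene, 4-type instance of the same
generator so that fifteen training runs stay cheap, and the attribution
checks reuse it.

The generator does *not* emulate batch effects, doublets, ambient
contamination, library-size variation, or realistic class-proportion
tails. Passing tests therefore demonstrate that the implementation is
correct and that the architecture can learn planted co-expression
structure at desk scale — not that it reaches any particular accuracy on
real tissue atlases, which in the published setting required ~15M cells
of pre-training on multi-GPU hardware (explicitly out of scope here).

# Problem sizes used by the tests and acceptance script

Chosen once, as the package's own desk-scale experimental design: the
2,000-cell fixture with a d=32, 2-layer, 2-head, 8-bucket encoder for
pre-training (3 epochs), fine-tuning (10 epochs of batch-4 steps) and
evaluation; the 500-cell reduced fixture with a d=16 encoder for the
five-fold cross-validation harness (whose per-fold training budget then
reaches convergence within desk runtime), for the 5-seed x 3-variant
ablation grid and for the attribution checks; 10,000 simulated cells for
the masking-rate statistics; and 100-instance sweeps for the attention,
reversibility and metrics oracles.

# What desk-scale experiments do and do not show

The end-to-end checks demonstrate that the full pipeline — tokenization,
masked pre-training, fine-tuning, prediction, metrics, attribution — is
correct and that the planted cell-type signal is recovered with high
accuracy (>= 95% on the 2,000-cell fixture against a ~33% majority
baseline). One published effect does *not* reproduce at this scale: the
accuracy ordering of the ablation grid (full model over random-embedding
initialization over from-scratch training). A linear probe shows the
pre-trained pooled features are genuinely more class-separable than a
random encoder's (0.93 vs 0.82 after ten pre-training epochs on the
reduced fixture), so the representation benefit is real, but across
training regimes the run-to-run noise of short full-model fine-tuning
(about ±0.1 accuracy) dwarfs the arm differences; the published gaps
arise at a corpus and model scale that desk experiments deliberately do
not attempt. The corresponding check is retained, at the standard
reduced-fixture protocol, and its outcome should be read with this in
mind.

# Known limitations

- Single-threaded, CPU-only; at the published scale (17,330 genes,
  d=200, 6 layers) this engine would be impractically slow — the
  implementation targets correctness and desk-scale experimentation.
- H5AD input is read through a small Python bridge (matrix and obs/var
  names only) and requires `python` with `anndata` on the PATH.
- Only level-1 labels are classified; levels 2-4 are stored and
  propagated but not predicted.
- The Shapley estimator's cost is linear in genes x cells x samples;
  the defaults are sized for the bundled fixtures.
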