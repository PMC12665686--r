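# screformer

Cell-type annotation for single-cell RNA-seq with a BERT-style two-stage
model whose encoder is a **Reformer**: locality-sensitive-hashing (LSH)
attention plus reversible residual layers, so the *full* filtered gene
sequence of every cell is attended to — no highly-variable-gene selection,
no dimensionality reduction.

The package is aimed at computational biologists who want a transparent,
fully-tested reference implementation of this architecture at desk scale:
every forward and backward pass is hand-written R (verified against
finite differences), every approximation has an exact oracle next to it,
and a negative-binomial simulator with planted marker modules makes the
whole pipeline reproducible without any download.

## The model

A cell is tokenized as a fixed-order gene sequence; gene *g* contributes
an input embedding

```
x_g = E_gene[g] + E_bin[b_g] + PE[g]
```

where `b_g` is the expression bin of gene *g* (B quantile bins of the
log1p-transformed nonzero values, bin 0 reserved for zeros), `E_gene` is
optionally initialized from Gene2vec-style co-expression vectors, and
`PE` is the sinusoidal positional encoding. The encoder stacks reversible
blocks

```
y1 = x1 + Attn(LN(x2));   y2 = x2 + FFN(LN(y1))
```

whose attention is the Reformer's shared-QK LSH attention: scaled
dot-product `softmax(q_i k_j / sqrt(d_k)) v_j` restricted to the
candidate set `P_i` of positions hashed near query *i* (angular LSH,
sort-by-bucket chunking, each chunk also attending to its predecessor).
With a single bucket this is *exactly* full attention — the identity the
test suite leans on.

Training is two-stage:

1. **Self-supervised pre-training** — mask 15% of each cell's expressed
   genes (90% of selections shown as a MASK token), reconstruct the
   original bins; cross-entropy `L = -Σ_i Σ_j log p_ij[y_ij]`.
2. **Supervised fine-tuning** — per-gene 1-D convolution, pooling over
   genes, three-layer perceptron to first-tier class probabilities;
   cross-entropy `L = -Σ_i log q_i[z_i]`; AdamW with linear schedule and
   10% warm-up; early stopping on validation accuracy.

Evaluation: confusion matrix, accuracy, macro F1, per-class one-vs-rest
AUC (exact rank statistic). Interpretation: sampling-based Shapley
attributions of a class logit to genes, ranked by mean |attribution|.

## Worked example

```r
library(screformer)

# simulated 10x-style data: 800 cells x 150 genes, 4 planted cell types
sim <- simulateCells(nCells = 800, nGenes = 150, nTypes = 4,
                     markersPerType = 10, dEmbed = 16, seed = 1)
sce    <- filterGenes(sim$sce, sim$embeddings)   # vocabulary filter
scheme <- fitBins(sce, nBins = 7)                # quantile binning
tokens <- tokenizeCells(sce, scheme)

split <- splitCells(sim$labels, c(0.6, 0.2, 0.2), seed = 1)
tr <- splitIds(split, "train"); va <- splitIds(split, "val")
te <- splitIds(split, "test")

cfg <- reformerConfig(seqLen = length(geneIds(tokens)), nBins = 7,
                      dModel = 16, nLayers = 2, nHeads = 2, nBuckets = 4,
                      nHashRounds = 1, dropout = 0, dFf = 32,
                      convChannels = 16, hiddenSizes = c(32, 32))

pre <- pretrainReformer(tokens, cfg, embeddings = sim$embeddings,
                        epochs = 2, batchSize = 32, lr = 1e-3, seed = 1)
fit <- finetuneReformer(pre, subsetCells(tokens, tr), sim$labels[tr, "level1"],
                        subsetCells(tokens, va), sim$labels[va, "level1"],
                        epochs = 12, batchSize = 4, lr = 3e-3,
                        patience = 12, seed = 1)

pred <- predictCells(fit, subsetCells(tokens, te))
evaluateClassifier(sim$labels[te, "level1"], as.character(pred$labels),
                   scores = pred$probs)
```

```
MetricsReport: 4 classes, 160 cells
  accuracy : 95.0%
  macro F1 : 93.0%
  one-vs-rest AUC:
    type1                0.997
    type2                0.999
    type3                0.996
    type4                0.988
```

The held-out reconstruction loss printed by `trainingHistory(pre)`
(1.71 nats after two epochs) sits below the uniform-predictor
baseline `log(7) = 1.95`, showing the masked-expression objective is
learning co-expression structure; the report above shows the fine-tuned
classifier recovering the planted types against a ~33% majority-class
baseline. `explainReformer()` + `topGenes()` then rank the planted
markers at the top of the attribution list for their type.

A command-line entry point wraps the same functions
(`inst/scripts/screformer`): `synth`, `preprocess`, `pretrain`,
`finetune`, `predict`, `evaluate`, `cv`, `explain`, and `run-all`.

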