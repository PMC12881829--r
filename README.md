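# scPathAlign

Zero-shot cell-type annotation for single-cell RNA-seq by aligning a
**pathway-token transformer** over expression profiles with an encoder of
free-text **cell-type names** in a shared embedding space.

## Who this is for

Computational biologists who want to annotate scRNA-seq data against an
open vocabulary of type names — including types absent from the training
labels — and methodologists who want a compact, fully inspectable R
implementation of contrastive text–expression alignment: every component
(transformer encoder, backpropagation, contrastive objective, OOD
detection, metrics, synthetic benchmark) is plain, tested R code.

## The method

1. **Tokenize genes by pathway.** Each pathway (GMT file) intersected
   with the assay's gene vocabulary becomes one "super token"; genes in
   no pathway are shuffled (seeded) into random sets of fixed size
   (110 by default). A gene may sit in several pathway tokens.
2. **Embed tokens by expression weighting.** With learnable gene
   embeddings G<sub>j</sub> ∈ R<sup>D</sup> and log-normalized expression
   x, the token for gene set S is

   Z<sub>S</sub> = (1/|S|) Σ<sub>j∈S</sub> x<sub>j</sub> G<sub>j</sub>,

   zero-expression genes included in the denominator.
3. **Encode without positions.** A learnable CLS token is prepended and
   a transformer encoder (768 dim / 12 layers / 12 heads / 3072
   intermediate at reference scale; no positional encoding — gene-set
   order is meaningless) produces the cell embedding at the CLS
   position.
4. **Align contrastively with names.** Names are encoded (built-in
   trainable word-embedding encoder, or any external language model via
   an adapter callable), both sides are projected into a shared space
   (512 dim at reference scale), and each batch of K cells with distinct
   names is trained with the symmetric softmax cross-entropy over the
   K×K cosine-similarity matrix (diagonal = matching pairs).
5. **Predict zero-shot; flag unseen types by entropy.** Any candidate
   name list is embedded once; cells take the argmax-cosine candidate.
   The Shannon entropy of the seen-candidate-restricted probabilities is
   thresholded at its test-set median (second quartile): cells above it
   are called unseen and reassigned to the best unseen candidate.

Evaluation (micro / weighted-macro F1, seen / unseen / mixed harmonic-mean
F1, per-type accuracy, 100-bin entropy curves) and prediction-augmented
clustering (K-Means, Leiden, Hungarian-matched clustering accuracy) are
included, as is a seeded synthetic generator producing
negative-binomial counts with dropout and library-size noise,
pathway-structured type signatures, and compositional cell names so that
zero-shot transfer is exercisable without any external data.

## Worked example

The complete study protocol on the default synthetic benchmark
(600 genes, 20 pathways, 10 types of which 2 are held out, 150 cells per
type, desk-scale encoder):

```r
library(scPathAlign)

res <- runZeroShotExperiment(seed = 1)
str(res$metrics)
#> List of 10
#>  $ seen_micro_f1      : num 0.867
#>  $ seen_macro_f1      : num 0.883
#>  $ unseen_micro_f1    : num 0.687
#>  $ unseen_macro_f1    : num 0.806
#>  $ mixed_micro_f1     : num 0.766
#>  $ mixed_macro_f1     : num 0.843
#>  $ mean_entropy_seen  : num 0.167
#>  $ mean_entropy_unseen: num 0.612
#>  $ flagged_fraction   : num 0.5
#>  $ chance_level       : num 0.1
```

Reading: cells of types seen in training are recovered at 0.87 micro-F1;
cells of the two *never-trained* types are labeled correctly 69% of the
time against a 10% chance level, purely because their names recombine
word tokens whose pathway signatures the model learned. Unseen cells
carry ~0.45 nats more seen-type entropy than seen cells, which is what
the median-entropy rule exploits (it flags exactly half the test set,
`flagged_fraction = 0.5`). Step by step the same run is:

```r
sp  <- syntheticSpec(seed = 1)
d   <- generateDataset(sp)                      # counts + GMT + split
pp  <- preprocessCells(d$matrix)                # filter, scale to 1e4, log1p
gr  <- buildGrouping(geneIds(pp), d$pathways, orphanSetSize = 110)
mod <- trainAlignment(pp[d$split$train, ], gr, tinyRunConfig(),
                      steps = 3000, validation = pp[d$split$val, ],
                      restarts = 2)
prd <- annotateCells(mod, pp[d$split$test, ],
                     candidates = vapply(sp@cellTypes, `[[`, "", "name"),
                     seenSet = d$split$seen)
evaluateAnnotation(prd, cellNames(pp[d$split$test, ]))
```

A thin command-line front end over the same functions ships at
`inst/cli/scpathalign.R` (`synth`, `preprocess`, `train`, `predict`,
`evaluate`, `cluster` subcommands).

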