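# mircnn

Prediction of miRNA target sites and target transcripts by a 1-D
convolutional neural network trained on raw chimeric interaction
sequence.

## The problem

Ligation-based interactome assays (CLASH and chimeric-read CLIP) capture
direct miRNA:target contacts as single *chimeric reads*: a ~21-nt miRNA
joined to the mRNA fragment it was bound to. `mircnn` implements a
classifier that learns miRNA targeting rules directly from such chimeras
— no hand-crafted seed/conservation/context features. Each chimera
(miRNA + target site, padded to exactly 110 nt with
anti-complementary random sequence) is one-hot encoded as a 110 × 4
matrix (A, U, G, C) and classified by a convolutional network:

    Conv1D(16, k2) → MaxPool(2) → Conv1D(32, k3) → MaxPool(2)
    → Conv1D(64, k4) → MaxPool(2) → Conv1D(128, k5) → MaxPool(2)
    → Flatten → Dropout(0.5) → Dense(128, ReLU, L2) → Dropout(0.3)
    → Dense(1, sigmoid)

166,001 trainable parameters; binary cross entropy, Adam, early stopping
on validation loss. The network, its backpropagation and the Adam
optimizer are implemented in vectorized base R (BLAS matrix products).

Full transcripts are scanned with windows of length 110 − |miRNA|;
windows are first filtered on the minimum free energy of the miRNA:site
duplex (internal nearest-neighbor dynamic program, threshold
−20 kcal/mol), survivors are scored by the CNN, and the transcript-level
call is the maximum site score compared against 0.5:

    call(transcript) = max over surviving sites s of P(interaction | s) > 0.5

Evaluation follows the field's five statistics — sensitivity,
specificity, F1, Matthews correlation coefficient, accuracy — plus
ROC/AUC and 10-fold cross-validation. A seeded synthetic-data generator
plants seed-complementary (nt 2–8) and 3'-supplementary motifs in random
target sites so the whole pipeline is testable without any downloads.

## Worked example

```r
library(mircnn)

# 1. synthetic interaction dataset: 5,000 chimeras, 110 nt each
ds <- gen_dataset(synth_config())  # seeded; defaults in the methods vignette
parts <- split_dataset(ds$table, c(4000, 500, 0), seed = 1)

# 2. train the CNN
model <- train_cnn(build_architecture(),
                   encode_batch(parts$train),
                   encode_batch(parts$validation),
                   training_config(max_epochs = 80,
                                   early_stop_patience = 10, seed = 1))

# 3. evaluate on the held-out chimeras
scores <- predict(model, encode_batch(ds$heldout))
metrics_from_counts(confusion(ds$heldout$label, scores))
#> Sen. 94.19%  Spe. 99.17%  F1 96.62%  MCC 93.33%  Acc. 96.60%
roc_auc(ds$heldout$label, scores)$auc
#> [1] 0.9917516

# 4. scan a transcript for a planted complementary site
mirna <- ds$mirnas[1, ]
set.seed(1)
rr <- function(n) paste(sample(c("A","C","G","U"), n, TRUE), collapse = "")
tx <- list(id = "tx", seq = paste0(rr(300), revcomp_rna(mirna$seq),
                                   rr(279)))
scan_transcript(model, mirna, tx, step = 5, seed = 1)
#> mir-001 vs tx: 104 candidates, 16 past the energy filter, max score 1.000 -> TARGET
```

The metrics line reads: of the 500 held-out chimeras, 94.2% of genuine
interactions and 99.2% of pseudo-negatives are recognized, for an overall
accuracy of 96.6% and an AUC of 0.992. In the scan, only the windows
overlapping the planted perfectly complementary locus survive the
−20 kcal/mol duplex filter, and the maximum CNN score over them exceeds
0.5, so the transcript is called a target.

A command-line interface wraps the same functions:

```sh
exec/mircnn simulate --out sim --seed 1
exec/mircnn train --train sim/train.tsv --validation sim/val.tsv --model m
exec/mircnn evaluate --model m --data sim/heldout.tsv --out eval
exec/mircnn scan --mirnas mir.fasta --transcripts tx.fasta --model m \
    --mfe-threshold -20 --step 5 --out scan.tsv
```

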