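# amyloidhex

Sequence-based classification of amyloid-fibril-forming hexapeptides on
**balanced** datasets.

Short hexapeptide "hot spots" can trigger aggregation of a whole protein
into amyloid fibrils, the deposits behind amyloidoses such as Alzheimer's
and type II diabetes. Experimental screens (electron microscopy, FTIR,
Thioflavin-T) are slow and expensive, so sequence-based predictors matter —
but most published predictors train on datasets dominated by non-amyloid
examples, which biases what they learn. This package implements a complete,
reproducible pipeline for studying amyloidogenicity prediction under class
balance: peptide dataset handling, a 4125-dimensional descriptor engine,
two from-scratch classifiers, and the evaluation and robustness protocols,
for bioinformaticians who want every stage scriptable and auditable in R.

## What is inside

**Descriptor engine.** Each hexapeptide is encoded into a named vector of
4125 descriptors from fifteen families:

| family | dim | family | dim | family | dim |
|---|---|---|---|---|---|
| AAINDEX | 3186 | GDPC | 25 | QSOrder | 50 |
| ZSCALE | 30 | CTDC | 39 | SOCNumber | 10 |
| EGAAC | 10 | CTDD | 195 | NMBroto | 40 |
| DDE | 400 | PAAC | 25 | Moran | 40 |
| GAAC | 5 | APAAC | 30 | Geary | 40 |

AAINDEX uses the 531 complete AAindex indices (via `seqinr`) positionally;
PAAC/APAAC are Chou's pseudo amino-acid compositions with λ = 5 correlation
terms; QSOrder/SOCNumber build on inter-residue distance matrices (Grantham,
plus a synthetic physicochemical distance documented in the vignette); the
autocorrelations (Moreau–Broto, Moran, Geary) use eight standardised
physicochemical properties at lags 1–5.

**Classifiers**, both authored here:

- *Kernel naive Bayes* — per class *c* and feature *j*, a Gaussian-kernel
  density estimate on the whole real line with Silverman bandwidths; the
  posterior is `P(c | x) ∝ π_c ∏_j f̂_cj(x_j)`, accumulated in the log
  domain.
- *GentleBoost* — an ensemble of weighted least-squares regression trees
  fitted to the ±1 response: `F(x) = Σ_t ν f_t(x)` with weight update
  `w ← w exp(−y ν f_t(x))`, including the published configuration
  (max 26 splits, 67 learners, ν = 0.5915).

**Protocols.** Class balancing by random downsampling, balanced train/test
splits (350 + 350 train, 33 + 33 test), stratified k-fold cross-validation
(k ∈ {5, 10, 15}), and a robustness protocol that redraws 100 distinct
train/test pairs, recomputes all descriptors, retrains and averages
ACC/SN/SP across pairs.

**Metric suite.** ACC, SN, SP, balanced accuracy Q = (SN+SP)/2, MCC, error
rate, and ROC/AUC by threshold sweep, all from first principles with
documented zero-denominator conventions.

A synthetic-data module generates rule-labelled hexapeptide corpora
(including one with the real corpus shape, 516 amyloid / 900 non-amyloid)
so the entire pipeline is testable with no external downloads.

## Worked example

```r
library(amyloidhex)

train <- gen_labelled_fixture(fixture_spec(n_per_class = 100, seed = 1))
test  <- gen_labelled_fixture(fixture_spec(n_per_class = 33, seed = 2))
fm_train <- extract_all(train)
fm_test  <- extract_all(test)
fm_train
#> feature_matrix: 200 records x 4125 descriptors (labelled)

model <- fit_kernel_nb(fm_train)
model
#> kernel naive Bayes: 4125 features; priors non-amyloid=0.500 amyloid=0.500; n=(100, 100)

pred <- predict_kernel_nb(model, fm_test)
report <- metrics(confusion(fm_test$labels, pred$labels),
                  auc = roc_auc(pred$score, fm_test$labels)$auc)
report$counts
#> confusion counts (rows = truth, cols = predicted):
#>             pred non-amyloid pred amyloid
#> non-amyloid               26            7
#> amyloid                    1           32
report
#> ACC 0.8788  SN 0.9697  SP 0.7879  Q 0.8788  MCC 0.7704  error 0.1212  AUC 0.8774
```

The confusion counts are read positive-class-first: of 33 true amyloid
hexapeptides 32 were recovered (SN 0.97), while 7 of 33 non-amyloids were
flagged (SP 0.79) — the FP-leaning profile typical of this classifier
family. MCC summarises both errors on a chance-corrected [−1, 1] scale.

The same pipeline is scriptable from a shell via the installed
`amyloidhex` executable (`extract`, `train`, `predict`, `evaluate`,
`robustness`, `fixture` subcommands); every command writes an
effective-config snapshot next to its outputs so runs can be reproduced
exactly.

## Scope

The package does not download or parse AmyLoad, WALTZ-DB, Pep424 or AmyPro;
real corpora are supplied as FASTA or `id,sequence,label` tables. Bayesian
hyperparameter search, PCA preprocessing and non-hexapeptide mixed-length
handling are out of scope. See the methods vignette
(`vignettes/amyloid-hexapeptide-classification.Rmd`) for the model details,
design decisions and known limitations.
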