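---
title: "Cross-modality learning for Cell Painting and transcriptomics profiles"
author: "morphoTx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modality learning for Cell Painting and transcriptomics profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(morphoTx)
```

## Scope and data model

`morphoTx` addresses a routine asymmetry in phenotypic drug discovery:
every screened compound gets cheap Cell Painting (CP) morphology —
several replicate profiles of ~800 Z-scored image features — while only
a subset gets the more informative but expensive transcriptomic (TX)
profile (one robust-Z-scored expression vector per compound, computed
against the DMSO vehicle). The package learns, from compounds that have
both, an embedding function that consumes **CP alone**, so that future
CP-only compounds benefit from what the transcriptome taught the
encoder.

Profiles live in a `ProfileMatrix`, a `SummarizedExperiment` whose
single assay stores features × profiles with the compound of every
column in `colData`; validity enforces finiteness, unique profile
identifiers and the one-TX-profile-per-compound rule. Pretraining
consumes a `PairSet`: one (CP replicate, TX) pair per replicate of
every compound present in both modalities. Compounds missing a modality
are dropped (the alternative — imputing the missing modality — would
leak the very signal the benchmark measures).

## Evaluation protocol

All feature learning sees only the `train` and `valid` compounds of a
scaffold-grouped 70/10/20 split; every number reported downstream comes
from the `test` compounds. The split unit is the compound (all
replicates and pairs move together) and the grouping key is the Bemis–
Murcko scaffold, so structural analogues of training compounds cannot
leak into evaluation. The split algorithm is greedy: scaffold groups
sorted by size (ties shuffled by the seed) are assigned to whichever
set has the largest remaining deficit against its target count. This is
deterministic, handles heavy-tailed scaffold-size distributions, and on
1,000 geometric-sized groups stays within 2% of the targets (asserted
in the test suite). All acyclic molecules share one sentinel scaffold
key and therefore move as a single group. Scaffold keys may be supplied
directly (the synthetic screen does), so the RDKit dependency of
`murckoKey()` is optional.

## The two pretraining objectives

**Contrastive learning.** Two MLP encoders (CP: hidden
`[1024, 1024, 1024]`; TX: `[4096, 4096, 4096]`; both output 512) feed
linear projections to a 256-dimensional space where the symmetric
InfoNCE loss is computed on cosine similarities divided by a
temperature τ. Both directional cross-entropy terms are *summed*, not
averaged — the package keeps the objective exactly as its printed form,
so a batch with all-equal similarities scores exactly `2·ln N`. The
temperature is a fixed configurable scalar; no published value exists
for this setting, so the package defaults to 0.07, the value popularised
by the CLIP family, and logs it in the config object. Both modalities
are augmented each batch by zeroing a uniformly random
`floor(0.10 · d)` of the input features per profile — masking to 0 is
semantically "control-like" for Z-scored data. Masks are redrawn every
batch; inference never masks. After training, the projection heads are
discarded: embeddings are the 512-dimensional (128 in the reduced test
profile) CP encoder outputs.

**Bimodal autoencoder.** One CP encoder (hidden `[1024, 512, 512]`,
embedding 512) and two decoders (`[512, 512, 1024]` to CP,
`[1024, 2048, 4096]` to TX) reconstruct *both* modalities from the
masked CP input; the targets are the unmasked originals (standard
masked-autoencoder practice; the alternative of reconstructing the
masked input would make the mask trivially invertible). The loss gives
each modality the same ½ weight. The printed objective sums squared
residuals over the batch; the text around it asks for an *average* mean
squared error. The package averages over rows *and* features per
modality so the two halves are comparable when the CP and TX dimensions
differ by a factor of five, and keeps the raw printed sum available via
`reduce = "sum"`. TX is never an input, so embedding generation needs
CP only, and re-initialising the decoders provably leaves embeddings
unchanged (a dataflow contract asserted in the tests).

**Optimisation, both models.** Neither optimiser nor schedule is
specified for pretraining, so the package uses Adam at a fixed default
learning rate of 1e-4 with early selection of the weights that minimise
the validation loss (computed on unmasked inputs for stability). Hidden
activations are ReLU with linear output layers, He-normal
initialisation, no normalisation layers. The whole network engine —
forward, backward, Adam, dropout, cosine-annealing warm restarts — is
hand-written on base-R matrix operations (BLAS underneath) because no
deep-learning framework exists in a plain R stack; every gradient path
is verified against central finite differences in the test suite, and
the InfoNCE implementation against a scalar triple-loop transcription
of the objective.

## Cluster-quality evaluation

`knnAccuracy()` scores a feature type as the fraction of points whose
majority label among the k = 5 nearest neighbours (Euclidean by
default, cosine available) matches their own label. Two conventions
exist: fitting the classifier on the queried points themselves
(`excludeSelf = FALSE`, the behaviour of a default kNN classifier fit
and evaluated on the same set, and the package default) or
leave-one-out voting (`excludeSelf = TRUE`). The package implements
both because the source protocol is ambiguous — and the choice matters:
with the package's deterministic tie-break (ties go to the tied class
with the nearest member) the self-inclusive mode lets every point's own
vote win singleton ties, so in the high-noise regime the replicate
score saturates towards 1 rather than falling towards chance. The
end-to-end benchmark therefore reports leave-one-out accuracies.
Replicate clustering labels test-split CP replicates by compound; MoA
clustering first median-aggregates replicate-level features per
compound (the labels are per compound) and keeps the 9 most-populated
annotated classes in the test split. `embed2D()` is an exact
O(n²) t-SNE (perplexity 10 for replicate panels, 20 for MoA panels,
random initialisation, 'auto' learning rate) — adequate for the few
hundred points these panels show; no tree approximation is attempted.

## Bioactivity evaluation

A single MLP (hidden 256 × 3 layers, dropout 0.3, one sigmoid output
per task) is trained on train+valid compounds for all tasks passing the
25/25/100 filter (≥25 positives, ≥25 negatives, ≥100 observed labels —
"observed labels", not compounds, is the reading adopted for the
datapoint floor). The loss is binary cross-entropy averaged over
observed labels only; missing entries contribute nothing, which is the
standard treatment for sparse binarised assay panels. Optimisation is
Adam (lr 1e-4, weight decay 1e-5, batch 128) under cosine-annealing
warm restarts that reset every 10 epochs, for exactly 100 epochs with
final-epoch weights — the protocol fixes the epoch count, so there is
no early stopping to tune. Inputs are standardised per feature on the
training compounds (the identical transform is applied at prediction
time): raw profiles are already Z-scores, but learned embeddings arrive
on arbitrary scales, and feeding them unstandardised saturates the
sigmoid head. One model is trained per feature type with a
bit-identical configuration object — the pipeline driver asserts this —
so the feature type is the only variable.

Scoring is per task on test compounds passing the 25/25 test filter:
rank-based AUROC with ties averaged, step-wise average precision for
AUPRC (trapezoidal interpolation is optimistic for PR curves), the
positive prevalence of the scored labels as the RIPtoP baseline, and
`RIPtoP = (AUPRC − BASELINE)/(1 − BASELINE)` mapping the random
baseline to 0 and perfection to 1. The "TX-strong/CP-weak" subset takes
tasks with TX AUROC strictly above 0.7 and CP AUROC strictly below 0.7
on identical task sets. Feature types are compared by one-sided paired
Wilcoxon signed-rank tests (zero differences dropped; exact
distribution below 25 pairs when no ties prevent it, otherwise the
normal approximation with continuity correction), with raw p-values at
the 0.05 level as in the source protocol; a Benjamini–Hochberg
correction is available to the caller via `stats::p.adjust` on the
returned p-values. Per-family summaries group tasks by protein target
family with unannotated tasks kept as an explicit remainder.

## The synthetic screen

The generator is deliberately the *simplest* world in which
cross-modality pretraining can provably help: linear-Gaussian.
Each compound carries a latent vector: shared dimensions (default 10)
drawn as MoA-class centroid plus within-class noise, and TX-only
dimensions (default 5) drawn independently. The TX profile is a fixed
random linear image of the *full* latent plus noise; every CP replicate
is a linear image of the *shared* dimensions only, plus independent
replicate noise — the generator's encoding of "some biology is visible
to TX but not CP". Scaffold groups (geometric sizes, mean 3) are
assigned independently of MoA so the split stays a pure generalisation
control. Bioactivity tasks threshold noisy linear scores of the latent
at the per-task median (positive rate ≈ 0.5); a configurable share of
tasks reads only TX-only dimensions. The default `taskMixing =
"shared"` keeps the remaining tasks on the shared block (so "no TX-only
dependence when the TX-only fraction is zero" holds exactly); the
`"full"` mode lets general tasks read the whole latent in standardised
coordinates, producing a continuum of tasks whose CP visibility varies
with the weight draw — the regime the benchmark needs, since an
all-or-nothing world contains no task that is both learnable from CP
and CP-weak. Replicate counts are drawn uniformly from a configured
range, and labels are observed with a configured density; neither
distribution is reported for the real data, so both are plain
placeholders. Everything is reproducible byte-for-byte from the
configuration: the three sampling stages use fixed offsets of the
configured seed, so running the samplers individually or composed gives
identical output.

What a green test does and does not establish: the generator has iid
feature noise, no plate or batch structure, no dose–response, and
linear modality maps. Passing the end-to-end criteria shows the
*machinery* — objectives, gradients, splits, filters, metrics — behaves
correctly and that the qualitative orderings the method claims are
recovered in a world where they must hold; it says nothing about effect
sizes on real screens.

## The benchmark world

`benchmarkConfig()` fixes the stated world of the end-to-end check:
2000 compounds, 12 MoA classes, 800 CP features, 4000 genes, 8 shared
and 6 TX-only latent dimensions, exactly 3 CP replicates per compound,
CP noise SD 5 against TX noise SD 0.3, MoA centroid/within-class SDs
1.5/1, 60 tasks (10% TX-only, `"full"` mixing), full label density.
The noise and centroid scales were calibrated so the *raw-CP baselines*
land in the regime the method was designed for (raw MoA kNN accuracy
≈ 0.78, raw replicate accuracy well below 0.5, a TX–CP gap large
enough that learning from TX can matter): with narrow centroids or low
replicate noise both modalities sit at the kNN ceiling and no embedding
can beat raw morphology — the aggregation of 800 features over 3
replicates is remarkably robust to iid noise. Network widths are
reduced (encoders 128 wide, embedding 128, projection 64, multitask
hidden 128) and the learning rate raised to 1e-3 so 30 contrastive and
40 classifier epochs converge in minutes on one CPU; architecture
shape, masking, temperature and the whole evaluation protocol are the
package defaults. The label-permuted control permutes compound rows of
the label matrix before training, which must and does leave test AUROC
at chance.

## Numerical choices and edge cases

* InfoNCE is computed with row/column log-sum-exp stabilisation;
  zero-norm projected rows raise an error rather than silently
  producing NaNs.
* `maskFeatures()` zeroes exactly `floor(rate·d)` positions per row,
  sampled independently per row.
* kNN ties (equal distances) are resolved by row index; majority-vote
  ties by the nearest member of the tied classes — both deterministic.
* Tasks with a single observed class in the test set are skipped with a
  warning at scoring time; empty filter results warn rather than error.
* A single scaffold covering all compounds degenerates to an all-train
  assignment with a warning.
* `aggregateReplicates()` uses closed-form medians for group sizes ≤ 4
  and a sorting fallback above; aggregation is idempotent.
* Replicate-level embeddings are produced per CP replicate row;
  compound-level features for MoA clustering and bioactivity modelling
  are median aggregates, consistent with per-compound labels.

## Known limitations

The simulator's linearity means a linear method could in principle
match the MLPs here; the MLPs are kept because the real pipeline is
nonlinear and the package's job is to implement it faithfully. The
exact t-SNE is quadratic in points and intended for visualisation-sized
inputs only. Parquet I/O is not provided (no Arrow bindings in the
supported stack) — CSV/TSV cover the interchange formats. Full-scale
pretraining of the published architecture (week-long runs, ~100k
compounds) is out of scope; the defaults reproduce the architecture,
not the compute.
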