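---
title: "Generative design of dual-target compounds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative design of dual-target compounds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Polypharmacology — one small molecule inhibiting two protein targets at
once — is attractive wherever a pair of targets is jointly essential (for
example synthetic-lethal pairs in cancer) but combination dosing of two
single-target drugs is impractical. `polygen` implements a generative
pipeline for proposing such compounds: a variational autoencoder (VAE)
over SMILES strings provides a continuous chemical embedding; per-target
regressors predict potency from structure; and a reinforcement loop
iteratively refocuses the embedding on regions scoring well against both
targets simultaneously, while keeping candidates synthesizable and
drug-like. This vignette documents the models, their assumptions, the
tunable parameters, and the design choices made where the design was
genuinely open.

## The chemical embedding

### Corpus curation

Training corpora follow the standard preparation rules for
ChEMBL-derived sets: salts are stripped by keeping the fragment with the
most heavy atoms (ties broken by lexicographically smallest canonical
SMILES, so curation is deterministic), +1/−1 formal charges are
neutralized, SMILES longer than 100 characters are removed, and molecules
containing elements outside {H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I}
are rejected. Each rejection carries one of three reasons (`unparseable`,
`too_long`, `disallowed_atom`); molecules whose residual charge cannot be
neutralized are filed under `disallowed_atom` with the detail recorded.

Parsing and canonicalization are delegated to OpenBabel. Because
OpenBabel accepts some strings a chemist would reject (it does not
enforce valence and silently repairs unbalanced parentheses), curation
adds its own syntactic balance check and a valence check on the parsed
graph (C ≤ 4, N ≤ 3, O ≤ 2, S ∈ {2,4,6}, and so on). The same validity
rule is applied to molecules decoded from the latent space, where
malformed output is a routine event that must be counted, not an error.

### Tokenization

SMILES are tokenized at character level, except that two-character
element symbols (Cl, Br, Si, Se) are single tokens — splitting them would
let the decoder emit fragments that are never individually valid. Each
sequence is framed as `<s> … </s>` and padded with `<pad>` to a fixed
length (default 100, so content length ≤ 98). The vocabulary is built
from the corpus deterministically: specials first, then sorted distinct
tokens. Tokenize/detokenize is an exact round trip on every curated
molecule, a property the test suite asserts corpus-wide.

### The variational autoencoder

The encoder embeds tokens (128-dim by default), runs a GRU (1 layer, 256
units, dropout 0.2 between layers when stacked) over the non-pad
positions, and maps the final hidden state through two linear heads to a
posterior mean $\mu_z$ and log-variance $\sigma_z$ over a 128-dimensional
latent space. Sampling uses the reparameterization
$z = \mu_z + \varepsilon\, e^{\sigma_z/2}$ with
$\varepsilon \sim N(0, I)$. We read the quantity exponentiated as
$e^{\sigma_z/2}$ as the log-variance — the only reading under which that
expression is a standard deviation — and the KL term uses the matching
closed form
$-\tfrac12\sum(1 + \sigma_z - \mu_z^2 - e^{\sigma_z})$, averaged over the
batch. The test suite checks this closed form against a Monte-Carlo
estimate at $10^6$ draws.

The decoder maps $z$ through a linear layer to the initial hidden state
of a GRU stack (3 layers, 512 units by default); at every step the input
is the previous token's embedding concatenated with $z$, and a linear
layer plus softmax over the vocabulary emits the next-token
distribution. Training uses teacher forcing; generation is free-running
from the start token (which plays the role of the dummy input used when
no source molecule exists), stopping at the end token, with either
argmax or multinomial token choice.

Training minimizes masked token cross-entropy plus the KL term, with
Adam (learning rate 3e-4, batch 1024, 200 epochs at full scale),
global-norm gradient clipping at 50, and a single run seed governing
initialization, noise draws and batch order. The reconstruction loss
masks pad positions beyond the end token — without masking, ~97% of the
signal on a 100-length frame would be padding. The KL weight is
configurable (default 1.0) with an optional linear warm-up; warm-up is
the standard remedy for early posterior collapse in sequence VAEs.

The whole network — embedding, GRU stacks, heads, backpropagation
through time, Adam, clipping — is implemented in base R matrix code.
Gradients of every parameter group are verified against central finite
differences in the test suite, which is the load-bearing correctness
argument for the implementation.

### Desk-scale configuration

Tests and the acceptance script run a reduced architecture chosen to fit
single-CPU budgets while preserving every mechanism: 32-dim embeddings,
64-unit encoder, 16-dim latent, 96-unit single-layer decoder, frame
length 30; 500 epochs at learning rate 5e-3, batch 50, KL weight 0.02
with 200-epoch warm-up. On the 50-molecule two-family fixture corpus this
memorizes the corpus (100% exact reconstruction from posterior means in
our runs, with ≥ 90% the asserted floor), decodes roughly 55–70% of
prior samples to valid molecules depending on the seed, and separates
the two families in latent space (one-sided t-test of intra- versus
inter-family distances, p ≪ 0.01). Free-running generation is capped at
the re-encodable content length (`max_len` minus the two frame tokens),
so every decoded molecule can pass back through the tokenizer during
fine-tuning. The KL weight matters here: at desk scale a full-weight KL
term overwhelms reconstruction on 50 molecules, while dropping it
entirely would detach the aggregate posterior from the prior and ruin
prior-sample validity; 0.02 with warm-up balances the two. These numbers
are properties of the synthetic fixture regime — memorization of a small
family-structured corpus — and demonstrate mechanism, not generalization
to ChEMBL-scale chemistry.

## Target scoring

Potency is modelled as ligand efficiency,
$y = 1.4\,(-\log_{10} \mathrm{IC}_{50}/N)$ with $N$ heavy atoms — potency
normalized by molecular size, so the regressor is not rewarded for
simply proposing bigger molecules. The inverse map
$\mathrm{pIC}_{50} = yN/1.4$ recovers absolute potency for
threshold-based classification; the two maps are exact inverses and are
tested as such.

Each target gets a random-forest regressor (1000 trees) over 2048-bit
circular Morgan fingerprints (radius 2; OpenBabel ECFP4 folded to 2048
bits). Split hyperparameters default to the behaviour of the reference
random-forest regressor this module mirrors — all features considered at
every split, leaves grown pure — rather than the `sqrt(p)` default some
forest libraries use: with 10 informative bits among 2048, per-split
feature subsampling rarely sees the signal and caps noise-free
cross-validated R² near 0.9, whereas all-feature splits reach ~1.0.
Both knobs (`mtry`, `min_node_size`) are exposed and recorded in the
scorer's provenance, together with the training-set hash. Performance is
measured by five-fold cross-validation with seeded fold assignment (plain
random folds; a scaffold split is available for honest generalization
estimates but is not the default, matching the plain five-fold
convention). Kd tables are supported identically via `affinity_kind`,
the configuration used when retraining the scorer on binding constants.

The synthetic-data generator plants a known structure–activity
relationship: $y$ is a linear map of designated fingerprint bits plus
Gaussian noise, and affinities are back-computed so the
ligand-efficiency identity holds exactly for every record. At the
default near-interpolation regime (500 records drawn with replacement
from a 40-molecule pool) the noise-free five-fold R² is ≈ 1 and degrades
monotonically with noise — the parameter-recovery ladder the acceptance
tests assert at σ ∈ {0, 0.05, 0.2}.

## The reward engine

Six rewards are computed per candidate: predicted ligand efficiency for
each target ($r_1, r_2$; maximized), mean Euclidean distance from the
candidate's posterior mean to the 20 closest known ligands of each
target ($r_3, r_4$; minimized), synthetic accessibility ($r_5$;
minimized) and drug-likeness ($r_6$; maximized). "Distance to the set of
closest 20" is read as the mean over the 20 smallest distances — a set
statistic is less noisy than a single nearest neighbour — with min-of-20
available by option; both reduce to brute-force-checkable forms the
tests verify against full sorts.

Each raw reward is normalized by half-Gaussian scaling:
$r' = \exp(-\tfrac12((r-\mu_i)/\sigma_i)^2)$ on the unsatisfied side of
the threshold mean $\mu_i$, and 1 on the satisfied side. The aggregate
$R$ is the arithmetic mean of the six normalized rewards, so $R \in
[0,1]$, is permutation-invariant, and is monotone in every component.
The per-reward thresholds $(\mu_i, \sigma_i)$ are run configuration; the
package ships documented placeholders (ligand efficiency 0.4/0.1,
distance 3/1, SA 4/1, QED 0.7/0.1) that any serious run should replace
with values set from its own ligand data, and the synthetic scenario
sets its own thresholds at its own scale (ligand efficiency μ = 0.6,
between its baseline ≈ 0.45 and active ≈ 0.75 levels).

Candidates that cannot be scored (invalid SMILES, featurization failure)
are dropped and counted, not scored zero — scoring them zero would let
garbage dilute the selection pool's statistics.

### Synthetic accessibility and drug-likeness

No installed R package provides the fragment-contribution SA score or
QED, so both rewards are the package's own calibrations of the familiar
constructions. The SA score keeps the complexity-penalty structure
(size penalty $n^{1.005}-n$, ring-bond density, branching, heteroatom
load) squashed onto the conventional 1 (easy) to 10 (hard) scale, but
omits the fragment-popularity term, which requires a precomputed
database of fragment frequencies in a large compound collection. The
drug-likeness score keeps the QED functional form — a geometric mean of
desirability functions over MW, logP, TPSA, H-bond acceptors and
donors, rotatable bonds and aromatic ring count (descriptors from
OpenBabel) — with smooth unimodal desirabilities centred on typical
oral-drug ranges and floored at 0.05 so one bad property cannot
annihilate the score; the published fitted histogram parameters and the
structural-alert term are not reproduced. Both scores are deterministic,
bounded, and ordered sensibly on reference structures (hexane scores
easier than a caged polycycle; a small drug scores more drug-like than a
C20 alkane), which is what the pipeline's selection pressure needs from
them. Absolute values are not comparable to other implementations.

## The reinforcement loop

Each cycle samples `samples_per_cycle` latent coordinates from the
$N(0, I)$ prior (8192 at full scale), decodes them, keeps valid
molecules, deduplicates by canonical SMILES, scores survivors, selects
the `top_k` (4096) by aggregate reward — exactly a full descending sort
truncated at $k$, ties broken by lexicographically smaller SMILES — and
fine-tunes the VAE on the selected molecules (2 epochs, batch 512,
keeping both loss terms: retaining the KL term prevents the refocused
model's posterior from collapsing). Sampling always draws from the
prior; fine-tuning re-maps the prior's mass onto high-reward regions, so
later cycles sample better candidates. One deliberate subtlety: the
canonical SMILES is only the deduplication key, while the decoded
spelling is what gets scored and fine-tuned on, because the canonical
respelling may use tokens outside the model's vocabulary.

Cycle logs record sampled/valid/unique/scored counts (which nest, and
are asserted to nest) and reward summaries. The final ranked table
collapses duplicates across cycles by canonical SMILES, keeping each
compound's maximum reward and first cycle of appearance. A cycle with
zero valid candidates leaves the model unchanged and the loop running.
Scores of previously seen compounds are recomputed per cycle rather than
cached: fine-tuning moves the embedding between cycles, so the distance
rewards of the same compound legitimately change; caching would be a
behaviour change, not an optimization.

At desk scale (10 cycles × 256 samples, top 64, on the synthetic
scenario below) the mean aggregate reward of scored candidates rises
from cycle 1 to cycle 10 in all three seeds we run, which is the
scaled analogue of progressive embedding refocusing. The climb is small
in absolute terms (≈ 0.03–0.06) because the toy landscape starts near
its ceiling: a memorizing VAE already emits mostly family molecules.

## The dual-activity benchmark

Given an activity table, compounds assayed against exactly two distinct
targets form (compound, target1, target2) triplets; compounds present in
the scorer training set are removed (matched by canonical SMILES), and
replicate measurements aggregate by geometric mean (median and min are
options; geometric mean is the natural average for log-scale affinities).
A side is dual-active iff both affinities are strictly below the
threshold (1 µM default; "less than" is read strictly, so boundary
values are inactive). Observed versus predicted labels populate a 2×2
table. The reported odds ratio is the sample cross-product ratio
$(\mathrm{tp}\cdot\mathrm{tn})/(\mathrm{fp}\cdot\mathrm{fn})$ — on
(90, 10, 10, 90) exactly 81 — with p-values from both the two-sided
Fisher exact test and the chi-squared test on the same table; the Fisher
test's own point estimate is a conditional MLE and is deliberately not
used as "the" odds ratio. With a zero cell the Haldane–Anscombe +0.5
correction is applied and flagged. Accuracy is reported alongside
balanced accuracy, since dual-actives are rare in realistic tables.

Threshold sweeps re-classify at each threshold (decade grid
$10^{-5}$–$10^{-10}$ M by default) and emit precision/recall and
TPR/FPR point sets. At empty margins the conventions are: recall 0 when
no observed positives exist, FPR 1 when no observed negatives exist —
these make the degenerate limits (everything active / nothing active)
come out as the expected 1 and 0.

## The synthetic scenario

`build_scenario()` expands one seed into a full study: a corpus of
scaffold families (default 6 families × 20 molecules of simple C/N/O
chemistry — rings, ethers, amides — kept deliberately easy so toy VAE
training is tractable on one CPU); per-family *marker bits* (fingerprint
bits present in ≥ 80% of the family and ≤ 10% elsewhere); two targets
each active against `n_active_families` (default 2) families, sharing a
`dual_overlap` fraction of them; and activity tables where carrying a
family's full marker set raises ligand efficiency by `effect_total`
(default 0.3) over the baseline (0.45), with Gaussian noise (σ = 0.05).
On a ~14-heavy-atom molecule that lifts pIC50 from ≈ 4.5 to ≈ 7.5,
placing actives and inactives on clearly opposite sides of the 1 µM
line — the bimodal structure a threshold benchmark needs. Dual-active
compounds are exactly the members of the shared active families, so
`dual_overlap = 1` makes the two targets' activities rank-correlated
near 1 and `dual_overlap = 0` decorrelates them, a property the tests
check. One realistic wrinkle survives: members of an active family that
are small have high ligand efficiency but absolute potency near or below
1 µM ($\mathrm{pIC}_{50} = yN/1.4$), so observed labels are not purely
family membership; predictions inherit the same size dependence, which
is why classification stays accurate.

In the acceptance benchmark the scorers are trained on a
family-stratified half of the molecules and evaluated on triplets from
the disjoint other half, reaching accuracy ≥ 0.9 and odds ratio ≥ 10 at
1 µM. What the scenario does *not* emulate: ChEMBL-scale structural
diversity, assay noise heterogeneity, activity cliffs, and any
train/test distribution shift beyond molecule identity — so passing it
demonstrates the machinery end to end, not real-data performance.

## Numerical choices and degenerate inputs

* All randomness flows from one master seed through a labelled hash
  (`derive_seed`), so sub-runs are independently reproducible and
  derived seeds stay within R's 32-bit integer range.
* Softmax rows are max-shifted before exponentiation; cross-entropy
  clamps probabilities at 1e-12.
* `select_top_k` with `k` above the candidate count returns everything
  with a warning; selection ties break by SMILES in the C locale
  (`method = "radix"`), making selection platform-independent.
* Sampling `n = 0` molecules returns an empty table with a `NULL`
  validity rate rather than 0/0.
* Checkpoints are self-describing (schema tag, config, vocabulary,
  weights, seed, loss trace) and reload to bit-identical evaluation
  outputs; an unknown schema tag is an error, not a guess.
* Unparseable SMILES yield `NA` fingerprint rows from the low-level
  featurizer but an error from the scorer-facing `featurize()`, which
  must never silently train on garbage.

## Known limitations

* The SA and QED rewards are own-calibration stand-ins for the published
  scores (see above); rankings are sensible but absolute values differ
  from other software.
* OpenBabel's ECFP bit assignment differs from other toolkits' Morgan
  hashing, so fingerprints (and hence scorer models) are not
  interchangeable with models trained elsewhere.
* The pure-R VAE is budgeted for desk-scale corpora (tens to thousands
  of molecules). The full-scale architecture is expressible in the same
  configuration objects, but training a million-molecule corpus is out
  of reach without a compiled backend.
* Reward thresholds $(\mu_i, \sigma_i)$ ship as placeholders; results
  at full scale depend on setting them from real ligand data.
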