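---
title: "Models and methods behind mhcbindr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mhcbindr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cytotoxic T cells recognise peptides presented on the cell surface by MHC
class I molecules (in humans, HLA-A, -B and -C). Predicting whether a given
peptide binds a given allele is the workhorse computation behind neoepitope
screening for cancer vaccines. Two properties make the problem awkward for
classical fixed-width classifiers: ligands vary in length (8–15 residues),
and the allele space is huge — thousands of class I alleles exist, most with
no binding data at all, so a useful predictor must generalise to alleles it
has never seen, using only their amino-acid sequence.

`mhcbindr` addresses both with a dual-branch recurrent network. A peptide is
treated as a sentence of amino-acid words and consumed by a gated recurrent
unit (GRU) layer, which handles any length natively. The allele enters
either as a bare identity (a one-hot embedding, which cannot extrapolate) or
as its *pseudo-sequence* — the 75 residues of the two alpha helices that
form the walls of the peptide-binding groove (reference positions 50–84 and
140–179 on HLA-B*35:01), read off a multiple sequence alignment. The two
branch outputs are concatenated and passed through two ReLU layers to a
single sigmoid unit: the binding probability.

## Data curation

Qualitative binding records (the five classes `Positive-High`, `Positive`,
`Positive-Intermediate`, `Positive-Low`, `Negative`) are parsed from TSV,
then filtered in a fixed order: non-specific allele names (e.g. `HLA-A30`),
alleles without a known groove sequence (sequence mode only), peptide
lengths outside 8–15, and peptides with letters outside the 20 standard
amino acids (this covers the ambiguity codes B, X, J, Z). Quantitative
affinities are out of scope by design: they come from heterogeneous assays
and are hard to pool.

The default label policy maps the two high-confidence positive classes to
1, `Negative` to 0, and drops the two low-confidence classes — dropping
them was observed to slightly improve downstream accuracy. A `lenient`
policy keeps them as positives.

Conflicts (same peptide and allele, opposite labels) are handled in a
strict sequence: records from blacklisted sources are removed first (so a
discredited source can never swing a vote), identical duplicates collapse,
mixed groups resolve by majority vote over distinct records, and exact ties
are removed entirely. Every stage's drop count lands in an audit that
satisfies `rows_in = rows_out + sum(drops)`; the test suite asserts this
conservation property on every run. Majority voting counts distinct
*records*, not distinct sources — a documented choice where either reading
is defensible.

The source blacklist ships empty: the one source known to dominate
conflicts in real IEDB-derived data (an HLA-B*27 transgenic-mouse ligand
study) is not identified by a machine-readable ID we could hard-code
responsibly, so excluding it is left to the user's configuration.

## Pseudo-sequences

Residue windows are specified 1-based on the *ungapped* reference sequence,
and mapped through the alignment by counting non-gap characters in the
reference row. The mapped columns are then read off every allele, gaps
preserved as a `-` token, so all pseudo-sequences share one length and the
gap becomes an ordinary vocabulary token downstream. Two consequences worth
stating loudly: the reference FASTA must use the same residue numbering as
the window definition (mature-protein vs precursor numbering differ by the
signal peptide), and inserting alignment columns outside the mapped windows
never changes any pseudo-sequence (tested as an invariant).

The beta-sheet floor of the groove (residues 3–37 and 94–126) is available
via `beta_sheet_windows()` but excluded from defaults: including the floor
was observed to *worsen* prediction, presumably because floor residues are
conserved and mostly add parameters, not signal.

## Amino-acid embeddings

Peptide tokens are single residues (1-grams) or non-overlapping triplets
(3-grams) in three reading frames offset 0/1/2 from the N-terminus.
Embeddings are pre-trained with skip-gram and negative sampling (5 noise
samples per pair, noise from the unigram distribution to the 3/4 power).
The implementation uses mean-gradient mini-batches rather than per-pair
updates — summed batched updates diverge — with the step size decayed
linearly; training is deterministic given a seed. The 1-gram dimension
default is 5 (4–6 all behave similarly); 3-grams use the conventional 100.
The MHC-branch residue embedding is *always* randomly initialised: gap
tokens have no pre-trainable context in protein corpora.

For large pre-trained 3-gram tables, naive fine-tuning overfits. The
`finetune_schedule()` implements the three-phase remedy: train with the
embedding frozen until the validation loss stops improving, unfreeze for
1–3 epochs, freeze again and train to early stopping. "Stops improving" is
operationalised with the same patience rule as early stopping.

## Training protocol

The dataset is split into five folds with all records sharing a peptide
sequence assigned to one fold (greedy balancing: groups in decreasing size
order, each to the currently lightest fold — fold sizes provably differ by
at most one group). Within each fold's training portion, 20% (again
peptide-grouped) is held out to drive early stopping on validation
cross-entropy, with best-weights restoration. Optimisation is Adam on
mini-batches; weights are shared across all alleles. The five fold models
form the final ensemble; its prediction is the member-wise median, which is
always bounded by the member range.

Early stopping is not allowed to trigger before `min_epochs` (default 15):
the loss surface has an initial plateau at chance level, and a patience
rule armed from epoch one occasionally kills a run that is still on the
plateau — this exact failure appeared in roughly one fold in ten before the
guard was added.

Default sizes (24 GRU units per direction, 48-unit MHC entry and head
layers, batch 512, Adam at 6e-3) are deliberately small: they are matched
to the desk-scale synthetic task this package trains in its tests, where
they converge in under a minute per fold on one CPU. For datasets in the
10^5 range one would raise the unit counts (GRUs were originally explored
up to 224 units, MHC fully connected layers up to 350, head layers 64–512)
and switch on unit-level dropout around 0.3–0.4 on fully-connected outputs
and GRU inputs with 0.3 recurrent dropout; at desk scale those dropout
rates only slow convergence, so unit-level dropout defaults to zero.

One dropout stays on by default: `dropout_mhc_pos` (0.15) zeroes whole
pseudo-sequence positions in the MHC branch during training. An unseen
allele differs from its nearest training neighbour at a few private
polymorphic positions; position dropout trains the allele reader to
tolerate exactly that perturbation, and it measurably stabilises
leave-one-allele-out transfer.

## Evaluation protocols

AUC is computed by the Mann–Whitney rank formula (ties half-credited) and
is tested to equal a brute-force all-pairs oracle to 1e-12. Best F1 scans
every distinct observed score as a threshold (predict positive at or above
it), ties broken toward the higher threshold. Per-allele AUCs are reported
only for alleles with at least 30 records, 5 positives and 5 negatives;
when fold labels are present, per-fold AUCs are averaged (single-class
folds skipped), otherwise the pooled value is reported and labelled as
such. Whether the eligibility filter should apply per fold or pooled is
genuinely ambiguous; this implementation applies it to pooled tallies and
says so in the report object. Bootstrap stability resamples 80% of records
with replacement 100 times (single-class resamples are redrawn, keeping the
count fixed) and reports sd/mean of the AUCs.

Leave-one-allele-out removes every record of one allele, retrains on the
rest, scores the held-out records, and averages over 5 random restarts. In
one-hot mode the held-out allele stays in the registry, so its embedding
exists but receives no training signal — that is the point of the baseline:
whatever AUC it achieves comes from peptide information alone.

Peptidome scoring mimics the real use case where a detected ligand may have
been presented by any of an individual's typed alleles: each peptide's
score is the maximum ensemble prediction over the allele set (order
invariant and monotone in the set, both tested), after removing peptides
that overlap the training data.

## The synthetic data generator

Everything trains and tests offline against a generator with a known
ground truth. Its design choices matter and are worth recording:

- **Anchor rule.** Each allele prefers a small residue set at peptide
  position 2 and at the C-terminus; a peptide binds iff both anchors match.
  This mirrors real class I anchor biology. The preference sets are spelled
  out *literally* at six fixed pseudo-sequence positions, so the map from
  groove sequence to motif is deterministic and learnable.
- **Disjoint motifs.** Distinct preference profiles draw disjoint residue
  sets (as far as 20 letters allow), like the largely non-overlapping
  motifs of real supertypes. Overlapping random profiles would let a model
  score unseen alleles from peptide composition alone.
- **Matched decoys.** Besides constructed binders (45% of records by
  default), an equal fraction of records pair a peptide built for one
  allele with a *different* allele. Such mismatched pairs are ubiquitous in
  real qualitative data. The exact balance makes a peptide's anchor pattern
  carry no marginal label information, so any model that ignores the allele
  input is reduced to chance — without decoys, a peptide-only model reaches
  high AUC and the one-hot/sequence comparison measures nothing.
- **Conserved background.** Pseudo-sequences share one random template with
  a 2% per-position mutation rate per allele, matching the high conservation
  of real groove sequences. Fully independent random backgrounds give every
  allele 70-odd private identifying positions; a network then memorises
  alleles by arbitrary background features, and its reading of a
  never-seen pseudo-sequence is undefined — in our experiments it was often
  *anti*-correlated with the truth, because a misread allele turns genuine
  binders into confident-looking decoys.
- **Recorded noise.** Labels are flipped independently with probability
  ε after generation and the flip mask is kept, so noise checks are exact.

What the generator does not emulate: realistic amino-acid composition,
length-dependent motif shifts, mass-spectrometry detectability bias, and
assay-specific label errors. Passing the synthetic tests therefore
demonstrates that the architecture, training loop and protocols work as
specified — not that any particular accuracy will be reached on real IEDB
data.

### The label-noise ceiling, and what "motif recovery" asserts

With flip rate ε and balanced classes, the best possible AUC measured
against the *noisy* labels is `0.5 + 0.5(a + b)` where `a = b = 1 − ε` are
the label purities — at ε = 0.05 that is exactly 0.95, a ceiling no
trained model can exceed in expectation. The acceptance test for motif
recovery therefore scores out-of-fold predictions against the generator's
recorded noise-free labels (ceiling 1.0), where ≥ 0.95 measures genuine
learning rather than luck against the ceiling; the observed values sit
around 0.99, and around 0.94 against the noisy labels, consistent with the
arithmetic.

### Problem sizes used by tests and the acceptance script

Cross-validation runs at 8 alleles / 5,000 records / ε = 0.05 over three
seeds. The unseen-allele study uses 16 alleles in 8 motif profiles (two
alleles per profile, so the held-out allele has a training "twin" sharing
its rule positions, as a new allele of a known supertype would), with 3
restarts per mode in the test suite and 5 in `scripts/acceptance.R`. These
sizes keep a full run in the tens of minutes on one CPU.

## Numerical choices and degenerate inputs

- Sigmoid outputs are combined with cross-entropy in logit space, so the
  gradient is `p − y` and never overflows; reported losses clamp
  probabilities at 1e-12.
- GRU recurrences use masked right-padding: a padded step never changes a
  sequence's hidden state (tested bit-for-bit).
- All analytic gradients — both GRU directions, three 3-gram branches, both
  MHC entries, embeddings, head — are verified against central finite
  differences in every architecture variant.
- Single-class training sets, empty datasets, ragged alignments, unknown
  alleles, and non-standard peptide letters all fail fast with named
  errors rather than propagating NaNs.
- One user seed drives everything; component seeds (fold split, validation
  split, initialisation, bootstrap, restarts) are derived by a documented
  multiplicative hash so that components do not share RNG streams.

## Known limitations

The network is trained in interpreted R; it is fast enough for the
desk-scale tasks here but not for the 10^5-record regime, where the unit
counts above and a compiled backend would both be warranted. The one-hot
allele mode cannot score alleles outside its registry by construction.
Pseudo-sequence extraction trusts the input alignment; a misaligned
reference row shifts every window silently, which is why the reference
fixed-point invariant (windowed reference residues must reappear in its own
pseudo-sequence) is worth running on any new alignment.
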