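# mhcbindr

Peptide–MHC class I binding prediction with recurrent neural networks, in R.

T cells survey peptides presented by MHC class I molecules (HLA-A/B/C in
humans); predicting which peptides an allele binds is the central
computation in neoepitope screening for cancer vaccines. `mhcbindr`
implements a universal binding predictor around two ideas:

1. **Peptides as sentences.** A peptide of any length (8–15 residues in the
   curated data) is tokenized into amino-acid words — single residues, or
   residue triplets in three reading frames — embedded via skip-gram
   vectors pre-trained on protein corpora, and consumed by a bi-directional
   GRU, so no fixed-width padding or per-length models are needed.
2. **Alleles as groove sequences.** An MHC allele enters the model either
   as a bare identity (one-hot, limited to training alleles) or as its
   *pseudo-sequence*: the 75 residues of the two alpha helices lining the
   peptide-binding groove (reference positions 50–84 and 140–179 of
   HLA-B\*35:01), mapped through a multiple sequence alignment. The
   sequence form lets one shared model score *any* allele whose sequence is
   known — including alleles absent from training.

The two branches feed two ReLU layers and a sigmoid unit:
`P(bind | peptide, allele) ∈ (0, 1)`. Training uses peptide-grouped 5-fold
cross-validation (records sharing a peptide never straddle folds), Adam
with early stopping on a 20% validation split, and a final 5-model ensemble
aggregated by the median. Evaluation includes overall and per-allele AUC
(eligibility: ≥30 records, ≥5 per class), best-F1 threshold scans,
bootstrap stability of the AUC, leave-one-allele-out generalization, and
max-over-alleles scoring of immunopeptidome samples.

The whole pipeline is testable offline: a synthetic-data module generates
alleles with anchor-motif binding rules spelled into their
pseudo-sequences, binding records with recorded label noise, pre-training
corpora, and peptidome samples. The network itself (masked GRUs,
backpropagation through time, Adam, dropout) is implemented in base R
matrix code and verified against finite differences in the test suite.

## Worked example

Simulate a small study (4 alleles, 1,200 records, 5% label noise), run the
grouped cross-validation, and inspect the report:

```r
library(mhcbindr)

al <- synthetic_alleles(n_alleles = 4, seed = 7)
ds <- synthetic_binding_data(al, n_records = 1200, noise = 0.05, seed = 7)
cv <- cross_validate(ds$records, model_config(seed = 7), pseudo = al$pseudo)

per_allele_report(cv$predictions)
#> overall AUC 0.9086  best F1 0.8164 (threshold 0.4685)  [fold_averaged per-allele AUC]
#> 4/4 alleles eligible (>=30 records, >=5 per class)

ensemble_predict(cv$ensemble, c("ALDKFYTSV", "SIINFEKL"), al$registry[1])
#> [1] 0.2133 0.4402
```

The report prints the pooled out-of-fold AUC (how well held-out records are
ranked), the best achievable F1 with its score threshold, and per-allele
AUCs averaged over folds. The two ensemble probabilities are median-of-5
predictions for two peptides against the first synthetic allele; both fall
below the report's F1 threshold, i.e. neither peptide matches that allele's
anchor motif. At the test suite's full study size (8 alleles, 5,000
records) the same pipeline reaches out-of-fold AUC ≈ 0.99 against the
generator's noise-free labels.

Real data enters through the same interfaces: `clean_binding_data()` for
IEDB-style qualitative tables (filter cascade, label policy, source
blacklist, majority-vote conflict resolution, with a full audit),
`read_aligned_fasta()` + `pseudosequences()` for allele sequences, and
`build_corpus()` + `train_skipgram()` for embedding pre-training.

## Command line

A thin CLI wraps the same functions. The script is installed with the
package — find it with `system.file("cli", "mhcbindr", package = "mhcbindr")`
and symlink it onto your `PATH`, or call it as
`Rscript $(Rscript -e 'cat(system.file("cli","mhcbindr",package="mhcbindr"))') <command>`:

```sh
mhcbindr simulate --outdir sim/ --alleles 8 --records 5000 --seed 7
mhcbindr clean    --input raw.tsv --output clean.tsv --audit audit.txt
mhcbindr pseudoseq --aligned aln.fasta --reference 'HLA-B*35:01' \
                   --windows 50-84,140-179 --output pseudo.tsv
mhcbindr embed    --fasta swissprot.fa --peptides ninemers.txt --output emb.tsv
mhcbindr train    --data clean.tsv --pseudo pseudo.tsv --outdir run1/
mhcbindr predict  --model run1/ --pairs pairs.tsv --output preds.csv
mhcbindr evaluate --preds preds.csv --output report.tsv --bootstrap 100
mhcbindr run-all  --outdir demo/ --seed 7
```

Every artifact-producing command echoes its resolved configuration
(`run_config.yaml`) next to its outputs; one `--seed` drives all
randomness.

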