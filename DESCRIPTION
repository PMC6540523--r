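Package: mhcbindr
Title: Recurrent Neural Network Prediction of Peptide-MHC Class I Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curates qualitative peptide-MHC class I binding data, represents
    MHC alleles by the binding-groove pseudo-sequence extracted from a
    multiple sequence alignment, pre-trains skip-gram amino-acid embeddings,
    and trains a dual-branch gated recurrent unit (GRU) network that maps a
    variable-length peptide and an MHC allele (by name or by sequence) to a
    binding probability. Includes peptide-grouped five-fold cross-validation
    with a median ensemble, per-allele AUC and best-F1 evaluation,
    leave-one-allele-out generalization tests, max-over-alleles peptidome
    scoring, and a synthetic motif-based data generator so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
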