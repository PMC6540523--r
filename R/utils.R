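## Shared internal helpers: seed derivation, logging, validation.

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
GAP_TOKEN <- "-"
UNK_TOKEN <- "<unk>"

#' Derive a component seed from a single user seed
#'
#' All randomness in the package is routed through one user-facing seed.
#' Component seeds (fold splitter, weight initialisers, bootstrap, restarts)
#' are derived deterministically so that independent components do not share
#' RNG streams. The derivation is `(seed * 2654435761 + hash(label)) mod
#' (2^31 - 1)`, a Knuth-style multiplicative mix of the seed with a simple
#' polynomial hash of the component label; it keeps every derived seed a
#' valid 32-bit R integer.
#'
#' @param seed integer master seed.
#' @param label character scalar naming the component.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% m
  # split the 64-bit-unsafe product into pieces to stay in double precision
  s <- as.numeric(seed) %% m
  mixed <- (s * 48271) %% m
  as.integer((mixed + h * 7919) %% m)
}

mhc_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(sprintf(...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Check peptides for letters outside the 20 standard amino acids
#' @param peptides character vector.
#' @return logical vector, TRUE where the peptide contains only standard letters.
#' @keywords internal
is_standard_peptide <- function(peptides) {
  !grepl(sprintf("[^%s]", paste(AA_LETTERS, collapse = "")), peptides)
}
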