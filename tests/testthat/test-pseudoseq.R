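test_that("aligned allele sets enforce equal length and unique names", {
  ok <- aligned_alleles(c(A1 = strrep("ACDEF", 18), A2 = strrep("GHIKL", 18)))
  expect_equal(ok$column_count, 90L)
  expect_error(aligned_alleles(c(A1 = strrep("A", 90), A2 = strrep("A", 89))),
               "ragged")
  expect_error(aligned_alleles(c(A1 = "ACD", A1 = "ACD")), "duplicate")
})

test_that("read_aligned_fasta parses headers up to whitespace", {
  path <- write_fasta(list("HLA-A*01:01 some description" = "AC-DE",
                           "HLA-B*07:02" = "AGGDE"))
  aln <- read_aligned_fasta(path)
  expect_setequal(names(aln$entries), c("HLA-A*01:01", "HLA-B*07:02"))
  expect_equal(aln$column_count, 5L)
})

test_that("reference position mapping skips reference gaps", {
  # ungapped reference: identity mapping
  aln <- aligned_alleles(c(REF = "ACDEF", X = "GGGGG"))
  expect_equal(reference_positions_to_columns(aln, reference_windows("REF", list(c(2L, 3L)))),
               c(2L, 3L))
  # reference "A-CD": residue 2 (C) is in column 3, residue 3 (D) in column 4
  aln2 <- aligned_alleles(c(REF = "A-CD", X = "EFGH"))
  expect_equal(reference_positions_to_columns(aln2, reference_windows("REF", list(c(2L, 3L)))),
               c(3L, 4L))
  # gaps before, inside and after the window
  aln3 <- aligned_alleles(c(REF = "-AB-CD-", X = "XXXXXXX"))
  # residues: A@2 B@3 C@5 D@6 ; window 2-4 = B, C, D
  expect_equal(reference_positions_to_columns(aln3, reference_windows("REF", list(c(2L, 4L)))),
               c(3L, 5L, 6L))
})

test_that("default alpha-helix windows yield exactly 75 positions", {
  ref <- paste(rep(c("A", "C", "D", "E"), length.out = 180), collapse = "")
  aln <- aligned_alleles(c("HLA-B*35:01" = ref, OTHER = strrep("G", 180)))
  cols <- reference_positions_to_columns(aln, reference_windows())
  expect_length(cols, 75L)
  expect_equal(cols, c(50:84, 140:179))
})

test_that("mapping errors are informative", {
  aln <- aligned_alleles(c(REF = "ACDEF", X = "GGGGG"))
  expect_error(reference_positions_to_columns(aln, reference_windows("MISSING", list(c(1L, 2L)))),
               "not in alignment")
  expect_error(reference_positions_to_columns(aln, reference_windows("REF", list(c(4L, 9L)))),
               "exceeds")
})

test_that("pseudo-sequence extraction preserves gaps and equal length", {
  aln <- aligned_alleles(c(REF = "ACDEFGH", B = "AC-EFGH", C = "MCDEFGW"))
  cols <- c(2L, 3L, 5L)
  ps <- extract_pseudosequences(aln, cols)
  expect_equal(ps$groove_sequence[ps$allele == "REF"], "CDF")
  expect_equal(ps$groove_sequence[ps$allele == "B"], "C-F")  # gap preserved
  # C differs from REF only outside the mapped columns
  expect_equal(ps$groove_sequence[ps$allele == "C"], "CDF")
  expect_length(unique(nchar(ps$groove_sequence)), 1L)
})

test_that("reference fixed point: windowed reference residues recovered", {
  set.seed(1)
  ref_ungapped <- paste(sample(c("A","C","D","E","F","G"), 200, TRUE), collapse = "")
  # insert gaps at arbitrary points
  chars <- strsplit(ref_ungapped, "")[[1]]
  gapped <- character(0)
  for (i in seq_along(chars)) {
    gapped <- c(gapped, chars[i])
    if (i %% 17 == 0) gapped <- c(gapped, "-")
  }
  other <- paste(sample(c("K","L","M"), length(gapped), TRUE), collapse = "")
  aln <- aligned_alleles(c(REF = paste(gapped, collapse = ""), O = other))
  rw <- reference_windows("REF")
  ps <- pseudosequences(aln, rw)
  recovered <- gsub("-", "", ps$groove_sequence[ps$allele == "REF"])
  expected <- paste0(substr(ref_ungapped, 50, 84), substr(ref_ungapped, 140, 179))
  expect_equal(recovered, expected)
})

test_that("all-gap column insertion outside windows leaves pseudo-sequences unchanged", {
  aln <- aligned_alleles(c(REF = "ACDEFGH", B = "MCDEFGW"))
  cols <- reference_positions_to_columns(aln, reference_windows("REF", list(c(2L, 4L))))
  before <- extract_pseudosequences(aln, cols)
  # insert a column (gap in all existing rows) after the mapped region
  aln2 <- aligned_alleles(c(REF = "ACDEF-GH", B = "MCDEF-GW", NEWB = "MCDEFAGW"))
  cols2 <- reference_positions_to_columns(aln2, reference_windows("REF", list(c(2L, 4L))))
  after <- extract_pseudosequences(aln2, cols2)
  expect_equal(after$groove_sequence[match(c("REF", "B"), after$allele)],
               before$groove_sequence[match(c("REF", "B"), before$allele)])
})

test_that("run_alignment passes through pre-aligned input and fails helpfully otherwise", {
  path <- write_fasta(list(A = "ACDEF", B = "AC-EF"))
  aln <- run_alignment(aligned = path)
  expect_equal(aln$column_count, 5L)
  unaligned <- write_fasta(list(A = "ACDEF", B = "ACEF"))
  expect_error(run_alignment(unaligned, tool_path = "no-such-aligner-binary"),
               "pre-aligned|aligner")
})

test_that("run_alignment drives an installed aligner on identical sequences", {
  skip_if(Sys.which("mafft") == "" && Sys.which("muscle") == "",
          "no aligner installed")
  path <- write_fasta(list(S1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
                           S2 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"))
  aln <- run_alignment(path)
  expect_equal(unname(aln$entries[1]), unname(aln$entries[2]))
})

test_that("pseudo table round-trips as TSV", {
  ps <- data.table::data.table(allele = c("X*01:01", "Y*02:01"),
                               groove_sequence = c("AC-DE", "ACFDE"))
  path <- tempfile(fileext = ".tsv")
  write_pseudo_tsv(ps, path)
  back <- read_pseudo_tsv(path)
  expect_equal(data.frame(back), data.frame(ps))
  writeLines(c("allele\tgroove_sequence", "A\tACD", "B\tACDE"), path)
  expect_error(read_pseudo_tsv(path), "share one length")
})
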