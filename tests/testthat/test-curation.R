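test_that("parse_binding_table reads rows, normalizes names and isolates bad labels", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("peptide\tallele\tlabel\tsource",
               "SIINFEKL\thla-a*02:01\tPositive\tsrcA",
               "ALDKFYTSV\tHLA-B*35:01:02\tPositive-Low\tsrcA",
               "NLVPMVATV\tHLA-A*02:01\tGarbage\tsrcB"), path)
  out <- parse_binding_table(path)
  expect_equal(nrow(out$records), 2L)
  expect_equal(out$records$allele_name, c("HLA-A*02:01", "HLA-B*35:01"))
  expect_equal(out$records$qualitative_label[2], "Positive-Low")
  expect_equal(nrow(out$rejects), 1L)
  expect_equal(out$rejects$reject_reason, "unparseable_label")
})

test_that("parse_binding_table flags missing columns and empty files", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("pep\tallele\tlabel\tsource", "SIINFEKL\tHLA-A*02:01\tPositive\ts1"), path)
  expect_error(parse_binding_table(path), "peptide")
  path2 <- tempfile(fileext = ".tsv")
  writeLines("peptide\tallele\tlabel\tsource", path2)
  expect_warning(out <- parse_binding_table(path2), "empty")
  expect_equal(nrow(out$records), 0L)
})

test_that("allele normalization truncates to 4-digit resolution and detects specificity", {
  expect_equal(normalize_allele_name(" hla-a*02:01:01:05 "), "HLA-A*02:01")
  expect_equal(normalize_allele_name("HLA-B*35:01"), "HLA-B*35:01")
  expect_true(is_specific_allele("HLA-A*02:01"))
  expect_false(is_specific_allele("HLA-A30"))
  expect_false(is_specific_allele("MHCCLASSI"))
})

test_that("filter_record applies rules in the documented order", {
  expect_true(filter_record("SIINFEKL", "HLA-A*02:01")$keep)
  expect_equal(filter_record("SIXNFEKLM", "HLA-A*02:01")$reason, "ambiguous_aa")
  expect_equal(filter_record("SIINFEKL", "HLA-A30")$reason, "nonspecific_allele")
  expect_equal(filter_record(strrep("A", 16), "HLA-A*02:01")$reason, "length")
  expect_equal(filter_record(strrep("A", 7), "HLA-A*02:01")$reason, "length")
  # first failing rule wins: nonspecific allele outranks bad peptide
  expect_equal(filter_record("SIXNFEKLM", "HLA-A30")$reason, "nonspecific_allele")
  # a 16-mer with an ambiguity code reports length (checked before letters)
  expect_equal(filter_record(paste0(strrep("A", 15), "X"), "HLA-A*02:01")$reason, "length")
  # sequence mode: allele must have a known sequence
  expect_equal(filter_record("SIINFEKL", "HLA-A*02:01",
                             known_alleles = "HLA-B*35:01")$reason,
               "unknown_allele_sequence")
})

test_that("map_label implements the strict and lenient policies", {
  expect_identical(map_label("Positive-High"), 1L)
  expect_identical(map_label("Positive"), 1L)
  expect_identical(map_label("Negative"), 0L)
  expect_identical(map_label("Positive-Intermediate"), "drop")
  expect_identical(map_label("Positive-Low"), "drop")
  expect_identical(map_label("Positive-Low", policy = "lenient"), 1L)
  expect_error(map_label("Maybe"), "unknown qualitative label")
})

test_that("resolve_conflicts votes by majority, removes ties, and dedupes", {
  rec <- data.frame(
    peptide = c(rep("AAAAAAAAA", 4), rep("CCCCCCCCC", 4), rep("DDDDDDDDD", 5)),
    allele_name = "HLA-A*02:01",
    binary_label = c(1L, 1L, 1L, 0L,  1L, 1L, 0L, 0L,  rep(1L, 5)),
    source_id = paste0("s", 1:13)
  )
  ds <- resolve_conflicts(rec)
  expect_equal(nrow(ds$records), 2L)
  expect_equal(ds$records[peptide == "AAAAAAAAA"]$binary_label, 1L)
  expect_false("CCCCCCCCC" %in% ds$records$peptide) # 2v2 tie removed
  expect_equal(ds$records[peptide == "DDDDDDDDD"]$binary_label, 1L)
  expect_equal(unname(ds$audit[["conflict_tie_removed"]]), 4L)
  expect_equal(unname(ds$audit[["duplicate_collapsed"]]), 4L)
})

test_that("blacklist is applied before voting", {
  rec <- data.frame(peptide = "EEEEEEEE", allele_name = "HLA-A*02:01",
                    binary_label = c(1L, 0L), source_id = c("bad", "good"))
  ds <- resolve_conflicts(rec, blacklist = "bad")
  expect_equal(nrow(ds$records), 1L)
  expect_equal(ds$records$binary_label, 0L) # the negative survives, no tie
  expect_equal(unname(ds$audit[["blacklisted_source"]]), 1L)
})

test_that("resolve_conflicts is idempotent, conservative, and order independent", {
  set.seed(7)
  rec <- data.frame(
    peptide = sample(replicate(30, paste(sample(LETTERS[1:8], 9, TRUE), collapse = "")),
                     120, replace = TRUE),
    allele_name = sample(c("HLA-A*01:01", "HLA-B*07:02"), 120, replace = TRUE),
    binary_label = sample(0:1, 120, replace = TRUE),
    source_id = sample(paste0("s", 1:5), 120, replace = TRUE)
  )
  ds <- resolve_conflicts(rec)
  # conservation
  expect_equal(nrow(ds$records) + sum(ds$audit), nrow(rec))
  # uniqueness
  expect_equal(anyDuplicated(ds$records[, .(peptide, allele_name)]), 0L)
  # idempotence
  ds2 <- resolve_conflicts(ds$records)
  expect_equal(ds2$records, ds$records)
  expect_equal(sum(ds2$audit), 0L)
  # order independence
  perm <- rec[sample(nrow(rec)), ]
  ds3 <- resolve_conflicts(perm)
  expect_equal(ds3$records, ds$records)
})

test_that("dataset_summary counts records, alleles and gene fractions", {
  rec <- data.frame(
    peptide = paste0(strrep("A", 8), LETTERS[1:6]),
    allele_name = c("HLA-A*01:01", "HLA-A*01:01", "HLA-A*02:01",
                    "HLA-B*07:02", "HLA-B*07:02", "HLA-C*04:01"),
    binary_label = c(1L, 0L, 1L, 1L, 1L, 0L)
  )
  ds <- resolve_conflicts(rec)
  s <- dataset_summary(ds)
  expect_equal(s$n_records, 6L)
  expect_equal(s$alleles_per_gene, c("HLA-A" = 2L, "HLA-B" = 1L, "HLA-C" = 1L))
  expect_equal(s$entries_per_allele, c(min = 1L, max = 2L))
  expect_equal(unname(s$gene_fraction), c(50, 33.3, 16.7)) # percentages at 1 digit
  expect_warning(s0 <- dataset_summary(data.frame(peptide = character(),
                                                  allele_name = character(),
                                                  binary_label = integer())),
                 "empty")
  expect_equal(s0$n_records, 0L)
})

test_that("cleaned TSV round-trips through write/read", {
  rec <- data.frame(peptide = c("SIINFEKL", "ALDKFYTSV"),
                    allele_name = "HLA-A*02:01", binary_label = c(1L, 0L))
  ds <- resolve_conflicts(rec)
  path <- tempfile(fileext = ".tsv")
  write_cleaned_tsv(ds, path, audit_path = paste0(path, ".audit"))
  back <- read_cleaned_tsv(path)
  expect_equal(data.frame(back$records), data.frame(ds$records))
  expect_true(file.exists(paste0(path, ".audit")))
})
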