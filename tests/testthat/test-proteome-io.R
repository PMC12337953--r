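test_that("FASTA parsing extracts ids, uppercases, and round-trips", {
  path <- writeTempFasta(c(">P1 some description", "MKV",
                           ">sp|Q9XYZ1|NAME_HUMAN", "acd",
                           ">P2", "EEE"))
  p <- readProteome(path, name = "t")
  expect_s4_class(p, "Proteome")
  expect_identical(proteinIds(p), c("P1", "Q9XYZ1", "P2"))
  expect_identical(as.character(sequences(p)),
                   c(P1 = "MKV", Q9XYZ1 = "ACD", P2 = "EEE"))

  out <- withr::local_tempfile(fileext = ".fasta")
  writeProteome(p, out)
  p2 <- readProteome(out, name = "t")
  expect_identical(as.character(sequences(p2)),
                   as.character(sequences(p)))
})

test_that("duplicate ids, missing and empty files are hard errors", {
  dup <- writeTempFasta(c(">P1", "MK", ">P1", "EV"))
  expect_error(readProteome(dup), "P1")
  expect_error(readProteome(tempfile("nope")), "not found")
  empty <- writeTempFasta(character(0))
  expect_error(readProteome(empty), "empty|FASTA")
})

test_that("non-canonical residues are skipped and logged, or error in strict mode", {
  expect_identical(validateSequence("mkv"), "MKV")
  v <- validateSequence("MKX")
  expect_true(is.na(v))
  expect_match(attr(v, "reason"), "X")
  expect_error(validateSequence("MKX", strict = TRUE), "non-canonical")
  expect_error(validateSequence(""), "empty")

  path <- writeTempFasta(c(">GOOD", "MKV", ">BAD", "MKXB", ">U1", "SEQS"))
  p <- readProteome(path)
  expect_identical(proteinIds(p), c("GOOD", "U1"))
  sk <- skippedRecords(p)
  expect_identical(sk$id, "BAD")
  expect_match(sk$reason, "non-canonical")
  expect_error(readProteome(path, strict = TRUE))
})

test_that("score tables parse both dialects and enforce contiguity and range", {
  pp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("P1\t0.42", "P2\t0.9"), pp)
  expect_equal(readScoreTable(pp, "per_protein"), c(P1 = 0.42, P2 = 0.9))

  pr <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("P1\t1\t0.9", "P1\t2\t0.1"), pr)
  expect_equal(readScoreTable(pr, "per_residue"), list(P1 = c(0.9, 0.1)))

  gap <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("P1\t1\t0.9", "P1\t3\t0.1"), gap)
  expect_error(readScoreTable(gap, "per_residue"), "contiguous")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("P1\t1.7", bad)
  expect_error(readScoreTable(bad, "per_protein"), "\\[0, 1\\]")
  expect_equal(readScoreTable(bad, "per_protein", disorder = FALSE),
               c(P1 = 1.7))
})

test_that("overlapSplit partitions the test proteome", {
  sp <- overlapSplit(c("A", "B", "C"), c("B", "C", "D"))
  expect_setequal(sp$overlap_ids, c("B", "C"))
  expect_identical(sp$unique_ids, "A")

  sp0 <- overlapSplit("A", character(0))
  expect_length(sp0$overlap_ids, 0)
  expect_identical(sp0$unique_ids, "A")

  # partition-complete and idempotent on randomized id sets
  set.seed(42)
  for (k in 1:20) {
    test_ids <- sample(sprintf("ID%03d", 1:200), sample(5:80, 1))
    ref_ids <- sample(sprintf("ID%03d", 1:200), sample(0:150, 1))
    sp <- overlapSplit(test_ids, ref_ids)
    expect_length(intersect(sp$overlap_ids, sp$unique_ids), 0)
    expect_setequal(c(sp$overlap_ids, sp$unique_ids), test_ids)
    expect_identical(overlapSplit(test_ids, ref_ids), sp)
  }
})

test_that("published overlap counts are consistent with proteome sizes", {
  ov <- retinaReferenceCounts("overlap")
  sizes <- retinaReferenceCounts("sizes")
  n <- setNames(sizes$n, sizes$proteome)
  expect_equal(ov$overlap + ov$unique, unname(n[ov$proteome]))
  expect_equal(ov$overlap[ov$proteome == "RetNet"], 290)
  expect_equal(ov$unique[ov$proteome == "RetNet"], 41)
})

test_that("Proteome validity rejects bad objects", {
  expect_error(Proteome("x", character(0)))
  expect_error(Proteome("x", c(A = "MKV", A = "EEE")), "duplicate")
  expect_error(Proteome("x", c(A = "MKXV")), "non-canonical")
  expect_error(Proteome("", c(A = "MKV")))
})
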