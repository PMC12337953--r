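test_that("normalized hydropathy hits scale endpoints and truncated-window means", {
  expect_equal(normalizedHydropathy(strrep("I", 10), 5), rep(1, 10))
  expect_equal(normalizedHydropathy(strrep("R", 10), 5), rep(0, 10))
  # "IR" with window 3: both windows truncate to the two residues
  expect_equal(normalizedHydropathy("IR", 3), c(0.5, 0.5))
  expect_error(normalizedHydropathy("MKV", 1), "odd")
  expect_error(normalizedHydropathy("MKV", 4), "odd")
})

test_that("window net charge follows the pH 7 convention", {
  expect_equal(windowNetCharge(strrep("E", 8), 3), rep(1, 8))
  expect_equal(windowNetCharge(strrep("G", 8), 3), rep(0, 8))
  expect_equal(windowNetCharge("KE", 3), c(0, 0))   # charges cancel
  expect_equal(windowNetCharge(strrep("H", 8), 3), rep(0, 8))  # H uncharged
})

test_that("FoldIndex-style profile maps charged and hydrophobic extremes correctly", {
  expect_equal(foldIndexProfile(strrep("K", 30), 21), rep(1, 30))
  expect_equal(foldIndexProfile(strrep("I", 30), 21), rep(0, 30))
  # FI = 0 exactly maps to score 0.5: engineer H = (|R| + 1.151)/2.785 is
  # awkward per-residue, so check the mapping at the whole-window level via
  # a mixed sequence staying strictly inside (0, 1)
  s <- foldIndexProfile(paste(rep("KI", 25), collapse = ""), 21)
  expect_true(all(s >= 0 & s <= 1))
})

test_that("propensity profile normalizes its scale to [0, 1]", {
  expect_equal(propensityProfile(strrep("P", 12), "topidp", 5), rep(1, 12))
  expect_equal(propensityProfile(strrep("W", 12), "topidp", 5), rep(0, 12))
  # alternating dipeptide, full-coverage window: mean of the two values
  s <- propensityProfile("PWPW", window = 7)
  expect_equal(s, rep(0.5, 4), tolerance = 1e-12)
  expect_error(propensityProfile("MKV", scale = c(A = 1, C = 1)),
               "unknown residue|degenerate")
})

test_that("profiles stay in [0, 1] for random sequences under both predictors", {
  set.seed(7)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:25) {
    seq <- paste(sample(aas, sample(30:300, 1), replace = TRUE),
                 collapse = "")
    for (pred in c("foldindex", "topidp")) {
      s <- getPredictor(pred)(seq, 21)
      expect_length(s, nchar(seq))
      expect_true(all(s >= 0 & s <= 1))
    }
  }
})

test_that("both predictors rank a charged archetype above a hydrophobic one", {
  charged <- paste(rep(c("E", "K", "P", "S"), 50), collapse = "")
  hydrophobic <- paste(rep(c("I", "L", "V", "F"), 50), collapse = "")
  for (pred in c("foldindex", "topidp")) {
    f <- getPredictor(pred)
    expect_gt(mean(f(charged, 21)), mean(f(hydrophobic, 21)))
  }
})

test_that("consensus is a weighted mean, permutation-invariant, identity for one", {
  p1 <- c(0.2, 0.8)
  p2 <- c(0.6, 0.4)
  expect_identical(consensusProfile(list(p1)), p1)
  expect_equal(consensusProfile(list(rep(0, 5), rep(1, 5))), rep(0.5, 5))
  expect_equal(consensusProfile(list(p1, p2), c(1, 3)), c(0.5, 0.5))
  expect_equal(consensusProfile(list(p1, p2), c(1, 3)),
               consensusProfile(list(p2, p1), c(3, 1)))
  expect_error(consensusProfile(list(p1, c(0.1, 0.2, 0.3))), "mismatch")
  expect_error(consensusProfile(list(p1, p2), c(0, 0)), "weights")
})

test_that("registry dispatch and external score tables act as drop-in predictors", {
  expect_true(all(c("foldindex", "topidp") %in% listPredictors()))
  expect_error(getPredictor("no-such"), "unknown predictor")

  p <- toyProteome()
  prof <- disorderProfiles(p, "foldindex", 21)
  expect_identical(names(prof), proteinIds(p))
  expect_identical(S4Vectors::metadata(prof)$predictor, "foldindex")
  expect_equal(lengths(prof), setNames(Biostrings::width(sequences(p)),
                                       proteinIds(p)))

  # round-trip through the TSV dialect and back in as an external predictor
  tab <- withr::local_tempfile(fileext = ".tsv")
  writeScoreTable(as.list(prof), tab)
  ext <- readScoreTable(tab, "per_residue")
  prof2 <- disorderProfiles(p, ext)
  expect_equal(as.list(prof2), as.list(prof))
  expect_identical(S4Vectors::metadata(prof2)$predictor, "external")

  expect_error(disorderProfiles(p, ext["P1"]), "missing")
  bad <- ext; bad$P1 <- bad$P1[-1]
  expect_error(disorderProfiles(p, bad), "length mismatch")
})
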