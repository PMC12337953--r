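test_that("window features compute the charge-hydropathy and sticker proxies", {
  cfg <- llpsConfig()
  polyI <- windowFeatures(strrep("I", 25), cfg)
  expect_lt(polyI[["disorder_proxy"]], 0)
  expect_equal(polyI[["contact_proxy"]], 0)

  rg <- windowFeatures(strrep("RG", 13) |> substr(1, 25), cfg)
  expect_gt(rg[["disorder_proxy"]], 0)
  expect_equal(rg[["contact_proxy"]], 1)

  polyA <- windowFeatures(strrep("A", 25), cfg)
  expect_equal(polyA[["contact_proxy"]], 0)
  expect_error(windowFeatures(strrep("A", 10), cfg), "length")
})

test_that("window classification labels archetypes and applies the length filter", {
  expect_true(all(classifyWindows(strrep("RG", 40)) == "P"))
  expect_true(all(classifyWindows(strrep("ILVA", 25)) == "F"))
  short <- classifyWindows(strrep("A", 24))
  expect_length(short, 0)
  expect_match(attr(short, "skipped"), "outside")
  long <- classifyWindows(strrep("A", 10001),
                          llpsConfig(max_seq = 10000))
  expect_length(long, 0)
  # disordered but sticker-poor: D
  d <- classifyWindows(paste(rep("EK", 50), collapse = ""))
  expect_true(all(d == "D"))
})

test_that("PS-IDR extraction follows coverage and minimum-length rules", {
  cfg <- llpsConfig(window = 5, min_region = 20)
  # 30 consecutive P-windows of width 5 cover 34 residues -> one region
  labels <- c(rep("P", 30), rep("F", 20))
  r <- findPsIdrs(labels, cfg)
  expect_length(r, 1)
  expect_equal(IRanges::width(r), 34)

  # a short P-run below min_region yields nothing
  r2 <- findPsIdrs(c(rep("P", 3), rep("F", 40)), cfg)
  expect_length(r2, 0)

  # two P-runs split by a long F block give two regions
  labels3 <- c(rep("P", 20), rep("F", 40), rep("P", 20), rep("F", 5))
  r3 <- findPsIdrs(labels3, cfg)
  expect_length(r3, 2)
})

test_that("psProfile scores coverage and skips out-of-bounds sequences", {
  p <- psProfile(strrep("RG", 50))
  expect_equal(p$ps_score, 1)
  expect_equal(p$max_region_length, 100)

  f <- psProfile(paste(rep("ILVA", 30), collapse = ""))
  expect_equal(f$ps_score, 0)
  expect_equal(f$max_region_length, 0L)

  s <- psProfile(strrep("A", 24))
  expect_true(is.na(s$ps_score))
  expect_match(s$skipped, "outside")
})

test_that("raising the contact threshold never increases ps_score", {
  set.seed(13)
  g <- generateProteome(20, c(PS_PRONE = 0.5, DISORDERED = 0.5), seed = 99)
  seqs <- as.character(sequences(g$proteome))
  for (seq in seqs[1:10]) {
    scores <- vapply(c(0.2, 0.4, 0.6, 0.8), function(th)
      psProfile(seq, llpsConfig(contact_threshold = th))$ps_score,
      numeric(1))
    expect_true(all(diff(scores) <= 1e-12))
  }
})

test_that("cumulative curve matches the worked (50, 15) example and is monotone", {
  ps <- S4Vectors::DataFrame(
    id = sprintf("P%03d", 1:100),
    n_regions = 1L,
    max_region_length = c(rep(60L, 15), rep(10L, 85)),
    ps_score = 0.1,
    skipped = NA_character_)
  curve <- cumulativePsCurve(ps, lengths = c(0, 50))
  expect_equal(curve$percent, c(100, 15))

  set.seed(21)
  ml <- sample(0:200, 500, replace = TRUE)
  ps2 <- S4Vectors::DataFrame(id = as.character(1:500), n_regions = 1L,
                              max_region_length = ml, ps_score = 0,
                              skipped = NA_character_)
  c2 <- cumulativePsCurve(ps2)
  expect_equal(c2$percent[1], 100)
  expect_true(all(diff(c2$percent) <= 0))
  expect_true(all(c2$percent >= 0 & c2$percent <= 100))

  none <- S4Vectors::DataFrame(id = "a", n_regions = 0L,
                               max_region_length = 0L, ps_score = 0,
                               skipped = NA_character_)
  expect_equal(cumulativePsCurve(none, lengths = c(20, 50))$percent,
               c(0, 0))
})

test_that("recall AUC equals the pairwise Mann-Whitney oracle", {
  expect_equal(recallAuc(c(0.9, 0.1), c(0.5, 0.5)), 0.5)
  expect_equal(recallAuc(c(2, 3), c(0, 1)), 1)
  set.seed(31)
  for (k in 1:20) {
    t <- round(runif(sample(3:12, 1)), 1)   # rounding forces ties
    r <- round(runif(sample(3:12, 1)), 1)
    expect_equal(recallAuc(t, r), aucOracle(t, r))
  }
  expect_error(recallAuc(numeric(0), 1), "empty")
})

test_that("planted PS-prone enrichment is recovered as AUC ordering", {
  rich <- generateProteome(120, c(PS_PRONE = 0.3, DISORDERED = 0.35,
                                  ORDERED = 0.35), seed = 41, name = "rich")
  poor <- generateProteome(120, c(PS_PRONE = 0.05, DISORDERED = 0.475,
                                  ORDERED = 0.475), seed = 41, name = "poor")
  s_rich <- psProfiles(rich$proteome)$ps_score
  s_poor <- psProfiles(poor$proteome)$ps_score
  expect_gt(recallAuc(s_rich[!is.na(s_rich)], s_poor[!is.na(s_poor)]), 0.5)
})
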