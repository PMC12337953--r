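# small fixtures built in code

writeTempFasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

toyProteome <- function(name = "toy",
                        seqs = c(P1 = strrep("MKVLAE", 10),
                                 P2 = strrep("EEKKPS", 10),
                                 P3 = strrep("ILVFAW", 10))) {
  Proteome(name, seqs)
}

# brute-force Pearson chi-squared oracle, independent of chiSquaredTest()
chi2Oracle <- function(tab) {
  N <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / N
  sum((tab - E)^2 / E)
}

# brute-force one-way ANOVA F from explicit sums of squares
anovaOracle <- function(groups) {
  gm <- mean(unlist(groups))
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1L
  dfw <- length(unlist(groups)) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

# brute-force pairwise Mann-Whitney AUC oracle
aucOracle <- function(test, ref) {
  wins <- 0
  for (t in test) for (r in ref)
    wins <- wins + (t > r) + 0.5 * (t == r)
  wins / (length(test) * length(ref))
}
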