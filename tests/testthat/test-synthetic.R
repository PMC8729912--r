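test_that("sampling from a near-degenerate model emits its consensus", {
  m <- degenerate_hmm("MKVLAWCDEF")
  expect_identical(sampleFromHMM(m, seed = 1L), "MKVLAWCDEF")
})

test_that("sampling is deterministic per seed and leaves the RNG alone", {
  m <- random_hmm(8)
  a <- sampleFromHMM(m, seed = 42L)
  b <- sampleFromHMM(m, seed = 42L)
  expect_identical(a, b)
  set.seed(7); x <- runif(1)
  set.seed(7); invisible(sampleFromHMM(m, seed = 9L)); y <- runif(1)
  expect_identical(x, y)
})

test_that("mean sampled length matches the chain-geometry expectation", {
  set.seed(13)
  m <- random_hmm(6)
  lens <- vapply(1:1000, function(i) nchar(prgscan:::sample_hmm_path(m)$seq),
                 numeric(1))
  expected <- prgscan:::expected_sample_length(m)
  se <- sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - expected), 3 * se)
})

test_that("reference alignments have the requested shape and closure", {
  ref <- makeReferenceMsa("TIR", nRows = 7L, divergence = 0.1, seed = 3L,
                          modelLength = 30L)
  m <- prgscan:::msa_matrix(ref$msa)
  expect_identical(nrow(m), 7L)
  expect_gte(ncol(m), 30L)
  expect_identical(domainLabel(ref$hmm), "TIR")
  # divergence 0 with a single-path generator: rows identical to consensus
  ref0 <- makeReferenceMsa("TIR", nRows = 3L, divergence = 1e-9, seed = 4L,
                           modelLength = 20L)
  expect_identical(unname(ref0$rows[1]), unname(ref0$rows[2]))
  # a model built from the alignment re-detects every row (criterion ii)
  built <- buildProfileHMM(ref$msa, "TIR")
  expect_true(all(vapply(ref$rows, function(s)
    viterbiLocal(built, s)$score > 0, logical(1))))
})

test_that("class counts follow largest-remainder rounding exactly", {
  config <- simConfig(seed = 7L, nProteins = 100L,
                      classMix = c(TNL = 0.5, RLK = 0.5))
  refs <- makeDomainReferences(seed = 5L, nRows = 4L, divergence = 0.1)
  sim <- makeSyntheticProteome(config, lapply(refs, `[[`, "hmm"))
  cls <- unique(sim$truth[, c("protein_id", "class_label")])
  expect_identical(sum(cls$class_label == "TNL"), 50L)
  expect_identical(sum(cls$class_label == "RLK"), 50L)
  expect_identical(length(sim$proteome), 100L)
  # uneven mix: 7 proteins over three classes, remainders resolved in order
  cfg2 <- simConfig(seed = 8L, nProteins = 7L,
                    classMix = c(TNL = 1 / 3, RLK = 1 / 3, RLP = 1 / 3))
  counts <- prgscan:::largest_remainder(cfg2@classMix, 7L)
  expect_identical(sum(counts), 7L)
  expect_identical(unname(counts["TNL"]), 3L)
})

test_that("planted segments stay in bounds and respect N-to-C order", {
  refs <- makeDomainReferences(seed = 21L, nRows = 4L, divergence = 0.1)
  config <- simConfig(seed = 9L, nProteins = 14L)
  sim <- makeSyntheticProteome(config, lapply(refs, `[[`, "hmm"))
  widths <- setNames(Biostrings::width(sim$proteome), names(sim$proteome))
  for (id in unique(sim$truth$protein_id)) {
    tt <- sim$truth[sim$truth$protein_id == id, ]
    expect_true(all(tt$start >= 1 & tt$end <= widths[[id]]))
    expect_true(all(tt$start <= tt$end))
    if (nrow(tt) > 1L) {
      expect_true(all(diff(tt$start) > 0))
      expect_true(all(tt$start[-1] > tt$end[-nrow(tt)]))  # non-overlapping
    }
    arch <- prgscan:::ARCHITECTURES[[tt$class_label[1]]]
    expect_identical(tt$domain_label, arch)
  }
})

test_that("noise-free planting from a degenerate generator is verbatim", {
  cons <- strrep("MKVLAWCDEF", 4)
  gen <- degenerate_hmm(cons)
  gen@domainLabel <- "NBS"
  config <- simConfig(seed = 31L, nProteins = 2L,
                      classMix = c(TNL = 1), substitutionNoise = 0)
  models <- list(TIR = gen, NBS = gen, LRR = gen)
  models$TIR@domainLabel <- "TIR"; models$LRR@domainLabel <- "LRR"
  sim <- makeSyntheticProteome(config, models)
  tt <- sim$truth[sim$truth$protein_id == "synthetic_0001", ]
  seqs <- as.character(sim$proteome)
  for (k in seq_len(nrow(tt))) {
    expect_identical(substr(seqs[["synthetic_0001"]], tt$start[k], tt$end[k]),
                     cons)
  }
})

test_that("simulation outputs are byte-identical across reruns", {
  refs <- makeDomainReferences(seed = 77L, nRows = 4L, divergence = 0.1)
  gens <- lapply(refs, `[[`, "hmm")
  config <- simConfig(seed = 123L, nProteins = 14L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeSimulation(makeSyntheticProteome(config, gens), config, d1)
  writeSimulation(makeSyntheticProteome(config, gens), config, d2)
  for (f in c("proteome.fasta", "truth.tsv", "config.yaml")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # a different seed changes the proteome
  cfg2 <- simConfig(seed = 124L, nProteins = 14L)
  d3 <- withr::local_tempdir()
  writeSimulation(makeSyntheticProteome(cfg2, gens), cfg2, d3)
  expect_false(identical(readLines(file.path(d1, "proteome.fasta")),
                         readLines(file.path(d3, "proteome.fasta"))))
})

test_that("a class without generator models is rejected", {
  config <- simConfig(seed = 1L, nProteins = 5L, classMix = c(LECRK = 1))
  expect_error(makeSyntheticProteome(config, list()), "LECM")
})
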