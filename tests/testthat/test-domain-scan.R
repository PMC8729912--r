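test_that("degenerate model scores its consensus at minus-sum-log-background", {
  cons <- "MKVLAW"
  m <- degenerate_hmm(cons)
  v <- viterbiLocal(m, cons)
  expected <- -sum(log(m@background[match(strsplit(cons, "")[[1]], AA20)]))
  expect_equal(v$score, expected, tolerance = 1e-6)
  expect_identical(c(v$start, v$end), c(1L, 6L))
  # forward also sums over partial-hit paths, so it strictly dominates here
  expect_gt(forwardLocal(m, cons), v$score)
  # with a single match state and one residue the path space is a singleton
  m1 <- degenerate_hmm("W")
  expect_equal(forwardLocal(m1, "W"), viterbiLocal(m1, "W")$score,
               tolerance = 1e-9)
})

test_that("viterbi and forward match brute-force enumeration on small cases", {
  set.seed(404)
  for (case in 1:40) {
    M <- sample(1:4, 1)
    L <- sample(1:6, 1)
    hmm <- random_hmm(M)
    seq <- random_protein(L)
    expect_equal(viterbiLocal(hmm, seq)$score, oracle_viterbi(hmm, seq),
                 tolerance = 1e-9)
    expect_equal(forwardLocal(hmm, seq), oracle_forward(hmm, seq),
                 tolerance = 1e-9)
  }
})

test_that("forward dominates viterbi and both reject empty sequences", {
  set.seed(5)
  for (i in 1:20) {
    hmm <- random_hmm(sample(2:5, 1))
    seq <- random_protein(sample(3:10, 1))
    expect_gte(forwardLocal(hmm, seq), viterbiLocal(hmm, seq)$score - 1e-12)
  }
  expect_error(viterbiLocal(random_hmm(2), ""), "empty")
  expect_error(forwardLocal(random_hmm(2), ""), "empty")
})

test_that("appending background residues never lowers the viterbi score", {
  set.seed(6)
  for (i in 1:25) {
    hmm <- random_hmm(sample(2:4, 1))
    seq <- random_protein(sample(3:8, 1))
    s0 <- viterbiLocal(hmm, seq)$score
    expect_gte(viterbiLocal(hmm, paste0(seq, random_protein(3)))$score,
               s0 - 1e-12)
    expect_gte(viterbiLocal(hmm, paste0(random_protein(3), seq))$score,
               s0 - 1e-12)
  }
})

test_that("equal-score hits resolve to the smallest start, then end", {
  m <- degenerate_hmm("MKVLAW")
  two <- "GGMKVLAWGGGGMKVLAWGG"
  v <- viterbiLocal(m, two)
  expect_identical(c(v$start, v$end), c(3L, 8L))
})

test_that("X residues score as background everywhere", {
  m <- degenerate_hmm("MKVLAW")
  with_x <- viterbiLocal(m, "XXMKVLAWXX")
  plain <- viterbiLocal(m, "GGMKVLAWGG")
  expect_equal(with_x$score, plain$score, tolerance = 1e-9)
})

test_that("BLOSUM62 hit scoring follows the matrix and gap costs", {
  expect_identical(blosumHitScore("ARN", "ARN"), 15)
  expect_identical(blosumHitScore("A", "R"), -1)
  # one-residue gap in a global alignment costs 11 + 1
  expect_identical(blosumHitScore("AR", "A"), 4 - 12)
  expect_identical(blosumHitScore("AXN", "ARN"), 4 + 0 + 6)
  expect_error(blosumHitScore("", "ARN"), "empty")
  set.seed(8)
  for (i in 1:50) {
    a <- random_protein(sample(2:8, 1))
    b <- random_protein(sample(2:8, 1))
    expect_identical(blosumHitScore(a, b), blosumHitScore(b, a))
  }
})

test_that("scanProtein finds planted domains and respects thresholds", {
  set.seed(21)
  ref <- makeReferenceMsa("NBS", nRows = 10L, divergence = 0.1, seed = 55L,
                          modelLength = 60L)
  model <- calibrateThreshold(buildProfileHMM(ref$msa, "NBS"), ref$rows)
  planted <- sampleFromHMM(ref$hmm, seed = 77L)
  bg1 <- random_protein(80, alphabet = c("G", "S", "T", "D", "E", "N", "Q"))
  bg2 <- random_protein(80, alphabet = c("G", "S", "T", "D", "E", "N", "Q"))
  protein <- paste0(bg1, planted, bg2)
  hits <- scanProtein(list(model), protein, proteinId = "p")
  expect_identical(nrow(hits), 1L)
  # the hit covers at least 80% of the planted interval
  p_start <- nchar(bg1) + 1L
  p_end <- nchar(bg1) + nchar(planted)
  overlap <- min(hits$end, p_end) - max(hits$start, p_start) + 1L
  expect_gte(overlap / nchar(planted), 0.8)
  expect_true(all(hits$blosum_score >= minBlosumScore(model)))
  expect_true(all(hits$logodds_score > 0))

  # a protein of 50 prolines triggers nothing
  expect_identical(nrow(scanProtein(list(model), strrep("P", 50))), 0L)

  # two planted copies, well separated, give two non-overlapping hits
  planted2 <- sampleFromHMM(ref$hmm, seed = 78L)
  protein2 <- paste0(bg1, planted, random_protein(100,
    alphabet = c("G", "S", "T", "D", "E", "N", "Q")), planted2, bg2)
  hits2 <- scanProtein(list(model), protein2, proteinId = "p2")
  expect_identical(nrow(hits2), 2L)
  expect_lt(hits2$end[1], hits2$start[2])
  # uncalibrated models are refused
  expect_error(scanProtein(list(buildProfileHMM(ref$msa, "NBS")), protein),
               "not calibrated")
})

test_that("resolveOverlaps merges same-label overlaps only", {
  hits <- data.frame(
    protein_id = "p",
    domain_label = c("NBS", "NBS", "LRR"),
    start = c(10L, 40L, 45L), end = c(50L, 90L, 120L),
    hmm_name = c("m1", "m2", "m3"),
    logodds_score = c(5, 7, 3), blosum_score = c(100, 90, 80),
    stringsAsFactors = FALSE)
  out <- resolveOverlaps(hits)
  expect_identical(nrow(out), 2L)
  nbs <- out[out$domain_label == "NBS", ]
  expect_identical(c(nbs$start, nbs$end), c(10L, 90L))
  expect_identical(nbs$logodds_score, 7)
  expect_identical(nbs$blosum_score, 100)
  expect_identical(nbs$hmm_name, "m2")
  # different labels are kept apart; disjoint same-label hits untouched
  expect_true("LRR" %in% out$domain_label)
  disjoint <- data.frame(
    protein_id = "p", domain_label = "NBS",
    start = c(10L, 60L), end = c(50L, 90L),
    hmm_name = "m", logodds_score = 1, blosum_score = 10,
    stringsAsFactors = FALSE)
  expect_identical(nrow(resolveOverlaps(disjoint)), 2L)
  # adjacency (end + 1 == start) is not an overlap
  adjacent <- transform(disjoint, start = c(10L, 51L))
  expect_identical(nrow(resolveOverlaps(adjacent)), 2L)
})

test_that("hit tables export to TSV and GFF3", {
  hits <- data.frame(
    protein_id = "p", domain_label = "NBS", start = 3L, end = 9L,
    hmm_name = "m", logodds_score = 12.3456, blosum_score = 42,
    stringsAsFactors = FALSE)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeHitsTsv(hits, tsv)
  back <- read.delim(tsv)
  expect_identical(back$logodds_score, 12.346)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeHitsGff3(hits, gff)
  lines <- readLines(gff)
  expect_true(any(grepl("protein_match", lines)))
  expect_true(any(grepl("^p\t", lines)))
})
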