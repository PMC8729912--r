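test_that("Laplace emission arithmetic matches the hand-computed example", {
  m <- buildProfileHMM(c(a = "MK", b = "MK"), "NBS", "CNL")
  expect_identical(nStates(m), 2L)
  expect_equal(matchEmissions(m)["1", "M"], 3 / 22)
  expect_equal(matchEmissions(m)["1", "A"], 1 / 22)
  expect_equal(matchEmissions(m)["2", "K"], 3 / 22)
  expect_identical(hmmName(m), "CNL_NBS_1")
})

test_that("gap-majority columns are not match states", {
  # column 2 has 3 gaps of 4 rows (0.75 >= 0.5): insert column
  msa <- c(a = "M-K", b = "M-K", c = "M-K", d = "MAK")
  m <- buildProfileHMM(msa, "LRR")
  expect_identical(nStates(m), 2L)
  # exactly half gaps is also excluded (rule is fraction < 0.5)
  msa2 <- c(a = "MAK", b = "M-K", c = "MAK", d = "M-K")
  expect_identical(nStates(buildProfileHMM(msa2, "LRR")), 2L)
  expect_error(buildProfileHMM(c(a = "--", b = "--", c = "-A"), "LRR"),
               "no match columns")
})

test_that("every probability vector of a built model is normalized", {
  set.seed(7)
  rows <- vapply(1:6, function(i) random_protein(30), character(1))
  names(rows) <- paste0("r", 1:6)
  m <- buildProfileHMM(rows, "KIN")
  expect_true(all(abs(rowSums(matchEmissions(m)) - 1) < 1e-9))
  tr <- m@transitions
  expect_true(all(abs(tr[, 1] + tr[, 2] + tr[, 3] - 1) < 1e-9))
  expect_true(all(abs(tr[, 4] + tr[, 5] - 1) < 1e-9))
  expect_true(all(abs(tr[, 6] + tr[, 7] - 1) < 1e-9))
  expect_equal(sum(m@background), 1)
  expect_true(all(m@matchEmissions > 0))
})

test_that("extractDomainSegments restricts columns and drops all-gap rows", {
  msa <- c(a = "MKVLAWCDEF", b = "MKVLAWCDEF", c = "MK---WCDEF")
  sub <- extractDomainSegments(msa, 3, 5)
  expect_identical(ncol(prgscan:::msa_matrix(sub)), 3L)
  expect_identical(nrow(prgscan:::msa_matrix(sub)), 2L)  # row c is all-gap inside 3-5
  # full-width region is the identity
  expect_identical(rownames(prgscan:::msa_matrix(extractDomainSegments(msa, 1, 10))),
                   c("a", "b", "c"))
  expect_error(extractDomainSegments(msa, 3, 11), "outside")
  expect_error(extractDomainSegments(c(a = "M-K", b = "M-K"), 2, 2),
               "fewer than 2 rows")
})

test_that("calibrateThreshold anchors below the weakest reference hit", {
  set.seed(11)
  ref <- makeReferenceMsa("NBS", nRows = 6L, divergence = 0.1, seed = 5L,
                          modelLength = 40L)
  m <- buildProfileHMM(ref$msa, "NBS")
  cal <- calibrateThreshold(m, ref$rows)
  # independent recomputation: floor(min - sd) of the reference hit scores
  cons <- consensusSequence(m)
  scores <- vapply(ref$rows, function(s) {
    h <- viterbiLocal(m, s)
    blosumHitScore(substr(s, h$start, h$end), cons)
  }, numeric(1))
  expect_identical(minBlosumScore(cal), floor(min(scores) - sd(scores)))
  expect_lte(minBlosumScore(cal), min(scores))   # references always pass
  expect_true(isCalibrated(cal))
  # recalibration with the same positives is idempotent
  expect_identical(minBlosumScore(calibrateThreshold(cal, ref$rows)),
                   minBlosumScore(cal))
  # a single positive gets the plain floored minimum
  one <- calibrateThreshold(m, ref$rows[1])
  h <- viterbiLocal(m, ref$rows[[1]])
  expect_identical(minBlosumScore(one),
                   floor(blosumHitScore(substr(ref$rows[[1]], h$start, h$end),
                                        cons)))
})

test_that("calibration fails loudly when a positive yields no hit", {
  m <- degenerate_hmm("MKVLAW")
  expect_error(calibrateThreshold(m, c("PPPPPP")), "no hit")
})

test_that("filterHMMs rejects non-relevant regions (criterion i)", {
  m <- degenerate_hmm("MKVLAW")
  m@domainLabel <- "TM"
  res <- filterHMMs(list(m), list("MKVLAW"))
  expect_length(res$retained, 0L)
  expect_identical(res$log$criterion, "i")
  expect_match(res$log$reason, "sliding-window")
})

test_that("filterHMMs rejects models that miss their own training set (ii)", {
  m <- degenerate_hmm("MKVLAWMKVLAW")
  res <- filterHMMs(list(m), list(c("MKVLAWMKVLAW", "PPPPPPPPPPPP")))
  expect_length(res$retained, 0L)
  expect_identical(res$log$criterion, "ii")
  ok <- filterHMMs(list(m), list(c("MKVLAWMKVLAW")))
  expect_length(ok$retained, 1L)
  expect_error(filterHMMs(list(m), list(character())), "no training")
})

test_that("filterHMMs keeps the better of candidate and legacy (iii)", {
  set.seed(23)
  fam <- makeReferenceMsa("NBS", nRows = 8L, divergence = 0.1, seed = 31L,
                          modelLength = 30L)
  new_model <- buildProfileHMM(fam$msa, "NBS", name = "new_NBS")
  # legacy built from an unrelated family cannot find these positives
  other <- makeReferenceMsa("NBS", nRows = 8L, divergence = 0.1, seed = 77L,
                            modelLength = 30L)
  legacy <- buildProfileHMM(other$msa, "NBS", name = "old_NBS")
  negatives <- vapply(1:8, function(i) random_protein(40), character(1))
  benchmark <- list(records = c(fam$rows, negatives),
                    labels = list(NBS = rep(c(TRUE, FALSE), each = 8)))
  res <- filterHMMs(list(new_model), list(fam$rows),
                    legacy = list(NBS = legacy), benchmark = benchmark)
  expect_length(res$retained, 1L)
  expect_identical(res$log$criterion, "iii")
  # swapped roles: the candidate trained on the other family loses
  res2 <- filterHMMs(list(legacy), list(other$rows),
                     legacy = list(NBS = new_model),
                     benchmark = benchmark)
  expect_length(res2$retained, 0L)
  expect_identical(res2$log$criterion, "iii")
})

test_that("model JSON serialization round-trips bit-identically", {
  set.seed(3)
  m <- calibrateThreshold(buildProfileHMM(
    makeReferenceMsa("LRR", nRows = 5L, divergence = 0.1, seed = 9L,
                     modelLength = 25L)$msa, "LRR"),
    makeReferenceMsa("LRR", nRows = 5L, divergence = 0.1, seed = 9L,
                     modelLength = 25L)$rows)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  writeHMM(m, f1)
  back <- readHMM(f1)
  writeHMM(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(back@matchEmissions, m@matchEmissions)
  expect_identical(minBlosumScore(back), minBlosumScore(m))
})

test_that("buildModelLibrary cuts regions, pools LYSM and names models", {
  set.seed(101)
  lysm_a <- makeReferenceMsa("LYSM", nRows = 4L, divergence = 0.05,
                             seed = 1L, modelLength = 20L)
  lysm_b <- makeReferenceMsa("LYSM", nRows = 4L, divergence = 0.05,
                             seed = 2L, modelLength = 20L)
  kin <- makeReferenceMsa("KIN", nRows = 4L, divergence = 0.05,
                          seed = 3L, modelLength = 30L)
  glue <- function(...) {
    ms <- list(...)
    mats <- lapply(ms, function(m) prgscan:::msa_matrix(m$msa))
    rows <- do.call(cbind, mats)
    out <- apply(rows, 1L, paste, collapse = "")
    names(out) <- paste0("s", seq_along(out))
    Biostrings::AAMultipleAlignment(Biostrings::AAStringSet(out))
  }
  wl <- ncol(prgscan:::msa_matrix(lysm_a$msa))
  wlb <- ncol(prgscan:::msa_matrix(lysm_b$msa))
  msas <- list(LYK = glue(lysm_a, kin), LYP = glue(lysm_b, kin))
  regions <- data.frame(
    msa_id = c("LYK", "LYK", "LYP"),
    domain_label = c("LYSM", "KIN", "LYSM"),
    col_start = c(1L, wl + 1L, 1L),
    col_end = c(wl, wl + ncol(prgscan:::msa_matrix(kin$msa)), wlb),
    subtype = NA_character_, stringsAsFactors = FALSE)
  lib <- buildModelLibrary(msas, regions)
  nms <- names(lib$models)
  expect_true("LYK_LYSM_1" %in% nms)
  expect_true("LYP_LYSM_1" %in% nms)
  expect_true("LYK_KIN_1" %in% nms)
  expect_true("pooled_LYSM_1" %in% nms)
  expect_true(all(vapply(lib$models, isCalibrated, logical(1))))
})
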