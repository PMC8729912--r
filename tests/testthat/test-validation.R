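test_that("criteria match the identical / equal-or-better definitions", {
  ref <- list(p1 = c("NBS", "LRR"), p2 = c("NBS", "LRR"),
              p3 = c("NBS", "LRR"))
  pred <- list(p1 = c("NBS", "LRR"),          # identical
               p2 = c("TIR", "NBS", "LRR"),   # superset
               p3 = c("NBS"))                 # subset
  out <- compareToReference(pred, ref)
  expect_identical(out$criterion1, c(TRUE, FALSE, FALSE))
  expect_identical(out$criterion2, c(TRUE, TRUE, FALSE))
})

test_that("evaluation is restricted to the five HMM resistance domains", {
  # CC/TM/KIN differences are invisible to the criteria
  ref <- list(p1 = c("NBS", "LRR"))
  pred <- list(p1 = c("NBS", "LRR", "KIN"))
  out <- compareToReference(pred, ref)
  expect_true(out$criterion1)
  # predicted-only proteins are excluded with a message
  expect_message(
    out2 <- compareToReference(list(p1 = "NBS", novel = "LRR"),
                               list(p1 = "NBS")),
    "absent from the reference")
  expect_identical(out2$protein_id, "p1")
  # reference proteins without predictions count against criterion 2
  out3 <- compareToReference(list(), list(p1 = "NBS"))
  expect_false(out3$criterion2)
})

test_that("confusion metrics reproduce the stated formulas exactly", {
  # construct sets realizing TP=5, FP=1, TN=3, FN=1 on one domain
  ids <- paste0("p", 1:10)
  ref <- setNames(c(rep(list("NBS"), 6), rep(list(character()), 4)), ids)
  pred <- setNames(c(rep(list("NBS"), 5), list(character()),  # 5 TP, 1 FN
                     list("NBS"), rep(list(character()), 3)), # 1 FP, 3 TN
                   ids)
  out <- confusionMetrics(pred, ref, vocabulary = "NBS")
  row <- out$per_domain
  expect_identical(c(row$TP, row$FP, row$TN, row$FN), c(5L, 1L, 3L, 1L))
  expect_equal(row$accuracy, 0.8)
  expect_equal(row$precision, 5 / 6)
  expect_equal(row$sensitivity, 5 / 6)
  expect_equal(row$specificity, 0.75)
  expect_equal(row$f_score, 5 / 6)
})

test_that("perfect agreement scores 1 everywhere it is defined", {
  ref <- list(p1 = c("TIR", "NBS"), p2 = "LRR", p3 = character())
  out <- confusionMetrics(ref, ref)
  expect_true(all(out$pooled[, c("accuracy", "precision", "sensitivity",
                                 "f_score")] == 1))
})

test_that("zero-denominator metrics are reported as NA, never 0", {
  ref <- list(p1 = character(), p2 = character())
  pred <- list(p1 = character(), p2 = character())
  out <- confusionMetrics(pred, ref, vocabulary = "NBS")
  row <- out$per_domain
  expect_true(is.na(row$precision))
  expect_true(is.na(row$sensitivity))
  expect_true(is.na(row$f_score))
  expect_identical(row$accuracy, 1)      # TN-only cells are still accurate
  expect_identical(row$specificity, 1)
})

test_that("criterion 1 implies criterion 2 on randomized set pairs", {
  set.seed(99)
  domains <- c("TIR", "NBS", "LRR", "LYSM", "LECM")
  for (i in 1:120) {
    ids <- paste0("p", 1:8)
    ref <- setNames(lapply(ids, function(i)
      sample(domains, sample(0:3, 1))), ids)
    pred <- setNames(lapply(ids, function(i)
      sample(domains, sample(0:3, 1))), ids)
    out <- compareToReference(pred, ref)
    expect_true(all(out$criterion2[out$criterion1]))
  }
})

test_that("swapping predictions and reference swaps FP with FN", {
  set.seed(123)
  domains <- c("TIR", "NBS", "LRR")
  ids <- paste0("p", 1:12)
  ref <- setNames(lapply(ids, function(i) sample(domains, sample(0:2, 1))),
                  ids)
  pred <- setNames(lapply(ids, function(i) sample(domains, sample(0:2, 1))),
                   ids)
  a <- confusionMetrics(pred, ref, domains)$pooled
  b <- confusionMetrics(ref, pred, domains)$pooled
  expect_identical(a$FP, b$FN)
  expect_identical(a$FN, b$FP)
  expect_identical(a$TP, b$TP)
  expect_equal(a$accuracy, b$accuracy)
})

test_that("validationReport tallies criteria per predicted class", {
  ann <- structure(list(
    hits = data.frame(
      protein_id = c("t1", "t1", "t1", "r1", "r1", "r1", "x1"),
      domain_label = c("TIR", "NBS", "LRR", "LRR", "TM", "KIN", "NBS"),
      start = 1L, end = 2L, hmm_name = "m", logodds_score = 1,
      blosum_score = 1, stringsAsFactors = FALSE),
    classes = data.frame(
      protein_id = c("t1", "r1", "x1"),
      class_label = c("TNL", "RLK", "NONCANONICAL"),
      code = c("TNL", "LKM", "N"),
      domains_present = c("LRR;NBS;TIR", "KIN;LRR;TM", "NBS"),
      n_hits = c(3L, 3L, 1L), stringsAsFactors = FALSE)),
    class = "prgscanAnnotation")
  ref <- list(t1 = c("TIR", "NBS", "LRR"), r1 = c("LRR"), x1 = c("NBS", "LRR"))
  rep <- validationReport(ann, ref)
  expect_s3_class(rep$criteria, "data.frame")
  tnl <- rep$by_class[rep$by_class$class_label == "TNL", ]
  expect_identical(c(tnl$n_total, tnl$n_criterion1, tnl$n_criterion2),
                   c(1L, 1L, 1L))
  nc <- rep$by_class[rep$by_class$class_label == "NONCANONICAL", ]
  expect_identical(c(nc$n_criterion1, nc$n_criterion2), c(0L, 0L))
  # criterion counts respect the subset relation classwide
  expect_true(all(rep$by_class$n_criterion1 <= rep$by_class$n_criterion2))
  d <- withr::local_tempdir()
  writeValidationReport(rep, d)
  expect_true(file.exists(file.path(d, "validation.json")))
  expect_true(file.exists(file.path(d, "confusion.tsv")))
})
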