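# Independent oracles and model builders used across the test files.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Construct a ProfileHMM directly from raw matrices (validity enforced).
make_hmm <- function(match_em, transitions, background,
                     insert_em = background, label = "NBS",
                     origin = "pooled", name = "test_model",
                     min_blosum = NA_real_) {
  colnames(match_em) <- AA20
  rownames(match_em) <- as.character(seq_len(nrow(match_em)))
  colnames(transitions) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  names(background) <- AA20
  names(insert_em) <- AA20
  new("ProfileHMM", name = name, classOfOrigin = origin, domainLabel = label,
      matchEmissions = match_em, insertEmissions = insert_em,
      transitions = transitions, background = background,
      minBlosumScore = min_blosum)
}

# Random fully-parameterized model (Dirichlet-like draws, all probs > 0).
random_hmm <- function(M, label = "NBS") {
  rdir <- function(k) { x <- stats::rgamma(k, 1) + 1e-6; x / sum(x) }
  match_em <- t(vapply(seq_len(M), function(j) rdir(20), numeric(20)))
  tr <- t(vapply(seq_len(M), function(j) {
    c(rdir(3), rdir(2), rdir(2))
  }, numeric(7)))
  make_hmm(match_em, tr, rdir(20), rdir(20), label = label)
}

# Near-degenerate model: consensus emissions and match-match transitions
# carry essentially all probability mass (validity requires > 0 everywhere).
degenerate_hmm <- function(consensus, background = rep(1 / 20, 20)) {
  M <- nchar(consensus)
  chars <- strsplit(consensus, "")[[1]]
  eps <- 1e-12
  match_em <- matrix(eps, nrow = M, ncol = 20)
  match_em[cbind(seq_len(M), match(chars, AA20))] <- 1 - 19 * eps
  tr <- matrix(rep(c(1 - 2 * eps, eps, eps,
                     1 - eps, eps, 1 - eps, eps), each = M), nrow = M)
  make_hmm(match_em, tr, background)
}

# Brute-force enumeration of every local alignment path: the independent
# oracle for viterbiLocal / forwardLocal. Paths start and end in a match
# state; match/insert consume one residue, delete none; transitions
# MM, MI, MD, IM, II, DM, DD.
oracle_path_scores <- function(hmm, seq) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  M <- nrow(hmm@matchEmissions)
  idx <- match(chars, AA20)
  lom <- function(i, j) {
    if (is.na(idx[i])) 0
    else log(hmm@matchEmissions[j, idx[i]]) - log(hmm@background[idx[i]])
  }
  loi <- function(i) {
    if (is.na(idx[i])) 0
    else log(hmm@insertEmissions[idx[i]]) - log(hmm@background[idx[i]])
  }
  lt <- log(hmm@transitions)
  scores <- numeric(0)
  rec_m <- function(i, j, sc) {
    scores[[length(scores) + 1L]] <<- sc          # path may exit here
    if (i < L && j < M) rec_m(i + 1L, j + 1L, sc + lt[j, "MM"] + lom(i + 1L, j + 1L))
    if (i < L)          rec_i(i + 1L, j,      sc + lt[j, "MI"] + loi(i + 1L))
    if (j < M)          rec_d(i,      j + 1L, sc + lt[j, "MD"])
  }
  rec_i <- function(i, j, sc) {
    if (i < L && j < M) rec_m(i + 1L, j + 1L, sc + lt[j, "IM"] + lom(i + 1L, j + 1L))
    if (i < L)          rec_i(i + 1L, j,      sc + lt[j, "II"] + loi(i + 1L))
  }
  rec_d <- function(i, j, sc) {
    if (i < L && j < M) rec_m(i + 1L, j + 1L, sc + lt[j, "DM"] + lom(i + 1L, j + 1L))
    if (j < M)          rec_d(i,      j + 1L, sc + lt[j, "DD"])
  }
  for (s in seq_len(L)) {
    for (j0 in seq_len(M)) {
      rec_m(s, j0, lom(s, j0))
    }
  }
  scores
}

oracle_viterbi <- function(hmm, seq) max(oracle_path_scores(hmm, seq))
oracle_forward <- function(hmm, seq) logsumexp(oracle_path_scores(hmm, seq))

random_protein <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Synthetic coiled-coil model with a transparent structure: leucine-zipper
# core positions favoured, helix breakers penalized.
test_coils_model <- function(window = 21L) {
  prop <- matrix(0.9, nrow = 20, ncol = 7, dimnames = list(AA20, letters[1:7]))
  prop[c("L", "I", "V", "M"), ] <- 0.45
  prop[c("L", "I", "V", "M"), c(1, 4)] <- c(4.0, 2.6, 1.9, 2.2)
  prop[c("E", "K", "Q", "R"), ] <- 1.55
  prop[c("E", "K", "Q", "R"), c(1, 4)] <- 0.35
  prop["P", ] <- 0.1
  prop["G", ] <- 0.5
  new("CoilsModel", propensities = prop, window = as.integer(window),
      gaussCc = c(1.8, 0.2), gaussGlob = c(0.85, 0.2),
      pCutoff = 0.5, minRun = 14L)
}
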