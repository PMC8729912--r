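# Internal constants and small helpers shared across modules.

# Canonical amino-acid order (BLOSUM matrix order).
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Resistance domains detected by profile HMMs, plus the two segment
# predictors (CC, TM) that never get an HMM of their own.
HMM_DOMAINS     <- c("TIR", "NBS", "LRR", "LYSM", "LECM", "KIN")
SEGMENT_DOMAINS <- c("CC", "TM")
ALL_DOMAINS     <- c(SEGMENT_DOMAINS[1], "TIR", "NBS", "LRR", "LYSM", "LECM",
                     "KIN", SEGMENT_DOMAINS[2])

CANONICAL_CLASSES <- c("CNL", "TNL", "RLK", "RLP", "LYK", "LYP", "LECRK")

# One-letter codes used in compact architecture strings, in display order.
DOMAIN_CODES <- c(CC = "C", TIR = "T", NBS = "N", LRR = "L",
                  LYSM = "Y", LECM = "E", KIN = "K", TM = "M")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats setNames
aa_index <- function(residues) {
  match(residues, AA_ALPHABET)
}

# Split a sequence-like object into a character vector of single residues.
seq_chars <- function(x) {
  strsplit(as.character(x), "", fixed = TRUE)[[1]]
}

assert_protein_sequence <- function(seq, what = "sequence", allow_stop = FALSE) {
  chars <- seq_chars(seq)
  if (length(chars) == 0L) {
    stop(what, " is empty", call. = FALSE)
  }
  ok <- c(AA_ALPHABET, "X", if (allow_stop) "*")
  bad <- setdiff(unique(chars), ok)
  if (length(bad) > 0L) {
    stop(what, " contains characters outside the amino-acid alphabet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(chars)
}

# Run an expression with a temporarily seeded RNG, restoring the caller's
# RNG state afterwards so library calls never perturb user simulations.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic number formatting for TSV output (criterion: byte-identical
# reruns), avoiding locale- or precision-dependent printing.
fmt_num <- function(x, digits = 3) {
  formatC(x, format = "f", digits = digits)
}
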