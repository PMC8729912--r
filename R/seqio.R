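#' Read a protein FASTA file
#'
#' Reads protein sequences into an [Biostrings::AAStringSet], enforcing the
#' contract the annotation pipeline relies on: unique non-empty identifiers,
#' non-empty uppercased sequences, and an alphabet restricted to the twenty
#' amino acids plus `X` (unknown) and, optionally, `*` (stop; only meaningful
#' transiently after translation).
#'
#' @param path Path to a FASTA file.
#' @param allowStop Accept `*` characters (default `FALSE`).
#' @return An `AAStringSet`, one element per record, input order preserved.
#'   Names hold the identifier (first whitespace-delimited token); the full
#'   header line is kept in the `description` metadata column.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 a kinase", "MKV"), f)
#' readFasta(f)
readFasta <- function(path, allowStop = FALSE) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  seqs <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        stop("FASTA file contains invalid sequence characters: ", path,
             call. = FALSE)
      }
      warning(w)
    })
  if (length(seqs) == 0L) {
    stop("FASTA file contains no records: ", path, call. = FALSE)
  }
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids))) {
    stop("FASTA record with empty identifier in ", path, call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- Biostrings::AAStringSet(toupper(as.character(seqs)))
  for (k in seq_along(seqs)) {
    assert_protein_sequence(seqs[[k]], what = paste0("sequence '", ids[k], "'"),
                            allow_stop = allowStop)
  }
  names(seqs) <- ids
  S4Vectors::mcols(seqs)$description <- headers
  seqs
}

#' Write sequences to FASTA
#'
#' @param records An `AAStringSet` (or named character vector).
#' @param path Output path.
#' @param wrap Line width for the sequence lines (default 60).
#' @return Invisibly, `path`.
#' @export
writeFasta <- function(records, path, wrap = 60L) {
  if (is.character(records)) records <- Biostrings::AAStringSet(records)
  if (wrap < 1L) stop("wrap must be a positive integer", call. = FALSE)
  if (length(records) == 0L) {
    warning("writing an empty FASTA file: ", path, call. = FALSE)
    file.create(path)
    return(invisible(path))
  }
  Biostrings::writeXStringSet(records, filepath = path, width = wrap)
  invisible(path)
}

#' Read an aligned FASTA file as a multiple sequence alignment
#'
#' @param path Path to an aligned FASTA file (gap character `-`).
#' @return An [Biostrings::AAMultipleAlignment].
#' @details Row lengths are checked before construction so that ragged input
#'   is reported with the offending identifiers and widths; an alignment must
#'   have at least two rows. Ungapping any row must yield a valid protein
#'   sequence.
#' @export
readMsa <- function(path) {
  if (!file.exists(path)) {
    stop("alignment file not found: ", path, call. = FALSE)
  }
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) < 2L) {
    stop("alignment must have at least 2 rows, found ", length(seqs),
         " in ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  w <- Biostrings::width(seqs)
  if (length(unique(w)) > 1L) {
    off <- paste(sprintf("%s (%d)", ids, w), collapse = ", ")
    stop("alignment rows differ in width: ", off, call. = FALSE)
  }
  seqs <- Biostrings::AAStringSet(toupper(as.character(seqs)))
  names(seqs) <- ids
  for (k in seq_along(seqs)) {
    ungapped <- gsub("-", "", as.character(seqs[[k]]), fixed = TRUE)
    assert_protein_sequence(ungapped, what = paste0("row '", ids[k], "'"))
  }
  Biostrings::AAMultipleAlignment(seqs)
}

# Alignment as a plain character matrix (rows = sequences).
msa_matrix <- function(msa) {
  if (is(msa, "AAMultipleAlignment")) {
    msa <- Biostrings::unmasked(msa)
  }
  if (is(msa, "XStringSet")) {
    sets <- as.character(msa)
  } else if (is.character(msa)) {
    sets <- msa
  } else {
    stop("unsupported alignment representation: ", class(msa)[1], call. = FALSE)
  }
  if (length(unique(nchar(sets))) > 1L) {
    stop("alignment rows differ in width", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(sets, "", fixed = TRUE))
  rownames(m) <- names(sets)
  m
}

#' Remove gaps from an alignment row
#'
#' @param x A character scalar or `AAString` with `-` gaps.
#' @return The ungapped sequence as a character scalar.
#' @export
ungap <- function(x) {
  gsub("-", "", as.character(x), fixed = TRUE)
}

#' Six-frame translation of a nucleotide sequence
#'
#' Translates all three forward frames and the three frames of the reverse
#' complement with the standard genetic code, so that DNA input can be
#' annotated the same way as protein input. Codons containing `N` translate
#' to `X`; internal stops are kept as `*` and can be split into scan-ready
#' segments with [orfSegments()].
#'
#' @param dna A character scalar or `DNAString` over `A C G T N`.
#' @param id Identifier prefix for the output records.
#' @return An `AAStringSet` of exactly six records named
#'   `{id}_frame+1..+3` and `{id}_frame-1..-3`, possibly of zero width for
#'   inputs shorter than a codon.
#' @export
#' @examples
#' translateFrames("ATGAAA")
translateFrames <- function(dna, id = "seq") {
  dna <- toupper(as.character(dna))
  bad <- setdiff(unique(seq_chars(dna)), c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L) {
    stop("non-nucleotide characters in input: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x <- Biostrings::DNAString(dna)
  rc <- Biostrings::reverseComplement(x)
  frame_of <- function(s, off) {
    n <- length(s) - off
    n <- n - n %% 3L
    if (n <= 0L) return(Biostrings::AAString(""))
    Biostrings::translate(Biostrings::subseq(s, start = off + 1L, width = n),
                          if.fuzzy.codon = "X")
  }
  out <- Biostrings::AAStringSet(c(
    lapply(0:2, function(o) frame_of(x, o)),
    lapply(0:2, function(o) frame_of(rc, o))
  ))
  names(out) <- paste0(id, "_frame", c("+1", "+2", "+3", "-1", "-2", "-3"))
  if (all(Biostrings::width(out) == 0L)) {
    warning("input shorter than one codon; all frames are empty", call. = FALSE)
  }
  out
}

#' Split translated frames into scan-ready segments
#'
#' `*` terminates a translated product: each frame is cut at stop codons and
#' only segments of at least `minLen` residues are kept for scanning, which
#' avoids spending scan time on nonsense products.
#'
#' @param frames An `AAStringSet` as returned by [translateFrames()] (may
#'   contain `*`).
#' @param minLen Minimum segment length in residues (default 30).
#' @return An `AAStringSet` of stop-free segments named
#'   `{frame}_seg{k}`.
#' @export
orfSegments <- function(frames, minLen = 30L) {
  out <- list()
  for (k in seq_along(frames)) {
    parts <- strsplit(as.character(frames[[k]]), "*", fixed = TRUE)[[1]]
    keep <- which(nchar(parts) >= minLen)
    for (i in seq_along(keep)) {
      nm <- paste0(names(frames)[k], "_seg", i)
      out[[nm]] <- parts[keep[i]]
    }
  }
  if (length(out) == 0L) {
    return(Biostrings::AAStringSet())
  }
  Biostrings::AAStringSet(unlist(out))
}
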