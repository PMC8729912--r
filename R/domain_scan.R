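# Log-odds matrices for one (model, sequence) pair. X (and any non-standard
# residue, e.g. the transient mask character) scores as background: log-odds 0.
logodds_inputs <- function(hmm, seq) {
  chars <- seq_chars(seq)
  idx <- aa_index(chars)
  M <- nStates(hmm)
  lom <- matrix(0, nrow = length(chars), ncol = M)
  known <- !is.na(idx)
  if (any(known)) {
    lom[known, ] <- log(t(hmm@matchEmissions[, idx[known], drop = FALSE])) -
      log(hmm@background[idx[known]])
  }
  loi <- numeric(length(chars))
  loi[known] <- log(hmm@insertEmissions[idx[known]]) -
    log(hmm@background[idx[known]])
  list(lom = lom, loi = loi, lt = log(hmm@transitions))
}

#' Best local alignment of a profile HMM to a sequence (Viterbi)
#'
#' Finds the maximal log-odds local alignment with free start and end in both
#' the sequence and the model: a path enters any match state at any residue,
#' moves through match/insert/delete states, and exits from any match state.
#' Log-odds are emission log-probabilities minus background
#' log-probabilities; transitions are charged in log space; residues outside
#' the hit score zero. Ties are broken towards the smallest start, then the
#' smallest end.
#'
#' @param hmm A [ProfileHMM-class].
#' @param seq Protein sequence (character scalar or `AAString`).
#' @return A list with `score` (nats), `start` and `end` (1-based inclusive
#'   protein coordinates).
#' @export
viterbiLocal <- function(hmm, seq) {
  seq <- as.character(seq)
  if (nchar(seq) < 1L) stop("empty sequence", call. = FALSE)
  inp <- logodds_inputs(hmm, seq)
  .viterbi_local_cpp(inp$lom, inp$loi, inp$lt)
}

#' Total local log-odds of a profile HMM against a sequence (forward)
#'
#' Sums over all local alignments in the same path space as
#' [viterbiLocal()], in log space. Always at least the Viterbi score; equal
#' to it when a single path carries all probability mass.
#'
#' @inheritParams viterbiLocal
#' @return Total log-odds in nats.
#' @export
forwardLocal <- function(hmm, seq) {
  seq <- as.character(seq)
  if (nchar(seq) < 1L) stop("empty sequence", call. = FALSE)
  inp <- logodds_inputs(hmm, seq)
  .forward_local_cpp(inp$lom, inp$loi, inp$lt)
}

# BLOSUM62 with the X row/column zeroed, built once per session.
blosum62_x0 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62
      m["X", ] <- 0
      m[, "X"] <- 0
      cache <<- m
    }
    cache
  }
})

#' BLOSUM62 score of a hit against a model consensus
#'
#' Global alignment score of the hit subsequence against the model's
#' consensus string under BLOSUM62 with affine gap penalties (open 11,
#' extend 1, i.e. a length-k gap costs 11 + k). `X` scores 0 against every
#' residue.
#'
#' @param hitSeq Hit subsequence (character scalar or `AAString`).
#' @param consensus Model consensus (see [consensusSequence()]).
#' @return Integer alignment score.
#' @export
#' @examples
#' blosumHitScore("ARN", "ARN") # 4 + 5 + 6
blosumHitScore <- function(hitSeq, consensus) {
  hitSeq <- as.character(hitSeq)
  consensus <- as.character(consensus)
  if (nchar(hitSeq) == 0L || nchar(consensus) == 0L) {
    stop("empty input to blosumHitScore", call. = FALSE)
  }
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(hitSeq), Biostrings::AAString(consensus),
    substitutionMatrix = blosum62_x0(),
    gapOpening = 11, gapExtension = 1,
    type = "global", scoreOnly = TRUE)
}

#' Scan one protein with a set of calibrated models
#'
#' For each model, the best local hit is found with [viterbiLocal()]; if its
#' log-odds score is positive the hit region is masked and the scan repeats,
#' so multiple non-overlapping occurrences are reported. Each hit is scored
#' against the model consensus with [blosumHitScore()] and dropped when it
#' falls below the model's calibrated minimum. Survivors are sorted by
#' `(start, domain_label)`.
#'
#' @param models List of calibrated [ProfileHMM-class] objects.
#' @param protein Protein sequence (character scalar or `AAString`).
#' @param proteinId Identifier used in the output table.
#' @param maxHitsPerModel Safety cap on mask-and-rescan iterations per model
#'   (default 15).
#' @return A `data.frame` with columns `protein_id`, `domain_label`,
#'   `start`, `end`, `hmm_name`, `logodds_score`, `blosum_score`.
#' @export
scanProtein <- function(models, protein, proteinId = "protein",
                        maxHitsPerModel = 15L) {
  protein <- as.character(protein)
  assert_protein_sequence(protein, what = paste0("protein '", proteinId, "'"))
  hits <- list()
  for (hmm in models) {
    if (!isCalibrated(hmm)) {
      stop("model '", hmm@name, "' is not calibrated", call. = FALSE)
    }
    cons <- consensusSequence(hmm)
    masked <- protein
    for (it in seq_len(maxHitsPerModel)) {
      hit <- viterbiLocal(hmm, masked)
      if (hit$score <= 0) break
      sub <- substr(protein, hit$start, hit$end)
      bsc <- blosumHitScore(sub, cons)
      if (bsc >= hmm@minBlosumScore) {
        hits[[length(hits) + 1L]] <- data.frame(
          protein_id = proteinId,
          domain_label = hmm@domainLabel,
          start = hit$start, end = hit$end,
          hmm_name = hmm@name,
          logodds_score = hit$score,
          blosum_score = bsc,
          stringsAsFactors = FALSE)
      }
      # mask the hit (with '#', which scores as background) and rescan
      substr(masked, hit$start, hit$end) <-
        strrep("#", hit$end - hit$start + 1L)
    }
  }
  if (length(hits) == 0L) {
    return(empty_hits())
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$domain_label), , drop = FALSE]
}

empty_hits <- function() {
  data.frame(protein_id = character(), domain_label = character(),
             start = integer(), end = integer(), hmm_name = character(),
             logodds_score = numeric(), blosum_score = numeric(),
             stringsAsFactors = FALSE)
}

#' Merge overlapping same-domain hits
#'
#' Hits on one protein that share a domain label and overlap by at least one
#' residue are merged to their union interval, keeping the maximum of each
#' score; hits with different labels are never merged.
#'
#' @param hits Hit `data.frame` as from [scanProtein()] (one protein).
#' @return The merged hit `data.frame`, sorted by `(start, domain_label)`.
#' @export
resolveOverlaps <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  if (length(unique(hits$protein_id)) > 1L) {
    stop("resolveOverlaps expects hits of a single protein", call. = FALSE)
  }
  out <- lapply(split(hits, hits$domain_label), function(h) {
    ir <- IRanges::IRanges(start = h$start, end = h$end)
    # min.gapwidth = 0: merge only true overlaps, not mere adjacency
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    ov <- IRanges::findOverlaps(ir, red)
    grp <- S4Vectors::subjectHits(ov)
    do.call(rbind, lapply(seq_along(red), function(g) {
      members <- h[grp == g, , drop = FALSE]
      data.frame(protein_id = members$protein_id[1],
                 domain_label = members$domain_label[1],
                 start = IRanges::start(red)[g],
                 end = IRanges::end(red)[g],
                 hmm_name = members$hmm_name[which.max(members$logodds_score)],
                 logodds_score = max(members$logodds_score),
                 blosum_score = max(members$blosum_score),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$start, out$domain_label), , drop = FALSE]
}

#' Write a hit table as TSV
#'
#' @param hits Hit `data.frame`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeHitsTsv <- function(hits, path) {
  out <- hits
  out$logodds_score <- fmt_num(out$logodds_score, 3)
  out$blosum_score <- as.integer(round(out$blosum_score))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export hits as GFF3 (protein coordinates)
#'
#' One feature per hit; the GFF score column carries the BLOSUM62 hit score.
#'
#' @param hits Hit `data.frame`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeHitsGff3 <- function(hits, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("GenomicRanges", quietly = TRUE)) {
    stop("GFF3 export needs the rtracklayer and GenomicRanges packages",
         call. = FALSE)
  }
  if (nrow(hits) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = hits$protein_id,
    ranges = IRanges::IRanges(start = hits$start, end = hits$end),
    type = "protein_match",
    source = "prgscan",
    score = as.numeric(hits$blosum_score),
    Name = hits$domain_label,
    Target = hits$hmm_name)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
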