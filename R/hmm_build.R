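#' Read a domain-region table
#'
#' The region table maps alignment column ranges to domain labels: one row per
#' domain region with columns `msa_id`, `domain_label`, `col_start`, `col_end`
#' and optionally `subtype` (e.g. `legume` or `bulb` for lectin-motif
#' subgroups).
#'
#' @param path Path to a tab-separated file with a header line.
#' @return A `data.frame` with the columns above (`subtype` is `NA` when
#'   absent).
#' @export
readDomainRegions <- function(path) {
  if (!file.exists(path)) {
    stop("domain-region table not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("msa_id", "domain_label", "col_start", "col_end")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("domain-region table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"subtype" %in% names(df)) df$subtype <- NA_character_
  if (any(df$col_start < 1L) || any(df$col_start > df$col_end)) {
    stop("region columns must satisfy 1 <= col_start <= col_end", call. = FALSE)
  }
  df[, c(need, "subtype")]
}

#' Extract the alignment columns of one domain region
#'
#' Restricts an alignment to the column range of a domain region. Rows that
#' are entirely gaps inside the region carry no information about the domain
#' and are dropped (with a message naming them).
#'
#' @param msa An `AAMultipleAlignment` (or `AAStringSet`/character of equal
#'   widths).
#' @param colStart,colEnd 1-based inclusive alignment columns.
#' @return An `AAMultipleAlignment` of width `colEnd - colStart + 1`.
#' @export
extractDomainSegments <- function(msa, colStart, colEnd) {
  m <- msa_matrix(msa)
  W <- ncol(m)
  if (colStart < 1L || colEnd > W || colStart > colEnd) {
    stop("region [", colStart, ", ", colEnd,
         "] outside alignment of width ", W, call. = FALSE)
  }
  sub <- m[, colStart:colEnd, drop = FALSE]
  all_gap <- apply(sub, 1L, function(r) all(r == "-"))
  if (any(all_gap)) {
    dropped <- rownames(sub)[all_gap] %||% which(all_gap)
    message("dropping ", sum(all_gap), " all-gap row(s) in region [",
            colStart, ", ", colEnd, "]: ", paste(dropped, collapse = ", "))
    sub <- sub[!all_gap, , drop = FALSE]
  }
  if (nrow(sub) < 2L) {
    stop("fewer than 2 rows survive in region [", colStart, ", ", colEnd, "]",
         call. = FALSE)
  }
  rows <- apply(sub, 1L, paste, collapse = "")
  out <- Biostrings::AAStringSet(rows)
  names(out) <- rownames(sub)
  Biostrings::AAMultipleAlignment(out)
}

#' Build a profile HMM from a domain sub-alignment
#'
#' Alignment columns with a gap fraction below 0.5 become match states.
#' Emission and transition probabilities are Laplace-smoothed relative
#' frequencies, `(count + 1) / (total + k)` with `k` the number of outcomes
#' (20 residues for emissions; 3 or 2 outgoing transitions per state class).
#' The background distribution is the Laplace-smoothed residue frequency of
#' the whole sub-alignment; insert states emit the background. `X` residues
#' are treated as unobserved (they contribute to no emission count and score
#' as background during alignment).
#'
#' @param subMsa An `AAMultipleAlignment` (or equal-width `AAStringSet` /
#'   character vector) restricted to one domain region.
#' @param domainLabel Domain the model will detect.
#' @param classOfOrigin PRG class of the source alignment (or `"pooled"`).
#' @param name Model name; defaults to `{classOfOrigin}_{domainLabel}_1`.
#' @return An uncalibrated [ProfileHMM-class].
#' @export
#' @examples
#' m <- buildProfileHMM(c(a = "MK", b = "MK"), "NBS", "CNL")
#' matchEmissions(m)["1", "M"] # (2 + 1) / (2 + 20)
buildProfileHMM <- function(subMsa, domainLabel, classOfOrigin = "pooled",
                            name = NULL) {
  m <- msa_matrix(subMsa)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 alignment rows", call. = FALSE)
  gap_frac <- colMeans(m == "-")
  match_cols <- which(gap_frac < 0.5)
  M <- length(match_cols)
  if (M == 0L) {
    stop("no match columns: every column is gap-majority", call. = FALSE)
  }

  # --- emissions ---
  match_em <- matrix(1, nrow = M, ncol = 20,
                     dimnames = list(as.character(seq_len(M)), AA_ALPHABET))
  for (s in seq_len(M)) {
    col <- m[, match_cols[s]]
    tab <- table(factor(col[col %in% AA_ALPHABET], levels = AA_ALPHABET))
    match_em[s, ] <- (as.numeric(tab) + 1) / (sum(tab) + 20)
  }
  res <- m[m %in% AA_ALPHABET]
  btab <- table(factor(res, levels = AA_ALPHABET))
  background <- (as.numeric(btab) + 1) / (sum(btab) + 20)
  names(background) <- AA_ALPHABET

  # --- transitions from per-row state paths ---
  # state sequence per row: match column + residue -> M, match column + gap
  # -> D, non-match column + residue -> I (assigned to the preceding match
  # state).
  cnt <- matrix(0, nrow = M, ncol = 7,
                dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  is_match_col <- logical(ncol(m))
  is_match_col[match_cols] <- TRUE
  state_of_col <- integer(ncol(m))          # match-state index per column
  state_of_col[match_cols] <- seq_len(M)
  last_state <- cumsum(is_match_col)        # preceding (or current) match state
  for (r in seq_len(n)) {
    prev_type <- NA_character_              # "M", "I" or "D"
    prev_state <- 0L
    for (cidx in seq_len(ncol(m))) {
      ch <- m[r, cidx]
      if (is_match_col[cidx]) {
        type <- if (ch == "-") "D" else "M"
        state <- state_of_col[cidx]
      } else {
        if (ch == "-") next                 # gap in insert column: no state
        type <- "I"
        state <- last_state[cidx]
        if (state == 0L) next               # insert before first match state
      }
      if (!is.na(prev_type) && prev_state >= 1L) {
        key <- paste0(prev_type, type)
        if (key %in% colnames(cnt)) {
          cnt[prev_state, key] <- cnt[prev_state, key] + 1
        }
      }
      if (type == "I" && !is.na(prev_type) && prev_state == 0L) {
        # unreachable: guarded above
      }
      prev_type <- type
      prev_state <- state
    }
  }
  tr <- matrix(0, nrow = M, ncol = 7,
               dimnames = list(NULL, colnames(cnt)))
  tr[, c("MM", "MI", "MD")] <-
    (cnt[, c("MM", "MI", "MD"), drop = FALSE] + 1) /
    (rowSums(cnt[, c("MM", "MI", "MD"), drop = FALSE]) + 3)
  tr[, c("IM", "II")] <-
    (cnt[, c("IM", "II"), drop = FALSE] + 1) /
    (rowSums(cnt[, c("IM", "II"), drop = FALSE]) + 2)
  tr[, c("DM", "DD")] <-
    (cnt[, c("DM", "DD"), drop = FALSE] + 1) /
    (rowSums(cnt[, c("DM", "DD"), drop = FALSE]) + 2)

  new("ProfileHMM",
      name = name %||% paste(classOfOrigin, domainLabel, "1", sep = "_"),
      classOfOrigin = classOfOrigin,
      domainLabel = domainLabel,
      matchEmissions = match_em,
      insertEmissions = background,
      transitions = tr,
      background = background,
      minBlosumScore = NA_real_)
}

#' Calibrate a model's minimum BLOSUM62 hit score
#'
#' Scans every reference positive with the model and anchors the threshold
#' to the weakest reference hit: `floor(min(scores) - sd(scores))`, the
#' minimum BLOSUM62 hit score observed minus the spread the reference family
#' itself exhibits (the spread term is zero for a single positive). Every
#' reference sequence is therefore re-detected at or above threshold, and
#' family members as distant from the consensus as the references are from
#' one another still clear it. A positive that yields no hit (non-positive
#' log-odds) makes calibration impossible and is an error: such a model
#' should already have failed the self-recognition retention criterion.
#'
#' @param hmm A [ProfileHMM-class].
#' @param positives `AAStringSet` (or character vector) of reference
#'   sequences, each of which must contain the domain.
#' @return The model with `minBlosumScore` set.
#' @export
calibrateThreshold <- function(hmm, positives) {
  positives <- as.character(positives)
  if (length(positives) == 0L) {
    stop("no positives supplied for calibration", call. = FALSE)
  }
  scores <- vapply(seq_along(positives), function(k) {
    hit <- viterbiLocal(hmm, positives[k])
    if (hit$score <= 0) {
      stop("calibration impossible for model '", hmm@name, "': positive ",
           names(positives)[k] %||% k,
           " yields no hit (the model fails self-recognition)", call. = FALSE)
    }
    sub <- substr(positives[k], hit$start, hit$end)
    blosumHitScore(sub, consensusSequence(hmm))
  }, numeric(1))
  spread <- if (length(scores) >= 2L) stats::sd(scores) else 0
  hmm@minBlosumScore <- floor(min(scores) - spread)
  validObject(hmm)
  hmm
}

#' Filter candidate models by the retention criteria
#'
#' Applies the three retention criteria used when the model library was
#' assembled:
#' \describe{
#'   \item{criterion i}{models for non-relevant regions are dropped: `TM`
#'     and `CC` segments are predicted by the dedicated sliding-window
#'     predictors, never by profile HMMs.}
#'   \item{criterion ii}{a model must recognize every protein used to
#'     construct it (a positive log-odds Viterbi hit on each training
#'     sequence).}
#'   \item{criterion iii}{when a legacy model for the same domain is
#'     supplied, the candidate replaces it only if its F-score on the
#'     labeled benchmark is at least as high (ties keep the candidate).}
#' }
#'
#' @param candidates List of [ProfileHMM-class] candidates.
#' @param trainingSeqs List (parallel to `candidates`) of `AAStringSet` /
#'   character vectors: the sequences each model was built from.
#' @param legacy Optional named list of competing legacy models, named by
#'   domain label.
#' @param benchmark Optional benchmark for criterion iii: a list with
#'   elements `records` (`AAStringSet`) and `labels` (named list mapping
#'   domain label to a logical vector, `TRUE` where the record contains the
#'   domain).
#' @return A list with `retained` (list of models) and `log` (a
#'   `data.frame` with one row per candidate: `name`, `domain_label`,
#'   `retained`, `criterion`, `reason`).
#' @export
filterHMMs <- function(candidates, trainingSeqs, legacy = NULL,
                       benchmark = NULL) {
  stopifnot(length(candidates) == length(trainingSeqs))
  retained <- list()
  log <- data.frame(name = character(), domain_label = character(),
                    retained = logical(), criterion = character(),
                    reason = character(), stringsAsFactors = FALSE)
  add_log <- function(hmm, keep, criterion, reason) {
    rbind(log, data.frame(name = hmm@name, domain_label = hmm@domainLabel,
                          retained = keep, criterion = criterion,
                          reason = reason, stringsAsFactors = FALSE))
  }
  for (k in seq_along(candidates)) {
    hmm <- candidates[[k]]
    train <- as.character(trainingSeqs[[k]])
    if (length(train) == 0L) {
      stop("candidate '", hmm@name, "' has no training sequences",
           call. = FALSE)
    }
    # criterion i: non-relevant regions
    if (hmm@domainLabel %in% SEGMENT_DOMAINS) {
      log <- add_log(hmm, FALSE, "i",
                     paste0(hmm@domainLabel, " segments are predicted by the ",
                            "dedicated sliding-window predictor, not by HMMs"))
      next
    }
    # criterion ii: self-recognition
    miss <- which(vapply(train, function(s) viterbiLocal(hmm, s)$score <= 0,
                         logical(1)))
    if (length(miss) > 0L) {
      log <- add_log(hmm, FALSE, "ii",
                     paste0("fails to recognize ", length(miss),
                            " of its ", length(train), " training sequence(s)"))
      next
    }
    # criterion iii: comparison against a legacy model
    old <- legacy[[hmm@domainLabel]]
    if (!is.null(old) && !is.null(benchmark)) {
      truth <- benchmark$labels[[hmm@domainLabel]]
      if (is.null(truth)) {
        stop("benchmark has no labels for domain ", hmm@domainLabel,
             call. = FALSE)
      }
      f_new <- model_fscore(hmm, benchmark$records, truth)
      f_old <- model_fscore(old, benchmark$records, truth)
      if (isTRUE(f_old > f_new)) {
        log <- add_log(hmm, FALSE, "iii",
                       sprintf("legacy model outperforms it (F %.3f > %.3f)",
                               f_old, f_new))
        next
      }
      log <- add_log(hmm, TRUE, "iii",
                     sprintf("outperforms or ties legacy model (F %.3f >= %.3f)",
                             f_new, f_old))
      retained[[hmm@name]] <- hmm
      next
    }
    log <- add_log(hmm, TRUE, "",
                   "passes retention criteria")
    retained[[hmm@name]] <- hmm
  }
  list(retained = retained, log = log)
}

# Presence/absence F-score of one model over labeled benchmark records.
# Detection requires a positive log-odds hit whose BLOSUM62 score against
# the consensus reaches the calibrated threshold (or at least 0 for a model
# not yet calibrated, so that incidental few-residue hits do not count).
model_fscore <- function(hmm, records, truth) {
  records <- as.character(records)
  stopifnot(length(records) == length(truth))
  floor_score <- if (isCalibrated(hmm)) hmm@minBlosumScore else 0
  pred <- vapply(records, function(s) {
    hit <- viterbiLocal(hmm, s)
    if (hit$score <= 0) return(FALSE)
    sub <- substr(s, hit$start, hit$end)
    blosumHitScore(sub, consensusSequence(hmm)) >= floor_score
  }, logical(1))
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  if (tp == 0 && (fp > 0 || fn > 0)) return(0)
  if (tp + fp == 0 || tp + fn == 0) return(NA_real_)
  prec <- tp / (tp + fp)
  sens <- tp / (tp + fn)
  2 * prec * sens / (prec + sens)
}

#' Build, filter and calibrate a model library from class alignments
#'
#' Runs the model-construction pipeline: for every row of the domain-region
#' table, the region is cut out of its class alignment, a profile HMM is
#' built, the retention criteria are applied and survivors are calibrated.
#' In addition to the per-class models, a pooled LysM model is built from the
#' row-concatenated LYK + LYP LYSM sub-alignments (receptor kinases and
#' receptor proteins share the motif, and pooling gives a more robust model);
#' lectin-motif regions tagged with a `subtype` (e.g. legume- vs bulb-type)
#' keep separate models per subtype.
#'
#' @param msas Named list of `AAMultipleAlignment` objects, one per PRG
#'   class, names matching `msa_id` in `regions`.
#' @param regions Domain-region `data.frame` as from [readDomainRegions()].
#' @param legacy,benchmark Passed to [filterHMMs()].
#' @return A list with `models` (calibrated retained models, named), and
#'   `log` (the retention log).
#' @export
buildModelLibrary <- function(msas, regions, legacy = NULL, benchmark = NULL) {
  candidates <- list()
  training <- list()
  counter <- list()
  add_candidate <- function(sub, label, origin, subtype = NA_character_) {
    key <- paste0(origin, "_",
                  if (is.na(subtype)) label else paste0(label, ".", subtype))
    counter[[key]] <<- (counter[[key]] %||% 0L) + 1L
    nm <- paste0(key, "_", counter[[key]])
    hmm <- buildProfileHMM(sub, label, origin, name = nm)
    candidates[[nm]] <<- hmm
    m <- msa_matrix(sub)
    training[[nm]] <<- apply(m, 1L, function(r) paste(r[r != "-"], collapse = ""))
  }
  lysm_subs <- list()
  for (k in seq_len(nrow(regions))) {
    rg <- regions[k, ]
    msa <- msas[[rg$msa_id]]
    if (is.null(msa)) {
      stop("no alignment supplied for msa_id '", rg$msa_id, "'", call. = FALSE)
    }
    sub <- extractDomainSegments(msa, rg$col_start, rg$col_end)
    add_candidate(sub, rg$domain_label, rg$msa_id,
                  if (is.na(rg$subtype) || !nzchar(rg$subtype)) NA_character_
                  else rg$subtype)
    if (rg$domain_label == "LYSM" && rg$msa_id %in% c("LYK", "LYP")) {
      lysm_subs[[length(lysm_subs) + 1L]] <- msa_matrix(sub)
    }
  }
  # pooled LYSM model across LYK and LYP
  if (length(lysm_subs) >= 2L) {
    wmax <- max(vapply(lysm_subs, ncol, integer(1)))
    padded <- lapply(lysm_subs, function(m) {
      if (ncol(m) < wmax) {
        m <- cbind(m, matrix("-", nrow(m), wmax - ncol(m)))
      }
      m
    })
    pooled <- do.call(rbind, padded)
    rownames(pooled) <- paste0("pooled_row", seq_len(nrow(pooled)))
    rows <- apply(pooled, 1L, paste, collapse = "")
    sub <- Biostrings::AAMultipleAlignment(Biostrings::AAStringSet(rows))
    add_candidate(sub, "LYSM", "pooled")
  }
  flt <- filterHMMs(candidates, training[names(candidates)],
                    legacy = legacy, benchmark = benchmark)
  models <- lapply(flt$retained, function(hmm) {
    calibrateThreshold(hmm, training[[hmm@name]])
  })
  list(models = models, log = flt$log)
}
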