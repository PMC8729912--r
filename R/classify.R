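#' Classify a domain architecture
#'
#' Maps a set of detected domains to one of the seven canonical PRG classes
#' or a non-canonical architecture code. Classification is set-based: class
#' membership depends only on which domains are present, and the first
#' matching rule in a fixed priority order wins:
#'
#' 1. `TIR + NBS + LRR` => **TNL**
#' 2. `CC + NBS + LRR`, no TIR => **CNL**
#' 3. `LRR + TM + KIN`, no NBS => **RLK**
#' 4. `LRR + TM`, no KIN, no NBS => **RLP**
#' 5. `LYSM + TM + KIN` => **LYK**
#' 6. `LYSM + TM`, no KIN => **LYP**
#' 7. `LECM + TM + KIN` => **LECRK**
#'
#' Anything else is `NONCANONICAL`. TNL/CNL calls tolerate a predicted TM
#' (some NLRs carry one), while rules 3-4 exclude NBS so an NLR with a TM is
#' never misread as a receptor kinase/protein. The compact code string
#' concatenates the present domains in the fixed order
#' `CC>C, TIR>T, NBS>N, LRR>L, LYSM>Y, LECM>E, KIN>K, TM>M` and is attached
#' to canonical calls too.
#'
#' @param domains Character vector (treated as a set) of detected domain
#'   labels, drawn from `CC, TIR, NBS, LRR, LYSM, LECM, KIN, TM`.
#' @return A list with `class_label` and `code` (empty string for the empty
#'   set).
#' @export
#' @examples
#' classifyArchitecture(c("TIR", "NBS", "LRR"))
#' classifyArchitecture(c("NBS", "LRR"))  # non-canonical "NL"
classifyArchitecture <- function(domains) {
  domains <- unique(as.character(domains))
  unknown <- setdiff(domains, names(DOMAIN_CODES))
  if (length(unknown) > 0L) {
    stop("unknown domain label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  has <- names(DOMAIN_CODES) %in% domains
  names(has) <- names(DOMAIN_CODES)
  label <-
    if (has["TIR"] && has["NBS"] && has["LRR"]) "TNL"
    else if (has["CC"] && has["NBS"] && has["LRR"] && !has["TIR"]) "CNL"
    else if (has["LRR"] && has["TM"] && has["KIN"] && !has["NBS"]) "RLK"
    else if (has["LRR"] && has["TM"] && !has["KIN"] && !has["NBS"]) "RLP"
    else if (has["LYSM"] && has["TM"] && has["KIN"]) "LYK"
    else if (has["LYSM"] && has["TM"] && !has["KIN"]) "LYP"
    else if (has["LECM"] && has["TM"] && has["KIN"]) "LECRK"
    else "NONCANONICAL"
  code <- paste(DOMAIN_CODES[has], collapse = "")
  list(class_label = label, code = code)
}

#' Annotate a proteome end to end
#'
#' Runs the full pipeline over a set of proteins: profile-HMM domain scan
#' (with overlap resolution), coiled-coil and transmembrane segment
#' prediction, and architecture classification. Per-protein failures are
#' logged and the protein skipped; the run never aborts on a single bad
#' record.
#'
#' @param proteome `AAStringSet` (or named character vector) of proteins.
#' @param models List of calibrated [ProfileHMM-class] objects.
#' @param coils A [CoilsModel-class]; `NULL` disables CC prediction.
#' @param tm A [TmModel-class]; `NULL` disables TM prediction.
#' @param maxHitsPerModel Passed to [scanProtein()].
#' @return A list of class `prgscanAnnotation` with elements `hits`
#'   (combined hit table; CC/TM rows carry `NA` scores), `classes`
#'   (`protein_id`, `class_label`, `code`, `domains_present`, `n_hits`),
#'   `summary` (named class counts) and `skipped` (character vector of
#'   failed protein ids, if any).
#' @export
annotateProteome <- function(proteome, models, coils = coilsModel(),
                             tm = tmModel(), maxHitsPerModel = 15L) {
  ids <- names(proteome) %||% paste0("protein", seq_along(proteome))
  seqs <- as.character(proteome)
  all_hits <- list()
  classes <- list()
  skipped <- character()
  for (k in seq_along(seqs)) {
    id <- ids[k]
    res <- tryCatch({
      hits <- scanProtein(models, seqs[k], proteinId = id,
                          maxHitsPerModel = maxHitsPerModel)
      hits <- resolveOverlaps(hits)
      if (!is.null(coils)) {
        cc <- predictCoiledCoils(coils, seqs[k], proteinId = id)
        if (nrow(cc) > 0L) {
          hits <- rbind(hits, data.frame(
            protein_id = cc$protein_id, domain_label = cc$domain_label,
            start = cc$start, end = cc$end, hmm_name = "COILS-window",
            logodds_score = NA_real_, blosum_score = NA_real_,
            stringsAsFactors = FALSE))
        }
      }
      if (!is.null(tm)) {
        tms <- predictTmSegments(tm, seqs[k], proteinId = id)
        if (nrow(tms) > 0L) {
          hits <- rbind(hits, data.frame(
            protein_id = tms$protein_id, domain_label = tms$domain_label,
            start = tms$start, end = tms$end, hmm_name = "TM-window",
            logodds_score = NA_real_, blosum_score = NA_real_,
            stringsAsFactors = FALSE))
        }
      }
      hits <- hits[order(hits$start, hits$domain_label), , drop = FALSE]
      call <- classifyArchitecture(unique(hits$domain_label))
      list(hits = hits, call = call)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("skipping protein '", id, "': ", conditionMessage(res),
              call. = FALSE)
      skipped <- c(skipped, id)
      next
    }
    all_hits[[id]] <- res$hits
    present <- sort(unique(res$hits$domain_label))
    classes[[id]] <- data.frame(
      protein_id = id,
      class_label = res$call$class_label,
      code = res$call$code,
      domains_present = if (length(present)) paste(present, collapse = ";")
                        else "none",
      n_hits = nrow(res$hits),
      stringsAsFactors = FALSE)
  }
  hits <- if (length(all_hits)) do.call(rbind, all_hits) else empty_hits()
  rownames(hits) <- NULL
  cls <- if (length(classes)) do.call(rbind, classes) else
    data.frame(protein_id = character(), class_label = character(),
               code = character(), domains_present = character(),
               n_hits = integer(), stringsAsFactors = FALSE)
  rownames(cls) <- NULL
  counts <- table(factor(cls$class_label,
                         levels = c(CANONICAL_CLASSES, "NONCANONICAL")))
  structure(list(hits = hits, classes = cls,
                 summary = stats::setNames(as.integer(counts), names(counts)),
                 skipped = skipped),
            class = "prgscanAnnotation")
}

#' @export
print.prgscanAnnotation <- function(x, ...) {
  cat("prgscan annotation:", nrow(x$classes), "proteins,",
      nrow(x$hits), "domain hits\n")
  nz <- x$summary[x$summary > 0]
  if (length(nz)) {
    cat("  classes:", paste(sprintf("%s=%d", names(nz), nz), collapse = " "),
        "\n")
  }
  if (length(x$skipped)) {
    cat("  skipped:", length(x$skipped), "protein(s)\n")
  }
  invisible(x)
}

#' Write annotation results to a directory
#'
#' Writes `hits.tsv`, `classes.tsv` and `summary.json` with deterministic
#' formatting: identical inputs produce byte-identical files.
#'
#' @param annotation A `prgscanAnnotation` from [annotateProteome()].
#' @param dir Output directory (created if needed).
#' @param gff Also write `hits.gff3` (default `FALSE`).
#' @return Invisibly, `dir`.
#' @export
writeAnnotation <- function(annotation, dir, gff = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hits <- annotation$hits
  out <- hits
  out$logodds_score <- ifelse(is.na(hits$logodds_score), "NA",
                              fmt_num(hits$logodds_score, 3))
  out$blosum_score <- ifelse(is.na(hits$blosum_score), "NA",
                             as.character(as.integer(round(hits$blosum_score))))
  utils::write.table(out, file.path(dir, "hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(annotation$classes, file.path(dir, "classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(jsonlite::toJSON(as.list(annotation$summary), auto_unbox = TRUE,
                              pretty = TRUE),
             file.path(dir, "summary.json"))
  if (gff) writeHitsGff3(hits, file.path(dir, "hits.gff3"))
  invisible(dir)
}
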