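# Resistance domains the agreement analysis is restricted to: CC and TM are
# predicted by external-style segment predictors, not profile HMMs, and KIN
# presence is shared by several classes, so the benchmark covers the five
# HMM-specific resistance domains.
VALIDATION_DOMAINS <- c("TIR", "NBS", "LRR", "LYSM", "LECM")

#' Read a reference domain annotation
#'
#' The reference (ground-truth) annotation is a two-column TSV with one row
#' per `(protein, domain)` pair: columns `protein_id` and `domain_label`.
#' A protein with no resistance domains may appear with the label `none`.
#'
#' @param path Path to the TSV file (with header).
#' @return A named list mapping `protein_id` to a character vector (possibly
#'   empty) of domain labels.
#' @export
readReferenceAnnotation <- function(path) {
  if (!file.exists(path)) {
    stop("reference annotation not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "domain_label")
  if (!all(need %in% names(df))) {
    stop("reference annotation needs columns protein_id, domain_label",
         call. = FALSE)
  }
  ref <- lapply(split(df$domain_label, df$protein_id),
                function(d) setdiff(unique(d), "none"))
  bad <- setdiff(unique(unlist(ref)), HMM_DOMAINS)
  if (length(bad) > 0L) {
    stop("reference annotation contains unknown domain label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ref
}

# Normalize per-protein domain sets to the evaluation vocabulary.
restrict_domains <- function(sets, vocabulary) {
  lapply(sets, function(d) sort(intersect(unique(as.character(d)), vocabulary)))
}

#' Criterion-based agreement with a reference annotation
#'
#' For every reference protein the predicted resistance-domain set is
#' compared with the reference set, restricted to the HMM-specific domains
#' (`TIR, NBS, LRR, LYSM, LECM`):
#' * **criterion 1** - the sets are identical;
#' * **criterion 2** - the prediction is equal to or a superset of the
#'   reference ("predicted equally or better"), so criterion 1 implies
#'   criterion 2.
#'
#' Proteins present in the predictions but absent from the reference cannot
#' be evaluated; they are excluded with a message. Reference proteins
#' without predictions are evaluated against the empty set.
#'
#' @param predicted Named list mapping `protein_id` to a character vector of
#'   predicted domain labels (e.g. from `annotationDomainSets()`).
#' @param reference Named list as from [readReferenceAnnotation()].
#' @param vocabulary Domains compared (default `TIR, NBS, LRR, LYSM, LECM`).
#' @return A `data.frame` with columns `protein_id`, `criterion1`,
#'   `criterion2`.
#' @export
compareToReference <- function(predicted, reference,
                               vocabulary = VALIDATION_DOMAINS) {
  extra <- setdiff(names(predicted), names(reference))
  if (length(extra) > 0L) {
    message("excluding ", length(extra),
            " predicted protein(s) absent from the reference: ",
            paste(utils::head(extra, 5L), collapse = ", "),
            if (length(extra) > 5L) ", ..." else "")
  }
  ids <- names(reference)
  if (length(ids) == 0L) stop("empty reference annotation", call. = FALSE)
  pred <- restrict_domains(predicted[intersect(names(predicted), ids)],
                           vocabulary)
  ref <- restrict_domains(reference, vocabulary)
  c1 <- logical(length(ids))
  c2 <- logical(length(ids))
  for (k in seq_along(ids)) {
    p <- pred[[ids[k]]] %||% character()
    r <- ref[[ids[k]]]
    c1[k] <- setequal(p, r)
    c2[k] <- all(r %in% p)
  }
  data.frame(protein_id = ids, criterion1 = c1, criterion2 = c2,
             stringsAsFactors = FALSE)
}

#' Confusion-matrix metrics per domain
#'
#' Every `(protein, domain)` cell over the reference proteins and the
#' vocabulary is tallied as TP (predicted and in the reference), FP
#' (predicted only), FN (reference only) or TN (neither); metrics are
#' derived per domain and pooled over all cells:
#' accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)` and F-score, the harmonic mean of
#' precision and sensitivity. A ratio with a zero denominator is undefined
#' and reported as `NA`, never as 0.
#'
#' @inheritParams compareToReference
#' @return A list with `per_domain` (a `data.frame` with counts and metrics
#'   per domain) and `pooled` (the same quantities over all cells).
#' @export
confusionMetrics <- function(predicted, reference,
                             vocabulary = VALIDATION_DOMAINS) {
  ids <- names(reference)
  if (length(ids) == 0L) stop("empty reference annotation", call. = FALSE)
  pred <- restrict_domains(predicted[intersect(names(predicted), ids)],
                           vocabulary)
  ref <- restrict_domains(reference, vocabulary)
  per <- lapply(vocabulary, function(d) {
    p <- vapply(ids, function(i) d %in% (pred[[i]] %||% character()),
                logical(1))
    r <- vapply(ids, function(i) d %in% ref[[i]], logical(1))
    counts_row(d, tp = sum(p & r), fp = sum(p & !r),
               tn = sum(!p & !r), fn = sum(!p & r))
  })
  per_domain <- do.call(rbind, per)
  pooled <- counts_row("pooled",
                       tp = sum(per_domain$TP), fp = sum(per_domain$FP),
                       tn = sum(per_domain$TN), fn = sum(per_domain$FN))
  list(per_domain = per_domain, pooled = pooled)
}

counts_row <- function(label, tp, fp, tn, fn) {
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  prec <- ratio(tp, tp + fp)
  sens <- ratio(tp, tp + fn)
  f <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
       else 2 * prec * sens / (prec + sens)
  data.frame(domain = label, TP = tp, FP = fp, TN = tn, FN = fn,
             accuracy = ratio(tp + tn, tp + tn + fp + fn),
             precision = prec, sensitivity = sens,
             specificity = ratio(tn, tn + fp),
             f_score = f, stringsAsFactors = FALSE)
}

#' Extract per-protein domain sets from an annotation
#'
#' @param annotation A `prgscanAnnotation` from [annotateProteome()].
#' @return Named list mapping `protein_id` to the character vector of
#'   detected domain labels (empty for proteins without hits).
#' @export
annotationDomainSets <- function(annotation) {
  sets <- lapply(split(annotation$hits$domain_label,
                       annotation$hits$protein_id), unique)
  all_ids <- annotation$classes$protein_id
  out <- stats::setNames(vector("list", length(all_ids)), all_ids)
  for (id in all_ids) out[[id]] <- sets[[id]] %||% character()
  out
}

#' Full validation report against a reference annotation
#'
#' Combines the criterion-based agreement counts (tallied per predicted
#' class) with the confusion-matrix metrics.
#'
#' @param annotation A `prgscanAnnotation` from [annotateProteome()].
#' @param reference Named list as from [readReferenceAnnotation()].
#' @param vocabulary Domains compared (default `TIR, NBS, LRR, LYSM, LECM`).
#' @return A list of class `prgscanValidation` with `criteria` (per-protein
#'   flags), `by_class` (per predicted class: `n_total`, `n_criterion1`,
#'   `n_criterion2`), `confusion` (per-domain counts and metrics) and
#'   `pooled`.
#' @export
validationReport <- function(annotation, reference,
                             vocabulary = VALIDATION_DOMAINS) {
  predicted <- annotationDomainSets(annotation)
  crit <- compareToReference(predicted, reference, vocabulary)
  cls <- annotation$classes[match(crit$protein_id,
                                  annotation$classes$protein_id),
                            "class_label"]
  cls[is.na(cls)] <- "unscanned"
  by_class <- do.call(rbind, lapply(split(seq_len(nrow(crit)), cls),
                                    function(idx) {
    data.frame(class_label = cls[idx[1]],
               n_total = length(idx),
               n_criterion1 = sum(crit$criterion1[idx]),
               n_criterion2 = sum(crit$criterion2[idx]),
               stringsAsFactors = FALSE)
  }))
  rownames(by_class) <- NULL
  conf <- confusionMetrics(predicted, reference, vocabulary)
  structure(list(criteria = crit, by_class = by_class,
                 confusion = conf$per_domain, pooled = conf$pooled),
            class = "prgscanValidation")
}

#' @export
print.prgscanValidation <- function(x, ...) {
  n <- nrow(x$criteria)
  cat("prgscan validation over", n, "reference proteins\n")
  cat(sprintf("  criterion 1 (identical): %d/%d\n",
              sum(x$criteria$criterion1), n))
  cat(sprintf("  criterion 2 (equal or better): %d/%d\n",
              sum(x$criteria$criterion2), n))
  p <- x$pooled
  cat(sprintf("  pooled: acc %.3f  prec %.3f  sens %.3f  spec %.3f  F %.3f\n",
              p$accuracy, p$precision, p$sensitivity, p$specificity,
              p$f_score))
  invisible(x)
}

#' Write a validation report (JSON + TSV)
#'
#' @param report A `prgscanValidation` from [validationReport()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
writeValidationReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$confusion, file.path(dir, "confusion.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$by_class, file.path(dir, "criteria_by_class.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  obj <- list(by_class = report$by_class,
              confusion = report$confusion,
              pooled = report$pooled)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, dataframe = "rows"),
             file.path(dir, "validation.json"))
  invisible(dir)
}
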