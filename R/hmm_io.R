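#' Write a profile HMM to JSON
#'
#' Models are stored one JSON file per model with sorted keys and full
#' numeric precision, so that write-read-write round-trips are
#' byte-identical.
#'
#' @param hmm A [ProfileHMM-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeHMM <- function(hmm, path) {
  obj <- list(
    background      = unname(hmm@background),
    class_of_origin = hmm@classOfOrigin,
    domain_label    = hmm@domainLabel,
    insert_emissions = unname(hmm@insertEmissions),
    length          = nStates(hmm),
    match_emissions = unname(apply(hmm@matchEmissions, 1L, c, simplify = FALSE)),
    min_blosum_score = if (is.na(hmm@minBlosumScore)) NULL
                       else hmm@minBlosumScore,
    name            = hmm@name,
    transitions     = unname(apply(hmm@transitions, 1L, c, simplify = FALSE))
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a profile HMM from JSON
#'
#' @param path Path written by [writeHMM()].
#' @return A [ProfileHMM-class].
#' @export
readHMM <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  M <- obj$length
  # fromJSON simplifies the list of per-state rows to an M x 20 matrix
  match_em <- rbind(obj$match_emissions)
  dimnames(match_em) <- list(as.character(seq_len(M)), AA_ALPHABET)
  tr <- obj$transitions
  dimnames(tr) <- list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD"))
  bg <- as.numeric(obj$background)
  names(bg) <- AA_ALPHABET
  ins <- as.numeric(obj$insert_emissions)
  names(ins) <- AA_ALPHABET
  new("ProfileHMM",
      name = obj$name,
      classOfOrigin = obj$class_of_origin,
      domainLabel = obj$domain_label,
      matchEmissions = match_em,
      insertEmissions = ins,
      transitions = tr,
      background = bg,
      minBlosumScore = as.numeric(obj$min_blosum_score %||% NA_real_))
}

#' Write a model library with a manifest
#'
#' @param models Named list of [ProfileHMM-class] objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
writeModelLibrary <- function(models, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(models))
  for (k in seq_along(models)) {
    files[k] <- paste0(models[[k]]@name, ".json")
    writeHMM(models[[k]], file.path(dir, files[k]))
  }
  manifest <- list(format = "prgscan-hmm-json-1", models = sort(files))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "library.json"))
  invisible(file.path(dir, "library.json"))
}

#' Read a model library written by [writeModelLibrary()]
#'
#' @param dir Directory holding `library.json` and the model JSON files.
#' @return Named list of [ProfileHMM-class] objects.
#' @export
readModelLibrary <- function(dir) {
  mf <- file.path(dir, "library.json")
  if (!file.exists(mf)) {
    stop("no library.json in ", dir, call. = FALSE)
  }
  manifest <- jsonlite::fromJSON(mf)
  models <- lapply(manifest$models, function(f) readHMM(file.path(dir, f)))
  names(models) <- vapply(models, function(m) m@name, character(1))
  models
}
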