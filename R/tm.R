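#' Construct a transmembrane model
#'
#' Loads a hydropathy scale and window parameters; the shipped default is the
#' Kyte-Doolittle scale with a 19-residue window and a mean-hydropathy cutoff
#' of 1.6, the classic setting at which windows of membrane-spanning length
#' stand out from soluble sequence.
#'
#' @param path JSON scale file; default the shipped Kyte-Doolittle scale.
#' @param window,threshold,minGap Optional overrides of the stored
#'   parameters.
#' @return A [TmModel-class].
#' @export
tmModel <- function(path = system.file("extdata", "kyte_doolittle.json",
                                       package = "prgscan"),
                    window = NULL, threshold = NULL, minGap = NULL) {
  obj <- jsonlite::fromJSON(path)
  hyd <- unlist(obj$hydropathy)[AA_ALPHABET]
  new("TmModel",
      hydropathy = hyd,
      window = as.integer(window %||% obj$window),
      threshold = as.numeric(threshold %||% obj$threshold),
      minGap = as.integer(minGap %||% obj$min_gap))
}

#' Predict transmembrane segments
#'
#' Windows whose mean hydropathy reaches the model threshold are unioned
#' into candidate segments; unions separated by fewer than `minGap` residues
#' are merged. Each segment reports the highest window mean among the
#' windows composing it. `X` residues take hydropathy 0.
#'
#' @param model A [TmModel-class].
#' @param protein Protein sequence (character scalar or `AAString`).
#' @param proteinId Identifier used in the output table.
#' @return A `data.frame` with columns `protein_id`, `domain_label`
#'   (`"TM"`), `start`, `end`, `peak_hydropathy`. Proteins shorter than the
#'   window yield zero rows.
#' @export
predictTmSegments <- function(model, protein, proteinId = "protein") {
  chars <- seq_chars(protein)
  L <- length(chars)
  W <- model@window
  empty <- data.frame(protein_id = character(), domain_label = character(),
                      start = integer(), end = integer(),
                      peak_hydropathy = numeric(), stringsAsFactors = FALSE)
  if (L < W) return(empty)
  idx <- aa_index(chars)
  h <- numeric(L)
  h[!is.na(idx)] <- model@hydropathy[idx[!is.na(idx)]]
  cs <- c(0, cumsum(h))
  nwin <- L - W + 1L
  means <- (cs[(W + 1L):(L + 1L)] - cs[1:nwin]) / W
  qual <- which(means >= model@threshold)
  if (length(qual) == 0L) return(empty)
  wins <- IRanges::IRanges(start = qual, end = qual + W - 1L)
  segs <- IRanges::reduce(wins, min.gapwidth = model@minGap)
  data.frame(protein_id = proteinId,
             domain_label = "TM",
             start = IRanges::start(segs), end = IRanges::end(segs),
             peak_hydropathy = vapply(seq_along(segs), function(g) {
               inside <- qual >= IRanges::start(segs)[g] &
                 (qual + W - 1L) <= IRanges::end(segs)[g]
               max(means[qual[inside]])
             }, numeric(1)),
             stringsAsFactors = FALSE)
}
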