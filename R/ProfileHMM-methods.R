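#' @describeIn ProfileHMM-accessors Model name.
#' @export
setGeneric("hmmName", function(x) standardGeneric("hmmName"))

#' @describeIn ProfileHMM-accessors Domain label the model detects.
#' @export
setGeneric("domainLabel", function(x) standardGeneric("domainLabel"))

#' @describeIn ProfileHMM-accessors Class whose reference alignment the model
#'   was built from.
#' @export
setGeneric("classOfOrigin", function(x) standardGeneric("classOfOrigin"))

#' @describeIn ProfileHMM-accessors Number of match states.
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))

#' @describeIn ProfileHMM-accessors M x 20 match emission matrix.
#' @export
setGeneric("matchEmissions", function(x) standardGeneric("matchEmissions"))

#' @describeIn ProfileHMM-accessors Consensus sequence (per-state argmax
#'   residue; ties resolved to the first residue in `A R N D C Q E G H I L K M
#'   F P S T W Y V` order).
#' @export
setGeneric("consensusSequence", function(x) standardGeneric("consensusSequence"))

#' @describeIn ProfileHMM-accessors Calibrated minimum BLOSUM62 hit score
#'   (`NA` before calibration).
#' @export
setGeneric("minBlosumScore", function(x) standardGeneric("minBlosumScore"))

#' @describeIn ProfileHMM-accessors `TRUE` once a threshold has been
#'   calibrated.
#' @export
setGeneric("isCalibrated", function(x) standardGeneric("isCalibrated"))

#' Accessors for ProfileHMM objects
#'
#' @param x A [ProfileHMM-class] object.
#' @name ProfileHMM-accessors
#' @aliases hmmName domainLabel classOfOrigin nStates matchEmissions
#'   consensusSequence minBlosumScore isCalibrated
NULL

#' @rdname ProfileHMM-accessors
#' @export
setMethod("hmmName", "ProfileHMM", function(x) x@name)

#' @rdname ProfileHMM-accessors
#' @export
setMethod("domainLabel", "ProfileHMM", function(x) x@domainLabel)

#' @rdname ProfileHMM-accessors
#' @export
setMethod("classOfOrigin", "ProfileHMM", function(x) x@classOfOrigin)

#' @rdname ProfileHMM-accessors
#' @export
setMethod("nStates", "ProfileHMM", function(x) nrow(x@matchEmissions))

#' @rdname ProfileHMM-accessors
#' @export
setMethod("matchEmissions", "ProfileHMM", function(x) x@matchEmissions)

#' @rdname ProfileHMM-accessors
#' @export
setMethod("consensusSequence", "ProfileHMM", function(x) {
  paste(AA_ALPHABET[apply(x@matchEmissions, 1L, which.max)], collapse = "")
})

#' @rdname ProfileHMM-accessors
#' @export
setMethod("minBlosumScore", "ProfileHMM", function(x) x@minBlosumScore)

#' @rdname ProfileHMM-accessors
#' @export
setMethod("isCalibrated", "ProfileHMM", function(x) !is.na(x@minBlosumScore))

setMethod("show", "ProfileHMM", function(object) {
  cat("ProfileHMM", object@name, "\n")
  cat("  domain:", object@domainLabel,
      " class of origin:", object@classOfOrigin, "\n")
  cat("  match states:", nStates(object), "\n")
  thr <- if (isCalibrated(object)) object@minBlosumScore else "uncalibrated"
  cat("  min BLOSUM62 hit score:", thr, "\n")
})

setMethod("show", "CoilsModel", function(object) {
  cat("CoilsModel: window", object@window,
      " pCutoff", object@pCutoff, " minRun", object@minRun, "\n")
  cat(sprintf("  score Gaussians: cc N(%.3g, %.3g)  glob N(%.3g, %.3g)\n",
              object@gaussCc[1], object@gaussCc[2],
              object@gaussGlob[1], object@gaussGlob[2]))
})

setMethod("show", "TmModel", function(object) {
  cat("TmModel: window", object@window, " threshold", object@threshold,
      " minGap", object@minGap, "\n")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: n =", object@nProteins, " seed =", object@seed, "\n")
  cat("  class mix:", paste(sprintf("%s=%.3g", names(object@classMix),
                                    object@classMix), collapse = " "), "\n")
  cat("  substitution noise:", object@substitutionNoise, "\n")
})
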