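#' @import methods
NULL

#' Profile hidden Markov model of a resistance domain
#'
#' A position-specific probabilistic model of a protein domain family with
#' match, insert and delete states. Models are built from a (sub-)alignment
#' with [buildProfileHMM()] and carry, after [calibrateThreshold()], the
#' minimum BLOSUM62 hit score a scan hit must reach to be reported.
#'
#' @slot name Model identifier, `{class}_{domain}_{region index}` when built
#'   through [buildModelLibrary()].
#' @slot classOfOrigin PRG class whose reference alignment the model was
#'   built from (`"CNL"`, `"TNL"`, `"RLK"`, `"RLP"`, `"LYK"`, `"LYP"`,
#'   `"LECRK"`, or `"pooled"` for models built across classes).
#' @slot domainLabel Domain the model detects: one of `TIR`, `NBS`, `LRR`,
#'   `LYSM`, `LECM`, `KIN` (candidate models may transiently carry `CC`/`TM`
#'   labels; these are rejected by [filterHMMs()]).
#' @slot matchEmissions M x 20 matrix of match-state emission probabilities,
#'   columns in the order `A R N D C Q E G H I L K M F P S T W Y V`.
#' @slot insertEmissions Length-20 insert-state emission probabilities
#'   (the background distribution).
#' @slot transitions M x 7 matrix of transition probabilities with columns
#'   `MM, MI, MD, IM, II, DM, DD` (source state = row).
#' @slot background Length-20 background residue distribution.
#' @slot minBlosumScore Calibrated minimum BLOSUM62 hit score
#'   (`NA` until [calibrateThreshold()] is run).
#'
#' @seealso [buildProfileHMM()], [viterbiLocal()], [scanProtein()]
#' @export
setClass("ProfileHMM",
  representation(
    name            = "character",
    classOfOrigin   = "character",
    domainLabel     = "character",
    matchEmissions  = "matrix",
    insertEmissions = "numeric",
    transitions     = "matrix",
    background      = "numeric",
    minBlosumScore  = "numeric"
  ),
  prototype(minBlosumScore = NA_real_)
)

setValidity("ProfileHMM", function(object) {
  msgs <- character()
  M <- nrow(object@matchEmissions)
  if (M < 1L) msgs <- c(msgs, "model must have at least one match state")
  if (ncol(object@matchEmissions) != 20L)
    msgs <- c(msgs, "matchEmissions must have 20 columns")
  if (length(object@insertEmissions) != 20L)
    msgs <- c(msgs, "insertEmissions must have length 20")
  if (length(object@background) != 20L)
    msgs <- c(msgs, "background must have length 20")
  if (!identical(dim(object@transitions), c(M, 7L)))
    msgs <- c(msgs, "transitions must be an M x 7 matrix")
  tol <- 1e-9
  probs <- c(object@matchEmissions, object@insertEmissions,
             object@background, object@transitions)
  if (any(probs <= 0))
    msgs <- c(msgs, "all probabilities must be > 0 (pseudocounted)")
  if (any(abs(rowSums(object@matchEmissions) - 1) > tol))
    msgs <- c(msgs, "match emission rows must sum to 1")
  if (abs(sum(object@insertEmissions) - 1) > tol)
    msgs <- c(msgs, "insert emissions must sum to 1")
  if (abs(sum(object@background) - 1) > tol)
    msgs <- c(msgs, "background must sum to 1")
  if (M >= 1L && ncol(object@transitions) == 7L) {
    tr <- object@transitions
    if (any(abs(tr[, 1] + tr[, 2] + tr[, 3] - 1) > tol))
      msgs <- c(msgs, "match transitions (MM+MI+MD) must sum to 1")
    if (any(abs(tr[, 4] + tr[, 5] - 1) > tol))
      msgs <- c(msgs, "insert transitions (IM+II) must sum to 1")
    if (any(abs(tr[, 6] + tr[, 7] - 1) > tol))
      msgs <- c(msgs, "delete transitions (DM+DD) must sum to 1")
  }
  if (length(object@minBlosumScore) != 1L)
    msgs <- c(msgs, "minBlosumScore must be a single number (or NA)")
  if (length(msgs)) msgs else TRUE
})

#' Coiled-coil sliding-window model
#'
#' Heptad-propensity model for coiled-coil prediction: a window of residues is
#' scored by the geometric mean of per-residue, per-heptad-position
#' propensities, and the score is converted to a probability by the ratio of
#' two Gaussian score densities (coiled-coil vs globular).
#'
#' @slot propensities 20 x 7 matrix of positive propensities; rows in the
#'   order `A R N D C Q E G H I L K M F P S T W Y V`, columns the heptad
#'   positions `a`..`g`.
#' @slot window Window length in residues (default 21, i.e. three heptads).
#' @slot gaussCc,gaussGlob Length-2 `(mean, sd)` of the window-score
#'   distribution in coiled coils and in globular sequence.
#' @slot pCutoff Per-residue probability cutoff for calling a segment.
#' @slot minRun Minimum run length (residues at or above `pCutoff`).
#'
#' @seealso [coilsModel()], [predictCoiledCoils()]
#' @export
setClass("CoilsModel",
  representation(
    propensities = "matrix",
    window       = "integer",
    gaussCc      = "numeric",
    gaussGlob    = "numeric",
    pCutoff      = "numeric",
    minRun       = "integer"
  )
)

setValidity("CoilsModel", function(object) {
  msgs <- character()
  if (!identical(dim(object@propensities), c(20L, 7L)))
    msgs <- c(msgs, "propensities must be a 20 x 7 matrix")
  if (any(object@propensities <= 0))
    msgs <- c(msgs, "all propensities must be > 0")
  if (object@window < 7L) msgs <- c(msgs, "window must be at least 7")
  if (length(object@gaussCc) != 2L || length(object@gaussGlob) != 2L)
    msgs <- c(msgs, "gaussCc and gaussGlob must be (mean, sd) pairs")
  else if (object@gaussCc[2] <= 0 || object@gaussGlob[2] <= 0)
    msgs <- c(msgs, "Gaussian sds must be > 0")
  if (object@pCutoff <= 0 || object@pCutoff >= 1)
    msgs <- c(msgs, "pCutoff must lie strictly between 0 and 1")
  if (object@minRun < 1L) msgs <- c(msgs, "minRun must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Transmembrane sliding-window model
#'
#' Hydropathy-window model for transmembrane segment prediction: windows whose
#' mean hydropathy reaches `threshold` are unioned into segments; unions
#' separated by fewer than `minGap` residues are merged.
#'
#' @slot hydropathy Named length-20 vector of per-residue hydropathy values
#'   (Kyte-Doolittle scale shipped as the default).
#' @slot window Odd window length (default 19).
#' @slot threshold Mean-hydropathy cutoff (default 1.6).
#' @slot minGap Minimum number of residues between reported segments.
#'
#' @seealso [tmModel()], [predictTmSegments()]
#' @export
setClass("TmModel",
  representation(
    hydropathy = "numeric",
    window     = "integer",
    threshold  = "numeric",
    minGap     = "integer"
  )
)

setValidity("TmModel", function(object) {
  msgs <- character()
  if (length(object@hydropathy) != 20L || is.null(names(object@hydropathy)))
    msgs <- c(msgs, "hydropathy must be a named length-20 vector")
  if (object@window %% 2L != 1L) msgs <- c(msgs, "window must be odd")
  if (!is.finite(object@threshold)) msgs <- c(msgs, "threshold must be finite")
  if (object@minGap < 1L) msgs <- c(msgs, "minGap must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Synthetic-proteome simulation settings
#'
#' Conditions under which [makeSyntheticProteome()] plants domain
#' architectures: class proportions, per-domain length ranges, substitution
#' noise inside planted segments, the background residue composition used for
#' linkers, and linker lengths.
#'
#' @slot seed Integer seed; the generator is fully deterministic given it.
#' @slot nProteins Number of proteins to simulate.
#' @slot classMix Named proportions over target classes; must sum to 1.
#' @slot domainLength Named list of `(min, max)` residue lengths (used
#'   directly for the CC and TM segments; HMM-planted domains take their
#'   length from the generating model).
#' @slot substitutionNoise Per-residue substitution probability applied inside
#'   planted segments.
#' @slot backgroundComposition Named length-20 residue probability vector for
#'   linkers, deliberately depleted in long hydrophobic runs.
#' @slot linkerLength `(min, max)` linker length range.
#' @slot stochastic If `FALSE` (default) class counts are realized exactly by
#'   largest-remainder rounding; if `TRUE` they are drawn multinomially.
#'
#' @seealso [simConfig()], [makeSyntheticProteome()]
#' @export
setClass("SimConfig",
  representation(
    seed                  = "integer",
    nProteins             = "integer",
    classMix              = "numeric",
    domainLength          = "list",
    substitutionNoise     = "numeric",
    backgroundComposition = "numeric",
    linkerLength          = "integer",
    stochastic            = "logical"
  )
)

setValidity("SimConfig", function(object) {
  msgs <- character()
  if (object@nProteins < 1L) msgs <- c(msgs, "nProteins must be >= 1")
  if (abs(sum(object@classMix) - 1) > 1e-9)
    msgs <- c(msgs, "classMix proportions must sum to 1")
  if (is.null(names(object@classMix)) || any(!nzchar(names(object@classMix))))
    msgs <- c(msgs, "classMix must be named by class")
  if (object@substitutionNoise < 0 || object@substitutionNoise >= 0.5)
    msgs <- c(msgs, "substitutionNoise must lie in [0, 0.5)")
  if (length(object@backgroundComposition) != 20L ||
      abs(sum(object@backgroundComposition) - 1) > 1e-9)
    msgs <- c(msgs, "backgroundComposition must be 20 probabilities summing to 1")
  if (length(object@linkerLength) != 2L ||
      any(object@linkerLength < 1L) ||
      object@linkerLength[1] > object@linkerLength[2])
    msgs <- c(msgs, "linkerLength must be an increasing positive (min, max) pair")
  bad <- vapply(object@domainLength, function(r) {
    length(r) != 2L || any(r < 1) || r[1] > r[2]
  }, logical(1))
  if (any(bad))
    msgs <- c(msgs, "domainLength entries must be positive (min, max) pairs")
  if (length(msgs)) msgs else TRUE
})
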