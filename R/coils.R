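#' Construct a coiled-coil model
#'
#' Loads the heptad-propensity table and score-distribution parameters. The
#' shipped default is a Lupas-style table authored for this package (versioned
#' in `inst/extdata/coils_propensities.json`): hydrophobic residues carry high
#' propensity at the core positions `a`/`d`, charged and polar residues at the
#' outer positions, and helix breakers (P, G) are penalized everywhere. The
#' Gaussian score-distribution parameters are calibrated to that table.
#'
#' @param path JSON model file; default the shipped table.
#' @param window,pCutoff,minRun Optional overrides of the stored parameters.
#' @return A [CoilsModel-class].
#' @export
coilsModel <- function(path = system.file("extdata", "coils_propensities.json",
                                          package = "prgscan"),
                       window = NULL, pCutoff = NULL, minRun = NULL) {
  obj <- jsonlite::fromJSON(path)
  prop <- matrix(unlist(obj$propensities[AA_ALPHABET]), nrow = 20,
                 byrow = TRUE, dimnames = list(AA_ALPHABET, letters[1:7]))
  new("CoilsModel",
      propensities = prop,
      window = as.integer(window %||% obj$window),
      gaussCc = as.numeric(obj$gauss_cc),
      gaussGlob = as.numeric(obj$gauss_glob),
      pCutoff = as.numeric(pCutoff %||% obj$p_cutoff),
      minRun = as.integer(minRun %||% obj$min_run))
}

# log-propensity lookup with X (or anything unknown) given propensity 1
coils_logprop <- function(model, chars) {
  lp <- log(model@propensities)
  idx <- aa_index(chars)
  out <- matrix(0, nrow = length(chars), ncol = 7)
  known <- !is.na(idx)
  out[known, ] <- lp[idx[known], , drop = FALSE]
  out
}

#' Score one window of residues
#'
#' The window score is the geometric mean of the per-residue propensities at
#' their heptad positions: residue `i` (0-based within the window) sits at
#' heptad position `(i + offset) mod 7` (`0` = `a` ... `6` = `g`).
#'
#' @param model A [CoilsModel-class].
#' @param window Residues, length exactly `model@window`.
#' @param offset Register offset, 0-6 (shifting by 7 is a no-op).
#' @return The window score (geometric mean of propensities).
#' @export
coilsWindowScore <- function(model, window, offset = 0L) {
  chars <- seq_chars(window)
  W <- model@window
  if (length(chars) != W) {
    stop("window must have exactly ", W, " residues", call. = FALSE)
  }
  lp <- coils_logprop(model, chars)
  pos <- ((seq_along(chars) - 1L + offset) %% 7L) + 1L
  exp(mean(lp[cbind(seq_along(chars), pos)]))
}

#' Convert a window score to a coiled-coil probability
#'
#' `P = Gcc(score) / (Gcc(score) + Gglob(score))` with `Gcc`, `Gglob` the
#' normal densities of the score in coiled-coil and globular sequence.
#' Computed via the log densities, so extreme scores do not underflow.
#'
#' @param model A [CoilsModel-class].
#' @param score Window score(s).
#' @return Probability in `[0, 1]` (vectorized).
#' @export
coilsProbability <- function(model, score) {
  lcc <- stats::dnorm(score, model@gaussCc[1], model@gaussCc[2], log = TRUE)
  lgl <- stats::dnorm(score, model@gaussGlob[1], model@gaussGlob[2], log = TRUE)
  stats::plogis(lcc - lgl)
}

#' Predict coiled-coil segments
#'
#' Every residue receives the maximum coiled-coil probability over all
#' windows covering it and all seven register offsets; maximal runs of at
#' least `minRun` residues with probability at or above `pCutoff` are
#' reported as segments.
#'
#' @param model A [CoilsModel-class].
#' @param protein Protein sequence (character scalar or `AAString`).
#' @param proteinId Identifier used in the output table.
#' @return A `data.frame` with columns `protein_id`, `domain_label`
#'   (`"CC"`), `start`, `end`, `max_probability`. Proteins shorter than the
#'   window yield zero rows.
#' @export
predictCoiledCoils <- function(model, protein, proteinId = "protein") {
  chars <- seq_chars(protein)
  L <- length(chars)
  W <- model@window
  empty <- data.frame(protein_id = character(), domain_label = character(),
                      start = integer(), end = integer(),
                      max_probability = numeric(), stringsAsFactors = FALSE)
  if (L < W) return(empty)
  lp <- coils_logprop(model, chars)
  nwin <- L - W + 1L
  presP <- numeric(L)
  # phase phi assigns residue i (1-based) to heptad column (i + phi) mod 7;
  # the 7 phases cover all (window, register-offset) combinations.
  for (phi in 0:6) {
    pos <- ((seq_len(L) + phi) %% 7L) + 1L
    v <- lp[cbind(seq_len(L), pos)]
    cs <- c(0, cumsum(v))
    scores <- exp((cs[(W + 1L):(L + 1L)] - cs[1:nwin]) / W)
    probs <- coilsProbability(model, scores)
    for (s in seq_len(nwin)) {
      idx <- s:(s + W - 1L)
      upd <- presP[idx] < probs[s]
      if (any(upd)) presP[idx[upd]] <- probs[s]
    }
  }
  above <- presP >= model@pCutoff
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= model@minRun)
  if (length(keep) == 0L) return(empty)
  data.frame(protein_id = proteinId,
             domain_label = "CC",
             start = starts[keep], end = ends[keep],
             max_probability = vapply(keep, function(k)
               max(presP[starts[k]:ends[k]]), numeric(1)),
             stringsAsFactors = FALSE)
}
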