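# Default match-state counts for the synthetic reference families. These are
# scaled-down but rank-realistic domain sizes (LysM motifs are short, NBS and
# kinase domains long) chosen once for the study conditions.
DEFAULT_MODEL_LENGTH <- c(TIR = 80L, NBS = 120L, LRR = 100L,
                          LYSM = 40L, LECM = 60L, KIN = 100L)

# N-to-C architectures planted per class. LysM receptors carry tandem
# motifs, as their natural counterparts do.
ARCHITECTURES <- list(
  TNL   = c("TIR", "NBS", "LRR"),
  CNL   = c("CC", "NBS", "LRR"),
  RLK   = c("LRR", "TM", "KIN"),
  RLP   = c("LRR", "TM"),
  LYK   = c("LYSM", "LYSM", "TM", "KIN"),
  LYP   = c("LYSM", "LYSM", "TM"),
  LECRK = c("LECM", "TM", "KIN")
)

#' Simulation settings for the synthetic proteome
#'
#' @param seed Integer seed (the generator is fully deterministic given it).
#' @param nProteins Number of proteins (default 200).
#' @param classMix Named proportions over target classes; default uniform
#'   over the seven canonical classes. Must sum to 1.
#' @param domainLength Named list of `(min, max)` residue lengths for the
#'   directly synthesized segments; defaults `CC = (35, 42)`,
#'   `TM = (21, 25)`. HMM-planted domains take their length from the
#'   generating model.
#' @param substitutionNoise Per-residue substitution probability inside
#'   planted segments (default 0.05).
#' @param backgroundComposition Named length-20 residue probabilities for
#'   linkers; the default is polar-biased and depleted in hydrophobic
#'   residues so spurious transmembrane calls are rare (a property of the
#'   fixture, not a claim about biology).
#' @param linkerLength `(min, max)` linker length (default 15-40).
#' @param stochastic Draw class counts multinomially instead of realizing
#'   `classMix` exactly by largest-remainder rounding (default `FALSE`).
#' @return A [SimConfig-class].
#' @export
simConfig <- function(seed, nProteins = 200L, classMix = NULL,
                      domainLength = NULL, substitutionNoise = 0.05,
                      backgroundComposition = NULL,
                      linkerLength = c(15L, 40L), stochastic = FALSE) {
  if (is.null(classMix)) {
    classMix <- stats::setNames(rep(1 / 7, 7), CANONICAL_CLASSES)
  }
  dl <- list(CC = c(35L, 42L), TM = c(21L, 25L))
  for (nm in names(domainLength %||% list())) dl[[nm]] <- domainLength[[nm]]
  if (is.null(backgroundComposition)) {
    backgroundComposition <- c(
      A = 0.07, R = 0.06, N = 0.05, D = 0.06, C = 0.01,
      Q = 0.05, E = 0.07, G = 0.09, H = 0.02, I = 0.02,
      L = 0.04, K = 0.07, M = 0.02, F = 0.02, P = 0.05,
      S = 0.12, T = 0.07, W = 0.01, Y = 0.03, V = 0.03)
  }
  backgroundComposition <- backgroundComposition[AA_ALPHABET]
  backgroundComposition <- backgroundComposition / sum(backgroundComposition)
  new("SimConfig",
      seed = as.integer(seed),
      nProteins = as.integer(nProteins),
      classMix = classMix,
      domainLength = lapply(dl, as.integer),
      substitutionNoise = substitutionNoise,
      backgroundComposition = backgroundComposition,
      linkerLength = as.integer(linkerLength),
      stochastic = stochastic)
}

# Sample one generative pass through the model; returns the emitted residues
# and the state path as a data.frame of (type, state) events.
sample_hmm_path <- function(hmm) {
  M <- nStates(hmm)
  tr <- hmm@transitions
  events <- list()
  emit <- character()
  j <- 1L
  type <- "M"
  repeat {
    if (type == "M") {
      r <- sample(AA_ALPHABET, 1L, prob = hmm@matchEmissions[j, ])
      emit <- c(emit, r)
      events[[length(events) + 1L]] <- c("M", j, r)
      if (j == M) break
      nxt <- sample(c("M", "I", "D"), 1L, prob = tr[j, c("MM", "MI", "MD")])
      if (nxt == "M") { j <- j + 1L; type <- "M" }
      else if (nxt == "I") { type <- "I" }
      else { j <- j + 1L; type <- "D" }
    } else if (type == "I") {
      r <- sample(AA_ALPHABET, 1L, prob = hmm@insertEmissions)
      emit <- c(emit, r)
      events[[length(events) + 1L]] <- c("I", j, r)
      nxt <- sample(c("M", "I"), 1L, prob = tr[j, c("IM", "II")])
      if (nxt == "M") { j <- j + 1L; type <- "M" }
    } else { # delete
      events[[length(events) + 1L]] <- c("D", j, "-")
      if (j == M) break
      nxt <- sample(c("M", "D"), 1L, prob = tr[j, c("DM", "DD")])
      j <- j + 1L
      type <- nxt
    }
  }
  ev <- do.call(rbind, events)
  list(seq = paste(emit, collapse = ""),
       events = data.frame(type = ev[, 1], state = as.integer(ev[, 2]),
                           residue = ev[, 3], stringsAsFactors = FALSE))
}

#' Sample a sequence from a profile HMM
#'
#' Generative pass through the match/insert/delete states using the model's
#' own emission and transition probabilities, starting at the first match
#' state and ending at the last. Deterministic per seed.
#'
#' @param hmm A [ProfileHMM-class].
#' @param seed Optional integer seed (the caller's RNG state is restored).
#' @return The emitted sequence as a character scalar.
#' @export
sampleFromHMM <- function(hmm, seed = NULL) {
  with_seed(seed, sample_hmm_path(hmm)$seq)
}

# Expected emitted length of a generative pass, by backward recursion over
# the chain geometry (used as the independent oracle in the tests).
expected_sample_length <- function(hmm) {
  M <- nStates(hmm)
  tr <- hmm@transitions
  EM <- numeric(M + 1L)  # expected future emissions entering M_j (1-based)
  ED <- numeric(M + 1L)
  for (j in M:1) {
    if (j == M) {
      EM[j] <- 1
      ED[j] <- 0
      next
    }
    # I_j: geometric number of insert emissions, then to M_{j+1}
    EI <- 1 / tr[j, "IM"] + EM[j + 1L]  # E[# inserts] = 1/P(IM); each emits
    ED[j] <- tr[j, "DM"] * EM[j + 1L] + tr[j, "DD"] * ED[j + 1L]
    EM[j] <- 1 + tr[j, "MM"] * EM[j + 1L] + tr[j, "MI"] * EI +
      tr[j, "MD"] * ED[j + 1L]
  }
  EM[1L]
}

#' Generate a synthetic reference alignment and its generating model
#'
#' Builds a randomly parameterized generator model for one domain family and
#' samples an alignment from it. Emission divergence puts `divergence` of
#' the probability mass off the consensus residue at every match state, and
#' rows additionally receive extra substitution noise evenly spaced between
#' 0 and `divergence`, so the family spans a range of identities the way a
#' real reference family (close paralogs plus distant orthologs) does.
#' Insertions are padded with gaps, so the rows are aligned by construction.
#'
#' @param domainLabel Domain the family represents.
#' @param nRows Number of sequences (default 12).
#' @param divergence Emission divergence and maximum extra row noise
#'   (default 0.15).
#' @param seed Integer seed.
#' @param modelLength Number of match states; default per-domain
#'   (`TIR 80, NBS 120, LRR 100, LYSM 40, LECM 60, KIN 100`, else 80).
#' @return A list with `msa` (an `AAMultipleAlignment`), `hmm` (the
#'   generating [ProfileHMM-class]) and `rows` (the ungapped row sequences).
#' @export
makeReferenceMsa <- function(domainLabel, nRows = 12L, divergence = 0.15,
                             seed = 1L, modelLength = NULL) {
  if (nRows < 2L) stop("nRows must be >= 2", call. = FALSE)
  M <- as.integer(modelLength %||%
                    DEFAULT_MODEL_LENGTH[domainLabel] %||% 80L)
  if (is.na(M)) M <- 80L
  with_seed(seed, {
    consensus <- sample(AA_ALPHABET, M, replace = TRUE)
    div <- max(divergence, 1e-10)   # probabilities must stay positive
    em <- matrix(div / 19, nrow = M, ncol = 20,
                 dimnames = list(as.character(seq_len(M)), AA_ALPHABET))
    em[cbind(seq_len(M), match(consensus, AA_ALPHABET))] <- 1 - div
    bg <- rep(1 / 20, 20)
    names(bg) <- AA_ALPHABET
    # indel rates scale with divergence so that divergence -> 0 yields
    # rows identical to the consensus (0.2 * 0.15 = 0.03 at the default)
    indel <- max(0.2 * divergence, 1e-12)
    tr <- matrix(rep(c(1 - 2 * indel, indel, indel, 0.6, 0.4, 0.6, 0.4),
                     each = M),
                 nrow = M, ncol = 7,
                 dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II",
                                         "DM", "DD")))
    gen <- new("ProfileHMM",
               name = paste0("generator_", domainLabel),
               classOfOrigin = "pooled", domainLabel = domainLabel,
               matchEmissions = em, insertEmissions = bg,
               transitions = tr, background = bg,
               minBlosumScore = NA_real_)
    paths <- lapply(seq_len(nRows), function(i) sample_hmm_path(gen))
    # column layout: per model position, the widest insert block observed
    n_ins <- integer(M)
    for (p in paths) {
      ev <- p$events
      ins <- table(factor(ev$state[ev$type == "I"], levels = seq_len(M)))
      n_ins <- pmax(n_ins, as.integer(ins))
    }
    col_of_match <- cumsum(1L + c(0L, n_ins[-M]))  # column of match state j
    width <- M + sum(n_ins)
    rows <- matrix("-", nrow = nRows, ncol = width)
    extra <- if (nRows == 1L) 0 else
      divergence * (seq_len(nRows) - 1L) / (nRows - 1L)
    for (r in seq_len(nRows)) {
      ev <- paths[[r]]$events
      ins_seen <- integer(M)
      for (e in seq_len(nrow(ev))) {
        st <- ev$state[e]
        if (ev$type[e] == "M") {
          rows[r, col_of_match[st]] <- ev$residue[e]
        } else if (ev$type[e] == "I") {
          ins_seen[st] <- ins_seen[st] + 1L
          rows[r, col_of_match[st] + ins_seen[st]] <- ev$residue[e]
        }
      }
      # extra per-row substitution noise (to random background residues)
      res_idx <- which(rows[r, ] != "-")
      mut <- res_idx[stats::runif(length(res_idx)) < extra[r]]
      if (length(mut) > 0L) {
        rows[r, mut] <- sample(AA_ALPHABET, length(mut), replace = TRUE)
      }
    }
    aligned <- apply(rows, 1L, paste, collapse = "")
    names(aligned) <- paste0(domainLabel, "_ref", seq_len(nRows))
    msa <- Biostrings::AAMultipleAlignment(Biostrings::AAStringSet(aligned))
    list(msa = msa, hmm = gen,
         rows = vapply(aligned, ungap, character(1)))
  })
}

#' Generate reference families for every HMM-detected domain
#'
#' @param seed Integer seed; each family uses a sub-seed derived from it.
#' @param nRows,divergence Passed to [makeReferenceMsa()].
#' @return Named list (by domain label) of [makeReferenceMsa()] results.
#' @export
makeDomainReferences <- function(seed = 1L, nRows = 12L, divergence = 0.15) {
  out <- lapply(seq_along(HMM_DOMAINS), function(k) {
    sub_seed <- as.integer((as.numeric(seed) * 1009 + k) %%
                             .Machine$integer.max)
    makeReferenceMsa(HMM_DOMAINS[k], nRows = nRows, divergence = divergence,
                     seed = sub_seed)
  })
  names(out) <- HMM_DOMAINS
  out
}

#' Build and calibrate scan models from reference families
#'
#' Convenience wiring of the model-construction pipeline for per-domain
#' reference alignments: each family's alignment is turned into a profile
#' HMM with [buildProfileHMM()], passed through the retention criteria of
#' [filterHMMs()], and calibrated on its own rows with
#' [calibrateThreshold()].
#'
#' @param refs Named list as from [makeDomainReferences()].
#' @return Named list of calibrated [ProfileHMM-class] objects.
#' @export
buildScanModels <- function(refs) {
  candidates <- lapply(names(refs), function(d) {
    buildProfileHMM(refs[[d]]$msa, d, "pooled",
                    name = paste0("pooled_", d, "_1"))
  })
  training <- lapply(refs, function(r) r$rows)
  flt <- filterHMMs(candidates, training)
  if (nrow(flt$log) > 0L && any(!flt$log$retained)) {
    warning("rejected candidate model(s): ",
            paste(flt$log$name[!flt$log$retained], collapse = ", "),
            call. = FALSE)
  }
  models <- lapply(flt$retained, function(hmm) {
    calibrateThreshold(hmm, training[[hmm@domainLabel]])
  })
  stats::setNames(models, vapply(models, domainLabel, character(1)))
}

# Exact class counts by largest-remainder rounding (ties by class order).
largest_remainder <- function(mix, n) {
  raw <- mix * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0L) {
    ord <- order(-(raw - base), seq_along(raw))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(base), names(mix))
}

sample_background <- function(n, comp) {
  if (n <= 0L) return(character(0))
  sample(AA_ALPHABET, n, replace = TRUE, prob = comp)
}

# Ideal heptad repeat: leucine zipper core (L at a/d), charged outer shell.
sample_cc_segment <- function(len) {
  pos <- ((seq_len(len) - 1L) %% 7L) + 1L
  res <- character(len)
  core <- pos %in% c(1L, 4L)
  res[core] <- "L"
  res[!core] <- sample(c("E", "K", "Q", "R"), sum(!core), replace = TRUE,
                       prob = c(0.35, 0.35, 0.15, 0.15))
  res
}

sample_tm_segment <- function(len) {
  sample(c("L", "I", "V", "F", "A"), len, replace = TRUE,
         prob = c(0.40, 0.25, 0.20, 0.10, 0.05))
}

apply_noise <- function(res, noise, comp) {
  if (noise <= 0 || length(res) == 0L) return(res)
  hit <- stats::runif(length(res)) < noise
  if (any(hit)) {
    res[hit] <- sample(AA_ALPHABET, sum(hit), replace = TRUE, prob = comp)
  }
  res
}

#' Generate a synthetic proteome with planted architectures
#'
#' Draws a class for each protein from the configured mix (exactly, by
#' largest-remainder rounding, unless `stochastic`), assembles its
#' N-to-C architecture from linkers and planted segments, applies
#' substitution noise inside the planted segments, and records the exact
#' coordinates of every planted domain. HMM domains are sampled from the
#' supplied generator models; CC segments are ideal heptad repeats and TM
#' segments hydrophobic stretches.
#'
#' @param config A [SimConfig-class].
#' @param models Named list (by domain label) of generator
#'   [ProfileHMM-class] objects covering every HMM domain used by the
#'   configured classes, e.g. `lapply(makeDomainReferences(seed), "[[",
#'   "hmm")`.
#' @return A list with `proteome` (a named `AAStringSet`) and `truth` (a
#'   `data.frame` with `protein_id`, `class_label`, `domain_label`, `start`,
#'   `end`).
#' @export
makeSyntheticProteome <- function(config, models) {
  stopifnot(is(config, "SimConfig"))
  needed <- setdiff(unique(unlist(ARCHITECTURES[names(config@classMix)])),
                    SEGMENT_DOMAINS)
  missing <- setdiff(needed, names(models))
  if (length(missing) > 0L) {
    stop("no generator model for domain(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  with_seed(config@seed, {
    counts <- if (config@stochastic) {
      stats::setNames(as.integer(stats::rmultinom(1L, config@nProteins,
                                                  config@classMix)),
                      names(config@classMix))
    } else {
      largest_remainder(config@classMix, config@nProteins)
    }
    class_of <- rep(names(counts), counts)
    comp <- config@backgroundComposition
    lk <- config@linkerLength
    seqs <- character(length(class_of))
    truth <- list()
    for (p in seq_along(class_of)) {
      cls <- class_of[p]
      id <- sprintf("synthetic_%04d", p)
      arch <- ARCHITECTURES[[cls]]
      if (is.null(arch)) {
        stop("no architecture defined for class ", cls, call. = FALSE)
      }
      res <- sample_background(sample(lk[1]:lk[2], 1L), comp)
      for (d in arch) {
        seg <- if (d == "CC") {
          rng <- config@domainLength$CC
          sample_cc_segment(sample(rng[1]:rng[2], 1L))
        } else if (d == "TM") {
          rng <- config@domainLength$TM
          sample_tm_segment(sample(rng[1]:rng[2], 1L))
        } else {
          seq_chars(sample_hmm_path(models[[d]])$seq)
        }
        seg <- apply_noise(seg, config@substitutionNoise, comp)
        truth[[length(truth) + 1L]] <- data.frame(
          protein_id = id, class_label = cls, domain_label = d,
          start = length(res) + 1L, end = length(res) + length(seg),
          stringsAsFactors = FALSE)
        res <- c(res, seg, sample_background(sample(lk[1]:lk[2], 1L), comp))
      }
      seqs[p] <- paste(res, collapse = "")
      names(seqs)[p] <- id
    }
    proteome <- Biostrings::AAStringSet(seqs)
    list(proteome = proteome, truth = do.call(rbind, truth))
  })
}

#' Write a simulation to disk
#'
#' Writes `proteome.fasta`, `truth.tsv` and a YAML echo of the
#' configuration; outputs are byte-identical across reruns with the same
#' configuration.
#'
#' @param sim Result of [makeSyntheticProteome()].
#' @param config The [SimConfig-class] used.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
writeSimulation <- function(sim, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFasta(sim$proteome, file.path(dir, "proteome.fasta"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- list(seed = config@seed, n_proteins = config@nProteins,
              class_mix = as.list(config@classMix),
              domain_length = config@domainLength,
              substitution_noise = config@substitutionNoise,
              background_composition = as.list(config@backgroundComposition),
              linker_length = config@linkerLength,
              stochastic = config@stochastic)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
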