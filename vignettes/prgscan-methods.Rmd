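---
title: "Models and methods behind prgscan"
author: "prgscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind prgscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Plant genomes defend themselves with two layers of inducible immunity.
Surface receptors — receptor-like proteins (RLP) and receptor-like kinases
(RLK), plus their LysM- and lectin-motif analogues (LYP, LYK, LECRK) —
recognize conserved pathogen patterns and trigger PAMP-triggered immunity.
Intracellular NLR receptors, which combine a nucleotide-binding site (NBS)
with leucine-rich repeats (LRR) and either a Toll/interleukin-1 receptor
domain (TNL) or a coiled coil (CNL), drive the stronger effector-triggered
response. All seven canonical classes are defined by their *domain
architecture*, which makes pathogen-recognition gene (PRG) annotation a
domain-detection-plus-classification problem:

1. locate resistance domains (TIR, NBS, LRR, LysM, lectin motif, kinase) on
   each protein with per-domain profile HMMs;
2. locate coiled-coil and transmembrane (TM) segments with dedicated
   sliding-window predictors;
3. map the detected domain set to a canonical class or a compact
   non-canonical architecture code;
4. benchmark the annotation against an independent reference.

`prgscan` implements that pipeline as a tested library plus a thin
command-line wrapper, together with a synthetic-data generator that plants
known architectures so every stage can be verified end to end without any
external downloads.

# Profile HMMs

## Construction

Each domain model is built from a reference multiple sequence alignment
(one per PRG class; regions of the alignment are mapped to domain labels by
a small TSV table). Columns with a gap fraction below 0.5 become match
states. Emissions and transitions are Laplace-smoothed relative
frequencies, `(count + 1) / (total + k)`, with `k = 20` residues for
emissions and `k = 3` or `2` outgoing transitions per state class; the
background is the smoothed residue frequency of the whole sub-alignment and
also serves as the insert-state emission distribution. Laplace smoothing is
the simplest estimator that keeps every probability positive; with a dozen
reference sequences per family, more elaborate priors (Dirichlet mixtures,
sequence weighting) would be dominated by the data anyway and are
deliberately out of scope.

In addition to the per-class models, LysM regions from the LYK and LYP
alignments are pooled (row-concatenated, with terminal-gap padding if the
two blocks differ in width) into one extra model, because the motif is
shared and the pooled family is more robust; lectin-motif regions tagged
with a subtype (legume- vs bulb-type) keep separate models.

## Scanning

Scanning uses *local* (free-endpoint) alignment semantics: a path may enter
any match state at any residue and exit from any match state, and residues
outside the hit score as background. Scores are log-odds in nats
(emission log-probability minus background log-probability, plus transition
log-probabilities). The dynamic programme is implemented in C++; multiple
occurrences are found by masking the best hit and rescanning. This is
simpler than a Plan7-style multi-hit architecture and, crucially, admits a
brute-force oracle: for models with up to 4 match states and sequences up
to 6 residues the test-suite enumerates *every* path and checks Viterbi and
forward scores to 1e-9 nats.

Each accepted hit is then scored a second time: the hit subsequence is
globally aligned to the model consensus (per-state argmax residue) under
BLOSUM62 with affine gap costs 11/1 (the standard pairing for that matrix),
through `Biostrings::pairwiseAlignment`. `X` scores zero against
everything. A hit is reported when its log-odds score is positive *and*
its BLOSUM62 score reaches the model's calibrated threshold.

## Retention criteria and threshold calibration

Candidate models pass three retention criteria before use: (i) models for
non-relevant regions are dropped — TM and coiled-coil segments are
predicted by the dedicated window predictors, never by HMMs; (ii) a model
must re-detect every sequence it was built from; (iii) when a legacy model
for the same domain exists, the candidate replaces it only if its
presence/absence F-score on a labeled benchmark is at least as high.

The per-model threshold is anchored to the reference family itself. We
score every reference positive and set

```
min_blosum_score = floor( min(scores) - sd(scores) )
```

with the spread term zero for a single positive. The minimum guarantees
that every reference sequence is re-detected at or above threshold — the
references act as anchors, which is also why calibration is idempotent.
The spread term matters for *novel* family members: a family whose
references span a range of identities produces hit scores with exactly that
spread, and an unseen member is as likely to sit one spread-width below the
weakest reference as between the references. Anchoring at the bare minimum
(a rule we tried first) rejected roughly the weakest 5-10% of held-out
family members in simulation while adding nothing to specificity — for
unrelated sequence the global BLOSUM62 score against a domain consensus is
strongly negative, hundreds of points below any calibrated threshold, so
the false-positive behaviour is insensitive to the exact anchor.

# Coiled-coil and transmembrane predictors

Classification only consumes the *presence* of CC and TM segments, so both
predictors are deliberately simple window models whose module boundaries
allow a drop-in replacement.

**Coiled coils** are scored in the classic heptad-propensity way: a
21-residue window (three heptads) is scored by the geometric mean of
per-residue propensities at their heptad positions `a`-`g`, the maximum
over the seven register offsets is taken, and the score is converted to a
probability by the ratio of two Gaussian score densities (coiled-coil vs
globular). Residues keep the maximum probability over all windows covering
them; maximal runs of at least 14 residues at probability 0.5 or higher
become segments. The shipped propensity table is a Lupas-style table
authored for this package — hydrophobics high at the core positions `a`/`d`,
charged/polar residues favoured at the outer positions, helix breakers
penalized everywhere — with Gaussian parameters
(cc: mean 1.85, sd 0.18; globular: mean 0.90, sd 0.22) calibrated to that
table so that an ideal leucine-zipper repeat scores ~1.9 and typical
globular windows score well below the ~1.4 decision point. The tests use a
separate synthetic table with the same qualitative structure, so no shipped
constant is load-bearing for correctness.

**Transmembrane segments** use a Kyte-Doolittle hydropathy window: windows
of 19 residues with mean hydropathy at least 1.6 are unioned, unions closer
than 5 residues are merged, and each segment reports its peak window mean.
This replaces a cyclic-HMM topology predictor (whose parameters are not
publicly printed) by the classic rule that reliably flags single membrane
spans; topology (in/out orientation) and signal peptides are out of scope.

# Architecture classification

Classification is a pure function of the detected domain *set* — the
canonical classes are defined by domain content, not order, so N-to-C order
is kept only in the display code. The first matching rule wins:

| rule | architecture | class |
|------|--------------------------------|-------|
| 1 | TIR + NBS + LRR | TNL |
| 2 | CC + NBS + LRR, no TIR | CNL |
| 3 | LRR + TM + KIN, no NBS | RLK |
| 4 | LRR + TM, no KIN, no NBS | RLP |
| 5 | LYSM + TM + KIN | LYK |
| 6 | LYSM + TM, no KIN | LYP |
| 7 | LECM + TM + KIN | LECRK |

Everything else is `NONCANONICAL`, labeled with a compact code over the
fixed order `CC>C, TIR>T, NBS>N, LRR>L, LYSM>Y, LECM>E, KIN>K, TM>M` (so
`{NBS, LRR}` reads `NL`). Three design points deserve a note. TNL/CNL do
not require the *absence* of a TM — some NLRs carry predicted membrane
spans — while rules 3-4 exclude NBS so such proteins are never misread as
receptor kinases. The rule order resolves the rare multi-match sets (e.g.
`{LRR, LYSM, TM, KIN}` classifies RLK, the LRR-bearing reading). And a
lectin motif without a kinase (`{LECM, TM}`) stays non-canonical because no
such canonical class is defined. The test-suite enumerates all 256 subsets
of the vocabulary against an independent restatement of these rules.

# Validation

Predictions are compared to a reference annotation at protein level, on
presence/absence of the five HMM-specific resistance domains (TIR, NBS,
LRR, LYSM, LECM — CC and TM come from stand-in predictors and the kinase
domain is shared by too many non-PRG proteins to be diagnostic).
*Criterion 1* requires the predicted domain set to be identical to the
reference; *criterion 2* accepts predictions that are equal or better,
operationalized as superset-of-reference — the only partial order under
which "identical" is the stronger criterion. Sets, not multiplicities, are
compared: the criteria are defined at protein level, and tandem repeats of
one motif carry no extra architectural information. Confusion-matrix
metrics (accuracy, precision, sensitivity, specificity, F-score) are
tallied per (protein, domain) cell, per domain and pooled; a ratio with a
zero denominator is reported as `NA`, never 0.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
verified.

**Reference families** (`makeReferenceMsa`): a generator model with a
random consensus puts `1 - divergence` emission mass on the consensus
residue (divergence 0.15 by default), with insertion/deletion rates scaled
as `0.2 * divergence` so that zero divergence yields identical rows. Rows
are sampled from the model and receive additional substitution noise evenly
spaced between 0 and `divergence` across rows, emulating a real reference
family's mix of close paralogs and distant orthologs — the property that
anchors threshold calibration. Because rows are sampled with their state
paths, the alignment is exact by construction (insertions padded with
gaps). Default model lengths are scaled-down but rank-realistic domain
sizes: TIR 80, NBS 120, LRR 100, LysM 40, lectin motif 60, kinase 100
match states, with 12 rows per family.

**Proteomes** (`makeSyntheticProteome`): classes are drawn from a
configurable mix (uniform over the seven canonical classes by default) and
realized *exactly* by largest-remainder rounding, so truth-table counts are
crisp (a `stochastic` flag restores multinomial sampling). Architectures
are assembled N-to-C with linkers of 15-40 residues: HMM domains are fresh
samples from the generator models (LysM receptors carry two tandem
motifs, as their natural counterparts do), coiled coils are ideal heptad
repeats (leucine at `a`/`d`, charged residues elsewhere; 35-42 residues),
TM segments are hydrophobic stretches of 21-25 residues, and every planted
segment receives 5% per-residue substitution noise by default. Linkers are
drawn from a polar-biased background composition deliberately depleted in
hydrophobic residues so spurious TM calls are rare — a property of the
fixture, not a claim about biology. Everything is deterministic per seed,
to the byte.

**What passing does and does not show.** The generator produces domains
whose divergence structure is i.i.d. per site; real domains have conserved
motifs, repeat structure (LRRs especially), and compositional bias, and
real proteomes contain decoy families that share motifs with PRGs. Recovery
of planted architectures therefore demonstrates the pipeline's internal
consistency — construction, calibration, scanning, classification and
bookkeeping agree — not field performance on real proteomes, which depends
on curated reference alignments.

# Numerical choices and degenerate inputs

* Scores are nats internally, printed to 3 decimals; TSV/JSON output uses
  fixed formatting so identical runs are byte-identical.
* Viterbi ties are broken towards the smallest hit start, then the smallest
  end; consensus ties towards the first residue in `A R N D C Q E G H I L K
  M F P S T W Y V` order — all deterministic.
* `X` is the only ambiguity code accepted in protein input (`N` in DNA,
  translated to `X`); it scores as background in HMMs, zero in BLOSUM62,
  propensity 1 in the coiled-coil model and hydropathy 0 in the TM model.
* Six-frame translation handles DNA input; `*` terminates a product and
  only stop-free segments of at least 30 residues are scanned.
* Proteins shorter than a predictor window yield empty output, not errors;
  a malformed record in a proteome is skipped with a warning and named in
  the annotation's `skipped` field.
* Mask-and-rescan is capped at 15 hits per model per protein — beyond any
  biological architecture, but a hard stop against pathological inputs.
* The model-construction study sizes (families of 12 rows, 200-protein
  study proteomes) keep the full test-suite and the acceptance run to a
  few minutes on a single core while leaving the statistics (hundreds of
  planted domains) stable.

# Known limitations

* The HMM scanner is single-hit-per-pass local alignment; domains split by
  very long insertions can be reported as two merged hits rather than one.
* CC and TM predictors are presence-oriented stand-ins: no topology, no
  signal-peptide discrimination, and the shipped coiled-coil constants are
  package-versioned rather than tool-identical.
* Thresholds assume the reference family spans the divergence of the
  sequences to be annotated; a family of near-identical references will
  calibrate a strict threshold and miss distant members (by design — the
  anchor logic follows the curated-database convention).
* Validation is presence/absence per domain type; per-residue boundary
  accuracy is not assessed.
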