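---
title: "Screening proteomes for pyrenoid Rubisco linker proteins"
author: "flipper package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening proteomes for pyrenoid Rubisco linker proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flipper)
```

## The problem

Most eukaryotic algae condense Rubisco into a pyrenoid, a liquid--liquid
phase-separated (LLPS) chloroplast subcompartment at the heart of their
CO2-concentrating mechanism.  The scaffold of the condensate is a linker
protein -- EPYC1 in *Chlamydomonas reinhardtii*, CsLinker in *Chlorella
sorokiniana* -- a multivalent intrinsically disordered protein whose short
repeated "sticker" motifs bind Rubisco and cross-link holoenzymes into a
dense phase.  Linkers from different lineages share essentially no sequence
homology (the two named above align at only ~25% identity), so homology
search does not transfer between species.  What they do share is an
architecture:

1. they are **largely disordered**;
2. they carry **several near-identical tandem repeat units**, each
   presenting a short amphipathic sticker motif with hydrophobic
   (&Phi;) and electrostatic (&zeta;) residues;
3. the units recur every **20--120 residues**, the ~2--8 nm chain length
   able to bridge adjacent Rubisco holoenzymes.

This package screens whole proteomes for that architecture rather than for
homology, and implements the quantitative curve analyses used to
characterize a candidate once found (binding affinity, FRAP mobility,
sedimentation titrations, absolute quantification).

## The screen

`runFlipper()` applies four filters in a fixed order, recording survivor
counts after each:

1. **Physicochemical bands** -- mature length, isoelectric point, and the
   &Phi; = \{A,V,L,I,M,F,W,Y\} and &zeta; = \{D,E,K,R\} residue-class
   fractions must fall inside configured bands.  pI comes from a
   Henderson--Hasselbalch charge model with the EMBOSS pKa set, solved by
   bisection to |net charge| < 10^-3^ (the root is unique because the
   charge is strictly decreasing in pH and both termini always titrate).
   Histidine sits in neither class by default: it is only weakly charged
   at neutral pH (configurable).  Cys and Tyr titrate for pI but do not
   count as &zeta; stickers.
2. **Tandem repeats** -- `findTandemRepeats()` must report a hit with unit
   length in the 20--120 band (details below).
3. **Sticker content** -- the best hit's consensus must contain at least 1
   &Phi; and 2 &zeta; residues ("interacting residues"; both counts are
   config keys).
4. **Disorder** -- at least half the residues must be called disordered,
   either by the built-in charge--hydropathy index or by an external
   per-residue predictor table.

Thresholds are not free-floating: `calibrateConfig()` derives them from a
known reference linker (pI band = reference ± 2 pH units; length band =
0.3--3&times; the reference; class-fraction minima = half the reference's;
all margins overridable) and then verifies that the reference passes its
own configuration, so a miscalibration fails immediately.  Screen hits are
ranked by `copies × identity × disorder fraction` -- a multivalency-times-
disorder surrogate for the manual structure inspection used downstream in
the original screen, not an equivalent of it -- and intersected with co-IP
enrichment tables (`enrichmentFilter()`, strict `log2FC > 4` and
`-log10 adjusted P > 4`) to pinpoint the linker.

## The repeat detector

The detector assumes a substitution-only model with a fixed unit length:
the repeat units of the known linkers are near-equal in length, so no
indel alignment is attempted inside units (declared limitation; the
`jitter` config key expresses the ±2-residue period tolerance used when
benchmarks compare a detected period against a planted one).  For each
candidate period *p* the sequence is compared to itself at lag *p*; runs
of high local match density seed candidate regions, which are refined by
enumerating nearby start phases and copy counts.  Each candidate
decomposition is scored against a per-column majority-vote consensus (ties
broken alphabetically, for determinism), trimmed to the first and last
copy with identity ≥ 0.7, and a trailing partial copy of at least half a
period counts fractionally.  Validity also requires at least 3 copies
(the minimum valence for cross-linking a network) and at least 5 distinct
consensus residues -- the low-complexity guard that stops short-period
repeats (poly-A, (GPP)~n~, ...) from re-entering the band through their
harmonics.

The objective maximized is `score = copies × period × identity`, with ties
preferring the smaller period, then the smaller start.  Two numerical
choices matter:

* **Exact below a work bound.**  When
  `(length − 2·periodMin) × band width ≤ 2000`, every start phase is
  enumerated and the returned top hit is exactly the score optimum;
  longer sequences use the seeded path with the identical scorer.  Seeding
  alone provably misses weak incidental repeats on short strings, because
  adjacent-copy self-matches understate copy-vs-consensus identity.  The
  test suite holds the detector to an independent brute-force enumeration
  oracle on short 4-letter strings.
* **Score-guarded harmonic suppression.**  A hit whose period is a
  multiple of a kept hit's period is dropped as a harmonic only when the
  base-period hit scores at least as high (and covers ≥ 80% of its span
  with identity within 0.05).  Without the score guard, suppression could
  demote the true score optimum.  A related edge is worth knowing: for a
  tandem with an *odd* copy count, the period-doubled representation can
  sometimes out-score the true period by absorbing a few lucky flank
  matches at the 0.7 identity floor; with even copy counts the doubled
  period can at best tie and loses the tie-break.

## Disorder scoring

The built-in predictor is the classic charge--hydropathy unfoldability
index: over a sliding window (default 51 residues, truncated at the
termini rather than padded),

$$I = 2.785\,\langle H\rangle - |\langle R\rangle| - 1.151,$$

with ⟨H⟩ the mean Kyte--Doolittle hydropathy rescaled to [0,1] and ⟨R⟩
the mean integer charge (K,R = +1; D,E = −1; H = 0 by default; X counts
toward window size but contributes zero).  Residues with *I* < 0 are
called disordered.  The published constants are fixed; the form is
self-contained, fast, and adequate for the coarse "largely disordered"
call the screen needs.  It is *not* a modern disorder predictor: screens
meant to mirror predictor-based runs should load per-residue probabilities
from any external tool via `loadDisorderScores()` (TSV of id/pos/score,
call at ≥ 0.5); proteins absent from such a table are reported missing,
never silently passed.  The default disorder-fraction threshold of 0.5
is a declared package default -- the screen's original threshold is not
recoverable -- and is a config key like every other cutoff.

## The synthetic benchmark

`generateProteome()` builds seeded proteomes with known ground truth so
the full pipeline is testable without downloads.  Planted linkers are a
leader (20--40 residues) plus 3--8 copies of a unit made of a 10-residue
amphipathic sticker (three hydrophobic residues, two basic plus one
acidic, at a fixed register -- an invented template, deliberately not any
real linker's motif; 10 residues matches the length of the single stable
helix in real linker repeats) followed by a disordered spacer biased
toward S, P, G, E, K, T.  Unit lengths are drawn from 35--90 residues:
the known linkers repeat at ~60--65-residue units, and a single
calibration reference's 0.3--3&times; length band cannot span proteins
built from the detector's full 20--120 feasibility band (a property of
calibration, not detection).  The spacer is lysine-biased over glutamate
(0.18 vs 0.10) so assembled linkers are net basic like the real,
Lys/Arg-rich linker class; each construct is verified post-generation to
be majority-disordered and net basic at pH 7, resampling up to 10 times
(bounded resampling rather than analytic guarantees), because tandem
copying amplifies any bias of the single drawn unit.  Copies are mutated
at a 5% per-residue substitution rate.

Three decoy classes each fail one designated stage by construction
(verified at generation): hydrophobic-rich globular-like sequence fails
the disorder call; non-repetitive disordered sequence carries no repeat;
short-period low-complexity repeats are rejected by the distinct-residue
guard.  Record order is shuffled and ids carry no class information.
`generateEnrichmentTable()` emulates the shape of a DIA co-IP
differential-abundance table, planting true positives above the strict
volcano thresholds and background below.

What passing the benchmark does and does not show: the generator emulates
the *architecture* (repeats, stickers, disorder, basicity) but not real
transit peptides, real amino-acid covariation, annotation errors, or
predictor-version effects; perfect sensitivity on synthetic linkers
therefore bounds expectations on real proteomes rather than predicting
candidate counts.  On a real annotated proteome the candidate count is
also sensitive to the disorder predictor used, which is why external
score tables are first-class inputs.

`syntheticLinkerReference()` provides two deterministic stand-ins built
from the same architecture -- a six-repeat, 65-residue-unit
CsLinker-style protein and a four-repeat, 60-residue-unit EPYC1-style
protein.  They are clearly synthetic (the real sequences are not
redistributed in this package) and serve as calibration references and
demonstration material.

## Curve fitting

`fitHill()` fits the hyperbolic occupancy form
`y = Bmax·x/(KD + x)` -- the Hill equation with the coefficient fixed at 1,
matching the printed model it reproduces -- so the half-occupancy
concentration K~0.5~ equals K~D~.  `fitFrap()` fits
`y(t) = A·(1 − e^{−kt})` to post-bleach data with `t = 0` at the first
post-bleach frame, and derives T~0.5~ = ln 2 / k.  `normalizeFrap()`
performs the standard double normalization in the order background
subtraction → photobleach correction (divide by the unbleached
reference) → full-scale normalization (divide by the mean pre-bleach
value); the order is declared and configurable in principle but fixed
here, and the pre-bleach mean of the output is exactly 1.  Both fits use
Levenberg--Marquardt least squares with documented initializations
(`Bmax0 = max y`, `KD0` = concentration nearest half-max; `A0` = last
intensity, `k0 = 1/t_half`), are scale-equivariant, and never end with a
worse residual sum of squares than their initialization.  Uncertainties
come from a seeded residual-resampling bootstrap (default 1,000
replicates, percentile intervals); the original analyses' intervals came
from an unstated fitting package, so a reproducible scheme is
standardized here instead.  Degenerate inputs fail loudly: flat FRAP
traces (k unidentifiable), all-zero responses, and titrations with fewer
than 3 distinct concentrations are errors, and a titration with no
points on both sides of the apparent midpoint warns.

`pelletFraction()` (P/(P+S)) and `titrationSeries()` quantify droplet
sedimentation assays; the series fit reports the concentration reaching
95% of the fitted plateau (19·K~D~ for the hyperbolic form) as the
saturation point of a demixing titration.  `calibrationQuantify()`
interpolates sample intensities on an ordinary least-squares standard
line and converts amounts to copies per cell and molar concentration in a
compartment of known volume; extrapolation beyond the standard range is
an error unless explicitly allowed, and is flagged either way.

## Worked example

```{r example}
ps <- generateProteome(syntheticSpec(
  seed = 7, nLinkers = 3,
  nDecoys = c(globular = 10, disordered = 10, lowcomplexity = 10)
))
cfg <- calibrateConfig(syntheticLinkerReference("epyc1"))
screen <- runFlipper(ps$proteome, cfg)
screen
rankCandidates(screen)[, c("id", "repeatPeriod", "repeatCopies",
                           "fractionDisordered", "rankScore")]
```

```{r enrich}
planted <- ps$truth$id[ps$truth$class == "linker"][1]
enr <- generateEnrichmentTable(ps$truth$id, planted, seed = 7)
intersectCandidates(rankCandidates(screen)$id, enrichmentFilter(enr))
```

## Problem sizes and defaults used by the checks

The shipped tests and the acceptance script run the screen on a
610-protein synthetic proteome (10 linkers, 200 decoys per class), hold
the detector to exhaustive enumeration on 200+ short 4-letter strings
(band 3--10, minimum identity 0.7, distinct-residue guard 2 -- a 4-letter
alphabet cannot meet the protein default of 5), verify the pI solver on
100 random peptides against a 10^-4^-step grid scan, and use 200-replicate
noise simulations for the fits (2% intensity noise for FRAP, 3% for
binding).  These sizes were chosen to exercise every code path at
desk scale.

## Known limitations

* No indel tolerance inside repeat units; linkers whose units drift in
  length by more than the jitter tolerance will score poorly.
* The built-in disorder index is a coarse charge--hydropathy rule; use
  external per-residue scores to mirror predictor-based screens.
* Transit peptides are handled by a manual `matureTrim` count, not
  predicted.
* Candidate counts on real proteomes depend on annotation and predictor
  versions; the package promises its stage logic and thresholds, not a
  particular count.
* `rankScore` orders candidates for triage; it encodes no structural
  information.
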