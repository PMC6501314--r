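---
title: "Methods: structural profiling of grass glucuronoarabinoxylan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural profiling of grass glucuronoarabinoxylan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaxr)
library(dplyr)
```

gaxr models the structural analysis of grass glucuronoarabinoxylan (GAX):
a β-1,4-xylan backbone whose xylopyranosyl (Xyl*p*) residues carry at most
one side chain — α-1,3-arabinofuranose (Ara*f*), α-1,2-(4-*O*-methyl)
glucuronate ([Me]GlcA), or the disaccharide branches
β-Xyl*p*-(1→2)-α-Ara*f*-(1→3) ("D^2,3^") and Ara*f*-(1→2)-α-Ara*f*-(1→3)
("B^2,3^"). This vignette documents the models, the tunable parameters,
and the design decisions behind each processing stage. Acetylation and
feruloylation are outside the structure model: the analytical workflow the
package mirrors saponifies the material, which removes both.

## The structure model and Faure nomenclature

A structure is an integer vector, one entry per backbone residue (position
1 = non-reducing end), each entry a side-chain code. The one-letter Faure
grammar maps one token to one backbone residue: `X` (unsubstituted),
`A^p`/`U^p` with attachment position p ∈ {2, 3}, `U^(4Me)p`, and the
disaccharide codes `D^2,3` / `B^2,3` (always O-3 attached). Parsing and
serialization are exact inverses, which the test suite asserts on random
structures; generic tokens such as `A^2` that do not occur in the packaged
library are still grammatical so that foreign structures (cereal-grain
arabinoxylan) can at least be represented and flagged downstream.
Di-substituted residues are not representable in the default encoding:
none were detected in the vegetative-tissue material the library
describes.

One library entry could not be resolved structurally (the `N11` species is
either `B^2,3U^(4Me)2XX` or `D^2,3U^(4Me)2XX`). The library carries both
names on a single entry (`faure_name` + `alt_name`) rather than deciding;
enzyme predicates use the D-type candidate, whose CgGH3 resistance is
modelled as steric blocking by the neighbouring [Me]GlcA — the same
observable behaviour the B-type assignment would give, so the choice does
not affect any tested cell.

## Masses and fragment-ion prediction

Monoisotopic residue masses: pentose 132.0423 Da, GlcA 176.0321 Da,
MeGlcA 190.0477 Da; neutral mass = residues + water (18.0106); the 2-AA
reducing-end label adds a net 121.0528 Da; all ions are sodiated
(+22.9898). Glycosidic B/C/Y/Z ions are enumerated for every backbone bond
*and* every side-chain bond (loss of a whole chain or of a disaccharide
chain's terminal residue); cross-ring ^1,5^X/^1,4^X ions sit at Y + CO and
^0,2^X at Y + C₂H₂O, the latter retaining an O-2 uronate as a lactone
(+ chain − H₂) when that position is substituted.

The extended diagnostic families (W, D, E, G, V, H) are generated from a
fitted offset table, not first-principles chemistry — the published
spectra use them with context-dependent compositions, so each rule is
anchored to printed instances and validated against the complete packaged
ion ledgers (`cid_ledgers()`, 14 spectra, every printed ion matched within
1 Da):

* **W** (sugar lactone, O-3 substitution marker): Y_k − m(O-3 chain) − H₂.
* **E** (O-2 probe): non-reducing fragment + Na − O, with a variant that
  eliminates an O-2 uronate on the fragment's reducing-boundary residue;
  **H** = E + CH₄O.
* **G**: Y_r − m(O-3 chain) − (H₂ + CH₄O) at O-3-substituted residues,
  Y_r − (H₂ + CH₄O) at O-2 uronate residues, precursor − 48.0 whenever the
  structure contains Ara*f*, and precursor − (H₂ + CH₄O) as the
  terminal-Xyl*p* diagnostic of D-type chains.
* **V** (4-*O*-methyl marker): precursor − 76.016 (C₂H₄O₃).
* **D**: disaccharide chain + Na − O.

Printed precursors above m/z 1000 sit up to ~0.5 Da above the monoisotopic
model — low-resolution MALDI calibration drift — so matching tolerances
default to 1.0 Da for observed spectra, with 0.5 Da used in fixture
assertions below m/z 1000. Prediction keeps one row per (family, index)
without collapsing equal-m/z duplicates (`^1,5X`/`^1,4X` coincide), so
that two observed peaks can each claim a partner; `collapse = TRUE` gives
the deduplicated view. Annotation is greedy nearest-match with each
observed peak and each predicted row used at most once; ties resolve
toward the lower fragment index for determinism. Candidate ranking orders
by observed peaks explained, then summed |error| — with a handful of
curated ledger ions, the fraction of the (deliberately generous) predicted
set that is observed would punish the correct, richer candidate.

## Enzyme models

Endo-xylanase specificity is a blocked-subsite map: for a scissile bond,
subsite −1 is the residue donating the product's new reducing end, +1 its
reducing-side neighbour. Defaults: GH10 — every substituent blocks {−1};
GH11 — Ara*f* blocks {−1, +1}, [Me]GlcA and the disaccharide chains block
{−2, −1, +1}. These minimal maps reproduce the characteristic product
families (`A^3X`/`U^(4Me)2X`-type from GH10; `XA^3XX`/`XU^(4Me)2XX`-type
from GH11) and every tested cell of the packaged sensitivity table.
Complete digestion is deterministic leftmost-greedy: scan bonds from the
non-reducing end, cut the first cleavable bond leaving both fragments at
least `min_product_dp` (default 2) long, recurse. A kinetic simulation
would change the product distribution but not the quantitation result:
substitution frequencies depend only on conserved residue totals.
`candidate_products()` enumerates every fragment bounded by cleavable
bonds or substrate ends — the product set across partial digests — and is
the membership test for "is this a GH10/GH11 product"; minor GH11 species
with substituted non-reducing ends arise only as non-reducing-terminal
fragments, matching the published interpretation.

Exo-enzyme action is a per-enzyme structural predicate (see
`?exo_rule`). Two points deserve note. GH67 is implemented as the
empirical "acts when [Me]GlcA is present and backbone DP ≥ 3": the
classical terminal-only mechanism would contradict the observed
sensitivity of `XU^2XX`, whose uronate sits on an internal residue; the
tension between mechanism and observation is left as documented
behaviour. GH115's requirement of an unsubstituted (or absent)
non-reducing-side neighbour reproduces both its action on
aldouronic acids and its failure on `A^3U^(4Me)2XX` and the N11 species.

## Electropherogram processing

Traces are two-column (seconds, RFU) series. Alignment maps observed
mobility-marker times onto fixed reference positions by a piecewise-linear
warp with linear extrapolation beyond the terminal markers; at least two
markers are required and order violations are errors. Peak detection runs
on the baseline-subtracted signal: baseline is a running median (default
window 121 s, chosen ≫ peak width so the median ignores peaks), noise is
1.4826 × MAD of the detrended signal, and maxima above `min_snr` (default
5) × noise count as peaks. The maxima scan is plateau-aware — a flat top
from an apex falling midway between samples reports its midpoint — and
apex times are refined by parabolic interpolation. Areas are trapezoids of
the detrended signal between flanking local minima: robust, shape-free,
and within 1% of the analytic area for isolated Gaussian peaks.

Glucose-unit calibration interpolates the dextran ladder (time → GU)
piecewise-linearly: monotone by construction, exact at the rungs, and with
rung spacing of 1 GU the curvature error against a realistic nonlinear
migration model is ≈ 0.005 GU, negligible at the annotation scale. The
two lightest library entries (GU 0.72 and 0.80) migrate before the first
glucose rung, so the pipeline enables linear extrapolation by default;
the first-segment extrapolation error at GU 0.72 is ≈ 0.006 GU.
Annotation assigns the nearest library entry within ±0.015 GU — half the
tightest spacing in the library (3.09 vs 3.12) — and reports all
candidates with an ambiguity flag when several fall inside the tolerance
instead of silently picking one.

## Quantitation

Fluorescence is assumed molar-proportional (one APTS label per reducing
end). Areas are normalised to a reference product (`XA^3X` for GH10
digests, `XA^3XX` for GH11); for each class S ∈ {Ara*f*, [Me]GlcA,
D^2,3^},

frequency(S) = 100 · Σ norm·n_S / Σ norm·n_xyl,

where n_xyl counts backbone Xyl*p* only (a D chain's Xyl*p* belongs to the
chain) and methylated and unmethylated uronates pool into one class; the
rare B-type chains count toward the disaccharide class. The reference
cancels, so frequencies are scale- and reference-invariant (tested), and
for a complete digest with molar areas the conservation of residue totals
makes the recovery of the substrate's true frequencies exact regardless of
cleavage pattern — the central correctness argument for the quantitation
stage. Ambiguous and unassigned peaks are excluded with a warning and
reported, mirroring the conservative treatment of unknown species;
multi-dilution experiments merge by taking saturating, abundant species
(xylose, xylobiose by default) from the higher dilution.

## The synthetic-data generator

The generator is the package's source of ground-truthed inputs. Polymers
are independent per-residue draws with per-class substitution
probabilities; the tissue presets encode the reported vegetative-tissue
frequencies as generating probabilities — miscanthus leaf: Ara*f* 0.10,
GlcA 0.005 + MeGlcA 0.030, D 0.013; stem: 0.12, 0.005 + 0.055, 0.002
(arabinosylation 10–12%, glucuronidation 3–6% and mostly methylated in
miscanthus, disaccharide branch 1.3% in leaf vs 0.2% in stem, GH10-digest
figures); rice stem is modelled largely unmethylated (GlcA 0.040,
MeGlcA 0.005) with leaf-like D abundance 0.010. Recovering these numbers
is therefore a round-trip consistency check of the pipeline's
bookkeeping, not an independent validation of the biology.

Trace synthesis uses a fixed monotone quadratic time axis
t(GU) = 2000 + 600·GU − 10·GU², arbitrary but fixed since no time axis is
published; a 12-rung ladder; seven evenly spaced markers (mirroring the
seven-standard marker set without claiming its positions); Gaussian peaks
of σ = 2 s (capillary-sharp, so neighbouring species resolve) with area
proportional to molar abundance; optional Gaussian noise and a saturation
ceiling. Digest products absent from the packaged library are placed at
deterministic synthetic GU positions spread over [6, 11.8] — inside the
ladder span, spaced ≥ 0.04 GU so default annotation stays unambiguous —
and returned as a `synthetic = TRUE` extension of the library, letting a
round trip either annotate everything (full recovery) or run against the
packaged library to exercise the unassigned path. What the generator does
*not* emulate: electrokinetic mobility physics, structure-dependent
labelling efficiency (equal molar response is assumed, unverifiable from
published data), isotope patterns, or MALDI intensity physics — so
passing round trips demonstrate internal consistency of the processing
chain, not instrument realism.

## Problem sizes and numerical choices

Property tests run on polymers of 40–3,000 residues; the trace-level
end-to-end recovery test uses 20,000 residues (≈ 70 distinct products,
recovery within 0.1 percentage point of the digest's realized
frequencies, typically within 0.002); the preset frequency recoveries in
`scripts/acceptance.R` use the full 200,000-residue polymers, where
binomial sampling error on the leaf disaccharide class is ≈ 0.025
percentage points. Sampling interval 0.5 s gives ≥ 4 samples per σ;
parabolic apex refinement brings apex error well below one sample. All
generators are seeded and byte-reproducible; the profiling pipeline hashes
its resolved configuration into every report.

## Known limitations

* The extended ion families are empirical offsets; applying them to
  chemistries outside the fitted ledger (different labels, adducts,
  hexose backbones) is unsupported, as are protonated/potassiated adducts
  and intensity prediction.
* Endo-digestion is an equilibrium end-point model; time courses and
  enzyme-dose effects are out of scope.
* The GU library is specific to APTS-labelled DASH mobilities; other
  separation chemistries need their own calibrated positions.
* Quantitation inherits the equal-molar-fluorescence assumption; species
  absent from the annotation library are excluded (and logged) rather
  than guessed.
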