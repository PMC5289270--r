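---
title: "Structural precedents: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural precedents: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structprec)
```

## The question and the method

Only a tiny fraction of the possible protein pairs in a cell — about 0.2%
in budding yeast — form functional interactions. structprec implements a
protocol for asking how many of the *non-interacting* pairs nevertheless
have structures compatible with interaction. A pair (A, B) has a
**structural precedent** when some experimental dimer (X, Y) exists such
that A is structurally similar to X and B to Y (or A to Y and B to X).
Similarity is measured by the TM-score, a length-normalized score in
(0, 1] with the distance scale

$$d_0 = \max\bigl(0.5,\; 1.24\,(L-15)^{1/3} - 1.8\bigr)$$

and the pair-level summary is **TMmin**, the minimum of the two per-chain
TM-scores, maximized over the two chain assignments. When TMmin clears a
threshold, the monomers are rigidly superposed onto the template chains to
build a hypothetical complex, the **interaction model**, which is accepted
only if it shows a credible interface: at least 20 interface residues at
the 5 Å cutoff and fewer than three CA–CA clashes. If several homology
models exist per protein, all model combinations are ranked by decreasing
TMmin and the first one with a valid interface wins.

Downstream of detection, the package carries three analyses:

* **Extrapolation arithmetic.** Observed precedent rates for negative and
  positive pairs, the interactome density, the expected contamination of
  negative sets by unreported interactions (positive rate × density), the
  enrichment of the observed negative rate over that expectation, and the
  completeness correction `100 * negative_rate / positive_rate`, which
  extrapolates the negative rate to a hypothetical complete template
  library.
* **Network impact.** Each candidate (non-interacting) pair is added
  separately to the native interaction network; the extra edge's
  betweenness is compared with the betweenness distribution of all edges,
  and candidates in the top 10% are called bottlenecks. Enrichment per
  category is reported as `log2(observed fraction / 0.10)` with
  chi-squared standardized-residual p-values.
* **Interface descriptors.** Interface size, buried surface area
  (Shrake–Rupley ASA, symmetric ΔASA/2 convention), the hydrophobic share
  of the buried area, a grid-based gap volume with its gap index
  (volume / interface ASA), and a 7-class amino-acid contact signature
  with a cosine distance between interfaces.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| TMmin threshold | 0.6 | precedent detection cutoff; 0.4 and 0.5 supported for rate curves |
| interface cutoff | 5 Å | any-atom inter-chain distance defining interface residues |
| minimum interface | 20 residues | pooled over both chains |
| CA clash cutoff / tolerance | 3.0 Å / ≤ 2 clashes | "fewer than three clashes" |
| contact-signature cutoff | 12 Å | CA–CA distance for interface contacts |
| ASA probe / sampling | 1.4 Å / 960 points | Shrake–Rupley water probe and sphere sampling |
| gap-volume grid / shell | 1.0 Å / 5.0 Å | voxel edge; max surface distance to both chains |
| bottleneck fraction | 0.10 | top share of edge betweenness called bottleneck |
| FNR path filter | > 10 | strict shortest-path distance for network-distant negatives |

The amino-acid classes for contact signatures are {V,I,M,C,L}, {A,S,P,T},
{G}, {Y,F,W}, {K,R,H}, {D,E}, {N,Q}; hydrophobic residues for interface
hydrophobicity are {A,V,L,I,P,F,M,W,C}; atom radii are C 1.87, N 1.65,
O 1.40, S 1.85 Å.

## What the synthetic generator emulates — and what it does not

No external structure or interaction databases are consulted; every
pipeline stage is exercised on generated data.

* `make_chain()` builds self-avoiding backbones from ideal
  secondary-structure segments (helix: 1.5 Å rise, 100°/residue, 2.3 Å
  radius; strand: 3.3 Å rise) joined by random turns, with N, CA, C, O and
  CB (except glycine) atoms. Side chains beyond CB are not built: every
  distance criterion in the protocol is a cutoff on backbone+CB geometry,
  so rotamer building would add cost without changing what is tested.
* `make_dimer()` docks two chains rigidly along a random approach axis
  until the inter-chain residue-contact count at 5 Å first reaches the
  configured target (default 40, comfortably above the >10-contact library
  inclusion rule) with no CA pair under 3 Å. Because not every pair of
  random folds can reach the target clash-free, `make_benchmark()` redraws
  a family's chains when docking fails; `make_dimer()` itself reports the
  failure, as a caller supplying fixed chains should see it.
* `make_benchmark()` organizes the library in *fold families* of two
  dimers sharing both chain folds but docked in different geometries.
  Positive pairs are noise-perturbed copies of one dimer's chains;
  structure-compatible negatives (20% of negatives by default) take chain
  X from one family member and chain Y from the other, so they carry a
  genuine precedent while being labelled non-interacting — the package's
  analogue of the real finding that some non-interacting pairs match
  templates. Because the two family members are structurally equivalent
  templates, recovery of a planted precedent is scored at family level.
* `make_network()` produces preferential-attachment graphs (heavy-tailed
  degree distributions, like real interactomes); `make_annotations()`
  draws localizations, log-normal abundances classed by quartiles
  (bottom 25% low, top 25% high) and Zipf-distributed term sets.

What passing tests on these data do **not** show: performance on real
homology models (whose errors are correlated along the chain, not i.i.d.
Gaussian), on real dimer libraries (which are redundant and biased toward
crystallizable complexes), or TM-align bit-parity (the aligner here is a
heuristic with the same scoring formula; see below). The synthetic noise
model is deliberately simple — a rigid move plus isotropic coordinate
noise — so that the expected CA-RMSD (σ√3) and hence the detection regime
is analytically known.

## Benchmark conditions

The acceptance script and the heavy tests run one fixed configuration:
8 templates in 4 fold families, 24 positive pairs planted round-robin,
40 negatives (8 structure-compatible), chain lengths 30–60 residues,
model noise σ = 0.3 Å. At that noise level the per-chain TM-scores of
planted pairs sit near 0.9–0.95, well above the 0.6 threshold, while
unrelated 30–60-residue chains align near 0.2–0.35; the planted-recovery
and false-positive checks therefore probe ranking, assignment and
interface validation rather than borderline score noise. These sizes keep
a full screen (64 pairs × 8 templates × 4 alignments) in the low minutes
on one CPU; the statistical conclusions the tests assert (recovery ≥ 90%,
thinned-library extrapolation within ±30%) are stable at this scale.

The thinned-library check mimics the paper-scale completeness correction:
dropping half (or three quarters) of the fold families lowers positive
and negative detection proportionally, so
`100 * negative_rate / positive_rate` recovers the full-library negative
rate. Thinning is done family-wise, because the two members of a family
are interchangeable templates.

## Numerical and design choices

* **Aligner.** Sequential CA alignment: seeds from gapless threading at
  all offsets plus fragment-pair superpositions; each seed transform is
  scored on all residue pairs by `1/(1 + (d_ij/d_0)^2)` and turned into a
  mapping by dynamic programming (gap opening 0.6, no extension, ties
  toward the diagonal, free end gaps); the best seeds are iterated
  (superpose → score → re-align) until the mapping repeats or 20 rounds.
  The returned TM-score is normalized by the query chain length and never
  falls below any threading seed's score. Both per-chain scores are kept
  in every hit so the other normalization convention can be recomputed.
* **TMmin ties** are broken by template id (lexicographic), then
  assignment order, then model-combination order, making
  `find_precedents()` fully deterministic.
* **Interface count** is pooled over both chains (per-chain counts are
  also returned, so the per-chain reading of the 20-residue rule remains
  auditable).
* **Signature distance** is the cosine distance on the flattened upper
  triangle of the 7×7 contact-count matrices — the simplest form that is
  0 for identical contact-type compositions and 1 for disjoint ones. It
  is isolated in one function so an alternative (e.g. normalized L1) can
  be swapped without touching callers.
* **Gap volume** uses a regular grid over the chains' overlapping
  bounding boxes: a voxel is gap if it lies outside every probe-expanded
  atom sphere, within 5 Å of both chains' surfaces, and *between* them
  (its nearest atoms from the two chains lie on opposite sides). The
  betweenness condition keeps the solvent shell wrapped around the
  complex out of the gap estimate; the quantity is comparable to, but not
  identical with, sphere-shrinking gap volumes and is labelled as such.
* **Balanced negatives** use stub matching with rejection and restarts,
  matching hub stubs first. Exact degree preservation is not always
  feasible (a hub adjacent to more than half the network cannot keep its
  degree among non-edges); the default errors in that case, and
  `allow_partial = TRUE` returns the maximal set with per-node degrees
  bounded by the native ones.
* **Cramér test** p-values come from label permutation by default (an
  ordinary bootstrap is available), with the statistic computed from a
  pooled absolute-difference matrix in compiled code; `n_boot = 199`
  makes the p-value grid include 0.05 exactly, which the calibration
  test exploits.
* **Fisher two-sided p** follows the probability-mass rule (sum of table
  probabilities not exceeding the observed one), the convention of the
  standard implementations.
* **Degenerate inputs**: collinear point sets are rejected by the
  superposition; all-zero contact matrices make the signature distance
  undefined (error); a zero buried area flags hydrophobicity and gap
  index as undefined (NA with a warning) rather than returning 0.

## Known limitations

* The aligner is a desk-scale heuristic: it shares TM-align's scoring
  formula and general strategy but claims no numerical parity with the
  published executable, and only sequential alignments are produced.
* ASA and gap volume are sampling/grid estimates; their tests assert
  convergence (≤ 1% on doubling the sphere sampling, ≤ 15% on halving the
  grid spacing), not exact NACCESS/SURFNET values.
* Binding-affinity prediction is out of scope; interface characterization
  accepts any scoring function via the descriptor tables, but no force
  field ships with the package.
* The generator's negatives are structurally clean-cut (either unrelated
  folds or exact fold matches); real negative datasets contain the full
  continuum in between.
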