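# structprec

Most protein pairs in a cell never interact — in yeast, roughly 0.2% of
the possible pairs do. `structprec` asks how many of the *non-interacting*
pairs nevertheless have structures compatible with interaction, and what
would happen to the interaction network if those interactions occurred.

It implements, as a tested R package:

* **Structural precedent detection.** A pair (A, B) has a precedent when
  an experimental dimer (X, Y) exists with both chains structurally
  similar to the pair's monomers. Similarity is the TM-score
  (`d0 = max(0.5, 1.24 (L-15)^(1/3) - 1.8)`), summarized per pair as
  `TMmin = min(TM_A, TM_B)` maximized over the two chain assignments, and
  screened at a threshold (0.6 by default). Superposing the monomers onto
  the template yields an **interaction model**, accepted if it has ≥ 20
  interface residues at 5 Å and fewer than three CA–CA clashes.
* **Interface descriptors**: interface size, Shrake–Rupley buried surface
  area, hydrophobicity, grid-based gap volume / gap index, and a 7-class
  amino-acid contact signature with a cosine distance between interfaces.
* **Network impact**: extra-edge betweenness of candidate interactions in
  the native network, top-10% bottleneck calls, per-category
  `log2(observed/expected)` enrichment with chi-squared residuals.
* **Negative datasets**: random and degree-preserving (balanced)
  sampling of non-edges, non-colocalization, network-distance and
  direct-evidence filters, minimum-rule pair abundance classes.
* **Extrapolation statistics**: precedent rate curves, interactome
  density, expected contamination, enrichment factors, the
  completeness-corrected rate `100 * negative_rate / positive_rate`,
  Fisher exact and Cramér two-sample tests, hypergeometric term
  enrichment with Benjamini–Hochberg correction.
* **A synthetic-data generator** (structures, dimer libraries with
  planted precedents organized in fold families, scale-free networks,
  annotation tables) so the entire pipeline runs end to end without any
  external database.

## Worked example

Generate a small benchmark with planted precedents, screen it, and look
at the detection rates:

```r
library(structprec)

cfg   <- generator_config(seed = 7, noise_sigma = 0.3, n_dimers = 4)
bench <- make_benchmark(4, 6, 6, cfg)   # 4 templates, 6 pos, 6 neg pairs
scan  <- precedent_scan(bench)
head(scan[, c("pair_id", "status", "template_id", "tmmin")])
#>   pair_id       status template_id     tmmin
#> 1  pos001    precedent        T001 0.9298863
#> 2  pos002    precedent        T001 0.9210421
#> 3  pos003    precedent        T003 0.9269551
#> 4  pos004    precedent        T003 0.9265664
#> 5  pos005    precedent        T001 0.9226996
#> 6  pos006    precedent        T001 0.9278654
```

All six positive pairs recover a template of their planted fold family
with TMmin ≈ 0.92–0.93 — far above the 0.6 threshold — while unrelated
negative pairs stay below it (`status == "no_precedent"`). One negative
pair is *structure-compatible* by construction and is detected too:
labelled non-interacting, structurally indistinguishable from a positive,
which is the phenomenon the package quantifies.

The extrapolation arithmetic on the published rates:

```r
extrapolation_summary(negative_rate = 2, positive_rate = 23, density = 0.2)
#> $expected_contamination    0.046      # percent
#> $enrichment_factor         43.5       # observed over expected
#> $completeness_corrected_rate 8.696    # percent, prints as 8.7
```

i.e. a 2% negative precedent rate is ~40–100× what random false-negative
contamination would produce, and extrapolating to a complete template
library gives 8.7% of non-interacting pairs with compatible structures.

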