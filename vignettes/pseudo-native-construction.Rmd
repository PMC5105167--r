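---
title: "Constructing and scoring pseudo-native mass spectra of intact glycoproteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and scoring pseudo-native mass spectra of intact glycoproteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glyconms)
```

## The problem and the model

Native MS of an intact glycoprotein measures the sum of all its
modifications at once; site-resolved proteomics measures each modification
site separately but says nothing about their combinations. `glyconms`
bridges the two with an explicit statistical model: each modification site
$i$ offers $k_i$ isoforms with masses $m_{ij}$ and normalized relative
abundances $P_{ij} = A_{ij} / \sum_k A_{ik}$ (the $A_{ij}$ are raw XIC
areas, so only their ratios matter), and sites are **independent**, so a
proteoform defined by choosing isoform $j(i)$ at each site has

$$M = M_\mathrm{pp} + \sum_{i=1}^{n} m_{ij(i)}, \qquad
  P = \prod_{i=1}^{n} P_{ij(i)},$$

with $M_\mathrm{pp}$ the disulfide-corrected backbone mass. Independence is
the key assumption and is untestable from site-level data alone — it is
exactly what comparing the constructed spectrum against the measured native
spectrum probes. Crosstalk between sites (e.g. steric competition between
neighbouring glycans) would appear as a depressed biosimilarity score.

All glycan arithmetic uses **average** residue masses, because native MS of
25–60 kDa glycoproteins does not resolve isotopes. The same reasoning fixes
what the model ignores: positional isomers (same total mass from different
site assignments) are merged, as no intact-mass measurement can separate
them, and glycan topology/linkage is outside scope entirely.

## Computing the proteoform distribution

Two routes produce the zero-charge spectrum:

* `enumerate_proteoforms()` expands all $\prod_i k_i$ combinations —
  transparent, and the reference for testing — with a hard cap (default
  $10^6$) beyond which it refuses and points to the convolution route;
* `site_convolution()` convolves per-site $(m, P)$ distributions one site
  at a time, merging peaks within `merge_tol` after each step. This keeps
  the peak count bounded by the number of *distinct masses*, not
  combinations; a 22-site binary-occupancy model stays in the thousands of
  peaks while its enumeration would have $4\,194\,304$ rows.

Numerical choices, made once:

* **`merge_tol` = 0.01 Da.** Native-MS peak widths at these masses are
  orders of magnitude wider, so merging at 0.01 Da only collapses genuine
  positional isomers and floating-point near-duplicates. Merged peaks sit
  at the abundance-weighted mean mass. Equivalence tests between the two
  routes use a 1e-6 Da merge tolerance instead of exactly 0, because the
  two routes sum masses in different orders and exact-equality merging of
  doubles is ill-defined.
* **`prune_threshold` = 1e-8** with *no renormalization*: the pruned
  probability mass is deliberately visible as
  `retained_probability < 1` rather than silently redistributed.
* **Disulfide correction** −2 × 1.00794 Da (average H) per bridge; proton
  mass in m/z projection 1.007276 Da (physical proton). The two constants
  differ for good reason — one removes hydrogen atoms, the other adds
  charges — and both are fixed for reproducibility.

The in-silico enzymes operate on the model, not the spectrum. Sialidase
zeroes Sia/NeuGc counts together with the Acetyl and Hydroxyl blocks that
decorate sialic acids, then merges isoforms that have become identical.
PNGase F removes N-glycans; because the real enzyme converts the glycan-
bearing Asn to Asp, the occupied fraction of each N-site is left as a
+0.9840 Da isoform by default (`deamidation_shift = TRUE`). A site that had
an unoccupied isoform therefore keeps two states — 0 and +0.9840 Da —
rather than collapsing to one, since only the occupied fraction is
deamidated.

## Projection to m/z and profile rendering

Each neutral mass emits one centroid per charge state at
$Q = (M + z \cdot 1.007276)/z$ with intensity $P \cdot A_z$. The default
envelope for rhEPO-scale work is $z \in \{8, 9, 10\}$, uniform $A_z$; when
an experimental spectrum is available `estimate_envelope()` derives
empirical $A_z$ from summed intensity per charge-state window. Profile
rendering gives each centroid a Gaussian of area equal to its intensity
with FWHM $= Q/R(Q)$, $R(Q) = R_\mathrm{ref} (Q_\mathrm{ref}/Q)^p$;
defaults $R_\mathrm{ref} = 17{,}500$ at $Q_\mathrm{ref} = 200$ Th and
$p = 0.5$, the square-root fall-off of Orbitrap-class analyzers. The grid
step is capped at a quarter of the narrowest FWHM (a coarser request is
refined with a warning) so that peak tops land within one grid step and
areas are conserved to 0.1%.

## Biosimilarity scoring and bin-width selection

Spectra are binned into left-closed windows of width $W$ over the
*intersection* of their ranges — zero-filling outside either spectrum's
data would inflate the correlation and is disallowed — with the bin origin
at the floor of the range start. The score is the standard Pearson $r$ of
the paired bin vectors; a zero-variance vector raises an error rather than
returning a silent 0 or NaN. Profile traces are binned directly, centroids
as sticks.

The bin-width selector works from matched peak pairs: peaks are picked as
local maxima above 1% of the base peak, the 20 most intense pairs are
matched greedily by proximity, and each pair's mass separation is projected
to m/z at three charge states, giving 60 candidate widths. The per-pair
width is taken as $2\,|\Delta m/z|$ — the smallest width that guarantees
the pair co-bins for *every* possible bin phase (with the worst-case
origin, a pair separated by $\delta$ can straddle a boundary unless
$W \ge 2\delta$). The plain $|\Delta|$ alternative is selectable
(`rule = "delta"`). The median of the 60 candidates is the selected width.
As an independent check, `binwidth_scan()` computes $r$ over widths 1–20 Th
in 0.1 steps (191 values), smooths with a LOESS fit (span 0.3 — chosen as a
conventional middle ground; the scan is a diagnostic, not an estimator) and
reports the width of maximum curvature (largest absolute second difference
of the smoothed curve) as the inflection point, flagging whether the
selected width lies near it. Identical inputs give a flat scan, which is
flagged instead of reporting a spurious inflection.

## Composition assignment

`assign_composition()` solves: which non-negative integer combinations of
residue masses match `measured − backbone` within a ppm tolerance? The
search is depth-first over building blocks in descending mass order with
remaining-mass window pruning, which is exact and complete with respect to
the bounds (verified against brute-force grids in the tests). Candidates
are ranked by |ppm|, ties by total residue count, then lexicographically —
fully deterministic. Co-ranked isobaric candidates are all returned;
ambiguity is surfaced, never resolved silently.

The default tolerance is 50 ppm — intact native masses of heavily
glycosylated proteins are accurate to a few tens of ppm, and the headroom
tolerates minor adducts. The generic default bounds (Hex ≤ 30, HexNAc ≤ 25,
Fuc ≤ 6, Sia ≤ 20, Acetyl ≤ 4, Hydroxyl ≤ 4, Pho ≤ 2, with
Acetyl + Hydroxyl ≤ Sia + NeuGc since those decorations ride on sialic
acids) describe a *search space*, not biological plausibility, and at
30 kDa they admit many isobars within tens of ppm. When the glycosylation
topology is known, the architecture constraints sharpen the search
decisively: for a protein with three complex-type N-glycans and one core-1
O-glycan (`rhepo_bounds()`), every complex N-glycan core fixes
Hex − HexNAc = 1 and the O-core 0, so Hex − HexNAc = 3 over the whole
protein, and with at most one sialic acid per antenna Sia ≤ HexNAc − 6.
Under these constraints the assignment of a modal rhEPO-type mass is
unique at 35 ppm. This is the package's reading of how base glycan series
are assigned in intact-mass annotation practice: the +42 Da O-acetyl and
+16 Da NeuGc variants are satellite annotations relative to base-series
peaks, not free search dimensions.

One caveat the tests document explicitly: 5 × Fuc (730.715 Da) and
2 × (Hex + HexNAc) (730.675 Da) differ by 0.04 Da, genuinely
indistinguishable at intact-mass accuracy. Recovery experiments therefore
cap Fuc at the range the generator actually uses; with unbounded Fuc the
ambiguity is real chemistry, not a search defect.

## The synthetic-data generator

`gen_protein_model()` emulates the site-table structure of the two model
proteins: the `"rhepo"` preset has three N-sites with 10, 9 and 8
glycoforms (complex di/tri/tetra-antennary N-glycans, up to one sialic acid
per antenna, with and without core fucose) plus a core-1 O-site with 0–2
sialic acids, on the stored 165-residue mature erythropoietin backbone
(18,235.92 Da with 2 disulfides); `"properdin"` has 17 binary
C-mannosylation sites with heterogeneous occupancy (the central Trp of
each repeat motif near-fully occupied), four O-sites and one N-site. Site
abundances are Dirichlet(1) — uniform over the simplex, the least
informative choice. Measurement noise is multiplicative log-normal in
intensity (ion statistics are heteroscedastic and positive), Gaussian
ppm-scaled in position (mass-accuracy drift), with optional per-peak
dropout and a flat baseline. Everything is seed-deterministic.

`perturb_sialylation()` implements noise that targets sialylation
heterogeneity specifically: it redistributes abundance among isoforms of a
site that share the same Sia-stripped base composition, preserving each
group's total. By construction in-silico sialidase exactly cancels this
perturbation, so desialylated construction-vs-experiment comparisons isolate
measurement noise — which is why desialylation must raise the biosimilarity
score whenever sialylation heterogeneity was the dominant mismatch, the
directional behaviour the validation suite asserts seed by seed.

What the generator does **not** emulate: chemical adducts, in-source decay
of labile sialic acids, charge-state-dependent ionization bias, detector
saturation, or correlated site occupancy. Passing tests therefore
demonstrate correctness of the computation under the model's assumptions,
not that the independence model holds for any particular real protein.

## Validation problem sizes

The test suite and the acceptance script exercise: convolution-vs-
enumeration equivalence on random models up to 6 sites × 4 isoforms (200
models in the acceptance suite, 1e-9 Da agreement after matching peaks);
probability conservation and mean-mass linearity on 40 random models;
recovery of the construction from noise-free simulation ($r = 1$) and mean-
$r$ monotonicity over 20 seeds × 4 dropout levels; the desialylation
direction on 20 seeds of the rhEPO preset; bin-width selection against a
hand-computed 60-candidate median; and planted-composition recovery (30
plantings, architecture bounds, ±0.2 Da simulated measurement error).
These sizes were chosen to pin each property with comfortable statistical
margin while keeping a full run in seconds.

## Known limitations

* The independence model cannot represent site crosstalk; a low score
  against a measured spectrum may reflect either quantification error or
  genuine dependence, and the package cannot distinguish them.
* Assignment completeness is relative to the bounds; the architecture
  constraints encode complex-type N-glycosylation and do not fit hybrid or
  high-mannose-dominated proteins without adjustment.
* Charge-envelope abundances are inputs (or estimated from a measured
  spectrum); the package does not model electrospray charging physics.
* mzML reading is optional (via mzR) and profile-mode only in the sense of
  taking the first scan; vendor raw files are out of scope.
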