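---
title: "Methods: structural solubility fingerprints, charge maps and ROESY localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural solubility fingerprints, charge maps and ROESY localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soluprint)
```

`soluprint` rationalizes where a hydrophobic guest molecule sits inside a
surfactant micelle by combining three independent lines of evidence: a
machine-learned map of which atoms help or hurt aqueous solubility, a
partial-charge map of the same molecule, and a direct spatial readout from
ROESY cross-peaks. This vignette documents the models, their assumptions,
the tunable parameters, and the design decisions taken where more than one
defensible choice existed.

## Circular fingerprints with provenance

The fingerprint is the extended-connectivity (ECFP) construction. Each
heavy atom starts from the invariant tuple *(atomic number, heavy-atom
degree, attached hydrogen count, formal charge, ring membership)*, hashed
to a 32-bit identifier. For rounds $r = 1,\dots,R$ each atom's identifier
is rehashed together with the sorted (bond order, neighbor identifier)
pairs of its neighbors, so the round-$r$ identifier describes the full
substructure within graph radius $r$. Environments that cover an atom set
already covered by an earlier environment are dropped (preferring the
smaller radius, then the smaller identifier); the survivors are folded to
bits by `id mod nbits`.

Defaults: `radius = 2` (the "diameter 4" fingerprint standard in
solubility QSAR) and `nbits = 2048` (the de-facto default length; shorter
vectors increase fold collisions, which only ever merge bits). Bits are
binary presence/absence; stereochemistry is ignored. All three choices are
exposed as arguments.

Two implementation details matter for reproducibility. The hash is FNV-1a
over a documented human-readable key string, implemented both in C++ (the
production path) and in plain R (a test oracle), so identifiers are
platform-independent and pinned by the test suite. And every on bit
retains its provenance — the list of (center atom, radius) environments
that produced it — which is what later allows coefficients to be mapped
back onto atoms.

## Bayesian ridge regression by evidence maximization

Given the binary design matrix $\Phi$ (molecules × bits) and targets $y$
(logS, i.e. $\log_{10}$ of aqueous solubility in mol/L), the model is

$$y = \Phi m + b + \varepsilon, \qquad m \sim \mathcal N(0, \alpha^{-1} I),
\qquad \varepsilon \sim \mathcal N(0, \beta^{-1}),$$

with the intercept $b$ excluded from the penalty by centering the columns
and the target. For fixed $(\alpha, \beta)$ the posterior mean is the
classical ridge solution with penalty $\lambda = \alpha/\beta$; the
package computes it through one SVD of the centered design, so the
hyperparameter iteration costs almost nothing beyond the first
factorization. The hyperparameters themselves are set by maximizing the
marginal likelihood with the MacKay fixed-point updates

$$\gamma = \sum_j \frac{\lambda_j}{\alpha + \lambda_j}, \qquad
\alpha \leftarrow \frac{\gamma}{m^\top m}, \qquad
\beta \leftarrow \frac{N - \gamma}{\lVert y - \Phi m\rVert^2},$$

where $\lambda_j = \beta d_j^2$ and $d_j$ are the singular values.
Evidence maximization replaces opaque auto-ML tuning with a deterministic,
search-free procedure in the same model family; the log evidence is
recorded at every iteration and is non-decreasing along the update path (a
property the test suite asserts).

Numerical choices: initialization $\alpha = 1$, $\beta = 1/\mathrm{var}(y)$;
convergence when both relative hyperparameter changes fall below
`tol = 1e-4`, capped at `max_iter = 300` with a warning (and
`converged = FALSE`) on the cap. If the residual sum of squares reaches
numerical zero (below $10^{-12}\sum y_c^2$) the iteration stops: the model
has interpolated the data, the $\beta$ update diverges geometrically, and
further iterations carry no information. Constant targets are refused
(the $\beta$ update would divide by zero), and zero-variance columns
receive exactly zero weight. A useful side effect of the formulation is
that $1/\sqrt{\beta}$ is an estimate of the residual noise standard
deviation, which the synthetic benchmark below exploits.

By default a final model is fitted on all rows; `cv = k` additionally
reports k-fold out-of-sample RMSE and $R^2$ next to the training-set
values, since the two can differ substantially for wide designs.

## From coefficients to atoms

For a query molecule, each on bit contributes exactly its coefficient
$m_j$ (bits are binary). The contribution is assigned to the *center
atoms* of the environments that set the bit, split equally when one bit
has several environments in the molecule — the similarity-map convention.
This conserves mass: the atom weights sum to
$\hat y - b$ to $10^{-10}$, which is asserted for every rendered map. An
alternative `mode = "spread"` divides each environment's share over all
atoms of the environment; it conserves the same total and is provided for
sensitivity analysis.

Interpretation caveat: attribution *smooths* credit over a radius-2
neighborhood. An atom's weight mixes its own effect with its
surroundings, so per-atom means systematically shrink toward zero
relative to the true group contributions, most strongly for fragments
whose counts vary little across the training set. Sign recovery is
robust (see the benchmark); fine rank distinctions between fragments with
similar contributions are not, and the test suite therefore checks rank
order only for well-separated contributions, comparing mean weight per
fragment *instance* (summed over the fragment's atoms).

Rendering uses a symmetric diverging scale — full red at
$+\max|w|$, white at 0, full blue at $-\max|w|$ (ColorBrewer RdBu
endpoints) — atoms with $|w| < 10^{-12}$ uncolored, and a deterministic
Kamada–Kawai layout from a fixed circular start, so identical inputs give
byte-identical SVG. For charge maps the default orientation draws
*negative* charge (high electron density) red; the convention is explicit
and flippable because the opposite choice is equally common.

## Mulliken population analysis

Atomic charges are $q_A = Z_A - \sum_{\mu \in A} (PS)_{\mu\mu}$ from a
supplied density matrix $P$ and overlap matrix $S$. The quantum-chemistry
step that produces $P$ (geometry optimization and an SCF calculation) is
deliberately out of scope: the package consumes plain-text matrices plus a
JSON header (basis→atom map, nuclear charges, total charge). Validation
refuses inputs whose electron count $\mathrm{tr}(PS)$ disagrees with
$\sum_A Z_A - q_\mathrm{tot}$ by more than $10^{-6}$, rather than
renormalizing silently. For symmetric $P$ and $S$, $\mathrm{diag}(PS)$
equals the symmetrized $\tfrac12\mathrm{diag}(PS + SP)$; the tests assert
this. Charge conservation $\sum_A q_A = q_\mathrm{tot}$ then holds by
construction, and basis-function permutation leaves the charges unchanged.

Three analytic fixtures pin the arithmetic: an orthonormal neutral case
(all charges zero), a symmetric two-center H₂ case with overlap
$s = 0.659$ where $\mathrm{diag}(PS) = (1,1)$ for *any* $s \in (0,1)$,
and an ionic case $P = \mathrm{diag}(1.8, 0.2)$ giving $(-0.8, +0.8)$.

## ROESY contact localization

A ROESY cross-peak places two protons within roughly 5 Å. The package
turns a transcribed cross-peak table into a per-solute-proton score by
classifying surfactant protons into radial regions and computing
$(n_\mathrm{core} - n_\mathrm{surface})/(n_\mathrm{core} + n_\mathrm{surface})$
with core = {chain, terminal methyl} and surface = {spacer, headgroup}.
Scores above $+1/3$ are labelled *core*, below $-1/3$ *surface*,
otherwise *interface*; the thresholds are an explicit convention with no
physical content. Contacts default to presence/absence weighting because
published cross-peak lists are typically qualitative; intensity weighting
is available.

The region map is configuration, not fact. For the 14-6-14 gemini
surfactant the default assigns Ha, Hb, Hc to the hydrophobic chains and
Hd, He, Hf to the headgroup neighborhood, following the structural
assignment of the proton labels; mid-chain protons such as Hc are
genuinely ambiguous (chain vs. spacer-adjacent descriptions both occur),
which is exactly why the map is a user-visible argument rather than a
constant. Swapping core and surface assignments negates every score — an
antisymmetry the test suite checks.

## The synthetic benchmark: what it emulates, and what it does not

The generator emulates the *role* of a large experimental logS table: a
population of small drug-like molecules whose solubility is an additive
function of functional-group counts. Each molecule is a random linear or
singly branched alkane skeleton decorated with hydroxyl, carbonyl,
carboxyl, phenyl and methyl groups; every heavy atom belongs to exactly
one fragment class (skeletal CH₃ count as *methyl*, other skeletal
carbons as *methylene*), and

$$\mathrm{logS} = b_0 + \sum_f n_f c_f + \varepsilon, \qquad
\varepsilon \sim \mathcal N(0, \sigma^2),$$

*exactly*, with the counts, the noiseless value, and each atom's class
emitted alongside the table. Default contributions (logS units per
instance) follow group-contribution intuition — hydrophobic groups
depress solubility (methyl −0.55, methylene −0.45, phenyl −1.3), polar
groups raise it (hydroxyl +0.9, carbonyl +0.5, carboxyl +0.7) — with
baseline +0.5 and $\sigma = 0.3$, roughly the per-group magnitudes and
noise level one sees in aqueous-solubility group-contribution fits.
Generation is fully determined by the seed carried in the
`solubility_spec` object; identical specifications give byte-identical
tables.

One design constraint deserves emphasis: the skeleton is capped at
**seven** carbons so that every skeletal atom lies within graph distance
3 of a chain end. Binary radius-2 fingerprints cannot distinguish the
interiors of longer chains — linear C₇ and C₈ skeletons produce
*identical* bit sets, because interior CH₂ environments hash to one
shared bit — so with longer backbones the methylene count, and hence the
additive target, would be unrecoverable *by construction* for the very
model family the package implements. The cap is an identifiability
requirement of the benchmark, not a tuning knob.

What passing the benchmark does **not** show about real data: real logS
is not additive in group counts (conformation, crystal packing and
intramolecular interactions all enter); real chemical space is far more
diverse than decorated heptanes; and real noise is neither Gaussian nor
homoscedastic. The benchmark validates the *machinery* — featurization,
regression, attribution, conservation — under conditions where the right
answer is known exactly, not the chemistry. Accordingly, on real
solubility data one should expect substantially higher RMSE and lower
$R^2$ than on the synthetic tables, as reported solubility models
invariably show.

## Problem sizes and determinism

The test suite and the acceptance script use: 20 random problems
($n \le 100$, $p \le 50$) for the ridge-vs-brute-force comparison
(agreement to $10^{-10}$); ten synthetic datasets of 1000 molecules,
6 fragments and $\sigma = 0.3$ for the recovery study (fragment signs
recovered in at least 9 of 10 seeds via mean per-fragment atom weights;
$1/\sqrt\beta$ within $[0.25, 0.35]$); 100 molecules each for attribution
conservation ($10^{-10}$) and fingerprint permutation invariance; the
three analytic population fixtures plus 50 random electron-count-valid
inputs for charge conservation ($10^{-10}$); and the transcribed 2 mM
(2 contacts) and 5 mM (3 contacts) ROESY tables, for which the acetyl
proton H22 scores +1 (*core*) under the default region map at both
concentrations while H20 is non-core at 5 mM. All randomness flows from
explicit seeds; every artifact the pipeline writes (SVG, CSV, JSON) is
byte-reproducible given the same configuration.

## Known limitations

- The SMILES dialect covers the organic subset, aromatic lowercase
  notation, bracket atoms with charges and explicit hydrogen counts, ring
  closures and branches; stereo descriptors are accepted and discarded,
  and no canonical SMILES writer is provided (round trips are verified
  structurally instead).
- Attribution assigns credit to environment centers; it is a
  visualization of a linear model's coefficients, not a causal
  decomposition, and inherits all collinearity artifacts of the bit
  design.
- The 2D depiction uses a graph layout, not a chemistry-aware sketcher;
  fused-ring drawings are legible but not publication-conventional.
- Count information beyond presence/absence is invisible to binary
  fingerprints; molecules differing only in repeated identical
  substructures beyond radius 2 are indistinguishable.
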