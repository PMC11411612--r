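---
title: "Methods: property and shape profiling of oral drug space"
author: "drugspace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: property and shape profiling of oral drug space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`drugspace` profiles a table of small molecules — typically oral drug
approvals over a period of years — against the descriptor framework of
oral drug-likeness: size, lipophilicity, hydrogen bonding, flexibility
and three-dimensional shape. This vignette records the models, the
conventions behind every number the package produces, and the design
choices made where more than one defensible convention exists.

## The descriptor model

For each compound the package computes, from its canonical SMILES:

* **MWt** (Da): isotope-averaged molecular weight, implicit hydrogens
  included.
* **clogP**: the OpenBabel atomic-contribution logP estimate
  (Wildman–Crippen-style atom typing). Any logP estimator shifts the
  fraction of compounds above 5, so the estimator is recorded in the
  descriptor table's metadata; values from different toolkits should
  not be mixed in one analysis.
* **HBD / HBA**: by default the rule-of-5 convention — donors are N or
  O atoms bearing at least one hydrogen, acceptors are *all* N and O
  atoms. This is the convention under which the >5 / >10 limits were
  originally derived, and it changes the acceptor column materially
  (e.g. an ester counts 2 acceptors here, 1 pharmacophorically). The
  toolkit's pharmacophoric typing is available via
  `descriptorConventions(hbond = "pharmacophore")`.
* **Rotatable bonds**: single, acyclic bonds between non-terminal,
  non-triple-bonded heavy atoms; the default "strict" variant excludes
  amide C–N bonds, `rotor = "loose"` keeps them.
* **Aromatic rings**: the circuit rank (bonds − atoms + components) of
  the aromatic-bond subgraph, which equals the number of smallest
  aromatic rings; naphthalene counts 2, biphenyl 2, benzene 1.
* **Fsp³**: sp³ carbons over all carbons (the standard saturation
  measure). Because hybridisation-based "atom" definitions are
  ambiguous about the denominator, the all-heavy-atom variant is
  available (`fsp3Denominator = "heavy"`); the carbon-based default is
  the one used in all shipped analyses. Fsp³ is undefined (an error)
  for carbon-free molecules.
* **Stereocentres**: a constitutional estimate — tetra-coordinated
  carbons whose four branches are pairwise distinct under
  Weisfeiler–Lehman colour refinement of the hydrogen-explicit graph.
  This counts atoms where chirality is *possible* by connectivity,
  assigned or not; centres whose chirality depends on other centres
  (meso compounds) are not resolved.

Salt and solvate inputs are reduced to their largest carbon-containing
fragment before descriptor work, and the reduction is flagged per
compound; summary statistics presuppose one parent structure per
record. Compounds whose SMILES cannot be parsed are never dropped
silently: they carry an explicit `descriptor-failure` flag through the
pipeline, mirroring how real datasets contain the occasional structure
(e.g. a boronic acid without force-field parameters) that generates no
calculated data.

## Classification rules

**Rule-of-5 assessment** uses strict inequalities (MWt > 500, clogP >
5, HBD > 5, HBA > 10); a compound *fails* when at least two limits are
exceeded, so boundary values never violate. Raising any descriptor can
only leave the violation count unchanged or increase it — this
monotonicity is property-tested.

**Macrocycles** are molecules containing a ring of 12 or more atoms.
The test runs on ring-perception output rather than ring-size SMARTS:
for every non-bridge bond, the smallest ring through that bond is one
plus the shortest path between its endpoints with the bond removed; a
molecule is macrocyclic when the largest such smallest ring is ≥ 12.
This matches smallest-ring SMARTS semantics across dialects and cannot
be fooled by fused-ring perimeters (naphthalene's 10-atom perimeter is
not a smallest ring). The implementation is verified against
brute-force cycle enumeration on random graphs.

**Ionisation classes** count acidic groups (carboxylic, sulfonic,
sulfinic, phosphonic acids, acyl sulfonamides, NH-tetrazoles) and basic
groups (aliphatic amines excluding amide/sulfonamide/aniline nitrogens,
amidines, guanidines) with shipped, editable SMARTS patterns. Patterns
are written to be mutually exclusive and to match each group once, so
counts can be summed; the net charge (bases − acids) maps to
monoacid (−1), monobase (+1), neutral (no groups), zwitterion/other
(balanced groups), or polyacid/polybase (|net| ≥ 2). The class sizes of
any dataset are convention-dependent — pKa is not predicted, and a
different pattern set shifts the subsets — which is why the patterns are
data, not code.

**Percentile-derived rules** re-derive rule-of-5-style limits from the
dataset at hand as the order statistic of each descriptor at a chosen
percentile (default 90th). The quantile rule is the (n+1)p empirical
quantile (`type = 6` in `stats::quantile()`), the default of the
statistics package commonly used for such tables; the interpolation
variant is exposed through `quantileType`. Thresholds are reported raw
and rounded to reporting precision (MWt and counts to integers, clogP
to one decimal).

## The conformer-ensemble shape model

Shape descriptors come from the principal moments of inertia: with
atomic masses mᵢ and perpendicular distances rᵢ from a principal axis
through the centre of mass, I = Σᵢ mᵢ rᵢ², and the three sorted
eigenvalues of the mass-weighted inertia tensor give I₁ ≤ I₂ ≤ I₃. The
normalised ratios NPR₁ = I₁/I₃ and NPR₂ = I₂/I₃ place each conformer
in the triangle with vertices rod (0, 1), disc (0.5, 0.5) and sphere
(1, 1). Masses are isotope-averaged atomic masses with hydrogens
explicit; a unit-mass variant is available for comparison with
geometry-only conventions.

Because a flexible molecule has no single shape, NPRs are computed per
conformer and **Boltzmann-averaged** at T = 300 K with weights
wᵢ ∝ exp(−Eᵢ/k_BT), Eᵢ the MMFF94 energy in kcal/mol and k_B =
0.0019872041 kcal mol⁻¹ K⁻¹ — the constant is pinned in the same units
as the energies because a unit mismatch here is the classic silent bug.
Energies are shifted by their minimum before exponentiation for
numerical stability; at T → 0 the average collapses onto the
minimum-energy conformer, at T → ∞ it becomes the plain mean, and both
limits are asserted in the tests. The average of ratios is reported
(each conformer's NPR is a property being averaged), not the ratio of
averaged moments; the lowest-energy conformer's NPRs are reported
alongside since shape-triangle plots use either convention.

The ensemble itself is built per molecule as follows:

1. the requested ensemble size comes from the rotatable-bond count:
   50 conformers for ≤ 7 rotatable bonds, 200 for 8–12, 300 above 12;
2. an initial 3D structure is embedded deterministically: a 2D layout
   with explicit hydrogens, a random out-of-plane displacement drawn
   from an RNG seeded by the global seed plus a stable hash of the
   canonical SMILES (so adding compounds to a run never reshuffles the
   ensembles of others), and a deep MMFF94 relaxation (1500 steps);
3. Confab's systematic diverse torsion search generates the ensemble
   with an RMS diversity cutoff of 0.1 Å and a 50 kcal/mol energy
   window;
4. each conformer is optimised with MMFF94 (conjugate gradients, 200
   steps, convergence 10⁻⁶ — both configurable), energies are
   recomputed, and the relaxed ensemble is re-pruned so every pair of
   kept conformers differs by more than 0.1 Å heavy-atom least-squares
   RMSD, lowest-energy conformers taking priority.

The protocol is bit-reproducible for a fixed (molecule, seed) — the
only stochastic step is the seeded displacement in step 2 — and the
pruning invariant is checkable post hoc (`minPairwiseRMSD()`). Its
known limitations: torsion enumeration does not sample ring
conformations, so macrocycles and saturated rings contribute a single
ring geometry (their NPR spread is underestimated); the RMSD used for
pruning is not symmetry-corrected, so symmetric molecules can retain
equivalent copies; and MMFF94 covers common drug chemistry but not
boron or metals, which surface as flagged per-molecule failures rather
than crashes. Absolute NPR values also depend on the embedding and
force field, so shape statistics should be compared within one
protocol, not across toolkits.

## Statistics

Summary tables report mean, SD (n − 1 denominator) and the 50/75/90th
order-statistic percentiles under the same type-6 quantile rule as the
derived limits. Correlations between descriptors are squared Pearson
coefficients, with zero-variance input an explicit error rather than a
silent 0.

Group comparisons use the **Tukey–Kramer HSD** test: for groups i, j
with means mᵢ, mⱼ and sizes nᵢ, nⱼ, the statistic
q = |mᵢ − mⱼ| / sqrt(MSE/2 (1/nᵢ + 1/nⱼ)) with the pooled within-group
mean square, referred to the studentized-range distribution with k
groups and N − k degrees of freedom (`stats::ptukey`). The Kramer
standard error makes the test valid for unequal group sizes, which the
pass/fail and ionisation-class subsets always are. Zero-variance groups
are absorbed by the pooled variance. The implementation is
cross-checked against `stats::TukeyHSD` on balanced designs and against
a label-permutation oracle on unbalanced ones, and a 1000-replicate
null simulation confirms the family-wise error rate at α = 0.05 within
Monte-Carlo error. When a partition is compared across all its classes,
the full pairwise family is reported; readers who care about one
contrast can subset it.

Temporal trends bin approvals into 2000–2009, 2010–2019 and 2020–2022
by default, reporting per bin the approval count, rule-of-5 failure
count and percentage, and per-descriptor means; years outside every bin
are an error that names the offenders, and counts are conserved under
re-binning.

## The synthetic library generator

Real approval datasets are curated and not always redistributable, so
the package ships a generator that emulates one with known ground
truth. Molecules are assembled from a curated fragment grammar — ring
scaffolds (benzene, pyridine, pyrimidine, thiophene, cyclohexane,
tetrahydropyran, naphthalene, valerolactam) joined by linkers (alkyl,
ether, amide, sulfonamide, alkyne), decorated with polar, lipophilic,
acidic or basic substituents, with optional macrocyclic cores
(cycloalkane, macrolactone, macrolactam) — so every generated SMILES is
chemically valid by construction. Ring-closure labels are renumbered at
assembly so fragments nest arbitrarily.

Each compound gets planted labels before assembly: an approval period
(weights 0.29/0.51/0.20) and year; a rule-of-5 verdict drawn at the
period's target failure rate (12%, 20%, 18%); macrocyclic character at
fraction 10/371; and an ionisation class (monoacid 0.15, monobase 0.30,
neutral 0.50, zwitterion 0.05 — a mix chosen once as realistic for oral
drugs, since ionisation-class proportions are convention-dependent).
The assembler steers towards a per-molecule MWt target (compliant
compounds ~N(420, 125) capped at 500, fails ~N(660, 140) floored at
530, giving a full-set mean near 432 with SD near 159) and a
lipophilicity target, and **rejection sampling against the real
descriptor pipeline** guarantees that every planted label is exactly
recovered by that pipeline: a candidate is discarded unless its
rule-of-5 verdict, macrocycle flag and ionisation class match the plan
and its canonical SMILES is unique. An impossible request (e.g. a mean
MWt too small to carry the requested acceptor load) fails fast with an
infeasibility error.

The defaults describe a 371-compound oral-drug-like library with mean
MWt 432 (SD 159), clogP 3.4 (2.1), HBD 1.9 (1.3), HBA 5.8 (2.7) and 6
(4) rotatable bonds. The realised MWt mean tracks its target within a
few percent (the ±10% tolerance is checked and a deviation warns);
realised clogP, HBD and HBA run modestly above their targets (about
+0.4, +0.3 and +1.4 respectively) because the grammar's ring-rich
chemistry bounds how polar a valid assembly can be — the realised means
are recorded in `provenance(x)$realised` for every run. What the
generator does *not* emulate: real substructural diversity and
medicinal-chemistry novelty, correlated descriptor structure beyond
what the grammar induces, stereochemistry, or curation artefacts.
Passing tests on synthetic data therefore demonstrate that the pipeline
measures what was planted — verdicts, fractions, rates, order
statistics — not that any scientific conclusion about real drugs
transfers.

## Problem sizes and determinism

The shipped tests and the acceptance script run the 2D pipeline on
libraries of 200 and 371 compounds, the planted-recovery study across
20 seeds of 60 compounds, the HSD null simulation at 1000 replicates,
and the 3D shape pipeline on 20-molecule libraries — sizes chosen so a
complete validation runs in minutes on one CPU while keeping binomial
and Monte-Carlo error bars tight enough to be informative. Every
stochastic step (library generation, simulations, conformer embedding)
is seed-controlled; OpenBabel's own stochastic 3D builder is
deliberately not used, precisely because it cannot be seeded from the
outside.

## Known limitations

* clogP is an atomic-contribution estimate; fractions of compounds
  above fixed clogP thresholds shift between estimators.
* No pKa prediction: ionisation classes come from substructure counts,
  not charge states at pH 7.4, and log D is out of scope.
* The stereocentre count is constitutional (no meso resolution).
* Ring conformations are not enumerated in ensembles; macrocycle shape
  statistics rest on a single ring geometry per molecule.
* Surface-area descriptors are not computed.
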