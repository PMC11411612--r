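# drugspace

Physicochemical property and conformer-ensemble shape profiling of oral
drug space, in R.

Medicinal chemists judge oral drug-likeness with a handful of calculable
descriptors: molecular weight (MWt) for size, calculated logP (clogP)
for lipophilicity, hydrogen-bond donor/acceptor counts (HBD/HBA) for
polarity, plus flexibility and shape proxies — rotatable bonds, aromatic
ring count, the fraction of sp³ carbons (Fsp³), and the normalised
principal-moment-of-inertia ratios (NPR) that place a molecule in the
rod–disc–sphere shape triangle. Lipinski's rule of 5 says poor oral
absorption becomes likely when two or more of

> MWt > 500 Da, clogP > 5, HBD > 5, HBA > 10

hold. `drugspace` implements the full analysis pipeline used to profile
a drug approval dataset against these ideas:

* **dataset handling** — CSV parsing with SMILES validation and
  canonicalisation, salt stripping, data-driven exclusions, SDF export
  (`parseDataset()`, `applyExclusions()`, `writeStructures()`);
* **2D descriptors** — MWt, clogP (atomic-contribution estimate),
  rule-of-5 HBD/HBA, rotatable bonds (strict or loose), aromatic rings,
  Fsp³, stereocentres, ring and atom counts (`computeDescriptors()`);
* **classification** — rule-of-5 assessment with strict inequalities,
  macrocycle detection (any smallest ring ≥ 12 atoms), ionisation-class
  assignment from editable acid/base SMARTS, and percentile-derived
  property rules (`lipinskiAssess()`, `isMacrocycle()`,
  `ionisationClass()`, `derivePercentileRules()`);
* **3D shape** — a deterministic conformer-ensemble protocol (seeded
  embedding, Confab systematic torsion search with 0.1 Å RMS pruning,
  MMFF94 optimisation), principal moments of inertia
  I₁ ≤ I₂ ≤ I₃ from the mass-weighted inertia tensor, NPR₁ = I₁/I₃ and
  NPR₂ = I₂/I₃, and Boltzmann averaging over the ensemble at 300 K with
  weights ∝ exp(−Eᵢ/k_BT) (`generateEnsemble()`, `optimiseEnsemble()`,
  `shapeDescriptors()`);
* **statistics** — distribution summaries (mean/SD and order-statistic
  percentiles), descriptor correlations, Tukey–Kramer HSD all-pairs
  comparisons via the studentized-range distribution, and temporal
  binning of rule-of-5 failures (`summariseDescriptors()`,
  `pearsonR2()`, `tukeyKramerHSD()`, `temporalTrend()`,
  `subsetCompare()`, `propertyReport()`);
* **synthetic data** — a fragment-grammar library generator with
  planted, recoverable ground truth (Lipinski verdicts per period,
  macrocycle fraction, ionisation classes) for validating every stage
  without a proprietary dataset (`generatorSpec()`,
  `generateLibrary()`, `fixtureMolecules()`).

Chemistry primitives (SMILES parsing, SMARTS matching, force fields) run
on OpenBabel through `ChemmineR`/`ChemmineOB` and the `obabel`/`obenergy`
command-line tools, which must be on the `PATH`.

## Worked example

```r
library(drugspace)

d <- computeDescriptors(c(
  aspirin = "CC(=O)Oc1ccccc1C(=O)O",
  macrolactone = "CCC1OC(=O)C(C)C(O)C(C)C(OC)CCCCCCC(=O)CCC1C"))
as.data.frame(d)[, c("id", "mwt", "clogp", "hbd", "hba",
                     "rotatable_bonds", "fsp3")]
#>             id mwt clogp hbd hba rotatable_bonds  fsp3
#> 1      aspirin 180  1.31   1   4               3 0.111
#> 2 macrolactone 385  4.30   1   5               2 0.909

lipinskiAssess(d)$fails
#> [1] FALSE FALSE

isMacrocycle("CCC1OC(=O)C(C)C(O)C(C)C(OC)CCCCCCC(=O)CCC1C")
#> [1] TRUE
```

Aspirin is small, polar and rule-of-5 compliant; the 16-membered
macrolactone is heavier and highly saturated (Fsp³ 0.91) but still
compliant — the kind of compound for which ring constraint, not raw
size, governs oral prospects. A full dataset analysis starts from a CSV
and ends with the report tables:

```r
analysis <- applyExclusions(parseDataset("approvals.csv"))
report   <- propertyReport(analysis, outDir = "report")
report$derived_rules          # 90th-percentile property limits
report$trends                 # rule-of-5 fails per approval period
```

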