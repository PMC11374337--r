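# cspfit

Chemical shift perturbation (CSP) mapping and global titration fitting
for protein NMR.

When an unlabelled binding partner is titrated into a ¹⁵N-labelled
protein under fast exchange, every amide crosspeak in the ¹H-¹⁵N HSQC
moves in proportion to the bound fraction of the protein. `cspfit`
turns assigned peak lists from such a titration into:

* per-residue **combined amide CSPs**,
  Δδ = 0.5·√(Δδ_H² + 0.14·Δδ_N²);
* a **global K_D** from the exact ligand-depletion one-site isotherm,

      f_B(P, L, K_D) = [(P + L + K_D) − √((P + L + K_D)² − 4PL)] / 2P,

  fitted simultaneously over many residues (one saturation shift
  Δδ_max per residue, one shared K_D), with covariance-based and
  bootstrap uncertainties plus an independent profile-likelihood
  cross-check;
* an **interface classification** by the mean + 1/2/3 s.d. endpoint-CSP
  tier rule, mappable onto a PDB structure through the B-factor column;
* **backbone rigidity** labels from heteronuclear ¹⁵N{¹H} NOE ratios
  (≥ 0.8 rigid) and **histidine zinc-coordination** labels from
  δ(Cε1) − δ(Cδ2) (> 17 ppm → Nδ1);
* a seeded **synthetic titration generator** with known ground truth,
  so the whole pipeline is testable without any external data.

It was built around titrations of integrin β cytoplasmic tails with
the paxillin LIM2/3 tandem domain, and is general to any fast-exchange
one-site system. Intended users: NMR spectroscopists and structural
bioinformaticians who have assigned peak lists and want reproducible,
scriptable interface mapping instead of spreadsheet fits.

## Worked example

Simulate a titration at the weak-affinity forward design (300 μM
labelled protein, titrant up to 900 μM, true K_D = 528 μM, eight
C-terminal binding residues), then analyse it as if it were real data:

```r
library(cspfit)

sim      <- simulate_titration(titration_preset("beta3", seed = 7))
profiles <- build_csp_profiles(sim$series)

residues <- select_fit_residues(profiles)   # endpoint CSP > mean + 1 s.d.
#> [1] 783 784 785 786 787 788

fit <- fit_global_kd(profiles, residues)
fit
#> <binding_fit> K_D = 491 +/- 66.4 uM (6 residues, 34 points)
#>   endpoint fraction bound 0.595; converged: TRUE

round(bootstrap_kd(profiles, residues, n_boot = 200, seed = 7)$interval, 1)
#> lower upper
#> 395.7 580.4

cls <- classify_by_sd(endpoint_csp(profiles))
subset(cls$tiers, tier != "none")
#>    residue_number    csp_ppm  tier
#> 35            783 0.03106732 ge1sd
#> 36            784 0.03670271 ge1sd
#> 37            785 0.04828222 ge2sd
#> 38            786 0.05373285 ge2sd
#> 39            787 0.06561397 ge2sd
#> 40            788 0.07481193 ge3sd
```

Reading the output: the global fit recovers K_D ≈ 491 μM against a
generating value of 528 μM — within one standard error, and the
bootstrap interval (396–580 μM) covers the truth. The endpoint bound
fraction of 0.60 warns that the titration ends well short of
saturation, which is exactly why the replicate spread of K_D is wide
for weak binders. The tier table flags the C-terminal residues
783–788 as the binding interface, with the strongest perturbation
(residue 788, 0.075 ppm) in the top (> 3 s.d.) tier.
`map_classification_to_structure(cls, "model.pdb", "scored.pdb",
offset = ...)` writes those tiers into a PDB B-factor column for
surface colouring.

`run_analysis(config)` composes the same steps from a JSON/YAML config
and writes `csp_profiles.csv`, `fit_report.json`,
`classification.csv` and a run log; `inst/scripts/cspfit-cli.R` wraps
`run_analysis()`/`run_simulate()` for shell use.

The methods vignette (`vignettes/csp-titration-mapping.Rmd`) documents
the model, the numerical choices, and what the synthetic generator
does and does not emulate.

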