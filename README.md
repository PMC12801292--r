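# PharmScreen

Consensus pharmacological-interaction scoring for structure-based
virtual screening.

Docking scores alone rank compounds noisily. For targets with known
inhibitors, the inhibitors' *interaction pattern* — which binding-site
residues they hydrogen-bond to and pack against — is far more conserved
than their scores. PharmScreen implements a post-docking rescoring
protocol built on that observation, for computational chemists running
structure-based screens:

1. **Detect and type interactions** in docked poses: hydrogen bonds
   (heavy-atom distance ≤ 3.5 Å, D–H···A angle ≥ 120° when the hydrogen
   is explicit) and hydrophobic contacts, subtyped alkyl (A),
   pi-stacking (P) or mixed (M).
2. **Build a per-structure pharmacological model**: dock a panel of
   known actives, take the top 30 by docking score, and keep the residue
   contacts formed by ≥ 50% of them (hydrogen bonds) or ≥ 80%
   (hydrophobic contacts).
3. **Rescore** every screened compound *i* by the pharmacological score

   *S*(*i*) = *N*(*i*) + (−0.01) × *D*(*i*),

   where *N*(*i*) is the number of model interactions the compound
   reproduces and *D*(*i*) its docking score (more negative = better).
4. **Fuse rankings across a receptor ensemble**: per-structure ranks are
   summed into a consensus score and compounds reranked by it
   (lower = better).
5. **Evaluate** with actives-vs-decoys ROC-AUC, validate docking by
   symmetry-corrected redocking RMSD (< 2.5 Å), prepare libraries with
   an HTS / Lipinski / Veber / PAINS / QED filter cascade, and pick
   chemotype representatives from the top consensus compounds by
   ECFP4/Tanimoto leader clustering.

A fully synthetic benchmark generator (geometric binding pockets, poses
with planted interactions, Gaussian mock docking scores) exercises the
whole pipeline with no external or proprietary data.

## Worked example

Generate the default planted-signal benchmark (3 synthetic receptor
structures, 30 actives vs 90 decoys), build per-structure models from
the actives, score everything and compare rankers:

```r
library(PharmScreen)

bench <- generateBenchmark(benchmarkSpec(seed = 1))
ev <- evaluateBenchmark(bench)
ev$aucs
#>                      model n_actives n_decoys   auc
#> 1             docking_SYN1        30       90 0.697
#> 2               pharm_SYN1        30       90 0.993
#> 3             docking_SYN2        30       90 0.657
#> 4               pharm_SYN2        30       90 0.978
#> 5             docking_SYN3        30       90 0.723
#> 6               pharm_SYN3        30       90 0.982
#> 7 consensus_SYN1+SYN2+SYN3        30       90 1.000
```

Raw docking separates actives from decoys at AUC ≈ 0.66–0.72 (the
benchmark's score model is calibrated near 0.75). Rescoring by the
pharmacological score lifts each structure to ≈ 0.98–0.99, and summing
the three per-structure rankings into a consensus separates the classes
completely — the qualitative ordering (consensus ≥ single-structure
pharmacological > docking-only) that motivates the method.

The model the package learned for the first structure:

```r
ev$models$SYN1
#> PharmacologicalModel SYN1 (HB >= 0.50, HP >= 0.80): 5 key interaction(s)
#>   SER87 HP/alkyl (0.93)
#>   LEU94 HP/alkyl (0.90)
#>   ASN101 HP/alkyl (0.97)
#>   THR122 HP/alkyl (0.90)
#>   TYR136 HB/both (0.87)
```

— the planted pattern (one hinge-like hydrogen bond plus a hydrophobic
shell) recovered from the actives' pose profiles, with the observed
frequency of each contact in parentheses.

Real data enter through the same interfaces: `readPDBReceptor()` for
structures, `loadPoseSet()` for a docking engine's poses + score
manifest (CSV: `compound_id,structure_id,docking_score,pose_file`),
`readSmilesFile()`/`readMoleculesSDF()` for libraries, and
`runScreen()` for the staged end-to-end screen (filter → docking-score
cut → pharmacological scoring → consensus → clustering →
representatives).

A command-line front end for the common steps ships with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","pharmscreen.R",package="PharmScreen"))')" \
    filter --in library.smi --out survivors.smi --report report.json
```

Subcommands: `fixtures`, `filter`, `model`, `score`, `consensus`,
`evaluate`, `simmatrix`.

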