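---
title: "Consensus pharmacological-interaction scoring: models and methods"
author: "PharmScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus pharmacological-interaction scoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PharmScreen)
```

## The problem

Docking scores alone are a noisy ranker: engines place most compounds
plausibly in a binding site, but the energy estimate discriminates true
binders from decoys imperfectly. For well-studied targets, however, the
*interaction pattern* of known inhibitors is highly conserved — for an
ATP-competitive kinase inhibitor, typically one or two hinge hydrogen
bonds flanked by a consistent hydrophobic shell. PharmScreen implements a
rescoring protocol that exploits this: it learns, per receptor structure,
which residue contacts the top-ranked known actives form consistently,
rescores every docked compound by how many of those contacts it
reproduces, and fuses the resulting rankings across an ensemble of
crystal structures.

## The model

### Interaction detection and typing

For one docked pose against one receptor structure, two interaction
classes are detected from geometry alone:

* **Hydrogen bonds (HB).** Every donor–acceptor pair with heavy-atom
  distance $\le d_{HB}$ (default 3.5 Å) counts; when the donor hydrogen
  is explicit, the D–H···A angle must also reach $\theta_{min}$ (default
  120°) — with implicit hydrogens the angle test is skipped, since no
  hydrogen position is defined. Donor/acceptor typing uses elements and
  bonding only: ligand N/O atoms donate when they carry an explicit or
  valence-implied hydrogen and accept unless positively charged;
  receptor N/O roles come from a residue–atom dictionary (backbone N
  donates, backbone O accepts, side chains follow their chemistry,
  unknown N/O fall back to both roles). No p$K_a$ or tautomer inference
  is attempted: it would make detection irreproducible across
  preparation pipelines.
* **Hydrophobic contacts (HP)**, subtyped *alkyl* (A), *pi-stacking*
  (P) or *mixed* (M). Alkyl: an apolar ligand carbon (no N/O/S
  neighbour) within $d_{HP}$ (default 4.5 Å) of a receptor side-chain
  carbon. Pi-stacking: aromatic ring centroids within $d_\pi$ (default
  5.5 Å) with interplanar angle $\le 30°$ (parallel) or 60–90°
  (T-shaped). Aromatic–aromatic carbon pairs are excluded from the alkyl
  channel — two stacked rings otherwise always trip the alkyl cutoff
  too, and their proximity is what the stacking test already measures. A
  residue contacted through both channels in one pose is reported once,
  as *mixed*. This residue-level merge defines the profile key: a
  profile is a set of (chain, residue, class) keys, so two alkyl
  contacts to one leucine count once, matching how per-residue frequency
  profiles are reported.

All thresholds live in one `interactionCriteria()` object and are
community-standard values; the upstream interaction-analysis tools this
protocol emulates do not publish their exact geometric definitions, so
these defaults are this package's own documented choice, and every
detector result equals a literal all-pairs enumeration under the same
criteria (a property the test suite enforces against an independent
brute-force oracle).

### The pharmacological model

For one structure, dock a panel of known actives, keep the best pose per
compound, select the top $n$ = 30 by docking score, and profile them.
The *pharmacological interactions* of the structure are the keys formed
by at least 50% of those actives (hydrogen bonds) or at least 80%
(hydrophobic contacts) — both bounds inclusive, reading "at least"
literally, so a frequency of exactly 0.50 or 0.80 qualifies. The
hydrophobic threshold is applied at residue level (one subtype letter
per residue, the modal subtype across profiles); subtype-resolved
counting is available via `interactionFrequencies(subtypeKeys = TRUE)`
because the residue-level aggregation is a presentation choice, not a
law.

### Scoring and consensus

Each screened compound $i$ with docking score $D(i)$ (more negative =
better) and $N(i)$ matched key interactions receives the pharmacological
score

$$S(i) = N(i) + (-0.01) \times D(i).$$

The small weight on $D$ makes the interaction count dominate — one
additional key contact outweighs any realistic docking-score
difference — while $D$ breaks ties among compounds with equal $N$.
Within a structure, compounds are ranked by $S$ descending; remaining
ties break by more-negative $D$, then compound id, making ranks a
deterministic, gap-free permutation.

For an ensemble of $m \ge 2$ structures the per-structure ranks are
summed into an integer consensus score (lower = better) and compounds
are reranked by it. Ordinal ranks (not midranks) keep the sum integral.
A compound missing from one structure's ranking — a docking failure —
receives rank $K+1$ there rather than being dropped: the consensus stays
defined over the union of compounds and the failure is penalized. Both
choices are this package's own, documented because the source protocol
is silent on them.

### Evaluation

Enrichment is measured as ROC-AUC with actives as positives, under the
midrank (Mann–Whitney) tie convention:
$\mathrm{AUC} = P(s_a > s_d) + \tfrac12 P(s_a = s_d)$ over active–decoy
pairs. Docking protocols are validated by redocking: the in-place
heavy-atom RMSD between redocked and crystal pose (no re-superposition —
both live in the receptor frame), minimized over graph automorphisms so
a benzene flip does not inflate the value, must be *below* 2.5 Å
(strictly, reading "below" literally; a 2.5 Å pose fails).

## The filter cascade

Screening libraries pass, in order: an HTS structural filter
(nonorganic elements outside H/C/N/O/S/P/halogens; a reactive-group
SMARTS catalogue — acyl halides, aldehydes, Michael acceptors, epoxides,
isocyanates and kin); Lipinski's rule of five (MW > 500, logP > 5,
HBD > 5, N+O acceptors > 10; by default **any** violation excludes,
with the classical one-violation-allowed reading available by
configuration, because "violated the rule" does not disambiguate);
Veber's criteria (rotatable bonds ≤ 10, TPSA ≤ 140 Å²); the published
PAINS SMARTS catalogue (all three families, 480 patterns, matched
against explicit-hydrogen structures); and a QED cutoff (below 0.25
removed — strictly below, so a compound at exactly the threshold stays;
0.25 is chosen where the protocol's own sections disagree between 0.25
and 0.24, and the threshold is configurable). QED itself is computed
from the published desirability functions and their published parameters
over MW, logP, acceptors, donors, TPSA, rotatable bonds, aromatic rings
and structural alerts, with the mean-weight scheme as default. The logP
estimator is OpenBabel's atom-contribution method and is named in the
filter config, since borderline Lipinski/QED results shift with the
estimator. Each removal records the first failing stage and a
machine-readable reason; the audit satisfies
`passed(stage k) = input(stage k+1)` and the chain is idempotent.

## Similarity and representative selection

Compound similarity uses extended-connectivity fingerprints of radius 2
folded to 2048 bits (ECFP4) and the Tanimoto coefficient
$|A \cap B| / |A \cup B|$, with the convention that two empty
fingerprints are identical (similarity 1). Note that absolute bit
positions of any hashed circular fingerprint are specific to the
generating implementation; what is stable, and tested, is determinism,
invariance to atom ordering, and the similarity values. Top consensus
compounds are clustered by sphere-exclusion (leader) clustering in
consensus-rank order at Tanimoto 0.6 — best-ranked compound founds a
cluster and absorbs everything at or above the threshold — and each
cluster's leader (its best-ranked member) becomes the representative.
The protocol this emulates did not name its clustering algorithm or
threshold; leader clustering was chosen because its determinism and
rank-awareness fit the screening context, and 0.6 is a conventional
ECFP4 similarity for "same chemotype".

## The synthetic benchmark

No part of the pipeline requires proprietary inputs: the fixtures module
fabricates everything.

* `generatePocket()` arranges 3–8 residues (a fixed diverse cycle of
  serine/threonine/asparagine/aspartate/lysine donors and acceptors,
  leucine, and phenylalanine/tyrosine aromatics) on a sphere cap of
  radius 10 Å around an origin cavity, side chains pointing inward.
  Two rings of four positions (polar angles 52° and 100°, azimuth step
  90°, offset 45°) keep every pair of residues ≥ ~64° apart, which — with
  contact atoms at ~2.5 Å depth and aromatic centroids at ~2.2 Å —
  guarantees that a ligand fragment placed against one residue stays
  outside every detection cutoff of all others. Coordinates carry a
  small seeded jitter (±0.1 Å) so no two pockets are identical;
  the placement margins absorb it.
* `plantPose()` realizes a requested set of (residue, class) keys with
  margin *inside* the cutoffs: hydrogen-bond distances sampled in
  2.7–3.3 Å with a collinear explicit donor hydrogen, alkyl contacts at
  3.7–4.2 Å, parallel stacks at 3.3–3.5 Å centroid separation. Margin
  sampling avoids boundary flakiness: no planted geometry sits near a
  threshold. The generator's contract — the detector finds exactly the
  requested keys — is tested residue-by-residue with the detector as
  oracle.
* `generateBenchmark()` draws, per structure, 1 planted hydrogen bond
  and 4 planted hydrophobic contacts (one hinge bond plus a hydrophobic
  shell, the conserved kinase-inhibitor pattern). Actives realize each
  planted key with probability 0.9, decoys 0.3, and everyone touches
  non-planted residues with probability 0.05; docking scores are
  Gaussian with active mean −6.95, decoy mean −6.0, sd 1.0, so
  docking-only enrichment sits near AUC 0.75 — a realistic mid-quality
  docking run with headroom for rescoring to improve, and the default
  benchmark is 30 actives vs 90 decoys over 3 structures, a desk-scale
  analogue of a 30-active / 990-decoy evaluation. With these
  conditions the pharmacological score reaches AUC ≈ 0.99 and the
  3-structure consensus ≈ 1.0 in the test suite's replicates: the
  synthetic signal is deliberately clean. What the benchmark emulates is
  the *protocol* — model building from actives, rescoring, rank fusion,
  AUC comparison; what it does not emulate is real chemistry: poses are
  geometric fragment scaffolds, not conformers of the 2D structures
  attached to the compounds, decoy difficulty is a dial rather than a
  property-matched decoy set, and interaction realization is
  independent across residues. Passing tests therefore demonstrate
  correctness and the qualitative ordering (consensus ≥ pharmacological
  > docking-only), not a real-target effect size.

## Numerical and engineering choices

* Ranks, counts and rank sums are integers end-to-end; $S$ is exactly
  $N - 0.01 D$ in double precision (asserted to machine precision).
* All randomness flows through explicit seeds; generators restore the
  caller's RNG state. Pipeline artifacts are plain CSV/JSON with no
  timestamps, so a rerun under the same config and seed is
  byte-identical.
* Aromatic ring perception for planted ligands uses SDF aromatic bond
  orders, with a planarity fallback (5–6-membered C/N rings, ≤ 3 heavy
  neighbours per atom, ≤ 0.15 Å deviation from the least-squares
  plane) for kekulized input.
* Symmetry-aware RMSD enumerates graph isomorphisms with element and
  bond-order colouring (VF2); for drug-sized molecules the automorphism
  count is small.
* Degenerate inputs are defined, not special-cased: an empty contact
  list gives an empty profile; an empty frequency table gives an empty
  model ($N \equiv 0$, so ranking falls back to the docking order); an
  empty library gives a zero-count filter report.
* Single-heavy-atom molecules (e.g. methane) are outside the SDF-backed
  2D path: the underlying container cannot represent bond-less records.
  Generated poses always carry a two-atom scaffold, so every artifact
  the package writes is well-formed.

## Scales used by the test suite

Unit tests run on pockets of 5–8 residues and compound sets of tens;
the enrichment simulation uses the default benchmark (120 compounds ×
3 structures) over 100 seeds, and the end-to-end determinism check
screens 200 compounds with a top-50 docking cut and top-10 consensus
cut. These sizes were chosen so the full protocol — including the
brute-force oracles — exercises every code path at interactive runtimes;
the algorithms are the same at library scale, where per-structure
scoring is linear in poses and the similarity matrix quadratic in the
clustered subset only.

## Known limitations

* Detection covers hydrogen bonds and hydrophobic contacts only — no
  halogen bonds, salt bridges, cation–pi or water bridges, mirroring
  the two-class frequency analysis it implements.
* Receptor donor/acceptor typing is dictionary-based and
  protonation-blind; histidine is treated as both donor and acceptor.
* The docking engine is an external adapter: the package ingests poses
  and scores, it never generates them.
* ECFP bit positions are implementation-specific (OpenBabel's ECFP
  here); fingerprints from other toolkits will not be bit-compatible,
  though Tanimoto similarities are typically close.
* The QED descriptor stack (OpenBabel logP, acceptor typing) differs in
  detail from other published implementations; absolute QED values can
  shift by a few hundredths at borderline compounds, which is why the
  estimator is recorded in the filter provenance.

## A worked miniature

```{r example, eval = FALSE}
bench <- generateBenchmark(benchmarkSpec(seed = 1))
ev <- evaluateBenchmark(bench)
ev$aucs
show(ev$models[[1]])
```
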