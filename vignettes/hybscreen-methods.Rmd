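---
title: "Methods: fragment hybridization, MLP screening and triage in hybscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragment hybridization, MLP screening and triage in hybscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hybscreen implements a ligand-based discovery pipeline for allosteric
kinase inhibitors — the motivating system is the JAK2 pseudokinase (JH2)
domain, where selective allosteric binders are sought as alternatives to
ATP-competitive JH1 inhibitors. Four stages are covered: 3D fragment
hybridization of known binders, an ECFP4 multilayer-perceptron (MLP)
activity classifier, applicability-domain / drug-likeness /
synthetic-accessibility triage, and early-recognition statistics for
validating ranked screens. This vignette records the models, the
parameters that matter, the numerical choices, and what the synthetic
fixtures do and do not establish.

## 1. BREED-style fragment hybridization

The hybridizer assumes its input ligands sit in a **common binding-site
frame** — in a real campaign that frame comes from crystallography or
docking. Alignment is deliberately out of scope: geometric bond matching
across unaligned molecules is meaningless, so `generate_library()` never
re-aligns. A Kabsch superposition helper (`align_ligand()`) is provided for
preparation but never invoked implicitly.

The algorithm:

1. **Fragmentation.** Every acyclic single bond between two heavy atoms is
   a candidate cut, provided each side retains at least
   `min_fragment_heavy_atoms` heavy atoms (default 3). The size floor is
   our operationalization of "preserve pharmacophore-sized pieces";
   nothing smaller than three heavy atoms is a useful pharmacophore, and
   the parameter is exposed for users who disagree. Ring bonds (detected
   exactly, by connectivity after bond deletion, so macrocycles count as
   rings) and bonds to hydrogen are never cut.
2. **Bond-vector matching.** Directed cut bonds from two different ligands
   match when both endpoint pairs superimpose within `d_max` (default
   1.0 Å, the distance below which the new bond has a chemically feasible
   length) and the bond vectors agree within `theta_max` (default 15°,
   beyond which the junction would be strained). Both tests are
   **boundary-inclusive**. The displacement test is applied at *both*
   endpoints (the stricter reading); a bond-midpoint variant is available
   via `displacement_mode = "midpoint"`.
3. **Recombination.** A matched pair yields up to two hybrids (head of A +
   tail of B and the complement). Atoms keep their original coordinates;
   the junction is a new single bond. Because the cut bond removed from
   each junction atom is replaced by exactly one new single bond, valence
   is conserved for well-formed inputs; the sanitizer (a per-element
   valence table plus an OpenBabel round-trip) exists to catch malformed
   inputs and drops offenders with a count.
4. **Deduplication.** Stereo-aware canonical SMILES (OpenBabel `can`) is
   the dedup key everywhere; coordinates do not participate. Hybrids that
   canonicalize to any input (or pool) structure are discarded. Output is
   sorted by canonical SMILES, and the module contains no randomness, so
   libraries are reproducible structure for structure.

With `generations > 1`, each cycle's novel hybrids join the next cycle's
ligand pool. The optional `untangle` step runs a short MMFF94
steepest-descent minimization to relax junction strain; topology is
asserted invariant (identical canonical SMILES before and after), and on
any failure the unrelaxed geometry is returned flagged rather than
silently altered.

## 2. The MLP activity classifier

Molecules are featurized as 2048-bit ECFP4 (Morgan radius-2) fingerprints.
The circular-environment identifiers come from OpenBabel's ECFP4
implementation and are folded to the requested width; counts and chirality
flags are off by default (configurable in `fingerprint_spec()`). Bit
patterns differ from other toolkits' ECFP4 — only internal consistency
matters, since the same featurizer produces training and screening
fingerprints.

The classifier is a 2048 → 512 → 128 → 1 network: ReLU hidden units, 20 %
dropout between the hidden layers, sigmoid output, trained for 20 epochs
with Adam (learning rate 0.001) on binary cross-entropy in minibatches of
32 (a conventional size, recorded in `model_spec()` for reproducibility).
The training loop is compiled (RcppArmadillo) but draws **all** randomness
— He-initialized weights, epoch shuffles, dropout masks — from R's RNG, so
one `set.seed()` (the spec's `seed`) makes training bit-reproducible. At
this scale a model trains in seconds on one CPU; there is deliberately no
GPU path, hyperparameter search or calibration.

The stratified 80/20 split keeps each class's proportion within one
example of the global proportion. Classification uses the standard 0.5
probability threshold; `evaluate()` returns the full panel (confusion
counts, per-class precision/recall/F1, macro and weighted averages,
rank-statistic ROC-AUC with midrank ties) with exact arithmetic, rounded
to three decimals only for display. Note that with precision 1.0 and
recall 11/12 the class-1 F1 is 22/23 ≈ 0.957 — the package reproduces the
arithmetic, whatever a report table may print.

## 3. Triage: applicability domain, QED, SA

The funnel applies four filters in a fixed order — activity (p ≥ 0.5),
applicability domain, drug-likeness, synthetic accessibility — and reports
sequential survivor counts and per-stage exclusion percentages relative to
the records entering each stage. Because the filters are independent
flags, reordering changes per-stage counts but never the final pass set.

**Applicability domain.** A prediction is trusted only for compounds with
max Tanimoto ≥ 0.4 to the training set — the *entire* training set,
actives and inactives, since the model learned from both. The maximum is
exact (full linear scan), not approximate.

**QED.** The quantitative estimate of drug-likeness is the weighted
geometric mean of eight desirability-transformed properties (MW, ALOGP,
HBA, HBD, PSA, rotatable bonds, aromatic rings, structural alerts), with
the published asymmetric-double-sigmoid parameters and weights hard-coded
as constants of the method. The arithmetic (`qed_score()`) reproduces the
reference implementation to full precision when fed identical property
values; the property engines differ in two places. Descriptors come from
OpenBabel (Wildman–Crippen logP, Ertl TPSA, JoelLib H-bond counts), which
agree with RDKit on our test panel, but rotatable-bond counts can differ
by one on esters, and the structural-alert term uses the package's own
curated Brenk-style SMARTS list (`inst/extdata/structural_alerts.tsv`, 37
named alerts) rather than another toolkit's internal list, which cannot be
redistributed. Whole-molecule QED therefore tracks RDKit within a few
hundredths rather than exactly — adequate for a 0.7 pass/fail threshold,
and the discrepancy sources are all inspectable text files.

**SA score.** Ertl-style synthetic accessibility in [1, 10]: a
fragment-frequency term (mean contribution of each heavy atom's radius-1
environment signature) minus complexity penalties — size
(n^1.005 − n), stereocentres, macrocycles (ring size > 8), spiro and
bridged ring pairs, each log10(k + 1) — mapped linearly from the raw range
[−3.5, 0.3] onto the 1–10 scale with logarithmic compression above 8. The
fragment table is built at first use from a built-in plain-text corpus of
~220 common drug and scaffold SMILES (`inst/extdata/sa_corpus.smi`) — a
package artifact standing in for the million-compound purchasable
collections the original idea was calibrated on. Contributions are
log10 frequencies centred on the corpus's upper-quartile fragment, clipped
to [−4, 0.5]; unseen fragments score −2 ("rare"). The raw-range constants
were fixed once against a reference panel (ethanol ≈ 1.6, benzene ≈ 1.7,
stereo-dense fused bicyclics > 4) and are not tuned thereafter. The scorer
is pluggable: any `list(table =, unknown =)` replaces the packaged one, so
a user with the original fragment table can drop it in.

## 4. Enrichment statistics and energy aggregation

`ranked_screen()` fixes the conventions: docking scores are
negative-better by default (`lower_is_better`), ranks are best-first, and
ties are broken by a stable (score, id) sort so the exponentially weighted
statistics are deterministic; midranks are used only inside the ROC-AUC.

RIE is the mean exponential rank weight of the actives normalized by its
uniform-ranking expectation; BEDROC is its min–max rescaling onto [0, 1].
The weighting parameter α = 160.9 concentrates the statistic on roughly
the top 1/α ≈ 0.6 % of the list — the regime a prospective screen actually
samples. EF at fraction f uses top-k with k = ⌈fN⌉ (floor/round variants
selectable). All three are invariant to monotone score transforms, equal
their analytic anchors at perfect/worst rankings, and have permutation
null expectation 1 (RIE, EF) — properties the test suite checks by Monte
Carlo rather than against any particular screen.

MM/GBSA aggregation is intentionally minimal: per frame
ΔE = E(complex) − [E(receptor) + E(ligand)], reported as ensemble mean ±
sample SD (n − 1). The package consumes per-frame energy tables (CSV); it
does not dock, simulate, or parse trajectories. Docking-selectivity gaps
are `score(off-target) − score(target)`, positive meaning
target-preferring.

## 5. What the synthetic fixtures establish

The generators in `fixtures` make every stage testable offline:

- **Aligned sets** (`make_aligned_set`) place 2–4 ligands on an exactly
  superimposed aromatic scaffold (literal coordinate tables, no
  embedding), with distinct ring decorations and three-atom tails and
  exactly one cut site each. The expected hybrid set — every head/tail
  swap — is enumerated by direct SMILES assembly, independently of the 3D
  code path, and an exhaustive brute-force enumerator in the test suite
  re-derives it a third way.
- **Activity datasets** (`make_activity_dataset`) plant a
  2-aminopyrimidine motif (a kinase-hinge-like core) in every active and
  rejection-sample decoys so no inactive contains it. Class sizes default
  to 614/614, the scale of a curated balanced kinase set. With zero label
  noise the classes are separable in ECFP4 space *by construction*; a
  held-out AUC ≥ 0.95 therefore validates the training machinery, not any
  claim about real-world kinase data, where actives and decoys share far
  more substructure. The label-shuffle null (AUC ≈ 0.5) checks the
  complementary failure mode: that the pipeline cannot hallucinate signal.
- **Funnel libraries** (`make_funnel_library`) plant per-stage survivor
  counts using structure templates with verified filter behaviour;
  generation fails loudly if a template stops satisfying its role under
  the default thresholds, so the planted counts are never silently wrong.
- **Ranked screens** (`make_ranked_screen`) produce perfect, worst,
  random, and exponentially enriched rankings with known statistics.

Problem sizes in the test suite — 600/600 compounds for classifier
recovery, 20 seeds for the shuffle null, 1,000 permutations for the
enrichment null, ≤ 5 ligands for oracle-equivalence — were chosen as the
smallest scales at which the statistical bands are tight; the same
generators run at any size.

## 6. Known limitations

- Hybridization handles neutral organic molecules; formal charges in the
  old-style molblock field or `M CHG` lines are not interpreted, and the
  valence sanitizer is permissive for hypervalent S/P rather than
  chemistry-aware.
- The OpenBabel ECFP4 bit mapping differs from other toolkits; models and
  applicability domains are portable only together with this featurizer.
- QED alert counts and the SA fragment table are package artifacts (see
  above); absolute values differ from other implementations even though
  thresholds behave equivalently on the tested panel.
- Aromatic-ring counting uses ring perception capped at 7-membered rings;
  large aromatic macrocycles (porphyrins) are out of scope.
- The docking and molecular-dynamics stages of a real campaign (pose
  generation, trajectory analysis) are consumed as tables, never
  computed.
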