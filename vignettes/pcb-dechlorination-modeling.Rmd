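---
title: "Modeling microbial reductive dechlorination of PCB mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling microbial reductive dechlorination of PCB mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcbDechlor)
```

## The problem

Polychlorinated biphenyls (PCBs) were sold as technical mixtures such as
Aroclor 1260, a blend dominated by hexa- and hepta-chlorobiphenyls. In anoxic
sediments, organohalide-respiring bacteria (*Dehalococcoides*,
*Dehalogenimonas* and relatives) remove chlorines reductively, one at a time,
moving mass from heavily chlorinated congeners toward lighter ones. Which
chlorines a community removes is not random: field and culture studies
summarize the observed substrate preferences as named *dechlorination
processes* (M, Q, H′, H, P, N, LP, T), each defined by the chlorophenyl-ring
motifs attacked — for example, Process H removes flanked *para*- and doubly
flanked *meta*-chlorines, while Process N removes flanked *meta*-chlorines.

Interpreting a dechlorination experiment therefore means congener-level
bookkeeping: which of the 209 congeners decreased, which appeared, whether the
pattern of losses and gains is consistent with a known process, how much
chlorine left the PCB pool, and how much dechlorinator growth that chlorine
flux supported. This package implements that bookkeeping as reusable,
testable code, together with a synthetic-data generator that stands in for
GC-ECD congener measurements and qPCR cell counts so that every stage of the
pipeline can be exercised and validated without instrument data.

## Congener structure and naming

A congener is an unordered pair of chlorophenyl rings. Chlorines sit at ring
positions 2–6 (carbon 1 bears the biphenyl bond and is never substituted), so
a ring is a subset of {2,3,4,5,6}. A 1-substituted ring has a mirror symmetry
2↔6, 3↔5, 4 fixed: the patterns {3,6} and {2,5} are the same physical ring.
`canonicalizeRing()` resolves this by taking the lexicographically smaller of
the two mirror images; exactly 20 canonical patterns exist, and unordered
pairs of them with at least one chlorine give the familiar 209 congeners
(`enumerateAllCongeners()`), partitioned mono through deca as
3/12/24/42/46/42/24/12/3/1.

Names follow the per-ring positional dialect used in the dechlorination
literature: `"2345-245-CB"`, with single-ring congeners written `"2345-CB"`.
The ring order in a printed name is governed by a convention we
reverse-engineered from the published tables and fixed as the package's
single naming authority: the ring with more chlorines is named first, and
ties are broken by the numerically smaller position string (hence
`"24-25-CB"`, `"245-24-CB"`, `"236-34-CB"`). Parsing and re-rendering any
printed name reproduces it exactly; non-canonical input (mirror images,
swapped ring order) is normalized silently. BZ/IUPAC congener numbers
(PCB-153 and the like) are deliberately not used anywhere: the profile
tables this package works with never use them.

Position classes are ortho (2,6), meta (3,5) and para (4). A chlorine is
*flanked* when an adjacent ring carbon in 2–6 is also chlorinated; carbon 1
never flanks, so ortho chlorines can be singly flanked at most.
`classifyChlorines()` exposes this classification, which is what the process
rule sets are written in terms of.

## Process rule sets

A `ProcessRuleSet` is a list of ring-level transformations: substrate ring,
removed position, derived product ring, a provenance tag naming the
structural motif, and a weight. Four rule sets are built in, encoding the
transformations evidenced in sediment-free Aroclor 1260 cultures:

* **H** — flanked para and doubly flanked meta removal: 34→3, 234→24,
  245→25, 2345→235, 2345→245.
* **N** — flanked meta removal: 234→24, 236→26, 235→25, 245→24, 2345→245,
  2345→234.
* **T** — only 2345→245 (the doubly flanked meta of a 2345 ring).
* **CG1** — doubly flanked meta removal (234→24, 2345→245) plus *partial*
  para (2345→235) and *partial* ortho (234→34) activity, a pattern seen in
  one culture that matches no single literature process.

Rules apply in **strict** mode by default: only listed transformations fire.
A **generic** mode derives removals from a structural predicate at
application time; it is implemented for N ("remove any meta chlorine with a
chlorinated neighbour") and cross-validated against the strict list on every
evidenced ring pattern. Strict is the default because generic predicates
over-generate — the H evidence never shows 234→23, which a generic
flanked-para predicate would permit. User rule sets load from a tab-separated
config (`readRuleSet()`); the product ring is always derived, never stored,
so a config cannot encode a chlorine-conservation violation.

The CG1 "partial" rules carry weight 0.2 relative to its meta rules. The
source evidence says only that ortho and para products appeared "partially",
with no quantity; 0.2 is the package's one-time choice of a minor-route
multiplier, configurable per rule in the TSV format and overridable in
`rateAssignment()`.

## Pathway graphs

`enumeratePathways()` closes a start congener under a rule set by
breadth-first search. Because every edge removes exactly one chlorine the
graph is a DAG, every path from the start to a node has length equal to the
chlorine difference, and the node set is bounded by the sub-patterns of the
start's chlorines (tiny in practice; the largest built-in closure has a few
dozen nodes). Distinct rule applications yielding the same product are kept
as separate labeled edges — a symmetric congener such as 245-245-CB has one
para chlorine per ring, and kinetics must count both. Reachability queries
(`reachable()`, `explainCongener()`) return shortest witness paths via
igraph, and all shortest routes are reported when several exist (234-245-CB
reaches 24-25-CB via both 234-25-CB and 245-24-CB under H).

## Classifying an observed profile change

The published studies attribute a culture's pattern to a process by expert
inspection of the loss/gain lists. The package formalizes that judgment; the
scoring function is this package's own construction, and every verdict
carries per-congener witness records so a user can audit it against the
congener chemistry:

* a **decreased** congener is *explained* by a process if at least one of its
  rules applies to it;
* an **increased** congener is *explained* if it is reachable (multi-step)
  under the process from some decreased congener;
* the explained-loss and explained-gain fractions (weighted by |Δ mol%|, or
  per congener for list input) are combined — by default their unweighted
  mean; harmonic and gain-only combinations are selectable — and candidates
  are ranked, with ties broken deterministically by name and reported as
  ties.

Changes count when they exceed a threshold, default 2 mol% as in the
published congener-change tables. The threshold has a knowable side effect:
on noiseless simulated data a gained congener can be fed by sources that
individually fall below it, leaving the gain formally unexplained even by
the generating process. At threshold 0 the generating process always scores
exactly 1 on its own noiseless data; at the default threshold it still ranks
first by a wide margin. Rule sets that are contained in richer ones (T ⊂ H
and T ⊂ N on their shared substrates) can tie on data they both explain
fully — the classifier reports the tie rather than guessing.

## Kinetics

`simulateDechlorination()` treats dechlorination as a first-order reaction
network: close the mixture's support under the rule set, assemble the linear
generator A (each rule application contributes its rate to the
product–substrate entry and subtracts it from the substrate diagonal), and
evaluate x(t) = e^{At} x(0) with the matrix exponential. Column sums of A
are zero by construction, so total mol% is conserved exactly — mirroring the
observation that total PCB moles stay constant during dechlorination — and
the mean number of chlorines per biphenyl is non-increasing. A deterministic
linear ODE was chosen over stochastic simulation because reachable sets are
tiny and the emulated experiments report deterministic bulk extents;
measurement noise lives in the synthetic-data layer, not in the dynamics.

Time is in months (the emulated readouts are at 3 and 6 months) and the
default rate is 1.0 per month for every rule, times the rule weight. No rate
constants are published for these cultures; rates are free parameters and no
fit is claimed beyond qualitative endpoint agreement. Chlorine release is
the mean-chlorine drop times the mixture concentration: at the nominal 81 µM
(= 81 nmol PCB/mL), the published homolog table's drop of 6.39 → 5.59
chlorines per biphenyl corresponds to ≈ 64.5 nmol Cl/mL, within 1% of the
printed 64.23.

## The synthetic-data generator

`generateMixture()` emulates an Aroclor 1260 control: homolog marginals are
fixed exactly to the published control distribution (tri 0.07, tetra 0.21,
penta 9.63, hexa 47.75, hepta 36.26, octa 5.51, nona 0.57 mol%; no mono/di
detected), and the reported dominant congeners are placed inside their
homologs. The true congener-level composition of Aroclor 1260 is not part of
the emulated study's data, so within-homolog allocation is a documented
stand-in: the named dominants split a `dominantShare` of the homolog mass
evenly (default 0.70, matching the reported order of magnitude — the four
dominant hexa congeners carry ~72% of hexa-CB), and the remainder goes to a
seeded random subset of the homolog's other congeners (default 10 per
homolog, a realistic count of GC-resolvable congeners) with Dirichlet(1)
proportions. Homolog-level statistics are therefore exact by construction;
congener-level identities below the dominants are synthetic.

`generateDechlorinatedReplicates()` simulates forward, then adds seeded
zero-mean Gaussian noise at the congener level, scaled as SD_h/√m_h so the
homolog-level replicate SD matches the published triplicate SD column
(0.01–2.10 mol% depending on homolog), clips at zero and renormalizes to
100. Noise is applied post-simulation — it models measurement scatter, not
rate variability. Clipping and renormalization shrink the realized SD
somewhat; the tested contract is agreement within a factor of two.
`generateGrowthSeries()` completes the loop for growth-yield accounting:
cells/mL = yield × mol Cl removed × (1 + noise), so the noiseless round trip
through `growthYield()` is exact.

What passing tests on these data do and do not show: they validate the
arithmetic, the rule logic, conservation, and the classifier's ability to
recover a generating process under realistic homolog-scale noise (the
package's recovery experiment runs 100 seeds of mixture → 3-month Process-N
simulation → noisy replicate → classification and requires ≥95 correct,
unique identifications). They cannot validate congener-level composition
claims about real Aroclor 1260, GC co-elution artifacts, detector
calibration, or bioavailability effects — none of which the generator
emulates.

## Numerical and design choices

* Profile sums must be 100 ± 0.5 mol% on ingest (published table columns
  drift by rounding); renormalization happens only on explicit request.
* The 2 mol% change threshold is the default everywhere a loss/gain decision
  is made; it is a parameter, not a constant.
* Mass conservation in simulation is tested to 10⁻⁶, the single-rule decay
  against e^{−kt} to 10⁻⁹; tiny negative round-off from the matrix
  exponential (−10⁻¹² scale) is clamped to zero.
* Homolog-level profiles (pseudo-congeners like `"hexa-CB"`) are accepted by
  every marginal-level operation and rejected by structure-requiring ones
  (pathways, classification, simulation) with a clear error.
* Ranking ties in classification break by process name, and the tie is
  flagged; node ordering in pathway graphs is chlorine count descending,
  then name — both purely for determinism.
* Pathway closures and parsed names are memoized (keyed by rule-set content)
  purely as a cache; results are identical with a cold cache.
* Problem sizes in the shipped tests — 100 recovery seeds, 60 replicates for
  the SD check, 40 sampled starts for the generic-N terminal property — are
  the package's chosen balance between statistical resolution and a test
  suite that runs in well under a minute.

## Known limitations

* Only the four evidenced rule sets are built in; the remaining literature
  processes (M, Q, H′, P, LP) are named in the field but not specified by
  the evidence this package encodes, so they must be supplied as user TSV
  configs.
* The classifier scores single processes; it does not deconvolve mixtures of
  processes acting simultaneously (a culture whose pattern "could be a
  combination of H and T" is reported as a ranking, with interpretation left
  to the user).
* Kinetic rates are unidentified free parameters; simulations are for
  hypothesis exploration and synthetic-data generation, not rate inference.
* Growth-yield accounting is a unit formula; per-culture cell counts and
  chlorine removals exist in the emulated study only as figure points, so no
  numeric reproduction is attempted.
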