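---
title: "Individualized driver panels: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized driver panels: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science implemented by `oncopanels`: the model
behind each pipeline stage, its assumptions, the tunable parameters with
their defaults and units, what the synthetic-cohort generator does and does
not emulate, and the numerical and design choices that were genuinely open.

## The problem

A tumour carries tens to hundreds of somatic mutations, of which only a few
drive the disease; which few differs from patient to patient. Cohort-level
driver catalogues only help patients carrying frequent signature mutations.
The pipeline here instead asks, for one patient at a time: *which of this
patient's mutated genes sit upstream of this patient's expression
perturbations in the interaction network?* The answer is deliberately
short — a panel a clinician could act on — rather than a ranked list of
hundreds.

## Stage 1: expression-contextualized networks

The shared substrate is a directed gene–gene interaction network. For each
patient, every gene $i$ receives a node weight proportional to its
expression fold change,

$$\mathrm{NW}_i = \frac{A_i + c}{B_i + c},$$

with $A_i$ the tumour expression, $B_i$ the control expression and $c$ a
pseudocount (default 0.5) that keeps the ratio defined when $B_i = 0$. The
ratio is clamped to $[10^{-4}, 10^4]$ so no single extreme measurement can
dominate a path sum. Users who only have fold changes (the common case for
TCGA-style processed data) can supply $\mathrm{NW}_i = 2^{\log_2\!FC_i}$
directly; both entry points are exposed. Genes without expression data
default to the neutral $\mathrm{NW} = 1$, which keeps the network connected
without biasing path costs, and the defaulted fraction is recorded on the
result.

Each edge $(i, j)$ is then weighted

$$\mathrm{EW}_{i,j} = \frac{1}{\sqrt{\mathrm{NW}_i \times \mathrm{NW}_j}},$$

so traversing a pair of upregulated genes is cheap and a pair of
downregulated genes expensive. Note the asymmetry this implies: the cost
function *rewards* upregulation and *penalizes* downregulation, rather than
treating perturbation magnitude symmetrically. That asymmetry is the
model's definition of "activity flow" and is implemented exactly as
defined; a |log-fold|-symmetric variant would find down-regulated cascades
too, but would be a different model. When multiple matched controls exist
the control value is taken as their mean before the ratio.

## Stage 2: least-cost path mining (Mutpaths)

From every mutated gene, Dijkstra's algorithm computes one minimum-cost
path to every reachable node; the path cost is the sum of its edge weights.
"Path length" means the number of edges, and a path qualifies only if it
has at least `min_edges = 3` of them — shorter routes are trivial
neighbourhoods rather than cascades, and a two-edge bound would make the
constraint vacuous for any non-adjacent pair. When the overall cheapest
route for a pair has fewer than three edges the pair is simply not
emitted; we do not substitute a costlier constrained route, because the
mined object is "the shortest path, if it is long enough", not "the
shortest long path".

Determinism matters for reproducible panels, so ties are fixed twice over:
the node popped among equal distances is the lexicographically smallest,
and among equal-cost relaxations the lexicographically smallest predecessor
is kept. The mined path (not just its cost) is therefore a deterministic
function of the inputs.

All candidate paths are ranked by ascending cost and the top
`percentile = 1e-4` (0.01%) retained, with two guards:

* a floor of `min_paths = 10` retained paths, without which small networks
  would yield empty subnetworks (the percentile of a few thousand candidate
  paths rounds to one);
* a single retry at `fallback_percentile = 2e-4` when the retained set
  contains no DEGs or the later coverage target cannot be attained —
  the remediation for patients with few perturbed genes.

The retained paths' union is the patient's *Mutpaths* subnetwork. The
percentile is applied per patient over that patient's own candidate set,
and over all (source, sink) pairs, not only DEG-terminated ones.

## Stage 3: driver panels by greedy set cover (iPanels)

Within the Mutpaths union graph, the DEG universe is the set of DEGs
(called at `|log2FC| >= 1` and `FDR <= 0.05`, boundaries inclusive) that
appear as nodes. Each mutated gene in the subnetwork is scored by

$$\mathrm{Netscore} = \sum_{n=1}^{4} \frac{\#\{\text{DEGs first reached at distance } n\}}{n},$$

a distance-discounted influence count with disjoint strata (a DEG counts
once, at its minimum distance). Reachability is computed inside the union
graph, not the full network: the scoring question is "how much of *this
patient's top-perturbed subnetwork* does this mutation command", and the
same choice is exposed as a configuration switch for users who prefer
full-network reach.

The panel is built greedily: candidates are pre-ranked by Netscore, and at
each step the candidate covering the most not-yet-covered universe DEGs is
added (ties by higher Netscore, then lexicographic symbol), stopping at
`coverage_target = 0.70` or when no candidate adds coverage. The greedy
gain is the raw DEG count — the cover problem is about coverage, while the
Netscore is kept for ranking and ties. When 70% is unattainable, the
exhausted panel is returned with `attained = FALSE` rather than an error,
and the pipeline retries once with the fallback percentile. The classic
$(\ln|U| + 1)$ approximation guarantee of greedy cover is checked
empirically against exhaustive subset search in the test suite.

## Stage 4: hazards and the risk score (PiRS)

Per-gene hazard ratios are estimated by Cox proportional-hazards fits with
a binary covariate: membership of the gene in the patient's panel (the
default; gene-mutated is the alternative switch). Panel membership is used
because the risk score consumes panel genes. A joint fit over all panel
genes is available and used per-gene when it converges with finite,
well-conditioned estimates; rare genes routinely break joint fits, so the
univariate fit is the fallback. Degenerate designs (no events, single-level
indicator) yield an explicitly flagged undefined hazard; undefined hazards
are *dropped* from the score with a warning, never imputed at 1, so a
patient's score reflects only estimable components.

The patient score is

$$\mathrm{PiRS} = \sum_{a \in \text{panel}} \mathrm{Netscore}_a \times \mathrm{HR}_a,$$

nonnegative, linear in both factors, and zero only for an empty or fully
undefined panel. The cohort is split into PiRS-low/PiRS-high by scanning
cutoffs at the score percentiles 10–90% (step 5), keeping splits with at
least 10% of the cohort per group, and choosing the minimum log-rank
p-value (ties resolved toward the median cutoff). Scanning minimizes over a
grid, which makes the reported minimum optimistic; the scan therefore also
reports a permutation-adjusted p (`n_perm` re-scans of permuted scores)
quantifying that multiplicity. Cutoff selection depends only on the induced
group memberships, so it is invariant under strictly monotone transforms of
the scores. Cox fitting, the log-rank statistic and Kaplan–Meier curves are
delegated to the `survival` package; the score, scan and adjustment are
package code.

## Cohort aggregation and benchmarking

Per-patient panels, in greedy pick order, are ballots. Genes absent from a
ballot are treated as tied below all listed genes — panels are truncated
ballots, and tied-last is the standard truncated-ballot completion. The
pairwise-preference matrix is aggregated with the Schulze method (strongest
beatpaths), a complete Condorcet-consistent rule: any gene beating every
other in pairwise majorities is provably ranked first, and majority cycles
resolve deterministically and are flagged. Copeland is available as an
alternative since Condorcet-consistent rules can differ when no Condorcet
winner exists. Rankings are benchmarked against a user-supplied
gold-standard list by top-*k* precision, recall and F1 (default `k = 20`),
and panel genes present in strictly fewer than 2% of patients are flagged
as rare drivers.

## Actionability rules

Panel genes first pass an expression triage: only genes perturbed more than
2-fold (`|log2FC| > 1`, strict) are paired, applied *before* drug pairing;
genes with missing expression are kept but direction-unknown and therefore
receive no recommendation. The pairing matrix has exactly two determinate
cells: upregulated oncogene → inhibitor-mode drugs; tumour suppressor (up-
or downregulated) → activator-mode drugs. A downregulated oncogene, or any
unknown role, is classified undetermined — the matrix defines only those
two rules, and inventing a third would be a modelling claim, not an
implementation choice. A gene matching a rule but lacking a drug of the
recommended mode is reported actionable-without-matched-drug. Role and drug
tables are user-supplied TSVs: the curated oncogene/TSG and drug-mode
databases they stand for are licensed, versioned externals, and a small
synthetic reference (clearly labelled as such) ships for tests.

For patients whose panel genes are not targetable, the analysis extends to
the DEGs within four directed hops downstream of any panel gene in the
Mutpaths union graph (excluding panel genes, so the two tiers are disjoint
per patient), each classified by its own expression direction — the
extended (iActE) tier.

## The synthetic cohort generator

The generator emulates the input *structure* of a tumour cohort analysis:
a directed network with heavy-tailed out-degree (lognormal out-degrees,
lognormal target attractiveness, giant weak component re-attached if
needed), sparse per-patient mutation lists (1–2 planted drivers plus 5
passengers), fold-change vectors with driver-downstream cascades, and
exponentially distributed, independently censored survival times whose
log-hazard is a baseline plus a per-driver increment.

Design points that make the ground truth recoverable *and verifiable*:

* **Cascades run along existing network edges** (no injected edges), so the
  path miner has genuine routes to find. Cascade genes get
  `log2fc ~ N(effect = 2, sd = 0.25)` with FDR 0.001; background genes get
  `N(0, 0.25)` with FDR 0.5, so the DEG filter separates them exactly. FDRs
  are assigned, not simulated from counts — differential-expression
  estimation is upstream tooling, out of scope.
* **Two-tier cascades.** A driver upregulates all its downstream genes
  within two hops (capped at `n_cascade = 40`) plus `n_deep = 5` genes at
  exactly three hops. The deep tier mimics the limited deep propagation of
  signalling cascades and bounds each driver's supply of all-cascade
  least-cost paths at roughly five, so the retained path set — ten paths at
  the reference scale — samples every planted driver instead of being
  monopolized by whichever driver's shared upstream edges drew slightly
  cheaper noise.
* **Disjoint driver regions.** When a patient carries two drivers, the
  second is planted outside the first's downstream region. Overlapping
  cascades let one driver's cheap paths run through the other's upregulated
  territory and cover its DEGs, which silently collapses the recoverable
  ground truth to a single driver.
* **Determinism.** Every level (network, patient, cohort, annotation
  tables) is a pure function of the spec's seed.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: measurement noise correlated along the network,
copy-number events, expression changes not caused by any mutation,
incomplete or false interaction edges, hazards that violate
proportionality, and informative censoring. Results on real cohorts depend
on the quality of the supplied network and expression contrasts in ways the
synthetic tests cannot certify.

## Problem sizes and numerical choices

The reference conditions used throughout the tests and the acceptance
script are a 200-gene network (mean out-degree 3), 50 patients, 1–2 planted
drivers each with their cascades reaching at least 70% of their DEGs within
four hops, 5 passengers, 30% censoring, and a per-driver log-hazard of
log 2. Property checks run on deliberately tiny instances where exhaustive
enumeration is the oracle: weighted digraphs of at most 12 nodes for path
mining, at most 15 candidate sets for the cover bound, at most 6 genes for
Condorcet profiles. These sizes make brute force exact and fast; the
algorithms themselves have no size-dependent branches, so correctness at
oracle scale transfers.

Numerical details worth knowing: path-cost comparisons use exact floating
equality for tie detection (identical arithmetic on identical inputs, hence
reproducible); the Mutpaths retention count is
`max(min_paths, ceiling(percentile × #candidates))` with ties at the
cutoff resolved by the deterministic (cost, source, sink) order, so the
retained set is always a prefix and its size exact; Wald confidence
intervals are reported for hazard ratios; and empty DEG universes, empty
panels, all-censored cohorts and constant scores all produce explicit
flags or errors rather than silent numbers.

## Known limitations

The two-rule actionability matrix cannot recommend anything for
downregulated oncogenes or unknown roles; variant-level drug matching,
resistance modelling and trial-phase triage are out of scope. The Cox
stage assumes proportional hazards with no covariate adjustment (age,
stage) and no competing risks. Gene identity is by case-sensitive symbol
with no alias resolution. The Condorcet output can depend on the chosen
rule when no Condorcet winner exists; the method used is stamped into the
output for that reason.
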