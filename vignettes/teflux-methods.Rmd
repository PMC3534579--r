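---
title: "Methods: estimating the metabolic impact of somatic retrotransposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating the metabolic impact of somatic retrotransposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the model

Somatic retrotransposition is unusually active in the mammalian brain:
L1 elements (and the Alu/SVA elements that borrow the L1 machinery)
insert into new genomic locations in individual neurons. An intronic
L1 insertion in sense orientation can reduce the host gene's
expression roughly 70-fold. `teflux` asks what such knockdowns do to
the metabolic capabilities of the cell: which metabolites can no
longer be synthesised at their full rate when an insertion-hit enzyme
gene is turned far down?

The analysis is constraint-based. A genome-scale metabolic
reconstruction supplies a stoichiometric matrix $S$, flux bounds
$lb \le v \le ub$, and gene–protein–reaction (GPR) boolean rules. At
steady state $S v = 0$ over the non-boundary metabolites (boundary
species stand for the environment and are exempt). The maximal
biosynthesis rate of metabolite $i$ is the flux-balance optimum

$$\max v_{e_i} \quad \text{s.t.}\quad S v = 0,\; lb \le v \le ub,$$

where $e_i$ is a single-metabolite export ("production objective")
consuming one unit of $i$ (`addProductionObjective()`, `fba()`,
`maxProduction()`).

## The knockdown procedure

For each insertion-hit gene:

1. **Isozyme screen** (`classifyGene()`). Every reaction's GPR is
   evaluated with the gene set to absent and all other genes present.
   Reactions whose rule turns false are *falsified*. A gene that
   falsifies nothing is *buffered* — an isozyme (OR-branch) or
   redundant complex covers for it — and can have no metabolic effect.
2. **Capacity reduction** (`applyKnockdown()`). Expression is coupled
   to flux linearly: a $f$-fold expression drop caps each falsified
   reaction's flux at $1/f$ of its attainable range. The attainable
   range is the flux-variability envelope `fva()` computed under the
   production objective currently being scored, so the cap reflects
   what the reaction could actually carry in that context rather than
   the nominal bounds (a `boundsMode = "raw"` switch uses raw bounds
   instead). Reversible reactions are scaled on both sides; the
   scaled interval is clipped to the correct sign side and intersected
   with the original bounds.
3. **Impact call** (`geneImpact()`). For every non-boundary metabolite
   with baseline production above `productionFloor`, the maximal
   production is recomputed under the knockdown. The metabolite is
   *affected* when the relative drop exceeds `dropThreshold`.

`scanInsertions()` runs this screen over a multi-donor insertion
table, pooling and per donor, and reports the count partitions (hit
genes = buffered + effective; effective = no-impact + impact),
distinct affected metabolites on compartment-stripped keys (the same
compound in cytosol and mitochondrion counts once), and donor
overlaps. Genes are perturbed one at a time — single insertions per
cell are assumed, synergies between insertions are out of scope.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `foldReduction` | 70 | expression/flux reduction of a sense-oriented intronic insertion (dimensionless fold) |
| `dropThreshold` | 1e-6 | relative production drop below which a change is treated as LP noise |
| `productionFloor` | 1e-9 | baseline production (flux units) below which a metabolite is considered not producible |
| `optimalityFraction` | 0 | fraction of the production optimum enforced during FVA; 0 ranges the whole reachable flux space, which matches using FVA to establish per-reaction flux boundaries |
| `maxMismatch` | 1 | Hamming distance allowed in the TTAAAA target-site scan |
| `samples` (N) | 100000 | Monte Carlo redistributions of the insertion set |

The conclusions of the screen are qualitative in the fold: any large
`foldReduction` identifies the same affected metabolite *sets*; the
fold only scales the residual rates.

## The target-site null model

Counting disease-linked metabolites among the affected set is
confounded by a mass effect: enough insertions anywhere will touch
something disease-linked. The null model redistributes the observed
number of insertions uniformly across the L1 endonuclease target
sites of the model's genes — TTAAAA hexamers and, because L1 target
specificity is loose, any hexamer within one mismatch, on both strands
(`scanTargetSites()`, reverse-strand sites appear as forward TTTTAA
matches; `N` counts as a mismatch). Insertions are drawn with
replacement (a without-replacement switch exists; with insertions
vastly outnumbered by sites the difference is negligible), so a
gene's null weight is proportional to its target-site count.

Each of the $N$ random samples is scored exactly like the observed
data: the union of affected-metabolite sets over the sampled genes (a
gene hit twice contributes once), intersected per disease with the
disease's metabolite set. All diseases are scored on the same sample
stream, mirroring the shared-sample design of the screen. The
one-sided empirical p-value is

$$p = \frac{n + 1}{N + 1},$$

with $n$ the number of samples whose statistic reaches the observed
one; $p$ is never zero and its minimum is $1/(N+1)$.

Disease maps are supplied as TSV (`disease`, `metabolite_key`);
matching between model metabolites and map entries is name-based on
case-folded, compartment-stripped keys, with an optional user synonym
table — the mapping between a reconstruction's namespace and a
metabolome database is not canonical, and reproduction of any specific
published disease table depends on the map and sequence set supplied.

## What the synthetic data emulate

`makeToyNetwork()` builds independent linear chains with unit
stoichiometry and capacity 10 throughout, so every optimum is
hand-computable: each internal conversion carries a sole-gene,
isozyme-pair (OR) or complex-pair (AND) rule, and the metabolites
truly affected by a gene are exactly those downstream of its reaction.
`makeGeneSequences()` plants exact target sites into backgrounds
repaired to contain no within-mismatch windows, making site counts
deterministic. `makeInsertions()` tilts insertions toward effective
genes by a bias parameter (0 = null, 1 = effective-only);
`makeDiseaseMap()` draws random disease sets and can plant one disease
from the truly-affected pool. Everything is seed-reproducible.

These toys deliberately lack features of real data: no branched or
cyclic pathway topology beyond parallel routes, no cofactor coupling,
no realistic gene structure (the supplied FASTA defines each gene's
extent — whether that includes introns and UTRs is the user's choice
and materially changes site counts), and no insertion-site preference
beyond the hexamer. Passing tests therefore demonstrate correctness
of the machinery, not biological fidelity of any particular genome-
scale result.

## Numerical and design choices

* **LP solver.** The package carries a two-phase tableau simplex with
  Bland's anti-cycling rule. Bland's rule is slow but terminates on
  the degenerate LPs that steady-state networks produce; at
  desk-scale problem sizes (tens of variables) robustness is worth
  far more than speed. Fluxes are shifted to nonnegative variables;
  redundant equality rows are removed by QR rank reduction (with a
  consistency check) before solving. Solver feasibility is asserted
  to $\|Sv\|_\infty \le 10^{-6}$; all bounds are required finite
  (defaults $\pm 1000$, the COBRA convention), so objectives are
  never unbounded.
* **Alternate optima.** Only objective values, never individual flux
  vectors, feed downstream decisions; flux vectors at degenerate
  optima are not unique.
* **FVA envelopes** depend only on the model and the metabolite
  objective, never on the donor, so they are shared across donors and
  across genes within one metabolite objective.
* **Boundary detection** accepts both the SBML `boundaryCondition`
  attribute and the compartment-suffix convention (compartment token
  `b`) used by genome-scale human reconstructions; GPRs are read from
  `fbc:geneProductAssociation` or legacy `GENE_ASSOCIATION:` notes.
  Reactions without bounds default to $[-1000, 1000]$ if reversible,
  $[0, 1000]$ otherwise, with a warning.
* **Site positions** are reported 1-based, the R/Bioconductor
  convention.

## Calibration and power of the enrichment test

The empirical p-value $(n+1)/(N+1)$ is exactly valid but
*conservative on coarse statistics*: when the affected-metabolite
count takes few values, ties inflate $n$ and the p-value distribution
under the null is stochastically larger than uniform. This is a
property of empirical p-values on discrete statistics, not a defect,
but it means a uniformity check must be run where the statistic is
rich. The package's calibration study therefore uses a genome-like
synthetic model — 100 chains of 12 metabolites (~1800 genes), two
planted target sites per gene, 400 insertions per replicate, disease
sets covering 25–55% of the 1200 metabolite keys, N = 500 samples,
500 replicates — where the statistic's within-condition spread (SD
≈ 15) makes the discreteness bias negligible. At this scale the
gene-to-affected-metabolite lookup is the generator's analytic truth;
its agreement with the LP pipeline is established separately by the
end-to-end toy-preset test, which recovers the planted effective-gene
set and gene-to-metabolite map exactly. The power study uses the same
model with effective-only insertions and a disease planted from the
truly-affected pool.

Problem sizes throughout the tests — random LP networks of up to six
reactions against a basic-feasible-solution enumeration oracle, 1 kb
sequences against a window-by-window Hamming oracle, the toy preset
for end-to-end runs — were chosen so each check completes in seconds
to a few minutes while still exercising every code path.

## Known limitations

* Genome-scale FVA (thousands of metabolite objectives on a model
  with thousands of reactions) is beyond the pure-R simplex; the
  per-metabolite loop is trivially parallelisable and the design
  caches envelopes per objective, but a compiled LP backend would be
  needed for routine genome-scale runs.
* No MILP, loopless FVA, thermodynamic constraints or quadratic
  objectives; no biomass-objective handling or model curation.
* Whether genes whose reactions are blocked under every objective
  should count as "no impact" is reported as-is (they appear as
  effective genes without impact); no separate blocked-gene category
  is split out.
* Mapping genomic insertion coordinates to genes, and
  downloading/parsing external model, sequence or disease resources,
  are out of scope: inputs arrive as SBML, FASTA and TSV.
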