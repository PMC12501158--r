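---
title: "Methods: quantifying predation screens, bottlenecks, and phase variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying predation screens, bottlenecks, and phase variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predscreen)
```

# The problem

A pooled transposon mutant library of a bacterium is exposed to a
phagocytic predator. Mutants that resist predation — for instance by
filamenting beyond the predator's ingestion size — rise in frequency;
everything else is eaten. Sequencing insertion sites before and after
predation turns this into a genome-wide resistance screen. The
complication is that predation removes far more than 99 % of cells, so
the screen runs through a drastic population bottleneck: lineage
frequencies after selection carry enormous sampling variance, many
lineages vanish outright, and a neutral lineage can end up strongly
"enriched" simply because a few of its cells happened to survive (a
jackpot event). Any honest analysis has to model that bottleneck
alongside the selection signal. This package implements the analysis
chain and a synthetic-data generator that reproduces the statistical
structure the chain assumes, with ground truth recorded for every
stochastic input.

# Quantification model

Insertion counts arrive as single-chromosome wig tracks (1-based,
`fixedStep` or `variableStep`). Counts are aggregated in two ways:

* **Windows**: non-overlapping 200 bp tiles anchored at position 1,
  the last window truncated at the chromosome end. 200 bp is below the
  length of most bacterial CDSs while spanning a typical intergenic
  region, so windows give sub-gene resolution without splitting most
  regulatory gaps. No wrap-around window is created for circular
  chromosomes; the terminal window is simply short.
* **Features**: annotated CDS spans, counted in full (no 3′
  trimming). Insertions inside overlapping features are counted once
  per feature — documented double counting rather than an arbitrary
  assignment — and insertions outside every feature are reported under
  per-gap `intergenic:` rows, so totals are conserved whenever the
  annotation does not overlap.

Samples are made comparable by scaling each column to an equal total
(counts per million). Nothing in the downstream chain depends on the
choice of total; ranks and fold changes are invariant to a global
rescaling. Low-coverage rows are then excluded: a row whose mean count
across the *starting-population* samples is below `fraction` (default
0.05) of the median input mean is moved to the matrix's excluded set.
The median is computed over rows with a nonzero input mean — a median
over all rows can be zero in sparse libraries, which would disable the
rule; with this convention all never-inserted rows are excluded for
any positive `fraction`, and raising `fraction` is monotone (it never
un-excludes).

# Enrichment calls

For predation columns $P$ and control columns $C$ of a normalized
matrix, each row gets

$$\mathrm{log_2FC} = \log_2 \frac{\bar x_P + c}{\bar x_C + c},$$

with pseudocount $c = 1$ CPM by default. The pseudocount keeps rows
that bottlenecked to zero finite while leaving large fold changes
essentially untouched; setting $c = 0$ restores exact antisymmetry
under group swap and exact scale invariance (both are tested).
Ranking uses the fold change of replicate means rather than the mean
of per-replicate fold changes: after a severe bottleneck individual
replicates contain many zeros, and the mean-of-ratios is dominated by
the pseudocount in exactly the replicates that carry no information.

Because jackpot survivors make any fixed log2FC threshold unreliable
under a severe bottleneck, calls are restricted to the most-enriched
quantile (default the top 1 %): exactly $\lceil q\,n \rceil$ rows,
boundary ties broken by row order so the flag set is deterministic.
The companion `jackpot_risk()` quantifies what the quantile is
protecting against: the Monte-Carlo probability, under a neutral
bottleneck at each grid survival value, that a lineage's log2FC
exceeds a threshold by chance. A cross-module test checks that neutral
screens exceed a fixed threshold at the rate this function predicts.

Sample structure is summarized by PCA of samples with rows as
variables, centered per row, after a `log2(x + 1)` transform by
default (count matrices are heavy-tailed; without the transform the
first component simply tracks the few largest windows).

# Bottleneck model and survival bracketing

The generative model for a screen passing through predation is:

1. allocate `population_size` cells to lineages proportional to the
   empirical input counts (largest-remainder rounding, so totals are
   exact and the allocation is deterministic);
2. each cell survives independently with probability $s$ — binomial
   survival per lineage;
3. survivors are resampled multinomially to `recovery_depth` reads.

Step 3 treats recovery growth plus sequencing as unbiased proportional
amplification. That is an assumption, not a theorem: it is appropriate
when control samples that skip predation show essentially unchanged
abundance distributions, and it fails if recovery growth itself
selects. Step 2 ignores cell-to-cell correlation in survival (e.g.
cells inside one aggregate dying together); correlated survival makes
the effective bottleneck harsher than the nominal $s$.

Depletion is summarized by the fraction of input rows with zero output
counts, plus the Spearman correlation of surviving rows with the
input. Both are computable on real count matrices and both are
monotone in bottleneck severity; the fraction lost has a useful
closed-form check — for a lineage with $m$ cells,
$P(\text{lost}) = (1-s)^m \approx e^{-sm}$ — which the simulation must
reproduce within Monte-Carlo error (tested at $sm = 0.1$ on
$10^4$ uniform lineages).

`estimate_survival_range()` compares the observed fraction lost
(averaged over replicates) with simulated distributions on a decade
grid of survival values, $10^{-1}\dots10^{-5}$ by default — decade
steps because the answer is reported as a decade bracket of the
consumed fraction. The rule: if the observation falls inside a grid
point's central 50 % simulated interval, the bracket is that point's
flanking grid values; otherwise it is the two adjacent grid survivals
whose median losses straddle the observation. Observations outside the
simulated range return an open bound, flagged rather than
extrapolated, and a non-monotone median depletion across the grid is
an error (it diagnoses an ensemble too small or a grid too wide to
order). The bracket is reported on the consumed scale, e.g. survival
in $(10^{-3}, 10^{-2})$ reads "between 99 and 99.9 % of cells are
consumed".

Two regimes are worth distinguishing. When the true survival lies
strictly between decades, the median-straddle rule recovers the
enclosing decade stably. When it sits exactly on a grid point, the
observation falls on either side of that point's median with roughly
equal probability, so the one-decade bracket legitimately flips
between the two adjacent decades — the bracket still contains the
truth (containment is checked inclusively), but its endpoints are not
seed-stable. The acceptance script therefore reports the decade
bracket from a screen generated at survival $3\times10^{-3}$
(mid-decade) and the containment rate from 50 screens at $10^{-3}$
(on-grid). No likelihood or ABC machinery is attempted: with one
scalar summary and a decade grid, bracketing is the resolution the
data support.

# Phase-variation calling

Slipped-strand mispairing gains or loses repeat units in homopolymer
tracts at rates orders of magnitude above the point-mutation rate; a
±1 bp change inside a CDS shifts the reading frame and usually
truncates the protein — a reversible genetic switch. The scanner
reports all maximal single-base runs of length ≥ `min_run` (default
8 nt, the conventional threshold above which slippage becomes
frequent; any base, with an optional base filter since polyadenine is
the canonical case).

In each ortholog the reference run is located by its exact 12 bp
flanking anchors rather than by alignment: each anchor must occur
exactly once and in order, the run length is the distance between
them, and the spanned region must be pure repeat base. Twelve bases
make a random double hit vanishingly unlikely at within-species
identity, and any corruption — a substitution in the anchor, a
rearrangement, a duplicated context — yields `unalignable`, which
removes the ortholog from denominators instead of guessing. This is a
deliberate trade: anchors are deterministic and exact at high
identity, and degrade by refusing to call, never by miscalling.

A call is *frameshifted* when the length change is not divisible by 3,
and *inactivating* when additionally the ortholog's first in-frame
stop codon lies before `stop_cutoff` (default 0.9) of the reference
protein length. The cutoff operationalizes "premature": a stop in the
last few percent of a protein rarely abolishes function, and 0.9 is
exposed as a parameter rather than buried. In-frame length changes are
never inactivating regardless of downstream sequence (tested
property). Per gene, the reported fraction is inactivated over
alignable orthologs; genes with no qualifying run are excluded rather
than reported as zeros, and the top 5 % of genes by fraction are
flagged with deterministic (locus-tag) tie-breaking.

# Phenotype statistics

**Filament threshold.** "Filamentous" means longer than twice the
single-cell mean, but the single-cell mean depends on which cells are
single — a circular definition. It is resolved as a fixed point:
$t_0 = 2\,\mathrm{median}(\ell)$, then
$t_{k+1} = 2\,\mathrm{mean}\{\ell \le t_k\}$ until the change is below
$10^{-6}$ µm (error, with the trace, after 100 iterations). The median
start is robust to the filament tail; on a clearly bimodal length
distribution the iteration converges in a handful of steps, and
appending cells above the converged threshold does not move it. The
mean can also be supplied directly (`mean_single = 4.96` gives
threshold 9.92 µm) to reproduce a published classification exactly.
Volume fractions treat cells as constant-width rods (volume ∝ length),
which is adequate for ratios in a bacterium whose width does not vary
with length.

**Rank-sum test.** Delegated to `stats::wilcox.test` (exact for small
tie-free samples, tie-corrected normal approximation otherwise), but
reported with *both* statistic conventions — Mann–Whitney $U$ of the
first group and the rank-sum $W = U + n_1(n_1+1)/2$ — because
published W values are ambiguous between software. Tests verify
agreement with an exhaustive permutation oracle for all group sizes up
to 8.

**Competition assays.** Mutant frequency is mutant events over total
events; inference is a one-sample t test of per-replicate frequencies
against the starting frequency (default 0.1 for a 10 % inoculum), and
of log(frequency/initial) against 0 — the log form weighs relative
changes symmetrically. Zero replicate variance reports a missing
p-value (with $t = 0$ when the mean equals the null) rather than a
fabricated one; the type-I error of the frequency test is verified at
the nominal 5 % over $10^4$ null simulations.

# What the synthetic generator emulates — and what it does not

The generator reproduces the statistical structure the analysis
assumes: log-normal lineage abundances over uniformly placed insertion
sites (`abundance_sigma = 1` by default, a realistic spread for a
passaged pool, and the heavy tail that makes jackpots visible);
binomial survival with a capped multiplicative advantage for planted
resistant sites; multinomial sequencing; genomes with log-normal CDS
(median 744 bp) and intergenic (median 115 bp) lengths matching a
typical *B. subtilis*-like chromosome; planted in-frame poly-A 9-mers
positioned so a −1 slip stops translation early; and bimodal
zero-truncated-normal cell lengths (single cells 4.96 ± 1.2 µm,
filaments 20 ± 8 µm by default).

Deliberate simplifications: essential genes are insertion-free zones
only (no fitness gradient); recovery growth is fitness-neutral;
survival is uncorrelated across cells; random sequence is generated
*free of accidental homopolymer runs ≥ 8 nt* so that planted repeat
genes are exact ground truth — real genomes of course contain such
runs, which is the point of scanning them. Passing recovery tests
therefore demonstrate that the methods are correct under their own
model, not that the model captures every property of real screens —
in particular replicate correlation induced by shared predation
micro-environments, and strand- or sequence-biased transposon
insertion, are not emulated.

# Numerical choices and problem sizes

Largest-remainder rounding is used wherever proportions must become
integers with an exact total (library scaling, cell allocation), with
ties broken by index so results are deterministic. Every generator
takes an explicit seed and restores the RNG state afterwards
(`withr::with_seed`); the pipeline derives one seed per stage from the
global seed and stage name. Test and acceptance problem sizes were
chosen as the smallest at which the targeted effects are clearly
resolved: $10^4$ sites and $10^6$ cells/reads for screen-scale checks
(expected 0.1 survivors per uniform lineage at $s = 10^{-3}$), 10–20
simulations per grid point for bracketing, 50 seeded screens for the
recovery rate, 400 strains for planted pangenome fractions, and
$10^4$ simulations for test calibration.

# Known limitations

* The survival bracket is only as fine as its grid, by design; users
  needing a point estimate should fit their own likelihood on top of
  `simulate_expected_counts()`.
* Anchor-based repeat localization refuses divergent orthologs
  (reported as `n_unalignable`) — at below ~95 % identity an
  alignment-based caller would recover more of them.
* `filter_low_coverage()` presumes the starting-population samples are
  identified correctly; filtering on post-selection samples would
  remove genuinely depleted (i.e. informative) rows.
* The enrichment module makes no multiple-testing-corrected
  significance claims; the top-quantile rule plus jackpot risk is a
  screening heuristic whose hits need targeted validation.
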