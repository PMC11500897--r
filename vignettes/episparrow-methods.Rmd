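---
title: "Detecting higher-order epistasis with a multi-objective sparrow search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting higher-order epistasis with a multi-objective sparrow search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episparrow)
```

## The problem

Complex diseases are shaped by joint effects of several loci — epistasis —
that single-SNP association scans cannot see. In a case-control GWAS panel
with $N$ SNPs coded 0/1/2 (minor-allele counts) and a binary phenotype,
exhaustive testing of all $\binom{N}{k}$ combinations is infeasible beyond
$k = 2$ on anything but tiny panels, and penalised regression struggles when
the interacting SNPs carry no marginal signal at all. `episparrow` searches
the combination space with a swarm heuristic patterned on the sparrow search
algorithm: a population of candidate SNP combinations ("sparrows") evolves
under three complementary association objectives, promising candidates are
purified and tested, and a final ratio filter strips weak tail findings.

## Candidate representation and automatic sizing

A sparrow is a vector of `mo` distinct SNP indices — `mo` is the *maximum
epistasis order*. True interactions of any order from 2 to `mo` are
recovered from these fixed-length vectors by the noise-elimination step, so
the user never pre-commits to an interaction order. By default

$$\texttt{mo} = \lfloor \ln(\min(m_0, m_1)) - 0.5 \rfloor,$$

with $m_0$ controls and $m_1$ cases, which keeps the average sample count
per genotype combination of an `mo`-SNP set near $e$; for the standard
$800+800$ benchmark panels this gives `mo = 6`.

## Three objectives on a truncated contingency table

Each candidate set $X$ is scored against the phenotype $Y$ through its
genotype contingency table, with three objectives, all minimised:

* **K2** — the negative log of the Cooper–Herskovits Bayesian score; for a
  binary phenotype each observed genotype cell with $m_x$ samples split
  $m_{x0}/m_{x1}$ contributes
  $\ln((m_x+1)!) - \ln(m_{x0}!) - \ln(m_{x1}!)$. All factorials are
  evaluated in log-gamma space (as table lookups over integer counts), so
  scores stay finite at any realistic sample size.
* **CE** — the conditional entropy $H(Y \mid X)$ in nats: 0 when the
  genotype determines the phenotype, $\ln 2$ under independence with
  balanced classes.
* **Gini** — the expected Gini impurity of $Y$ within genotype cells, in
  $[0, 0.5]$ for a binary phenotype.

All three are biased downward on long tables: a high-order random
combination scatters the samples over hundreds of cells, most of which look
spuriously pure. The *table-length truncation* caps the number of
contributing cells at

$$\texttt{ml} = \lfloor \min(m_0, m_1) / 10 \rfloor$$

(80 for $800+800$): when more cells are observed, the `ml − 1` cells with
the largest per-objective contribution — the weak-evidence cells, whose raw
K2 factors are the *smallest* — are kept individually and all remaining
cells are pooled into one aggregate cell. Pooling the many small,
chance-pure cells restores the evidence they hid, so sparrows whose
observed tables happen to be long no longer outrank sparrows of the same
order with shorter tables. (The spuriously strong cells are pooled, not the
weak ones: pooling weak cells was tried and measurably preserves the length
bias.) Each objective ranks cells by its own contribution, so the retained
sets may differ between objectives. Truncation applies to the three
population objectives only — not to the noise-elimination descent or the
G-test, for reasons given below.

## Rank-sum aggregation

Raw objective values are never mixed. Within the population each member is
ranked separately by K2, CE and Gini (competition ranking, lowest score =
rank 1) and the ranks are summed. The population is kept sorted by
`(rank_sum, k2, insertion counter)` — the raw K2 breaks rank ties, mirroring
its privileged role in noise elimination, and the insertion counter makes
every run reproducible. Ranks are recomputed over the full population after
every insertion or removal; the aggregation is invariant under any strictly
increasing transform of an objective column, so only orderings matter.

## The search loop

With population size $n$ (producer fraction `pd = 0.4`, scout fraction
`sd = 0.2`, safety threshold `st = 0.8`), one iteration performs:

1. **Producers** (the top $\lfloor pd \cdot n \rfloor$ members): one uniform
   draw $r$ per pass; if $r < st$ each producer proposes a mutant with one
   position replaced by a random SNP, otherwise with
   $\lfloor mo/2 \rfloor$ positions replaced. Every proposal is inserted,
   ranks recomputed, and the worse of incumbent and proposal removed.
2. **Scroungers** (the rest): members in the better half cross with a
   randomly chosen producer (half the indices from each, duplicates redrawn
   from the parents' union); the bottom half draw fresh vectors with
   probability proportional to the per-SNP weight vector `pss`.
3. **Scouts**: $\lfloor n \cdot sd \rfloor$ members are picked at random;
   scouts derived from the population best (or from members no producer
   strictly beats) are fresh `pss` draws, the others cross with a strictly
   better producer. All scouts are added, enlarging the population.
4. **Detection**: the top $\lfloor n \cdot sd \rfloor$ members are purified
   by K2 backward elimination (below) and gated by a G-test.
5. **Trimming**: the population returns to size $n$. The diversity
   statistic `spasChaos` — distinct SNPs present divided by
   $\min(n \cdot mo, N)$ — decides which end is cut: below the threshold
   (default 0.6) the population has converged on few SNPs, a local optimum
   is declared and the *best* members are removed; otherwise the worst. The
   denominator is capped at $N$ because a population can never show more
   distinct SNPs than the panel contains; on a 100-SNP panel with
   $n \cdot mo = 120$ slots the uncapped statistic could never reach 0.6
   and every iteration would read as converged.

All randomness flows from one seeded generator in a fixed call order, so a
run is a pure function of (dataset, seed).

## Noise elimination, G-test gate and the pss vector

A top-ranked 6-SNP vector typically contains a true interaction plus
hitch-hiking noise. Backward elimination strips it by greedy steepest
descent on the *raw* (untruncated) K2: score every single-SNP removal; if
the best removal does not increase K2, commit it (ties go to the lowest
SNP index) and repeat; stop when every removal strictly increases K2 or
one SNP remains. The stopping rule rests on an asymmetry of the raw score:
dropping an uninformative SNP merges cells threefold and can only lower
K2, while dropping a signal SNP destroys the class-separating partition
and raises it by far more than the cell-count saving. The truncated score
must *not* be used here — it is length-neutral by construction, which
leaves the stopping rule undecided on noise; measured on phenotype-permuted
panels, truncated-K2 descent stalls roughly a third of random 6-SNP
vectors at full length (flooding the store with false records at ~6x the
nominal rate), whereas raw-K2 descent strips them to single SNPs and keeps
the per-sparrow record rate at or below the significance threshold.

Purified sets of size ≥ 2 are tested for independence against the phenotype
with the likelihood-ratio G-test, $G = 2\sum O \ln(O/E)$ over observed
genotype combinations (no truncation is applied here). The gate charges a
$k$-SNP set for its *complete* genotype space, $(3^k - 1) \times 1$ degrees
of freedom: an overfit high-order set that scatters the samples over
hundreds of chance-pure cells then reads as non-significant, while a true
low-order interaction — whose genotype space is fully observed — is
unaffected. (`g_test()` also offers the generic observed-table df for
testing a given table on its own terms.) Sets with $p \le c_G$ (default
0.05, applied raw) enter the finding store, deduplicated on the SNP set
with the first-seen record kept. On a set's *first* recording, the `pss` weight of
each of its SNPs is multiplied by 0.9, steering future sampling away from
already-reported SNPs. Decay is deliberately not applied on rediscoveries:
a strong pair is rediscovered every iteration, and per-event decay would
drive its SNPs' weights to $10^{-3}$ within tens of iterations —
extinguishing exploration of any higher-order interaction sharing those
SNPs. With first-recording decay the engine still assembles a planted
triple whose internal pair is independently significant, and the ratio
filter then removes the pair from the report.

## The p-ratio tail filter

Across a run the store can accumulate several findings spanning a huge
significance range — the true interaction, occasionally a significant
sub-pair of a higher-order interaction, and rare chance survivors of the
elimination and G-test gates. After sorting by ascending p-value (ties: smaller set,
then lexicographic names), the ratio $p_i / p_{i-1}$ of consecutive
p-values is computed ($0/0 := 1$, $x/0 := \infty$), and the report keeps
only findings before the *largest* jump (the largest index attaining the
maximal ratio, so ties retain more findings). Real interactions sit many
orders of magnitude below the noise floor, so the cut lands between signal
and tail; zero p-values can never be cut because the infinite ratio sits at
the first nonzero p. A single finding passes through unfiltered; with
exactly two, the one ratio decides and only the stronger survives. A
nonempty store always yields a nonempty report.

## The simulator

`simulate_gwas()` emulates the tabular dialect of the GAMETES simulator: a
penetrance model gives $P(\text{disease} \mid g)$ for each joint genotype
of $k$ functional SNPs; functional genotypes are drawn under
Hardy–Weinberg equilibrium from the model's MAFs, disease status is a
Bernoulli draw with the genotype's penetrance, and draws accumulate by
rejection until both class quotas are filled. Noise SNPs are independent
Hardy–Weinberg draws with MAFs uniform on $[0.05, 0.5]$ — the lower bound
avoids near-monomorphic columns whose degenerate tables none of the
objectives handle informatively. Functional SNPs are placed at random
positions and named `M0P0…`, noise SNPs `N<j>`; the planted truth is
written to a companion manifest.

`find_dnme_model()` builds models *without marginal effects* (every SNP's
three marginal penetrances equal, so no single-SNP scan can see the
signal): from a random table it alternates projection onto the
equal-marginals affine subspace (subtracting each SNP's marginal deviation,
which preserves prevalence) with an affine rescale
$f \leftarrow K + c(f - K)$ toward the target heritability ($h^2$ scales as
$c^2$ and affine maps preserve marginal equality), clipping to $[0,1]$ and
restarting from a fresh table when clipping prevents convergence. The
initialisation targets prevalence 0.25 by default: published benchmark
tables for complex disease sit well below 0.5, and at a fixed heritability
a prevalence near 0.5 carries the least case-control contrast, which makes
free-prevalence models an unrepresentative (and unrealistically penetrant)
test bed. Models *with* marginal effects are supported through penetrance
tables loaded with `read_penetrance_table()`.

What the generator does not emulate: linkage disequilibrium between loci,
population structure, covariates, genotyping error or missingness. Passing
benchmarks here therefore show that the search machinery recovers planted
interactions under idealised sampling — not that it is robust to the
correlation structure of real genotype panels.

## Benchmark protocol and problem sizes

`epi_benchmark()` scores a directory of simulated files: a finding counts
as a true positive only under exact set equality (a superset of the planted
pair is a false positive — partial credit would mask the false-positive
control that the elimination and filter steps exist to provide). The model
F-measure is the mean of per-file F-measures and power is the fraction of
files in which every planted interaction was recovered, matching the
standard evaluation of epistasis detectors. Per-file seeds derive from a
base seed plus the file index, so sweeps are reproducible and shardable.

The package's own validation suite runs, per run of the test suite or
acceptance script: the 100-SNP second-order protocol (8 models spanning
MAF $\{0.2, 0.4\}$ and $h^2 \{0.025, 0.05, 0.1, 0.2\}$, $800+800$ samples,
population 20, 160 iterations) over 10–20 files per model; the third-order
protocol (population 20, 4000 iterations) on 2 models; and a reduced
1000-SNP smoke (population 40, 3000 iterations, 2 models × 3–10 files). The
full 1000-SNP experiments of the benchmark literature (6000–8000
iterations, 100 files per model) are overnight runs; the smoke version is
sized so that a desk-scale check still separates this method's F-measure
regime (≈ 0.8–1.0) from the strongest alternatives' (≈ 0.4–0.6) at that
panel size. On no-marginal-effect pair models a 1000-SNP panel is a pure
needle-in-haystack search — partial overlap with the pair carries no
signal — so power at this panel size is governed by the number of fresh
pss-guided draws, i.e. by the iteration budget.

## Numerical and degenerate-input choices

* Scores are memoised per deduplicated SNP set within a run; memoisation
  cannot change results because scores are pure functions of the set.
* Tie handling is deterministic everywhere: competition ranks, K2 then
  insertion order in the population sort, lowest SNP index in elimination,
  the largest index at the filter's maximal ratio.
* A purified set whose genotype table degenerates (a single observed
  combination) cannot be G-tested and is skipped rather than recorded.
* Genotypes outside $\{0,1,2\}$, phenotypes outside $\{0,1\}$, duplicate
  SNP names and empty files are rejected with located errors; missing
  genotypes are not imputed.
* `mo` and `ml` resolve automatically from sample counts when given as 0;
  datasets too small for `mo ≥ 1` or `ml ≥ 2` are rejected.

## Limitations

The search is stochastic: at fixed iteration budgets power is a random
variable, and on large panels it degrades gracefully rather than sharply.
The G-test p-values are asymptotic; with `cg` applied raw (as the method
specifies) the store admits its expected share of chance findings, and the
ratio filter — not multiple-testing correction — is the false-positive
control (a Bonferroni option exists behind `bonferroni = TRUE`). Exact
recovery scoring means a reported superset counts as a miss plus a false
positive, which is the conservative reading. Real-data concerns — LD
pruning, covariate adjustment, gene mapping — are outside this package's
scope.
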