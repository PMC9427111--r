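---
title: "Models and methods behind mtdrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mtdrift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtdrift)
```

# The scientific setting

Budding yeast exposed to chronic mitochondrial superoxide stress (for
example from the redox cycler paraquat) can adapt with remarkable speed —
far faster than a Darwinian supply of nuclear mutations can plausibly
deliver. The adaptation is driven by regulated segmental deletion of the
mitochondrial genome: adjacent mtDNA genes drop in copy number
concomitantly and to the same extent, respiratory (OXPHOS) capacity is
sacrificed, and cells settle into petite (ρ⁻, ρ⁻⁻, ρ⁰) states. A slower
second adaptation phase is driven by conventional nuclear changes, chiefly
whole-chromosome duplications.

`mtdrift` implements the computational core needed to study this process
end to end on synthetic or user-supplied data:

1. an individual-based simulator of serial-bottleneck experimental
   evolution — the *null model* quantifying what nuclear mutation plus
   selection alone can achieve;
2. doubling-time phenotyping of colony growth curves with spatial control
   normalization;
3. read-depth copy-number analysis: aneuploidy calls, mtDNA copy number,
   segmentation into retained/lost blocks, petite classification, and
   gene-level loss reports;
4. qPCR relative copy number (capped −ΔΔCt);
5. a permutation enrichment test for categories among top-ranked strains;
6. generators for every input, with ground truth, so each stage is
   testable without external data.

# The evolution simulator

## Population process

A population of `N` cells expands through asynchronous divisions on an
event queue: a cell with division time $D$ divides every $D$ hours, each
division producing a daughter (age 0) and incrementing the mother's
division count. Cells stop dividing after `max_divisions` (default 12)
divisions — yeast replicative aging — but remain alive, countable, and
samplable. The instant the population reaches $2^{M_t} N$ cells, `N`
survivors are drawn uniformly without replacement to seed the next cycle.
Ties in due time are resolved by insertion order; the cap check runs after
every division.

Two consequences of these rules are worth noting. First, with
`max_divisions >= 1` a cycle cannot go extinct: every daughter starts at
age 0, so lineages persist even as mothers age out; the extinction flag
can only trigger when an inoculum is already entirely at the age limit.
Second, aged-out cells still dilute the bottleneck sample, exactly as
non-dividing cells would in a real subsampling.

## Mutations and diminishing-returns epistasis

At each division the daughter draws: a Poisson($\mu_{snp} \cdot G$) number
of point mutations ($\mu_{snp} = 0.33\times10^{-9}$/bp/division over a
$G = 12$ Mb genome), each landing on an *effectual* site of gene $g$ with
probability proportional to the gene's count of stop-gain plus strongly
deleterious nonsynonymous sites, otherwise neutral; and, with probability
$\mu_{dup} = 4.85\times10^{-5}$, a duplication of a uniformly chosen
not-yet-duplicated chromosome. Genes and chromosomes mutate at most once
per lineage.

A mutation with headline effect size $D_r$ (the log2 fold-change it alone
would confer on the founder's stressed doubling time $D_{fs}$) updates the
genotype's doubling time $D_G$ as

$$k = \max\!\left(\frac{2^{D_r} D_{fs} - D_{fn}}{D_{fs} - D_{fn}},\, 0\right),
\qquad D_m = k\,(D_G - D_{fn}) + D_{fn},$$

where $D_{fn}$ is the founder's unstressed doubling time (93 min), a hard
physiological floor. Each mutation therefore multiplies the *remaining
gap* to the floor by its own factor $k$: benefits shrink as the genotype
improves (diminishing returns), and no genotype ever beats the unstressed
founder. Neutral mutations have $D_r = 0$, hence $k = 1$.

Two conventions for $D_r$ exist because the defining expression is
ambiguous when typeset without its exponent. The default reads $2^{D_r}
D_{fs}$ as the mutant's absolute phenotype, with $D_r$ a log2 fold-change
— consistent with the log2 doubling-time convention used throughout this
kind of analysis. The alternative (`epistasis = "absolute"`), where the
effect size *is* the mutant's absolute doubling time, is one switch away
and tested to be equivalent under the change of variables.

Mutation draws are assigned to the daughter cell at each division, the
convention under which per-division mutation rates are usually measured in
mutation-accumulation studies; `mutate_both = TRUE` applies draws to both
post-division cells instead.

## Scale and what the null model shows

The package defaults are desk-scale: `N = 5000`, `M_t = 5`,
`n_replicates = 48`. The experiment-scale settings (bottlenecks near
50,000 cells, 1152 replicates, 50 cycles with per-cycle empirical $M_t$)
are reachable through `sim_config()` but are not needed to reproduce the
core result: with the printed mutation rates and an effect-size supply
whose best single effects match the measured beneficial aneuploidies
(31 and 38 min on a ~215 min adaptation span), the simulated mean
adaptation at generation 10 sits near 0% of maximum — nowhere near the
~49% real populations achieve. That negative result is robust to the
population scale because it is mutation-supply-limited: in ten
generations a beneficial mutant born at frequency $1/(2^{M_t}N)$ cannot
approach fixation regardless of `N`.

The simulator core is compiled (Rcpp); a cycle at the defaults runs in
well under a second, and the fixation statistics of a two-type population
at small `N` match an exact deterministic-growth/hypergeometric-bottleneck
Markov chain, which the test suite checks by direct enumeration.

# Growth-curve phenotyping

## Doubling-time extraction

Counts are median-filtered (width 5) and log2-transformed; least-squares
slopes over a sliding window (9 points, i.e. 3 h at 20-min imaging) locate
the exponential phase, and the steepest window provides the provisional
rate. When the curve has clearly saturated (final window slope below a
quarter of the maximum), the estimate is refined by fitting the logistic

$$N(t) = \frac{K}{1 + \frac{K - N_0}{N_0}\, 2^{-t/D}}$$

to the log2 counts by Levenberg–Marquardt least squares, initialized from
the window stage. The refinement exists because colony growth curves span
only ~5–6 doublings between inoculum and plateau: a plain window
regression then systematically under-estimates the slope (2% even without
noise, worse under count noise), while the logistic fit uses the whole
curve, is unbiased under the generator's model, and recovers truth within
2% for ≥95% of positions at 5% multiplicative count noise. Curves without
a plateau skip the refinement, so an exact exponential is recovered
exactly. Curves whose best slope corresponds to a doubling time above 24 h
are flagged `no_growth` and reported at the 24 h sentinel.

## Spatial normalization

Plates carry smooth spatial gradients. Interleaved wild-type controls on a
regular subgrid (every fourth position by default: odd rows × odd columns)
measure the gradient directly. `build_control_surface()` interpolates
control log2 doubling times bilinearly on the control grid — exact at
controls, exact for planes, bounded by the control extremes — with
nearest-neighbour clamping at plate edges. Normalization subtracts the
interpolated control value: $\log_2(D)_{norm} = \log_2 D - \text{surface}$.
Cycle-zero adjustment ($\log_2(D)_{adj}$) removes residual pre-cultivation
offsets, and `doubling_to_hours()` rescales by the grand mean control
doubling time so normalized values read as hours.

Generations per cycle are $\log_2(N_{final}/N_{initial})$; interior
missing cycles take the mean of their flanking observed cycles (runs of
missing cycles all take the mean of the two flanking values), and missing
end cycles are refused since they have no interpolation anchor. Percent of
maximum adaptation is the realized fraction of the gap between the initial
stressed doubling time and the unstressed floor, clipped to [0, 100] with
a warning. The display adjustment rescales curves in log space to a common
inoculum, $N_{adj}(t) = 2^{\log_2 N_t \cdot \log_2(\text{median }N_0) /
\log_2 N_0}$ — the form that actually preserves log-scale shape while
pinning $N_{adj}(0)$ (the verbatim published expression collapses curves
to a constant and was evidently a typesetting casualty).

# Copy-number analysis

All coordinates are 0-based half-open (bedGraph convention). Aneuploidies
are called from 200 bp windows against a founder sequenced on the same
flow cell: per-window $\log_2(\kappa\, w_i / w_{founder,i})$ with
$\kappa$ the founder/sample total-depth ratio (cancelling library size),
then a per-chromosome median, called duplicated at ≥ 0.5 — halfway to the
$\log_2 = 1$ a haploid gaining one copy produces. Zero-depth founder
windows are dropped with a warning. MAPQ < 1 read exclusion is an upstream
contract of the depth tracks.

mtDNA copy number uses 1 kb windows normalized to the median of nuclear
windows on euploid chromosomes (aneuploids are called first, then
excluded — the natural ordering since the aneuploidy caller is
founder-normalized and needs no euploid median). The absolute copy
estimate is $2^{\text{median}(\log_2 \text{ratio over mtDNA})}$, assuming
one nuclear copy and no sequencing bias; it is untouched by deletions
covering less than half the molecule because it is a median. Zero-depth
windows get a configurable −10 log2 floor instead of −∞.

Segmentation classifies windows lost at ≤ −2 log2 (≤ 25% of the
euploid-relative level), absorbs runs shorter than `min_windows`
(default 2) into their flanking state (leading short runs join the
following run), and emits maximal runs: segments always tile the molecule
and alternate in state, the signature of concerted segmental loss. Petite
classes follow retained span: ρ⁺ at ≥ 70 kb of the 77 kb molecule, ρ⁻ in
[2, 70) kb, ρ⁻⁻ below 2 kb, ρ⁰ at zero; all thresholds configurable since
reported boundaries vary (<1 kb vs <2 kb for ρ⁻⁻). A gene is reported lost
when ≥ 50% of its span overlaps lost segments.

# qPCR relative copy number

Ct values are capped at 30 (beyond that, signal is background), then
$\Delta Ct = Ct_{target} - Ct_{reference}$ against a single-copy nuclear
control, and the result is $-(\Delta Ct_t - \Delta Ct_0)$ — algebraically
identical to $\log_2 2^{-(\Delta Ct_t - \Delta Ct_0)}$, the composed
published form, which the tests assert. Replicates are averaged after the
transform (averaging Ct before or after transforms differs only at
third-order for the Ct noise levels involved; after-transform averaging
keeps the estimator linear in the reported quantity). A per-record
`force_cap` flag supports pushing known-artifact replicates to the cap, as
needed for primer pairs with non-PCR background. Adjacent genes whose
endpoint changes agree within 0.5 log2 (inclusive) group into concerted
segments, mirroring the coverage-based segmentation at gene resolution.

# Permutation enrichment

The observed statistic is the category fraction among the top `k` ranked
strains; the null resamples `k` strains without replacement (equivalent to
label permutation for a top-k statistic); the one-sided p-value uses the
+1 correction so it is never exactly 0 and bottoms out at
$1/(n_{perm}+1)$. Default $n_{perm} = 10^5$. For small universes the
permutation p matches the exhaustive hypergeometric tail within
Monte-Carlo error, which the tests verify by full enumeration.

# The synthetic-data generators

The generators define the conditions under which the pipeline is
validated:

* **Growth plates** (`gen_growth_plate()`): logistic growth in linear cell
  count — the simplest form with an exponential early phase and a
  stationary-phase plateau — from a log-normal inoculum (mean 5×10⁴ cells,
  CV 0.1) to a 5×10⁶ carrying capacity (~6.6 doublings, matching the
  2.5–6 doublings-per-cycle regime), sampled every 20 min, with a linear
  column-wise gradient multiplying apparent doubling times and
  multiplicative log-normal count noise (default CV 5%). Controls carry
  the control genotype at every fourth position.
* **Coverage** (`gen_coverage()`): 16 nuclear chromosomes at reference
  lengths plus a 77 kb mtDNA; expected window depth = 30× per copy;
  Poisson noise on window read sums (negative-binomial optional for
  over-dispersion); deletions as zero-copy (or reduced-copy) intervals;
  whole-chromosome duplications at 2×. The bundled mtDNA gene map is a
  synthetic, approximately scaled layout of the canonical gene order — it
  supports gene-level reporting on generated data and is not the
  annotation of any sequenced strain.
* **qPCR** (`gen_qpcr()`): 100% amplification efficiency (one Ct per
  twofold), matching a quantification formula with no efficiency term;
  absent targets emitted above the cap.
* **Effect tables** (`gen_effect_tables()`): 4947 genes over 12 Mb; a 10%
  beneficial fraction under stress with exponentially distributed
  reductions (mean 8 min) capped at 38 min so the best single effects
  match the strongest measured aneuploidy benefit; log-normal costs
  otherwise; negative-binomial effectual-site counts (mean 300/gene,
  ~1.5 M sites genome-wide); chromosome II and V duplications at −31 and
  −38 min, chromosome III neutral, all others mildly costly — the measured
  pattern.

What the generators do *not* emulate — and hence what passing tests do not
show about real data: pixel-to-count calibration error and its
correlation structure, diauxic or non-logistic growth phases, mappability
and GC bias in coverage (noise is exchangeable across windows),
heteroplasmy gradients within a population, qPCR efficiency differences
between primer pairs, and any linkage between nuclear and mitochondrial
events. Round-trip validation demonstrates internal consistency of
estimator and model, not robustness to those real-world artifacts.

# Numerical choices and degenerate inputs

* Doubling estimation refuses curves with fewer than 10 points,
  non-increasing times, or non-positive counts; windows must be odd and
  ≥ 5.
* The control surface refuses fewer than 4 controls or an incomplete
  control subgrid.
* `percent_max_adaptation()` refuses a floor at or above the initial
  stressed phenotype; out-of-range values clip with a warning rather than
  erroring, since measurement noise routinely produces slightly negative
  realized adaptation.
* The euploid median must be positive; mtDNA-only input is refused.
* Segmentation tie-break: a short run bordered by two different states
  joins the *preceding* run (the following run if it leads the molecule) —
  deterministic and direction-stable.
* All generators and the simulator are deterministic given their seed;
  the simulator uses R's global RNG so `set.seed()` governs `run_cycle()`
  directly.

# Problem sizes used in validation

The shipped tests and acceptance checks run at sizes chosen to exercise
every code path while staying comfortable on a laptop: 384-position
plates, full-genome coverage at 200 bp/1 kb windows, 48-replicate
simulations at `N = 5000` over two cycles for the null-model check, 400
Markov-chain comparisons at `N = 8` for the fixation oracle, and 10⁵
permutations for enrichment. Experiment-scale runs are configuration
changes, not code changes.

# Known limitations

* The simulator models no mitochondrial genome, mating, meiosis, ploidy
  change, essential-gene lethality, or cell–cell interaction; it is a
  null model for nuclear adaptation, not a model of the mtDNA editing
  process itself.
* Tandem-amplification junctions and structural rearrangements are out of
  scope; segmentation sees only depth.
* The growth QC is limited to sanity checks (positivity, monotone time);
  the full curve-rejection heuristics of production phenotyping platforms
  are not reproduced.
* The logistic refinement assumes a single saturating phase; strongly
  diauxic curves will fall back to the window estimate.
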