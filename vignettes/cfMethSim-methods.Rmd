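---
title: "cfMethSim: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cfMethSim: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfMethSim)
```

# What this package models

Cell-free DNA (cfDNA) circulates as short, mostly mononucleosomal
double-stranded fragments whose CpG methylation patterns still carry the
signature of the cell type that released them. Methylation sequencing of
cfDNA therefore supports *tissue-of-origin deconvolution*: estimating what
fraction of the circulating DNA came from each reference tissue. But the
measurement chain is not neutral. Many cfDNA duplexes carry single-stranded
5' overhangs ("jagged ends"). A double-stranded library preparation (dsLP)
blunts these ends before adapter ligation by filling the recessed 3' strand
with *unmethylated* cytosines; after enzymatic conversion those synthesized
cytosines read as unmethylated, depressing apparent methylation exactly
where the fragment was jagged. A single-stranded preparation (ssLP) ligates
splint adapters to denatured strands without any end repair and leaves the
patterns untouched.

cfMethSim implements this entire chain as an explicit generative model, so
that every bias the chemistry can produce is available on demand, with
known ground truth, at desk scale - together with the analyses that detect
or suffer from it: within-read M-bias profiles, global CpG and CHH
methylation, spike-in conversion QC, the Jagged Index-Unmethylated (JI-U),
site-based deconvolution with an undetermined fraction, and fragment-level
U/X/M deconvolution.

# The generative model

## Fragments and latent methylation

A sample is parameterized by a `SimConfig`. Fragment tissues are drawn from
the mixture; fragment lengths from a normal distribution (default mean 165
bp, sd 20 bp, floored at 50 bp - the mononucleosomal cfDNA peak; the
urine-like preset shortens and widens this to 140/25, since urinary cfDNA
is more degraded). Fragment positions are uniform over the atlas territory,
so every CpG site sees the same expected coverage. Each covered CpG's
latent methylation state is Bernoulli with the atlas beta value of the
fragment's tissue, and both strands of the duplex share that truth.
Fragment placement is independent of tissue - an idealization (no
tissue-specific fragmentation).

## Jagged ends

Each duplex end independently carries a 5' overhang with probability
`jagProb`. Overhang lengths follow a shifted geometric distribution
(support 1, 2, ...; mean `jagMean`), truncated at fragment length - 1. A
long-tailed family was chosen deliberately: observed dsLP bias profiles
imply overhang lengths ranging from nearly blunt to almost fully
single-stranded, which a geometric tail reproduces. A `jagDist = "fixed"`
option (every overhang exactly `round(jagMean)` bp) exists for limit
checks. The overhang at the left fragment end belongs to the strand whose
5' terminus lies there (the "top" strand) and leaves the *bottom* strand's
3' end recessed; mirrored on the right.

## Library preparation

One sequenced molecule is produced per fragment, from a uniformly chosen
strand:

* **dsLP** - the recessed 3' end of the chosen strand is filled across the
  overhang region; every CpG whose reported base was synthesized this way
  is flagged (`repair = TRUE`) and enters conversion as unmethylated. The
  jag model produces only 5' overhangs, so the protocol's 3'-overhang
  digestion is a no-op here; it is modelled (and documented) as position
  dropping, which cannot alter methylation.
* **ssLP** - the duplex is denatured; the chosen strand becomes a molecule
  of its own, possibly 3'-recessed, extent. Nothing is altered; no repair
  flags exist under ssLP (a class invariant).

Read 1 covers the first `readLength` bp from the molecule's 5' end; read 2
the first `readLength` bp from its 3' end, with per-CpG read offsets kept
on every call. Because the filled material sits at the sequenced strand's
3' terminus, dsLP fill-in lands at read-2 5' offsets - reproducing the
read-2-dominant bias shape seen in real dsLP data without asserting any
further sequencer chemistry. Real urinary dsLP data also show a read-1
bias whose cause is unknown; the simulator makes no attempt to model it,
and conclusions about read-1 artifacts are outside what a green test here
establishes.

## Conversion and spike-ins

The enzymatic conversion channel is two Bernoulli error rates: an
unmethylated C reads T with probability `conversionRate` (default 0.994),
a methylated (or hydroxymethylated - the chemistry protects both, so they
are deliberately not distinguished) C reads C with probability
`protectionRate` (default 0.966). The defaults are the spike-in performance
of the single-stranded kit (conversion 99.4%, pUC19 methylation 96.6%);
the lower pUC19 retention seen with double-stranded kits is attributed
here to end repair of the sheared spike-ins, which the spike-in channel
does not route through. Spike-ins are simulated as unmethylated lambda and
fully methylated pUC19 cytosine calls, defaulting to a 20:1 count ratio
(mirroring the 20 ng : 1 ng input ratio). CHH methylation is simulated as
a fixed number of non-CpG cytosines per fragment (default 10) with
methylation probability `chhMeth` (default 0.003, the order of magnitude
of reported cfDNA CHH rates); its apparent rate is conversion-failure
dominated, which is exactly why it is a QC metric.

All randomness flows from one seeded stream, and the stream is consumed in
the same order whichever library is simulated: two configs differing only
in `library` see identical fragments, jags and conversion draws, so with
`jagProb = 0` their outputs are bit-identical. This is what makes
matched-seed ssLP/dsLP contrasts exact.

# Metrics

**Site counts and trimming.** `extractSiteCounts()` pools informative
calls per CpG after trimming read 5' ends (`TrimPolicy`); a CpG covered by
both mates counts once when `dedupOverlap = TRUE`, the read-1 call winning
(the common extractor behaviour; since both mates read the same molecule
the values agree anyway - which also means overlap dedup cannot rescue the
fill-in bias). M-bias profiles are computed *pre*-trimming because their
role is to justify the trim; site counts are computed *post*-trimming. The
scenario runner uses trim (2, 2) for ssLP and (2, 5) for dsLP, the
extractor settings used in practice; whether 5 bp suffices for heavily
jagged samples is precisely the question the bias metrics answer, so the
policy is a user parameter, not a claim. Positions with no calls are
reported `NA`, never 0, to keep flatness tests honest.

**JI-U.** `jaggedIndexU()` computes `(M1 - M2)/M1 * 100` with `M1` the
pooled methylation over the first 30 bp from read-1's 5' end. The original
index defines `M2` over "the first 30 bp at the 3'" read by read 2; read
2's first sequenced cycles *are* the fragment's 3' terminus, so the
primary `M2` window here is read-2 offsets `[0, 30)`. The alternative
literal reading - the last 30 sequencing cycles of read 2, a window that
sits mid-fragment and never sees fill-in - is also computed and reported
(`m2Alt`, `jiUAlt`) so the two interpretations can be compared on any
dataset; only the primary one responds to jaggedness, which is the
behaviour that makes the index an index. Aggregation is pooled-call rather
than per-read ratios (stable at low per-read CpG counts), a window needs
at least `minCalls = 50` calls, and `M1 = 0` yields an explicitly
undefined result rather than a number.

# Deconvolution

## Site-based, with an undetermined fraction

With atlas matrix $A \in [0,1]^{S \times T}$ and observed per-site
methylation $b$, the estimate solves

$$\min_x \|Ax - b\|_2^2 \quad \text{s.t.}\quad 0 \le x_i \le 1,\;
\textstyle\sum_i x_i \le 1,$$

and reports $1 - \sum_i x_i$ as the *undetermined* fraction. The
inequality (rather than equality) constraint is the only reading
consistent with reporting an undetermined percentage at all: signal that
matches no reference tissue relaxes the sum below one instead of being
forced onto the nearest tissue. Missing sites are dropped row-wise
(pairwise deletion, no imputation); sites are unweighted by default, with
an optional $\sqrt{\text{coverage}}$ row weighting.

Because the upper bounds $x_i \le 1$ are implied by the simplex
inequality, the problem reduces to non-negative least squares with a slack
variable $s \ge 0$ and the equality $\sum_i x_i + s = 1$. No NNLS or
quadratic-programming package is available in the supported environment,
so the package carries its own Lawson-Hanson active-set NNLS, and the
equality is enforced by a heavily weighted penalty row. Numerical
choices: penalty weight $10^4 \times \max|A|$ - large enough that the
constraint violation at the optimum ($\approx$ gradient$/\lambda^2$) stays
below $10^{-8}$, small enough that floating-point cancellation in the
augmented gradient ($\approx \lambda^2 \epsilon_{mach}$) stays below the
dual tolerance, which is $10^{-7}$ on the scale of the *unaugmented*
gradient. The primal feasibility tolerance is absolute ($10^{-11}$)
because proportions live on the unit scale. Iteration caps are treated as
solver failure and raised as errors - an infeasible solution is never
returned silently. Correctness is certified two independent ways in the
test suite: an exhaustive simplex-grid oracle (`bruteForceDeconv()`, step
0.01, capped at 4 tissues) and `mgcv::pcls` on random instances.

## Fragment-level (U/X/M)

Each fragment restricted to a marker block with $k \ge$ `minCpgs`
informative calls and $m$ methylated is labelled U if $m/k \le 0.25$, M if
$m/k \ge 0.75$, X otherwise (boundaries inclusive; defaults configurable
and logged - the external algorithm this emulates does not publish its
defaults). The observed per-block U-fractions $u$ are fitted against the
reference matrix $U_{\mathrm{ref}}$ by NNLS, $\min_{w \ge 0}
\|U_{\mathrm{ref}} w - u\|^2$, and the weights renormalized to proportions
(raw weights are also reported). Blocks with no classified fragments are
dropped, never imputed; a fragment overlapping two blocks contributes to
both.

# The toy atlases

`makeToyAtlas()` builds a synthetic single-chromosome genome of one marker
block per tissue (default 30 CpGs at 12 bp spacing, 60 bp gaps). Tissue
specificity is encoded as *hypo*methylation - a tissue has beta `lowBeta`
(default 0.1) in its own block and `highBeta` (default 0.9) elsewhere -
because the fragment-level method counts unmethylated fragments, and this
makes the site and block atlases mutually consistent. The beta matrix is
deterministic (and therefore full rank by construction).

The reference U-fractions are *calibrated*: a pure sample of each cell
type is simulated through the same fragment/conversion model (default
20000 fragments, ssLP, no jag) and the realized per-block U-fractions are
recorded. This mirrors how real fragment-level atlases are built from
deep-sequenced sorted cell populations, and it is deliberate: an analytic
U-probability is highly sensitive to the distribution of informative-CpG
counts per fragment (a k-CpG binomial tail probability), which depends on
fragment length, CpG spacing and block geometry. Calibration embeds all of
that, plus the conversion error channel, making the reference unbiased for
samples generated under the same settings - and subtly wrong for samples
generated under different conversion rates, which is faithful to how real
atlas/sample mismatches behave.

# Scenario grid and statistics

`runScenarioGrid()` executes the fluid x library design with matched
seeds: plasma-like (jag probability 0.3, mean 8 bp) and urine-like (0.8,
25 bp) presets, both libraries, any number of replicates, all runs at
equal fragment counts (the in-silico version of down-sampling to equal
coverage; `downsampleSample()` exists for unequal inputs). The preset
values are illustrative model inputs chosen once so the simulated
contrasts have the direction and rough size of the real plasma/urine
ones; they are not estimates from data. Comparisons use two-sided t-tests
(`compareMetric()`), paired or unpaired; the unpaired form is the
classical equal-variance statistic. Bonferroni correction multiplies by
the family size and caps at 1; the family is whatever list of comparisons
the caller assembles, and since significance depends on it, the family
size is recorded on every result. Degenerate inputs follow an explicit
contract: identical paired vectors give p = 1 by convention; constant
non-zero paired differences raise an error rather than emitting p = 0.

# What a green test does and does not establish

The simulation reproduces the *mechanism* of library-preparation bias -
jagged ends, fill-in with unmethylated cytosines, conversion error - and
the tests verify index formulas exactly, solver optimality against
independent oracles, parameter recovery of known mixtures, and the
direction of every bias contrast on replicate seeds. The synthetic world
omits, among other things: alignment and duplication artifacts, sequence
context and coverage heterogeneity, tissue-specific fragmentation,
5-mC/5-hmC distinction, the unexplained read-1 bias of urinary dsLP data,
and real atlas noise (the toy atlas is cleanly block-structured, so
deconvolution here is easier than against 25 real tissues at 7890 loci).
Quantities like a JI-U of 45 or an undetermined fraction of 0.15 from the
scenario grid characterize the stated synthetic world, not any patient
cohort; only orderings and recovery errors are asserted.

```{r example, eval = FALSE}
atl <- makeToyAtlas(3, 30, seed = 1)
cfg <- SimConfig(c(tissue1 = 0.6, tissue2 = 0.3, tissue3 = 0.1),
                 nFragments = 50000, library = "ssLP", seed = 42)
ds <- simulateSample(cfg, atl$site)
counts <- extractSiteCounts(fragments(ds), TrimPolicy(2, 2))
deconvolveSite(sampleBetaFromCounts(counts, atl$site), atl$site)
```
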