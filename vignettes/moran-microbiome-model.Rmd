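---
title: "Neutral short-term microbiome dynamics under a Moran host genealogy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neutral short-term microbiome dynamics under a Moran host genealogy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MoranMicrobiome)
```

## The model

MoranMicrobiome simulates the composition of host-associated microbial
communities across one host generation, under the assumption that all
microbial taxa are ecologically equivalent (neutrality). The only forces are
stochastic sampling (ecological drift), transmission mode, environmental
assembly, and host population structure.

**Host genealogy.** A population of `N` hosts evolves by a Moran process: at
each time step one host (in one uniformly chosen deme) reproduces and one
dies, the offspring filling the vacated slot. `N` steps constitute one host
generation. Each host carries exactly `M` microbes over `g` taxa
(`HostMicrobiome` counts always sum to `M`).

**Parental versus environmental acquisition (mixed acquisition, MA_x).** A
newborn receives all `M` microbes as a multinomial sample of its parent's
composition. Every subsequent step, a host re-draws its microbiome from the
blend of its previous self and the local environment with weights
`M : t`, i.e. a single multinomial draw of size `M` from
`(M c + t e) / (M + t)`, where `c` is the host's current composition and `e`
the local mixed environment. Over a host's expected lifetime the fraction of
its microbiome tracing back to its parent is

\[
x \;=\; \frac{1}{N}\sum_{i=0}^{N-1}\Big(\frac{M}{M+t}\Big)^i
\;\xrightarrow{N\to\infty}\; \frac{1-e^{-a}}{a},
\qquad a = \frac{T}{M} = \frac{N\,t}{M} .
\]

The package parameterizes simulations by the generation-level parental
fraction `x`: `solveAcquisition()` inverts the closed form by bisection
(the target is strictly decreasing on `a > 0`; `x = 1` maps to `a = 0`
exactly), and `envPerStep()` converts `a` to the per-step environmental
count `t = aM/N`. `t` is kept real-valued and enters only through the
mixture weights; this is identical in expectation to literally removing and
inserting `t` microbes, costs O(g) per host per step, and avoids rounding
bias at small `M`.

**Environmental assembly (mixed environment, ME_y).** Each deme's
environment at each step is `e = (1 - y) f + y p`: a fixed component `f`
(drawn once per deme at initialization as a large multinomial sample —
default 1e6 — of the common environmental profile, then held constant) and a
pooled component `p`, the mean composition of the deme's hosts at the end of
the previous step. Host contributions to the pool fully replace earlier
ones, so `y` needs no generation-level integration.

**Subdivision and migration.** The population is split into `2^k` equal
demes. At the end of every step, each deme `j` nominates
`z_j ~ Binomial(n_j, q)` migrants; all migrants are pooled and reassigned to
the vacated slots by one uniform permutation, so a migrant can land back
home (with probability shrinking as demes multiply). Migration permutes
hosts — their microbiomes are conserved exactly.

**Diversity summaries.** α is the mean per-host Shannon index, γ the Shannon
index of the pooled mean composition (γ ≥ α by Jensen's inequality), γ_w the
per-deme γ averaged over demes. β is the mean pairwise Bray–Curtis
dissimilarity, partitioned into between-deme (β_b) and within-deme (β_w)
pairs; the overall β is exactly the pair-count-weighted blend of the two.
Shannon indices use natural logarithm by default (`shannonBase` is
configurable); Bray–Curtis is computed on raw counts, which with equal `M`
coincides with the relative-abundance version.

## Initial communities

Real applications fit the generative model to a genus-level
relative-abundance table (`readAbundanceTable()` + `fitTrMVN()`). For
self-contained work, `generateBaselineTable()` synthesizes a stool-like
table: taxon base abundances follow a geometric rank-abundance series whose
rarest/dominant ratio is fixed (default 1e-4, i.e. the dominant genus at
tens of percent and a tail reaching below 0.01%), perturbed per sample by
multiplicative log-normal noise (sd 1 on the log scale) and renormalized.
Defining the tail by its abundance *range* rather than a fixed decay keeps
the community shape comparable whatever `g`; with a fixed decay, small-`g`
test communities would lose the rare tail that drives drift sensitivity.

`fitTrMVN()` takes column means and the sample covariance (ridge 1e-10 on
the diagonal to guarantee positive semidefiniteness). `sampleTrMVN()` draws
from the multivariate normal, clamps negatives to zero (truncation) and
renormalizes (rescaling); all-zero draws are redrawn up to a retry cap.
Rejection sampling was rejected on cost grounds at `g = 129`.

Deme-structured starts use a complete binary tree (`buildDemeTree()`): each
child's mean is one truncated draw from its parent's model and its
covariance is the parent's scaled by `shrinkFactor` (default 1). Hosts are
multinomial draws of size `M` from per-host profiles sampled from their
deme's leaf model. With `k = 0` the single deme's fixed environment is the
common profile itself; otherwise each deme gets an independent multinomial
sample of it.

`ksValidate()` compares per-taxon abundance distributions and per-sample
Shannon distributions between a source table and resampled profiles by
two-sample Kolmogorov–Smirnov tests. Two honest caveats, both visible in the
test suite: the clamp-and-rescale family is not closed under fit/resample
when truncation is heavy (many taxa with mean near zero relative to their
spread), so faithfulness holds in the mild-truncation regime; and the
log-normal synthetic baseline is deliberately *not* trMVN-shaped, so a
trMVN fitted to it reproduces its moments, not its marginal shapes.

## Parameters and defaults

| parameter | meaning | default |
|---|---|---|
| `N` | hosts (= steps per generation) | 4096 |
| `M` | microbes per host | 1e7 |
| `g` | taxa (genus-level) | 129 |
| `x` | parental fraction per generation, (0, 1] | 0.5 |
| `y` | pooled weight of the environment, [0, 1] | 0.5 |
| `k` | deme levels (2^k demes), N divisible by 2^k | 0 |
| `q` | host dispersal rate, [0, 1] | 0 |
| `feSampleSize` | multinomial size of each deme's fixed environment | 1e6 |
| `shrinkFactor` | covariance multiplier per tree level | 1 |
| `pairCap` | exact-enumeration cap for pairwise β | 1e5 |
| `baselineRange` | rarest/dominant base-abundance ratio | 1e-4 |
| `baselineSdLog` | log-normal sample noise (log scale) | 1 |

Tests and the vignette-scale experiments use `N = 64`, `M = 1e4`, `g = 30`
with 10–50 replicates — small enough that a full sweep runs in well under a
minute per condition on one core, while preserving the per-generation drift
scale and the rank-abundance shape. Full-scale settings are supported but
not exercised by the test suite.

## Numerical and design choices

- **Bisection tolerance** for `solveAcquisition()` is 1e-12 on the closed
  form; the bracket cap (default 1e6) turns pathologically small `x` into an
  explicit error.
- **Newborns skip acquisition in their birth step**: the finite-population
  sum starts at `(M/(M+t))^0 = 1`, i.e. a newborn is 100% parental at age 0.
- **Update order** within a step: environments are rebuilt from
  end-of-previous-step hosts (the dying host still contributes), then the
  birth–death event, then acquisition for every host except the newborn,
  then migration. Newborns are eligible to migrate in their birth step.
- **Parent and dying host may coincide** (standard Moran convention).
- **β subsampling**: above `pairCap` unordered pairs, a uniform random
  subset of exactly `pairCap` pairs is scored; the weighted between/within
  identity is exact only in enumeration mode.
- **RNG discipline**: one root seed per run; replicate and sweep drivers
  derive child seeds deterministically (`root·1000 + index`, modulo 2^31−1),
  so replicates are independent and every artifact is bit-reproducible.
- **Degenerate inputs**: all-zero profiles, non-normalized rows, mismatched
  taxon counts, non-divisible `N`/`2^k`, and out-of-range fractions raise
  immediate errors rather than propagating silently.

## What the synthetic generator does and does not emulate

It reproduces the two features that matter to neutral dynamics — a dominant
head and a rare tail spanning ~4 orders of magnitude, plus large
between-sample compositional noise. It does not emulate phylogenetic
correlation between taxa, zero-inflation from detection limits, sequencing
depth variation, or taxon-specific niche effects. Passing tests therefore
certify the engine's sampling laws and the direction of diversity responses
under neutrality; they do not certify that any real community is neutral.

## Known limitations

- The configured `x` is the large-`N` closed form; at finite `N` the exact
  expected parental fraction is the geometric sum, which differs by O(1/N)
  (about 0.016 at `N = 64`, `x = 0.1`; under 1e-3 at `N = 4096`). Retention
  checks compare simulations against the exact finite-`N` expectation.
- Truncation bias compounds along deep deme trees with `shrinkFactor = 1`:
  each level's clamp-and-renormalize draw inflates rare-taxon mass, so
  strongly subdivided starts carry a slightly elevated initial γ (a few
  percent at `k = 4`) that relaxes over the first generation. Whole-
  population γ is otherwise stable over a generation.
- At desk scale with moderate parental contribution, environmental
  recruitment from the (more even) mixed environment can raise α within one
  generation even at `x = 0.9`; the robust, scale-free statements are the
  comparative ones (higher `x` ⇒ lower α and higher β than lower `x`) and
  the strict α decline in the pure-vertical limit `x = 1`, and those are
  what the tests assert.
- One generation only: host lineage extinction effects that need many
  generations (declines of γ and late β reversals) are outside this model's
  scope by construction.

## A worked desk-scale run

```{r example, eval = FALSE}
cfg <- simConfig(N = 64, M = 1e4, g = 30, x = 0.9, y = 0.5, k = 0,
                 recordEvery = 16)
res <- runGeneration(cfg, seed = 1)
traceRecords(res$trace)

# hours of real time per Moran step for a human population
realTimePerStep(30, 4096)
```
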