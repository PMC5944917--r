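---
title: "Models and methods in gsclines"
author: "gsclines authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in gsclines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsclines)
```

# The scientific problem

Genome size in *Zea* (maize landraces and highland teosinte) varies by more
than a gigabase within subspecies, almost entirely through repetitive
sequence — transposable elements, heterochromatic knobs (180-bp and TR1
tandem repeats), B chromosomes and rDNA. Genome size declines with altitude
on independent clines, but a raw trait–altitude correlation cannot
distinguish selection from shared ancestry: populations at similar altitude
are also close kin. `gsclines` implements the full inference chain needed to
ask, at desk scale, whether such clines exceed their kinship null, whether
individual repeat classes are targets of selection beyond their contribution
to total genome size, and whether genome size plausibly affects fitness
through the rate of cell production and thence developmental timing.

All inputs can be generated by the package's own simulators, which reproduce
the statistical structure each analysis assumes, so every stage is testable
without any external data.

# The kinship-null mixed model

The selection test models a quantitative trait (genome size in Gb, or Mb of
one repeat class) as

$$P = \mu + \beta_{alt} A + g + \epsilon, \qquad
  g \sim MVN(0, V_A K), \qquad \epsilon \sim N(0, V_\epsilon I)$$

with altitude $A$ a fixed effect and the kinship matrix $K$ defining the
null covariance of the additive genetic values $g$. For a repeat class, the
trait's own genome size enters as a second fixed covariate, so the altitude
coefficient measures association *conditional on* total genome size — without
that conditioning, any selection on genome size masquerades as selection on
the class that dominates it (transposable elements are ~85% of the genome).
A third mode re-tests total genome size after subtracting the Mb
attributable to both knob classes, asking whether knobs alone carry the
cline. Genome size is treated as fully heritable in the modelling sense
(it is the sum of inherited base pairs); $V_\epsilon$ is still estimated and
absorbs measurement error rather than being fixed at zero.

`fit_lmm()` eigendecomposes $K$ once and profiles the restricted likelihood
in the variance ratio $\delta = V_\epsilon / V_A$ on a grid of
$\ln\delta \in [-10, 10]$ (100 points), refining every bracket that contains
a local maximum by Brent search (tolerance $10^{-8}$ in $\ln\delta$). Exact
boundary fits ($V_A = 0$, i.e. ordinary least squares, and $V_\epsilon = 0$)
are evaluated in closed form and admitted when they dominate, because the
finite grid can only approach them. Variance components and Wald tests are
reported from REML; the likelihood-ratio test for the altitude term
compares full and reduced maximum-likelihood fits on 1 df. Altitude and
genome-size covariates are mean-centred before fitting (slopes unchanged;
conditioning improved).

Wald reference distributions use Satterthwaite degrees of freedom computed
from the expected REML information of $(V_A, V_\epsilon)$. This matters:
with ~70 individuals in 8 populations the altitude contrast has far fewer
effective degrees of freedom than $n - 2$, and plug-in $t$ intervals
under-cover. With the correction, simulation at the default study conditions
puts 95% interval coverage at 93–96% (the acceptance suite measures this),
while the LRT holds its 5% size within Monte-Carlo error under pure drift.
Both p-values are reported; calibration claims are made for the LRT, interval
claims for the Satterthwaite-Wald.

The per-family transposable-element scan fits the conditional model to each
family, counts the families with LRT $p < \alpha$, and compares that count to
Binomial($m$, $\alpha$) by an exact two-sided test — a planted clinal family
should surface as the minimum p-value, while a pure-noise panel should show
about $\alpha m$ hits.

Slopes are reported in Gb/m and converted to Mb/m and Kb/m, since clines of
this kind are conventionally quoted as kilobases lost per metre of altitude.

# Genotype processing and kinship

The genotype pipeline mirrors standard GBS practice: sites with more than
40% missing data and then individuals with more than 90% missing data are
removed; missing calls are imputed by drawing from the empirical
distribution of observed calls at the site (random imputation keeps the
kinship diagonal unbiased for inbreeding; mean imputation is provided for
robustness comparisons); kinship is the centred identity-by-state estimator

$$K = \frac{W W^\top}{2 \sum_j p_j (1 - p_j)}, \qquad W = M - 2P,$$

with monomorphic sites dropped. This normalisation makes the expected
diagonal 1 for an outbred individual, so inbreeding is read off as
$\mathrm{diag}(K) - 1$. IBS distance is defined as one minus half the average
number of shared alleles over co-observed sites; pairs closer than 0.07 are
resolved in ascending-distance order by dropping the lower-depth member.
The Hardy–Weinberg filter uses a 1-df chi-squared goodness-of-fit test over
genotypes with read depth in [9, 300], keeping untestable sites
(conservative). LD thinning removes the lower-coverage member of any pair
closer than 1 kb, and of any tested pair (≥ 12 high-depth genotypes each)
with $r^2 > 0.8$ and correlation-test $p < 0.05$, in a deterministic
left-to-right sweep.

Where a published description names a tool but not a formula (the exact IBS
distance normalisation, HWE degrees of freedom), the definition used here is
stated above and fixed; tests pin the behaviour.

# Repeat abundance from low-coverage reads

Repeat abundance per individual is estimated exactly as a fraction-of-reads
estimator: reads assigned to organellar contamination (plastid by default,
optionally mitochondrial) are removed from the total; a read tied between
several repeat classes contributes equal fractional weight to each
(best-hit-random resolution would also be defensible; tie-splitting is
deterministic and is the default); the class fraction times genome size
(× 1000) gives Mb of repeat. No per-class reference-length normalisation is
applied — the estimator deliberately measures the fraction of the genome
occupied by a class, not copy number. Mask construction consumes externally
computed homology-hit intervals (BED, 0-based half-open; the upstream search
is out of scope), unions them per sequence, and keeps unmasked segments
strictly longer than 70 bp as new reference entries named
`<id>:<start>-<end>`. Concordance between cytological knob counts and
sequence Mb is plain Pearson correlation per class.

# The growth mediation model

Leaf elongation rate is modelled as the product of cell size and cell
production rate, $LER = CS \times CP$, log-linearised. CP is never observed;
it is identified because cell lengths pin down $\log CS$ while daily
increments pin down $\log CS + \log CP$:

* observation level: $\log(\text{cell length}) \sim N(\log CS_i,
  \sigma^2_{cell})$, $\log(\text{daily increment}) \sim N(\log CS_i + \log
  CP_i, \sigma^2_{ler})$;
* seedling level: $\log CS_i = \gamma_0 + \gamma_{GS}\widetilde{GS}_i +
  a_{m(i)} + e_i$, $\log CP_i = \beta_0 + \beta_{GS}\widetilde{GS}_i +
  b_{m(i)} + f_i$ with genome size centred, in Gb (2C), so slopes are
  per-Gb;
* maternal level: $a_m \sim N(0, \tau^2_a)$, $b_m \sim N(0, \tau^2_b)$.

Priors are informative on measurement scales: the cell-size intercept is
centred at $\log(0.003\,\mathrm{cm})$ (a typical maize stomatal cell) and
the production intercept at $\log(4.0\,\mathrm{cm/day}) - \log(0.003\,
\mathrm{cm})$, so the two intercepts jointly encode a prior elongation rate;
slopes are centred at zero (SD 0.5 per Gb); variances have half-normal
priors (scale 0.5). Exact prior variances for this kind of analysis are a
genuinely open choice; they are isolated in `growth_model_spec()` so
alternatives are one argument away, and `prior_sensitivity_scan()` maps the
posterior mean and sign probability of both slopes over a grid of prior
means — with informative data the sign of $\beta_{GS}$ is stable across the
grid, which is the check that matters.

The sampler is a bespoke Metropolis-within-Gibbs written for this model (the
model is the package's contribution, so it is implemented, not delegated):
all location parameters — both latent mediators per seedling, maternal
effects, and the four regression coefficients — have conjugate normal full
conditionals; the six variances use random-walk Metropolis on the log scale,
with step sizes adapted toward 44% acceptance during burn-in only, so the
post-burn-in chain is a fixed-kernel Markov chain. Two chains by default;
split R-hat and a Geyer initial-positive-sequence ESS are reported per
parameter. An independent implementation of the same posterior in a
general-purpose Gibbs engine (JAGS) agrees with the bespoke sampler within
Monte-Carlo error in the test suite. Maternal effects are placed on both
mediators; placing them on one only is a plausible alternative reading of
the original analysis and would be a two-line change in the model unit.

Because every draw carries $\log LER_i \equiv \log CS_i + \log CP_i$ by
construction, the structural identity holds exactly per draw — the test
suite asserts it at machine precision. The model-free companion,
`marginal_gs_effect()`, regresses seedling-mean log increments on genome
size with maternal-clustered standard errors; on noiseless data its slope
equals $\gamma_{GS} + \beta_{GS}$ identically (path-sum identity).

Default chain settings follow a long production run (200,000 burn-in,
500,000 iterations thinned by 500). All recovery tests and the acceptance
script use 2,000 / 10,000 / 10, which this model mixes well at (R-hat
< 1.05, ESS in the hundreds); the scaled-down settings are a package choice
to keep the full suite runnable on a laptop and are stated wherever used.

# SAM cell counts and flowering time

Re-analysis of an inbred-panel design proceeds in two stages. Per growth
phase, line BLUEs of SAM cell counts come from a mixed model with genotype
fixed and replicate block random — fitted with the same spectral REML
machinery, the block design entering as a $ZZ^\top$ covariance. Flowering
time is then regressed on the BLUEs with additive fixed effects for the
BAK1 and SDA1 candidate loci and a polygenic term $g \sim MVN(0, V_A K)$
over the standardized GRM ($w_{ij} = (x_{ij} - 2p_j)/\sqrt{2p_j(1-p_j)}$,
missing set to 0 after centring, $K = WW^\top/m$, MAF ≥ 0.01, missingness
≤ 0.6). Candidate-locus effects are applied in the flowering model only (not
inside the BLUE model) by default; their genotype coding is additive 0/1/2.
With $K = I$ the fit reproduces ordinary multiple regression exactly, which
the tests assert.

# Synthetic data: what it emulates, and what it does not

`simulate_genotypes()` draws Balding–Nichols populations: ancestral
frequencies uniform on (0.05, 0.95), population frequencies Beta-distributed
with variance $F p (1-p)$, genotypes binomial — so the realized
Weir–Cockerham FST matches the target and the centred-IBS kinship shows the
block structure the selection test must absorb. Defaults are the study
conditions the tests target: 8 populations, 70 individuals, FST 0.1,
altitudes spanning 1,600–2,700 m, mean 2C genome size 5.5 Gb, a clinal loss
of 270 kb/m, $V_A = 0.04$, $V_\epsilon = 0.01$ Gb², and a repeat makeup of
85% TE with knobs an order of magnitude apart (6% vs 0.8%). Genome-size
positivity is enforced by resampling $\epsilon$ only, preserving the
covariance of $g$; resample counts are recorded. Read counts are multinomial
at the class level — there is no sequence-level read simulation, no mapping
error, and no coalescent recombination structure, so passing tests show the
inference machinery is correct under its own assumptions, not that real
mapping pipelines are unbiased.

The growth simulator defaults to 200 seedlings in 50 maternal families, 2C
genome sizes uniform over 1.13 Gb, slopes $+0.05$ and $-0.3$ per Gb on cell
size and production respectively, three daily length measurements (two
increments), ten cell lengths per seedling, and log-scale variances of 0.01
(hierarchy) and 0.04 (observation). The production intercept is set so the
expected observed elongation rate is 4.56 cm/day, matching the observed mean
daily growth such experiments report; the implied LER range (roughly 2–9
cm/day) brackets published maize rates. The cytometry simulator's two
defaults (between-line SD 0.104 pg, measurement SD 0.031 pg) encode the
repeatability typical of replicated plant flow cytometry — a replicate
correlation near 0.92 and mean absolute replicate difference near 0.035
pg/1C — and the acceptance script recomputes both from fresh draws.

Every generator draws from a named RNG substream derived from its master
seed, so stage reordering never changes any single stage's output, and
pipeline re-runs are byte-identical (manifests with input hashes are written
per stage).

# Numerical choices and degenerate inputs

* Kinship matrices must be symmetric to 1e-10 and PSD to −1e-8 after a 1e-8
  diagonal jitter; violations are errors, not warnings.
* A constant trait returns a boundary fit ($V_A = V_\epsilon = 0$) with NA
  tests rather than an error.
* Sites monomorphic after imputation are dropped before kinship; all-missing
  sites are a validation error (filter first).
* Zero and negative daily increments are excluded (with a count) before the
  growth model; a seedling with no positive increment is excluded with a
  warning.
* Ties in the duplicate-removal depth comparison drop the first-listed
  individual; the pair order is ascending distance, so resolution is
  deterministic.
* Units: genome size is Gb internally; picogram inputs convert at 1 pg =
  0.978 Gb (configurable). BED intervals are 0-based half-open; genotype
  site positions are 1-based.

# Known limitations

The LD-thinning $r^2$ rule tests all within-chromosome pairs by default
(quadratic in sites); restrict `r2_window_bp` for large panels. The growth
model assumes lognormal observation error and linear genome-size effects on
the log scale; systematic measurement drift across days is not modelled.
The selection test conditions on a single environmental axis (altitude);
correlated environmental covariates would be attributed to altitude. The
family scan treats families independently and applies no multiplicity
correction beyond the binomial excess test, by design.

# Problem sizes used in checks

Simulation-based checks use: 20 random fixtures (n ≤ 10) for the
mixed-model oracle; 1,000 pure-drift simulations at n = 70 for LRT size;
500 simulations for slope recovery and interval coverage; 100 multinomial
replicates for the repeat round trip; one n = 200 dataset (two chains) for
growth-slope recovery plus 50 null replicates (one chain) for credible
interval coverage, at the scaled-down MCMC settings above. These sizes are
package choices balancing Monte-Carlo error against a runnable suite.
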