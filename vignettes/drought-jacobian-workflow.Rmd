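---
title: "From yield indices to differential biochemical Jacobians"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From yield indices to differential biochemical Jacobians}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtjac)
library(dplyr)
```

## The problem

Breeding drought-tolerant crops needs two things joined: a phenotype-level
ranking of genotypes by how much yield they sacrifice under stress, and a
mechanistic reading of *why* the tolerant ones cope — which biochemical
reactions respond differently in their leaf metabolism. droughtjac
implements that joined analysis for genotype panels phenotyped under paired
well-watered (WW) and drought (DS) conditions with accompanying GC–MS
metabolite profiles:

1. the Fischer–Maurer **stress susceptibility index** (SSI) and a
   tolerance/production quadrant classification,
2. a per-metabolite **Pearson screen** of log abundances against SSI,
3. **inverse Jacobian inference**: the covariance of log metabolite levels,
   combined with a metabolic network constraint, is inverted through the
   Lyapunov equation to estimate reaction elasticities, and two genotype
   groups are contrasted through the **differential Jacobian**.

Every stage has a seeded synthetic generator emulating its inputs with
known ground truth, so the whole pipeline is testable end to end without
any external data.

## Stress susceptibility index

For genotype $i$ with trait value $Y_{p,i}$ under WW and $Y_{s,i}$ under
DS, and panel grand means $MY_p$, $MY_s$:

$$ SI = 1 - \frac{MY_s}{MY_p}, \qquad
   SSI_i = \frac{1 - Y_{s,i}/Y_{p,i}}{SI}. $$

$SI$ is the panel-level stress intensity; $SSI_i$ is genotype $i$'s loss
relative to it. $SSI < 1$ means less-than-average loss (tolerant),
$SSI > 1$ more (susceptible). Two properties anchor the tests: the
$Y_p$-weighted mean of SSI is exactly 1 for every panel, and SSI is
invariant to the trait's units.

A caution for readers comparing with older literature: the index is
occasionally printed with the ratio transposed ($1 - Y_p/Y_s$). That form
yields negative values for every stressed genotype and contradicts the
"below 1 = tolerant" reading, so droughtjac implements the canonical
Fischer–Maurer form above.

The quadrant classification crosses SSI (at threshold 1 by default) with
the stressed trait value: Q1 tolerant/high-yielding, Q2 tolerant/low,
Q3 susceptible/low, Q4 susceptible/high. The trait split is the median of
$Y_s$ by default — the source studies rarely state their seed-weight
split, and the median gives a balanced, scale-free partition — with
`mean` and `explicit` policies available when a published membership list
needs to be pinned exactly. Ties go to the tolerant (and high-yield) side,
because "above 1" is the stated susceptibility rule, so equality is not
susceptible.

```{r ssi}
panel <- generate_yield_panel(panel_spec(n_genotypes = 36, seed = 1))
ssi <- compute_ssi(panel)
glance(ssi)
quad <- classify_quadrants(ssi)
table(quad$quadrant)
```

## Metabolite–SSI screen

Relative abundances are log-transformed (natural log by default; Pearson
correlation is invariant to the base) and each replicate observation is
paired with its genotype's SSI — with 36 genotypes and 3 replicates the
correlations use $n = 108$ pairs. That replicate-level pairing matters:
the p-values reported by comparable studies are consistent with
$n \approx 108$, not with genotype means at $n = 36$. For each metabolite
the screen reports $r$, $t = r\sqrt{n-2}/\sqrt{1-r^2}$, its two-sided
p-value, the Benjamini–Hochberg $q$ across the metabolite family (raw
p-star conventions differ between papers, so both are kept), and
$r^2$ as variance explained. Zero-variance metabolites are flagged
undefined and kept out of the BH family. The default analysis slice is
DS at harvest time point 2 — the mid-pod-filling stage, where the
drought response of leaf metabolism peaks — and both are configurable
because some figure panels in the literature blend slices.

```{r screen}
met <- generate_ssi_correlated_metabolome(ssi, rho = -0.4, n_replicates = 3,
                                          seed = 2, n_filler = 10)
screen <- correlate_to_ssi(log_transform(met), ssi)
head(screen, 3)
```

## Inverse Jacobian inference

Near a metabolic steady state, fluctuations of log metabolite levels
$x$ follow a linear stochastic system $\dot x = J x + \text{noise}$, whose
stationary covariance $C$ obeys the Lyapunov equation

$$ J C + C J^\top = -2D, $$

with $J$ the biochemical Jacobian (reaction elasticities) and $D$ the
diagonal matrix of fluctuation intensities. The forward direction
($J, D \to C$) is a linear solve and powers both the simulator and the
test oracle. The estimator runs the inverse direction: given the sample
covariance of log abundances and a network constraint that fixes which
$J$ entries may be non-zero (edge $j \to i$ allows $J_{ij}$; the diagonal
is always free), it solves the $n(n+1)/2$ equations in the masked unknowns
by least squares. When the system is rank-deficient — the realistic case,
e.g. ~48 metabolites against ~39 observations per group — the
minimum-norm solution is taken, deterministically, and the rank deficiency
is reported rather than hidden.

Because $D$ is arbitrary, the calculation is repeated (default $10^4$
times) with random diagonal noise matrices and the entry-wise median is
the estimate, with the IQR as spread. Two numerical choices matter:

* **Noise draws are half-normal** ($|z|$, $z \sim N(0,1)$) by default. A
  negative diagonal entry of $D$ has no meaning as a fluctuation
  intensity, and signed draws make the solutions for $+D$ and $-D$ exact
  negatives, collapsing the median toward zero. A `noise_mode = "normal"`
  switch keeps literal signed draws for replication of older protocols.
* **The Monte-Carlo loop is a single linear map.** The least-squares
  design depends only on $(C, \text{mask})$; each iteration changes only
  the right-hand side through $\mathrm{diag}(D)$. The loop is therefore
  one pseudoinverse applied to a matrix of draws — mathematically
  identical to iterated solves (asserted in the tests against a literal
  loop) and fast enough that $10^4$ iterations on a 48-metabolite,
  ~150-edge mask take seconds.

The solution map is homogeneous: scaling $C$ by $\alpha$ scales every
estimate by $1/\alpha$ at fixed seed, which the tests assert.

```{r jacobian}
sys <- make_toy_network(6, "ring", seed = 3)
est <- monte_carlo_jacobian(sys$C_true, sys$mask, n_iter = 2000, seed = 4)
est
tidy(est) |> head(4)
```

## Differential Jacobian

Two genotype groups (by default the Q1 and Q3 quadrant members, sharing
seed and noise draws so they differ only through their covariances) are
contrasted entry-wise:

$$ dJ_{ij} = \ln \frac{|J^{(1)}_{ij}|}{|J^{(2)}_{ij}|}. $$

Positive $dJ$ marks a faster-responding reaction in group 1. The
log-ratio is undefined for vanishing entries — entries where either
magnitude falls below $10^{-9}\times$ the median masked magnitude are
flagged, symmetrically, so the antisymmetry $dJ(\text{swap}) = -dJ$ holds
exactly, flags included — and it ignores signs, so sign concordance is
reported separately, with concordant entries labelled activating
(shared sign positive) or inhibiting (negative). `classify_edges()`
thresholds $|dJ|$ into the tidy table behind a circular
differential-flux diagram.

```{r differential}
sys2 <- sys
J2 <- sys$J_true
off <- which(sys$mask & !diag(TRUE, 6))
J2[off[1:3]] <- J2[off[1:3]] / 2          # three slower edges in group 2
C2 <- forward_lyapunov(J2, diag(6))
C1 <- forward_lyapunov(sys$J_true, diag(6))
e1 <- monte_carlo_jacobian(C1, sys$mask, n_iter = 200, seed = 5)
e2 <- monte_carlo_jacobian(C2, sys$mask, n_iter = 200, seed = 5)
d <- differential_jacobian(e1, e2, group_names = c("Q1", "Q3"))
classify_edges(d, threshold = log(2) * 0.8)
```

## What the synthetic generators emulate — and what they do not

The generators reproduce the statistical structure the estimators assume:
`make_toy_network()` draws Jacobians that are Hurwitz by construction
(negative diagonal dominating each row's off-diagonal absolute sum, a
simple always-valid sufficient condition) and computes their exact
stationary covariance; `simulate_abundances()` draws stationary
multivariate-normal log levels and exponentiates them, so the pipeline's
log transform recovers the Gaussian layer exactly;
`generate_yield_panel()` plants two tolerance classes (defaults: 36
genotypes, half tolerant, 10% vs 50% relative yield loss, 5%
multiplicative noise, WW 100-seed weight log-normal around 25 g —
realistic for desi chickpea); `generate_ssi_correlated_metabolome()`
plants an exact population correlation between log abundance and SSI,
with replicates inheriting their genotype's SSI.

They deliberately do **not** emulate GC–MS instrument artefacts: drift,
batch effects, missing peaks, non-stationarity across harvests, or
genotype-specific network rewiring. Passing recovery tests therefore
demonstrates correctness of the estimators under their own model, not
robustness to everything field data can do. The most consequential
real-data gap is covariance sampling noise: with ~50 observations per
group, sample covariances carry ~20–25% entry-wise error, and planted
factor-two elasticity differences are recovered reliably from exact
covariances but only partially from sampled ones — the end-to-end tests
and the acceptance script report both regimes rather than papering over
the difference.

## Problem sizes and numerical settings

The shipped tests and the acceptance script use: panels of 36 genotypes ×
3 replicates; toy networks up to 10 nodes for exact round-trip checks; a
48-variable, ~150-edge random mask with $10^4$ Monte-Carlo draws for the
full-scale ensemble; 200 seeds for planted-correlation recovery and 500
for the null type-I rate; and $n_{\text{iter}} = 200{-}500$ for
differential comparisons. Exact recoveries are asserted at $10^{-8}$
relative error, identities at $10^{-12}$, stochastic recoveries at their
analytic sampling tolerances. Degenerate inputs (non-positive abundances,
constant SSI, empty networks, unstable Jacobians, all-zero covariance)
raise typed errors or documented warnings rather than propagating NAs.

## Running everything at once

`run_pipeline(pipeline_config(...))` executes SSI → quadrants → screen →
per-group covariance → Monte-Carlo Jacobians → differential → edge
report, writes every table as TSV plus a JSON manifest when an output
directory is set, and errors (rather than emitting empty output) on
missing slices or groups too small to support a covariance estimate.
Re-running an identical configuration reproduces byte-identical outputs.
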