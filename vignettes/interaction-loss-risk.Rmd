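---
title: "Methods: estimating the risk of interaction loss in mutualistic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating the risk of interaction loss in mutualistic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkrisk)
```

`linkrisk` treats the loss of a single plant–animal link as a risk with two
components: the likelihood of the loss (link *vulnerability*) and the
severity of its consequences for the community (link *feasibility
contribution*). This vignette documents the models, the parameters that
matter, the numerical choices, and what the synthetic validation data can
and cannot tell you about real networks.

## Vulnerability

For a link between plant $i$ and animal $j$ in one local network,

$$V_{ij} = (1 - f_{ij})(1 - D_{ij}),$$

where $f_{ij}$ is the link's visitation frequency, $\log_{10}$-transformed
and min–max standardised to $[0,1]$ within the network, and $D_{ij}$ is the
link's generalisation — the mean *binary* degree of the two partner species
— likewise standardised (no log transform; weighted degrees are deliberately
not used, because redundancy of a link is about how many alternative
partners exist, not how strong they are). $V$ runs from 0 (frequent link
between generalists) to 1 (rare link between specialists), the links
empirical studies find are lost first as habitat shrinks.

Two numerical rules make $V$ total: a constant column (all frequencies, or
all generalisations, equal within a network) is standardised to 0.5 for
every link, since ties carry no ranking information and the alternative is a
0/0; and links must have strictly positive weight, which the ingestion layer
guarantees by construction.

## The dynamical model and feasibility

Consequences are evaluated on a generalized Lotka–Volterra mutualism model.
With plant abundances $P$ and animal abundances $A$,

$$\frac{dP_i}{dt} = P_i\Big(r_i - \sum_k \alpha_{ik} P_k + \sum_j \gamma_{ij} A_j\Big),$$

and symmetrically for animals. Competition is mean-field within guilds
($\alpha_{ii} = 1$, $\alpha_{ik} = \rho$; the analysis designs use $\rho = 0$
to isolate mutualistic effects, with $\rho = 0.01$ as the weak-competition
variant). The mutualistic benefit is
$\gamma_{ij} = \gamma_0 L_{ij} / d_i^{\delta}$: binary adjacency, discounted
by the receiving species' degree through the trade-off $\delta$.

At equilibrium $r = B N$, where $B$ has the block form
$[[\alpha^{(P)}, -\gamma^{(P)}], [-\gamma^{(A)}, \alpha^{(A)}]]$. The set of
intrinsic growth-rate vectors compatible with positive abundances of all
$S$ species is therefore the cone $\{B N : N > 0\}$, and *feasibility*
$\Omega$ is the fraction of the unit sphere this cone occupies — the
community's safe operating space under environmental change of any
direction.

### Estimating $\Omega$

Two estimators are provided, both invariant to positive rescaling of the
cone generators (so ratios of $\Omega$ are well defined under either):

* `omega_solid_angle()` — hit-or-miss: the fraction of uniform random
  directions $r$ with $B^{-1} r > 0$ componentwise. Unbiased, with the
  binomial standard error $\sqrt{\Omega(1-\Omega)/n}$, and directly testable
  against the analytic value $2^{-S}$ for identity systems. Its weakness is
  intrinsic: $\Omega$ itself decays roughly like $2^{-S}$, so beyond a dozen
  species a practical sample contains no hits.
* `omega_center_deviation()` — boundary probing from the analytic
  *structural center* $r_c \propto \sum_k B_{\cdot k}/\lVert B_{\cdot k}\rVert$
  (the normalised sum of cone generators). For each sampled tangent
  direction, $r_c$ is rotated along the great circle until feasibility is
  lost; the critical angle $\theta^\*$ is found by bisection to $10^{-4}$
  rad ($\pi$ if feasibility never fails). Each angle is then converted to
  the sphere measure of the geodesic cap it subtends,
  $G(\theta^\*) = \mathrm{pbeta}\!\big((1-\cos\theta^\*)/2,\ (S-1)/2,\ (S-1)/2\big)$,
  and $\Omega$ is the mean of $G$.

The cap conversion is the one genuinely open design point here, so it
deserves its rationale. The feasibility region on the sphere is geodesically
convex and contains $r_c$, so the sphere decomposes exactly in geodesic
polar coordinates around $r_c$: averaging $G(\theta^\*)$ over uniform
tangent directions *is* the solid angle, estimated with lower variance
(every direction contributes a conditional expectation instead of a 0/1
hit). The superficially simpler summary — the mean of $\theta^\*/\pi$
itself — measures something different: it is dominated by how *eccentric*
the cone is around the center rather than by how large it is, and in our
experiments it can rank link removals in the opposite order from the
solid angle. Because the quantity of interest is defined as a volume, the
cap-measure average is used; in two dimensions it reduces to
$\theta^\*/\pi$ exactly. The bisection itself is cross-checked in the test
suite against the closed-form first-exit angle
$\min_i\,\mathrm{atan2}(b_i, a_i) + \pi/2$ with $a = B^{-1} r_c$ and $b$
the image of the tangent direction.

`omega_solid_angle()` remains the default of the low-level functions — it is
the more transparent estimator, and on the small systems where it works the
two agree — but the pipeline configuration defaults to `center_deviation`,
which stays informative at the community sizes the pipeline actually
processes ($S \approx 20$ and beyond).

### Calibrating $\gamma_0$ and $\delta$

The working mutualistic strength is half the *stability threshold*: the
largest $\gamma_0$ at which the symmetric part $(B + B^\top)/2$ stays
positive definite, a sufficient condition for global stability of the
feasible equilibrium. The threshold is found by doubling/halving bracketing
plus bisection to a relative tolerance of $10^{-6}$, with the smallest
eigenvalue of the symmetric part as the monotone criterion. The threshold
and $\gamma_0$ are computed once per network, on the original topology, and
held fixed across all link removals so that contributions are comparable
within a network.

The trade-off $\delta$ is estimated from the data by two regressions fitted
jointly with a common slope and guild intercepts:
$\log\!\big(f_{ij}/(d_i^P d_j^A)\big) = a^P - \delta \log d_i^P$ on the
plant side and the analogue with the animal degree on the animal side, every
link contributing one stacked observation per guild. The fit is ordinary
least squares; it errors when the pooled degrees carry no variation (a
regular graph, or a pure star where degree is collinear with guild — for
such inputs the pipeline accepts a fixed `delta_value` instead).

### Contribution of a link

$I_{ij} = 100\,\Omega_O/\Omega_R - 100$, comparing the intact network with
the network missing the focal link. Degrees are recomputed after removal, so
the benefits of the remaining links of the two partner species strengthen —
faithful to $\gamma_{ij} = \gamma_0 L_{ij}/d_i^\delta$. Both $\Omega$ values
use the *same* direction sample (common random numbers), which removes most
Monte Carlo noise from the ratio; the default is 2,000 directions per
network in the pipeline (10,000 in the low-level functions), with per-network
seeds derived deterministically from the master seed. A removal that would
leave a species with no partners does not define a comparable community; such
links are flagged `excluded`, retained in the output, and counted, rather
than dropped silently or given a value.

## Taxonomic consistency

An interaction is the metaweb-level identity of a link (all its occurrences
across networks, aggregated at genus, family or order level; species-level
recurrence is typically too sparse to test). Consistency asks whether an
interaction keeps similar *relative* property values wherever it occurs:
vulnerability is re-standardised to $[0,1]$ within each network (same tie
rule), while feasibility contribution is already a relative quantity and is
passed through unchanged.

For each interaction with at least two links (singletons are dropped and
counted), the observed sample variance (always the $n-1$ estimator) is
compared with `n_null` null sets of the same size drawn without replacement
from all other links' values at the same aggregation level — the focal
links are excluded from the pool, and pools smaller than the group size make
the test impossible (reported, not silently approximated).
$P$ is the proportion of null sets with *strictly* lower variance (ties
count as not lower, per the definition of $P$ as "proportion lower"), and
`mean_paired_diff` is $\mathrm{mean}(\mathrm{Var}_{null} -
\mathrm{Var}_{obs})$, positive when the interaction is more consistent than
chance. Significance is $P < 0.05$. The test is validated two ways:
exhaustive enumeration of all null sets on small pools, and type-I
calibration on metawebs generated *without* planted consistency, where the
share of significant interactions must sit in the binomial band around 5%.

## The regression layer

The headline relationship — does contribution increase with vulnerability?
— is a linear mixed model (REML, via `lme4`) with feasibility contribution
as response, vulnerability as fixed effect and network identity as a random
intercept. The package computes on top of the fit: the Wald
$\chi^2 = (\hat\beta/\mathrm{SE})^2$ with one degree of freedom, and the
variance-decomposition R²,
$R^2_m = \sigma^2_f/(\sigma^2_f + \sigma^2_\alpha + \sigma^2_\varepsilon)$
and $R^2_c = (\sigma^2_f + \sigma^2_\alpha)/(\sigma^2_f + \sigma^2_\alpha +
\sigma^2_\varepsilon)$, with $\sigma^2_f$ the variance of the fixed-effect
linear predictor. REML is used rather than full ML because the variance
components enter the R² directly and REML's are the less biased at modest
network counts; this choice is recorded in the model report. Degenerate
inputs (no usable links, a single network, zero response variance) yield a
flagged result, not an error, so upstream exclusion-heavy runs complete.

## What the synthetic generator emulates — and what it does not

`generate_metaweb()` produces collections of local networks sharing a
species pool and a genus–family–order taxonomy, with:

* heavy-tailed degree distributions (`topology = "propensity"`: link scores
  are products of log-normal species propensities with multiplicative noise,
  thresholded to the target connectance);
* visitation rates obeying the planted law
  $\log f_{ij} = a + \log(d_i d_j) - \delta\,\log d_i$ with log-normal noise
  of scale `noise_sigma`;
* optional planted consistency: each genus-pair interaction carries a latent
  log-frequency effect (s.d. `between_interaction_sd`) realised across its
  occurrences with s.d. `within_interaction_sd`. The effect is planted in
  vulnerability's *ingredients* (frequency), not in $V$ itself, so
  consistency must emerge through the real pipeline to be detected.

Defaults are chosen to resemble a quantitative visitation study at desk
scale: 10 networks from pools of 24 plant and 36 animal species, inclusion
probability 0.5, connectance 0.2 (roughly 40–60 links per network),
`true_delta = 0.339`, `noise_sigma = 0.3`, and a baseline frequency that
puts the median sampling intensity $\sqrt{\sum w/(n_P n_A)}$ near 0.9, the
magnitude typical of such surveys. Weights are kept as positive real rates
rather than rounded to integer counts: rounding would perturb the planted
power law and destroy the exact-recovery tests, and the weighted-network
container explicitly admits rates.

One structural subtlety is worth knowing. The planted law fixes frequency
from the *plant* side only, while the $\delta$ regression pools both guilds
with a common slope. On an arbitrary topology these two constraints cannot
both hold exactly — exact recovery requires every link to join species of
equal degree. `topology = "modular"` therefore builds networks as unions of
fully connected plant–animal modules of sizes 2–4 (module structure is
itself a recurring feature of mutualistic communities), on which both guild
equations hold simultaneously and the noise-free fit recovers `true_delta`
to machine precision; the noisy-recovery checks use the same topology. On
propensity topologies the pooled estimate is a compromise between the two
guild-side fits and systematically smaller than the planted value — as with
real data, the regression there is a calibration device for
$\gamma_{ij}$, not an unbiased estimator of a structural constant.

What the generator does *not* emulate: abundance dynamics behind visitation
(frequencies are drawn, not simulated from populations), spatial or temporal
structure, sampling error in link detection, and phylogenetic signal beyond
the planted interaction effects. Passing tests on synthetic metawebs
therefore validates the *machinery* — standardisation, cone geometry, null
models, seeds — not the ecological claims one might make from a particular
empirical dataset.

## Numerical choices, in one place

* Min–max standardisation throughout, constant columns to 0.5.
* Stability threshold: bisection, relative tolerance $10^{-6}$; positive
  definiteness via the smallest symmetric-part eigenvalue.
* Critical angles: bisection on $(0, \pi]$ to $10^{-4}$ rad; directions
  parallel to the center get $\theta^\* = \pi$.
* Common random numbers for every $\Omega_O/\Omega_R$ ratio; per-network and
  per-interaction seeds derived by hashing the master seed with stage and
  identity tags, so any stage can be re-run in isolation and byte-identical
  artifacts are a tested invariant.
* Null sets: sampling without replacement, strict `<` for $P$, $n-1$
  variances everywhere.
* Excluded links keep their records (`excluded = TRUE`, `I_percent = NA`).
* Ingestion prunes all-zero rows/columns with one warning per species and
  rejects networks left with fewer than two species per guild.

Validation problem sizes (the package's own choice of desk scale): identity
cones to $S = 8$ at $10^5$ directions; $\delta$ recovery over 20 seeds of
roughly 1,100 pooled links each; consistency calibration over 20 metawebs
of 12 networks (about 2,900 interactions) at 400 null sets; pipeline
determinism on 6-network runs at 800 directions and 100 null sets.

## Known limitations

* The solid-angle estimator is uninformative for communities beyond roughly
  a dozen species; use the center-deviation estimator there (the pipeline
  default).
* The structural center must be strictly feasible; for pathological cones
  (possible far above the stability threshold) the center-deviation
  estimator refuses rather than guesses.
* The $\delta$ regression assumes degree variation that is not collinear
  with guild membership.
* Consistency tests at coarse levels (order) often rest on few interactions;
  the summaries report the counts alongside the proportions for that reason.
* Feasibility contributions are conditional on the mean-field competition
  approximation and on $\gamma_0$ fixed at half the stability threshold;
  both are standard but untested assumptions at the single-link scale.
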