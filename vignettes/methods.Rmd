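---
title: "Longitudinal cognitive diagnosis with a supervised SOM: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal cognitive diagnosis with a supervised SOM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssomcda)
library(dplyr)
```

## The problem

Cognitive diagnostic assessment reports, for each examinee, a binary
*attribute-mastery profile* $\alpha \in \{0,1\}^K$ over $K$ fine-grained
skills, rather than a single score. Longitudinal assessment asks how those
profiles move over repeated test administrations. `ssomcda` implements a
two-part model for this task:

1. a **measurement model** that classifies an item-response vector into one
   of the $2^K$ mastery patterns — here a three-layer *supervised
   self-organizing map* (SSOM) trained on ideal responses; and
2. a **transition model** — a first-order Markov chain over patterns (or
   single attributes), with initial distribution $\pi$ and row-stochastic
   transition matrices $A_t$ estimated by count normalization from the
   wave-wise classifications.

This is a hidden-Markov structure in which the observation component is
replaced by a hard classifier: no Baum–Welch or Viterbi machinery is used,
because the state sequence is read directly off the classifier, wave by
wave.

## Data generation: the DINA model

The simulator generates dichotomous responses from the deterministic-input
noisy-AND (DINA) model. With Q-matrix entries $q_{jk}$, profile
$\alpha_i$, slip $s_j$ and guess $g_j$, the ideal response is
$\eta_{ij} = \prod_k \alpha_{ik}^{q_{jk}}$ and

$$P(X_{ij} = 1) = (1 - s_j)^{\eta_{ij}} \, g_j^{1 - \eta_{ij}}.$$

Two discrimination regimes are built in: *high* draws $s_j, g_j \sim
U(0, 0.2)$ and *mixed* draws them from $U(0, 0.4)$. The bundled 20-item
Q matrices and their slip/guess draws for both regimes are available via
`cda_fixture()`; 40-item designs stack the 20-item Q twice (preserving each
attribute's coverage profile) and draw fresh parameters from the regime's
range.

**Initial profiles.** Wave-1 profiles come from a Gaussian copula: latent
scores $Z_k = \sqrt{\rho}\, W + \sqrt{1-\rho}\, E_k$ with a shared factor
$W$ give an exchangeable correlation $\rho$ (default 0.5), and attribute
$k$ is mastered when $Z_k$ exceeds the $(1 - p_k)$ standard-normal
quantile, so the marginal mastery rate is exactly $p_k$. Defaults are
$p = (0.4, 0.4, 0.2)$ for $K = 3$ and $(0.4, 0.4, 0.3, 0.3, 0.2, 0.2)$ for
$K = 6$. `pattern_distribution()` computes the implied exact pattern
probabilities by one-dimensional quadrature over $W$.

**Transitions.** Each attribute evolves independently given its current
state through its own $2 \times 2$ conditional matrix per interval; the
bundled generators for both attribute counts encode substantial gains for
most attributes and a pronounced loss probability for the last ones.
`forward_mastery()` gives the Chapman–Kolmogorov forward curve; for the
three-attribute generators the wave-2 mastery of attribute 1 is
$0.6 \times 0.45 + 0.4 \times 0.97 = 0.658$.

All randomness flows from one root seed through named substreams
(parameters, initial profiles, each interval, each wave's responses), so
any single wave is reproducible in isolation and identical seeds give
bitwise-identical samples.

## The supervised self-organizing map

The network has an input layer with one node per item, an $r \times c$
competition grid (default $10 \times 10$ for $K = 3$, $20 \times 20$ for
$K = 6$, $9 \times 9$ in the empirical workflow), and an output layer with
one node per mastery pattern. Presentation of input $x$ selects the winner

$$g = \arg\min_j \lVert x - W^{\text{in}}_{\cdot j} \rVert,$$

and, within the winner's neighborhood $N_c(t)$, both layers update:

$$W^{\text{in}} \leftarrow W^{\text{in}} + f\,\eta_1(t)\,(x - W^{\text{in}}),
\qquad
W^{\text{out}} \leftarrow W^{\text{out}} + f\,\eta_2(t)\,(y - W^{\text{out}}),$$

where $y$ is the one-hot vector of the true class and $f = 1$ when the
winner's current label (the argmax of its output row, ties to the lowest
class) equals the true class, $f = \mu$ otherwise.

### Design choices that were genuinely open

*The mismatch coefficient $\mu$.* The update rule only says that label
disagreement rescales the step by $\mu$. Two readings exist. A negative
$\mu$ repels mismatching neurons (LVQ2-style). Implemented and measured,
this reading is numerically unstable here: early in training labels are
essentially random, so most steps mismatch, and repeated repulsion
multiplies $|W - x|$ by $(1 - \mu\eta) > 1$ per step — weights diverge
geometrically and wrong-class output weights grow rather than correct.
The default is therefore $\mu = +0.5$: a mismatching neighborhood still
moves toward the input and the *true* one-hot target, at half the rate, so
supervision modulates the learning speed without destabilizing it. On the
three-attribute design this reaches the training-accuracy ceiling set by
the Q matrix (see below) in two iterations. Negative $\mu$ remains
available in `ssom_config()`.

*The neighborhood $N_c(t)$.* The classic ordering phase (Chebyshev radius
decaying from half the grid width) is implemented, but the default radius
is 0 — every update touches the winner only, the vector-quantization limit
of the map. The reason is structural: the training inputs are ideal
response vectors, so their support is at most $2^K$ distinct binary
points. Any wide early neighborhood drags the prototypes of never-winning
neurons off that support, and because those neurons never win a training
input again they are never pulled back; at test time they capture noisy
responses under labels that do not match the nearest ideal vector. Across
every schedule we measured (hard radii 1–5, Gaussian neighborhoods,
various decay spans) this cost 3–10 points of pattern accuracy, while the
winner-only limit classifies exactly like a
minimum-distance-to-ideal-vector rule — which is also the behavior implied
by the published accuracy levels this package reproduces, and consistent
with the observation that the competition-layer size has little effect.

*Initialization.* Input weights are seeded with randomly drawn training
rows (the standard SOM initialization for discrete data); uniform random
initialization is available but suffers the stranded-prototype problem
above. Output weights start uniform on $[0, 0.1]$.

*Schedules.* $\eta_1$ and $\eta_2$ decay linearly from 0.5 to 0.01 over
the total step count; values are not critical once the neighborhood choice
is fixed, and they are configurable.

*Presentation order* is a fresh seeded shuffle per iteration.

### Training sets and the collision ceiling

Training pairs each pattern's ideal response with the pattern label.
`build_training_set()` supports exact uniform stratification and
*population* weighting (patterns drawn from the copula-implied
distribution). `run_condition()` defaults to population weighting, for an
empirical reason: the three-attribute 20-item Q matrix contains no item
measuring attribute 3 alone, so patterns 000 and 001 share an identical
ideal response (`ideal_response_collisions()` enumerates this). Under
uniform training weights no classifier can exceed $7/8$ training accuracy
on that design, while under population weights the ceiling is
$1 - P(001) \approx 0.971$ — the level the trained network actually
attains, and the only reading compatible with near-perfect published
training accuracies for this design.

## Transition estimation and criteria

`estimate_transitions()` is maximum-likelihood count normalization;
never-observed origin states yield `NaN` rows rather than an invented
distribution, and an optional additive-smoothing constant exists for
sparse $64 \times 64$ pattern matrices. Pattern-level counts marginalize
*exactly* to attribute-level counts (`attribute_transitions()`), which is
tested as an invariant.

Two recovery criteria are computed side by side by
`correct_transition_rate()`:

- the **pairwise rate** — the fraction of examinees whose estimated
  (state$_t$, state$_{t+1}$) ordered pair equals the true pair. It is
  bounded above by each wave's pattern accuracy (both endpoints must be
  right) and below by the Fréchet bound
  $\text{PCCR}_t + \text{PCCR}_{t+1} - 1$;
- the **matrix score** — $1 - \overline{|A_{\text{est}} - A_{\text{true}}|}$
  over cells of occupied rows, a direct agreement measure between the
  estimated and true transition probabilities.

These answer different questions. The pairwise rate scores individual
trajectories and can never exceed per-wave classification accuracy; the
matrix score compares the estimated transition *probabilities* and can be
high even when individual classifications err, because errors cancel in
the counts. Published correct-transition values for these designs exceed
the per-wave pattern accuracies, which is only possible under the
matrix-level reading; the replication summaries in `run_condition()`
therefore report both.

Classification accuracy itself is scored by `accr()` (per-attribute
agreement) and `pccr()` (whole-pattern agreement), with
$\text{PCCR} \le \min_k \text{ACCR}_k$ always.

## Replication design and problem sizes

`run_condition()` replicates simulate → train → classify → score under one
root seed. The package's standard check sizes, chosen to estimate
stochastic quantities with standard errors around 0.01 while keeping a
full run in tens of seconds, are: $N = 500$ examinees, 10 replications,
training sets of $\max(N,\ 2^K \times 32)$ rows (the second term keeps an
average of 32 rows per pattern when the class count grows). Dispersion
across replications is reported as a standard error even though means are
the primary summary, so that stochastic comparisons have an explicit
scale.

## What the simulator does and does not emulate

The generator reproduces the study conditions it was built for: DINA
response noise, copula-correlated initial mastery, independent
per-attribute Markov transitions, and redrawn (or fixed, via fixtures)
item parameters per replication. It does **not** emulate several features
of real assessment data: item-memory effects across waves (responses are
conditionally independent given the wave's profile), covariate- or
instruction-driven transitions, polytomous items or attributes,
higher-order latent abilities driving the attributes, or model misfit
(the data are generated by the same conjunctive kernel the ideal-response
training assumes). Passing simulation checks therefore demonstrates
internal consistency of the pipeline under its own assumptions, not
robustness to violations of them.

## Known limitations

- **Incomplete Q matrices bound every classifier.** With 20 items and six
  attributes, 22 of the 64 patterns share an ideal response with another
  pattern; brute-force oracles put the best achievable wave-1 pattern
  accuracy near 0.48 (nearest-ideal) and 0.56 (Bayes-optimal with the true
  item parameters and pattern prior). The pipeline honestly reports values
  near that ceiling for the six-attribute design; higher published values
  for this condition are not attainable under these generating conditions.
- The SSOM with winner-only updates abandons topological ordering of the
  grid; the map is used purely as a classifier, and neighbors on the grid
  need not encode similar patterns.
- Transition estimation assumes aligned examinees across waves and a
  first-order chain; attrition, covariates and higher-order dependence are
  out of scope.

## A worked example

```{r example, eval = FALSE}
design <- study_design(k = 3, j = 20, n = 500, regime = "high")
res <- run_condition(design, params = cda_fixture("params_high_20"),
                     replications = 10, seed = 42)
res$accuracy %>% filter(criterion == "PCCR")
res$transition
```
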