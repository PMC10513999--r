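---
title: "Emotion episodes as binary component networks: model, dynamics, and estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emotion episodes as binary component networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emonet)
```

## The model

`emonet` treats one emotion (for one person or situation) as a network of
binary components: appraisals, feelings, motivations, physiological changes,
expressions. Component $i$ is either active or inactive, written as a spin
$s_i \in \{-1, +1\}$. Three ingredients govern the dynamics:

* **Coupling weights** $w_{ij}$ (symmetric, zero diagonal): the strength of
  the direct causal relationship between components $i$ and $j$. The average
  strength of these couplings is the network's *connectivity*; multiplying
  all weights by a factor (`scale_connectivity()`) is the connectivity
  manipulation.
* **Thresholds** $\tau_i$: the state component $i$ tends toward absent any
  input. Negative thresholds mean the component is inactive at rest. Adding a
  constant to all thresholds (`shift_thresholds()`) is the threshold
  manipulation.
* **External field** $e(t)$: an emotion-eliciting event, entering as a
  uniform addition to every threshold while it lasts.

The joint stationary distribution is the Boltzmann distribution of the
pairwise (Ising) model,

$$P(s) \propto \exp\!\Big(\beta \big(\textstyle\sum_{i<j} w_{ij} s_i s_j +
\sum_i (\tau_i + e)\, s_i\big)\Big),$$

and the dynamics are single-component Glauber updates: component $i$
resamples its state with

$$P(s_i = +1 \mid s_{-i}) =
\frac{1}{1 + \exp\!\big(-2\beta(\sum_j w_{ij} s_j + \tau_i + e)\big)}.$$

One *sweep* --- $n$ single-component updates --- is the unit of time. The
chain satisfies detailed balance, so at constant field it converges to the
Boltzmann distribution; the test suite verifies this against exact
enumeration on small networks.

**Emotion intensity** at a sweep is the fraction of active components: with
seven of ten components active, intensity is 0.7.

### Why spin coding is canonical

The same model can be written with $x_i \in \{0, 1\}$ states
("binary" coding). `convert_coding()` maps between the parametrizations
exactly ($w' = w/4$, $\tau_i' = \tau_i/2 + \sum_j w_{ij}/4$), and the
distribution over states is identical — tested to $10^{-10}$. The package
nevertheless simulates in spin coding, for a substantive reason: only in
spin coding do *inactive* neighbours actively suppress a component through
positive couplings. That mutual suppression at rest is what produces the
model's signature prediction that higher connectivity *lowers* baseline
intensity (inactive components keep each other in check) while still
prolonging episodes. Estimated networks come back in binary coding, because
nodewise logistic-regression coefficients live naturally there; convert
before comparing.

## Episodes and their duration

`simulate_network()` runs replicate trajectories under an `event_schedule()`:
a pre-event baseline window, a hold phase at full amplitude (the person is
occupied with the event), a fade back to zero, and a post-event window. The
defaults — 100 baseline sweeps, amplitude 2, 20 hold sweeps, a linear
50-sweep fade, 200 post-event sweeps, $\beta = 1$ — are the package's
reference conditions for all shipped analyses: amplitude 2 is strong enough
to activate a network whose thresholds are around $-0.4$ without saturating
the dynamics, and the fade is slow enough that the distinction between
field-driven and feedback-sustained activation is visible.

Runs start at rest. For networks of up to 20 components the initial state is
drawn exactly from the field-zero Boltzmann distribution by enumeration.
This matters in strongly coupled (bistable) networks: a uniform random start
lands in the rare high-intensity mode far more often than the stationary
distribution warrants, and no affordable burn-in corrects that, which would
bias the measured baseline.

The **end of the episode** follows the first-return-to-baseline rule: the
episode ends at the first sweep, after the event, at which the cross-run
mean intensity $m_t$ is no longer significantly larger than the pre-event
baseline, operationalized as $m_t \le \text{baseline} + k \cdot SE_t$ with
$SE_t$ the cross-run standard error. Two details are deliberate:

* $k$ defaults to 1.645 (a one-sided 5% criterion) and is configurable. A
  plotting band of $\pm 25\,SE$ is a display choice, not a decision rule,
  but the qualitative results here are robust over $k \in [1, 25]$.
* A *return* requires a prior departure: the end-scan starts at the first
  sweep where $m_t$ rises significantly *above* the baseline band. Without
  this gate, a wide band (large $k$) swallows the rising phase and declares
  the episode over before it began. A corollary is that with no event at
  all, isolated false-positive exceedances (at rate $\approx 5\%$ per sweep
  for $k = 1.645$) can open and immediately close a one-sweep "episode";
  the package reports it as such rather than pretending the detector is
  noise-free.

Duration is counted from event onset (the first hold sweep). If the mean
intensity never returns within the recording, the episode is censored;
summary helpers then use the maximum observable duration as a conservative
lower bound. Because the rule yields *one* duration per ensemble, the
uncertainty of a duration is estimated by replicating whole ensembles
(`episode_duration_stats()`), not from within one ensemble.

The decay half-life statistic (sweeps from the end of the hold until the
mean intensity first falls below the midpoint between peak and baseline)
summarises the profile shape. One caution from our own simulations: under
high connectivity, individual runs collapse abruptly but at widely different
times, so the *ensemble mean* declines slowly and the absolute half-life
grows with connectivity. The abrupt-collapse signature that is stable is the
half-life *relative to episode duration*, which shrinks as connectivity
grows. Similarly, the model's "calmer between episodes" prediction is
measured as per-run intensity variance in the baseline window; the variance
of the post-episode ensemble mean mostly reflects residual tail relaxation.

## Probable states

`exact_intensity_distribution()` enumerates all $2^n$ states (up to
$n = 20$, about $10^6$ states; log-sum-exp normalization keeps large $\beta$
or strong fields finite) and aggregates the Boltzmann probabilities by the
number of active components — the distribution of intensities one would
meet across many persons or occasions with the same network, computed at
field zero (the between-event regime). `sampled_intensity_distribution()`
estimates the same object by thinned Glauber sampling; the two must and do
agree (total-variation distance below 0.02 at the shipped problem sizes),
which is the package's standing cross-check between its sampler and its
enumerator.

`shape_statistics()` reduces a distribution to the masses below 0.2, between
0.4 and 0.6, and above 0.8, a bimodality flag, and the standardized skewness.
The two regimes of interest:

* **High connectivity** polarizes: mass accumulates at especially low *and*
  high intensities at the expense of the middle (bimodality flag).
* **High thresholds** tilt: mass concentrates at high intensities with a
  skewed tail of low-intensity states (negative skewness). This regime is
  demonstrated at a threshold shift of $+0.8$, which mirrors the fixtures'
  mean resting threshold of $-0.4$ to its positive counterpart; the $+0.4$
  shift used in the duration experiments moves thresholds only to
  neutrality, where low states still dominate the stationary distribution.

## The common-cause comparator

The alternative architecture inspired by affect-program theories — one
latent cause drives all components, components share no direct couplings —
is `common_cause_model()`, embedded for simulation as an $(n+1)$-node star
network. Because components cannot reactivate each other, activation is not
self-sustaining: episodes end when the external activation has vanished,
essentially independently of how strong the cause-component loadings are.
This is the discriminating contrast with the component network, where
doubling connectivity multiplies the episode duration several-fold.

One subtlety we report rather than hide: in the spin parametrization a
stronger loading couples each component to the (inactive) cause at rest and
thereby suppresses baseline intensity slightly — the same mechanism as the
connectivity-driven baseline suppression. Since the return-to-baseline
criterion tracks each condition's own baseline, the detected duration shifts
by a few sweeps (about 68.7 vs 73.0 under the reference conditions for
loadings 0.3 vs 1.0). Both end within a tight margin of the fade end, but
the difference is systematic, so an equivalence test at a few multiples of
the replication standard error will flag it. It is a property of any
bidirectional star embedding, not a simulation artifact; at the scale of the
network model's connectivity effect (roughly 79 vs 269 sweeps under the same
conditions) it is negligible.

## Synthetic fixtures

`make_fixture_network()` generates 10-component networks in two qualitative
regimes: `fear_like` (dense, mostly positive couplings, edge probability
0.5, weights $|N(0.30, 0.10)|$ with ~10% negative signs) whose feedback
loops can sustain activation, and `awe_like` (same topology regime, weights
$|N(0.12, 0.05)|$) with many weak relationships that cannot. Both share a
resting-threshold regime of $N(-0.4, 0.1)$: components tend to be inactive
between episodes. These are synthetic calibration constants, not empirical
estimates; they were chosen so that the two kinds *discriminate* — in
particular, the threshold regime is mild enough that doubling connectivity
produces genuine bistability (the bimodal probable-states regime) rather
than freezing the network near all-inactive, and that a threshold shift
alone does not significantly prolong awe-like episodes while the same shift
on the doubled-connectivity awe network does. With deeper thresholds (e.g.
$-0.7$) the high-intensity mode is suppressed by the resting field and both
of those qualitative contrasts disappear.

What the generator emulates: the qualitative coupling/threshold regimes of
small emotion networks and exact sampling from their stationary law. What it
does not: ordinal rating scales, measurement error, person-to-person
heterogeneity, temporal dependence within persons, or the specific empirical
awe/fear structures. Passing the shipped checks therefore demonstrates the
mechanisms on networks with known ground truth, not fidelity to any
particular data set.

## Network estimation

`estimate_network()` implements the standard nodewise procedure for binary
psychological networks (eLasso): per node, an $\ell_1$-penalized logistic
regression on all other nodes over 50 penalties log-spaced down from the
per-node maximum by $10^3$, penalty selected by EBIC with $\gamma = 0.25$
(the conventional default; $\gamma = 0$ is plain BIC), an AND rule for edge
retention, mean-of-coefficients edge weights, intercepts as thresholds.
Near-separable fits (deviance below 1% of the null, or runaway
coefficients) are flagged, with the smallest grid penalty acting as the
floor. `binarize()` prepares ordinal ratings (median split with ties going
to inactive, or a fixed cut) and refuses constant columns by name.

Recovery is validated against networks with *known* parameters via
`sample_cross_sectional()`, which draws independent observations exactly
from the enumerated stationary distribution. The shipped recovery study uses
random 10-node targets in an identifiable regime (weights $|N(0.25, 0.08)|$,
thresholds $N(-0.2, 0.2)$): at $N = 3000$ the median weight correlation is
about 0.97 with perfect median sign agreement over ten targets. The regime
matters: networks frozen near all-inactive generate almost constant data,
and no estimator recovers couplings from data without variation — a
degenerate design rather than an estimator failure, which is why such
targets are not used for the recovery benchmark.

## Numerical and design notes

* Determinism: every simulation derives per-run seeds from one master seed
  (`sim_config(seed = )`); identical configurations give bit-identical
  ensembles, including across the CLI.
* Updates are asynchronous random-sequential (each update picks a site
  uniformly at random); a fixed cyclic order is available. Synchronous
  updating is deliberately absent — it can introduce artificial oscillations.
* The enumeration limit is $n \le 20$; beyond it the exact routines refuse
  and point to the samplers. Emotion component sets (~10 items) sit well
  inside the limit.
* Reference problem sizes used by the shipped analyses: ensembles of 200
  runs, 10 replicate ensembles for duration uncertainty, 50,000-sweep
  sampling runs thinned by 10, recovery at $N \in \{500, 1500, 3000\}$.
* Ties and degenerate inputs: median-split ties go to inactive; constant
  columns are an error naming the column; a point-mass intensity
  distribution reports skewness 0 with a degenerate flag; a trajectory that
  never rises above the baseline band has duration 0 and is not censored.

## Limitations

Weights are undirected and symmetric; directed-acyclic extensions are out of
scope. Networks large enough to need sparse or parallel machinery are not
targeted. The episode detector operates on ensemble means; single-trajectory
(within-person) episode segmentation is a different problem. Fixture
constants are calibration choices for qualitative regimes, and all shipped
results are statements about those synthetic conditions.
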