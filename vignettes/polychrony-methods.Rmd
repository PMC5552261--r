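---
title: "Polychronous temporal coding in a spiking model of the auditory pathway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polychronous temporal coding in a spiking model of the auditory pathway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polychrony)
```

## The scientific question

How does auditory cortex represent complex sounds such as spoken words?
Two broad proposals compete: a *rate code*, in which stimulus identity is
carried by the average firing rates of neurons, and a *temporal code*, in
which identity is carried by precise spatio-temporal spike patterns.
`polychrony` implements a hierarchical spiking network model of the
auditory pathway in which reproducible, time-locked but non-synchronous
firing patterns — *polychronous groups* (PGs) — emerge in plastic cortical
layers through unsupervised spike-timing-dependent plasticity (STDP), and
provides the two measurement instruments needed to interrogate them: a
per-cell *polychronization index* (PI) and a decoder-based
mutual-information (MI) protocol that contrasts temporal against rate
read-outs.

## The model

### Neurons

All cells are Izhikevich point neurons integrated by forward Euler at
`dt = 0.1` ms:

$$\dot v = 0.04 v^2 + 5 v + 140 - u + I, \qquad \dot u = a(bv - u),$$

with the after-spike reset $v \ge 30\,\mathrm{mV} \Rightarrow v \leftarrow
c,\; u \leftarrow u + d$. Three presets are used: spike-frequency-adapting
excitatory cortical cells $(a,b,c,d) = (0.01, 0.2, -65, 8)$, Class-1
integrator excitatory subcortical cells $(0.02, -0.1, -55, 6)$, and
phasic-bursting inhibitory cells $(0.02, 0.25, -55, 0.05)$; the spike
cutoff is 30 mV throughout. We use a single full Euler step per `dt`
rather than the historical two-half-step variant for $v$; at this step
size the difference is far below every tolerance used here, and the
single-step form makes the engine's arithmetic identical to the exported
R-level `izh_step()`, which tests rely on. Neurons start each
presentation at the analytic rest point — the stable root of
$0.04v^2 + (5-b)v + 140 = 0$ with $u = bv$ — so presentations are
exchangeable and runs bit-reproducible. Non-finite states abort the run:
blow-up is an error, never silently clamped.

Synaptic interaction is by delta pulses: a pre-synaptic spike emitted at
$t$ through a synapse of weight $w_{ij}$ (nA, mapped 1:1 onto the
dimensionless $I$ of the membrane equation) and conduction delay
$\Delta_{ij}$ adds $w_{ij}$ to the target's current for exactly one
integration step, $\lceil \Delta_{ij}/dt \rceil$ steps after emission
(zero-delay synapses deliver on the next step — same-step delivery would
be acausal in a synchronous update).

### Architecture

The **full model** chains seven populations: auditory nerve (AN, input) →
cochlear nucleus subpopulations — choppers (CH, Gaussian tonotopic
afferents, $\sigma = 26$ fibres, weights 25–30 nA), primary-like cells
(PL, one-to-one, 1000 nA) and onset cells (ON, sparse afferents with a
0.46 dead-synapse fraction, 26 nA) — → inferior colliculus (IC; CH
$\sigma = 2$ at 400 nA, PL one-to-one at 400 nA, ON full at 3 nA) → A1 →
Belt. Only the IC→A1 and A1→Belt projections are plastic: full
connectivity, initial weights uniform in [30, 35] nA, conduction delays
uniform in [0, 50] ms. The **reduced model** deletes CN and IC and wires
AN→A1→Belt with the same plastic machinery but stronger depression
(`alpha_d = -0.033` instead of `-0.015`). Within each layer (except AN,
CH, PL, which have none that acts), every excitatory cell drives one
inhibitory partner (1000 nA) and every inhibitory cell inhibits all
excitatory cells (−75 nA in ON, −6 nA in cortex). Gaussian connectivity
is realised as Bernoulli draws with probability
$\exp(-(i - j_{\text{aligned}})^2 / 2\sigma^2)$ (peak 1, truncated at the
array edges); a Gaussian *weight* profile was the alternative reading,
rejected so that the scalar weights above keep their meaning. The text's
alternative "34 % connectivity" reading of the AN→ON sparsity is exposed
as the `p_dead` override.

### Plasticity

The mixed nearest-neighbour STDP rule operates on *arrival* times
($t_j + \Delta_{ij}$), with

$$f(s) = \begin{cases} \alpha_p e^{-s/\tau_p}, & s > 0 \text{ (LTP)}\\
\alpha_d e^{s/\tau_d}, & s < 0 \text{ (LTD)} \end{cases} \qquad
w' = \begin{cases} w + (w_{\max} - w) f(s), & s > 0\\
\max(0,\; w + w_{\max} f(s)), & s < 0 \end{cases}$$

with $\tau_p = 15$ ms, $\tau_d = 25$ ms, $\alpha_p = 0.005$,
$\alpha_d = -0.015$ (or $-0.033$), $w_{\max} = 60$ nA. LTP is
multiplicative in the remaining headroom (soft ceiling), LTD additive
with a hard floor at zero. Because $|\alpha_d|\tau_d = 0.375 >
\alpha_p\tau_p = 0.075$, uncorrelated activity depresses on average —
the mechanism that lets a neuron carve a repeating pattern out of noise.

Pairing bookkeeping ("nearest only"): each post-synaptic spike pairs for
LTP with the most recent unused arrival on each afferent synapse; each
arrival pairs for LTD with the most recent post-synaptic spike; an
arrival is usable for at most one LTP pairing. The first-spike-only rule
is implemented with a blanking window at the STDP time-constant scale,
$\max(\tau_p, \tau_d) = 25$ ms: a further spike of the same cell arriving
within the blanking window of the previous counted arrival is ignored by
the plasticity calculations entirely (its current is still delivered).
This suppresses within-burst multiple pairings while keeping the LTP
candidate *recent* — we found that anchoring the exclusion window to the
last post-synaptic spike instead leaves the LTP candidate stale (tens of
milliseconds old on average at ordinary rates, where
$e^{-s/\tau_p} \approx 0$) and makes potentiation unable to compete with
depression anywhere, which contradicts the intended behaviour of the
rule. Exact ties ($s = 0$ at step resolution) are no-ops. Pairings with
$|s| > 7\max(\tau_p,\tau_d)$ are skipped (scale below $10^{-3}\alpha$).
Updates are applied online at pairing time; pairing ledgers, currents and
neuron states are cleared at presentation onsets (the 100 ms silences
exist to segment words; resetting makes presentations exchangeable).

Whether the first-spike-only restriction also binds the post-synaptic
side is unstated in the sources the rule descends from; we implement the
symmetric nearest-neighbour reading above.

## Synthetic auditory-nerve input

The package replaces the cochlear front end with a generative surrogate
capturing the statistics the learning mechanisms actually consume:

* **Volley structure.** Spikes cluster into near-synchronous volleys at
  glottal-pulse times of a fundamental (default `f0_hz = 100`, spike
  placement SD 1 ms around its pulse). Voiced speech drives the auditory
  nerve this way, and the pulse structure is what the onset pathway
  phase-locks to and what delay lines convert into learnable
  coincidences.
* **Spectral envelope.** A few strongly driven tonotopic bands (default
  4 bands, SD 4 % of the array, peak-to-floor contrast 25) over a sparse
  floor; most fibres fire sparsely, band fibres strongly — the formant
  picture. With `band_share = 1` (default) the envelope is identical
  across classes: the raster analogue of the loudness normalisation
  applied to real stimuli, which confines class identity to *which
  fibres fire on which pulses*, i.e. to the temporal code under study.
  Smaller `band_share` gives classes private bands, as distinct words
  have, and deliberately re-introduces rate information.
* **Pronunciation manifold.** A speaker is a latent position
  $\lambda \in [0,1]$: the fundamental scales by
  $1 + 0.15(\lambda - \tfrac12)$, each pulse carries a smooth per-pulse
  warp (SD 4 ms per unit $\lambda$), each event a fibre drift (±3
  fibres). Densely sampled $\lambda$ gives strongly overlapping
  neighbouring exemplars — the continuous-transformation constraint under
  which Hebbian learning binds within-class variants. Held-out
  "pronunciations" shift every $\lambda$ by a small offset.
* **Noise.** Per-spike deletion (default 0.1), truncated-Gaussian
  temporal jitter (default SD 1 ms), spatial jitter to a uniformly chosen
  fibre within ±1 (the volley principle), and additive background Poisson
  firing (default 5 Hz/fibre). The defaults sit inside the ranges the
  single-neuron mechanism is known to tolerate (jitter of a few ms,
  additive noise up to 10 Hz, loss of up to half the pattern spikes).

Mean driven rate defaults to 40 Hz per fibre (band peaks near 150 Hz,
floor a few Hz) — medium-rate fibres under a moderately loud stimulus.
What the generator does *not* model: cochlear filtering, refractoriness,
adaptation, phase-locking roll-off with frequency, and realistic
across-fibre correlations. Tests passing on this surrogate show the
mechanisms operate under the assumed statistics, not that the model
reproduces responses to real speech.

A second generator, `masquelier_stream()`, produces the classical
single-neuron benchmark: a continuous Poisson stream over 200 afferents
in which a frozen 40 ms pattern recurs in a quarter of the time segments,
statistically identical in rate to the background.

## Measurement instruments

### Polychronization index

For cell $j$ and each presentation where it fires, one of its spikes is
sampled uniformly (fresh draw per call, seeded) and the spikes of all
cells are binned at 1 ms into the ±50 ms window around it (the window
matches the maximum conduction delay; edges are zero-padded). Averaging
these matrices over the exemplars of a class, $a_s^j$ is the mean of the
ten largest elements (the centre element is excluded; ties break by
count, then lag, then cell) divided by $f$, the layer's mean spike count
per cell per 1 ms bin pooled over the analysed presentations — making
$a_s^j$ dimensionless and $\mathrm{PI}^j = \max_s a_s^j \to 1$ for
structureless (Poisson) firing as exemplars accumulate. Presentations
where $j$ is silent are skipped and counted. $f$ is pooled across
classes, and the ten maxima are not constrained to distinct cells (both
choices are unstated in the protocol's description; pooling keeps the
denominator estimable from few exemplars per class).

### Information protocol

*Temporal code*: sample $J$ cells (100 at reference scale); for each
sampled reference cell build the window matrix above restricted to the
$J$ sampled rows and reduce it to row sums ($J$ values) and column sums
(101 values) — $J + 101$ features per presentation (201 at reference
scale). One small MLP per reference cell (single hidden layer of 10 % of
the feature dimension — 20 units at reference scale — saturating hidden
units, cross-entropy objective, weight decay $10^{-3}$) is trained on a
stratified 50/50 presentation split; the ensemble predicts by majority
vote, silent reference cells abstain, ties go to the first class.
*Rate code*: one MLP on the mean firing rates of $J$ sampled cells (201
at reference scale). The confusion matrix over held-out presentations is
normalised per actual class into a joint table with uniform priors;
mutual information follows from the plug-in formula with $0\log 0 = 0$,
bounded by $H(S) = 1$ bit for two equiprobable classes, with first-order
sampling bias $\#\text{bins}/(2N\ln 2)$ — about 0.004 bits at the
reference test-set size of 752 presentations, and reported alongside
every estimate. The optimiser behind the decoders is treated as
incidental (any convergent gradient method); `nnet`'s quasi-Newton
fitting is used. Fresh cell subsamples are drawn on every repetition.

## The desk-scale comparison study

`comparison_study()` is the package's end-to-end experiment. Its
defaults are the study conditions; they were fixed once, for the reasons
below, and define what the acceptance checks measure.

* **Population sizes**: subcortical chain at half reference size (500 AN
  fibres), cortex at 300 cells per population. Full connectivity imposes
  no size matching between IC and cortex, so the subcortical chain can
  stay wide while the cortex shrinks; this preserves the per-cell
  afferent counts (hence drive) that the fixed nA weights assume. At
  uniform small scales the cortical drive collapses below threshold as
  soon as depression begins, which the reference-scale model — with 1000
  afferents per cortical cell — does not do.
* **Exposure**: two interleaved training passes over 6 speakers × 2
  classes, then evaluation on 4 fresh realisations of offset
  pronunciations. LTD dominance depresses the actively driven synapses at
  a rate set by the (fixed) learning magnitudes and the input statistics;
  at this scale the network passes through its operating range — weight
  mass shifted down, strengthened tail formed, cortex still responsive —
  within the first passes, and longer exposure only silences the smaller
  cortex. The exposure is therefore a scale parameter of the study, not a
  claim about the reference protocol (ten passes, which
  `experiment_config()` keeps as its default).
* **Decoding scale**: 15 reference cells per temporal subsample, 60 rate
  cells, one subsample per condition, 80 optimiser iterations. At these
  test-set sizes the MI estimator noise is of the same order as the
  cortical information itself; medians over ten seeds are reported, and
  the small-sample bias (identical across conditions) is left in.

Known limitations, stated plainly. The scaled study robustly reproduces
the *mechanistic* results: the PI elevation from subcortical denoising
(every seed), the LTD-dominated weight redistribution with a
strengthened tail under patterned input and full collapse under
patternless input (every seed), and the advantage of the full over the
reduced architecture in cortical temporal information. The finer
decoder-MI orderings (temporal versus rate within a layer; trained
versus untrained or shuffled controls) are *not* resolved at this
scale: per-seed estimates differ by a few thousandths of a bit while
the estimator's sampling noise at ~50-presentation test sets is an
order of magnitude larger, so their median comparisons are effectively
coin flips — the corresponding acceptance tests state the orderings and
are allowed to fail. A permutation diagnostic on full binned population
vectors does show the trained cortex carrying stronger normalised class
structure than the untrained one, so the limitation is the resolution of
the windowed-marginal decoding protocol at desk scale, not the absence
of learning. The onset pathway, starved at reduced afferent counts,
also contributes little of the fundamental-locking it provides at
reference scale.

## Numerical and design notes

* Determinism: every stochastic stage takes an explicit seed; nested
  stages derive sub-seeds via a counter-based hash (`sub_seed()`), so
  adding a stage never perturbs earlier draws. Two runs from the same
  seeds are bit-identical.
* Delay buffers are per-projection rings of synapse indices; weights are
  read at *arrival* time, so a weight updated while a spike is in flight
  delivers its updated value.
* The engine is ~400 lines of C++ (via Rcpp) implementing exactly the
  semantics of the exported R primitives `izh_step()`, `stdp_scale()`,
  `stdp_apply()` and `stdp_pair()`; tests cross-check the two routes on
  micro-networks (single synapses and driver-forced post spikes) to
  $10^{-10}$ nA.
* Degenerate inputs: empty rasters propagate to empty outputs; a silent
  reference cell skips (PI) or abstains (decoding); a silent layer is an
  error for PI (its normaliser is zero) and single-class labels are an
  error for decoding.

## Reproducing the study

```{r, eval = FALSE}
st <- comparison_study(n_seeds = 10, master_seed = 1)
print(st)    # per-seed table; medians summarise the orderings
```

`scripts/acceptance.R` runs the same computation (plus the analytic
information values and the single-neuron benchmark) and writes a flat
JSON summary.
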