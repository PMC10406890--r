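---
title: "Reverse engineering generative models from neuronal ensemble responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse engineering generative models from neuronal ensemble responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fepnet)
```

# The paradigm and the model

`fepnet` models a blind source separation experiment on cultured neuronal
networks. Two binary hidden sources $s = (s_1, s_2)$ are drawn
independently each trial from categorical priors with ON expectation
$D_1$ (so $D_1 + D_0 = 1$). They generate 32 binary stimuli through a
likelihood (mixing) tensor $A$: for mixing fraction $m$, the ON
probability of a left-group input over the joint states
$(1,1), (1,0), (0,1), (0,0)$ is $(1,\, 1-m,\, m,\, 0)$ and of a
right-group input $(1,\, m,\, 1-m,\, 0)$. The standard condition is
$m = 0.25$; $m = 0$ is the unmixed (separable) limit and $m = 0.5$ the
uniformly mixed (unidentifiable) limit. There are no state transitions
and no actions: each trial is an independent draw, which is what makes
the per-trial mean-field treatment below exact in structure.

Two complementary formulations of the learner are implemented, and their
equivalence is what the package exploits.

**Ideal Bayesian observer.** Beliefs factorise into categorical state
posteriors and a Dirichlet posterior over $A$. Per trial,
$\mathbf{s}_t = \sigma(\ln\mathbf{A} \cdot o_t + \ln D)$ with both
observation levels entering the evidence ($o$ and $1-o$);
$\mathbf{a} \leftarrow \mathbf{a} + o_t \otimes \mathbf{s}_t$, adding one
unit of mass per input per trial; and
$\ln\mathbf{A} = \psi(\mathbf{a}) - \psi(\mathbf{a}_1 + \mathbf{a}_0)$.
The variational free energy of the state beliefs is
$F = \sum_\tau \mathbf{s}_\tau \cdot (\ln\mathbf{s}_\tau -
\ln\mathbf{A}\cdot o_\tau - \ln D)$; the parameter-complexity term of
order $\ln t$ is constant in the states and omitted throughout, so all
reported differences across sessions are unaffected.

**Canonical neural network.** Two rate-coded ensembles obey
$\dot{x} \propto -\mathrm{sig}^{-1}(x) + W o + h$ with
$W = W_1 - W_0$ and thresholds
$h_l = \ln(\overline{\widehat{W}_l})\vec{1} + \phi_l$, where
$\widehat{W}_l = \mathrm{sig}(W_l)$. Integrating the right-hand side
gives a cost $L$ whose response gradient reproduces the dynamics and
whose weight gradient is a Hebbian rule with an activity-dependent
homeostatic term,
$\dot{W}_1 \propto \langle x o^\mathsf{T}\rangle -
\langle x \rangle \odot \widehat{W}_1$. Solving the plasticity fixed
point yields
$W_1 = \mathrm{sig}^{-1}(\langle x o^\mathsf{T}\rangle \oslash
\langle x \rangle)$ and its $W_0$ mirror with $\bar{x} = 1 - x$.
Under the correspondence
$(x; \bar{x}) \leftrightarrow \mathbf{s}$,
$\mathrm{sig}(W_l) \leftrightarrow \mathbf{A}_{1l}$,
$\phi \leftrightarrow \ln D$, the cost $L$ equals $F$ exactly on the
time-sum (the package's test suite checks this equality to $10^{-9}$
nats by constructing the joint likelihood additively over the two
factors).

The two formulations are deliberately not identical computations: the
observer's likelihood is the full joint tensor over the four source
states, so inferring one source *explains away* evidence about the
other, while the network is the per-factor marginal model in which each
ensemble sees the stimuli independently. Their trajectories correlate at
about $r = 0.9$ on matched runs; the package treats the network as the
model of tissue and the observer as the normative reference.

Reverse engineering inverts the correspondence on data: threshold
factors are estimated as $\phi = \ln \langle (x_t; \bar{x}_t) \rangle$
over an initial window (default 10 sessions), so the implicit prior
$\hat{D} = e^{\phi_1}$ satisfies $e^{\phi_1} + e^{\phi_0} = 1$ exactly;
effective connectivity is the plasticity fixed point of cumulative
statistics through each session; and prediction iterates
$x^P_t = \mathrm{sig}(W^P o_t + h^P)$ with
$h^P = \ln(\overline{\widehat{W}^P_1})\vec{1} -
\ln(\overline{\widehat{W}^P_0})\vec{1} + \phi_1 - \phi_0$ and the
fixed-point weight update on *predicted* statistics, never touching
empirical responses after the initial window (a property the tests
check bitwise).

# Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `n_sessions`, `trials_per_session` | 100, 256 | — | training protocol; each session replays one fixed 256-trial sequence |
| `mix_fraction` | 0.25 | probability | source mixing; 0 separable, 0.5 unidentifiable |
| `d1` (state prior) | 0.5 | probability | generative ON expectation per source |
| `lambda_w` | 2560 | trials-equivalent | inverse learning rate: evidential mass anchoring weights at their initial value; 2560 equals the 10-session window's weight |
| `n_init_sessions` | 10 | sessions | reverse-engineering / prediction window |
| `clip_eps` | 1e-3 | probability | co-activation ratio clip before the logit, keeping weights finite under deterministic coupling |
| `magnitude`, `jitter_sd`, `structure_tilt` (Dirichlet prior) | 1, 0.01, 0.1 | — | prior mass per cell, its random jitter, and the basin-selecting tilt (below) |
| `sigma`, `structure_tilt` (weights) | 0.01, 0.03 | logit | random and structured components of the initial connectivity |

The inverse learning rate maps to the Dirichlet prior strength
($\lambda^W \odot \widehat{W}^{\mathrm{init}} \leftrightarrow a_1$), so
2560 — the evidential weight of the 10-session initialisation window —
is used both for prediction and as the plasticity damping of the
synthetic tissue, making latent learning gradual over tens of sessions
rather than jumping to the fixed point after one session.

# Degenerate optima and the structured initialisation

Mean-field source separation in this model family has two exact
degeneracies and one rugged feature, all of which shaped defaults:

* **Permutation/inversion symmetry.** Which latent factor binds to which
  source, and whether a factor codes a source or its complement, is
  undetermined by the data. Evaluation therefore aligns recovered
  sources to the truth by correlation (`align_sources()`), standard in
  source-separation work.
* **The global-activity attractor.** From any neutral initialisation
  (flat or randomly jittered), the fastest-growing unstable mode of
  both formulations is the *global* mode — both factors encode total
  stimulation — which is a self-consistent local minimum of $F$ with
  markedly higher free energy than the separating solution, yet
  unreachable-from by local dynamics once entered. We verified this
  numerically (online and batch, across seeds) and by fixed-point
  algebra. Real cultures do not start neutral: pre-existing
  connectivity biases decide each network's basin. The package
  therefore gives initialisations a weak structured tilt — left inputs
  toward latent 1, right inputs toward latent 2, plus (for the network)
  a small excitatory bias selecting upright coding. The tilt's
  evidential mass is negligible (a fraction of one trial per Dirichlet
  cell; about 0.015 in sigmoid space per weight), so learned *values*
  come from the data; the tilt only chooses among the degenerate
  solutions. Setting `structure_tilt = 0` reproduces the collapse.
* **Coordinate-ascent corner commitment.** Iterating the two per-source
  softmax updates from an uninformative start lets the conjunction
  states' extreme likelihoods dominate the first update, committing
  mixed trials to the wrong corner roughly half the time. The solver
  instead starts from the exact four-state joint posterior's marginals
  (enumeration over four states is trivial) and then iterates; when the
  exact posterior factorises, the result equals it, which the tests
  check against brute-force enumeration.

# The synthetic recordings

`generate_recording()` emulates the statistical structure of evoked MEA
responses, not their biophysics. A latent canonical network (threshold
factors set by condition) supplies two source-coding trajectories;
electrodes are assigned to source-1, source-2 or no-preference groups
(default 44 electrodes at fractions 0.39/0.34/0.27, matching reported
counts of 17.1/15.0/11.5); counts are negative binomial (size 20)
around `baseline + gain * latent + session trend`, with lognormal
per-electrode heterogeneity (sd 0.2 for baselines, 0.4 for gains —
real electrodes vary widely in evoked-response strength). No-preference
electrodes are driven directly by a small random subset of stimulation
channels, emulating the directly evoked response component; with the
fixed repeated stimulus sequence this gives them reproducible,
sequence-locked response patterns, as in real recordings. Baselines per
condition (1.5 control, 1.8 bicuculline, 1.2 diazepam) put grand means
near the observed 3.0/3.7/2.3 spikes per trial.

Condition mapping: bicuculline (GABA$_A$ antagonist, hyper-excitable)
sets the latent prior expectation to 0.8; diazepam (agonist,
hypo-excitable) to 0.2; APV (NMDA-receptor antagonist) keeps the control
prior but multiplies the inverse learning rate twenty-fold — slowed but
nonzero plasticity; `mix0` and `mix50` change the stimulus mixing.

Preprocessing follows the recording conventions: electrodes averaging
$\le 1$ spike/trial are excluded; the preference statistic is the
all-session average of $E[r\,|\,(1,0)] - E[r\,|\,(0,1)]$ with a strict
$\pm 0.5$ spike/trial rule (ties are no-preference); group-averaged
series are detrended by a linear fit of session means against session
number (drift only — the all-session offset survives, so
condition-related excitability shifts remain visible to the threshold
estimator); and normalisation maps the OFF-state and ON-state evoked
*response levels* — means of the lower and upper 20% tails — to 0 and 1,
clipped to $[10^{-3}, 1-10^{-3}]$. Tail means rather than extreme
quantiles matter here: count noise variance grows with the mean, so a
1st/99th-percentile min–max systematically biases the normalised mean
downward (by roughly 0.06 at control settings), while cluster-centre
levels keep the recovered prior faithful without forcing it (a biased
prior condition still maps to a shifted mean, as it must for the
pharmacology analysis).

What the generator does **not** emulate: spike waveforms, detection and
sorting; the 10–30 ms counting window (counts are generated directly at
trial resolution); electrode geometry; non-stationarities beyond a
linear trend; and cross-electrode correlated noise. Passing tests on
this generator therefore show that the estimators and predictions are
correct *given* the assumed response structure — they cannot certify
robustness to, e.g., bursting artefacts or electrode crosstalk in real
recordings.

# Metrics and operationalisations

* Likelihood error: per conditioning-source-level column,
  $\|\hat{A} - A\|^2 / \|A\|^2$, against the ideal marginal
  conditionals implied by the generative process (for the control
  design, $P(o_\mathrm{left}=1 \mid s_1=1) = 0.875$, etc.).
* Weight prediction error: squared error between predicted and
  estimated $(\widehat{W}_1, \widehat{W}_0)$ over the squared Frobenius
  norm of the estimate, in sigmoid space.
* Response prediction error: $err = E[|x_t - x^P_t|^2]/2$ per session;
  "proportion predicted" is $1 - err/0.5$, the complement against the
  worst case on the unit box.
* Response specificity: ON-minus-OFF mean response for the preferred
  source. Two readings are reported: the change from session 1 (the
  learning curve) and the final-session raw difference. Condition
  comparisons use the raw final difference: in vitro the two coincide
  because session-1 cultures are unspecialised, whereas the synthetic
  tissue's structured initialisation gives balanced controls a small
  session-1 head start that the change metric would subtract away.
  Under uniform mixing the raw difference remains nonzero through
  global stimulation-count coding; the source-separation readout there
  is the left/right differential structure of the likelihood beliefs,
  which is zero.
* Empirical free energy: the cost $L$ of each session's observed
  responses under that session's estimated connectivity, reported as
  change from session 1. On noisy recordings it drops steeply over the
  first ~10 sessions and then fluctuates (about $\pm 50$ nats around a
  $\sim 1000$-nat drop), so monotonicity is asserted strictly only for
  the noiseless network cost; recordings are checked for a
  non-increasing block trend within the plateau's sampling noise.
* Free-energy landscape: projected onto the mean effective weights from
  left-group and right-group inputs onto ensemble 1 (other entries held
  at a base estimate), with responses at their fixed point per grid
  node. The projection is this package's reconstruction — the original
  2-D embedding is not published — and is symmetric in its two
  coordinates for balanced designs, which the tests verify.

# Numerical choices

Responses are clamped to $[10^{-12}, 1-10^{-12}]$ at the sigmoid fixed
point (a saturated drive would otherwise round to exactly 0/1 and make
the leak term infinite); probabilities inside logarithms are floored at
$10^{-8}$ with the $0\ln 0 = 0$ convention for entropies; co-activation
ratios are clipped at $10^{-3}$ before the logit; Euler integration of
the rate dynamics uses step 0.1 (the dynamics' time constant is not
empirically constrained — only the fixed point matters at session
resolution, and the fixed-point shortcut is the default path). The
observer's per-trial likelihood refresh is the default; a vectorised
per-session schedule gives near-identical results (recovered likelihood
within ~1.5 percentage points) at a fraction of the cost and is used for
multi-seed experiments.

# Known limitations

Mean-field inference here is a local scheme: basin selection is supplied
by initial structure, not discovered, and the package makes that
explicit rather than hiding it. Threshold-mismatch sensitivity is
asymmetric — with anchored closed-loop prediction, the minimum-error
threshold can sit slightly off the generating one, so prediction error
is guaranteed to degrade only at the worst-case mismatch, not
monotonically in each direction. The synthetic generator's realism
boundaries are listed above; headline numbers reproduced on it are
scaled-down stand-ins for in vitro results, not re-analyses of the
original recordings (which are available externally but not required).

# Session info

```{r}
sessionInfo()
```
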