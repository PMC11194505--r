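---
title: "Synapse-type-specific competitive Hebbian learning: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synapse-type-specific competitive Hebbian learning: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hebbnet)
```

## The model

`hebbnet` simulates recurrent networks of excitatory (E) and inhibitory (I)
rate neurons that receive structured input from a feedforward population (F)
and whose synapses are shaped by Hebbian plasticity stabilized by the
competition for limited, synapse-type-specific synaptic resources.

**Dynamics.** Membrane potentials follow leaky rate dynamics

$$\tau_A \dot u_A = -u_A + W_{AF}\, r_F + W_{AE}\, r_E - W_{AI}\, r_I,
\qquad A \in \{E, I\},$$

with rates given by a rectified power law
$r_A = f(u_A) = a\,[u_A - b]_+^{\,n}$.  The six weight matrices $W_{AB}$
(postsynaptic population first) are non-negative; inhibition acts through
the explicit minus sign, so Dale's law holds by construction.  The equations
are integrated with the explicit Euler scheme in steps of $\Delta t$, with
the drive evaluated at the pre-step rates.

**Plasticity.** Every plastic block follows the plain Hebbian rate rule
$\dot W_{AB} = \epsilon_{AB}\, r_A r_B^\top$, discretized as
$\Delta W = \Delta t\, \epsilon\, r_A r_B^\top$ (the learning rates are
specified in ms$^{-1}$, so the Euler factor applies).  After every
integration step each postsynaptic neuron's weights are divisively
renormalized within two separate resource pools:

* the *excitatory pool*: its recurrent excitatory row plus its plastic
  feedforward row, rescaled so their joint sum equals the excitatory norm
  $W_{AE}$;
* the *inhibitory pool*: its inhibitory row, rescaled to the inhibitory
  norm $W_{AI}$.

This L1 (plain-sum) form of the normalization follows the discrete update
rule of the model family; a synapse can only grow at the expense of other
synapses drawing on the same pool, and excitatory and inhibitory synapses
never compete with each other.  Static feedforward blocks are normalized
once per row at setup and are excluded from the excitatory pool thereafter.

For comparison, the package also implements the classic homeostatic
inhibitory rule $\dot w_{EI} = \epsilon_{EI}(r_E - r_0)\, r_I$, applied
*without* normalization; entries driven negative are clipped at zero, a
case the continuous rule leaves unspecified.

**Input model.** Input neurons are orientation tuned: a grating of
orientation $\theta$ and contrast $c$ elicits
$r_F = c\, A_F \exp(-|\theta, \theta_F|^2 / 2\sigma_F^2)$, where
$|\cdot,\cdot|$ is the circular distance on the 180° orientation ring and
the preferred orientations $\theta_F$ tile $[0°, 180°)$ evenly.  During
training, single gratings with i.i.d. uniform orientations are each
presented for 200 ms.  Compound stimuli (plaids) superpose additively at
the input stage; this is the minimal composition rule that keeps the
single-grating expression as its special case, and it matters for the
interpretation of masking experiments: any sublinearity of the *network*
response to a plaid is then attributable to recurrent dynamics, not to the
input model.

## The linear theory module

For linear activation, the isolated feedforward circuit's fixed points
("input modes") are eigenvectors of the *uncentered* input second moment
$C = \langle y_E y_E^\top \rangle$ — the module deliberately implements the
uncentered form; center the ensemble first if you want covariance proper.
With paired excitatory and inhibitory input streams the joint weight drift
is governed by the modified covariance matrix

$$\bar C = \begin{pmatrix} \langle y_E y_E^\top\rangle & -\langle y_E y_I^\top\rangle \\
\langle y_I y_E^\top\rangle & -\langle y_I y_I^\top\rangle \end{pmatrix},
\qquad
\langle \dot{\bar w}\rangle \propto \bar C \bar w -
\begin{pmatrix}\gamma\, w_E \\ \rho\, w_I\end{pmatrix}.$$

The normalization multipliers $\gamma, \rho$ are realized as the block-wise
mean Hebbian drive divided by the block's total weight — the unique scalars
for which the drift sums to zero within each block, i.e. for which the L1
norms maintained by the discrete rule are preserved under the flow.  When
$y_I$ is clamped to $y_E$, every block of $\bar C$ is a signed copy of $C$
and proportional weight vectors aligned with an eigenvector of $C$ are
fixed points: stimulus selectivity and E–I balance develop jointly.

Recurrently connected neurons tuned to the same mode form an
*eigencircuit* whose members modify the mode's effective attraction
$\bar\lambda = \lambda + \sum_i \sigma^2_{E,i} - \sum_j \sigma^2_{I,j}$:
excitatory rate variances attract, inhibitory rate variances repel.  The
collapse of all tunings onto one mode is prevented exactly when
$N_E \sigma_E^2 < N_I \sigma_I^2$ (strict inequality; the boundary case is
reported as not prevented).  Degenerate leading eigenvalues in
`principal_eigenvector()` are flagged, not silently resolved.

## Parameters and presets

`hebbnet_config()` bundles the standard parameter sets as presets (see its
help page for the list).  The tunable parameters that matter most:

| parameter | meaning | units | typical values |
|---|---|---|---|
| `tau_E`, `tau_I` | membrane time constants | ms | 12.5–200 |
| `dt` | Euler step | ms | 10–200 |
| `a`, `b`, `n` | activation gain, threshold, exponent | — | 0.04, 0, 2 |
| `eps_*` | Hebbian learning rates | ms⁻¹ | 10⁻¹⁰–10⁻⁴ |
| `W_EE` … `W_II` | resource-pool norms | — | 0.3–10 |
| `sigma_F`, `A_F` | input tuning width, peak rate | deg, rate | 12–20°, 1–140 |
| `contrast` | training contrast | — | 0.5–1 |

Sub-population variants (e.g. the two network sizes of the decorrelation
experiment) are separate presets (`recurrent_small`, `recurrent_large`);
the bracketed parameters of the microcircuit presets configure the
statically tuned lateral neurons (their own gain, tuning width and
feedforward norm).

## Numerical choices

* **Update order.** Within one step: integrate the dynamics, apply the
  Hebbian increments using the *new* rates, re-zero the autapse diagonals,
  then renormalize.  The exported operations `euler_step()` and
  `competitive_plasticity_step()` are the reference semantics; the fused
  training loop is tested to reproduce them bitwise.
* **Autapses** (diagonals of $W_{EE}$, $W_{II}$) are excluded by default: a
  Hebbian autapse is a pure self-amplification term and the model family's
  circuit diagrams show none.  The flag `exclude_autapses` exposes the
  choice, and the fully plastic recurrent presets (`recurrent_small`,
  `recurrent_large`) *include* autapses.  The reason is the eigencircuit
  theory itself: a mode's attraction sums the rate variances of *all* its
  member neurons, including each neuron's own — and in circuit terms that
  self-term is exactly the Hebbian autapse.  Without it a lone neuron has
  no anchor on its own mode and existing clusters slowly swallow the
  population (excitatory uniformity decays monotonically and tunings merge
  into a band); with it the excitatory uniformity follows the expected
  U-shape — a clustering transient, then inhibition-driven recovery — and
  the tunings tile the ring.
* **No membrane reset between stimuli.** Transients decay within a few
  $\tau$, which is short against every training protocol; potentials start
  at zero at $t = 0$ only.
* **Zero rows.** A row whose pooled weight is zero carries no resource and
  is left untouched by the normalization (with a warning in the exported
  operations; silently during training, where rows that have not yet
  received Hebbian mass are expected).
* **Initialization.** Weights are drawn $\mathcal N(\mu_W, \sigma_W)$ with
  $\mu_W = 2\sigma_W$ in all presets, negatives replaced by their absolute
  value, then normalized once.  In the presets with plastic feedforward
  weights, all recurrent excitatory-origin blocks ($W_{EE}$ *and* $W_{IE}$;
  configurable) start at zero so the untrained network is feedforward
  dominated; they grow inside pools whose feedforward part keeps the sum
  positive.  In the presets with *static* feedforward weights the recurrent
  weights are the pool's only members, and a zero-initialized pool is
  singular under divisive normalization: the first Hebbian increment would
  be inflated instantly to the full norm, a violent rank-one connectivity
  jump that reproducibly destabilizes the supralinear dynamics under
  independent center/surround statistics.  These presets therefore start
  from random *normalized* recurrent weights (`zero_recurrent_E = "none"`).
* **Divergence guard.** The integrator aborts with an error of class
  `hebbnet_divergence` naming the stimulus and step once any $|u|$ exceeds
  $10^6$ or becomes non-finite.
* **Preferred orientations** are measured as the argmax of the steady-state
  response (20 $\tau_E$ settling) on a 1° probe grid at contrast 1 by
  default; ties break toward the smallest angle.  Connectivity profiles use
  18 bins of 10° over $[-90°, 90°)$ and normalize by the block's largest
  weight; empty bins are `NA`.
* **Semi-saturation contrast** is the first contrast at which a
  contrast-response curve reaches half of its maximum, linearly
  interpolated between grid points.
* **Probe contrasts stay at or below the training contrast** for the
  strongly recurrent (static-feedforward) networks: after training at 50%
  contrast these circuits supersaturate — the steady-state excitatory
  response peaks near the training contrast and then *declines*, reaching
  near zero at 100% contrast (a genuine stable state, independent of
  settling time and of ramped versus step stimulus onset).  Contrast-response
  and surround-suppression probes therefore use grids within `[0, 0.5]` and
  a center stimulus at contrast 0.5.
* **Compiled inner loop.** The training loop is implemented in C++
  (RcppArmadillo) and advances chunks of stimulus presentations between
  snapshot/convergence events; it reproduces the exported R operations
  ([euler_step()], [competitive_plasticity_step()]) to machine precision,
  which the test suite asserts.

## The synthetic-data generator

All inputs are generated internally; the package's fixtures
(`make_fixture()`, `collapse_regime_config()`) construct miniature
configurations with analytically known structure:

* `two_channel_pca` draws a non-negative two-channel Gaussian ensemble with
  its mean along the construction axis and a 4:1 variance anisotropy, so
  the axis is exactly the principal eigenvector of the population's
  uncentered second moment (the mean contributes only along the axis).
  Rectification at zero clips rare negative excursions.
* `paired_ei_pca` feeds the same ensemble to a mirrored inhibitory input
  stream ($y_I = y_E$), the configuration whose balanced fixed point the
  linear theory predicts.
* `collapse_regime_config()` builds linear-activation networks driven by
  near-one-hot patterns over six channels (so the input modes are
  essentially the channels themselves, with slightly unequal amplitudes
  making one mode the most attractive).  A small common baseline keeps
  every channel weakly co-active — with strictly one-hot patterns a fully
  committed weight vector would be an absorbing state that no Hebbian
  input can ever leave, a degeneracy ruled out by the overlap of realistic
  tuning curves.  The `"collapse"` regime has no inhibition, so the
  excitatory variance term necessarily dominates; the `"prevented"` regime
  couples six excitatory to twelve fully plastic inhibitory neurons whose
  pooled rate variance outweighs the excitatory one, with weak I-to-I
  suppression so that inhibition repels committed excitatory neurons
  without silencing them.  The condition itself is re-evaluated from
  *measured* steady-state rate variances of the *untrained* network: the
  inequality governs the stability of the uniform configuration (that is
  where the perturbation argument applies), whereas the final variances of
  a successfully distributed network are dominated by each neuron's
  committed response and say nothing about the transition.

What the generator emulates is the *statistical structure* of oriented
inputs — smooth unimodal population profiles, uniform orientation
statistics, correlated or independent region statistics.  What it does not
emulate: pixel-level images and spatial receptive fields, input noise
(the dynamics are deterministic given the stimulus sequence), temporally
correlated stimulus sequences, and the developmental timeline of real
circuits.  Tests passing on these inputs show that the learning rules have
the claimed fixed-point and self-organization behavior under the stated
input statistics, not that the model reproduces any particular biological
dataset.

## Training lengths and problem sizes

The underlying study does not state training durations, so runs are
convergence-monitored: training stops once the largest relative weight
change per 100 stimuli falls below `tol_convergence` (default $10^{-4}$ of
the block norm), with `n_stimuli` as a hard cap chosen per preset.  The
learning rates of the recurrent presets are small, and full restructuring
of recurrent connectivity (the decay of cross-orientation weights toward
zero) is one to two orders of magnitude slower than the initial formation
of tuned receptive fields.  The preset caps are: 2000 presentations for the
single-neuron circuit (converged), 240k for the small decorrelation network
(the uniformity recovery completes and the preferred orientations tile the
ring around 220k presentations), 5000 for the masking network and 16k for
the center/surround networks (the stages at which tuned recurrent structure
and the suppression order relations are established).  The excitatory
uniformity of the decorrelation experiment is non-monotonic by design — an
initial clustering transient precedes the inhibition-driven recovery — and
the inhibitory population stays near-uniform throughout, which is itself
one of the model's claims.

Two consequences of these timescales are worth knowing.  First, the
cross-orientation floor of the recurrent excitatory block decays very
slowly, and because stimuli switch without a membrane reset, region
switches under independent center/surround statistics leave a few
membrane-time-constants of genuine cross-region co-activity on every
trial; cross-region weights therefore decay toward a positive floor rather
than to zero on any practical timescale.  Second, at reachable training
stages a weak cross-oriented mask can slightly *facilitate* low-contrast
test responses through that same residual cross-orientation excitation,
so the rightward shift of the contrast-response function is robust for
strong masks but not guaranteed for weak ones.

## Known limitations

* Purely rate-based and deterministic: no spiking, no synaptic delays, no
  noise terms.
* The linear theory module is exact only for linear activation; with the
  supralinear activation used in simulations it is a guide, not an oracle.
* Divisive normalization is implemented in its discrete per-step form; the
  continuous-time limit is only approximated when rates or learning rates
  are large.
* Training to full asymptotic connectivity structure at the reference
  learning rates is computationally long; see the section above for how
  the package handles intermediate stages.
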