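# hebbnet

Simulates the self-organization of recurrent networks of excitatory (E) and
inhibitory (I) rate neurons in which *every* synapse follows a Hebbian rule
stabilized by competition for a limited pool of synaptic resources — with
excitatory and inhibitory synapses drawing on *separate* pools
(synapse-type-specific competition).  The package is for computational
neuroscientists who want to study how structured cortical connectivity —
stimulus-selective, inhibition-balanced receptive fields, assembly-like
recurrent structure, response normalization and surround suppression — can
emerge from a single unsupervised plasticity principle, without hand-tuned
connectivity.

## The model

Membrane potentials of the recurrent populations follow leaky rate dynamics

    tau_A du_A/dt = -u_A + W_AF rF + W_AE rE - W_AI rI,   A in {E, I}

with a rectified power-law rate function `r = a [u - b]_+^n`, integrated by
the explicit Euler method in steps of `dt`.  Plastic weights follow the
Hebbian rule `dW_AB/dt = eps_AB r_A r_B^T` and, in sync at every
integration step, each neuron's weights are divisively renormalized within
two separate resource pools: its pooled excitatory inputs (recurrent E +
plastic feedforward) to the norm `W_AE`, and its inhibitory inputs to the
norm `W_AI`.  Inputs are orientation-tuned:
`rF = c A_F exp(-|theta, theta_F|^2 / 2 sigma_F^2)` for a grating of
orientation `theta` and contrast `c`.

A companion linear-theory module implements the fixed-point analysis: the
uncentered input second moment `C = <y y^T>`, the modified covariance
`Cbar = [[<yE yE^T>, -<yE yI^T>], [<yI yE^T>, -<yI yI^T>]]` whose
eigenvectors give the balanced fixed points, the eigencircuit attraction
`lambda_eff = lambda + sum(var_E) - sum(var_I)`, and the tuning-collapse
condition `NE sigma_E^2 < NI sigma_I^2`.

## Worked example

Train the single-neuron circuit: one excitatory neuron receiving plastic
excitatory input from 10 orientation-tuned channels and plastic disynaptic
inhibition from input-mirroring inhibitory units, 2000 gratings of uniform
random orientation, 200 ms each:

```r
library(hebbnet)
fit <- hebbnet("single_neuron", seed = 1)
summary(fit)
#> Trained competitive Hebbian E-I network ('single_neuron')
#>   populations: NE = 1, NI = 10, NF = 10
#>   plasticity rule: competitive
#>   stimuli presented: 2000
#>   feedforward tuning uniformity: U_E = 0.8259, U_I = 0.993
#>   resource-pool conservation residual: 1.78e-16
#>   mean excitatory training rate: 1.804
round(drop(coef(fit, "W_EF")), 2)
#>  [1] 1.32 0.54 0.15 0.05 0.11 0.37 0.98 1.86 2.44 2.18
round(drop(coef(fit, "W_EI")), 2)
#>  [1] 0.63 0.23 0.06 0.02 0.05 0.18 0.48 0.96 1.28 1.12
cor(drop(coef(fit, "W_EF")), drop(coef(fit, "W_EI")))
#> [1] 0.9990...
```

Reading the output: the excitatory weight profile over the input channels
(preferred orientations 0°, 18°, …, 162°) has become unimodal — the neuron
is now orientation selective, peaking near 144° — while the total
excitatory weight stays exactly at its resource norm (conservation residual
at machine precision).  The inhibitory profile has the same shape
(correlation 0.999) at its own norm: stimulus selectivity and E–I balance
developed *jointly*, which is precisely what the classic target-rate
inhibitory rule cannot do (`hebbnet("single_neuron_classic")` yields a
near-uniform excitatory profile, U_E > 0.99, with the mean rate pinned at
the target).

Other entry points: `hebbnet_config()` / `load_config()` for presets and
YAML experiment files, `predict()` for steady-state probe responses,
`preferred_orientations()`, `connectivity_vs_delta_theta()`,
`tuning_uniformity()`, `suppression_curves()` and `contrast_response()` for
the analysis metrics, `make_fixture()` and `collapse_regime_config()` for
the analytically tractable miniature experiments, and
`inst/scripts/hebbnet-cli.R` for a shell interface.  The methods vignette
(`vignettes/competitive-hebbian-learning.Rmd`) documents the model,
numerical choices and design decisions.

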