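# somnet

A thalamo-cortical spiking-network model of how deep-sleep-like slow
oscillations reorganise recently learned memories.  The package is for
computational neuroscientists who want a compact, fully scriptable
implementation of the sleep-consolidation loop: unsupervised training of a
spiking network on visual feature vectors, induction of Up/Down slow
oscillations, and measurement of what the sleep period did to the synaptic
matrix, the internal representation and classification performance.

## The model

Four all-to-all connected populations of adaptive exponential
integrate-and-fire (AdEx) neurons with conductance-based alpha synapses:
excitatory cortex `cx` (20 neurons per trained image), inhibitory cortex
`in`, thalamic relay `tc` (one cell per feature bit), reticular `re`.
Membrane dynamics

$$\dot V = -\tfrac{V-E_l}{\tau_m} + \tfrac{\Delta_V}{\tau_m}
  e^{(V-\theta)/\Delta_V} + \tfrac{I_{syn} - W}{C},\qquad
 \tau_W \dot W = a(V-E_l) - W,$$

with spike emission at $V_{spike}=\theta+5\Delta_V$, reset, and a
spike-triggered adaptation increment $b$.  Three projections
(`cx->cx`, `cx->tc`, `tc->cx`) are plastic under multiplicative STDP,

$$\Delta w = \lambda\,(w^{max}-w)\,e^{-|\Delta t|/\tau}
 \ \ (\text{pre}\to\text{post}),\qquad
 \Delta w = -\alpha\lambda\,w\,e^{-|\Delta t|/\tau}
 \ \ (\text{post}\to\text{pre}),$$

symmetric ($\alpha=1$) during training, depression-dominated ($\alpha=3$)
during sleep.  Images are encoded as 324-bit one-hot-blocked feature
vectors (a 28x28 histogram-of-oriented-gradients code: 9 cells x 9
orientation bins x 4 quantisation levels); during training each image's
feature drive coincides with a private contextual facilitation of its
cortical group, so only the conjunction fires, and one presentation carves
the group's engram.  Sleep is induced by raising spike-frequency
adaptation ($b = 60$ pA), weakening cortical inhibition, and driving the
cortex with non-specific 700 Hz Poisson noise; Up states then replay
learned patterns, the cortico-thalamo-cortical loop recruits groups with
similar thalamic codes, and depression-biased STDP simultaneously
down-scales the strongest synapses (differential synaptic homeostasis).

## Worked example

```r
library(somnet)

rep <- run_full_protocol(somnet_config(seed = 24, sleep_s = 200,
                                       n_holdout = 0))
glance(rep)
#> # A tibble: 1 x 9
#>    seed n_images n_classes thalamic_feedback awake_control sleep_s so_hz ...
#> 1    24        9         3 TRUE              FALSE             200  1.33 ...

report_block_stats(rep)
#> # A tibble: 3 x 5
#>   category      mean_pre mean_post ratio     n
#> 1 same_instance    67.1      49.9  0.744  3420
#> 2 same_class        1.00      1.70 1.70   7200
#> 3 cross_class       1.00      1.31 1.31  21600
```

The network was trained once on 9 synthetic patterns (3 classes x 3
instances), slept 200 s under slow oscillations (`so_hz` 1.33 Hz), and its
recurrent weight matrix shows the signature the analysis battery is built
around: synapses inside one image's engram down-scaled (ratio 0.74 < 1),
synapses between different images of the same class strengthened (1.70)
well above those between classes (1.31).  Re-running with
`thalamic_feedback = FALSE` ablates the cortico-thalamic prediction
pathway and the same-class/cross-class separation disappears;
`awake_control = TRUE` replaces sleep by wake-parameter asynchronous
activity.  `plot_raster(rep$net$log$sleep$raster)`, `autoplot(rep)` and
`plot_block_stats()` visualise the phases.

A command-line interface wrapping the same protocol is installed at
`system.file("cli", "somnet-cli", package = "somnet")` with subcommands
`full-run` and `analyze`.

## Package layout

* `build_network()`, `apply_phase()`, `set_thalamic_feedback()` -- network
  construction and phase schedules
* `run_training()`, `run_retrieval()`, `run_sleep()`,
  `run_awake_control()`, `classify_images()`, `run_full_protocol()` -- the
  experimental protocol
* `compute_hog()`, `binarize()`, `features_to_drive()` -- visual input
  encoding; `make_synth_set()`, `make_toy_images()` -- synthetic data
* `detect_up_states()`, `so_frequency()`, `weight_block_stats()`,
  `population_correlations()`, `rate_change_analysis()`, `accuracy()` --
  the analysis battery
* `stdp_allpairs()` -- brute-force plasticity oracle used by the tests
* `tidy()`/`glance()`/`autoplot()` methods on protocol reports

See the vignette (`vignettes/somnet-methods.Rmd`) for the full account of
the model, every constant's provenance, and known limitations.
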