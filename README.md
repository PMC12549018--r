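# brainfluid

Whole-brain network simulation and the complexity metrics of consciousness
research, in one package: a delayed, noise-driven network of
Montbrió–Pazó–Roxin neural masses coupled by a structural connectome, a
simulated perturbational-complexity protocol (sPCI), and the resting-state
metric battery — fluidity of dynamic functional connectivity, Lempel–Ziv
complexity, neuronal-avalanche functional repertoires with branching
ratios, and the global activation potential (GAP) — together with an EEG
bootstrap pipeline, synthetic connectome/EEG generators, parameter-plane
sweeps, and single-feature linear classification.

## The science in brief

Each brain region is the exact mean field of quadratic
integrate-and-fire neurons,

$$\dot r = \Delta/\pi + 2rv, \qquad
  \dot v = v^2 + \bar\eta + Jr + I(t) - (\pi r)^2,$$

with $\bar\eta=-5$, $\Delta=1$, $J=15$: a bistable unit with a quiet
downstate and an oscillatory upstate. Regions couple through delayed
firing rates, $I_n = G\sum_m W_{nm} r_m(t-\tau_{nm})$, where $G$ is the
global coupling. Sweeping $G$ at fixed noise reveals three regimes: sparse
and quiet (low $G$), a stable locked coactivation pattern (high $G$), and
in between a *fluid* working point where coactivation cascades of varying
size come and go. At that working point, and only there, a single-pulse
stimulus can create (or destroy) complexity — the simulated analogue of
the perturbational complexity index — and the resting-state metrics all
peak. The same metric battery, applied to EEG, separates wakeful from
anesthetized brain states.

## A worked example

```r
library(brainfluid)

cn <- generate_synthetic_connectome(84, seed = 1)
cn
#> connectome: 84 regions (68 cortical), 2273 edges, density 0.65
#>   weights: max 1.64, mean node strength 2

eq <- stationary_states(nmm_params())
eq
#>            r          v         type stable
#> 1 0.08113444 -1.9616200  stable-node   TRUE
#> 2 0.47298034 -0.3364938       saddle  FALSE
#> 3 1.03059680 -0.1544299 stable-focus   TRUE
```

The isolated mass has a low-firing stable downstate (r ≈ 0.081), a saddle,
and a high-firing upstate focus (r ≈ 1.031). Simulate 20 s of spontaneous
activity at the working point and quantify it:

```r
cfg <- sim_config(g = 0.55, sigma_noise = 0.036, dt = 0.05,
                  duration = 20000, record_dt = 10, init = "random",
                  seed = 7)
sim <- simulate_network(cn, config = cfg)

fluidity_of(sim$r, fs = 100, fc_window_spec(3, 1, "pearson"))
#> [1] 0.0004279727

raster <- binarize_rates(sim$r)       # upstate raster, threshold r > 0.7
functional_repertoire_sim(raster)     # distinct network states
#> [1] 1992
cascade_profile(sim)$auc              # coactivation cascading, z * s
#> [1] 3.876786
```

One stimulation trial against its seed-matched baseline:

```r
stim <- stimulus_spec(node = 5, onset = 5000)   # 10 ms, amplitude 5
spci_trial(cn, nmm_params(), cfg, stim)
#> spci_result: node 5 at t=5000 ms, stim 0.410 / baseline 0.411 = ratio 0.998
```

Synthetic EEG through the resting-state pipeline:

```r
wake <- generate_synthetic_eeg(60, 256, 60, "wake-like", seed = 1)
anes <- generate_synthetic_eeg(60, 256, 60, "anesthesia-like", seed = 1001,
                               condition = "anesthesia", drug = "propofol")
tab <- metric_table(list(preprocess_eeg(wake), preprocess_eeg(anes)),
                    n_boot = 10)
subset(tab, segment_id == "full")[, c("condition", "fluidity", "repertoire")]
#>     condition fluidity repertoire
#>  wakefulness    0.0444        162
#>   anesthesia    0.0310         31
```

(Numbers above are from the stated seeds; regenerate them with the same
calls.)

## Layout

* `R/connectome.R` — load/validate/normalize connectomes; modular
  synthetic-connectome generator with working-point calibration
* `R/simulator.R` — the delayed stochastic network integrator (Rcpp core
  in `src/montbrio.cpp`) and fixed-point analysis
* `R/complexity.R` — binarization, LZ76 (`src/lz76.cpp`), normalized
  complexity, the sPCI trial/protocol, cascade profiles
* `R/fluidity.R` — windowed FC (Pearson/circular), dFC, fluidity
* `R/events.R` — avalanches, branching ratios, repertoires, GAP
* `R/eeg.R` — filtering, bootstrap segmentation, metric tables, the
  synthetic-EEG generator
* `R/sweep.R` — (G, σ) sweeps with replayable manifests
* `R/classify.R` — single-feature linear classification
* `vignettes/brainfluid-methods.Rmd` — models, calibrations, and design
  decisions

The methods vignette documents every numerical choice (noise convention,
taming, recording, calibration constants) and the limits of what the
synthetic generators can show.
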