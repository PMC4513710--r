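# plvnet

Functional brain networks from multichannel EEG via time-frequency phase
synchrony.

Swallowing, motor and cognitive EEG studies increasingly ask not *where*
activity occurs but *how regions coordinate*. plvnet implements a complete
analysis chain for that question on non-stationary signals, where
correlation- and coherence-style estimators are unreliable:

1. **Signal conditioning** — Fourier resampling to 256 Hz, zero-phase
   elliptic band-pass (0.1–100 Hz) and power-line notch (58–62 Hz),
   decomposition into the Delta/Theta/Alpha/Beta/Gamma bands, fixed-length
   epoch extraction around annotated events.
2. **Phase synchrony** — a reduced-interference Rihaczek time-frequency
   distribution with a Choi–Williams kernel,
   `C(t,ω) = ∬ exp(−(θτ)²/σ) exp(jθτ/2) A(θ,τ) exp(−j(θt+τω)) dτ dθ`,
   gives each channel a time-varying phase; the phase-locking value across
   N trials, `PLV(t,ω) = |N⁻¹ Σₖ exp(jΦ₁₂ᵏ(t,ω))| ∈ [0,1]`, scores the
   stability of each channel pair's phase difference and fills a
   per-band connectivity matrix.
3. **Networks** — density thresholding (5–100 % in 5 % steps, deterministic
   tie-breaks) yields binary undirected graphs; degree, clustering `C`,
   characteristic path length `L` and local efficiency are computed, and
   small-worldness `S = (C/C_random)/(L/L_random)` is evaluated against 100
   degree-preserving Markov-chain null networks (`S > 1` = small-world).
4. **Statistics** — per (band × density × metric) cell, a first-principles
   Wilcoxon rank-sum test (exact enumeration for small tie-free samples)
   compares conditions, e.g. neutral vs chin-tuck swallowing.

A synthetic coupled-oscillator generator with analytic ground truth (von
Mises phase jitter, population PLV `I₁(κ)/I₀(κ)`) and reference graph
constructions make every stage testable without clinical data.

## Worked example

```r
library(plvnet)

# channels 1-2 tightly coupled (kappa = 8), 1-3 loosely (kappa = 2),
# channel 4 independent; 30 trials of 2 s at 256 Hz
spec <- coupling_spec(data.frame(i = c(1, 1), j = c(2, 3),
                                 kappa = c(8, 2), freq_hz = 10))
ds <- gen_phase_locked_trials(spec, n_channels = 4, n_trials = 30, seed = 42)
round(ds$ground_truth_plv, 3)
#>       [,1]  [,2]  [,3]  [,4]
#> [1,] 1.000 0.935 0.698 0.162
#> [2,] 0.935 1.000 0.653 0.162
#> [3,] 0.698 0.653 1.000 0.162
#> [4,] 0.162 0.162 0.162 1.000

conn <- pairwise_connectivity(as_epoch_set(ds, band = "Alpha"))
round(conn$weights, 3)
#>       ch01  ch02  ch03  ch04
#> ch01 0.000 0.928 0.694 0.028
#> ch02 0.928 0.000 0.643 0.091
#> ch03 0.694 0.643 0.000 0.062
#> ch04 0.028 0.091 0.062 0.000
```

The estimated Alpha-band PLV matrix reproduces the ground truth: 0.928 vs
0.935 for the strong pair, 0.694 vs 0.698 for the weak pair, 0.653 vs the
path product 0.653 for the indirectly coupled pair, and chance-floor
values (the expected resultant of 30 uniform phasors is 0.162) for the
independent channel.

```r
ws <- gen_ws_smallworld(64, 8, 0.1, seed = 1)       # rewired ring lattice
sw <- small_worldness(ws, null_ensemble(ws, n_random = 100, seed = 2))
sw
#> Small-worldness vs 100 nulls: C = 0.5554 (C_rand 0.1040), L = 3.0045 (L_rand 2.1867)
#>   gamma = 5.339, lambda = 1.374, S = 3.886

rank_sum_test(c(3.1, 2.7, 3.4), c(4.2, 4.8, 3.9))$p_value   # exact: 2/20
#> [1] 0.1
```

`S = 3.886 > 1`: the rewired lattice keeps lattice-like clustering (γ ≈
5.3) at near-random path lengths (λ ≈ 1.4) — the small-world signature.

`run_pipeline(run_config(...))` chains everything (synthetic or CSV+JSON
recordings plus annotation CSVs), persists every stage's artifacts as
TSV/CSV/JSON and writes a checksummed manifest; `inst/cli/plvnet.R` is a
thin command-line wrapper with `simulate`/`connectivity`/`networks`/
`metrics`/`compare`/`run-all` subcommands.  See the vignette
(`vignettes/phase-synchrony-networks.Rmd`) for the model, parameter and
convention details.

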