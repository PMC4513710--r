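---
title: "Time-frequency phase synchrony brain networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-frequency phase synchrony brain networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

plvnet builds functional brain networks from multichannel EEG in five
stages: signal conditioning, time-frequency phase synchrony estimation,
density thresholding, graph analysis against degree-preserving null
ensembles, and nonparametric condition comparison.  This vignette explains
the model behind each stage, the tunable parameters and their defaults, the
numerical choices, and what the synthetic validation battery does and does
not demonstrate.

## Signal conditioning

Recordings (channels x samples, microvolts) are resampled to 256 Hz on the
Fourier grid — an ideal brick-wall anti-alias low-pass followed by
decimation, so a band-limited tone survives with its amplitude intact —
then band-pass filtered 0.1–100 Hz and notch filtered 58–62 Hz with
order-4 elliptic IIR designs (0.5 dB passband ripple, 40 dB stopband
attenuation; both configurable).

Zero-phase filtering deserves a note.  The conventional forward–backward
(`filtfilt`) recursion realizes the squared magnitude response
$|H(\omega)|^2$ only up to edge transients, and the broadband high-pass
edge at 0.1 Hz of a 256 Hz design places poles at radius 0.9997, whose
transients decay over tens of thousands of samples.  plvnet therefore
applies $|H(\omega)|^2$ of the elliptic design directly on the Fourier
grid: this is the exact transfer function of forward–backward filtering,
is exactly time-reversal symmetric, and its realized response is what the
test suite measures (`filter_response_db()`).  The price is circular
boundary handling, which is immaterial for the multi-second continuous
records filtered here.

Band decomposition uses the canonical bands Delta 0.1–4, Theta 4–7, Alpha
8–15, Beta 16–31, Gamma 32–100 Hz.  The Delta lower edge and Gamma upper
edge are tied to the broadband filter limits.  A direct order-4 elliptic
band-pass is numerically unstable for Delta at 256 Hz (pole radius > 1);
the design routine checks pole radii and falls back to a high-pass +
low-pass elliptic cascade for such bands.

Epochs are fixed-length windows (default 2 s) centred on each annotated
swallow midpoint, because trial-averaged phase locking requires
equal-length trials; band filtering is applied to the continuous record
before epoching to avoid filter transients inside short epochs.  Windows
exceeding the recording bounds are dropped with a warning.  The reference
electrode carries no information relative to itself and is excluded from
connectivity in the pipeline.  An optional peak-amplitude epoch-rejection
hook (`reject_epochs_by_amplitude()`, off by default) stands in for manual
artifact screening, which cannot be reproduced automatically.

## The reduced-interference Rihaczek distribution

For each channel and trial, the complex time-frequency distribution is
computed through the ambiguity domain.  Writing $A(\theta,\tau)$ for the
ambiguity function of the analytic signal, the distribution is

$$C(t,\omega) = \iint e^{-(\theta\tau)^2/\sigma}\, e^{j\theta\tau/2}\,
A(\theta,\tau)\, e^{-j(\theta t + \tau\omega)}\, d\tau\, d\theta ,$$

the Rihaczek distribution smoothed by a Choi–Williams kernel that
suppresses cross-terms between signal components.  Discretely, the lag
products $x(t)\,x^*(t-\tau)$ on an $n$-point circular grid are Fourier
transformed over $t$, multiplied by the kernel
($\theta \in [-\pi,\pi)$ rad/sample, $\tau$ in samples), and transformed
to $(t,\omega)$.  Because both kernels equal 1 on the $\theta = 0$ and
$\tau = 0$ axes, the discrete time marginal
$\sum_\omega C(t,\omega) = |s_a(t)|^2$ holds exactly, and a tone at a bin
frequency stays confined to its bin.

**Phase carriage.**  Any bilinear auto-distribution is invariant under a
constant phase shift of its signal — the quadratic products cancel it — so
the argument of $C$ alone cannot express the channel's absolute phase,
while phase locking across trials is defined through exactly that phase.
The grid returned by `rid_rihaczek()` therefore stores the distribution
modulated by the analytic signal's unit phasor
$e^{j\arg s_a(t)}$: its magnitude (and the modulus of its time marginal)
is the reduced-interference distribution, and its argument carries the
instantaneous phase of the amplitude/phase decomposition
$a(t)e^{j(\omega t + \phi(t))}$.  Normalized cross products of two such
grids recover inter-channel phase differences — including constant offsets,
which a pure energy distribution would silently discard — and shifting one
channel's phase by a constant shifts the phase difference uniformly,
leaving the PLV invariant.

Parameters: the Choi–Williams $\sigma$ defaults to 0.01 (strong cross-term
suppression; the recovery battery passes for $\sigma \in \{0.005, 0.01,
0.05\}$); the frequency grid defaults to the epoch length ($n_{fft} = n$),
because zero-padding spreads the ambiguity support and destroys the exact
bin-concentration and marginal identities (padding remains available via
`rid_params(n_fft = ...)`); the analytic pre-transform is on by default to
suppress negative-frequency terms.

## Phase differences and the phase-locking value

The phase difference of two grids is
$\Phi_{12}(t,\omega) = \arg\left[C_1 C_2^* / (|C_1||C_2|)\right] \in
(-\pi,\pi]$.  Points where either magnitude falls below $10^{-10}$ times
its grid maximum are flagged undefined: the argument of a near-zero
complex number is numerical noise.  Across $N$ trials,

$$\mathrm{PLV}(t,\omega) = \frac{1}{N}\left|\sum_{k=1}^{N}
e^{j\Phi_{12}^k(t,\omega)}\right| \in [0,1],$$

with undefined points excluded per trial and the defined-trial count
reported.  A single trial gives the degenerate PLV of 1 (warned about);
$N$ independent uniform phase differences give the chance floor
$\sqrt{\pi}/(2\sqrt{N})$ in expectation.

**Scalar edge weight.**  The reduction of $\mathrm{PLV}(t,\omega)$ to one
number per channel pair is the least constrained choice in the chain, so
it is isolated in one place (`pairwise_connectivity(reduce = )`).  The
grid is restricted to the central 80 % of time samples (edge guard) and
the frequency bins inside the band of interest.  A plain mean over those
bins is dominated by bins that carry only noise — their phases are
uniform, pulling every weight toward the chance floor regardless of the
true coupling — so the default weights each point's PLV by the trial-mean
cross magnitude $|C_1||C_2|$, i.e. the phase locking of the band's
energy-carrying components.  Plain mean, median and max remain available.
Locking ratios other than 1:1 are out of scope.

Two conventions are deliberate decisions where the field leaves room: PLV
is computed per subject (its $N$ is that subject's trial count) and
subjects are the statistical unit downstream; and the time–frequency
reduction is a (weighted) mean rather than a median or maximum.  Both are
configurable.

## Networks, graph measures and small-worldness

Weighted matrices are binarized by connection density: at density $d$ %,
the $k = \mathrm{round}(d/100 \cdot M)$ strongest of the $M = N(N-1)/2$
upper-triangle weights become edges (half-up rounding, documented so other
implementations can match edge counts exactly).  Ties are broken by
descending weight then ascending index pair, making the networks
deterministic and invariant under any strictly monotone transform of the
weights.  The ladder runs 5–100 % in 5 % steps; its edge sets are nested
by construction.  A density that rounds to zero edges is rejected.

Measures (all on binary undirected graphs): mean degree; clustering
$C_i = 2E_i / (D_i(D_i-1))$ with $C_i = 0$ for degree $\le 1$ (the 0/0
convention keeping the all-node mean defined); characteristic path length
with per-node means over *reachable* pairs only and the unreachable-pair
count reported alongside — disconnection is inevitable at 5 % density, and
one auditable rule beats silently switching conventions (note that under
this convention adding an edge can *raise* the mean by connecting a
distant pair, so sparse-density path lengths must be read together with
the unreachable counts); local efficiency as the mean inverse distance
within each node's neighbour-induced subgraph, unreachable pairs
contributing zero and nodes with fewer than two neighbours contributing
zero.

Null ensembles preserve the degree sequence exactly by Markov-chain
double-edge swaps — pick edges $(a,b), (c,d)$ with four distinct
endpoints and no existing $(a,d)$ or $(c,b)$, rewire — with a budget of
$10\times|E|$ attempted swaps per network (configurable).  Small-worldness
uses the ensemble means: $\gamma = C / C_{rand}$,
$\lambda = L / L_{rand}$, $S = \gamma/\lambda$, with $S > 1$ read as
small-world organization.  Graphs with no legal swap (e.g. complete
graphs) yield an ensemble of copies and $S = 1$, with a warning; ensembles
with zero clustering make $S$ undefined and raise a classed error.

## Condition comparison

The Wilcoxon rank-sum test is implemented from first principles: midranks;
exact enumeration of all $\binom{n}{n_1}$ rank assignments when
$n \le 12$ without ties (doubled smaller tail, capped at 1); otherwise the
normal approximation with tie correction and 0.5 continuity correction.
Identical pooled samples return $p = 1$ with a degeneracy flag.  One test
is run per (band, density, metric) cell containing both conditions, at
$\alpha = 0.05$ uncorrected — deliberately mirroring the uncorrected
analysis style of the study design this pipeline targets; a
Benjamini–Hochberg column is available but off by default, and the
multiplicity caveat stands.

## The synthetic generator

`gen_phase_locked_trials()` produces unit-amplitude sinusoidal carriers
plus white Gaussian noise (default sd 0.1, i.e. roughly 20 dB carrier SNR
— a clean but realistic band-limited oscillation), 256 Hz, default 2 s
trials.  Within a trial each channel's carrier phase is constant; a
coupled pair shares its phase up to a von Mises offset with concentration
$\kappa$, chosen because its population PLV has the closed form
$I_1(\kappa)/I_0(\kappa)$ — an analytic recovery target.  Couplings may
form a forest; the ground-truth PLV between channels joined by a path is
the product of the per-edge Bessel ratios (independent increments), and
unlinked channels carry independent uniform phases with the finite-$N$
chance floor as their expected sample PLV.

By default the $N$ offsets of a coupled pair are the von Mises quantiles
at $(k - 0.5)/N$, in random order, rather than i.i.d. draws.  The
generator exists to deliver trial sets whose *realized* coupling embodies
the nominal $\kappa$: with i.i.d. draws the sample resultant of 30 phasors
has a standard deviation of roughly 0.02–0.11 across $\kappa$, so a
recovery check against the closed form would largely measure von Mises
sampling noise instead of estimator error.  Stratified sampling removes
that variance while keeping the marginal distribution; `jitter_sampling =
"iid"` restores independent draws, and $\kappa = 0$ pairs are treated as
uncoupled (i.i.d. uniform), matching the chance-floor analysis.

Reference graphs — ring lattices (closed-form clustering
$3(k-2)/(4(k-1))$), Watts–Strogatz-style rewired lattices (edge count
preserved; rewiring here is *not* degree-preserving, that role belongs to
the null model), and Erdős–Rényi graphs — give the graph stage fixtures
with known values.

What the generator does **not** emulate: volume conduction and common
reference leakage, 1/f background spectra, within-trial phase drift,
nonstationary amplitude envelopes, artifacts, or realistic electrode
geometry.  Passing the validation battery therefore demonstrates that the
estimator chain recovers known phase locking under controlled conditions,
not that real EEG effects of comparable size are detectable — on real
data, volume conduction alone can produce spurious zero-lag locking that
this pipeline, like any undirected PLV analysis, does not remove.

## Problem sizes and determinism

The test battery uses 2–4 channel, 0.5–2 s epochs at 256 Hz, up to 30
trials and 64-node graphs with ensembles of 50–100 nulls; the type-I
calibration uses 1000 replicate null grids.  These sizes keep the full
suite in a few minutes while leaving every scientific claim at the scale
it was stated.  All randomness is seeded: generators and the null
ensemble take explicit seeds, and `run_pipeline()` derives per-stage seeds
from one master seed, records them in every output, and writes a manifest
with MD5 checksums — identical configurations yield identical manifests.

## Known limitations

Input is a CSV matrix + JSON sidecar (and annotation CSVs); EDF files
should be converted upstream.  PLV per subject assumes the subject's
trials are exchangeable; the per-swallow mode exists but inflates the
effective sample.  The energy-weighted reduction assumes the band's
energy-carrying component is the one whose locking matters; for broadband
coupling a plain mean may be preferable.  Path lengths at 5–15 % density
average over few reachable pairs and should be interpreted with the
reported unreachable counts.
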