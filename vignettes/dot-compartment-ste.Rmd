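---
title: "Quantifying isotropically restricted water with spherical tensor encoding at high b"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying isotropically restricted water with spherical tensor encoding at high b}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stedot)
```

## The signal model

Each tissue compartment is, at the level of this analysis, a water pool
with a signal fraction $f_i$ and a diffusion behaviour. For a Gaussian
pool with diffusion tensor $\mathbf{D}_i$ probed by an encoding tensor
$\mathbf{B}$,

$$S_i(\mathbf{B}) = S(0)\, f_i \exp(-\mathrm{Tr}(\mathbf{B}\mathbf{D}_i)),$$

and the total signal is the sum over non-exchanging pools. The B-tensor
is characterised by its trace $b$ (the b-value) and anisotropy
$b_\Delta = (b_\parallel - b_\perp)/(b_\parallel + 2 b_\perp)$: linear
encoding (LTE) has $b_\Delta = 1$, spherical encoding (STE) $b_\Delta = 0$.
For STE the trace collapses every Gaussian pool to its mean diffusivity
$\bar D_i = \mathrm{Tr}(\mathbf{D}_i)/3$:

$$S(b) = S(0) \sum_i f_i e^{-b \bar D_i}.$$

This is the core identity the method rests on: orientation and
anisotropy drop out exactly (`signal_gaussian()` is tested for rotation
invariance at the $10^{-12}$ level), so at high $b$ the only surviving
signal comes from pools whose diffusion is slow *in every direction*.
A dot compartment ($\bar D = 0$) would leave a plateau
$f_\mathrm{dot} \approx S(b)/S(0)$; a slowly diffusing isotropic pool
leaves a shallow mono-exponential

$$S(b) \approx S(0) f_1 e^{-b D_1}, \qquad b > b_s .$$

The estimation stage fits exactly this representation and nothing more:
working where the other compartments are compressed avoids committing to
a full multi-compartment model of them.

Units are chosen so that $b\,D$ is order one: $b$ in ms/µm²
(1 ms/µm² = 1000 s/mm²), diffusivities in µm²/ms, times in ms, gradients
in mT/m with $\gamma = 267.513$ rad·ms⁻¹·mT⁻¹·m. External tables use
s/mm² and are converted only at the I/O boundary.

## The estimation pipeline

`run_analysis()` executes, per voxel:

1. **Rician debiasing** of every volume:
   $\hat S = \mathrm{sign}(M^2 - 2\sigma^2)\sqrt{|M^2 - 2\sigma^2|}$,
   with $\sigma$ the per-channel Gaussian noise standard deviation
   (so $E[M^2] = S^2 + 2\sigma^2$ and the rectified floor is
   $\sigma\sqrt{\pi/2}$). The signed output is kept — clipping at zero
   would re-introduce exactly the floor bias the step removes.
2. **Shell averaging**: arithmetic mean per unique (b, TE).
3. **$\tilde S(0)$** by log-linear extrapolation from the two lowest
   non-zero shells (250 and 1500 s/mm²), which deliberately suppresses
   CSF: a fast pool bends the low-b log-signal downwards, so the
   extrapolation undershoots the measured b0. The estimator sits behind
   one function (`estimate_s0_lowb()`) so alternatives can be swapped in.
4. **$\tilde f_\mathrm{dot}$** = mean debiased signal at the highest
   shell divided by $\tilde S(0)$; negative values are reported as such.
5. **High-b fit** of $A e^{-bD_1}$ to shells with $b > b_s$
   (default 10 000 s/mm², i.e. shells 10 500–15 000, strictly greater).
   Only $A = S(0)f_1$ is identifiable from high-b data alone, so the fit
   estimates $(A, D_1)$ and reports $\tilde f_1 = A/\tilde S(0)$
   afterwards. With four TEs, a joint fit of
   $C e^{-TE/T_{2,1}} e^{-bD_1}$ adds $T_{2,1}$.
6. **ROI summary**: voxel-wise medians and 10–90 percentiles (linear
   interpolation), formatted by `format_roi_table()`.

### Fitting: multi-start bounded least squares

All fits use Levenberg–Marquardt with box bounds (`minpack.lm`),
10 random starts, parameter/residual tolerances $10^{-10}$, best
residual norm kept and ties broken by the lower diffusivity (then the
smaller radius for the sphere fit). Start boxes: $S(0)$ uniform in
$[0, \max S(0)]$ and $f_1$ in $[0, 0.3]$ with $A$ their product; $D_1$
uniform in $[0, 1]$ µm²/ms (a box wide enough to bracket any plausible
slow pool — the published constraint covers only the amplitude terms);
$T_{2,1}$ in $[0, 300]$ ms, constrained to the same interval; sphere
radius in $[0, 20]$ µm with intra-sphere diffusivity fixed at 3 µm²/ms.
Bounds for $A$ and $D_1$ are $[0, \infty)$. Degenerate inputs (all-zero
signal, TE-independent data, radius at the bound) return flagged fits
with the boundary value rather than errors, so voxel loops never die
mid-ROI. Each voxel's starts are seeded from `config$seed + voxel`,
making results independent of voxel order and bit-reproducible.

### The noise floor and the debiasing trade-off

The per-sample signed estimator has a useful exact identity: its signed
square returns $M^2 - 2\sigma^2$, an unbiased estimate of $S^2$. Its
arithmetic mean, however, carries a residual bias of about
$-\sigma^2/2S$ at moderate SNR — the mirror image of the $+\sigma^2/2S$
of raw magnitude averaging — while deep below the floor ($S \lesssim
\sigma$) it is far closer to the truth than the floored raw mean. The
moment-level combination of $n$ repeats,
$\mathrm{sign}(u)\sqrt{|u|}$ with $u = \overline{M^2} - 2\sigma^2$
(`debias_mean_moments()`), shrinks the residual bias with $n$ and is the
right tool when a single shell mean is the quantity of interest. The
fitting pipeline nevertheless uses plain arithmetic means of the
debiased volumes: it keeps shell means linear in the data, matches how
debiased images are averaged in practice, and the residual bias is small
against the 10–90 percentile spread at the SNRs the protocol reaches
(this is quantified in the test suite at $S/\sigma \in [1,5]$).

## Forward models beyond Gaussian pools

**Watson-dispersed sticks and zeppelins.** Orientation dispersion is
parameterised by $OD = (2/\pi)\arctan(1/\kappa)$ (exposed both ways as
`watson_kappa()` / `watson_od()`). LTE signals are computed by
Gauss–Legendre quadrature in $\cos\theta$ crossed with a periodic
trapezoid in azimuth, with the order doubled until the result is stable
to $10^{-6}$ (an error, not a warning, if 512 nodes do not converge).
In the uniform limit the stick quadrature reproduces the closed-form
powder average $\sqrt{\pi}\,\mathrm{erf}(\sqrt{bD})/(2\sqrt{bD})$ to
$10^{-6}$; at finite concentration it is checked against Monte-Carlo
orientation sampling. Under STE both variants collapse exactly to
$e^{-b(D_\parallel + 2D_\perp)/3}$, independent of OD — the package
computes them that way rather than by quadrature.

**Restricted spheres under arbitrary waveforms.** The
Gaussian-phase-distribution (GPD) attenuation uses the eigenmode
expansion of the position autocorrelation in an impermeable sphere:
$\langle x(t_1)x(t_2)\rangle = \sum_k B_k e^{-\lambda_k D_s |t_1-t_2|}$
with $\lambda_k = \alpha_k^2/r_s^2$, $B_k = 2r_s^2/(\alpha_k^2(\alpha_k^2-2))$
and $\alpha_k$ the roots of $j_1'$. Numerically, the waveform is
resampled to ≤ 20 µs, the weighted gradient autocorrelation is
precomputed once per waveform (FFT), and each eigenmode contributes one
exponentially weighted sum; the series stops when a term falls below
$10^{-8}$ of the accumulated $\ln S$, with a cap of 100 modes chosen so
that radii up to the 20 µm fit bound still converge at that tolerance.
The implementation is validated against a frozen Monte-Carlo
random-walk oracle (reflecting sphere, ≥ 30 000 walkers; the generator
script ships under `tools/`). GPD is an approximation: it assumes the
accumulated phase is Gaussian, which is excellent in the
motional-narrowing regime (small spheres) and degrades at intermediate
correlation times — a known limitation discussed below.

**Two-pool exchange.** The Kärger illustration treats encoding as
narrow-pulse with a single effective diffusion time $\Delta$:
magnetisation dephases at $bD_i/\Delta$ per pool while exchanging at
rates $k_{12} = f_2/t_\mathrm{ex}$, $k_{21} = f_1/t_\mathrm{ex}$
(equilibrium $f_1 k_{12} = f_2 k_{21}$,
$t_\mathrm{ex} = 1/(k_{12}+k_{21})$ — the rate parameterisation is a
package choice, stated because conventions differ). The $2\times 2$
system is solved by eigendecomposition and reproduces both closed-form
limits to $10^{-9}$. Free gradient waveforms really have a spectrum of
diffusion times, so this operation is an illustration of how exchange
depresses the apparent dot fraction, not a quantitative exchange model.

## The synthetic data generator

`paper_protocol()` reproduces the in-vivo STE acquisition: shells
b = [250, 1500, …, 15 000] s/mm² repeated [6, 9, …, 36] times per TE,
interleaved so no two adjacent volumes share a shell (greedy
apportionment), with a b0 volume every 15th image; multi-TE variants
repeat the 231 encodings per TE ∈ {88, 115, 140, 165} ms.

`make_preset()` encodes the tissue regimes. Where the source analysis
publishes medians they are used directly: the cerebellar-GM slow pool
(f = 0.097, D = 0.12 µm²/ms, T2 = 61 ms, b0 SNR 452), the occipital- and
cerebellar-WM slow pools (0.026/0.16 and 0.054/0.23 at SNR 415/242), and
the dispersed-fibre scenarios (stick D∥ = 2.1, zeppelin 1.9/0.8 µm²/ms,
OD 0.7 without and 0.5 with a 2 % dot). Everything not published is a
declared, overridable default: fast-pool diffusivity 1.0 µm²/ms and
T2 = 90 ms in cGM (the high-b estimates are insensitive to them — the
fast pool retains < 10⁻⁴ of its signal beyond 10 500 s/mm²), single-ball
models for mWM/dGM (whose signals sit at the floor), and a 50/50
stick/zeppelin split of the non-dot fraction in the scenarios. With that
split the two scenario LTE signals agree to within a few percent at
b ≤ 4 ms/µm² while their STE signals at b = 15 ms/µm² differ by two
orders of magnitude — the separation the encoding is chosen for; the
exact low-b gap depends on the split, which no printed value pins down.

Per voxel, parameters receive multiplicative lognormal jitter (default
5 %, off for exact-recovery tests) to create percentile spreads;
fractions are renormalised after jittering. Noise is Rician with
$\sigma = S(b{=}0, TE_\mathrm{min})/\mathrm{SNR}$, plus a 1.5 %
multiplicative temporal fluctuation per volume — enough to separate tSNR
from SNR the way repeated b0 images do in vivo. Signal fractions are
defined at TE = 0; the truth table stores, per voxel, both the defined
fractions and the TE-apparent slow fraction
$f_1 e^{-TE/T_{2,1}}/S(0, TE)$, because the latter is what a single-TE
high-b fit estimates. Recovery tests compare against the apparent value
— at TE = 88 ms the cGM apparent slow fraction is ≈ 0.064, not 0.097.

What the generator does *not* emulate: imaging physics (EPI distortion,
eddy currents, motion, Gibbs ringing, gradient-nonlinearity fields —
though `effective_btensor()` applies a user-supplied coil tensor),
spatially non-stationary noise, and partial voluming. Passing recovery
tests therefore demonstrates the estimator chain is correct and
well-calibrated under its own assumptions, not that those assumptions
hold in scanner data.

## Problem sizes and runtime choices

The test suite exercises: 10⁶ draws for the Rayleigh-floor checks,
2×10⁵ orientation samples for the Watson oracle, 3×10⁴-walker frozen
random walks for the sphere oracle, 400–500 replicate shells for the
debiasing-bias comparisons, and 1000 simulated cGM voxels (≈ 250 000
volumes) for the end-to-end median-recovery check — sizes chosen so the
Monte-Carlo standard errors sit well inside the asserted tolerances
while the whole suite stays comfortably interactive.

## Known limitations

- The GPD sphere signal inherits the Gaussian-phase assumption; at
  intermediate correlation times ($r_s^2/D_s$ comparable to the pulse
  separation) its error against exact random-walk simulation can reach
  a few percent of the attenuation. The fitted radius should be read
  with that (and the fixed $D_s$) in mind.
- The Kärger operation is a narrow-pulse idealisation; it is not a
  model of exchange under free waveforms.
- Noise is assumed stationary with an effective single coil; σ comes
  from background voxels or simulation truth, not from a full noise-map
  estimator.
- `ste_waveform()` is an idealised isotropic-encoding waveform
  (a magic-angle q-sweep linearly symmetrised to an exactly isotropic
  B-tensor). It shares the defining properties of optimised STE
  waveforms but not their gradient-amplitude efficiency, so simulated
  hardware limits should not be inferred from it.
- Whether a measured slow signal reflects restriction, exchange, or
  both is not identifiable from this protocol alone; the package
  provides the forward models for all three readings precisely so the
  degeneracy can be explored.
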