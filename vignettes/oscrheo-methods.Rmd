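---
title: "Inferring effective cell rheology from pulsatile fluorescence time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring effective cell rheology from pulsatile fluorescence time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscrheo)
```

## The problem

Apically contracting epithelial cells — the motivating system is the
amnioserosa of the *Drosophila* embryo during dorsal closure — pulse: medial
myosin II foci assemble and disperse with periods of roughly 1.5–6 minutes,
driving apical-area oscillations around a slowly contracting trend. Because
every cell is continuously subjected to an oscillatory internal load, each
tracked cell is a natural cyclic-loading experiment. If myosin fluorescence
is accepted as a proxy for active contractile force, the joint statistics of
the two oscillations — amplitudes and phase lag at each frequency — determine
the effective mechanical response of the cell without touching the tissue.

`oscrheo` implements that inference chain: tracked-cell tables in, effective
stiffness and loss tangent over developmental time out, plus the conversion
of relative ablation stresses into stress fold-changes between stages.

## The constitutive model

The cell apex is modelled as a contractile linear viscoelastic (Maxwell)
fluid with an active forcing term:

$$\sigma + \tau_R\,\dot\sigma \;=\; \bar\tau\,\kappa\, c_m \;+\; \tau_R\,\kappa\,\dot\varepsilon,$$

where $\sigma$ is stress, $\varepsilon$ the apical area strain, $c_m$ the
rescaled myosin signal, $\kappa$ a bulk elastic modulus, $\tau_R$ the stress
relaxation time, and $\bar\tau = \tau_R/\tau_m$ the ratio of stress
relaxation to active force generation timescales. $\kappa$ and $\tau_R$ only
set the stress and time units; they are never estimated. $\bar\tau$ is
physiologically constrained to $[0.1, 100]$ and defaults to 1; the package
always offers a scan over that range, because stiffness scales linearly with
$\bar\tau$ (so relative time evolution is unaffected) while the loss tangent
is largely insensitive to it.

For sinusoidal inputs
$\varepsilon = \varepsilon_0\cos(\omega t)$,
$c_m = c_0\cos(\omega t + \delta_m)$
the steady-state stress is $\sigma = E\,\varepsilon_0\cos(\omega t + \delta)$
with closed-form stiffness and loss angle (with
$\bar\omega = \omega\tau_R$):

$$E = \frac{\kappa}{\varepsilon_0}\sqrt{\frac{c_0^2\bar\tau^2\cos^2\delta_m +
(\varepsilon_0\bar\omega + c_0\bar\tau\sin\delta_m)^2}{1+\bar\omega^2}},\qquad
\tan\delta = \frac{\varepsilon_0\bar\omega - c_0\bar\tau\bar\omega\cos\delta_m + c_0\bar\tau\sin\delta_m}
{\varepsilon_0\bar\omega^2 + c_0\bar\tau\cos\delta_m + c_0\bar\tau\bar\omega\sin\delta_m}.$$

`stiffness()` and `loss_angle()` evaluate these exactly; `stress_series()`
integrates the ODE with an exact exponential integrator (piecewise-linear
forcing), and the package's central consistency test drives the two routes
against each other over random parameter sets. The `c_0 \to 0` limit is the
passive Maxwell fluid, $E = \kappa\bar\omega/\sqrt{1+\bar\omega^2}$ and
$\tan\delta = 1/\bar\omega$, crossing from liquid-like ($\tan\delta > 1$) to
solid-like behaviour exactly at $\bar\omega = 1$.

The single-argument arctangent above has range $(-\pi/2, \pi/2)$; for lags
near $\pi$ with large $\bar\tau$ the denominator can turn negative (an
active-material regime the model itself does not disambiguate). The default
`loss_angle_mode = "literal"` evaluates the expression as written;
`"quadrature"` uses the two-argument arctangent, which matches the actual
phase of the ODE's steady state. Both are exposed because neither choice is
canonical.

## From raw tracks to dimensionless signals

**Apical strain.** The area trend is a centred 360-s boxcar (37 samples at
the nominal 10-s sampling). A plain boxcar leaks a fraction of the
oscillation into the trend — its frequency response at the oscillation
period, the Dirichlet kernel $\sin(N\pi\nu\Delta t)/(N\sin(\pi\nu\Delta t))$,
which reaches $-0.20$ at 3.5 mHz — biasing the recovered amplitude by the
same fraction. `area_trend()` therefore refines the trend: the band-limited
oscillation estimate is divided out of the raw series and the boxcar
re-applied. Each iteration multiplies the bias by the boxcar response again;
two iterations (the default, `trend_refine`) reduce a 20 % bias to below
1 %. `trend_refine = 0` recovers the plain boxcar. Strain is
$(A - \bar A)/\bar A$, bandpassed.

**Rescaled myosin.** Fluorescence is background-subtracted, divided by the
lower-envelope minima trend, offset by $-1$ and bandpassed:
$c_m = (I - I_{bg})/\mathrm{env} - 1$. Division (rather than subtraction,
available via `envelope_mode = "subtract"`) makes the result invariant under
any positive gain applied above background, which is what makes values
comparable across embryos and imaging sessions.

The envelope itself is the subtle part. Pulses *add* fluorescence to a
non-oscillating baseline, so the signal's minima trace background plus
baseline (which decays by photobleaching). Naive interpolation through
strict local minima is exact on clean data but biased upward under noise
(noise minima occur at every pulse phase); morphological opening trades that
for a staircase-versus-photobleaching bias. `myosin_envelope()` instead
detects pulse peak positions on a band-limited copy (linear filtering, so
broadband noise cannot spawn spurious peaks), places troughs midway between
consecutive peaks, measures each trough as a small windowed mean of the
pre-smoothed signal, and corrects the known boxcar attenuation at the
measured cycle length by solving the two-point peak/trough system for the
baseline. No extremal *value* selection occurs anywhere, so noise does not
drag the envelope down; measured bias is below 0.5 % on clean and about 1 %
on noisy (amplitude SNR 3) synthetic data.

**Bandpass.** Both signals are band-limited to 1–12.5 mHz with a
Hann-windowed FIR, applied forward-backward (implemented as one centred
convolution with the kernel's autocorrelation, which is algebraically the
same on the interior and exactly zero-phase). The default 201 taps are the
shortest standard length meeting the response requirements: forward-backward
DC rejection below $10^{-3}$, unity gain (≥ 0.99) at 5 mHz, stopband below
$10^{-2}$ at 25 mHz. Edges where the filter support is incomplete are
trimmed, never padded: padding would fabricate low-frequency content in
exactly the band of interest. Mid-track gaps split a track into segments at
read time; segments shorter than the trend window are dropped with a logged
count, since every windowed operation assumes contiguity.

## Spectral decomposition

For each grid frequency $\nu$ (1 → 12.5 mHz in 0.195-mHz steps) a
Hann-tapered window of length $3/\nu$ slides in steps of $1/(2\nu)$. The
single-frequency Fourier coefficient gives the component amplitude,
normalised so a unit sinusoid reads 1.00; the default `"peak"` estimator
reports the reconstruction's extremum nearest the window centre
(parabolically refined), and the plain coefficient estimator is kept
alongside — the two agree within a few tenths of a percent on clean
sinusoids, bounding the ambiguity between the conventions.

**The lag.** Two constructions are provided. The default takes the phase
difference of the two windowed Fourier coefficients of the *same* window:
both coefficients carry the identical complex leakage factor of the window,
which cancels in the difference, so the lag of an oscillatory component is
recovered exactly at every grid frequency whose window responds to it. The
alternative (`lag_source = "hilbert"`, and the standalone
`band_phase_lag()`) band-isolates each signal around $\nu$ by Fourier-domain
masking — exactly zero-phase, one step — and differences the
analytic-signal phases. The Hilbert construction yields a genuinely
*instantaneous* lag, but it is only meaningful at frequencies whose narrow
band truly contains signal; at bins populated only by window leakage of a
distant component its phase is arbitrary. Since the amplitude estimator's
3-period window deliberately responds to nearby frequencies, consistency
between "what carries amplitude" and "what defines the lag" favours the
Fourier-pair construction for the per-component lag, and parameter-recovery
on synthetic chirps confirms it (loss-tangent errors fall from tens of
percent to a few percent). A FIR realisation of the narrowband isolation was
rejected on first principles: at bandwidth $\nu/3$ the required impulse
response (~3700 s) exceeds typical track lengths.

**Coherence.** Morlet wavelet coherence (centre frequency $\omega_0 = 6$)
with mandatory smoothing — a boxcar over 3 oscillation periods in time at
each scale and an average across scales within a ±15 % frequency band.
Unsmoothed wavelet coherence is identically 1; these spans give roughly 4–5
effective degrees of freedom, so independent noise scores well below a
coherent pair. The significance reference is a resampling null: the myosin
signal of one randomly drawn cell against the strain signal of another,
1000 pairings, the 90th percentile of the null coherence pooled over
iterations and frequencies reported per time step.

**Hysteresis loops.** The instantaneous oscillation phase defined by the
strain signal (analytic-signal argument) bins both signals into 24 phase
bins within each 600-s developmental interval. For sinusoids of amplitudes
$a, c$ and lag $\phi$ the enclosed area is $\pi a c \sin\phi$; the
phase-binned polygon recovers it within ~2 % (the inscribed-polygon and
bin-averaging factors are both $\mathrm{sinc}$-like and known), and the
signed area quantifies how loops tighten as the lag approaches $\pi$.

## Binning, averaging and uncertainty

Per component, stiffness and loss angle are evaluated with
$\bar\omega = 2\pi\nu\,\tau_R$ and averaged in 100-s bins of analysis time
across frequencies and cells:

* **Noise-floor selection** (`component_floor`, default 1.5): a component
  enters the averages only if both its amplitudes exceed 1.5 times the
  cell's median amplitude over the frequency grid at that window time. Most
  grid frequencies carry no signal, so the median tracks the noise floor;
  bins below it have uniformly random lags that would otherwise bias the
  loss-angle average. Setting 0 disables selection.
* **Amplitude weighting** (`freq_weighting = "amplitude"`): weights
  $w = \varepsilon_0 c_0$; for components representing the same physical
  oscillation the stiffness is weight-independent (it depends on the
  amplitude ratio), while noise-dominated components are down-weighted.
  `"uniform"` gives plain means.
* **Angles before tangents** (`angle_average = "angle"`): loss angles are
  averaged and the tangent applied to the mean; the tangent is unbounded
  and a single component near $\pi/2$ would dominate a mean of tangents.
  The alternative is behind the flag.

Confidence intervals are hierarchical-bootstrap percentiles honouring the
embryo → cell → observation nesting: embryos are resampled with
replacement, then cells within each chosen embryo, keeping all observations
of a chosen cell (time points within a cell are strongly autocorrelated and
are never resampled). At each stage $n-1$ of the $n$ units are drawn:
resampling $n$ deflates the bootstrap variance of a mean by $(n-1)/n$, and
the $n-1$ draw is the standard correction. On a nested Gaussian simulation
(10 embryos × 10 cells × 10 observations, unit variances at every level)
the 95 % interval achieves ~95 % empirical coverage. A single-embryo
dataset yields an interval reflecting only within-embryo variation, flagged
with a warning.

## Stress fold-changes from relative ablation stresses

Under the hysteretic damping law, the creep response to a unit stress step
is $\varepsilon(t) = (\sigma/G_0)(t/t_0)^{2\delta/\pi}$ and the sinusoidal
stiffness is $E(\omega) = G_0\,\Gamma(1 - 2\delta/\pi)\,(\omega t_0)^{2\delta/\pi}$.
Given $(\omega, \delta, E)$ triples, `fit_scale_factors()` estimates
$(G_0, t_0)$ by least squares in log space — the problem is linear in
$(\log G_0, \log t_0)$ once $\delta$ is known, so the optimum is exact, and
the log transform equalises relative residuals across the multiplicative
range of $E$. At least two distinct loss angles are required; with one,
$t_0$ is unidentifiable. Ablation experiments deliver relative, unscaled
stresses $\Delta = \sigma/(G_0 t_0^{2\delta/\pi})$; the fold-change between
stages is then

$$\frac{\sigma_{\mathrm{late}}}{\sigma_{\mathrm{early}}} =
\frac{\Delta_{\mathrm{late}}}{\Delta_{\mathrm{early}}}\;
t_0^{\,2(\delta_{\mathrm{late}}-\delta_{\mathrm{early}})/\pi},$$

in which $G_0$ cancels identically. Uncertainty is propagated to first
order from the $\Delta$ standard errors, the fit covariance of $\log t_0$
and optional loss-angle errors. The frequency paired with each bin's
$(E, \delta)$ is the amplitude-weighted dominant frequency of the bin.
$\Delta$ values are user data (a small CSV); the package ships none.

## Neighbour analysis

The myosin phase of a cell is its position between consecutive pulse peaks
(strict maxima at least 60 s apart, merging closer peaks by keeping the
larger); a cell counts as *fluctuating* when the cycle length lies in
1–6 min and amplitude × frequency exceeds 0.3 (amplitude is half the
peak-to-trough range, frequency in cycles per minute; the product's units
are a convention, exposed in config). Neighbour pairs where both cells
fluctuate are classified by $r_m = \cos(\Delta\text{phase})$ at ±0.33 into
correlated / uncorrelated / anti-correlated — the thresholds partition
$[-1, 1]$ without gaps.

Cell-shape strain rates come from the symmetric linear map that best
transforms one centroid-relative outline into the next (no rotation),
$(M - I)/\Delta t$ symmetrised; its trace equals the relative area rate for
small steps, and projections $n^\top T n$ along the centroid–centroid axis
give the pair-axis strain rate. The randomised null rebuilds every pair
with a partner drawn uniformly from the other cells present at the same
time, preserving pair counts.

## The synthetic generator

`generate_embryo()` emulates the phenomenology the pipeline is designed
for: an exponentially contracting area trend carrying oscillations whose
frequency ramps 3.51 → 6.54 mHz, strain amplitude decaying 0.08 → 0.04,
constant myosin amplitude 0.2, a strain-to-myosin lag ramping
$3\pi/2 \to 9\pi/8$, a photobleached myosin baseline on a constant
background, random-walk phase jitter (so coherence stays below 1) and
additive Gaussian noise. Noise scales with the local trend/baseline
(shot-noise-like): a fixed absolute noise level would silently degrade the
myosin signal-to-noise ratio as the baseline bleaches. Myosin pulses *add*
to the baseline, `background + B(t)(1 + c_0(1 + \cos(\phi + \delta_m)))`,
so that the signal minima trace `background + B(t)` — the property the
envelope rescaling relies on, and the physically sensible reading of
pulsatile foci on a non-oscillating pool. The noise spectrum is white
Gaussian by assumption; no empirical noise spectrum was available to match.

The ctMLCK preset only changes amplitudes and baseline (higher $c_0$ and
baseline, lower $\varepsilon_0$), mirroring a constitutively-active-kinase
perturbation as a configuration rather than new machinery.

`generate_neighbour_lattice()` places cells on a toroidal square lattice
with prescribed phases (equal, checkerboard-antiphase, or independent).
Each cell's width along an axis is
$w_0 + u_i - c\,(u_{\mathrm{left}} + u_{\mathrm{right}})/2$ with
$u_i = d\cos\phi_i$ and coupling $c = 1/3$, so the width-oscillation
amplitude of anti-correlated neighbours is exactly twice that of correlated
ones ($(1+c)/(1-c) = 2$) — a constructed oracle for the neighbour analysis,
not a force-balance simulation. Phases are prescribed, not emergent; no
mechanical coupling across the sheet is simulated.

What the generator does *not* emulate — segmentation errors, spatially
correlated noise, junctional myosin, non-sinusoidal pulse shapes beyond the
raised-cosine, cell rearrangements — bounds what passing tests show about
real data: the pipeline's estimators are validated as correct and noise-
robust under the stated signal model, not as robust to every imaging
artefact.

## Numerical choices and degenerate inputs

* Sampling must be uniform within 1 %; gap-split segments are analysed
  independently and short segments dropped with a logged count.
* Strain amplitudes below `amplitude_floor` ($10^{-6}$) make stiffness
  undefined (stress with no strain) and are masked, never reported as
  infinite; bins average only defined components and report
  `n_components`.
* The ODE integrator is exact for piecewise-linear forcing; strain rates
  default to central differences (one-sided at the ends).
* Hysteresis phase bins with no observations are dropped from the loop
  polygon; loops with fewer than 3 populated bins report no area.
* Envelope and trend estimators fall back to the plain boxcar trend when a
  signal has no detectable pulse structure (constant signals reproduce
  themselves exactly).
* Analysis time is track time plus the per-track developmental offset
  (`dev_time_offset_s`), an input, so t = 0 aligns to the onset of net
  tissue contraction.
* All stochastic stages (generators, bootstrap, nulls, randomised
  partners) are deterministic given their seed.

## Problem sizes

The shipped tests and the acceptance script run, per invocation: 100 random
parameter sets for the ODE-versus-closed-form consistency check; 20-cell,
6000-s embryos for parameter recovery and the $\bar\tau$ scan; 1000
resampling iterations for the coherence null on six 5000-s cells; 500
replications × 1000 bootstrap resamples for the coverage simulation; and
4 × 4 lattices for the neighbour construction. These sizes were chosen so
the full suite completes in a few minutes on one CPU while keeping every
Monte-Carlo standard error well below the tolerance it is tested against.

## Known limitations

* The constitutive model is linear with a single relaxation time; nonlinear
  loops (non-elliptic strain–myosin trajectories) are outside its scope and
  will be averaged into effective linear parameters.
* Absolute stresses are not obtainable: $\kappa$, $\tau_R$ set free units,
  and only relative changes are meaningful.
* With a single embryo, bootstrap intervals understate between-embryo
  variability by construction.
* Adjacent 100-s material bins share spectral windows (length $3/\nu$), so
  neighbouring bins are strongly correlated and should not be treated as
  independent measurements.
* The vertex-correspondence requirement for shape strain rates is an input
  contract; no point-matching across frames is implemented.
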