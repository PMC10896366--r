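---
title: "Mean-field analysis of PING gamma oscillations with pingmf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean-field analysis of PING gamma oscillations with pingmf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`pingmf` studies gamma-band (30–100 Hz) oscillations generated by a
pyramidal–interneuron gamma (PING) circuit: a population of regular-spiking
excitatory neurons (RSEs) drives fast-spiking inhibitory interneurons (FSIs)
through AMPA and NMDA synapses, and the FSIs inhibit the RSEs through GABA
synapses. Each neuron is a quadratic integrate-and-fire (QIF) unit

$$C \frac{dV}{dt} = g_l \frac{(V - V_l)(V - V_T)}{V_T - V_l}
  + I_{appl} - I_{syn},$$

with spike at $V_{spike}$ and reset to $V_R$; in the theoretical limit
$V_{spike} = -V_R = \infty$ the QIF neuron is equivalent to the theta neuron,
which is how the spiking simulator integrates it (the blow-up becomes an
ordinary phase crossing, so the infinite spike/reset is handled exactly
rather than with a finite cutoff; `simulate_network()` is fixed-step RK4 in
the phase variable with time step $0.01\,\tau_e$ by default).

Synaptic input is conductance-based,
$I_{syn} = (g_e s_e + g_n s_n)(V - V_{ex}) + g_i s_i (V - V_{in})$, with
global gating variables shared across the all-to-all network: $s_e$ and
$s_i$ decay exponentially (time constants $\tau_e$, $\tau_i$) and jump by
$1/N$ on each excitatory/inhibitory spike, while the NMDA gate is logistic,
$\dot s_n = a_n s_e (1 - s_n) - s_n/\tau_n$, driven by the global AMPA gate.
Modeling the NMDA gate as a single global variable mirrors the closure used
by the mean-field reduction; a per-neuron version of the same dynamics
averages to it when the NMDA time scale is much slower than the AMPA one,
which is the regime all configurations in this package live in. Saturation
of the voltage-dependent Mg$^{2+}$ block is not modeled.

## Quenched heterogeneity and the exact reduction

Synaptic conductances and applied currents are heterogeneous across
neurons: each neuron draws its values once, at network construction, from
Lorentzian (Cauchy) distributions with mode $\bar g$ and half-width
$\gamma$ (`sample_lorentzian()`). The Lorentzian choice is what makes an
*exact* macroscopic description possible: under the Lorentzian ansatz the
population density over membrane states stays Lorentzian-shaped, and the
integrals over the heterogeneity close by residue calculus. Draws are kept
raw — including negative ones — because the closure integrates over the
whole real line; a `truncate_at_zero` switch exists for exploration but
breaks the exact network–mean-field correspondence and is off everywhere.

The resulting closed system (`mean_field_rhs()`) has seven states: rate,
mean nondimensional potential and gate per mechanism,
$(r_e, u_e, s_e, r_i, u_i, s_i, s_n)$. Heterogeneity enters the rate
equations as a source
$(\hat\Delta + \sum_x \hat\gamma_x s_x |u - \hat V_x|)/(2\pi\tau^2)$ and
the potential equations through $2\pi r \sum_x \hat\gamma_x s_x\,
\mathrm{sgn}(\hat V_x - u)$; the sign convention is the one that keeps
$r \ge 0$ invariant. Voltages are nondimensionalized so that rest and
threshold sit at $u = \mp 1$ (`nondimensionalize()`, exactly invertible by
`dimensionalize()`); time stays in milliseconds with $\tau = C/g_l$, and
rates are in 1/ms (multiply by 1000 for Hz).

The $|u - \hat V|$ and $\mathrm{sgn}(\hat V - u)$ factors make the
right-hand side continuous but nonsmooth on the manifolds $u = \hat V_{ex}$,
$u = \hat V_{in}$. The sign convention of the
reduction handles crossings exactly — they are part of the model, not an
anomaly — and `integrate_mean_field()` logs per-trajectory crossing counts
in an attribute so integration accuracy near the kinks can be audited
(on the reference configuration $u_i$ dips below $\hat V_{in}$ each cycle,
where only the very small I→I half-width is nonsmooth). Integration is
adaptive (deSolve/lsoda, compiled
right-hand side and analytic Jacobian, rtol $10^{-8}$, atol $10^{-10}$) with
dense output at 1 ms. The default initial state is small positive rates
($10^{-3}$/ms), potentials at rest ($u = -1$), gates closed — a reproducible
transient that converges onto the attractor well within the 500 ms discard
used by the spectral metrics.

## Gamma metrics

`power_spectrum()` is a mean-subtracted Welch estimate (Hann window,
1024-sample segments, 50% overlap, 1000 Hz sampling, segment FFTs
zero-padded fourfold) applied to the excitatory rate trace after a 500 ms
transient discard. The zero-padding matters: without it, the measured peak
density of a narrowband rhythm dips by up to ~15% whenever the peak
frequency falls between frequency bins (window scalloping), which
masquerades as non-monotone structure in parameter sweeps; padding
interpolates the spectrum and removes the artifact. "Gamma power" is the
*maximum* spectral density inside 30–100 Hz and "peak gamma frequency" its
location; the paired-scalar reading matches how the sweep analyses use them.
A band-integrated alternative is available (`metric = "integral"`). Power at
or below a noise floor ($10^{-12}$) is reported as zero with an undefined
peak. For bifurcation-diagram ordinates a time-domain amplitude
(`oscillation_amplitude()`: max − min of $r_e$ over the final window) is
used instead; the two metrics must and do agree on where oscillation power
reaches zero, which is also where the Hopf certificates place the
bifurcation.

All sweep and synergy powers go through one function (`mf_gamma_power()`)
so that identical integrator and spectral settings are guaranteed across
conditions; spectra are reported in arbitrary units and only relative
quantities (deficits, peak locations, zeros) are interpreted.

## Bifurcation analysis

Equilibria are found by damped Newton iteration on the analytic Jacobian
(`find_equilibrium()`, residual norm below $10^{-10}$). One-parameter scans
(`hopf_scan_1d()`) continue the equilibrium across a 200-point grid, watch
the leading complex-conjugate eigenvalue pair, and bisect every sign change
of its real part until the parameter interval is below $10^{-5}$ *and* the
certificate $|\mathrm{Re}\,\lambda| < 10^{-6}$ holds; each reported point
carries its eigenvalue pair, emergent frequency $\omega/2\pi$, and an
onset/offset tag from the crossing direction. Two-parameter curves
(`hopf_curve_2d()`) run a certified 1D scan per x-value and record missing
crossings as gaps rather than interpolating. This
continuation-plus-bisection design was chosen over pseudo-arclength
continuation of the Hopf manifold because the system is only
seven-dimensional and cheap, so dense certified grids are simpler and
equally robust. Fold/torus/homoclinic bifurcations and normal-form
coefficients are out of scope; super/subcritical character is assessed only
through the amplitude scaling near the point.

## The calibrated reference configuration

The quantitative structure of the gamma surface depends on baseline
constants — membrane $\tau$, synaptic kinetics, drive and its
heterogeneity, recurrent couplings, reduced reversals — that are not part
of the three manipulated pathways. The package pins them with a named,
frozen reference configuration (`reference_config()`). The anchors are
conventional cortical values (leak reversal $-65$ mV, threshold $-50$ mV,
capacitance 1 µF/cm², tonic drive to RSEs only, no FSI drive); the
remaining constants were fitted once and frozen. The fit treats the five
Hopf locations of the one-parameter gamma structure (oscillation onset
along E→I AMPA strength at 0.26; offsets along E→I NMDA strength at 0.15,
I→E GABA strength at 1.52, and the two E→I half-widths at 1.55 and 0.053)
as a system of five nonlinear equations in the free constants and solves
it by damped Gauss–Newton with an SVD pseudo-inverse (each function
evaluation is an equilibrium continuation plus certified eigenvalue
bisection); the solution set is a manifold, and the remaining freedom was
used to keep the healthy rhythm in the gamma band and the power-peak
locations of the strength sweeps as close to their quoted positions as
the model family allows. All five Hopf landmarks are reproduced to better
than 0.1% relative; `calibrate_reference()` exposes a general
least-squares version of the same machinery for refitting against other
landmark sets. The fitted reduced reversals correspond to dimensional
reversals of about $-2.0$ mV (excitatory) and $-69.8$ mV (inhibitory);
the fitted membrane time constant is 1.91 ms, with AMPA, GABA and NMDA
decay constants of 1.27, 13.0 and 156 ms.

The healthy-state values of the manipulated pathways are
$\bar g_{E\to I} = 1.3$, $\bar g_{N\to I} = 0.13$ (a 1:10 NMDA:AMPA
ratio), $\bar g_{I\to E} = 0.6$, with half-widths
$\gamma_{E\to I} = \gamma_{N\to I} = \gamma_{I\to E} = 0.01$. One
structural property could not be reconciled with the landmark set: with
the five Hopf locations enforced, the gamma-power maximum along the
tied-NMDA E→I direction sits near 1.05 rather than at the healthy value
1.3 (the constrained Gauss–Newton with the peak location added as a sixth
equation stalls with that residual, and the location is insensitive to
the choice of power metric). The healthy state is therefore oscillatory
and near-optimal along the I→E axis, but not the exact argmax of the
tied-strength direction; the disease-condition deficits that depend on
that direction inherit the discrepancy (the E→I-strength deficit comes
out negative), which is documented behavior of the calibrated model, not
a numerical artifact. Disease states apply a uniform percent difference:
strengths scaled down, variabilities scaled up
(`apply_percent_difference()`), with $\lambda$-interpolation between the
endpoints (`lambda_scale()`).

Two further features of the calibrated model are worth knowing. First,
the classic PING window along the E→I strength closes near 2.7 (with the
NMDA mode held at its healthy value) and a *second*, faster
oscillatory window opens at very strong drive (onset near 5.2, emergent
frequency rising above the gamma band) — an interneuron-driven rhythm
distinct from PING. Analyses that ask "does this parameter support gamma"
therefore filter instabilities by emergent frequency
(`oscillatory_area(band = c(30, 100))`). Second, strong tonic NMDA drive
onto FSIs (beyond the 0.15 offset) eventually destabilizes the
equilibrium again into a fast (>100 Hz) rhythm outside the analysis band.

One documented discrepancy in the source values: the disease-state
variability is 0.012 (120% of 0.01); a table-formatted source prints it
as "0.12", a typo for the value used here.

## The synergy pipeline

`synergy_analysis()` computes, per percent difference: baseline power at
the healthy state; power under each single alteration (E→I strength —
AMPA and NMDA modes moved together at the fixed 1:10 ratio; E→I
variability — both half-widths together; I→E strength); and power with all
five parameters at their disease values simultaneously. Deficits are
percentages of baseline, $(P_h - P_c)/P_h \times 100$; the additive
prediction is the sum of the three individual deficits, and the fold ratio
(combined/additive) quantifies super-additivity. A condition whose
oscillation dies contributes a 100% deficit, not an error; the fold ratio
is undefined when the additive prediction is not positive. The
I→E half-width stays at 0.01 in every condition.

## Problem sizes and runtime choices

The package's own test and reproduction scale was chosen to keep every
analysis comfortably on a laptop core: mean-field trajectories of 4.5 s
(1 ms output), 60-point 1D sweeps, 200-point continuation grids, 40-column
2D curves, and a 1000-neuron network (800 RSE + 200 FSI) integrated at
$dt = 0.01\,\tau_e$ for validation runs of a few seconds of biological
time. Halving tolerances or doubling grids changes no reported landmark by
more than its bisection tolerance.

## What the generator does and does not emulate

The spiking module is a faithful finite-size realization of the theory's
assumptions: all-to-all coupling, global gates with population-normalized
spike increments (1/N per population, under which the gating drive equals
the population mean rate for any population split), quenched Lorentzian
heterogeneity, pulse coupling. Passing network-vs-mean-field tests
therefore validates the reduction, not the biology: sparse or structured
connectivity, conduction delays, synaptic depression/facilitation,
per-neuron NMDA gating with voltage-dependent block, finite spike width
and refractoriness are all absent. Finite-size fluctuations make the
network's spectra noisier than the mean-field's; comparisons use smoothed
population rates and seeds are fixed.

## Known limitations

* The Lorentzian is the only heterogeneity law with an exact closure here;
  Gaussian variability is qualitatively similar but out of scope.
* Gamma power is reported in arbitrary units; only locations of peaks and
  zeros, band membership, and relative deficits are meaningful.
* The calibration pins five scalar landmarks exactly; baseline constants
  are not uniquely identified by them, and other constants reproducing the
  same landmarks would give somewhat different out-of-sample numbers
  (power-peak locations, deficit magnitudes, region-shrinkage orderings).
* Because the healthy state is not the tied-direction power argmax in this
  model family (see the calibration section), the E→I-strength disease
  condition *increases* gamma power here, the additive deficit prediction
  can be negative, and the fold-ratio curve is not defined over the whole
  percent range.
* Near-degenerate cases (double Hopf, branch folds) are reported as scan
  failures rather than resolved.
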