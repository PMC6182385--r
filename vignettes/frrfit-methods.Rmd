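---
title: "Models and methods behind frrfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind frrfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frrfit)
```

## The measurement

Fast repetition rate fluorometry (FRRf) probes photosystem II (PSII) with
a train of sub-saturating microsecond flashlets (here 40 flashlets of
1.2 µs separated by 1.0 µs of darkness) that cumulatively drive a single
photochemical turnover: the primary quinone acceptor Q~A~ is reduced,
reaction centres close, and the chlorophyll fluorescence yield rises from
the minimal level F~0~ to the maximal level F~M~ (the *induction* curve).
Once excitation stops, Q~A~^−^ is reoxidised and fluorescence decays back
(the *relaxation* curve). Fitting both curves yields the biophysical state
of the PSII pool: F~0~, F~M~, the effective absorption cross section for
PSII photochemistry σ~PSII~ (Å² quantum^−1^), the coefficient of excitonic
connectivity ρ, and the fast and slow reopening lifetimes τ~1~ and τ~2~
(µs) with amplitudes α~1~ + α~2~ = 1.

Measured at the end of each step of a light protocol — once in the
presence of the background actinic light and once after 1 s of darkness —
these parameters support the standard quenching arithmetic: the estimated
minimal fluorescence under light F~0~′, the photochemical quenching
coefficient q~P~ (and excitation pressure 1 − q~P~), and the quantum-yield
partition

$$Y(\mathrm{PSII}) = \frac{F_M' - F_S}{F_M'},\qquad
  Y(\mathrm{NPQ}) = \frac{F_S}{F_M'} - \frac{F_S}{F_M},\qquad
  Y(\mathrm{NO}) = \frac{F_S}{F_M},$$

which telescope to $Y(\mathrm{PSII}) + Y(\mathrm{NPQ}) + Y(\mathrm{NO})
\equiv 1$ as an algebraic identity. The absolute electron transport rate
per PSII is

$$\mathrm{ETR} = \frac{E_\mathrm{Å}\; \sigma_{PSII}'\; Y(\mathrm{PSII})}
                      {(F_M - F_0)/F_M}
  \quad [e^-\,\mathrm{PSII}^{-1}\,\mathrm{s}^{-1}],$$

with the incident PAR converted via 1 µmol photons m^−2^ s^−1^ =
6.022140 × 10^−3^ photons Å^−2^ s^−1^ (Avogadro's number per µmol over
10^20^ Å² m^−2^; the literature leaves these units implicit, so the
constant is fixed here once). The PSII-per-chlorophyll factor n~PSII~ is
deliberately excluded: ETR is per photosystem, not per pigment.

## The forward model

Closure maps to fluorescence through the connectivity yield

$$F(C) = F_0 + (F_M - F_0)\,\frac{C\,(1-\rho)}{1-\rho C},$$

linear in the closed fraction $C$ when $\rho = 0$ and increasingly
sigmoidal as connected PSII units share excitons. During the flashlet
train each flashlet delivers an integrated dose $E$ (photons Å^−2^) and
closes open centres at rate $\mathrm{d}C/\mathrm{d}E =
\sigma\,(1-C)/(1-\rho C)$. **The per-flashlet recursion advances $C$ by
the exact flow of this equation**, which at $\rho = 0$ is
$C^+ = 1 - (1-C)\,e^{-\sigma E}$ and otherwise solves a one-dimensional
implicit equation by Newton iteration. The flow formulation was a
deliberate choice over a one-step (Euler) update: flows compose, so the
simulated closure is invariant to how the dose is subdivided within a
flashlet, and the recursion agrees with a brute-force 1000-substep
integration to better than 10^−4^ — a physical-consistency property an
Euler map cannot satisfy at saturating doses, where its error is of order
$\sigma E/2 \approx 6\%$ per flashlet. Closed forms at $\rho = 0$
($C_k = 1 - e^{-\sigma E k}$) anchor the oracle tests.

Flashlet intensity is an instrument calibration, not a fitted quantity:
`calibrate_dose()` chooses the dose so the fluorescence rise saturates at
a target flashlet ($E = -\ln(1-C_\mathrm{target})/(\sigma_\mathrm{ref}
k_\mathrm{target})$; the default saturates to 98% closure by flashlet 30
of 40). Reopening relaxation between flashlets is off by default — the
train spans ~88 µs against τ~1~ ≈ 500 µs, which is the single-turnover
assumption — but can be switched on for sensitivity analyses.

Relaxation follows the biexponential reopening
$C(t) = C_0\,(\alpha_1 e^{-t/\tau_1} + \alpha_2 e^{-t/\tau_2})$,
label-symmetric under $(\alpha_1,\tau_1) \leftrightarrow
(\alpha_2,\tau_2)$ and therefore canonicalized to τ~1~ ≤ τ~2~ on output.
A third kinetic phase is out of scope.

## Fitting

Both fits minimise squared residuals with bounded quasi-Newton least
squares (PORT, `stats::nlminb`) from fixed, documented starts, with a
relative tolerance of 10^−10^ on the residual sum of squares and at most
500 iterations; every start is deterministic, so a fit is a pure function
of its data.

*Induction* (`fit_induction()`): free parameters (F~0~, F~M~, σ, ρ);
starts F~0~^0^ = mean of the first two points, F~M~^0^ = maximum, σ^0^ =
ln 2 / (k~half~ · dose) from the half-amplitude flashlet index, ρ^0^ ∈
{0.3, 0} (two starts guard the σ–ρ ridge); bounds ρ ∈ [0, 0.8] and σ ∈
(0, 10 σ^0^] prevent the ridge from diverging on noisy high-light
transients. A constant trace raises a degenerate-input error; a rise that
has not plateaued — judged by the last quartile sitting below 85% of the
amplitude or carrying a tail slope that is both statistically (t > 3) and
practically (> 10% of amplitude across the quartile) positive — is
returned unconverged with a `non_saturating` flag rather than raised,
because very high actinic light legitimately suppresses the remaining
variable fluorescence.

*Relaxation* (`fit_relaxation()`): free parameters (τ~1~, τ~2~, α~1~)
with F~0~, F~M~, ρ fixed from the paired induction fit and C~0~ taken
from the model closure after the last flashlet. Lifetimes are optimised
on the log scale (the τ~1~–τ~2~ valley is badly conditioned linearly) and
initialised by exponential peeling: the tail of the log-closure decay
gives τ~2~ and the slow amplitude, the early residual gives τ~1~. When
one amplitude collapses below 10^−3^ the decay is single-phase, the
second lifetime is unidentifiable, and both lifetimes are reported equal
under a `single_phase` flag. Under actinic light the fit decays toward a
closure floor (see below) instead of zero, because the background light
re-establishes the steady state rather than full reopening.

### In-light transients and the identifiability ridge

A transient measured under actinic light starts at the steady-state
fluorescence F~S~ with a substantial fraction of centres already closed.
In that regime (F~0~, ρ, C~init~) lie on a near-flat likelihood ridge —
exactly flat at ρ = 0, where only F~M~, σ and the product
(F~M~−F~0~)(1−C~init~) are identifiable — and an unconstrained fit
returns σ′ biased by up to ~20%, a bias that grows with closure and would
corrupt every downstream light-response relationship. The pipeline
therefore refines each in-light fit using only measurable quantities from
its paired 1-s-dark measurement: ρ is fixed to ρ′~1s~ (identifiable,
since that trace starts from zero closure), C~init~ is fixed by inverting
the closure mapping at F~S~ with F~0~′ estimated from the standard
1-s-dark scaling formula $F_0' = F_0'^{1s}\, F_M'/F_M'^{1s}$, and
(F~0~, F~M~′, σ′) are refit. The restricted problem is exactly
identifiable: noiseless synthetic experiments round-trip σ′ to machine
precision, and at 1% multiplicative noise σ′ carries a ~4% coefficient of
variation. The trade-off is that the in-light record reports ρ′~1s~ as
its connectivity rather than an independent in-light estimate — a
deliberate exchange of one poorly identified parameter for the integrity
of σ′.

## Protocols

Two designs are built in. The **non-sequential rapid light curve** runs
nine 30 s light steps after a ~2 min dark adaptation and a dark-adapted
reference measurement (which occupies the first 30 s slot of the protocol
clock): PAR 34, 74, 114, 300, 470, 300, 470, 540, 74 µmol photons
m^−2^ s^−1^, so the 470 step ends 180 s into the protocol, the 540 step
ends at 270 s, and 300, 470 and the growth irradiance 74 are each visited
twice. Revisits are the point of the design: `upregulation_index()`
compares first-visit and revisit ETR at every repeated PAR, a ratio above
1 revealing light-history-dependent upregulation. The two earliest (ramp)
steps are not pinned by the design and are config-overridable. The
**induction–recovery** design applies one long actinic segment (default
1200 s at 300 or 600 µmol photons m^−2^ s^−1^) followed by 900 s of dark
recovery, measured every 60 s.

`pair_measurements()` keys the pairing on timestamps, not input order:
each in-light measurement is joined to the nearest dark measurement
within (0, 5] s after it. Unmatched or unconverged measurements are kept
with quality flags — never dropped — and out-of-range yields are stored
unclipped with flags, so the record table remains auditable. Each
experiment carries exactly one dark-adapted reference (F~0~, F~M~,
σ~PSII~) against which Y(NO), ETR and normalised σ′ are computed; which
σ′ (in-light or 1-s-dark) enters ETR is switchable, defaulting to
in-light.

## The synthetic-data generator

No instrument data ship with the package; the generator renders complete
experiments whose statistical structure matches what the analysis
assumes, so every stage is testable end to end. Its defaults are the
stated world of the emulated study system:

| parameter | default | meaning |
|---|---|---|
| F~0~, F~M~ (dark) | 0.2, 0.5 | F~v~/F~m~ = 0.6, so dark Y(NO) = 0.4 |
| σ~PSII~ (dark) | 400 Å² | dark-adapted cross section |
| ρ | 0.3 | held constant by the generator |
| τ~1~ base / ceiling | 500 / 1800 µs | dark value / full-excitation-pressure value |
| τ~2~ | 5000 µs | slow reopening phase (α~1~ = 0.7) |
| NPQ PAR threshold | 305 µmol m^−2^ s^−1^ | onset of time-dependent Y(NPQ) induction |
| NPQ induction / relaxation rate | 0.003 / 0.0005 s^−1^ | ~30 s e-folding above threshold; incomplete reversal within 900 s dark |
| dσ′/dY(NPQ) | −0.65 | normalised σ′ decline per unit Y(NPQ) |
| upregulation | on; τ~1~ × 0.5 | after > 35 s cumulative supra-threshold exposure; resets at ≤ 74 µmol m^−2^ s^−1^ |
| noise | 1% CV | multiplicative Gaussian, one seeded stream per experiment |

The dynamic functional forms are the package's own minimal choices — the
emulated study reports endpoints and thresholds, not differential
equations:

1. **Y(NPQ)** integrates $\dot Y = r\,(1-Y)$ while PAR exceeds the
   threshold and decays slowly otherwise (forward Euler, 1 s steps). The
   quenching algebra bounds Y(NPQ) by the headroom $F_S/F_M'$, so the
   reported value — and everything coupled to it — is capped at 95% of
   that headroom; on long high-light runs the trajectory therefore
   plateaus near 0.55 rather than ramping to 1, which an unbounded ramp
   would demand but no fluorescence trace could express. The 0.003 s^−1^
   rate puts a ~25% Y(NPQ) range into a single 270 s RLC. With the
   threshold at 305, the 300 µmol m^−2^ s^−1^ induction treatment induces
   no Y(NPQ) at all — a knife-edge consequence of a strict threshold that
   real organisms soften; those runs contribute null points to the pooled
   regressions.
2. **σ′** = σ~dark~ (1 + slope · Y(NPQ)): regulated quenching shrinks the
   functional antenna.
3. **τ~1~ under light** rises from base toward ceiling linearly in the
   instantaneous excitation pressure; the upregulation mode halves it
   once cumulative supra-threshold exposure passes 35 s, emulating the
   opening of additional electron flux away from PSII, and the history
   resets when PAR returns to the growth irradiance. τ~1~ measured after
   1 s darkness is always the base value — the acceleration is strictly
   light-dependent. Because the 300 µmol m^−2^ s^−1^ revisit accumulates
   no supra-threshold exposure, the generator's acceleration first
   appears at the 470 revisit, one step later than the emulated system
   shows it; the headline revisit/first-visit ETR contrast at 470 is
   unaffected.
4. **Steady-state closure** under light balances the excitation rate
   (PAR~Å~ · σ′, around 10^3^ s^−1^ at 470 µmol m^−2^ s^−1^) against the
   amplitude-weighted reopening rate α~1~/τ~1~ + α~2~/τ~2~, solved
   jointly with (1)–(3) by fixed-point iteration.
5. **Quenching scale**: both F~0~ and F~M~ are scaled by
   $s = 1 - Y(\mathrm{NPQ})/(F_S/F_M')$, which makes the rendered
   fluorescences reproduce the intended Y(NPQ) *exactly* through the
   Klughammer–Schreiber algebra — the generator states its world in the
   same coordinates the analysis measures.
6. **DTT mode** forces the NPQ rate to zero (xanthophyll-cycle
   inhibition), leaving Y(NO) to absorb all non-photochemical
   dissipation; it doubles as the null world for the upregulation and
   slope tests.

What the generator does **not** emulate: instrument gain drift, blanks
and stray light; spectral (wavelength-dependent) corrections; biological
replicate-to-replicate variance in the dark parameters; a softened NPQ
threshold; mechanistic xanthophyll chemistry; and any third relaxation
phase. A green end-to-end test therefore establishes that the estimation
machinery inverts data *of the assumed structure* at the stated noise —
not that field data will be this well behaved.

## What the acceptance suite establishes

The emulated study's printed regression statistics were computed on
undeposited measurements, so acceptance is property-based
(`tests/testthat/test-acceptance.R`): the yield-partition identity at
10^−12^ over 10^4^ random tuples; forward-model agreement with a
1000-substep oracle at 10^−4^; noiseless self-consistency of both fits at
10^−4^ over a σ × ρ × τ~1~ grid; Monte-Carlo medians at 1% noise within
5% (σ, F~0~, F~M~), 0.05 (ρ) and 10% (τ~1~) with no bias beyond
Monte-Carlo error; saturation by flashlet 30 under the calibrated dose;
end-to-end recovery of the σ′–Y(NPQ) slope within ±0.1 on the pooled
default experiment set (the single-RLC Y(NPQ) range is too narrow to pin
a slope at 1% noise, so the pooled set mirrors the emulated study's
pooling of induction–recovery data) together with an upregulation ratio
above 1 at PAR 470 and a clean null under DTT (ratio within 0.1 of 1; a
slope statistically indistinguishable from 0, since with a pure-noise
regressor only significance, not the point estimate, is meaningful);
exact dark Y(NO) = 0.400; and byte-identical reruns at a fixed seed.

Tolerances worth restating: fit convergence is 10^−10^ relative on the
residual sum of squares; the induction Newton solve iterates to 10^−14^;
yields are never clipped in stored tables; and all randomness in the
generator flows from a single integer seed recorded in every output's
provenance header alongside the configuration hash and package version.
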