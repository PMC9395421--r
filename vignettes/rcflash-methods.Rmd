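---
title: "Modelling flash-induced cytochrome oxidation in intact photosynthetic bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling flash-induced cytochrome oxidation in intact photosynthetic bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The system and the model

Purple photosynthetic bacteria convert light into chemical energy at the
reaction center (RC), a membrane pigment–protein complex. A photon oxidizes
the special bacteriochlorophyll pair P; the electron lands on the primary
quinone Q~A~ and, through the two-electron gate at the Q~B~ site, leaves the
RC as quinol after two turnovers. On the donor side, P^+^ is re-reduced by
*c*-type cytochromes — a bound tetraheme subunit in *Rubrivivax gelatinosus*,
diffusible periplasmic cytochrome *c*~2~ in *Rhodobacter sphaeroides*. An RC
is **open** when P is reduced and Q~A~ oxidized; any other combination is
closed to photochemistry. Measuring how much cytochrome each saturating flash
oxidizes — and how the steps shrink from flash to flash (**damping**) —
reports on the availability of reduced donors in the living cell.

`rcflash` implements this turnover cycle as one explicit mean-field state
space: the cross product of P redox state (2), Q~A~ electrons (2), Q~B~-site
state (4: quinone, semiquinone, quinol, empty) and the donor docking site (3:
vacant, reduced or oxidized cytochrome bound), 48 discrete states in all,
with two continuous bookkeeping variables (net oxidized cytochrome per RC,
reduced fraction of the cytochrome pool). A single chain of linear ODEs —
nonlinear only through the pool-dependent docking rate — replaces the set of
separate per-flash reaction schemes, so conservation laws hold exactly in one
integrator. Integration uses `deSolve::lsoda` with an analytic Jacobian,
relative tolerance 1e-8, on the protocol's output grid (default 50 µs, the
instrument resolution the package emulates).

A saturating flash is an instantaneous projection: all occupancy in open
states moves to the corresponding P^+^Q~A~^−^ state. This is justified by the
3 µs flash duration being far below the 50 µs sampling; the operator is
idempotent and occupancy-conserving by construction.

## Rates, units and defaults

All rates are first-order, in s^−1^:

* `k_L` — excitation rate under continuous light (default 1.5e4);
* `k_AB1`, `k_AB2` — first and second interquinone electron transfer
  (strain presets use 1e4 and 7.2e3 for *Rvx.*, 1.2e4 and 6e3 for *Rba.*);
* `k_Qex` — quinol release / quinone rebinding, default (1 ms)^−1^, the
  literature order of magnitude for the quinone exchange;
* `k_bind`, `k_unbind` — cytochrome docking and release; docking is scaled
  by the reduced-pool fraction (reduced cytochromes bind) and its
  complement (oxidized cytochromes bind — product inhibition makes the
  donor side a true equilibrium);
* `k_ET`, `k_ETr` — forward and reverse electron transfer between the
  bound cytochrome and P; their ratio is the electron-transfer
  equilibrium constant. `k_ETr = 0` (the default) makes donor oxidation
  irreversible, which yields the exact saturation limits (one turnover
  under terbutryne, three electrons per three flashes with the quinone
  gate shut). `k_ETr` may be a vector of three values indexed by the
  RC's acceptor electron count — the donor poise in the i-hole state;
  see the calibration section;
* `N_pool` — reduced cytochromes per RC; `k_bc1` — pool re-reduction by
  the bc~1~ complex, default (10 ms)^−1^, reduced tenfold by the
  myxothiazol flag;
* `k_ext` — pseudo-first-order P^+^ re-reduction by an external donor
  (ferrocene at 0.5 mM vastly exceeds P^+^, so a pseudo-first-order
  treatment is adequate; the flash-number dependence of the collisional
  rate is not modelled).

Inhibitor flags: terbutryne zeroes both interquinone rates; dithionite
pre-reduces Q~A~ (no photochemistry); myxothiazol slows `k_bc1`.

## Step damping and equilibrium constants

The stationary analysis of the flash train gives the step heights in terms
of generalized donor (K~Di~) and acceptor (K~Ai~) equilibrium constants:

$$\Delta_1 = \frac{K_{D1}}{1+K_{D1}},\qquad
  \Delta_2 = \frac{K_{A1}}{1+K_{A1}}\,\Delta_1\frac{K_{D2}}{1+K_{D2}},\qquad
  \Delta_3 = \frac{K_{A1}}{1+K_{A1}}\frac{K_{A2}}{1+K_{A2}}\,
             \Delta_1\frac{K_{D2}}{1+K_{D2}}\frac{K_{D3}}{1+K_{D3}}.$$

Because the acceptor-side equilibria lie far to the right, the inversion
neglects them by default,

$$K_{D1}=\frac{\Delta_1}{1-\Delta_1},\quad
  K_{D2}=\frac{r_2}{1-r_2},\quad K_{D3}=\frac{r_3}{1-r_3},\qquad
  r_2=\Delta_2/\Delta_1,\; r_3=\Delta_3/\Delta_2,$$

but `invert_steps(steps, K_A = c(...))` also offers the exact finite-K~A~
inversion so the size of that approximation can be quantified. A step ratio
at or above 1 means no damping and an unidentifiable constant: the default
is to raise an error; a clip tolerance can be enabled explicitly, because
silent clipping would hide unidentifiable constants. Note that `K_D1`
computed from Δ1 is only as accurate as the absolute normalization of the
trace to 1 cytochrome/RC (in practice supplied by the cytochrome-less
*cycA* calibration strain).

The delayed-flash experiment varies the spacing T between consecutive
flashes; the step ratio follows the re-opening law times a free asymptote,

$$\mathrm{ratio}(T) = R_\infty\,(1-e^{-k_A T})(1-e^{-k_D T}),$$

which `fit_damping_curve()` fits by nonlinear least squares (multi-start
simplex seeded from the half-rise delay, polished by Levenberg–Marquardt).
The asymptote R~∞~ is a deliberate addition: measured ratios saturate below
one at the equilibrium damping level, so a curve without an amplitude could
not match them; setting R~∞~ = 1 recovers the bare law, and both raw and
self-normalized ordinates are thereby supported. The law is symmetric in the
two rates, so the fit reports `k_slow` and `k_fast`; identifying the slow,
rate-limiting one with the acceptor side is a biological interpretation left
to the caller. Both `1/k` and `ln 2/k` are printed as characteristic times,
since both conventions appear in the literature for "half time".

## Calibration of the strain presets

What is published for each strain are the interquinone rates and the K~D~
constants, not microscopic docking parameters. Each preset therefore fixes
the acceptor side at the measured rates and back-solves the donor side so
that a noiseless simulated staircase — measured exactly as the analysis
pipeline measures it (plateau means over 100–350 µs after each flash,
then differences) — reproduces the steps implied by the target constants.

Two donor architectures cover the strains. For the tetraheme-bearing
*Rvx.* wild type the lever is the reverse electron-transfer rate indexed
by the RC's acceptor electron count: the poise of the donor equilibrium
in the i-hole state, which is precisely what the generalized K~Di~
denote. A single fixed donor equilibrium plus pool depletion cannot
reproduce its cascade (K~D2~ = 49 falling to K~D3~ = 3.7 while the steps
barely shrink): the published constants fall much faster than the pool is
drawn down, because successive flashes burn through donors of
progressively lower potential (the tetraheme hemes), and intra-tetraheme
electron hopping is outside this package's scope. The per-hole poise is
the minimal phenomenological encoding of that cascade, and because the
staircase is causal in the hole count, the back-solve is three
*sequential bracketed root searches*, each exact to ~1e-9 on the step
height. For *Rba.* wild type and the *pufC* mutant — strains whose
damping is carried by the redox state and depletion of a small soluble
pool — the levers are one electron-transfer equilibrium constant, the
dark reduced-pool fraction and the pool size (a damped Newton solve on
the 3-by-3 system), with small per-hole corrections zeroing the residual
exactly. All solves are deterministic and cached per session.

Before any illumination the model is relaxed to its dark steady state:
with a reversible donor and a partially oxidized pool the dark
equilibrium holds some P^+^ (the pool oxidizes part of the special pair),
and starting off-equilibrium would tilt the pre-flash baseline. The
bookkeeping counters are zeroed after relaxation so the observables count
light-induced chemistry only.

Preset K~D1~ values are a package choice (the source constants cover only
flashes 2 and 3): 99 for `rvx_wt` (first step visually complete), 9 for
`rba_wt`, 1.5 for `rvx_pufC` (clearly reduced first step). The pool sizes
(8, 4, 4 cytochromes/RC) are likewise qualitative choices — large for the
tetraheme-bearing wild type, smaller otherwise; the poise schedule, not
the pool, carries the quantitative damping. Presets set `k_bc1 = 0`
because the source analysis itself treats bc~1~ resupply as negligible on
the flash-train timescale (rates above (1 ms)^−1^); with the published
(10 ms)^−1^ resupply active, plateau means would droop by several percent
per interval and the strictest constants (K~D2~ = 49 needs the step ratio
accurate to ~0.2%) would be unmeasurable even in principle.

## The continuous-illumination design

Under strong continuous light the cytochrome oxidation shows three phases:
a light-limited initial rise, a turnover-limited stationary phase, and a
pool-limited tail. The generator treats the three published slopes
(1.5e4, 3.0e3, 50 cyt^3+^/RC/s) as *observables of the segmented fit* and
root-solves the excitation rate, the quinol-exchange rate and the docking
rate until the fit on the simulated trace reports them; the pool size is
set from the cumulative oxidation at the designed exhaustion time (10 ms).
Calibrating to the fitted slope rather than the raw parameter matters
because the mechanistic curve bends smoothly between phases; the published
slopes are themselves fitted slopes of such a curve. With a three-electron
acceptor buffer the light-to-turnover transition falls at
capacity/(slope1 − slope2) ≈ 0.3 ms, so the first fitted breakpoint lands
in the 0.1–2 ms band (the stationary phase's onset "around a millisecond"
read as an order of magnitude), while pool exhaustion is placed at 10 ms.

`fit_three_phases()` fits a continuous 3-segment piecewise-linear model by
exhaustive search over log-spaced breakpoint pairs (each candidate is a
linear least-squares problem) followed by a simplex refinement — cheap and
deterministic on short traces, with no derivative heuristics. Samples are
weighted by 1/t by default so each time decade carries equal leverage;
uniform weighting is available. If no pair of adjacent segments differs in
slope by at least a factor of 2, the fit is flagged degenerate in the
diagnostics (one global slope reported three times), not raised as an
error.

## The synthetic spectrometer

`generate_flash_experiment()` converts the simulated per-RC trajectory to a
551−540 nm difference-absorbance trace via Beer–Lambert with
Δε = 21.1 mM^−1^cm^−1^ (20 is selectable; both values circulate for the
cytochrome coefficient and the package does not guess which produced which
figure), path 1 cm and [RC] = 1 µM by default, so trace amplitudes are of
order 10^−2^ absorbance units, matching the detectability of ~0.1–1 µM
cytochrome. Oxidation is negative-going at 551−540 and at the P/P^+^ pair
790−750 (Δε = 70 mM^−1^cm^−1^); the sign is wavelength-pair metadata, never
inferred from data, so noisy traces reduce deterministically. Gaussian white
noise of per-sweep SD σ is divided by √n for an n-sweep average (default
σ = 1e-4, n = 32). The instrument's real noise amplitude is not published;
these defaults make the staircases statistically recoverable and are
exposed as parameters, not claimed as instrument values. One integer seed
governs all randomness and is recorded in the ground-truth sidecar.

Ferricyanide titration shifts the ambient redox poise by the Nernst
factor exp(−k~ox~ t~inc~) (default half-time 30 min within the 2 h
monitored window — the uptake is known only to be slow and progressive,
so a single-exponential is the simplest monotone emulation). For
pool-mechanism presets the factor multiplies the reduced-pool fraction,
which docking samples; for the poise-mechanism preset it scales every
donor equilibrium through the reverse electron-transfer rates
(`apply_redox_poise()`). All three recovered constants then decline
monotonically with incubation time, as required.

What the generator does *not* emulate: flash-lamp width, detector
bandwidth, scattered-light artifacts, baseline drift, spectral overlap of
multiple cytochromes, and intra-tetraheme electron hopping. Passing tests
therefore show that the analysis pipeline is correct and well-conditioned
under the stated noise model — not that real instrument artifacts are
handled.

## Numerical choices and degenerate inputs

* Stiff integration, rtol 1e-8 / atol 1e-12, analytic Jacobian; occupancy
  conservation is checked to 1e-9 in the tests.
* Near-duplicate output times (flash time colliding with a grid point) are
  deduplicated at 1e-12 s before integration.
* `invert_steps` raises on ratios ≥ 1 unless an explicit clip tolerance is
  given; `fit_damping_curve` raises when the ratios span less than 2% of
  their maximum (no kinetic information) and requires ≥ 4 delays.
* Problem sizes in the tests: flash trains of 1.6 ms at 50 µs sampling,
  continuous traces of 30 ms, 100 noisy replicates for the damping-fit
  statistics, and a 10^4^-triple sweep for the inversion round trip —
  enough for the statistics asserted while keeping the suite quick.

## Known limitations

* The per-interval donor poise reproduces the published constants but does
  not *predict* them from structure; it is a calibration, and the pool
  sizes are qualitative.
* The damping law's symmetric form means assignment of the slow rate to
  the acceptor side rests on outside knowledge, not on the fit.
* Sub-microsecond primary photophysics, proton uptake, membrane potential
  and stochastic (single-RC) effects are out of scope; the mean-field ODE
  is the modelling grain.
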