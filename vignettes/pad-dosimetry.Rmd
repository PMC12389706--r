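---
title: "Monte Carlo dosimetry of high-Z doped hydrogel radiotherapy pads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo dosimetry of high-Z doped hydrogel radiotherapy pads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Flexible hydrogel pads — hydrated carbohydrate polymers (alginate, chitosan
or cellulose, 80 wt% water / 20 wt% dry polymer) doped with a high atomic
number oxide (Bi₂O₃ or ZnO at 5–10 wt%) — are candidate contact shields for
superficial radiotherapy. Whether such a pad protects or *harms* depends
strongly on beam type, energy and depth: a high-Z filler that stops an
electron beam outright can, under low-energy photons, *increase* the skin
dose through photoelectric secondaries. padMC quantifies these effects with
an analog coupled photon–electron Monte Carlo through a pad placed on a
four-layer skin phantom:

| layer     | material (ICRP-style)     | extent (mm)       |
|-----------|---------------------------|-------------------|
| pad       | hydrogel composite        | [−t, 0), t = 2/10 |
| epidermis | skin                      | [0, 0.1)          |
| dermis    | soft tissue               | [0.1, 1.1)        |
| subcut    | adipose tissue            | [1.1, 11.1)       |
| muscle    | skeletal muscle           | [11.1, 111.1)     |
| backing   | water                     | [111.1, 211.1)    |

A pencil beam (photons or electrons, 50–1000 keV) enters at the top surface
travelling in +z. Every layer is a scoring volume; tallies are mean energy
deposited per primary particle (MeV) with batch standard errors, plus
upstream/downstream escape accounts. Geometry is one-dimensional in z with
full 3-D directions (infinite lateral slabs): at these energies and with a
20 cm-scale world, lateral leakage is negligible compared to the tallied
effects.

## Photon physics

Per-element partial mass attenuation coefficients (photoelectric,
incoherent, coherent; 10–2000 keV) are embedded as a frozen plain-text
table and combined by the mixture rule
$\mu/\rho = \sum_i w_i (\mu/\rho)_i$. The table is generated
deterministically from:

* **incoherent** — the exact Klein–Nishina total cross section per electron
  times $N_A Z/A$, damped by a one-parameter screening factor
  $u^2/(1+u^2)$, $u = E/(2.2\,Z^{2/3}\ \mathrm{keV})$. The factor is a
  compact stand-in for the incoherent scattering function; it is a ≤5%
  correction for tissue above 30 keV and irrelevant for Bi below ~300 keV
  where photoelectric absorption dominates.
* **coherent** — Thomson scattering with a Thomas–Fermi exponential
  form factor, integrated in closed form. The exponential form factor
  falls too fast at intermediate momentum transfer, so the screening
  length is shortened by a fixed factor 0.70. Angles are sampled from the
  bare Thomson distribution (no form-factor peaking): coherent scattering
  is retained mainly so total attenuation stays consistent, and a config
  switch (`include_coherent = FALSE`) removes it.
* **photoelectric** — anchored to published total-attenuation values for
  H, C, N, water (→ O), Fe and Pb by subtracting the modelled incoherent
  and coherent parts wherever photoelectric absorption is a >3% share,
  with log–log power-law continuation elsewhere. Zn is scaled from Fe and
  Bi from Pb by the $Z^{4.62}/A$ rule, with the Bi K edge placed at
  90.526 keV as a duplicated-energy grid pair so interpolation never
  crosses the edge. Minor tissue elements (Na…Ca) interpolate the reduced
  quantity $\tau A/Z^{4.62}$ between O and Fe. Bi L-edge fine structure
  (13–16 keV) is smoothed; only bremsstrahlung-tail photons reach it.

Because the O and Bi photoelectric curves are obtained by subtraction from
published *totals*, any imperfection of the incoherent/coherent models is
absorbed into the photoelectric channel: the total attenuation of water and
of Bi-bearing materials stays anchored to the published values (the shipped
reference anchors verify water at 50/100/500/1000 keV to 2%), at the cost
of a few percent of misattribution between channels near 50–100 keV.

### Photoelectric events: the shell model matters

The epidermal dose enhancement under Bi₂O₃ pads at 100 keV is carried by
photoelectrons generated in the last ~0.1 mm of the pad. Just above the Bi
K edge (90.5 keV), only ~78% of photoelectric events ionize the K shell —
and those release a *9.5 keV* photoelectron plus a 77 keV K X-ray that
mostly leaves the neighbourhood. It is the other ~22% (L and outer shells)
that produce ~87 keV electrons with ranges comparable to the epidermis
thickness. A model that assigned every event to the K shell would
essentially erase the enhancement mechanism. padMC therefore resolves the
shell: with probability $f_K$ (from edge-jump ratios, 0.78 for Bi) a
K-shell event ejects $E - E_K$ and relaxes by fluorescence (probability
$\omega_K$; the mean K X-ray is transported isotropically, $E_K - E_{Kx}$
deposited locally) or non-radiatively ($E_K$ deposited locally, standing in
for the short-ranged Auger cascade); otherwise an outer-shell event ejects
$E - E_L$ with the L binding deposited on the spot. Photoelectrons are
emitted isotropically — a deliberate simplification (the Sauter
distribution is moderately forward-tilted at these energies) that slightly
understates forward electron flow from the pad into the skin.

Compton scattering is sampled from the Klein–Nishina distribution on free
electrons (Kahn's rejection method) with the electron direction from
two-body kinematics; Doppler broadening and binding are neglected, which is
standard at 50–1000 keV and a known fidelity gap at 50 keV. Photons below
10 keV (the table floor) deposit locally; their mean free path in tissue is
under 2 mm, i.e. below the resolution at which conclusions are drawn, and
the cutoff-insensitivity test bounds the effect.

## Electron physics

Class-I condensed-history transport: continuous collisional loss with the
Bethe/Møller stopping power evaluated from mixture-rule $\langle Z/A
\rangle$ and Bragg-additivity mean excitation energy (density-effect
correction omitted, a sub-2% effect below 2 MeV); no δ-ray production and
no energy-loss straggling (sub-mm ranges at ≤1 MeV keep δ-rays within
layer resolution). Step length is the minimum of a 5% fractional energy
loss, one fifth of the current layer thickness (resolving the 0.1 mm
epidermis), and the distance to the next boundary.

Multiple scattering uses the Highland formula with $x$ the step's areal
density and $X_0$ the mixture radiation length (Dahl's closed form per
element, inverse additivity). Highland's $13.6\,\mathrm{MeV}$ width is a
*projected*-angle sigma: the space polar deflection is sampled from the
corresponding Rayleigh distribution (two independent Gaussian projections).
Using the projected width directly as the polar angle — a tempting one-line
shortcut — under-scatters noticeably: in a 1 MeV electron depth-dose test
it pushed ~3% of the beam energy one layer too deep and suppressed
backscatter by an order of magnitude. Lateral displacement within a step is
ignored (second-order in this 1-D depth geometry).

Bremsstrahlung uses the compact radiative stopping power
$S_{rad} = S_{col} \cdot Z_{eff} E[\mathrm{MeV}]/800$ with
$Z_{eff} = \sum w_i Z_i^2/A_i \,/\, \sum w_i Z_i/A_i$ — crude, but it
reproduces the Z-driven yield that makes Bi₂O₃ pads leak dose to depth
under electron beams. A photon is emitted per step with the probability
that reproduces $S_{rad}\rho\,ds$ *in expectation* under the $1/k$
spectrum on [10 keV, E] (an emission probability of
$S_{rad}\rho\,ds/E$ with the same spectrum would systematically
under-radiate by the factor $\ln(E/k_c)\,\langle k\rangle/E$), and the
electron loses the photon energy, keeping per-history energy conservation
exact. Emission is forward, along the electron direction. Electrons below
10 keV (range < 3 μm in tissue) deposit locally.

## Transport and tallies

Analog transport, no variance reduction: every keV of each primary ends in
a layer deposit or an escape account, exactly (the conservation audit
asserts a relative residual below 1e-9). Secondaries are managed LIFO.
Histories are split into batches; each batch reseeds R's generator from
the master seed by a fixed splitting rule, so runs are bit-for-bit
reproducible and batch means give the standard errors. Upstream of the
stack is vacuum (the source abuts the pad); the muscle is backed by 100 mm
of water to emulate a water-tank world.

## The study grid and derived metrics

`sweep_config()` defaults enumerate the full study: 3 polymers × 5 filler
states × 2 thicknesses + the No-Pad control, × 2 particles × 5 energies =
310 runs. `relative_metric()` reports 100·(pad − No-Pad)/No-Pad per layer
with propagated errors; `attenuation_summary()` negates it into percent
dose reduction; `pad_heatmap()` assembles the pad-layer deposition matrix
(compositions × energies), labelled explicitly as MeV *per primary* — the
normalization is stated on the figure because per-pad absolute "deposited
energy" numbers are meaningless without it. Enhancement claims are
evaluated at 2 mm thickness, where the pad is thin enough that attenuation
does not mask the photoelectric secondary source near the skin.

Default problem sizes: 1e5 histories per configuration for sweeps
(layer-mean standard errors of roughly 0.3–2%), 2e5–1e6 for single-run
quantities; `n_histories` scales freely and the 1e6 of the original study
conditions is a single argument away. The smoke configuration
(`smoke_config()`) exercises the entire pipeline at 2e4 histories in about
a minute.

```{r example}
library(padMC)
pad <- make_pad_material("alginate", "Bi2O3", 0.10)
stack <- build_stack(pad, pad_thickness_mm = 2)
tally <- run_beam(beam_spec("photon", 100, 2e5, seed = 1), stack)
tally
conservation_check(tally)
```

## What the generator emulates — and what it does not

The embedded tables and the generator reproduce the *study conditions*:
the material recipes (80/20 hydration, 5/10 wt% doping, the tabulated
densities with inverse-volume mixing for composites), the exact layer
thicknesses, the beam grid, and per-primary scoring. They do not emulate:
condensed-phase effects on cross sections, polarization, Rayleigh form
factors in the angular distribution, Doppler-broadened Compton profiles,
L/M fluorescence, δ-ray transport, or the specific physics-list choices of
a general-purpose toolkit. Passing tests therefore demonstrate internal
consistency with standard analytic physics (Beer–Lambert, Klein–Nishina
quadrature, CSDA integrals, published attenuation/stopping anchors) and
reproduction of the study's *relative* structure; absolute agreement with
another engine is expected only at the 10–25% level, which is how the
acceptance tolerances are set.

## Numerical choices

* Log–log linear interpolation per element per partial; edges handled by
  duplicated grid energies; energies outside 10–2000 keV are an error,
  never an extrapolation.
* The mixture $\mu/\rho$ is evaluated element-by-element and then summed,
  so the mixture-rule identity holds between grid nodes exactly.
* Boundary crossings restart the photon flight (exponential memorylessness)
  and terminate the electron step at the boundary, with a 1e-9 cm nudge
  into the next layer; deposits along a step go to the layer traversed.
* Compton recoils below 1 keV deposit locally rather than spawning
  sub-cutoff electron histories.
* Degenerate inputs: zero filler loading returns the unchanged hydrogel;
  filler fractions above 0.5 are rejected as physically implausible;
  non-normalized compositions are an error reporting the observed sum.

## Open design points resolved here

The dry-polymer densities are read as exactly that — densities of the dry
polymer — and hydrated/doped composite densities follow the inverse-volume
rule, with a `density` override exposed for sensitivity checks, because no
combined density is given for the hydrated pads. The hydrated-gel density
so obtained (≈1.01–1.02 g/cm³) is what a water-dominated gel should have.
Pad-layer absolute deposits for *2 mm electron* configurations are not
reproducible under any per-primary reading (printed values exceed the beam
energy), so per-primary normalization is adopted throughout and 2 mm
heatmap absolutes are out of scope.

## Known limitations

Isotropic photoelectron emission; K-only fluorescence; no δ-rays or
straggling (sharper end-of-range than reality); Highland Gaussian core
without the single-scattering tail (electron backscatter is
underestimated, which biases surface doses slightly low and deep doses
slightly high for electron beams); the $1/k$ bremsstrahlung spectrum and
forward emission are first-order stand-ins. These are the right trades for
layer-integrated doses at 50–1000 keV; they would not be for
micro-dosimetry or for MeV-range beams.
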