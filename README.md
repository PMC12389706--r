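# padMC

Monte Carlo dosimetry of carbohydrate-hydrogel radiotherapy pads doped
with high-Z fillers.

Flexible hydrogel pads — 80 wt% water, 20 wt% alginate, chitosan or
cellulose, doped with 5–10 wt% Bi₂O₃ or ZnO — are candidate contact
shields for superficial radiotherapy. Whether a given pad shields or
*enhances* dose depends on beam type, energy and depth: a high-Z filler
that absorbs an electron beam completely can, under 50–300 keV photons,
raise the skin dose through photoelectric secondaries (the cross section
scales roughly as Z³/E³). padMC answers these questions quantitatively for
anyone evaluating composite shielding materials: it transports photons and
electrons through a pad resting on a four-layer skin phantom (0.1 mm
epidermis, 1 mm dermis, 10 mm subcutaneous fat, 100 mm muscle, water
backing) and tallies the mean energy deposited per primary particle in
every layer, with batch standard errors.

The physics core:

* **Photons** — per-element partial mass attenuation tables (10–2000 keV,
  photoelectric / incoherent / coherent) combined by the mixture rule
  μ/ρ = Σᵢ wᵢ (μ/ρ)ᵢ; exponential free flights; Klein–Nishina (Kahn)
  Compton sampling; shell-resolved photoelectric absorption with K
  fluorescence (Bi K edge at 90.526 keV carried as a duplicated-energy
  grid pair); Thomson-angle coherent scattering.
* **Electrons** — class-I condensed history: Bethe/Møller collision
  stopping with Bragg-additivity mean excitation energy, CSDA ranges,
  Highland multiple scattering (Rayleigh-sampled space angle), and 1/k
  bremsstrahlung whose emission probability reproduces the radiative
  stopping power in expectation.
* **Transport** — analog, no variance reduction; energy conservation is
  exact per history; runs are bit-for-bit reproducible from a master seed
  via a fixed batch-splitting rule.

The history loop is compiled (Rcpp); a full 1e5-history configuration runs
in a few seconds on one CPU.

## Worked example

A 2 mm alginate pad doped with 10 wt% Bi₂O₃ under a 100 keV photon beam:

```r
library(padMC)
pad <- make_pad_material("alginate", "Bi2O3", 0.10)
pad
#> <material> alginate + Bi2O3 10%  (rho = 1.1078 g/cm3, derived-mixture)
#>   H  0.086984
#>   C  0.065479
#>   O  0.736948
#>   Na 0.020889
#>   Bi 0.089699

stack <- build_stack(pad, pad_thickness_mm = 2)
tally <- run_beam(beam_spec("photon", 100, 2e5, seed = 1), stack)
tally
#> <tally> photon beam, 100 keV, N = 200000 (20 batches, seed 1)
#>   pad                  0.00978966 MeV/primary  (se 5.9e-05)
#>   epidermis           7.26203e-05 MeV/primary  (se 2.3e-06)
#>   dermis              0.000443117 MeV/primary  (se 9.4e-06)
#>   subcut               0.00364473 MeV/primary  (se 2.4e-05)
#>   muscle                0.0387379 MeV/primary  (se 8.7e-05)
#>   backing               0.0143997 MeV/primary  (se 5.7e-05)
#>   escape_upstream       0.0230428 MeV/primary  (se 8.9e-05)
#>   escape_downstream    0.00986955 MeV/primary  (se 7.3e-05)
#>   sum                         0.1 MeV  (beam 0.1)
```

Reading the numbers: of each 100 keV primary, ~10 keV is absorbed in the
pad itself (mostly Bi photoelectric events), the deep layers receive most
of what crosses, and ~23 keV is backscattered out of the top surface. The
epidermis mean of 7.26e-5 MeV/primary is *higher* than the bare-phantom
value (4.6e-5 at this energy):

```r
np <- run_beam(beam_spec("photon", 100, 2e5, seed = 2), build_stack())
100 * (tally_layer(tally, "epidermis")[["mean"]] /
       tally_layer(np, "epidermis")[["mean"]] - 1)
#> +59%
```

— the photoelectric skin-dose enhancement that makes Bi₂O₃ pads
double-edged under low-energy photons. The full study grid (3 polymers ×
5 filler states × 2 thicknesses + No-Pad control × 2 particles × 5
energies = 310 runs) is driven by `sweep_config()` / `run_sweep()`, with
`relative_metrics()`, `attenuation_summary()` and `pad_heatmap()` for the
derived shielding metrics.

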