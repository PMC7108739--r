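# phagesector

Simulation and analysis of the sector-shaped lysis patterns that lytic
bacteriophages carve into expanding swim rings of motile, chemotactic
host bacteria on soft-agar plates.

## The science

Place a bacterial inoculum at the centre of a soft-agar nutrient plate
and a drop of lytic phage suspension 1 cm away. The bacteria consume
nutrient, chemotax up the self-generated gradient and form an expanding
swim ring; when the ring sweeps over the phage spot, infection produces
a wedge-shaped lysis zone whose *straight radial boundaries stay frozen*
behind the advancing front. The package implements a mean-field
reaction–diffusion–advection model of this system: four area-density
fields — susceptible bacteria `B`, infected bacteria `L`, free phages
`P`, nutrient `n` — coupled by

* Keller–Segel motility gated by nutrient, `∇·[D_B ν(n) ∇B] −
  ∇·[D_B α_c ν(n) K_c/(n+K_c)² B ∇n]` with `ν(n) = (n/(n+K_v))²`,
* Monod growth `g_max n/(n+K_n) B` with proportional nutrient
  consumption (factor `λ`),
* density-inhibited phage adsorption `η₂D K_b/(B+L+K_b) B P` (with
  multi-adsorption onto infected cells),
* nutrient-gated lysis `k_l L n` releasing `β` phage progeny per burst.

Local nutrient depletion behind the front simultaneously shuts down
growth, motility and lysis — immobilizing the pattern — while the
sector's angle is set early, by the "phage initiation zone": the region
phages occupy when nutrient first runs out at their inoculation point
(the 5% rule). The headline observables the package computes are the
initiation-zone radius (≈ 0.7 cm), the ring's wall-arrival time
(≈ 14 h), the sector-angle profile θ(r) with a
straight/flared/closed classification, and the co-propagation outcome
(phages and bacteria advancing together vs one encircling the other).

Who it is for: quantitative microbiologists and modellers studying
spatial phage–host dynamics, range expansion and co-propagation, who
need a reproducible solver plus the pattern metrics, not plate
photography.

## Worked example

```r
library(phagesector)

cfg  <- drop_assay_config(h = 0.1, T = 14)   # Table of defaults, d = 1 cm
traj <- run_simulation(cfg)                  # ~15 s on one CPU
ps   <- pattern_summary(traj)
print(ps)
```

```
<pattern_summary>
  ring arrival: 13.28 h | class: straight (slope 0.468 rad/cm) | outcome: co_propagation
  initiation zone: t* = 3.32 h, equivalent radius 0.95 cm
  theta(r):  1.5:1.46 2:1.85 2.5:2.34 3:2.58 3.5:2.69 4:2.80 4.5:2.89
```

Reading it: the swim ring reaches the plate wall (0.95 × 5.5 cm) at
13.3 h; nutrient at the phage inoculation centre drops below 5% of its
initial level at t* = 3.3 h, when phages occupy a region of equivalent
radius 0.95 cm (0.76 cm on the finer h = 0.05 cm grid with the run
stopped exactly at t* — the value the acceptance report prints); the
sector-angle profile is classified
*straight* against the package's frozen calibration band (slope 0.4 ±
0.2 rad/cm; finite-resolution fronts carry a positive baseline slope,
see the methods vignette), and phages and bacteria co-propagate.

Parameter sweeps mirroring the figure panels:

```r
tab <- run_sweep(preset("fig3a"))   # g_max x eta grid -> class per cell
```

Command line (after installing):

```sh
Rscript inst/cli/phagesector simulate --config cfg.json --out out/
Rscript inst/cli/phagesector analyze  --traj out/
Rscript inst/cli/phagesector sweep    --preset fig2a --out sweep/
Rscript inst/cli/phagesector selftest
```

## Layout

* `R/`, `src/stepper.cpp` — model, operator-split finite-volume solver
  (adaptive exponential reaction integrator), pattern analysis, presets,
  IO/CLI.
* `vignettes/lysis-sector-model.Rmd` — model assumptions, units (incl.
  the volumetric-adsorption-constant conversion), numerical scheme,
  calibration and known limitations.
* `tests/testthat/` — unit, property and acceptance suites; heavy runs
  are memoised and shared. A handful of acceptance sub-claims are
  documented expected failures of the solver at desk resolution (grid
  convergence of the sector angle, a few figure-trend contrasts smaller
  than the lattice bias); the methods vignette lists them.
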