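# oxykin

Trajectory statistics and kinetics of gas handling in protein cavities.

`oxykin` is an R package plus a numbered analysis workflow for the
quantitative questions behind O₂ delivery in a cofactor-independent
(α/β-hydrolase-fold) dioxygenase — or any system where a small gas
molecule must reach, and stay in, a buried pocket:

* **Occupancy mapping** — bin gas positions sampled along a trajectory on
  a voxel grid, detect high-occupancy sites as 26-connected clusters
  above an iso level, Boltzmann-invert the density into free energies
  (G = −k_B·T·ln p/p_max), reweight bias-accelerated sampling, and
  measure minimax (bottleneck) barriers between sites.
* **Residence kinetics** — detect entry/exit events at a spherical region
  with a hysteresis rule, build right-censored residence-time tables, and
  estimate k_off⁻¹ by the censored-exponential MLE
  (τ̂ = Σtᵢ/n_escapes) or by least-squares fitting of the cumulative
  escape fraction 1 − e^(−t/τ). The closed form
  E[T | T &lt; c] = m − c·e^(−c/m)/(1 − e^(−c/m)) bridges fitted means to
  censored observations.
* **Conformation** — χ1 (N-CA-CB-OG) rotamer computation and
  classification into plus/trans/minus (+60°/180°/−60°, fixed 120°
  sectors), replica-averaged histograms, occupancy-conditioned state
  fractions, and iterative-superposition RMSF.
* **Spin-forbidden kinetics** — the effective barrier of an
  intersystem-crossing step is E_MECP − k_B·T·ln p for hopping
  probability p; `effective_barrier()` compares it with a competing
  spin-allowed barrier and names the rate-limiting step. A documented
  Landau–Zener utility is included.
* **Synthetic generator** — seeded, tested generators (Gillespie pocket
  hopping, censored exponential escapes, occupancy-coupled rotamer
  switching, exact-geometry structure fixtures) so the whole pipeline is
  testable without MD engines.

File formats: multi-model PDB and XYZ trajectories, TSV event tables,
OpenDX scalar grids, JSON reports/sidecars.

## Worked example

Is the spin-forbidden O₂-addition step or the subsequent CO release rate
limiting, given a crossing point at 10.2 kcal/mol with hopping
probability 0.005 and a competing transition state at 10.8 kcal/mol?

```r
library(oxykin)

barrier_correction(0.005, 298.15)
#> [1] 3.139167

effective_barrier(spin_crossing_params(
  hop_probability = 0.005, temperature = 298.15,
  e_mecp = 10.2, e_competing = 10.8))
#> $correction_kcal
#> [1] 3.139167
#> $effective_isc_barrier_kcal
#> [1] 13.33917
#> $competing_barrier_kcal
#> [1] 10.8
#> $verdict
#> [1] "ISC-limiting"
```

The 0.005 hopping probability costs 3.1 kcal/mol, lifting the crossing
point to ≈ 13.3 kcal/mol — above the 10.8 kcal/mol competing step, so
intersystem crossing limits the overall rate.

Residence statistics under censoring, at the water-clearance study scale
(30 runs, 50 ns cutoff, true mean 15 ns):

```r
ev <- simulate_escape_events(escape_model(15, 50, 30), seed = 2)
summarize_events(ev)[c("n_escapes", "escape_fraction_pct", "mean_ns")]
#> $n_escapes
#> [1] 29
#> $escape_fraction_pct
#> [1] 96.66667
#> $mean_ns
#> [1] 12.93548
fit_koff(ev)$koff_inv_ns   # censored-exponential MLE
#> [1] 14.65961
truncated_mean(15, 50)     # why escaped events average below 15 ns
#> [1] 13.15031
```

29/30 runs escape (96.7%), the escaped events average ≈ 13 ns even though
the underlying mean is 15 ns — exactly the censoring bias the truncated
mean predicts — and the censored MLE recovers ≈ 15 ns.

## The analysis workflow

Numbered drivers under `analysis/` regenerate the full synthetic study
and write tables under `results/`:

```sh
Rscript analysis/01_generate_synthetic.R   # trajectories + event tables
Rscript analysis/02_occupancy_map.R        # density, sites, DX grid, barriers
Rscript analysis/03_residence_kinetics.R   # censored summaries, koff fits
Rscript analysis/04_rotamer_dynamics.R     # chi1 histograms, coupling, RMSF
Rscript analysis/05_spin_crossing.R        # effective barriers, verdict
Rscript analysis/06_full_report.R          # one-call deterministic report
```

Each script states what it found on stderr; `06_full_report.R` is the
end-to-end demo (`run_pipeline()`), deterministic per seed and complete
in seconds.

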