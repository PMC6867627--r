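# ringlane

Run-and-rest motility fingerprinting for single cells migrating on
ring-shaped 1D micro-lanes.

## The problem

Cells confined to narrow adhesive lanes do not drift smoothly: they
alternate between **run states** (persistent, ballistic motion in one
direction) and **rest states** (random wiggling with no net motion). On a
ring-shaped lane of radius *r* a cell's state is a single coordinate, the
unwrapped angle φ(t), and its motility is captured by a five-parameter
fingerprint:

- **v_run** — mean |v_tang| over run-state time points, v_tang = r·dφ/dt;
- **τ_run, τ_rest** — exponential lifetimes of the two states, from a
  weighted log-linear fit of the dwell-time survival function
  S(t) = P(T > t) on t ∈ [2, 16] h (states entering the sample only if they
  start ≥ 16 h before their track ends);
- **P_run** — fraction of observation time spent in run states;
- **q** — persistence, (max φ − min φ) / Σ|Δφ|: 1 for one-directional
  motion, near 0 for pure wiggling;

plus the fraction of cells that never leave the rest state. This package is
aimed at anyone quantifying single-cell migration on 1D micropatterns
(or validating such an analysis): it takes tracking tables, produces
per-cell and population fingerprints with honest uncertainties, compares
conditions, and ships a two-state trajectory simulator that provides ground
truth for every stage. A small morphology module computes min/max Feret
shape factors and relative staining intensities from binary masks.

## Worked example

```r
library(ringlane)

# simulate a motile control population on 75 um rings:
# median run speed 30 um/h, lifetimes 4 h (run) / 2 h (rest), 10% immobile
sim <- simulate_population(ctrl_like_params(n_cells = 100, seed = 101))
fp  <- fingerprint(sim$collection)
fp
#> motility fingerprint (100 cells):
#>   v_run      29.70 um/h (se 1.10, n = 90 mobile)
#>   tau_run     3.84 h    (99% CI 3.34-4.44, 527 states)
#>   tau_rest    2.73 h    (99% CI 1.69-4.34, 479 states)
#>   p_run      0.588      (se 0.025)
#>   q          0.509      (se 0.022, n = 100)
#>   immobile   0.100
```

The estimates recover the generating parameters: runs at ≈ 30 µm/h with a
≈ 4 h lifetime, rests of ≈ 2 h (its wider CI reflects the smaller usable
tail), P_run near the stationary value τ_run/(τ_run+τ_rest) = 2/3 scaled by
the 10% immobile cells, and the immobile fraction itself.

Comparing against a low-motility condition (20 µm/h, 2 h/6 h, 30% immobile)
reproduces a coherent multi-parameter shift:

```r
ind <- fingerprint(simulate_population(induced_like_params(n_cells = 100, seed = 102))$collection)
compare_fingerprints(fp, ind)
#> fingerprint comparison (difference = b - a):
#>  parameter value_a value_b difference statistic   p_value significant       method
#>      v_run 29.6992 18.6846  -11.01464    -8.510 1.883e-14        TRUE      welch_t
#>      p_run  0.5882  0.1979   -0.39028   -13.982 4.998e-29        TRUE      welch_t
#>          q  0.5090  0.4288   -0.08019    -2.586 1.042e-02        TRUE      welch_t
#>    tau_run  3.8391  1.9594   -1.87972        NA        NA        TRUE ci99_overlap
#>   tau_rest  2.7251  6.1614    3.43631        NA        NA        TRUE ci99_overlap
#> parameters shifted toward lower motility in b: 5 / 5
```

Real tracking data enters through `read_trajectories()` (CSV with cell id,
time, and x/y in µm or φ in radians; `trajectory_dialect()` maps column
names), with ring geometry from `ring_geometry()`.

## Analysis workflow

The `analysis/` directory holds the narrative pipeline, each stage a thin
driver over package functions, writing its tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # two simulated conditions + manifests
Rscript analysis/02_fingerprint.R  # fingerprints, per-cell + segment tables
Rscript analysis/03_compare.R      # condition comparison + spider-plot data
Rscript analysis/04_shapes.R       # Feret shape factors, relative intensity
```

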