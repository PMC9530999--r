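# hjdimer

Trajectory analysis of cyanine dye dimers covalently tethered to DNA
four-arm (Holliday) junctions.

DNA-scaffolded dye aggregates are a route to engineered excitonic
materials: two dyes held by a DNA Holliday junction can form strongly
coupled dimers whose optical behaviour depends on how the transition
dipoles of the two dyes sit relative to each other. Molecular-dynamics
trajectories of such constructs are the raw material; `hjdimer` turns a
topology plus multi-frame coordinates into the quantities that
characterise the dimer:

- **Orientation factor** for dyes *m*, *n*:
  κ<sub>m,n</sub> = μ̂<sub>m</sub>·μ̂<sub>n</sub> −
  3(R̂<sub>m,n</sub>·μ̂<sub>m</sub>)(R̂<sub>m,n</sub>·μ̂<sub>n</sub>),
  where μ̂<sub>i</sub> is the unit transition-dipole vector along the
  dye's long axis and R̂<sub>m,n</sub> the unit vector between the
  dipole centres. |κ| ≤ 1 indicates predominantly stacked (H-like)
  dyes, |κ| > 1 predominantly end-to-end (J-like) dyes.
- **Centre-to-centre distance** R<sub>m,n</sub> (nm).
- **Excitonic hopping parameter** J<sub>m,n</sub> (meV) in the extended
  dipole approximation: each dipole is replaced by end charges
  ±q<sub>i</sub> = ±μ<sub>i</sub>/l<sub>i</sub> and
  J<sub>m,n</sub> = J₀ (1/|r<sub>m</sub>−r<sub>n</sub>| +
  1/|s<sub>m</sub>−s<sub>n</sub>| − 1/|r<sub>m</sub>−s<sub>n</sub>| −
  1/|s<sub>m</sub>−r<sub>n</sub>|) with
  J₀ = μ<sub>m</sub>μ<sub>n</sub>/(4πε₀n²l<sub>m</sub>l<sub>n</sub>),
  screened by the solvent refractive index squared. A point-dipole
  (Kasha) closed form, J = κ μ<sub>m</sub>μ<sub>n</sub>/(4πε₀n²R³),
  serves as the far-field oracle.
- **Dye–DNA contact maps**: the six central bases of each of the four
  strands plus the two dyes (26 residue groups), contact = shortest
  distance between group representative points (base centre of mass;
  for dyes also both dipole ends) within 1.2 nm, averaged over frames.
- **2-D histograms** of |κ| or |J| versus R, H-/J-like classification,
  and multi-trial mean ± SD summaries.
- **Junction arm descriptors**: inter-duplex angle (IDA) and twist
  angle from principal-axis fits to base-pair centroids.

Because μs-scale all-atom trajectories are not shippable, the package
includes a seed-controlled synthetic generator: rigid-rod dimer
ensembles drawn from stated orientation/distance distributions
(stacked, end-to-end, separated, monomer modes) and a pseudo-atom mock
junction in Iso I / Iso II-like arm arrangements, both with exact
ground truth, so every analysis stage is testable end to end.

## Worked example

```r
library(hjdimer)

# a stacked (H-like) dimer ensemble: R ~ Normal(0.5 nm, 0.04 nm),
# 10 degrees angular noise, Cy5-like rods (l = 1.4 nm, mu = 15.35 D)
spec <- synthetic_spec("H_dimer", n_frames = 1000, seed = 42)
gen  <- generate_dimer_trajectory(spec)

obs <- observe_dimer(gen$trajectory, gen$dyes[[1]], gen$dyes[[2]],
                     coupling = coupling_config())
head(obs, 3)
#>   time      R_nm     kappa abs_kappa     J_meV     abs_J
#> 1    0 0.5548383 0.9649126 0.9649126  91.25087  91.25087
#> 2  100 0.4957550 0.9955317 0.9955317 112.64246 112.64246
#> 3  200 0.5521948 0.8636619 0.8636619  81.23009  81.23009

summarize_trials(obs)
#> trial_summary over 1 trial(s), 1000 observations
#>   R_nm      0.5004 +- 0.0403 (pooled sd; across-trial sd 0.0000)
#>   abs_kappa 0.9428 +- 0.0753 (pooled sd; across-trial sd 0.0000)
#>   abs_J     125.8716 +- 48.8224 (pooled sd; across-trial sd 0.0000)

table(classify_dimer(obs$abs_kappa, obs$R_nm))
#> H_like_dimer J_like_dimer
#>          831          169
```

The recovered mean R (0.50 nm) and SD (0.04 nm) match the generator's
distribution; mean |κ| < 1 and the dominant `H_like_dimer` class
confirm the stacked arrangement; |J| of order 10²  meV is the expected
coupling scale for closely spaced cyanine dimers.

The same operations run from a YAML config through the pipeline
functions (`pipeline_analyze`, `pipeline_contacts`, `pipeline_heatmap`,
`pipeline_junction`, `pipeline_synth`) or the bundled CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","hjdimer.R",package="hjdimer"))')" \
    analyze --config inst/extdata/example_config.yaml --out-prefix out/run
```

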