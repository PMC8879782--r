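# fluorovol

Fluoroscopic (time-resolved) 3D image estimation from patient-specific
PCA motion models derived from 4D cone-beam CT, driven frame by frame by
single cone-beam projections.

## The problem

In image-guided radiotherapy of lung tumors, the anatomy breathes while
the on-board imager delivers only one 2D cone-beam projection at a time.
A respiratory-correlated 4D-CBCT acquired immediately before treatment,
however, captures that day's anatomy and motion. `fluorovol` turns the
4D-CBCT into a low-dimensional motion model and then inverts each incoming
projection for the model coefficients, producing one volumetric image per
projection — a "fluoroscopic 3D" sequence from which the tumor (and any
other structure) can be localised in 3D throughout delivery.

The model is a principal-component decomposition of the displacement
vector fields (DVFs) obtained by Demons registration of every 4D-CBCT
phase to the peak-exhale reference phase:

    D(u) = D̄ + Σ_{i=1..N} u_i v_i          (N = 3 modes by default)

and each frame solves, by gradient descent with an analytic gradient,

    min_u J(u) = || M ⊙ ( P·f(D(u), f0) − λ·x ) ||²

where `f0` is the reference phase, `f(D,f0)` its deformation by `D(u)`,
`P` the cone-beam forward projector at the frame's gantry angle, `x` the
measured projection, `λ` a closed-form intensity scale, and `M` a detector
region of interest around the projected tumor and diaphragm apex.

Because clinical projection data cannot be shipped, the package includes a
deformable digital thorax phantom and acquisition simulator with known
ground-truth tumor motion (quasi-periodic SI-dominant breathing, amplitude
jitter, baseline drift), so the entire chain — Amsterdam-shroud respiratory
trace → phase sorting → short-scan FDK → Demons → PCA → per-projection
optimisation → tumor-localisation evaluation — is buildable and testable
end to end with no external data.

## Worked example

```r
library(fluorovol)

run <- run_pipeline(run_config(seed = 1), out_dir = "demo_run")
run$report
#> tumor SI error over 330 frames: MAE 0.71 mm, 95th percentile 2.02 mm
run$tracking_r
#> [1] 0.9576998
100 * run$explained$cumulative[3]
#> [1] 90.03207
```

This simulates one minute of breathing (330 projections over a 200° arc at
5.5 fps) of a 64³ digital thorax, rebuilds the motion model from the data
alone, estimates all 330 fluoroscopic volumes, and compares the estimated
tumor trace against the simulator's ground truth. The three printed
numbers mean: the tumor's superior–inferior position is recovered with a
mean absolute error of ~0.7 mm at isocenter (well under the 4 mm voxel),
the estimated and true SI traces correlate at ~0.96, and the first three
motion modes carry ~90 % of the DVF variance (breathing plus drift leave
little beyond mode 3). `demo_run/` contains the frozen config, the
respiratory trace and phase bins, the motion model (mean + modes as NIfTI,
eigenvalue spectrum as CSV), per-frame coefficients and tumor positions,
and a plain-text report.

Individual stages are ordinary functions (`amsterdam_shroud()`,
`extract_phase()`, `fdk_reconstruct()`, `demons_register()`,
`build_pca_model()`, `estimate_frame()`, ...); a thin CLI wrapper with
`run` and `phantom` subcommands lives in `inst/cli/fluorovol`.

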