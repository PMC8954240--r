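# cosreg

Deformable multimodal image registration driven by a joint co-sparse
analysis model, with a normalized-mutual-information (NMI) baseline, a
brain-mimicking phantom simulator, and standard registration metrics.

## The problem

Brain shift — intra-operative deformation of brain tissue after a
craniotomy — invalidates pre-operative MR images during image-guided
neurosurgery. Photoacoustic (PA) imaging renders the vessel meshwork
brightly in real time, so registering intra-operative PA to pre-operative MR
can track the deformation. The registration is hard because PA and MR
intensities are related nonlinearly and non-globally.

## The model

The co-sparse analysis model represents a patch `x ∈ R^n` through an
over-complete operator `Ω ∈ R^{k×n}` (k > n, unit-norm rows) whose response
`Ωx` is sparse; the index set of zero responses (the *co-support*) encodes
the local structure. Sparsity is measured by the log-square surrogate
`g(α) = Σ_k log(1 + ν α_k²)`. A pair of operators `(Ω_PA, Ω_MR)` is learned
jointly from co-located patches of an aligned image pair by ADMM, minimizing

```
(1/N) Σ_i g_joint(Ω_PA x_PA,i, Ω_MR x_MR,i) + κ [h(Ω_PA) + h(Ω_MR)] + μ [r(Ω_PA) + r(Ω_MR)]
```

where `g_joint(a, b) = Σ_k log(1 + ν(a_k² + b_k²))` couples the modalities
row-by-row and `h` (log-determinant full-rank penalty) and `r` (row
coherence penalty) exclude degenerate operators. Registration then searches
for the cubic B-spline free-form deformation `T` that maximizes the overlap
of the matched patches' co-supports: the per-window Pearson correlation of
the soft co-support indicators `log(1 + ν (Ω_s p)²)` of reference and
transform-mapped float patches, with `Ω_s = [Ω_PA; Ω_MR]` applied to both.
An NMI registrar sharing the identical optimization scaffold (pyramid,
sample windows, finite-difference descent, line search) serves as the
baseline, so method comparisons isolate the similarity measure. Evaluation
reports displacement-field RMSE, target registration error (TRE) at vessel
landmarks, and the 95th-percentile Hausdorff distance (HD95) between vessel
boundaries, all in mm.

## Worked example

Simulate the default phantom study (256×256 px at 0.6 mm: a 150×40 mm gel
body with a curved top and two vessels of 1.2/1.4 mm diameter), apply a
smooth brain-shift-like deformation (max 8 px = 4.8 mm) to the PA image,
learn the operator pair on the aligned images, register with both methods,
and evaluate against the known ground truth — five independently seeded
repeats:

```r
library(cosreg)
res <- run_experiment(experiment_config(n_repeats = 5))
res$report
```

```
Registration evaluation (mm):
       method          RMSE           TRE          HD95 runs
 unregistered 2.045 ± 0.320 1.851 ± 0.507 1.659 ± 0.261    5
        JACSM 1.896 ± 0.298 1.046 ± 0.409 0.600 ± 0.000    5
          NMI 1.892 ± 0.301 1.147 ± 0.534 0.600 ± 0.000    5
```

(~7 minutes on one CPU.) Reading the table: before registration the
simulated brain shift displaces the vessel landmarks by 1.85 mm on average;
co-sparse registration (JACSM) cuts the landmark error to 1.05 mm — the
median per-repeat reduction is 53% — and beats the NMI baseline (1.15 mm)
run under identical settings. HD95 of 0.600 mm equals one pixel: after
either registration the vessel boundaries agree to the grid resolution.
RMSE is dominated by the structureless background, where no method (and no
metric) has information to recover the field, and is therefore close to its
unregistered value for both methods.

Individual stages are exposed as ordinary functions —
`generate_phantom()`, `generate_deformation()`, `extract_patch_pairs()`,
`learn_operators()`, `register_jacsm()` / `register_nmi()`,
`evaluate_run()` — and as a thin command line
(`Rscript inst/cli/cosreg.R simulate|learn|register|evaluate|pipeline ...`)
reading and writing NIfTI images and fields, landmark CSVs and JSON
configurations.

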