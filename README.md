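# adaptherm

Adaptive 3D bioheat simulation from rotated MR thermometry.

## What it does, and for whom

During MR-guided thermal ablation (radiofrequency, microwave, focused
ultrasound), proton-resonance-frequency-shift (PRFS) thermometry
delivers one 2D temperature map at a time, while the clinician needs the
volumetric heat distribution to judge the coagulation zone and its
safety margin. When the acquisition planes are rotated uniformly around
the applicator's main axis, every image contains the full heat profile,
and a physical simulation can be kept consistent with the measurement
stream in real time. `adaptherm` is for researchers developing or
evaluating such interventional thermometry pipelines: it provides the
full reconstruction chain plus a synthetic phantom generator with known
ground truth for validation.

## The method

1. **Isothermal filter.** Each map is reduced to M isotherms: for an
   isovalue T_iso the cost map D_i = |T_i − T_iso| is built and the
   minimum-cost path, forced in the needle-axis direction (one vertex
   per image row, ≤ 1 column lateral step), is extracted on each side of
   the axis. Summing deviations along the path cancels pixel noise and
   rejects outliers; corrupted applicator-band pixels carry infinite
   cost.
2. **Diffusion-form bioheat model.** The Pennes equation is reduced to
   ∂T/∂t = D ∇²T + P(x,t,T) with D = k/(ρc) and P the perfusion sink
   w_b·c_b·(T_a − T)/(ρc) inside a known vessel mask. No explicit
   treatment-specific heat-source term is introduced: axis voxels are
   clamped to T_i = q_i·T_max, where the relative axial profile
   q_i = Σ_m |r_i − t_m| / q_max comes from the summed radial isotherm
   distances. The solver is Crank–Nicolson with Douglas ADI splitting
   and Thomas tridiagonal solves (second-order, unconditionally stable).
3. **Per-image inverse estimation.** For every incoming map the
   parameters P = {D, T_max} minimize the sum of squared differences
   between the simulation (advanced from the accepted previous state)
   and the measured temperatures at the isotherm vertices, via bounded
   Levenberg–Marquardt (D ∈ [0.1, 5] mm²/s, T_max ∈ [80, 300] °C).
4. **Evaluation.** Necrosis = thresholded volume (global threshold in
   [50, 60] °C, or the median of per-orientation best thresholds);
   overlap by Dice = 2TP/(2TP+FP+FN); spread by σ and
   SEM·1.96; robustness via orientation-subset and parameter-override
   configurations.

## Worked example

```r
library(adaptherm)

# synthetic ablation: 8 rotated orientations, one image every 6 s,
# 1 degC pixel noise, corrupted applicator band, known ground truth
spec <- phantom_spec(true_D = 1, true_Tmax = 150, noise_sigma = 1,
                     n_timepoints = 24, acquisition_interval = 6,
                     seed = 1)
phantom <- generate_series(spec)

# sequential adaptive reconstruction on the default 60x60x60 mm grid
rec <- run_reconstruction(phantom$maps, opts = list(interval = 6))
tail(rec$fits[, c("time_index", "D", "T_max", "sse_after")], 3)
#>    time_index        D    T_max sse_after
#> 22         21 1.051041 142.2068  918.7544
#> 23         22 1.137669 142.8090  917.7423
#> 24         23 1.264420 144.7968  962.8227

dice(necrosis_mask(rec$state$field, 55), phantom$true_mask)
#> [1] 0.9733075
```

The fitted diffusivity (1.26 mm²/s vs the true 1.0) and peak source
temperature (144.8 °C vs 150) recover the generator's parameters from
noisy data, and the reconstructed coagulation necrosis overlaps the
ground truth with Dice 0.97. The per-image log in `rec$fits` shows the
sum squared error of each update and the parameter trajectory.

A thin CLI wraps the same functions
(`inst/cli/adaptherm simulate|reconstruct|evaluate`), reading a JSON run
configuration and writing NIfTI volumes, CSV fit logs and JSON metrics.

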