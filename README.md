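# gubquant

Quantitative analysis of the fetal gubernaculum — the ligamentous/muscular
organ that guides testicular descent. Defective androgen-receptor (AR)
signaling in this organ is linked to cryptorchidism (undescended testis),
and characterizing it requires three quantitative readouts that this
package implements as a tested, reusable pipeline:

1. **Regional AR quantification in cleared 3D confocal volumes.** The
   nuclear counterstain channel is enhanced (anisotropic 3D median filter
   with a 3.3 × 3.3 × 4.3 µm kernel, plane-by-plane rolling-ball background
   subtraction with a 66.4 µm radius, grayscale ellipsoidal closing with a
   20 µm radius to fill the gaps between cells) and the organ segmented by
   hysteresis thresholding. The organ is partitioned into the AR-enriched
   *tip* (between the gubernacular cord and the dense muscular layer) and
   the *core* (the rest), and the mean **raw** AR intensity is reported per
   region together with the tip:core contrast.

2. **Micropipette-aspiration mechanics.** The apparent elastic modulus of
   aspirated tissue follows the elastic half-space model

   $$E_{app} = \frac{3\,a\,\Delta p}{2\pi L\,\Phi(a,w)}, \qquad
     \Phi \cong \tfrac{1}{2}\left(1+\tfrac{w}{a}\right)
     \left(1+\tfrac{w}{2a}\right)\ln\!\frac{8a}{w},$$

   with pipette inner radius $a$, wall thickness $w$, pressure magnitude
   $\Delta p$ and aspirated length $L$. Measurements are binned into
   anatomic positions by height fraction (base ≤ 25 %, midportion 40–60 %,
   tip ≥ 75 %) and compared across positions (one-way ANOVA) and
   gestational days (two-sample t or Mann-Whitney).

3. **Muscle-fiber morphometry.** Objects from a myosin-stained outgrowth
   assay are measured (area; feret diameters by rotating calipers;
   aspect = feret max/min), background debris is removed by the rule
   *delete records with aspect < 5 or area < 500 µm²*, and morphology is
   summarized per group on a log scale.

Because no raw data accompany the source study, a first-class
**synthetic-data module** generates ground-truthed inputs for every stage:
confocal phantoms (ellipsoidal organ + cord, stratified nucleus packing,
AR-enriched tip, AR-poor muscle shell, Gaussian/Poisson noise), aspiration
cohorts drawn through the forward mechanical model, and fiber tables with
known fiber/debris composition. A self-contained statistics toolbox
(one-/two-way ANOVA, pooled/Welch t, exact Mann-Whitney U, paired
t/permutation) backs all comparisons and is oracle-tested against
independent implementations.

## Worked example

```r
library(gubquant)

## ground-truthed phantom -> segmentation -> regional quantification
ph   <- generate_confocal_volume(volume_phantom_spec(seed = 1))
mask <- segment_organ(ph$volume)
dice_coefficient(mask$mask, ph$organ_mask$mask)
#> [1] 0.9496278

lab <- default_tip_partition(mask, ph$truth$cord_landmark_um,
                             fraction = 0.25, ph$volume$spacing_um)
summarize_regions(ph$volume, lab)
#>   specimen_id strain day tip_mean core_mean tip_n core_n tip_core_ratio
#> 1   phantom-1  LE/wt E17 789.4308  411.1355  3716 120659       1.920123

## aspiration cohort through the forward model, then regional analysis
co  <- generate_aspiration_cohort(aspiration_cohort_spec(seed = 1))
res <- apparent_modulus(co)
out <- regional_analysis(res)
out$region_tests[["LE/wt:E19"]]
#> one-way ANOVA: statistic = 90.26, df = 2, 42, p = 6.216e-16 [significant at alpha = 0.05]
```

The Dice coefficient is the voxel overlap between the recovered organ mask
and the generative ground truth (1 = perfect). The regional summary shows
raw AR means over the tip and core label sets; on the default phantom the
measured regional contrast (1.92 here) differs from the per-nucleus
tip:core contrast of 1.5 because AR-poor muscle nuclei dilute the core
mean and the camera background enters both means — the regional mean of a
nuclear stain conflates expression with cell density, exactly as in real
data. The contrast-calibrated preset `contrast_phantom_spec()` pins the
generative *regional* ratio for recovery experiments. The ANOVA detects
the simulated midportion-stiffer pattern of the wild-type cohort.

## Command line

```sh
gubquant simulate volume --config cfg.json --seed 1 --out sim/
gubquant segment --in sim/volume.tif --out seg/
gubquant quantify --volume sim/volume.tif --mask seg/organ_mask.tif \
         --tip sim/tip_mask.tif --out quant/
gubquant aspirate --in measurements.csv --out mech/
gubquant fibers --in records.csv --out fib/
gubquant stats --in tidy.csv --test anova --out stats/
```

(`exec/gubquant` is installed with the package; `gubquant::gub_cli()` runs
the same interface in-process.)

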