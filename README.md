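# msiStage

Quantitative histopathological staging of cutaneous squamous cell
carcinoma (cSCC) from microscopical multispectral imaging (MSI) of
ordinary H&E-stained sections.

## The problem

Grading cSCC — normal skin vs poorly vs well differentiated tumor — is
traditionally a subjective visual judgement. Under narrow-band LED
illumination (13 bands, 420–680 nm), the two H&E dyes give each tissue
structure a characteristic per-band contrast: hematoxylin absorbs
around 560 nm with a red shoulder that keeps nuclei dark at **630 nm**;
eosin peaks near 518/528 nm, making collagen and diseased epidermis
dark at **520 nm** and keratin pearls prominent at **600 nm**. `msiStage`
turns a multispectral acquisition into objective staging numbers:

1. **Preprocess** — average the 5 repeated frames per field; correct
   uneven illumination with a per-pixel 2-D gamma map,
   `O = I^γ(x,y)`, `γ = log m / log L`, where `L` is a wide Gaussian
   estimate of the illumination field and `m = mean(L)`.
2. **Stitch** — corner features + normalized patch descriptors, Lowe
   ratio matching, RANSAC similarity registration estimated once on a
   reference band and applied to all 13 bands, feather fusion, edge
   cropping.
3. **Segment** — adaptive local-mean thresholds at 520 nm (matrix) and
   600 nm (droplets/pearls); a 100-tree random-forest pixel classifier
   at 630 nm (nuclei); watershed instance splitting; fixed-LUT
   pseudo-color composites.
4. **Quantify** — 200×200 px sliding windows under exposure / centroid /
   pearl quality control (5 windows per mosaic, 2 mosaics per section =
   10 windows per section); nucleo/cytoplasmic ratio
   `NC = |nucleus px| / |tissue px − nucleus px|`; fraction of nuclei
   below 10/20/30/40 µm²; keratin-pearl counts and areas.
5. **Compare** — pooled-variance Student's t-tests and ROC/AUC
   (Mann–Whitney identity, ties at ½) for the three pairwise grade
   comparisons.

Because no public multispectral cSCC data exist, the package ships a
synthetic 13-band H&E phantom generator (Beer–Lambert rendering of
grade-specific tissue geometry with pixel-level ground truth) that every
stage is validated against. See `vignettes/msiStage-methods.Rmd` for the
full model description.

## Worked example

```r
library(msiStage)

# phantom training fields (one per grade) and the nucleus classifier
train <- lapply(c("normal", "poorly", "well"),
                function(g) simulateFields(g, 1, seed = 100)[[1]])
model <- trainNucleusRF(lapply(train, `[[`, "stack"),
                        lapply(train, `[[`, "truth"), seed = 1)

# a held-out well-differentiated field: segment all classes
field <- simulateFields("well", 1, seed = 7)[[1]]
mask  <- segmentField(field$stack, model, grade = "well")
mask
#> ClassMask 600 x 600 px
#> background     matrix  bright600    nucleus        pit
#>     124957     161293      24873      12970      35907

# QC windows and their nucleo/cytoplasmic ratios
wins <- selectWindows(field$stack, mask, grade = "well")
lab <- labels2d(mask); nuc <- classLayer(mask, "nucleus"); tissue <- lab != 0
vapply(seq_len(nrow(wins)), function(i) {
  rr <- wins$row0[i]:(wins$row0[i] + 199); cc <- wins$col0[i]:(wins$col0[i] + 199)
  ncRatio(nuc[rr, cc], tissue[rr, cc])
}, numeric(1))
#> [1] 0.0354 0.0534 0.0598 0.0913

# nuclear atypia: fraction of nuclei below each area threshold (um^2)
inst  <- splitInstances(nuc)
fractionBelow(nucleusAreas(inst, pixelSize(field$stack)))$fractions
#>     10     20     30     40
#> 0.0798 0.8685 0.9953 1.0000

# keratin pearls (the scene truly contains 8)
keratinPearlStats(splitInstances(classLayer(mask, "bright600"), classOf = 2L),
                  pixelSize(field$stack))$count
#> [1] 8
```

The window NC ratios (~0.03–0.09) sit an order of magnitude above
normal dermis (~0.001–0.004 with the default generator), which is what
drives the perfect normal-vs-tumor ROC separation; 87 % of this field's
nuclei fall below the 20 µm² atypia threshold, typical for the
well-differentiated grade (poorly differentiated phantoms sit near
10–20 %).

A full study — simulate, preprocess, stitch, segment, quantify, compare
— is one call:

```r
res <- runPipeline(defaultRunConfig(seed = 0), outDir = "runs/exp1")
res$reports$nc_ratio$summary
#>               pair   metric positive n_a n_b      t   p_value auc auc_oriented
#>   normal_vs_poorly nc_ratio   poorly  10  10 -14.06 3.787e-11   1            1
#>     normal_vs_well nc_ratio     well  10  10 -16.03 4.220e-12   1            1
#>     poorly_vs_well nc_ratio   poorly  10  10  12.61 2.276e-10   1            1
#>    normal_vs_tumor nc_ratio    tumor  10  20  -3.54 1.421e-03   1            1
```

(Numbers above are from a one-slide-per-grade run; the output directory
additionally contains per-mosaic masks, pseudo-color composites,
blue/red atypia overlays, per-pair ROC curves as CSV + PNG, and a
manifest with the config hash. Reruns with the same config are
byte-identical on all CSV outputs.)

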