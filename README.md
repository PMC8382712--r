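# mctsnuclei

Single-cell nuclear cytometry of DNA-stained multicellular tumor
spheroids (MCTS).

Spheroids are the workhorse 3D in vitro model of solid tumors, but most
single-cell readouts (flow cytometry, sequencing) destroy the spatial
information that makes them interesting. This package extracts that
information from a *single* fluorophore: a confocal z-stack of a cleared,
DNA-counterstained (e.g. DAPI) spheroid. Because a stoichiometric DNA
stain reports genome content — 2N in G1, 4N in G2/M, in between during S —
segmented nuclei carry their cell-cycle state in their integrated stain
intensity, leaving the rest of the spectrum free for other probes. It is
aimed at microscopy and image-cytometry groups running spheroid drug
screens or tumor-biology experiments, and at methods developers who need
a fully ground-truthed synthetic benchmark for 3D nuclear segmentation.

What it does:

* **3D nuclear segmentation** — the classical three-stage pipeline:
  z-interpolation to isotropic voxels, Gaussian smoothing, local-mean
  adaptive threshold (window = stack volume / 8), hole filling and
  debris removal; seeds from the H-minima-suppressed Euclidean distance
  transform; marker-controlled watershed; pruning of seeds whose objects
  fall below 70 % of the median volume; flagging of clusters 40 % above
  the median with programmatic replacement-seed injection; final
  watershed. All in exact 3D, deterministic, in Rcpp.
* **Per-nucleus measurement** — volume, marching-tetrahedra surface
  area, extent, principal axes from second central moments (full axis
  length `2√(5λ)`, regionprops3 semantics), sphericity
  `π^(1/3)(6V)^(2/3)/A`, integrated per-channel intensity, plus the
  60–180 %-of-median volume gate.
* **Cell-cycle classification** — FUCCI reference labelling, linear
  depth correction, per-spheroid median normalization of DNA content,
  the optimal TPR−FPR intensity threshold, and a balanced
  RBF-kernel SVM on neighbor-normalized volumetrics
  (`e1071` underneath), with full confusion-matrix reporting
  (TPR, FPR, precision, accuracy, balanced accuracy = (TPR+TNR)/2).
* **Spatial organization** — spheroid surface by morphological closing,
  nucleus–perimeter distances, concentric 10 µm layers with per-layer
  S/G2 counts and fractions, nuclear alignment angles
  (α = arcsin|r̂·ê₃|: 0° radial, 90° tangential), axis ratios, radial
  trends, and the axial-elongation artefact fit.
* **Synthetic phantoms** — seeded, bit-reproducible spheroid stacks with
  exported truth labels and per-nucleus truth tables, plus a
  record-level statistical twin for cohort-scale experiments.

## Worked example

Generate a 60-nucleus phantom spheroid (radius 45 µm) with DAPI + FUCCI
channels, segment it, and run the full measurement chain:

```r
library(mctsnuclei)

spec <- phantom_spec(spheroid_radius = 45, n_nuclei = 60, seed = 7)
ph   <- generate_phantom(spec)

seg  <- segment_nuclei(ph$channels$dapi, segmentation_config(), verbose = TRUE)
#> foreground voxels: 704036
#> initial seeds: 60
#> seeds after pruning: 59
#> oversized clusters: 5
#> final objects: 59

chans <- lapply(ph$channels, interpolate_isotropic)
rec   <- measure_nuclei(seg$labels, chans, spheroid_id = "demo")
gate  <- volume_gate(rec)          # keep 60-180 % of the median volume
rec   <- gate$kept                 # 58 of 59 nuclei pass

rec <- depth_correct(rec, "itg_dapi")          # undo depth attenuation
rec <- normalize_dna(rec, "itg_dapi_corrected")# 2N -> 1, 4N -> 2
rec <- classify_fucci(rec)                     # reporter-based reference
table(rec$fucci_class)
#>   G1  G1S  NONTRANSFECTED  SG2
#>    7    5              44    2

summary(rec$dna_content)
#>  Min. 1st Qu. Median  Mean 3rd Qu.  Max.
#>  0.98    0.99   1.00  1.07    1.02  2.05

geom <- approximate_surface(seg$labels)        # closed spheroid body
rec  <- filter_detached(rec, geom)$kept
rec$perimeter_distance <- perimeter_distance(rec, geom)
rec$alignment_angle    <- record_alignment_angle(rec, geom$center)
head(rec[, c("label", "volume", "sphericity", "dna_content",
             "perimeter_distance", "alignment_angle")], 4)
#>   label volume sphericity dna_content perimeter_distance alignment_angle
#> 1     1   1004      0.948       0.992               4.83           16.40
#> 2     2    729      0.934       1.059               4.07           81.98
#> 3     3    928      0.941       0.986               4.91            6.72
#> 4     4   1224      0.949       0.989               5.98            3.37
```

Reading the output: 59 of the 60 phantom nuclei are recovered (one small
nucleus loses its seed to the 70 %-of-median pruning rule; the 5 flagged
clusters are size outliers, one of which the volume gate then removes);
DNA content sits at 1 for the diploid majority with S/G2 cells ranging up
to 2; volumes are ~700–1200 µm³ with sphericities ~0.94; the four shown
nuclei sit 4–6 µm under the spheroid surface at mostly radial alignment
angles. `threshold_classify(rec$dna_content, 1.25)` or a trained
`train_svm()` model then turns DNA content (+ volumetrics) into G1/S-G2
calls, and `assign_layers()` / `layer_stats()` / `radial_trend()` map
them across the spheroid.

The same flow is scriptable end to end from one YAML config with
`run_pipeline()`, or from a shell via `inst/cli/mcts_nucleus.R
(run|simulate|segment|features)`.

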