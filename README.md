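# ki67count

Automated measurement of the Ki67 proliferation index from multiplexed
fluorescence images of tumor tissue.

## The problem

The Ki67 index — the percentage of tumor cell nuclei expressing the
proliferation marker Ki67 — is a key prognostic quantity in breast cancer,
graded low (index ≤ 10%), moderate (> 10% and < 50%) or high (≥ 50%).
Manual counting is slow and visual estimation is unreliable, especially at
low and moderate grades. Multiplexed fluorescence imaging yields three
aligned single-channel views of one field: DAPI (all cell nuclei), Ki67,
and cytokeratin (CK, epithelial cytoplasm). Because CK marks epithelium,
its stained area defines the tumor compartment; stromal nuclei outside it
must not be counted even when Ki67-positive.

`ki67count` is for image-analysis and pathology-informatics users who have
such unmixed three-channel fields (TIFF/PNG, 8- or 16-bit) and want a
reproducible, parameter-explicit index measurement, together with the
validation machinery to trust it.

## The method

For a field with nuclei plane $D$, Ki67 plane $K$ and CK plane $C$:

1. per channel: median filter, percentile contrast stretch;
2. Otsu binarization (256-bin histogram, threshold $t^\*$ maximizing the
   between-class variance $\sigma_B^2(t) = w_0 w_1 (\mu_0 - \mu_1)^2$),
   then morphological opening/closing and hole filling, giving masks
   $M_D, M_K, M_C$;
3. touching nuclei in $M_D$ are split by marker-controlled watershed: the
   Euclidean distance transform is computed, its regional maxima (thinned
   to a minimum mutual distance) seed a watershed on the negated distance
   transform; area-bound postprocessing corrects over- and
   under-segmentation;
4. nucleus $i$ with centroid $c_i$ and pixel set $P_i$ is counted iff
   $c_i \in M_C$, and is Ki67-positive iff
   $|P_i \cap M_K| / |P_i| \ge \tau$ (default $\tau = 0.5$);
5. the index is
   $100 \times \#\{i : c_i \in M_C,\ \text{positive}\} / \#\{i : c_i \in M_C\}$,
   graded by the clinical bands above.

The package also provides the grid-assisted reference counting rule used
for careful manual scoring (3 × 3 partition, objects on each part's
upper/left lines counted, right/bottom ignored — realized as half-open
assignment of centroids), inter-method agreement statistics (repeated
measures ANOVA with paired contrasts, two-way mixed single-measure
consistency ICC, mid-rank Spearman correlation, stratified by grade), and
a seeded synthetic-field generator with exact ground truth.

## A worked example

```r
library(ki67count)

spec  <- scene_spec(seed = 1)     # default study conditions, true index 25%
scene <- generate_scene(spec)     # three planes + exact ground truth
fit   <- ki67_count(scene$field)  # the automated count
fit
#> <ki67_result> 293 nuclei in tumor compartment, 77 Ki67-positive
#>   Ki67 index: 26.28% (grade: moderate)
scene$truth$true_index_percent
#> [1] 25
```

The scene has 300 tumor nuclei (75 Ki67-positive) in a cytokeratin region
plus 40 stromal distractors, with touching-nucleus clusters, blur and
noise. The pipeline finds 293 nuclei inside the tumor compartment and
calls 77 positive: an index of 26.28% against a ground truth of 25%, and
the correct moderate grade. `summary(fit)` adds the per-stage detail
(Otsu thresholds, nucleus area distribution), `plot(fit)` draws the
pseudocolor overlay (green = counted nuclei, cyan = counted Ki67-positive
nuclei), and `write_results()` writes `result.csv`, `records.csv`, label
image, overlay and a run log.

A command-line interface wrapping the same functions (subcommands
`simulate`, `count`, `markcount`, `compare`) is installed at
`inst/scripts/ki67_cli.R`.

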