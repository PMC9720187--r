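# surflight

Surface-based grid-searchlight multivariate pattern analysis (MVPA) for
fMRI decoding on spherical cortical templates.

Searchlight MVPA maps *where* local activity patterns carry information
about experimental conditions by repeating a decoding test in a small
neighborhood around every cortical location. surflight implements the
surface variant in which each neighborhood is an n₁ × n₁ grid of angular
cells on the registration sphere: the sphere is rotated so the current
vertex p(α, β) sits at the origin, nearby full-resolution vertices are
binned into cells of 1/35 rad (defaults: 11 cells per side, circular mask
of radius n₁/2), per-cell BOLD averages form a small image, and a
classifier decodes condition labels under leave-one-run-out
cross-validation. Searchlight centers live on a downsampled geodesic
sphere built by icosahedron subdivision (n edge divisions → 10n² + 2
vertices; 40 divisions → 16,002 centers vs the 163,842-vertex
full-resolution template). Group inference tests subject accuracy maps
against chance (1/k for k classes) with a one-tailed t-test, thresholds at
a vertex-wise −log₁₀(p) level, groups suprathreshold vertices into
clusters by mesh adjacency, and controls family-wise error with a
max-cluster-size sign-flip permutation null: with 2,000 permutations and
FWE 0.01, clusters must be strictly larger than the 20th largest
permutation maximum.

The package covers the full scriptable pipeline: template construction,
searchlight layout building and caching, paradigm/surface-series readers,
trial extraction at a fixed post-onset latency, SVM and CNN decoding
streams, group inference, a synthetic ground-truth dataset generator, and
a command-line interface (`inst/cli/surflight.R`).

## Worked example

Simulate 8 subjects × 3 runs with a 2-condition information patch injected
around a known vertex, decode every searchlight, and run group inference:

```r
library(surflight)

cfg <- pipeline_config(
  simulate    = sim_config(n_subjects = 8, seed = 11),  # ground-truth patch at vertex 1
  contrast    = "1 vs 2",        # two conditions, chance = 0.5
  n_perm      = 500,
  null_method = "subject",       # subject-level sign flips (see vignette)
  seed        = 11)
res <- run_pipeline(cfg, "demo_out")

length(res$inference$surviving)
#> [1] 1
res$report
#>   size_vertices peak_t peak_vertex peak_alpha peak_beta size_mm2
#> 1             6    239           1      2.124         0     4086
max(res$maps[[1]]$accuracy)
#> [1] 1
```

One cluster of 6 downsampled vertices survives FWE correction, peaking at
vertex 1 — exactly the vertex where the generator injected the pattern
patch. `peak_t` is the cluster's largest t value (huge here because
decoding accuracy saturates near 1 inside the patch); `size_mm2` converts
the cluster size to surface area on a 100 mm sphere. Outputs (per-subject
accuracy maps, t-map, null maxima, cluster table, manifest with all
parameters and seeds) are written under `demo_out/`.

The same analysis runs from a shell:

```sh
Rscript inst/cli/surflight.R run --data-dir Subjects_Dir --contrast "1 vs 4" \
  --high-div 128 --low-div 40 --timepoint 7 --n-perm 2000 --out results/
```

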