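# pollinet

An agent-based model of bee foraging and flower visitation over binary
forest/open landscapes, with everything needed to run in-silico
deforestation experiments on plant–pollinator networks: a fractal
neutral-landscape generator with nested habitat-loss gradients,
FRAGSTATS-style class metrics, bipartite network descriptors, and a
GLM/Spearman analysis layer.

It is aimed at landscape and pollination ecologists who want to ask how
landscape pattern shapes network structure when sampling is perfect — a
question field data cannot answer, because real networks are always
under-sampled.

## The model in brief

Bees forage over a 100 × 100 raster of 10 m cells (1 km², non-wrapping).
Twenty flower species occupy random cells of their habitat guild (ten
forest, ten open; 20 cells each). Twenty bee species in three functional
groups — 9 specialists (flight energy 50 cell-lengths, diet of 1 flower
species, forest-only nesting), 8 generalists (100, 4, nest anywhere) and
3 super-generalists (200, 8, nest anywhere) — leave their nests with 10
individuals each and move by a correlated random walk: wrapped-normal
turning angles (σ = 40°), normal step lengths (mean 2 cells = 20 m,
SD 0.5, floored at 0.1), specular reflection at world edges, one energy
unit per cell-length flown. A bee landing on a cell that hosts a flower
of its diet records a visit; visits are summed into a bee × flower
matrix — the pollination network. Flights end when energy is exhausted
(all well before the 150-tick cap).

Networks are summarised by connectance, NODF nestedness, the
complementary-specialization index

H₂′ = (H₂max − H₂) / (H₂max − H₂min),  H₂ = −Σ pᵢⱼ ln pᵢⱼ,

network size and web asymmetry; landscapes by PLAND, AREA_MN, AREA_AM,
SHAPE_MN, SHAPE_AM (SHAPE = 0.25·p/√a) and CONNECT (patch pairs within
50 m). The default experiment crosses 11 forest-cover levels (0–100%)
with 10 replicated nested gradients (Hurst exponent 0.9) and analyses the
110 runs with 30 single-predictor GLMs (Gaussian; Poisson for network
size) plus the Spearman correlations among landscape metrics.

## Worked example

```r
library(pollinet)

g <- habitat_gradient(fractal_surface(hurst = 0.9, seed = 5),
                      levels = 0.5)$grids[[1]]
g
#> <landscape_grid> 100 x 100 cells of 10 m, forest cover 50.0%

landscape_metrics(g)
#> # A tibble: 1 × 7
#>   pland area_mn area_am shape_mn shape_am connect n_patches
#> 1    50    3.85    44.9     1.39     2.94    14.1        13

m <- run_simulation(g, community_config(), seed = 42)
m
#> <visit_matrix> 20 bee x 20 flower species, 100 visits over 42 links (seed 42)

network_metrics(m)
#> # A tibble: 1 × 7
#>   connectance nestedness    h2  size asymmetry n_links nestedness_method
#> 1       0.179       23.2 0.561    31     0.161      42 nodf
```

At 50% cover this landscape holds 13 forest patches; the mean patch is
3.85 ha but the area-weighted mean is 44.9 ha (one large patch dominates),
and 14.1% of patch pairs lie within 50 m. The simulated network connects
31 of the 40 species through 42 distinct links (connectance 0.179 on the
active matrix) with moderate specialization (H₂′ = 0.561) and slightly
more active plant than bee species (asymmetry 0.161).

A full experiment and its analysis:

```r
design  <- experiment_design(base_seed = 1)   # 11 levels x 10 replicates
results <- run_experiment(design)             # ~40 s on one CPU
analysis <- analyze_experiment(results)       # 30 GLMs + Spearman matrix
plot_level_summary(results)                   # mean ± SE vs forest cover
```

`reproduce_study("out/", base_seed = 1)` runs the whole pipeline and
writes maps, visitation matrices, result and analysis tables, figures and
a manifest of seeds and file digests. A thin command-line front end with
the same stages lives in `inst/cli/pollinet.R`.

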