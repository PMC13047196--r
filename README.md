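# micasa

**Mi**crobial **c**ommunity **a**ssembly, **s**tructure and **a**ssociation
networks for gradient-design soil microbiomes.

Casing soil — the layer spread over colonized substrate to trigger mushroom
fruiting — is a small, tractable microbial habitat whose community shifts
along management gradients such as the proportion of peat in the mix.
Understanding those shifts takes more than diversity indices: one wants to
know *how* the communities assemble (selection versus dispersal versus
drift), how their co-occurrence networks are wired and how stable those
networks are, and which soil variables drive the turnover. micasa packages
that entire workflow for OTU tables from crossed gradient designs
(groups × stages × replicates), together with a synthetic community
generator so every estimator can be validated against known ground truth.

## What it computes

| Stage | Methods |
|---|---|
| Alpha diversity | richness, bias-corrected Chao1, Shannon (ln), Pielou evenness, inverse Simpson; one-way ANOVA + Tukey HSD |
| Beta structure | Bray–Curtis, PCoA (negative eigenvalues reported), PERMANOVA / ANOSIM / MRPP, per-group core-taxon screen (occupancy > 80 %, abundance ≥ 0.1 %) |
| Assembly | pairwise βMNTD, βNTI against a taxa-shuffle null, Raup–Crick on Bray–Curtis against a pool null; five-process classification (variable / homogeneous selection, dispersal limitation, homogenizing dispersal, undominated) |
| Networks | per-group correlation networks at \|r\| ≥ 0.75 on log10 relative abundance; topology (2E/N, geodesic, clustering, modularity, scale-free R²), degree-preserving random nulls, robustness under 50 % random node removal, vulnerability via global efficiency, Zi–Pi keystone roles |
| Drivers | partial Mantel screen over the physicochemical table, variance partitioning between physical and chemical predictor sets |

The null-model machinery (βMNTD/βNTI, Raup–Crick, process classifier), the
network stability metrics and the generator are implemented in the package;
standard steps (distances, ordination, permutation tests, Mantel, VPA,
graph algorithms, trees) are delegated to vegan, igraph and ape.

The classification rule per sample pair:

```
βNTI > +2            → variable selection
βNTI < −2            → homogeneous selection
|βNTI| < 2, RC > +0.95 → dispersal limitation
|βNTI| < 2, RC < −0.95 → homogenizing dispersal
otherwise            → undominated
```

## Worked example

```r
library(micasa)

design <- sim_design(n_taxa_pool = 120, groups = c(0, 50, 100), stages = 3,
                     replicates = 3, depth = 10000, selection_strength = 5,
                     dispersal_regime = "limited", dispersal_sigma = 1,
                     trait_signal = 1, seed = 1)
cfg <- run_config(design = design, out_dir = tempfile(), n_perm = 499,
                  n_null = 99, n_rand = 20, n_rep_robustness = 50, seed = 1)
man <- run_all(cfg, quiet = TRUE)
res <- man$results

res$beta$permanova
#> $pseudo_F
#> [1] 11.93799
#> $p
#> [1] 0.002

round(res$assembly$fractions, 3)
#>     variable_selection homogeneous_selection dispersal_limitation homogenizing_dispersal undominated
#> 0                0.222                     0                0.500                      0       0.278
#> 100              0.000                     0                0.833                      0       0.167
#> 50               0.028                     0                0.972                      0       0.000

res$networks[["50"]]$stats
#> Nodes 39 | links 90 | avg connectivity 4.615
#>   geodesic 2.377 | clustering 0.446 | modularity 0.376 (11 modules)
#>   positive links 45.6% | power-law R2 0.341

head(res$mantel[order(-res$mantel$r), ], 3)
#>       variable         r     p
#> 10     density 0.3925278 0.002
#> 6           TS 0.3633952 0.002
#> 11 unit_weight 0.3311066 0.002
```

Reading it: the three peat groups separate strongly in composition
(PERMANOVA pseudo-F 11.9, p = 0.002, the floor for 499 permutations). The
generating regime was dispersal-limited with moderate selection, and the
partition recovers exactly that — dispersal limitation is the modal process
in every group (50–97 % of pairs), with a variable-selection minority where
environments contrast. The CT50 network retains 39 of 120 taxa at the 80 %
occupancy filter and links them at |r| ≥ 0.75, and the variables the Mantel
screen ranks first (density, total sulfur, unit weight) are noisy
transforms of the latent peat axis the generator used — the ground truth.

Each run writes its outputs (TSV/JSON per stage), the resolved
configuration, and an md5 manifest; identical config and seed reproduce
identical hashes. A command-line wrapper lives at
`inst/scripts/run_pipeline.R`.

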