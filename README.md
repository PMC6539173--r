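# rmtnet

Microbial co-occurrence network inference with an automatic,
random-matrix-theory (RMT) based correlation threshold — plus the
downstream analyses that typically accompany it: fast-greedy module
separation, Zi–Pi keystone-role classification, module-eigengene vs
host-trait correlation, and (partial) Mantel tests relating node
connectivity to trait association.

## Who this is for

Microbiome researchers with an OTU (or ASV) abundance table over a small
number of samples — the 6–9 samples per treatment group typical of animal
experiments — who want a co-occurrence network whose edge threshold is
chosen by the data rather than by hand, and who want to relate the
resulting modules to host physiology (e.g. blood urea nitrogen, creatinine
ratio, malondialdehyde, superoxide dismutase activity).

## The method

Let `X` be the filtered, transformed OTU × sample abundance matrix and
`S = |cor(X)|` its absolute Pearson similarity matrix. For a candidate
cutoff `s_t`, zero all entries below `s_t`, drop isolated OTUs, and take
the eigenvalues `λ_1 ≤ … ≤ λ_n` of the thresholded matrix. After spectral
unfolding (rescaling so the mean local spacing is 1), the nearest-neighbor
spacing distribution `P(d)` distinguishes two regimes:

* noise-dominated (GOE): `P(d) = (πd/2)·exp(−πd²/4)` — eigenvalue repulsion;
* structure-dominated (Poisson): `P(d) = exp(−d)` — independent blocks.

The selected threshold is the lowest grid candidate that begins a stable
run of Poisson-consistent candidates (chi-square goodness of fit,
`p > 0.05`). Downstream: Clauset–Newman–Moore fast-greedy modularity
(`Q = Σ_m (e_mm − a_m²)`), within-module degree `Zi` and participation
coefficient `Pi = 1 − Σ_t (k_it/k_i)²` with Olesen role quadrants at
`Zi = 2.5`, `Pi = 0.62`, module eigengenes (first PC of standardized
member profiles), OTU significance `GS = r²` against traits, and seeded
permutation Mantel / partial Mantel tests.

A synthetic community generator (`simulate_community`) with known module,
connector, and trait-coupling ground truth makes every stage testable
without sequencing data.

## Worked example

```r
library(rmtnet)

sc  <- simulate_community(synthetic_config(seed = 1))
ab  <- sc$otu |> prevalence_filter() |> transform_abundance()
sim <- pearson_similarity(ab)

scan <- detect_rmt_threshold(sim)
#> <rmt_scan> 70 candidates, selected threshold s_t = 0.70
#>   (lowest candidate starting 3 consecutive p_poisson > 0.05)

net   <- build_network(sim, scan$threshold)
part  <- fast_greedy_modules(net)
#> <module_partition> 125 nodes in 6 modules, Q = 0.681 (fast_greedy (unweighted Q))

roles <- node_roles(net, part)
table(roles$role)
#>  connector peripheral
#>          2        123

egs <- module_eigengenes(ab, part)
module_trait_table(egs, sc$truth$traits) |> dplyr::arrange(p)
#> # A tibble: 16 × 7
#>   module module_label trait      r      p     n module_size
#> 1      2 M02          CR     0.756 0.0301     8          31
#> 2      2 M02          BUN    0.718 0.0448     8          31
#> 3      4 M04          SOD    0.717 0.0454     8          18
#> ...

score_recovery(part, sc$truth, roles)
#> # A tibble: 1 × 4
#>     ari n_structured n_recovered connector_recall
#> 1     1           76          76                0
```

Reading the output: the scan placed the cutoff at `|r| ≥ 0.70`, above the
noise floor and below the planted within-module correlation (0.9). The
fast-greedy partition recovers the four planted modules exactly
(`ari = 1`); the inferred module M02 corresponds to the planted module
whose latent factor drives the BUN and CR traits, and its eigengene
correlates with both (raw two-sided p ≈ 0.03–0.04 at n = 8). Almost all
nodes are peripherals, the expected pattern for strongly thresholded
modular networks.

Plots: `autoplot(scan)` (p-value vs candidate cutoff), `plot_zipi(roles)`
(Zi–Pi role quadrants), `plot_module_trait(mt)` (module × trait heatmap).
Exports: `export_network(net, roles, part, format = "graphml", path = ...)`
for Cytoscape-class viewers (also `"sif"` and `"edge-tsv"`), or
`run_pipeline(pipeline_config(...))` for the whole flow with TSV outputs
and a JSON run manifest. A thin CLI lives at `inst/cli/rmtnet.R`.

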