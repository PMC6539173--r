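---
title: "Methods: RMT-thresholded co-occurrence networks and trait association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RMT-thresholded co-occurrence networks and trait association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmtnet)
```

## The problem

Correlation-based co-occurrence networks for microbial communities face one
central methodological question: where to cut the similarity matrix. A
Pearson correlation of OTU abundance profiles across a handful of samples is
noisy; cut too low and the network is dominated by false edges, cut too high
and real structure is discarded. `rmtnet` implements the random-matrix-theory
answer: scan candidate cutoffs and place the threshold where the *eigenvalue
fluctuation statistics* of the thresholded similarity matrix change character.

A dense matrix of partly spurious correlations behaves like a correlated
random matrix: its eigenvalues repel, and the nearest-neighbor spacing
distribution (NNSD) of the unfolded spectrum follows the Wigner surmise of
the Gaussian orthogonal ensemble (GOE),
$P(d) = (\pi d / 2)\, e^{-\pi d^2/4}$. Once the cutoff removes the noise
floor and only system-specific block structure remains, eigenvalues from
effectively independent blocks superpose and the spacings become Poisson,
$P(d) = e^{-d}$. The transition between the two regimes is an intrinsic
property of the matrix, which is what makes the threshold *automatic* rather
than user-chosen.

## Pipeline and defaults

1. **Prevalence filter** (`prevalence_filter`, default 0.5): OTUs detected
   (count > 0) in fewer than `ceiling(0.5 * n_samples)` samples are removed.
   Ties at the boundary are retained, since the exclusion rule is stated for
   OTUs present in *less than* half of the samples.
2. **Abundance transform** (`transform_abundance`, default
   `log10_relative`): per-sample relative abundances, then
   `log10(x + pseudocount)` with pseudocount equal to half the smallest
   nonzero relative abundance. The half-minimum rule scales with the data,
   so toy tables and deep tables behave alike; the pseudocount used is
   recorded on the returned object. `raw` and `relative` are selectable —
   which transform the original molecular-ecology pipelines applied is not
   documented, so the choice is explicit and logged per run.
3. **Similarity** (`pearson_similarity`): `s = |r|` with the sign kept
   separately for edge annotation. Zero-variance profiles have undefined
   `r`; they get similarity 0 with a warning rather than silent removal.
4. **Threshold scan** (`detect_rmt_threshold`): grid 0.30–0.99 by 0.01,
   Poisson-consistency level `alpha = 0.05` (the conventional
   "significance > 0.05" stringency), spectral floor `min_nodes = 50`.
5. **Modules** (`fast_greedy_modules`): Clauset–Newman–Moore agglomeration
   via igraph, with the cut along the merge dendrogram re-selected by this
   package's own unweighted modularity evaluation (ties to the coarser
   partition), which makes the returned `Q` exactly
   `modularity_q(net, partition)` and the procedure deterministic.
6. **Roles** (`node_roles`): within-module degree z-score `Zi` (population
   SD; `sd = 0` modules give `Zi = 0` instead of NaN) and participation
   coefficient `Pi = 1 - sum_t (k_it/k_i)^2`. Olesen quadrants at
   `Zi = 2.5`, `Pi = 0.62`: module hubs require `Zi > 2.5` *and*
   `Pi <= 0.62`; connectors `Pi > 0.62`; both boundaries are non-strict on
   the peripheral side, following the published wording of the cuts.
7. **Trait association** (`module_eigengene`, `module_trait_table`,
   `otu_significance`, `taxon_connectivity_mantel`): eigengenes are the
   first principal component of the standardized member profiles (minimum
   module size 6, the floor used when modules are related to physiology),
   oriented to correlate non-negatively with the mean member profile and
   standardized to zero mean and unit population SD. Module–trait p-values
   are raw two-sided Pearson t-tests (`p.adjust` columns available behind a
   flag); the partial Mantel construction for taxon-level tests is
   D1 = |k_i − k_j| on degree, D2 = |GS_i − GS_j| for the focal trait,
   D3 = Euclidean distance over the remaining traits' GS. The published
   analyses describe this step in one sentence; our distance construction
   is declared in the result (`control` tag) rather than inferred.

Degrees and modularity are unweighted by default: every edge has already
passed a stringent threshold, so weights are compressed into a narrow band
just above the cutoff and carry little extra information. Weighted variants
sit behind `weighted = TRUE`.

## Numerical choices in the spectral step

**Unfolding stiffness.** The cumulative spectral function is fitted with a
cubic smoothing spline at plotting positions $(i - 1/2)/n$, monotonicity
enforced by a running maximum. The spline's flexibility is deliberately
capped at `df = min(10, max(4, round(n/15)))`. This is the one place where
an "obvious" default is wrong: letting generalized cross-validation pick the
smoothness makes the spline track the empirical staircase itself, which maps
every spectrum to near-uniform spacings and erases exactly the
Poisson-vs-GOE signal being tested. A stiff spline follows the global
density, leaves the local fluctuations intact, and keeps the mean unfolded
spacing at 1 (the plotting-position construction makes the mean spacing
$n(F(\lambda_{max}) - F(\lambda_{min}))/(n-1) \approx 1$ without any
rescaling step).

**Spacing goodness of fit.** Spacings are binned on [0, 3] at fixed width
0.1 plus an overflow bin, with expected counts from the closed-form ensemble
CDFs. At the spacing counts a scan actually sees (50–150 spacings), most
raw bins have expected counts far below the chi-square validity rule and the
test rejects a true Poisson sample about half the time. Adjacent bins are
therefore pooled until each pooled bin has expected count ≥ 5 (Cochran's
rule) before forming the Pearson statistic with `occupied - 1` degrees of
freedom. The fixed binning keeps the statistic deterministic; the pooling
restores its calibration.

**Threshold selection rule.** The selected cutoff is the *lowest grid
candidate that begins a run of 3 consecutive Poisson-consistent candidates*
(`run_length = 3`). A single passing candidate can be a fluke of the
chi-square at modest spacing counts, so "first crossing" is too eager. The
opposite extreme — demanding that every higher candidate also pass — fails
for a structural reason: at very high cutoffs the network degenerates into
near-pure cliques whose massively degenerate spectra produce atomic spacing
distributions that fail the Poisson fit, so a full-suffix condition is
almost never satisfiable. A short stable run is the middle ground: robust to
single-point flukes, not hostage to the degenerate clique regime.
Candidates retaining fewer than `min_nodes = 50` OTUs are skipped (not
failed): below that, spectral statistics are too noisy to interpret.

**Degenerate inputs.** All-identical eigenvalues abort unfolding; fewer
than 20 spacings abort the GOF with advice to use a larger network; an
empty thresholded matrix is a signal object during scanning and an error
only when a network is explicitly requested. The `|r|` matrix (not signed
`r`) feeds the spectral step; signs are kept for edge annotation — the
alternative (signed spectra) is noted as an open variant but not
implemented.

## What the synthetic generator emulates — and what it does not

`simulate_community` emulates the study regime this class of analysis runs
in: 6–9 samples per group (default 8), a few hundred OTUs of which a
minority co-vary in tight modules, heavy-tailed abundances
(lognormal-Poisson counts; negative binomial selectable), and physiological
traits (BUN, CR, MDA, SOD) coupled to module latent factors.

Defaults, chosen once: 4 modules of sizes 22/20/18/16 at within-module
correlation target 0.9, 50 unstructured OTUs, 2 connector OTUs, traits BUN
and CR coupled to module 1 (targets 0.9, 0.8), MDA to module 2 (0.7), SOD
unstructured. Several modules (rather than two) are the realistic and
favorable case for the method: the Poisson regime at the transition arises
from superposing several independent block spectra.

Two calibration details matter at n = 8. First, module factors are
orthogonalized in-sample: independently drawn factors over 8 samples
correlate with standard deviation ≈ 0.38, so without orthogonalization
"distinct" planted modules are frequently not distinct in the realized data
and the ground-truth labels would simply be wrong. Second, member noise is
residualized against the own-module factor, so pairwise within-module
correlations concentrate at the target instead of scattering around it.
Trait vectors are scaled to their target correlation exactly in-sample.

Known departures from real data:

* **Compositional closure.** The generator plants structure on the
  log-abundance scale; converting to relative abundances couples every OTU
  to the dominant ones. The pipeline operates on the compositional scale
  (as the field's pipelines do), so realized within-module correlations
  there are somewhat below the planted target. Tests that verify the
  *planted* structure therefore measure it on log counts.
* **Connectors.** A node loading equally on two orthogonal factors has
  per-module correlation at most $\rho/\sqrt{2} \le 0.70$ — below the
  thresholds the RMT scan typically selects in this regime — so planted
  connectors usually fall out of the network rather than appearing as
  Zi–Pi connectors. Real connectors presumably arise from *correlated*
  modules, which the orthogonal-factor design deliberately excludes. The
  Zi/Pi machinery is therefore validated by exact brute-force oracles on
  arbitrary graphs, not by connector recovery.
* No sequencing-depth variation, chimeras, or phylogenetically structured
  taxonomy; lineage strings are labels, not biology.

Consequently, a passing test suite demonstrates that the *method* behaves
as specified on data with known truth in the study's sample-size regime; it
does not certify performance on real 16S data, where unmodeled effects
(compositionality, depth variation, correlated modules) are in play.

## Problem sizes used by the test suite

The suite exercises the scan on ~130-OTU communities (10 seeds), the
spacing GOF on 100 replicates of 500 spacings per family, Mantel
calibration on 500 null replicates at 199 permutations, and Zi/Pi oracles
on 100 random graphs of up to 20 nodes — sizes chosen so the full suite
runs in well under a minute per property while keeping Monte Carlo standard
errors small relative to the asserted bands.

## Limitations

* With 6–9 samples, individual pairwise correlations are extremely noisy;
  the method's protection is the stringency of the selected threshold, not
  the precision of any single edge.
* The chi-square spacing test at 50–150 spacings has limited power;
  adjacent scan candidates can disagree, which is why the selection rule
  smooths over a run of candidates.
* Module–trait p-values are raw, mirroring the customary presentation;
  with 20+ module × trait pairs, a few nominally significant correlations
  are expected by chance. The `adjust` flag adds Benjamini–Hochberg
  columns.
* Eigengenes summarize a module by its dominant axis; modules with low
  variance-explained are poorly represented by any single vector (the
  fraction is reported as `variance_explained`).

## A worked run

```{r, eval = FALSE}
sc <- simulate_community(synthetic_config(seed = 1))
ab <- sc$otu |> prevalence_filter() |> transform_abundance()
sim <- pearson_similarity(ab)
scan <- detect_rmt_threshold(sim)
autoplot(scan)

net <- build_network(sim, scan$threshold)
part <- fast_greedy_modules(net)
roles <- node_roles(net, part)
plot_zipi(roles)

egs <- module_eigengenes(ab, part)
module_trait_table(egs, sc$truth$traits) |>
  dplyr::arrange(p)

score_recovery(part, sc$truth, roles)
```
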