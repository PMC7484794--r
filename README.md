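# softcorona

Analytics for click-chemistry capture of the **soft protein corona** on
nanoparticles.

When nanoparticles are exposed to serum, a tightly bound *hard corona* (HC)
survives purification while the weakly bound, rapidly exchanging *soft
corona* (SC) is washed away. Covalently trapping soft-binding proteins onto
azide-modified hard-corona proteins yields a captured sample (HC+SC) that
can be compared against four hard-corona controls (HC, HC-N3, D Ctrl,
N3 Ctrl). This package implements the quantitative workflow behind that
comparison:

1. **Absolute quantification** — per-protein copy numbers per nanoparticle
   from emPAI tables, BCA total mass and particle counts:
   `mass_i = (emPAI_i·Mw_i / Σ emPAI_j·Mw_j) · M_total`,
   `copies_i = mass_i/Mw_i · N_A` (with the convention `N_A = 6.023e23`).
2. **SC identification** — square-root z-scaling, two-way Ward/Euclidean
   clustering, and an explicit enrichment-plus-consistency rule: captured
   copies ≥ 1.5 × max(controls) *and* control CV ≤ 0.5 (or all controls
   zero → "new").
3. **Binding-state classification** — hard copies = mean of the controls,
   soft copies = captured excess; Type 1 (more hard), Type 2 (similar),
   Type 3 (more soft), "new" (capture-only), plus fold-increase ranking.
4. **Physicochemistry** — molecular weight, isoelectric point
   (Bjellqvist/ProtParam pKa set), Kyte–Doolittle GRAVY and Guruprasad
   instability index, with copy-number-weighted corona averages.
5. **Monolayer coverage** — geometric footprints (equivalent sphere
   `R = 0.066·M^(1/3)` nm, or min/max projected cross-sections from
   coordinates) summed per particle against `π·d²`.
6. **SPR kinetic decomposition** — Tikhonov-regularized non-negative
   distribution `P(K_D, k_off)` of 1:1 Langmuir sites on a 21×21 log grid
   (`K_D` ∈ [1e-9, 1e-3] M, `k_off` ∈ [1e-5, 1] s⁻¹), global fit over a
   five-concentration titration (20–3000 nM), parsimony-selected at 95%
   confidence, with population fractions per kinetic region.
7. **Synthetic data** — generators for corona experiments with planted
   HC/SC ground truth and for noisy multi-site sensorgrams, so every stage
   is benchmarked without any external download.

## Worked example

The numbered scripts under `analysis/` run the whole study on a simulated
80-protein corona (4 controls + HC+SC, 20 planted SC proteins):

```sh
Rscript analysis/01_simulate_corona.R
Rscript analysis/02_quantify.R
Rscript analysis/03_classify_sc.R
Rscript analysis/04_protein_properties.R
Rscript analysis/05_coverage.R
Rscript analysis/06_spr_fit.R
```

Stage 2 prints the per-particle totals — capture adds soft-state copies on
top of a stable hard corona:

```
Total copies per nanoparticle by sample:
     HC   HC-N3  D Ctrl N3 Ctrl   HC+SC
  751.7   740.5   730.7   731.6  1047.1
Total copy-number change after capture: 1.42-fold
```

Stage 3 recovers the planted soft corona with the rule-based call
(Type-1 plants are intentionally near-undetectable at 1.3× enrichment
under 10% control noise — see the methods vignette):

```
SC proteins called: 15 of 80 (types: new 5, type2 5, type3 5)
Agreement with planted truth: 93.8%
```

Stage 5 places the corona at monolayer scale and quantifies the increase
on capture:

```
             lower upper
control_mean 1.130 1.130
captured     1.576 1.576
```

Stage 6 fits a two-population sensorgram set (minor strong/slow + major
weak/fast binding, 0.3 RU noise) and decomposes the signal:

```
Planted populations: strong/slow 30%, weak/fast 70% of signal
Fitted populations:  strong/slow 24.0%, weak/fast 76.0%, unassigned 0.0%
```

In code, the core loop is three calls:

```r
library(softcorona)
m   <- build_corona_matrix(read_empai_table("empai.csv"),
                           read_sample_config("samples.yaml"))
sc  <- identify_sc_cluster(m, enrichment_factor = 1.5, max_control_cv = 0.5)
cls <- classify_sc_types(m, sc, similarity_ratio = 1.5)
```

## Layout

```
R/                  package code (quantification, clustering, protparam,
                    coverage, SPR fitting, synthetic generators, I/O)
analysis/           numbered workflow drivers writing results/
scripts/acceptance.R  benchmark recomputation
vignettes/          methods vignette (models, conventions, limitations)
inst/extdata/       ProtParam reference panel (synthetic sequences)
tests/testthat/     unit, property and end-to-end benchmark tests
```
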