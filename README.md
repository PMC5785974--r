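# mitoapop

Fractional killing — only part of a clonal cell population dying under a
uniform apoptotic stimulus — is one of the cleanest demonstrations that
non-genetic cell-to-cell variability matters. `mitoapop` implements a
computational account of fractional killing in TRAIL-treated cells in which
a single global variable, the cell's mitochondrial content *m*, co-varies
with the initial levels of the apoptotic machinery and thereby predicts
both fate and time to death.

The package is aimed at computational/systems biologists who want to
simulate heterogeneous cell ensembles through a mechanistic apoptosis
model, and at analysts who need the accompanying statistics for their own
single-cell data.

## What it implements

* **Kinetic model.** A mass-action ODE network of the extrinsic pathway
  (receptor/DISC → Caspase-8 ⊣ Flip, Bar → Bid/tBid ⊣ Mcl-1 → Bax
  oligomerisation ⊣ Bcl-2 → pore → Smac/CytoC release → apoptosome/
  Caspase-3 ⊣ XIAP, with Caspase-6 feedback), integrated per cell with a
  stiff solver behind a compiled mass-action right-hand side. Conserved
  moieties are auto-detected and checked on every trajectory.
* **Correlated ensembles.** Per-cell mitochondrial levels `m ~ logN` and
  protein copies sampled from the bivariate log-normal conditional
  `log p | log m ~ N(mu_p + rho sigma_p z, sigma_p^2 (1 - rho^2))`, so each
  protein keeps its marginal mean and CV while correlating with
  mitochondria at exactly `rho` in log space.
* **Fate rule.** A cell dies iff its maximum Caspase-8 activation rate
  (evaluated from the model right-hand side) exceeds a threshold `theta`
  calibrated once at the sensitive dose (32 ng/ml) against the
  experimental death probability, then held fixed across doses. Time to
  death is the first crossing of 90% of maximal cytosolic Smac; cells
  without release are censored.
* **Statistics.** Tie-corrected Mann–Whitney ROC/AUC; the mitochondrial
  contribution to variability `MCV = (1 - CV_det/CV) * 100` with linear
  (or log-space) de-trending; CV and mean-scaled IQR with bootstrap CIs;
  Spearman correlation; percentile bootstrap.
* **Experiments.** Dose–response with bootstrap CIs, mitochondria and
  single-protein fate classifiers, AUC sensitivity to each
  mitochondria–protein correlation (common random numbers), MCV pair
  sweeps for Bax/Bcl-2 and Bid/Mcl-1, correlation scenarios (rho = 0,
  experimental, 1), and a null division ensemble showing how selection
  alone couples death and division times.
* **Expression processing.** FPKM→TPM, the 0.34 per-cell RNA content
  correction, detection-threshold estimation from one-zero/one-non-zero
  genes, flooring, and fold-change-vs-genome-band computation.
* **Synthetic data.** Seeded generators for live-imaging-style fate
  tables, immunofluorescence-style intensity tables with a target MCV, and
  toy expression tables with a planted detection threshold.

## Worked example

```r
library(mitoapop)

net <- build_network()
net
#> Mass-action reaction network
#>   species:            60
#>   reactions:          74
#>   conserved moieties: 18 (L, R, flip, C8, Bid, BAR, C3, C6, XIAP, PARP,
#>                           Mcl1, Bax, Bcl2, M, CytoC, Apaf, C9, Smac)

# a pro-apoptotic cell (reduced Bcl-2) at a high TRAIL dose commits to MOMP:
tr <- simulate_cell(net, cell_init(net, copies = c(Bcl2 = 4000),
                                   trail_copies = trail_copies_from_dose(250)))
time_to_death(tr)
#> [1] 4.128442
```

The Smac-release rule puts this cell's death 4.1 h after TRAIL addition.
The synthetic live-imaging fixture reproduces the reference single-cell
statistics at the sensitive dose:

```r
fx <- make_imaging_fixture(300, dose_profile = list(dose = 32), seed = 1)
imaging_fixture_stats(fx)
#> $spearman                    # rank correlation of mito level vs death time
#> [1] -0.5679324
#> $mean_t_death_high_mito      # mean death time, top mito quartile (hours)
#> [1] 2.744504
#> $mean_t_death_low_mito       # mean death time, bottom mito quartile (hours)
#> [1] 6.055046
#> $n_apoptotic
#> [1] 125
#> $mito_auc                    # mitochondrial content as a fate classifier
#> [1] 0.7907936
```

High-mitochondria cells die about twice as fast as low-mitochondria cells,
and the rank correlation is about −0.5: mitochondrial content modulates the
time to death. The MCV statistic round-trips through the
immunofluorescence-style generator:

```r
tab <- make_if_table(10000, target_mcv = 50, seed = 2)
mcv(tab$protein_intensity, tab$mito)
#> MCV = 47.6%  (CV = 0.447, de-trended CV = 0.234)
```

i.e. removing the linear dependence on mitochondria cuts this protein's
cell-to-cell CV roughly in half — mitochondria account for about half of
its variability.

For the full simulation experiments, build a study object, calibrate the
fate threshold once, and run:

```r
study <- calibrate_study(apop_study(), n = 2000, seed = 1)
run_dose_response(study, doses = c(2, 8, 32, 125, 250), n = 2000, seed = 1)
run_protein_classifiers(study, correlated = FALSE, n = 2000, seed = 1)
run_auc_sensitivity(study, n = 2000, seed = 1)
```

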