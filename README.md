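# glycotrack

Quantification toolkit for studies that combine differential
O-glycoproteomics with live imaging of migrating embryonic macrophages.
It covers three kinds of measurement that usually live in ad-hoc scripts:

1. **Differential Tn/T O-glycoproteomics** from dimethyl isotope-doublet
   labelling. Glycopeptides from a mutant (light channel, CH2O) and a
   control (medium channel, CD2O) genotype are quantified as
   log10 light/medium ratios; the log-ratio distribution of
   *non-glycosylated flow-through peptides* — which carry no biological
   signal — serves as an empirical null. Modelling that null as
   N(mu, sigma^2), the candidate cutoff is the half-width of its central
   99.73% interval, `3 * sigma` (~0.55 log10 units on embryo flow-through
   data). Quantified glycosites are then classified into fold-change tiers
   (`|log10 r| >= log10 3`: three-fold; `>= 1`: ten-fold, signed), and
   summarized per glycosite (protein, position, residue, Tn/T glycoform
   class, median PSM ratio) and per protein (site multiplicity, strongest
   change, direct-target flag: a site decreased >= 3-fold while another
   site on the same protein is unchanged or increased). A Mann–Whitney U
   test compares glycosite multiplicity of altered proteins against the
   glycoproteome.
2. **Trajectory metrics** for 3D nuclei tracks: instantaneous speed
   (um/min), segment directionality (net displacement over path length in
   10-frame segments, 1 = straight), tissue entry time (T1 − T0, the gap
   between the first nucleus reaching a boundary and the first nucleus
   inside it), and percent speed reduction between conditions.
3. **Image quantifications**: pixelwise Pearson colocalization, per-day
   arbitrary-unit (AU) normalization of background-subtracted ROI
   intensities (control mean of each imaging day = 1, cancelling laser /
   staining gain), bilinear multichannel line profiles in micrometre
   coordinates, and border-cell migration as percent of expected distance.

Synthetic-data generators (`simulate_flowthrough_ratios()`,
`simulate_glyco_dataset()`, `simulate_tracks()`, `simulate_image_pair()`)
emit every input with a separate ground-truth table, so the whole pipeline
is testable at desk scale.

## Worked example

```r
library(glycotrack)

# empirical null from flow-through peptide ratios
ft   <- simulate_flowthrough_ratios(50000, sigma = 0.55 / 3, seed = 1)
null <- fit_null_model(ft)
null
#> Empirical null of log10 M/L ratios (n = 50000 )
#>   mu     = -0.0004474
#>   sigma  = 0.1844
#>   cutoff = 0.5531 (encloses 99.73% of the null, z = 3.000)

# a synthetic glycoproteome with 15% of sites shifted ten-fold
sim   <- simulate_glyco_dataset(glyco_sim_config(
           n_proteins = 100, frac_changed = 0.15,
           effect_log10 = c(-1, 1), null_sigma = 0.1, seed = 2))
sites <- aggregate_glycosites(sim$records)
prots <- summarize_proteins(sites)
glycoproteome_report(sites, prots, null_model = null)
#> Glycoproteome report
#>   239 glycosites on 100 proteins
#>   site classes (%):    Tn-only=77  T-only=3  both=20
#>   protein classes (%): Tn-only=58  T-only=2  both=40
#>   residue split (%):   S=21.8  T=77  Y=1.2
#>   proteins changed >= 3-fold: 34; >= 10-fold: 23
#>   null candidate cutoff: 0.553 log10 (= 3.57-fold)
#>   direct-target proteins: 12; singleton PSMs: 54
```

239 glycosites were aggregated from the PSM table; 77% carry only Tn
glycans and 34 proteins have at least one site shifted three-fold or more
(here: exactly the proteins with spiked quantifiable sites). The cutoff
line makes the two thresholds comparable: the fitted null excludes changes
below ~3.6-fold, slightly stricter than the literal 3x classification
bound.

```r
# trajectory metrics on simulated persistent-random-walk tracks
tr <- simulate_tracks(track_sim_config(n_tracks = 20, n_frames = 40,
                                       speed = 2.46, persistence = 0.45,
                                       seed = 3))
condition_mean_speed(tr)$mean        # 2.46 um/min (exact by construction)
condition_directionality(tr)$mean    # 0.53
percent_reduction(2.46, 1.66)        # 33 (percent slower than control)
```

The CLI in `exec/glycotrack` exposes the same stages
(`simulate-glyco`, `glyco-run`, `track-metrics`, `coloc`, `au-normalize`,
`line-profile`, ...) for shell pipelines; every subcommand exits non-zero
on error.

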