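# eddyforage

Do mesoscale ocean eddies concentrate forage fauna? `eddyforage` is an R
package plus analysis workflow for answering that question from ship-borne
acoustics: it collocates georeferenced 38 kHz backscatter profiles (NASC,
m² nmi⁻², a proxy of forage-fauna density) with a daily eddy-trajectory
atlas, computes per-eddy inside-versus-outside anomalies of backscatter,
sea-surface temperature and chlorophyll, classifies each eddy's effect with
rank-sum tests, relates the verdicts to eddy characteristics, and grids
them spatially. It is written for quantitative marine ecologists and
fisheries-acoustics practitioners.

Because the real inputs are large external products (altimetric eddy
atlases, sonar archives, satellite SST/Chl), the package includes a
synthetic eddy-ocean generator with known ground truth; every stage is
tested and calibrated against it, and the CSV readers document the schema
real products can be converted to.

## The method in brief

For each eddy sampled by a survey track:

* profiles on a 73-bin 10-m grid (20–750 m) are labelled day/night from
  solar elevation; twilight (sun 0–18° below the horizon) and
  continental-shelf profiles (seabed < 1000 m) are removed;
* the eddy's *effective contour* decides inside vs outside; inside profiles
  get a zone (core / intern / speed border / effective border, 30 %
  radial-fraction bands); the *control ribbon* is the annulus out to twice
  the effective radius; eddies need ≥ 2 inside zones plus control to be
  retained;
* the relative anomaly is `(mean_in − mean_out) / mean_out`, per depth bin
  and per layer (epipelagic 20–200 m, mesopelagic 200–750 m), computed
  day-with-day and night-with-night so diel vertical migration cannot
  masquerade as an eddy effect;
* a two-sided Wilcoxon rank-sum test (exact enumeration for small samples,
  tie-corrected normal approximation otherwise, van-Elteren stratification
  across periods) classifies the eddy as **increase**, **decrease** or
  **null** at α = 0.05, per variable (NASC by layer, SST, Chl);
* the water-mass-trapping metric U/c (rotational over translation speed,
  5-day centred window) and five other characteristics are compared between
  increasing / decreasing / null eddies, and a 3° grid maps the percentage
  of significant eddies.

## Worked example

The numbered scripts under `analysis/` run the whole study on the synthetic
ocean (seed 42: 8 eddies, 2 of them with a ×1.5 inside NASC effect, noise
CV 0.3) and narrate what they find:

```
$ Rscript analysis/01_simulate.R
Simulated 8 eddies (2 with a x1.50 inside NASC effect), 538 atlas records.
Survey: 4854 km of track, 1942 profiles (2015-03-01 to 2015-03-12), noise CV 0.30.

$ Rscript analysis/02_prepare_acoustics.R
Prepared 1711 of 1942 profiles: removed 231 twilight and 0 shelf profiles.
Day/night split: 981 day, 730 night.

$ Rscript analysis/03_collocate.R
Collocated 1711 profiles: 454 inside eddies, 452 in control ribbons.
Inside zones: core=45, effective_border=129, intern=157, speed_border=123
Retention rule: 8 of 8 sampled eddies retained.

$ Rscript analysis/04_anomalies.R
Computed anomalies for 8 eddies (6 AE, 2 CE).
Epipelagic NASC anomaly: mean +16.4% (range -12.5% to +45.0%).
Surface signals: SST +0.073 degC (AE mean), -0.142 degC (CE mean).

$ Rscript analysis/05_classify.R
Classified 8 eddies on 4 variables.
Epipelagic NASC: 3 increase, 0 decrease, 5 null.
Ground truth: 2/2 effect eddies recovered as increase; 5/6 non-effect eddies null.

$ Rscript analysis/06_grid_summary.R
Gridded 8 eddies into 8 occupied 3-degree cells.
```

Reading the output: both injected effect eddies are recovered as
"increase"; one of the six no-effect eddies is a false positive, consistent
with the 5 % level at which each eddy is tested (no multiple-testing
correction is applied across eddies — each eddy is an independent
question). The AE-warm / CE-cold SST signatures and the per-cell
percentages mirror how a real survey would be summarized. All tables land
under `results/`.

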