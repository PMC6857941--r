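# ugtcap

Structure-based prediction of the glucuronidation capacity of UGT1A1
variants from molecular-docking poses.

UDP-glucuronosyltransferase 1A1 (UGT1A1) conjugates glucuronic acid from
the coenzyme UDP-glucuronic acid (UDPGA) onto substrates such as
bilirubin, SN-38 (the active metabolite of irinotecan), acetaminophen and
estradiol. Variants — coding mutations and the \*28 promoter polymorphism —
reduce this capacity, which matters clinically (irinotecan toxicity,
hyperbilirubinemias), but the capacity of a newly sequenced variant is
usually unknown. `ugtcap` turns docking output into a capacity prediction
in three steps:

1. **Pose classification.** For each of the `S_DT` docking runs of a
   variant-substrate pair, a pose counts as a *hydroxyl orientation* when a
   substrate hydroxyl oxygen lies within 3.8 Å (a 3.2 Å hydrogen bond plus
   0.6 Å docking error) of the midpoint of UDPGA's glycosidic C–O bond —
   the bond broken during conjugation. A UDPGA pose is in the *correct
   binding mode* when it contacts the pocket residues S38, H173, G308,
   L355, S375, H376, G377.
2. **Capacity model.** Relative capacity follows a sigmoid in the
   oriented-pose fraction `f = S_DH / S_DT`:

   `P_c = sigma * kappa * (1 / (1 + exp(-gamma (f - mu))))^beta + epsilon`

   with `beta = S_DT / S_DH(wild)` fixed per substrate,
   `kappa = 1.0 / 0.74 / 0.21` for the wild/wild, wild/\*28 and \*28/\*28
   promoter genotypes (from Vmax 16.2 / 12.0 / 3.4 nmol/min/mg), and
   `epsilon = 0` in vitro. `(sigma, gamma, mu)` are estimated by bounded
   multi-start least squares against variants with known in vitro
   capacity.
3. **Validation.** Leave-one-out cross-validation refits without each
   variant in turn and predicts it; agreement is summarized by Pearson's
   r with the exact t-based two-sided p-value.

Docking itself (AutoDock, receptor preparation, MD) is out of scope: the
package consumes receptor PDB/PDBQT files, multi-MODEL pose files and CSV
summary tables. Because docking outputs are not redistributable, a
synthetic-data module generates pose fixtures with planted orientation
labels and variant panels with known model constants, so the entire
pipeline is testable offline.

## Worked example

Simulate a 20-variant panel whose generating constants are known
(`sigma = 50, gamma = 8, mu = 0.4, beta = 2.5`, 5% assay noise), recover
them, and cross-validate:

```r
library(ugtcap)

gen <- generate_variant_panel(panel_spec(n_variants = 20, seed = 1))
fit <- fit_parameters(gen$panel, fit_control(seed = 17))
fit
#> <capacity_fit> n=20 variants, SSE=2.50189
#> <model_params> sigma=50.5212 gamma=7.76017 mu=0.397824 epsilon=0 beta=2.5

loo <- loo_cross_validate(gen$panel, fit_control(seed = 17))
loo$correlation
#> <correlation> r = 0.9997, n = 20, p = 5.8e-31
```

The fitted constants land within a few percent of the generating values
at this noise level, and held-out predictions track observed capacities
almost perfectly (r = 0.9997 across the 20 folds; each fold's
`predicted_pct` / `observed_pct` pair is in `loo$folds`).

The same flow applies to real data: read docking summaries and capacities
with `read_summary_csv()` / `read_capacity_csv()`, assemble a panel with
`capacity_panel()`, and classify raw poses with `read_poses()`,
`locate_glycosidic_midpoint()` and `count_orientations()`.

## Analysis workflow

The `analysis/` scripts run the full study on synthetic inputs, writing
tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # pose fixture + variant panel
Rscript analysis/02_classify.R        # orientation + binding-mode classification
Rscript analysis/03_fit.R             # constant estimation, recovery report
Rscript analysis/04_cross_validate.R  # LOO CV, correlation, scatter plot
```

Each script takes an optional seed as its first argument.

## Documentation

The methods vignette (`vignettes/capacity-model.Rmd`) describes the model
and its assumptions, the estimation and validation procedures, what the
synthetic data does and does not emulate, and known limitations.
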