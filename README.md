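# cmrtc — quantitative CMR tissue characterization with a digital phantom

Reperfused acute myocardial infarction is often complicated by
intramyocardial hemorrhage and microvascular obstruction (MVO), and
quantitative cardiovascular MR (CMR) can separate those tissue states
in vivo: edema raises T2, iron from hemorrhage shortens T2\*, infarct
enhances on late gadolinium enhancement (LGE), and MVO appears as a
hypoenhanced core inside the enhanced infarct.

`cmrtc` is an R implementation of the full measurement chain for studies of
this kind, aimed at imaging scientists who need a tested, auditable pipeline:

* **relaxometry** — per-voxel mono-exponential least-squares fitting
  `S(TE) = A·exp(−TE/T)` of T2 (T2-prepared series) and T2\* (multi-echo
  gradient echo), log-linear initialization plus vectorized
  Levenberg–Marquardt refinement, explicit validity flags;
* **segmentation** — hemorrhage (`T2* < 20 ms`, strict), edema
  (`T2 > remote mean + 2·SD`, plus enclosed hypointense core fill), infarct
  (full-width-half-maximum on LGE), MVO (hypoenhanced region enclosed by the
  infarct, seeded front propagation), all with threshold provenance;
* **quantification** — lesion volumes in mL/g/% of LV myocardium, infarct-zone
  and remote T2/T2\* on the mid-ventricular slice, EF/EDV/ESV/LV mass from
  cine masks;
* **association** — ordinary least squares of infarct-zone T2 on T2\*
  (`R² = 1 − SS_res/SS_tot`) over the hemorrhagic arms;
* **digital phantom** — an LV short-axis stack with an anteroseptal lesion
  (edema shell, hemorrhagic core, infarct, MVO core) under Rician noise at
  configurable SNR, emulating three experimental arms (`+HEM`, `I-HEM`,
  `I+HEM`) with exact ground truth, so every stage is verifiable without
  animal data;
* **I/O and CLI** — NIfTI-1 volumes + JSON sidecars, YAML scenario/config
  files, and a command line (`simulate`, `fit`, `segment`, `quantify`,
  `associate`, `run-all`).

See `vignettes/cmrtc-methods.Rmd` for the models, parameter rationale and
limitations.

## Worked example

```r
library(cmrtc)
spec <- phantom_spec("I+HEM", seed = 42)   # hemorrhagic infarct, Rician SNR 20
res  <- analyze_subject(spec)
res$volumes
#> <volume_report> LV 85.2 mL / 89.5 g
#>       label n_voxels volume_ml    mass_g percent_lv
#>  hemorrhage       97   1.75085  1.838392   2.055085
#>       edema      604  10.90220 11.447310  12.796610
#>     infarct      399   7.20195  7.562047   8.453390
#>         mvo       80   1.44400  1.516200   1.694915
res$cardiac
#> <function_report> EF 55.3%, EDV 65.0 mL, ESV 29.1 mL, LV mass 88.9 g
```

The report reads: at SNR 20 the pipeline segments a 7.2 mL hyperenhanced
infarct (8.5% of the LV) containing a 1.4 mL MVO core and a 1.8 g
hemorrhagic core, inside a 12.8% edematous territory. Infarct-zone
relaxation values from the same run
(`res$region_stats`): T2 44.0 ms vs 39.2 ms remote (edema elevation), T2\*
20.8 ms vs 37.8 ms remote (iron-induced depression).

A cohort run over the three arms reproduces the qualitative injury pattern —
no infarct in `+HEM`, no hemorrhage/MVO in `I-HEM`, everything in `I+HEM`,
edema burden ordered `I+HEM > I-HEM > +HEM` — and a negative infarct-zone
T2–T2\* regression across the hemorrhagic arms:

```r
cohort <- run_pipeline(list(arms = list("+HEM" = 7, "I-HEM" = 7, "I+HEM" = 7),
                            snr = 20, seed = 1))
cohort$association
#> <regression_result> Y = -0.388 X + 53.82, R^2 = 0.663, n = 14
```

## Command line

```sh
Rscript inst/cli/cmrtc simulate --scenario inst/extdata/scenarios/i_plus_hem.yaml \
    --seed 7 --out /tmp/study
Rscript inst/cli/cmrtc fit --study /tmp/study
Rscript inst/cli/cmrtc segment --study /tmp/study
Rscript inst/cli/cmrtc quantify --study /tmp/study
```

Exit codes: 0 success, 2 validation/configuration error, 3 data error.

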