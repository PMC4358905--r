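# qsarkit

`qsarkit` is an R toolkit for the full life cycle of QSAR (quantitative
structure–activity relationship) models in production settings:
**building** a model from an SDF training series, **validating** it by
leave-one-out cross-validation, **predicting** new compounds with a
per-prediction reliability category and 95% confidence interval,
**retraining** with new data, and keeping every model version in a
**versioned store** so that historical predictions can be reproduced
bit-exactly ("forensic" requirement). A **confidential mode** exports a
model as a plain-text file holding one aggregate value per descriptor
variable — coefficients and scaling only, no per-compound information —
so models trained on proprietary structures can be shared safely.

It is aimed at modellers in drug-safety / drug-discovery groups who need
a self-contained, auditable pipeline rather than a modelling IDE: every
step is callable from R or from a single CLI, and a minimal JSON-over-HTTP
endpoint serves published models.

## The model at the core

Given a training series of `n` compounds with descriptor matrix
`X (n × p)` and activities `y`, the package autoscales `X` (sample SD,
divisor `n−1`) and fits PLS1 by NIPALS. For each dimensionality
`A = 1, …, A_max` it reports

* `r²` (goodness of fit) and `SDEC = √(RSS/n)`,
* `q² = 1 − PRESS/TSS` and `SDEP = √(PRESS/n)` from leave-one-out
  cross-validation, where the scaling and the model are refitted inside
  every fold and TSS is taken about the full-data mean.

`A_opt = argmax q²` (ties to the smallest `A`). For qualitative (0/1)
activities the same engine runs in discriminant mode and estimates the
cutoff on cross-validated scores as the midpoint balancing sensitivity
and specificity. FFD variable selection (balanced two-level design with
~20 % dummy variables; a variable is dropped when excluding it lowers
SDEP by more than twice the mean absolute dummy effect) can be switched
on per model. Reliability of each prediction is the count (0–6) of
violated applicability-domain criteria — distances to the training
centroid and nearest neighbour in descriptor and in latent-variable
space, DModX, and the activity spread of the `k` nearest neighbours —
each thresholded at its training 95th percentile; the category maps to a
95 % CI half-width calibrated on the training LOO residuals.

Structures are normalized (largest covalent fragment, explicit-H
removal) and indexed by a canonical, atom-order-invariant structure key;
a query identical to a training compound is reported with its
experimental value.

## Worked example

```r
library(qsarkit)
root <- tempfile()                       # model store
toy  <- gen_toy_sdf(30, seed = 7, noise_sd = 0.5)  # synthetic SDF series
build_workflow("LOGS", toy$path, list(seed = 1L), root = root)
```

```
Model 'LOGS': n = 30, regression mode
 A     r2   SDEC     q2   SDEP
 1 0.9592 3.1221 0.9449 3.6273
 2 0.9889 1.6275 0.9822 2.0589
 ...
 7 0.9993 0.4023 0.9986 0.5733
 8 0.9994 0.3858 0.9983 0.6397
A_opt = 7 (q2 = 0.9986, SDEP = 0.5733)
```

The quality table is the per-dimensionality report: `r²`/`SDEC` describe
the fit, `q²`/`SDEP` the cross-validated predictive ability; dimension 7
is selected because its `q²` (0.9986) is the maximum. Publishing and
predicting:

```r
publish_version("LOGS", root)            # -> 1
q   <- gen_toy_sdf(5, seed = 99)
predict_workflow("LOGS", 1, q$path, root = root)
```

```
  compound_id y_pred is_training_copy experimental_value adan_category  ci95
1     mol_001  9.230            FALSE                 NA             0 1.141
4     mol_004 60.752            FALSE                 NA             4 1.124
...
```

`adan_category` 0 means the query violates none of the six
applicability-domain criteria (reliable); mol_004 violates 4 of 6 — it
sits far from the training series and its prediction should be
distrusted. `ci95` is the half-width of the 95 % confidence interval for
that category.

The same cycle through the CLI (`inst/cli/qsarkit`):

```sh
qsarkit build   -e LOGS -v 0 -f training.sdf
qsarkit manage  -e LOGS --publish
qsarkit predict -e LOGS -v 1 -f query.sdf -o out.csv
qsarkit manage  -e LOGS --list
qsarkit manage  -e LOGS --export-confidential 1
qsarkit serve   --port 8080
```

## Documentation

The methods vignette (`vignettes/qsarkit-methods.Rmd`) describes the
statistical machinery, the synthetic-data generators, the numerical
conventions and the known limitations (including one acceptance property
of FFD selection that is statistically out of reach at the default
design size, kept as a deliberately failing test).
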