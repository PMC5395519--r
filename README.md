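# rdnad — reliability-density neighbourhood applicability domains

Binary QSAR classifiers are only trustworthy inside the region of
descriptor space where the training data actually supports them — the
applicability domain (AD). Most AD techniques rank new compounds by a
single property of the training data: distance, density, or the spread of
an ensemble's predictions. Each has a blind spot. Density-only methods
(dk-NN) admit compounds that sit in dense but *badly modelled* regions;
ensemble-spread methods (STD) are blind to *systematic bias* — a compound
can receive ten tightly agreeing predictions that are all wrong.

`rdnad` implements the **reliability-density neighbourhood (RDN)** AD,
which combines both signals. Every training instance *i* gets a local
neighbourhood radius from the density k-NN construction:

- the average Euclidean distance (standardized descriptors) of each
  training compound to its *k* nearest neighbours is computed;
- the list is bounded by the Tukey outlier fence
  `RefVal = Q3 + 1.5 × IQR`;
- the instance's radius `D_i` is its mean distance to all training
  neighbours within `RefVal` (zero if none qualify).

That radius is then shrunk by a per-instance **reliability weight**

```
W_i = (1 − STD_i) × agreement_i
```

where `STD_i` is the sample standard deviation of an M-member ensemble's
predictions for compound *i* (precision) and `agreement_i` is the
fraction of members predicting the observed class (bias; a
probability-based variant `1 − |Y_i − ȳ_i|` is also provided). A query is
inside the AD when it falls within the effective radius
`D_i × step × W_i` of at least one training instance. Scanning
k = 1…65 — with radii scaled by 1/3 for k ≤ 30 and 1/2 for k = 31–40 so
the dense core is explored slowly — traces a profile of cumulative
accuracy against the fraction of data inside the AD.

The package also provides:

* the unweighted **dk-NN** profile (the special case `W ≡ 1`, unit steps);
* **ensemble-STD tiers** and a **KDE density AD** on the first principal
  component, as comparators;
* an **AD robustness score** comparing the profiles of two external sets:
  per segment, slope penalties (1 negative / 2 null / 4 positive) are
  multiplied across the two curves, weighted by the fraction of data
  added, scaled by `1 + |y_i − z_i|`, and the sum is normalised by
  `F_added`, the fraction of data added after the first iteration. Lower
  is better; identical strictly decreasing curves score exactly 1;
* **ReliefF** feature weighting with rank averaging, for selecting
  AD-specific descriptor sets;
* a **synthetic-data generator** with planted regimes (dense reliable
  core, high-precision/high-bias pocket, sparse noisy fringe) so the
  whole workflow is testable without any external dataset;
* a command-line interface (`exec/rdn`) with subcommands
  `simulate`, `relieff`, `reliability`, `profile`, `score`.

## Worked example

```r
library(rdnad)

study <- simulate_study(seed = 42)           # train + two external sets
fit   <- rdn(study$train, weights = study$weights)
fit
#> <rdn> reliability-density neighbourhood applicability domain
#>   training instances: 175; descriptors: 5
#>   k = 1..65; min covering neighbours: 1
#>   reliability weights: median 0.947 [0.000, 0.979]

prof <- ad_profile_rdn(fit, list(iv = study$external_1,
                                 te = study$external_2))
subset(as.data.frame(profile_dataset(prof, "iv")),
       iteration %in% c(1, 20, 41, 65))
#>    iteration threshold_param dataset n_included_cum accuracy_cum
#> 1          1               1      iv              1    1.0000000
#> 20        20              20      iv              9    1.0000000
#> 41        41              41      iv             50    0.8400000
#> 65        65              65      iv             53    0.8113208

ad_score(profile_dataset(prof, "iv"), profile_dataset(prof, "te"))
#> <ad_score> 2.5601 (lower is better)
#>   F_added = 0.817 (total coverage at last iteration 0.833)
#>   65 iterations, 26 contributing segments
```

The profile reads: the AD core (first iterations) contains only
perfectly predicted compounds, and accuracy degrades to the external
set's base rate (0.81) as the AD expands to cover ~83% of the data —
the planted biased and sparse regions enter last. The score of 2.56
quantifies how similarly the expansion behaves on the two independent
external sets (1 would be two identical, strictly degrading curves).

The median training weight of 0.95 reflects the reliable core, while
compounds in the planted high-precision/high-bias pocket receive
`W ≈ 0` — exactly the compounds an STD-only AD would admit first, since
their ensemble spread is tiny.

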