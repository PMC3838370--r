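# FisherSum

Univariate detection of differentially expressed **patient subgroups** in
two-group omics data.

In case-control expression studies (gene expression, protein microarrays),
the clinically interesting variables are often those where only a *subset*
of the disease group is dysregulated — disease subtypes, heterogeneous
oncogene activation, differential therapy response. Standard two-sample
tests assume a homogeneous disease group and lose power on exactly these
variables. This package is for biostatisticians and omics analysts who want
to rank variables by evidence for such subgroups, and to understand which
statistic works under which kind of deviation.

## What is implemented

The centerpiece is the **FisherSum score**. With a cutpoint *cut* chosen as
the order statistic below which 90% of the disease values lie (so at most
10% of *D* exceeds it), and med<sub>C</sub> the control median,

```
FS = (1/n_D) * sum_{x in D, x > cut} (x - med_C)_+
   - (1/n_C) * sum_{x in C, x > cut} (x - med_C)_+
```

The subtracted control sum penalises *non-disease-specific* subgroups
(up-regulated samples in both groups), the main source of false positives
for outlier-type statistics. The companion `fisher10_pvalue()` is the
one-sided Fisher exact test on the 2×2 exceedance table.

Six established comparators are included behind a uniform interface:
outlier sum (OS), outlier-robust t (ORT), a PADGE-like percentile score,
pooled excess kurtosis, Bartlett's test, and the one-sided pooled t-test.

Around the statistics sits a simulation benchmark:

* `simulate_subgroup_matrix()` — variables × samples matrices with planted
  subgroups under three scenarios (mean shift N(δ,1); mean+variance
  N(0,1)+U[0,b]; pure variance N(0,σ²)) and a *composite null* mixing
  "no subgroup" (H0a) and "subgroup in both groups" (H0b) rows;
* `log_likelihood_ratio()` — the Neyman-Pearson oracle that upper-bounds
  every method when the generative parameters are known;
* `auc()` / `roc_curve()` / `auc_grid()` / `table4_report()` — rank-based
  AUC evaluation of each method's ability to separate disease-specific
  subgroup variables from the composite null, AUC-vs-deviation curves, and
  the two-block summary table (AUC at the oracle's 0.95 operating point;
  smallest deviation reaching AUC 0.95 per method);
* `subgroup_scan()` — apply all methods to a (real or simulated) matrix,
  with `print`/`summary`/`plot` methods and TSV I/O
  (`read_matrix_tsv()`, `cmd_simulate`/`cmd_score`/`cmd_benchmark`, plus a
  thin CLI at `inst/cli/subgroup-bench.R`).

## Worked example

Simulate the standard benchmark design — 70 controls vs 70 diseased, a 10%
subgroup, scenario I at δ = 2.5, 1000 variables of which 250 are H0a, 250
H0b and 500 carry a disease-specific subgroup — then scan and rank:

```r
library(FisherSum)
spec <- scenario_spec("I", z = 2.5, p = 0.1)
sim <- simulate_subgroup_matrix(spec, n = 70, seed = 2024)
scan <- subgroup_scan(sim$x, sim$group, methods = c("fs", "fisher10", "ttest"))
head(summary(scan, rank_by = "fs"), 5)
#>   variable rank        fs    fisher10       ttest
#> 1  var0676    1 0.3464582 0.006674952 0.041277823
#> 2  var0740    2 0.3306803 0.031266880 0.018144422
#> 3  var0841    3 0.3296963 0.006674952 0.002701499
#> 4  var0511    4 0.3288430 0.006674952 0.005364717
#> 5  var0610    5 0.3275447 0.031266880 0.004021980
```

Each row is one variable, ranked by decreasing FisherSum; the `fisher10`
and `ttest` columns are the exact-test and t-test p-values for the same
variable (note the heavy ties in the discrete Fisher p-values — the reason
the sum-based score ranks better). All ten top-ranked variables here are
true H1 rows. Judged against the ground truth, FisherSum separates
subgroup variables from the composite null with AUC 0.951 at this
deviation, the t-test only 0.840:

```r
top10 <- summary(scan, rank_by = "fs")$variable[1:10]
table(sim$truth[match(top10, rownames(sim$x))])
#> H1
#> 10
```

On real data: put your log-intensity matrix in a TSV (rows = variables,
columns = samples, a `group` row of C/D labels under the header — see
`?read_matrix_tsv`) and run `cmd_score("matrix.tsv", "scores.tsv")`, or
call `subgroup_scan()` directly.

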