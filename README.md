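# zooprior

Collaborative prioritization of zoonotic diseases for settings where
surveillance data are scarce. Human and animal health stakeholders agree on
criteria that define what makes a zoonosis important, attach one categorical
question to each criterion, rank the criteria by pairwise comparison, and
score every candidate disease through a weighted decision tree — producing a
transparent, normalized ranked disease list both sectors can stand behind.
zooprior implements that whole workflow as a tested, scriptable R package:
validated plain-text inputs, the Analytic Hierarchy Process (AHP) ranking
layer, decision-tree scoring with full per-disease score traces, a
leave-one-out sensitivity scan, seeded synthetic-data generators for
robustness experiments, and a command-line interface.

## The method in brief

- Each participant judges every pair of criteria on Saaty's 1–9 ratio scale,
  giving a positive reciprocal matrix *A* with *a(j,i) = 1/a(i,j)*. Their
  priorities are the normalized principal eigenvector *p* of *A*; judgment
  coherence is summarized by the consistency ratio
  *CR = CI / RI(n)*, *CI = (λ_max − n)/(n − 1)*.
- Participants are merged by the element-wise geometric mean of their
  matrices (AIJ; arithmetic aggregation of priorities, AIP, is available),
  and the *n* criteria receive sequential integer weights *n, n−1, …, 1*
  from highest to lowest group priority.
- A disease's answer to a binomial question scores 1 (the designated
  full-score answer) or 0; the *k*-th of *m* ordered multinomial categories
  scores *k/m*. Each score is multiplied by its criterion's weight, summed
  into the disease total *T = Σ w·s*, and normalized as *N = T / T_max*
  against the maximum observed total. Ties share a rank.

## Worked example

The package ships a complete example exercise: five criteria, ten
participants' pairwise judgments, and a 20-disease answer table.

```r
library(zooprior)

fx <- fixture_country_x()
res <- prioritize(fx$config, fx$judgments, fx$answers)

res$weights
#> Criterion weights (sequential 5..1)
#>   severity             weight  5   priority 0.3366
#>   bioterror            weight  4   priority 0.2678
#>   economic             weight  3   priority 0.1994
#>   collaborate          weight  2   priority 0.1316
#>   epidemic             weight  1   priority 0.0647
#>   group consistency ratio: 0.0000
```

Severity of illness ranks first, so it gets weight 5 and becomes the first
node of the decision tree. The trace for rabies shows every point: a yes on
the severity question (binomial, full score) contributes 1 × 5 = 5, "both"
on the 3-category collaboration question contributes (3/3) × 2 = 2, and a
yes on epidemic potential adds 1, for a total of 8:

```r
res$traces[["Rabies"]]
#> Score trace: Rabies
#>  criterion_id weight label raw_score weighted_score
#>      severity      5   yes         1              5
#>     bioterror      4    no         0              0
#>      economic      3    no         0              0
#>   collaborate      2  both         1              2
#>      epidemic      1   yes         1              1
#>   total: 8
```

Totals are normalized against the best-scoring disease, which defines 1.0:

```r
head(res$ranked$entries, 6)
#>   rank                           disease total_score normalized_score
#> 1    1 Highly Pathogenic Avian Influenza   14.333333        1.0000000
#> 2    2                           Anthrax   14.000000        0.9767442
#> 3    3                 Rift Valley Fever   13.666667        0.9534884
#> 4    4                            Plague   11.333333        0.7906977
#> 5    5               Ebola Virus Disease   10.666667        0.7441860
#> 6    5                       Lassa Fever   10.666667        0.7441860
```

(Ebola and Lassa tie on 10.67 and share rank 5; rank 6 is skipped.)

The same run from the shell, writing `weights.json`, `ranked.csv`,
`traces.json` and run manifests:

```sh
root=$(Rscript -e 'cat(system.file("extdata", "country_x", package = "zooprior"))')
Rscript inst/cli/zooprior run --config "$root/config.yaml" \
    --judgments "$root/judgments" --answers "$root/answers.csv" --out-dir out/
```

Other subcommands: `rank-criteria`, `score`, `simulate` (seeded synthetic
scenarios), `sensitivity` (leave-one-out criterion scan), `report`
(re-render a saved ranking); global flags `--strict` and `--seed`.

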