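# lbassign

Learning online patient-to-professional assignment policies from
offline-optimal schedules.

Hospitals assign patients to physicians (and imaging studies to
radiologists) online, under partially conflicting objectives — clinical
risk, waiting times, length of stay, crowding, interruptions, reading
tardiness — usually with myopic heuristics. `lbassign` implements a
learning-based alternative for two settings:

1. **Emergency department**: small night-shift scenarios are solved to
   *exact* optimality (branch-and-bound over slot-level assignment
   decisions with preemption, validated against an independent enumeration
   oracle and constraint checker), each optimal decision is expanded into
   pairwise preferences, and an anti-symmetric comparator network
   \(C(x,y)\in[0,1]\) with \(C(x,y)+C(y,x)=1\) and \(C(x,x)=0.5\) *by
   construction* (cross-wired shared-weight towers, difference-of-towers
   head) is trained on the pairs. Online, all candidate
   (patient, physician) assignments plus wait-room options are compared
   all-pairs and the majority-vote winner is applied; the baseline is
   First-Come-First-Served-with-Urgencies (FCFSwU).
2. **Radiology**: the policy controls each reader's *exposure pool* (at
   most `k` studies); readers pick from their pools by quantal response
   (softmax of revealed-preference utilities). Training decisions come from
   Monte-Carlo tree search over exposure actions minimising the total
   exponential lateness loss \(\sum_i e^{2\,\mathrm{lateness}_i}\)
   (lateness in hours); baselines are blanket exposure ("Naive") and an
   interval heuristic ("H") that widens exposure in deadline thirds.

Everything is generated, solved, trained and evaluated in code — no
external data — and every stage derives its randomness from one master
seed.

## Worked example

```r
library(lbassign)

# one simulated night shift under the conventional heuristic
sc <- generate_ed_scenario(ed_config(), seed = 42)
sc
#> <ed_scenario> 34 patients, 3 physicians, horizon 96 slots of 5 min (seed 42)
simulate_shift("fcfswu", sc)
#> <shift_metrics> policy: fcfswu  objective: 283.698
#>   components: risk=119.4 wait=2 los=2075 crowd=2075 preempt=17  preemptions: 2
```

The objective is the weighted five-component score (risk of adverse
consequences, excess-wait penalties beyond the triage bound, length of stay
in minutes, crowding in patient-minutes, preemption penalties); the weights
and penalty tables are documented package defaults in `ed_weights()`.

The full learning loop, end to end (here at a demonstration scale of 40
training scenarios; the default configuration uses 260):

```r
res <- run_lba_pipeline(ed_experiment_config(n_train = 40, n_eval = 20, seed = 11))
res
#> <experiment_result> ed domain
#>   mean scores: lba=344.18  fcfswu=306.16
#>   paired t-test: t = 0.9549  p = 0.3516  mean diff = 38.02 (a_higher)
report_tables(res)$marginal_improvement
#>        criterion     fcfswu        lba improvement_pct
#> 1           risk  113.95910  124.89300       -9.594583
#> 2     wait_times   13.00175   13.23093       -1.762705
#> 3 length_of_stay 1829.25000 1682.25000        8.036080
#> 4    crowdedness 1829.25000 1682.25000        8.036080
#> 5  interruptions   24.15000    8.00000       66.873706
```

At this toy scale the learned policy already cuts interruptions by two
thirds and shortens stays, but its overall score is not yet reliably below
the baseline's; at the default scale (260 training scenarios, model
selection over four candidates, 100 evaluation shifts) a run of
`scripts/acceptance.R --seed 1` printed a mean score of 249.0 for the
learned policy against 304.5 for FCFSwU — an 18.3% improvement, paired-t
p = 4.8e-08 — with interruptions down 86%.

The reading-room loop works the same way (again at a toy scale here):

```r
rres <- run_lba_pipeline(rad_experiment_config(n_train = 4, n_eval = 10, seed = 11))
report_tables(rres)$lateness_distribution # five bins x policies, in percent
#>               bin naive   h dnn_k10 dnn_k5 dnn_k2
#> 1 before_deadline  98.3 100    98.5     99   98.8
#> 2   slightly_over   1.7   0     1.5      1    1.2
#> 3            late   0.0   0     0.0      0    0.0
#> 4       very_late   0.0   0     0.0      0    0.0
#> 5  extremely_late   0.0   0     0.0      0    0.0
report_tables(rres)$pool_sizes            # mean/sd exposed studies per reader
#>    policy  pool_mean    pool_sd
#> 1   naive 15.7375000 11.1517787
#> 2       h  0.2665997  0.5414304
#> 3 dnn_k10  6.0074167  4.1615074
#> 4  dnn_k5  2.9723333  2.1678340
#> 5  dnn_k2  1.2310000  0.8713108
```

The pool cap binds only for the learned policy; blanket exposure averages
nearly 16 studies per reader with high variability.

A thin command-line wrapper over the same functions ships in
`inst/cli/lba.R`:

```sh
Rscript inst/cli/lba.R ed simulate --seed 42 --policy fcfswu
Rscript inst/cli/lba.R run --domain rad --seed 1 --out results/
```

The methods vignette (`vignettes/learning-based-assignment.Rmd`) documents
the models, the objective components, the search algorithms, the training
design (including why the training scenarios open with an arrival burst),
all default parameters, and known limitations.

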