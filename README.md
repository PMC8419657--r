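# heatlag

Detects significant temporal shifts ("heat variations") in keyword
co-occurrence networks built over **expanding overlapping time windows** of a
bibliographic corpus, clusters keyword trajectories into trend groups, and
measures the **day lag** between rising-heat periods of research clusters and
the issuance dates of related policies.  It is aimed at scientometrics and
science-policy researchers studying how literature and policy-making
co-evolve during fast-moving episodes such as disease outbreaks.

## The method in brief

For windows `[origin, end_w]` whose ends advance in 10-day steps, each
keyword's *heat* is its **total link strength** — the sum over other
keywords of the number of documents in which both co-occur (full counting,
occurrence threshold 2) — normalized to a percentage of the window total.
Keywords absent from a window's network are *missing not at random*
(signal below the detection floor) and are imputed by uniform draws from
the central 90% of the per-window observed minima.  For item *i* at window
*w* (third valid window onward) a one-sample left-tailed Student test

    t = (X̄ − μ0) / SE,   SE = sd(priors) / √n_priors,   df = n_priors − 1

compares the current percentage `μ0` against all prior windows; results are
averaged over 10 random imputations and flagged at `p < 0.05`.  Significant
items are Z-scored and clustered (average linkage, Euclidean), cluster mean
curves are scanned for maximal strictly-increasing runs ("rising-heat
waves"), and each policy promulgation wave is matched to the nearest heat
wave; start-date differences within 30 days average into per-cluster and
overall mean lags.

## Worked example 1: the seven-cluster wave timetable

The package bundles a worked timetable of policy promulgation waves and
rising-heat waves for seven research-topic clusters observed during China's
early COVID-19 response (30 Dec 2019 – 26 Jun 2020):

```r
library(heatlag)
tt <- example_wave_timetable()
lt <- build_lag_table(tt$policy_waves, tt$heat_waves)
lt[, c("cluster", "combined_lag")]
#>   cluster                    combined_lag
#> 1 aged_patients                       1.0
#> 2 antibody_test                       3.0
#> 3 asymptomatic_infection             12.0
#> 4 children_pregnant_patients          0.0
#> 5 chinese_medicine                   12.0
#> 6 mental_health                      21.0
#> 7 severe_symptoms                     9.5
overall_mean_lag(lt)
#> [1] 8.36
```

So across these seven clusters, policy issuance and rising research heat
were separated by 8.36 days on average.

## Worked example 2: end-to-end recovery of a planted lag

A synthetic corpus with two topics planted to triple in prevalence at days
60 and 90, policies issued exactly 8 days after each change point, and
noise-free (deterministic) sampling:

```r
h0 <- as.Date("2019-12-30")
tp <- example_topics()
topics <- lapply(tp, function(t) topic_spec(t$name, t$keywords))
topics[[1]] <- topic_spec("severe_disease", tp[[1]]$keywords,
                          change_point = h0 + 60, multiplier = 3)
topics[[2]] <- topic_spec("antibody_testing", tp[[2]]$keywords,
                          change_point = h0 + 90, multiplier = 3)
corp <- generate_corpus(topics = topics, sampling = "deterministic")
pol  <- generate_policies(corp$truth, lag_days = 8, jitter_days = 0, seed = 1)
res  <- run_pipeline(pipeline_config(k = 2, seed = 1),
                     documents = corp$documents, policies = pol,
                     cluster_labels = function(m) label_clusters(m, corp$truth))
res$waves[, 1:5]
#>   cluster          wave start      end        rise
#> 1 antibody_testing    1 2020-03-28 2020-06-26 2.85
#> 2 severe_disease      1 2020-02-27 2020-04-17 2.17
#> 3 severe_disease      2 2020-05-07 2020-06-06 0.0757
res$overall_lag
#> [1] 9
```

Both clusters' rising waves start at the window end immediately preceding
their change points, and the planted 8-day lag is recovered as 9 days — the
1-day difference is the quantization of wave boundaries to window end
dates.  The vignette (`vignettes/heat-trends.Rmd`) discusses the model,
its calibration under the serial dependence that expanding windows induce,
and the design decisions behind the wave and lag rules.

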