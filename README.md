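# syncphase

Quantifying interpersonal body-motion synchrony from head-worn triaxial
accelerometers.

When two people converse, their head movements — the speaker's emphatic nods,
the listener's backchannel nods — become temporally coupled. `syncphase`
measures that coupling from paired accelerometer recordings of a speaker and
a listener (nominally 100 Hz), producing per-dyad synchrony features and the
two-group statistics used to contrast typically developing (TD–TD) dyads
with dyads in which the listener is on the autism spectrum (TD–ASD). It is
aimed at researchers in social neuroscience and digital behavioral
phenotyping who need a continuous, language-independent index of social
timing.

## Method

For each participant the triaxial trace \(a_x, a_y, a_z\) is collapsed to
its Euclidean magnitude

\[ a(t_i) = \sqrt{a_x^2(t_i) + a_y^2(t_i) + a_z^2(t_i)}, \]

z-scored over the active recording window, \(a'(t_i) = (a(t_i) - \bar a)/\sigma_a\)
(sample SD, divisor \(T-1\)), and smoothed with a forward 100 ms moving
average (11 samples at 100 Hz). A sample is a movement peak when it is a
strict local maximum with \( \bar{a'}(t_i) \ge 2.0 \) — two standard
deviations above that person's mean movement intensity. Speaker and listener
peaks are then paired one-to-one: each speaker peak claims the nearest
listener peak within ±1.0 s (conflicts resolved greedily by ascending
absolute offset), and the signed lag
\( \Delta t = t_{listener} - t_{speaker} \) (ms, positive = listener follows)
is one synchrony event. The per-dyad lag distribution is summarized by four
features:

| feature | meaning |
|---|---|
| density (events/min) | synchrony activity |
| mean lag (ms) | directionality (leader–follower structure) |
| SD of lags (ms) | variability (temporal precision) |
| excess kurtosis | coherence (concentration around the central lag) |

Groups are compared with Student's pooled two-sample t tests and Cohen's
*d* (pooled SD), plus Mann–Whitney U for ordinal ratings, Pearson
correlations for duration confounds, and leave-one-dyad-out sensitivity
re-tests.

Because no raw recordings are publicly deposited, the package ships an
event-based dyad simulator (`simulate_dyad()`, `simulate_group_study()`)
with exact ground truth — planted nod times, response probabilities and
response lags — so the whole pipeline is validated by parameter recovery.

## Worked example

```r
library(syncphase)

sim <- simulate_dyad(td_sim_config(duration_s = 300, seed = 7), dyad_id = "demo")
fit <- dyad_synchrony(sim$speaker, sim$listener, dyad_id = "demo")
summary(fit)
#> Dyad synchrony fit: demo (5.00 min)
#>   speaker peaks: 122   listener peaks: 49   matched events: 48
#>   density 9.60 /min, mean 10.0 ms, sd 306.1 ms, kurtosis -0.639
#>   speaker nod density 24.40 /min, listener 9.80 /min
#>   60.4% of events within +/- 300 ms of the mean lag
```

The fit recovers the generative regime: the speaker nodded ~23/min and
responded to 41% of nods, so ~9.6 matched events/min; the lag jitter of
300 ms reappears as the SD of the matched lags. `coef(fit)` returns the four
features, `plot(fit)` draws the 100 ms-binned lag histogram, and
`simulate(fit)` draws fresh synthetic dyads at the fitted parameters.

The statistical layer accepts either raw per-dyad samples or published
summary statistics:

```r
t_and_d(c(mean = 9.63, sd = 3.23, n = 18),
        c(mean = 5.96, sd = 2.73, n = 18), metric_name = "density")
#> density: M = 9.630 (SD 3.230, n 18) vs M = 5.960 (SD 2.730, n 18)
#>   t(34) = 3.68, p = 0.0007979, Cohen's d = 1.23
```

A batch interface mirrors the study workflow: `cmd_simulate()` writes a
corpus (trace CSVs + YAML manifest + ground-truth JSON), `cmd_analyze()`
runs the pipeline over a manifest and writes `features.csv`, per-dyad
histograms and a run log, and `cmd_compare()` emits the group-comparison
report. A thin shell front end wrapping these lives at
`inst/cli/syncphase.R`:

```sh
Rscript inst/cli/syncphase.R simulate --config scenario.yaml --out corpus/
Rscript inst/cli/syncphase.R analyze  --manifest corpus/manifest.yaml --out results/
Rscript inst/cli/syncphase.R compare  --features results/features.csv
```

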