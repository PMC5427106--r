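# ethoscore

Scriptable manual behavioral scoring for rodent tests.

In preclinical behavioral pharmacology, tests such as the forced swim test
(FST), novel object recognition (NOR) and the elevated plus maze (EPM) are
still often scored by a trained human pressing keys while watching the
animal (live or on video). `ethoscore` turns those timestamped keystroke
logs into analyzable data:

* **Ethograms** — behavior catalogues with key bindings, colors and
  session/trial schemes; built-in FST/NOR/EPM templates, all customizable
  and shareable as plain-text `.etho` files.
* **Timelines** — keystroke logs become validated bout timelines (ordered,
  disjoint half-open intervals `[start, end)` for *state* behaviors, plus
  instantaneous *point* events), with time-window slicing and coverage QC.
* **Metrics** — per-behavior total time, bout/event counts and latencies
  (censored at the trial duration when a behavior never occurs), plus
  test-specific indices: percent time and entries in open arms for EPM,
  and for NOR the discrimination index
  `DI = (T_novel − T_familiar) / (T_novel + T_familiar)` and preference
  index `PI = 100 · T_novel / (T_novel + T_familiar)` (so `PI = 50(DI+1)`).
* **Visual maps** — each trial renders as a horizontal color-coded bar
  (bout colors per ethogram, gaps in gray, point events as vertical ticks)
  written as deterministic PNG files; multi-animal / trainer-vs-trainee
  collations for training and audit.
* **Rater agreement** — per-measure Pearson correlations across animals
  with two-tailed p-values from the t reference (`df = n − 2`), and a
  timeline concordance audit (percent sample agreement and Cohen's kappa
  on a 0.1 s grid).
* **Simulation** — a semi-Markov bout generator and a rater-noise model
  (boundary jitter, bout mislabeling, point miss/false-alarm) so the whole
  pipeline is testable without animal data.
* **Projects** — subjects, descriptors, deferred group assignment and
  scored trials in a single-file store, exported as RFC-4180 CSV tables
  and per-animal PNG maps.

## Worked example

Score a 5-minute second-session FST trial from five keystrokes
(`s` swimming, `i` immobility, `h` head shake):

```r
library(ethoscore)
fst <- builtin_template("FST")
ev <- key_events(c(0, 95.2, 180.7, 200.1, 240.0), c("s", "i", "h", "s", "i"))
trial <- keystrokes_to_timeline(ev, fst, duration_s = 300,
                                subject_id = "R1", session_index = 2,
                                rater_id = "NK")
trial
#> <scored_trial> subject=R1 s2t1 rater=NK duration=300s
#>   4 bout(s), 1 point(s), coverage 1.000
summarize_trial(trial, fst)
#> <measure_set> subject=R1 s2t1 rater=NK (300 s)
#>    behavior  kind total_s count latency_s latency_censored
#>  immobility state   164.9     2      95.2            FALSE
#>    swimming state   135.1     2       0.0            FALSE
#>    climbing state     0.0     0     300.0             TRUE
#>  head_shake point     0.0     1     180.7            FALSE
```

Reading: the rat first swam, went immobile after 95.2 s (its immobility
latency), briefly swam again at 200.1 s, and accumulated 164.9 s of
immobility in two bouts; one head shake was recorded; climbing never
occurred, so its latency is censored at 300 s. A visual map of the same
trial (`render_map(trial, fst, file = "R1.png")`) draws red/blue runs
proportional to the bout durations with a green tick at 180.7 s.

A command-line interface wraps the same operations
(`inst/cli/ethoscore`): `template`, `score`, `export`, `map`, `agree` —
see `?ethoscore_main`.

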