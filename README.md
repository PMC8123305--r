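# painwatch

Surveillance of first-person back-pain complaints in social-media streams.

Public social-media posts are a noisy but voluminous signal for
population-level musculoskeletal health. The difficulty is that most posts
matching a symptom phrase such as "back pain" are not complaints at all —
they are advertisements, professional discussion, scams, and verbatim
repeats. `painwatch` implements the full analysis chain needed to turn a raw
two-period tweet stream into a defensible statement of the form *"complaint
frequency changed by X% between period A and period B, and the difference
is (not) statistically significant"*:

1. **Corpus I/O** — JSON-lines tweet corpora (UTF-8, ISO-8601 UTC
   timestamps) and CSV label files.
2. **Preprocessing** — exact-text deduplication (earliest copy wins), then
   surface normalization in a fixed rule order: image links → `_IMAGE`,
   character runs ≥ 3 collapse to 2 (`"aaaaaaaaaa"` → `"aa"`), retweet
   markers → `_RETWEET`, generic links → `_URL`, emoji → textual names
   (`:two_hearts:`), then removal of non-English posts via an injectable
   language-detector contract.
3. **Annotation** — inter-annotator agreement via nominal Krippendorff
   alpha, `α = 1 − D_o/D_e`, computed from the coincidence matrix, with an
   acceptance floor (default 0.8) and unanimity/two-of-three majority
   adjudication to a single gold label per item.
4. **Classification** — a two-stage filter: a pluggable text feature
   extractor (default: deterministic hashed word n-grams; a transformer
   CLS-vector encoder satisfies the same contract) feeding a
   gradient-boosted tree classifier (xgboost), evaluated under stratified
   fivefold cross-validation with fixed test sets and pooled held-out
   predictions.
5. **Evaluation** — the full binary metric suite from the 2×2 confusion
   matrix: accuracy, balanced accuracy = (TPR + TNR)/2, macro/micro/
   weighted F1, MCC = (tp·tn − fp·fn)/√((tp+fp)(tp+fn)(tn+fp)(tn+fn)), and
   macro-averaged precision/recall.
6. **Temporal statistics** — day/hour count series (empty bins kept),
   Shapiro–Wilk normality, two-group one-way ANOVA at α = 0.05 (for two
   groups, F = t²), degree-6 polynomial display trends on an orthogonal
   basis, and percent ratio/change summaries.
7. **Synthetic data** — a seed-deterministic two-period stream simulator
   (per-hour Poisson arrivals, period-B intensity multiplier, template
   complaint/other grammars, duplicates, artifacts, non-English posts,
   noisy annotators, and a biased localized subpopulation), so the whole
   pipeline is testable without any platform download.

## Worked example

The metric suite on a pooled cross-validation confusion matrix with
(tn, fp, fn, tp) = (1895, 128, 100, 2877):

```r
library(painwatch)
cm <- confusion_matrix(tn = 1895, fp = 128, fn = 100, tp = 2877)
compute_metrics(cm)
#> accuracy           0.9544
#> balanced accuracy  0.9516
#> F1 macro           0.9526
#> F1 micro           0.9544
#> F1 weighted        0.9543
#> MCC                0.9052
#> precision          0.9536
#> recall             0.9516
misclassification_rate(cm)   # 0.0456, i.e. 4.56% wrongly classified
```

A full simulated surveillance run at the reference study conditions (two
30-day periods, 20 expected tweets/hour, true period ratio 1.84, 46%
duplicate rate, three annotators with 5% flip noise, 5000-item labeled
sample):

```r
cfg <- pipeline_config(simulate = sim_config(seed = 1), seed = 1)
rep <- run_pipeline(cfg)
rep
#> == Complaint surveillance report ==
#> downloaded 40886 | after dedup 21757 (53.21%) | complaints 12776 (31.25% of original, 58.72% of filtered)
#> agreement alpha 0.8066 (accepted)
#> labeled 5000 items; CV misclassification 0.0074
#> ...
#> period counts: A 4466, B 8310; ratio 186.07% (change +86%)
#> One-way ANOVA: F = 1029.5762, df = (1, 58), p = 1.294e-38 (significant at 0.05)
```

Reading the report: of 40,886 simulated downloads, 53.21% survive
exact-text deduplication (the simulator's 46% duplicate rate plus removed
non-English posts); the cross-validated classifier mislabels 0.74% of the
5000 annotated items; the period-B/period-A complaint ratio estimate of
186.07% brackets the configured 184% ground truth; and the two-group ANOVA
on daily counts rejects equal means. `report_json(rep, "report.json")`
serializes every number shown.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/painwatch.R` (subcommands `simulate` and `run`).

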