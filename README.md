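# convrecur

Conceptual recurrence and content-based engagement analysis for annotated
dyadic conversations.

`convrecur` is built for a question that comes up wherever communication
training is evaluated — dementia care being the motivating setting: *which
specific carer communication behaviours are followed by the partner
actually engaging with the carer's content?* It combines human-coded
behaviour labels (bracketed codes such as `[ActListen]` embedded in
speaker-turn transcripts) with an automated, term-based measure of content
sharing between turns, and links the two with per-behaviour odds-ratio /
logistic association models.

## The method in brief

For each conversation, analysed in isolation:

1. **Recurrence.** Utterances are tokenised, stopwords removed, and a
   per-conversation vocabulary capped at 200 terms is built by frequency.
   Similarity between turns *i* and *j* is the binary cosine
   `s(i,j) = |T_i ∩ T_j| / sqrt(|T_i||T_j|)` over term-presence sets.
2. **Windowed metrics.** Per turn, twelve primitive metrics cross time
   scale (short = adjacent turn, medium = 10 turns, long = all turns),
   direction (forward / backward) and type (other / self); medium and long
   are means of `s(t,u)` over qualifying turns in the window.
3. **Engagement labels.** Per carer turn and direction, binary labels with
   isolation rules: short iff the short metric is positive; medium only
   when positive *and* short absent; long only when both shorter ranges
   are absent.
4. **Association.** For every behaviour code on ≥ 1% of carer turns, a 2×2
   table of code presence against each label gives `OR = ad/(bc)` with a
   95% Wald interval `exp(ln OR ± 1.96·sqrt(1/a+1/b+1/c+1/d))` — equal, on
   all-positive tables, to the exponentiated coefficient of the univariate
   logistic fit the package also provides.

A synthetic dyad generator (`synthetic_config()`, `generate_corpus()`)
injects known odds multipliers on term reuse so the whole pipeline can be
validated end-to-end: null calibration of false-positive rates and
parameter recovery of injected effects (`recovery_report()`).

## Worked example

Reconstructing an association from published 2×2 counts — 17/40 odds of
engagement when the behaviour was present against 166/1520 when absent:

```r
library(convrecur)
odds_ratio(list(a = 17, b = 40, c = 166, d = 1520))
#> 2x2 association [closed_form]: OR 3.892 (95% CI 2.158-7.018), p 6.28e-06,
#>   P(engaged | present) 29.8%
```

The odds of engagement are 3.9 times higher when the behaviour occurs, and
the partner engages after 29.8% of the turns carrying it.

Running the full pipeline on the packaged annotated excerpt:

```r
cv <- parse_transcript(system.file("extdata", "dyad_excerpt.csv",
                                   package = "convrecur"))
an <- analyze_conversation(cv)
round(an$metrics[3:4, 1:4], 3)
#>   index other_forward_short other_forward_medium other_forward_long
#> 3     2                 0.5                  0.1              0.083
#> 4     3                 0.0                  0.0              0.000
```

Turn 2 (partner: "...you could pet them and they wouldn't *yelp*") is
picked up by the carer's next turn ("...horrors aren't they when they
*yelp*"), giving a short-range similarity of 1/√4 = 0.5 that dilutes to
0.5/5 = 0.1 over the 5 partner turns of the medium window.

End-to-end on a synthetic corpus with a known injected effect (odds
multiplier 3 on short-range reuse after `ActListen`):

```r
cfg <- synthetic_config(n_conversations = 6, turns_per_conversation = 160,
                        turn_jitter = 0,
                        behaviour_rates = c(ActListen = 0.2, GiveTime = 0.15),
                        behaviour_effects = list(
                          ActListen = list(multiplier = 3, window = "short")),
                        seed = 42)
corp <- generate_corpus(cfg)
results_table(build_turn_table(corp$conversations), "forward")
#> Engagement associations (forward direction, logistic, 480 carer turns)
#>  behaviour  range      p    or            ci prob_present odds_present odds_absent stars
#>  ActListen  short <0.001 4.219 (2.612-6.815)          41%        45/64      53/318   ***
#>  ActListen medium 0.9614 1.016 (0.536-1.925)          13%        14/95      47/324
#>  ActListen   long 0.1279 0.641 (0.362-1.136)          16%        17/92      83/288
#>  ...
```

The injected short-window effect is detected on the short label and, as it
should, nowhere else; `recovery_report(corp)` confirms the 95% interval
(2.61–6.81) covers the injected multiplier.

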