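# trigtag

Label-aware biomedical event trigger detection in R.

Event trigger detection — finding the word or phrase that signals a
biomedical event ("activation" → Positive-Regulation, "secretion" →
Localization) and typing it against a corpus schema — is the first step of
biomedical event extraction, and the step where most extraction errors
originate. Trigger words are heavily context-dependent ("proliferation" can
signal Growth or Cell-Proliferation), while the event-type labels themselves
carry usable semantics. trigtag implements a detector built around that
observation, for text-mining researchers and practitioners working with
BioNLP shared-task style corpora.

## The model

Trigger detection is cast as BIO sequence labelling (tag set of size
2k + 1 for k event types). The model has three stages:

1. **Joint encoding.** A label prompt L (one dedicated token per event
   type, in a fixed random order) is concatenated with the sentence S as
   ⟨[CLS], L, [SEP], S, [SEP]⟩ and run through a transformer encoder, so
   self-attention mediates direct label–text interaction. Splitting the
   output gives label encodings H_L (m × d) and word-level sentence
   encodings H_S (n × d). A small trainable transformer ships for CPU-scale
   runs; the encoder is a pluggable contract.
2. **Label-based representations.** Two per-token views of the labels:
   a *label-context attention* representation
   C_i = (1/N) Σ_j ã_ij v_j (token as query, labels as keys/values,
   softmax attention at scale 1/√d), and a *label–trigger affinity*
   A_ij = σ(h_S(i)ᵀ W h_L(j) + b) from a learnable bilinear form. Three
   separate affine heads project H_S, C and A to tag space and combine as a
   weighted residual sum x = X′ + α·X̂ + (1 − α)·X̃, α ∈ (0, 1).
3. **CRF decoding.** A linear-chain CRF with virtual START/STOP states
   scores tag sequences by emissions x plus transitions
   (score(x,y) = Σ T\_{y_i,y_{i+1}} + Σ F\_{x,y_i}), is trained by exact
   negative log-likelihood (forward algorithm in log space) and decoded by
   Viterbi — so BIO constraints like "I must not directly follow O" are
   learned as sequence structure.

All gradients (transformer blocks, attention, bilinear affinity, CRF) are
hand-derived and finite-difference checked. The package also provides
BioNLP standoff (.txt/.a1/.a2) corpus I/O with built-in MLEE and GENIA
schemas, a seeded synthetic-corpus generator with planted trigger lexicons
and cue-resolved ambiguous triggers, span-level micro/macro evaluation,
ablation switches, an α-sweep utility, and a command-line interface
(`inst/cli/trigtag.R`).

## Worked example

The BIO view of the classic example sentence:

```r
library(trigtag)
spans <- tibble::tibble(start = c(3, 5, 8), end = c(3, 5, 8),
                        type = c("Positive_Regulation", "Growth", "Localization"))
spans_to_tags(spans, 8, builtin_schema("mlee"))
#> [1] "O"                     "O"                     "B-Positive_Regulation"
#> [4] "O"                     "B-Growth"              "O"
#> [7] "O"                     "B-Localization"
```

Train on a synthetic corpus and evaluate held-out:

```r
spec  <- synthetic_spec()                       # 5 types, ambiguity rate 0.3
train <- generate_corpus(spec, 800, seed = 1)
dev   <- generate_corpus(spec, 100, seed = 2)
test  <- generate_corpus(spec, 200, seed = 3)

model <- train_trigger_model(train$sentences, spec$schema,
                             trigger_config("tiny", seed = 1),
                             dev = dev$sentences, quiet = FALSE)
#> epoch 1  loss 1.9001  dev F1 74.60
#> ...
#> epoch 6  loss 0.0033  dev F1 100.00

pred <- predict(model, test$sentences)
evaluate_triggers(test$sentences$gold_spans, pred$pred_spans,
                  schema = spec$schema)
#> <eval_report> micro P 99.12% R 99.12% F1 99.12% (TP 113 FP 1 FN 1)

lexicon_baseline(train, test$sentences)         # context-blind lookup
#> <eval_report> micro P 83.33% R 83.33% F1 83.33% (TP 95 FP 19 FN 19)
```

The trained model recovers nearly all planted triggers, including the
ambiguous ones it must resolve from in-sentence cues, while the
context-blind most-frequent-type lookup is capped by the planted ambiguity.
`tidy()`/`glance()` give per-type and one-row summaries; `autoplot()` plots
training curves and α sweeps.

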