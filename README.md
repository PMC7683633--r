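# eventbtm

Event-based topic learning for full-text neuroimaging literature.

Word-level topic models (LDA and friends) applied to fMRI papers return
scattered, hard-to-interpret topic words ("brain", "region", "study").
`eventbtm` instead learns topics over *research events* — structured
trigger + argument mentions such as

> **Event**_deduce-result_ = [ trigger "reveals";
> ⟨"task difficulty", research object⟩, ⟨"BOLD responses", biological mechanism⟩ ]

and is aimed at text-mining practitioners who want document topics that
read like statements about experiments rather than word lists.

## What it implements

1. **Event element recognition.** Sentences are vectorized as
   `V_word = [V_w, V_c, V_t, V_char]` — word embedding (d=100), one-hot
   case vector, terminology-dictionary scalar, character-CNN vector
   (width 3, 30 outputs over 25-d character embeddings) — and tagged by a
   bidirectional LSTM (hidden 200 per direction) with per-token
   log-softmax over a 37-tag BIO inventory (9 trigger + 9 argument
   categories).
2. **Event extraction.** For each candidate trigger–argument pair, lexical
   features `V_lf = [E_1t, E_2t, E_1tf, E_1tb, E_2tf, E_2tb, r]` and
   sentence features `V_sf = tanh(W_2 · max(M_1 v_wp))` (convolution over
   word + position-distance representations) feed a softmax over argument
   roles plus a "none" class; assembled mentions are validated against a
   configurable event-role table.
3. **Event-BTM.** Canonicalized events are paired into biterms per
   document; the biterm topic model
   `P(b) = Σ_z θ_z φ_{i|z} φ_{j|z}` is fitted by collapsed Gibbs sampling
   (C++ core, exact-enumeration oracle in the tests), and document topics
   follow from `P(z|d) = Σ_b p(z|b) p(b|d)`.
4. **Evaluation.** UMass-style topic coherence
   `Σ log((D(v_i,v_j)+ε)/D(v_j))` on document co-occurrence counts, and
   mean pairwise KL divergence `Σ p log(p/q)` between topic distributions.
5. **Synthetic gold data.** A seeded generator plants topics over event
   templates and emits corpus, BIO, role-annotation and dictionary files
   in exactly the formats the pipeline reads, so every stage is testable
   without any external corpus.

## Worked example

```r
library(eventbtm)

toks <- tokenize_text(
  "Task difficulty reveals the BOLD responses in frontal and parietal cortices")[[1]]

# position features of "frontal and parietal cortices" w.r.t. the
# trigger "reveals" and the argument "Task difficulty"
position_distances(target = c(7, 10), trigger = c(2, 2), argument = c(0, 1))
#> d_pft d_pfa
#>     5     7

ev <- event_mention("DeduceResult",
  trigger = list(start = 2, end = 2, text = "reveals"),
  arguments = list(
    list(start = 0, end = 1, text = "task difficulty",
         category = "TSK", role = "research object"),
    list(start = 4, end = 5, text = "BOLD responses",
         category = "GRO", role = "biological mechanism")))
validate_event(ev)          # character(0): the mention is schema-valid
canonicalize_event(ev)
#> [1] "DeduceResult|reveal|bold_respons+task_difficulti"
```

An end-to-end run on synthetic data (simulate → distant supervision →
tagger → role classifier → extraction → topics → evaluation):

```r
cfg <- pipeline_config(overrides = list(
  out_dir = "run1", seed = 3,
  simulate = list(n_docs = 12, sentences_per_doc = 5),
  tagger = list(epochs = 8), roles = list(epochs = 8),
  btm = list(iterations = 300, burn_in = 100)))
pipeline_run_all(cfg)
#> [..] train_ner: 55 sentences, 8 epochs, 7.7s, held-out F1 1.000
#> [..] extract: 55 event mention(s) from 12 document(s)
#> [..] topics: fitted K = 2 on 101 biterm(s), logLik -457.45
#> [..] evaluate: coherence 0.0668, mean KL 4.6428
```

`run1/` then holds the corpus, BIO/role annotations, model checkpoints,
the extracted-events table, the topic-model dump (`model_btm.yml`), the
per-document topic distributions and a `report.tsv` with the two metrics.
The held-out F1 of 1.0 reflects that the synthetic corpus is
dictionary-generated and nearly separable; the mean KL of 4.64 says the
two fitted topics put their mass on clearly different events. The same
stages are available from a shell via `inst/cli/eventbtm <subcommand>`.

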