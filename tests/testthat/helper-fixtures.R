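# Shared fixtures, built in code and cached across test files.

.fixtures <- new.env()

# The worked-example sentence: a deduce-result mention with trigger
# "reveals", arguments "Task difficulty" (experimental task) and
# "BOLD responses" (gross brain anatomy).
fig_sentence <- function() {
  c("Task", "difficulty", "reveals", "the", "BOLD", "responses", "in",
    "frontal", "and", "parietal", "cortices")
}

fix_bundle <- function() {
  if (is.null(.fixtures$bundle))
    .fixtures$bundle <- generate_corpus(synthetic_config(
      n_docs = 12L, sentences_per_doc = 5L, noise_rate = 0.1, seed = 11L))
  .fixtures$bundle
}

# A small trained tagger shared by the recognition tests.
fix_tagger <- function() {
  if (is.null(.fixtures$tagger)) {
    sents <- bundle_bio_sentences(fix_bundle())
    .fixtures$tagger <- train_tagger(
      sents[seq_len(40)], dictionaries = default_dictionaries(),
      epochs = 10L, seed = 5L)
  }
  .fixtures$tagger
}

# Tiny biterm set over 3 event tokens used by the sampler tests.
fix_tiny_biterms <- function() {
  structure(list(wi = c(1L, 1L, 2L, 3L), wj = c(2L, 3L, 3L, 3L),
                 doc = c("d1", "d1", "d2", "d2"), vocab = c("a", "b", "c"),
                 doc_ids = c("d1", "d2")),
            class = "biterm_set")
}

random_simplex <- function(n) {
  x <- runif(n)
  x / sum(x)
}
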