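fig_spans <- function() {
  list(target = c(7L, 10L),    # "frontal and parietal cortices"
       trigger = c(2L, 2L),    # "reveals"
       argument = c(0L, 1L))   # "Task difficulty"
}

test_that("position distances reproduce the worked example", {
  sp <- fig_spans()
  d <- position_distances(sp$target, sp$trigger, sp$argument)
  expect_equal(unname(d), c(5L, 7L))
  # self-distance and unit offset
  expect_equal(unname(position_distances(sp$trigger, sp$trigger,
                                         sp$argument)),
               c(0L, 2L))
  expect_equal(unname(position_distances(c(3L, 3L), sp$trigger,
                                         sp$argument)[1]), 1L)
})

test_that("lexical features fill NULL slots exactly as in the example", {
  emb <- random_embeddings(tolower(fig_sentence()), dim = 8L, seed = 3L)
  sp <- fig_spans()
  lf <- lexical_features(fig_sentence(), sp$trigger, sp$argument, 1L, emb)
  zero <- numeric(8L)
  # trigger and argument adjacent: E_1tf and E_2tb are NULL vectors;
  # the argument is sentence-initial: E_2tf is NULL too
  expect_equal(lf$E1tf, zero)
  expect_equal(lf$E2tb, zero)
  expect_equal(lf$E2tf, zero)
  # E_1tb is the word after the trigger ("the")
  expect_equal(lf$E1tb, unname(emb[, "the"]))
  expect_false(all(lf$E1t == 0))
  expect_equal(length(lf$vlf), 6L * 8L + 1L)
  expect_equal(lf$vlf[length(lf$vlf)], 1)
  # a mid-sentence pair with distinct neighbors has no zero slots
  lf2 <- lexical_features(fig_sentence(), c(6L, 6L), c(8L, 8L), 2L, emb)
  for (nm in c("E1t", "E2t", "E1tf", "E1tb", "E2tf", "E2tb"))
    expect_false(all(lf2[[nm]] == 0), info = nm)
})

test_that("sentence features stay in (-1,1), are deterministic and
           position-sensitive", {
  emb <- random_embeddings(tolower(fig_sentence()), dim = 10L, seed = 4L)
  model <- role_classifier(embeddings = emb, seed = 7L)
  sp <- fig_spans()
  v <- sentence_features(fig_sentence(), sp$trigger, sp$argument, model)
  expect_length(v, 30L)
  expect_true(all(v > -1 & v < 1))
  expect_identical(
    sentence_features(fig_sentence(), sp$trigger, sp$argument, model), v)
  # swapping two distant tokens changes the max-pooled features
  toks2 <- fig_sentence()
  toks2[c(5L, 8L)] <- toks2[c(8L, 5L)]
  v2 <- sentence_features(toks2, sp$trigger, sp$argument, model)
  expect_false(isTRUE(all.equal(v, v2)))
  # sentences shorter than the convolution width still encode
  expect_length(sentence_features(c("reveals"), c(0L, 0L), c(0L, 0L), model),
                30L)
})

test_that("role probabilities form a distribution over the inventory", {
  emb <- random_embeddings(tolower(fig_sentence()), dim = 10L, seed = 4L)
  model <- role_classifier(embeddings = emb, seed = 7L)
  sp <- fig_spans()
  pr <- classify_role(fig_sentence(), sp$trigger, sp$argument, 1L, model)
  expect_equal(sum(pr), 1, tolerance = 1e-6)
  expect_true(all(pr >= 0))
  expect_equal(length(pr), nrow(default_event_role_table()) + 1L)
  expect_true("none" %in% names(pr))
  # equal logits give the uniform distribution
  model$params$Wout[] <- 0
  model$params$bout[] <- 0
  pr0 <- classify_role(fig_sentence(), sp$trigger, sp$argument, 1L, model)
  expect_equal(unname(pr0), rep(1 / length(pr0), length(pr0)),
               tolerance = 1e-12)
})

role_training_fixture <- function() {
  bundle <- generate_corpus(synthetic_config(
    n_docs = 14L, sentences_per_doc = 5L, noise_rate = 0, seed = 31L))
  bio <- bundle_bio_sentences(bundle)
  roles <- unlist(bundle$roles, recursive = FALSE, use.names = FALSE)
  examples <- eventbtm:::.role_examples(bio, roles,
                                        default_event_role_table())
  vocab <- sort(unique(tolower(unlist(lapply(bio, `[[`, "tokens")))))
  emb <- random_embeddings(vocab, dim = 50L, seed = 8L)
  list(examples = examples, emb = emb)
}

test_that("the role classifier separates planted roles after training", {
  fx <- role_training_fixture()
  n <- length(fx$examples)
  train_idx <- seq_len(floor(0.85 * n))
  model <- role_classifier(embeddings = fx$emb, seed = 2L)
  model <- train_role_classifier(fx$examples[train_idx], model,
                                 epochs = 60L, seed = 2L)
  expect_true(all(diff(model$loss_history[1:5]) < 0))
  held <- fx$examples[-train_idx]
  pred <- vapply(held, function(ex) {
    pr <- classify_role(ex$tokens, ex$trigger, ex$argument, ex$r, model)
    names(pr)[which.max(pr)]
  }, character(1))
  acc <- mean(pred == vapply(held, function(e) as.character(e$label),
                             character(1)))
  expect_gt(acc, 0.9)
})

test_that("assembled events always satisfy the event-role table", {
  bundle <- fix_bundle()
  tagger <- fix_tagger()
  fx <- role_training_fixture()
  rc <- role_classifier(embeddings = fx$emb, seed = 2L)
  rc <- train_role_classifier(fx$examples[seq_len(120)], rc, epochs = 10L,
                              seed = 2L)
  tab <- default_event_role_table()
  n_events <- 0L
  for (d in seq_len(6L)) {
    doc <- bundle$corpus$documents[[d]]
    for (s in doc$sentences) {
      rec <- recognize(s$tokens, tagger)
      evs <- suppressMessages(assemble_events(rec, s$tokens, rc,
                                              sentence_id = s$id,
                                              document_id = doc$id))
      for (ev in evs) {
        expect_identical(validate_event(ev, tab), character(0))
        expect_true(ev$meta_event %in% trigger_categories()$name)
      }
      n_events <- n_events + length(evs)
    }
  }
  expect_gt(n_events, 0L)
  # a trigger with no surviving arguments still yields an event
  rec0 <- list(triggers = data.frame(start = 0L, end = 0L,
                                     category = "DeduceResult",
                                     stringsAsFactors = FALSE),
               arguments = data.frame(start = integer(0), end = integer(0),
                                      category = character(0),
                                      stringsAsFactors = FALSE))
  evs <- assemble_events(rec0, c("reveals"), rc)
  expect_length(evs, 1L)
  expect_length(evs[[1]]$arguments, 0L)
  # an argument category no role admits is dropped with a log entry
  rec1 <- list(triggers = data.frame(start = 0L, end = 0L,
                                     category = "PerformCognitiveTask",
                                     stringsAsFactors = FALSE),
               arguments = data.frame(start = 1L, end = 1L,
                                      category = "GRO",
                                      stringsAsFactors = FALSE))
  expect_message(evs <- assemble_events(rec1, c("performed", "cortex"), rc),
                 "not admitted")
  expect_length(evs[[1]]$arguments, 0L)
})
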