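test_that("the case classifier is total and matches the listed order", {
  expect_equal(names(which(case_vector("DMN") == 1)), "allUpper")
  expect_equal(names(which(case_vector("2019") == 1)), "numeric")
  expect_equal(names(which(case_vector("fMRI") == 1)), "other")
  expect_equal(names(which(case_vector("cortex") == 1)), "allLower")
  expect_equal(names(which(case_vector("Task") == 1)), "initialUpper")
  expect_equal(names(which(case_vector("B12") == 1)), "mainly_numeric")
  expect_equal(names(which(case_vector("alpha2") == 1)), "contains_digit")
  # exactly one coordinate is set for arbitrary printable tokens
  tokens <- c("a", "Z", ".", "3T", "fMRI1", "e-3", "Abc123", "''")
  for (tok in tokens) expect_equal(sum(case_vector(tok)), 1)
})

test_that("the dictionary scalar carries the matched category index", {
  dicts <- default_dictionaries()
  # "cortex" inside the GRO match "auditory cortex" -> index 1
  expect_equal(dict_scalar(c("the", "auditory", "cortex"), dicts),
               c(0L, 1L, 1L))
  expect_equal(dict_scalar(c("showed"), dicts), 0L)
  # a TSK match carries the index assigned to TSK in the schema (6)
  idx <- dict_scalar(c("stroop", "task"), dicts)
  expect_equal(idx, c(6L, 6L))
})

test_that("character features are deterministic with the configured size", {
  model <- fix_tagger()
  v <- char_features("cortex", model)
  expect_length(v, 30L)
  expect_identical(char_features("cortex", model), v)
  # 1-character and unseen-character tokens still work via padding/unknown
  expect_length(char_features("a", model), 30L)
  expect_length(char_features("é", model), 30L)
})

test_that("combined word vectors concatenate to the declared dimension", {
  model <- fix_tagger()
  total <- sum(unlist(model$dims))
  expect_equal(total, 100L + 7L + 1L + 30L)
  X <- vectorize_sentence(c("Task", "difficulty", "reveals"), model)
  expect_equal(dim(X), c(138L, 3L))
  # OOV token: shared unknown embedding plus correct case/dict/char parts
  X2 <- vectorize_sentence(c("zyzzyva"), model)
  expect_equal(X2[seq_len(100), 1], unname(model$params$E[, "<unk>"]))
  expect_equal(X2[100L + seq_len(7L), 1], unname(case_vector("zyzzyva")))
  expect_equal(dim(vectorize_sentence(character(0), model)), c(138L, 0L))
})

test_that("encoding concatenates directional states and normalizes tags", {
  model <- fix_tagger()
  toks <- c("patients", "performed", "the", "stroop", "task", ".")
  enc <- encode_sentence(toks, model)
  expect_equal(dim(enc$h), c(2L * model$hyper$hidden, length(toks)))
  # per-token probabilities exponentiate and sum to 1
  expect_equal(colSums(exp(enc$log_probs)), rep(1, length(toks)),
               tolerance = 1e-6)
  # dual route: the forward half must equal a manual forward pass and the
  # backward half a manual pass over the reversed sentence
  X <- vectorize_sentence(toks, model)
  p <- model$params
  fwd <- eventbtm:::.lstm_forward(X, p$Wf, p$Uf, p$bf)$H
  bwd <- eventbtm:::.lstm_forward(X[, rev(seq_along(toks))],
                                  p$Wb, p$Ub, p$bb)$H
  expect_equal(enc$h[seq_len(model$hyper$hidden), ], fwd)
  expect_equal(enc$h[model$hyper$hidden + seq_len(model$hyper$hidden), ],
               bwd[, rev(seq_along(toks))])
  # fixed input -> identical encoding
  expect_identical(encode_sentence(toks, model), enc)
})

test_that("training reduces the loss and is reproducible per seed", {
  sents <- bundle_bio_sentences(generate_corpus(synthetic_config(
    n_docs = 10L, sentences_per_doc = 6L, noise_rate = 0, seed = 21L)))
  m1 <- train_tagger(sents, dictionaries = default_dictionaries(),
                     epochs = 5L, seed = 2L)
  expect_true(all(diff(m1$loss_history) < 0))
  m2 <- train_tagger(sents, dictionaries = default_dictionaries(),
                     epochs = 5L, seed = 2L)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$params, m2$params)
  # label set is checked against the schema before training
  bad <- sents
  bad[[1]]$labels[1] <- "B-NOPE"
  expect_error(train_tagger(bad, epochs = 1L), "outside the schema")
})

test_that("recognition decodes grouped, typed, non-overlapping spans", {
  model <- fix_tagger()
  expect_equal(bio_spans(c("O", "B-TSK", "I-TSK", "O")),
               data.frame(start = 1L, end = 2L, category = "TSK",
                          stringsAsFactors = FALSE))
  expect_equal(nrow(bio_spans(rep("O", 4L))), 0L)
  # a gold-labeled separable sentence is recovered exactly
  sent <- bundle_bio_sentences(fix_bundle())[[1]]
  rec <- recognize(sent$tokens, model)
  gold <- bio_spans(sent$labels)
  got <- rbind(
    data.frame(start = rec$triggers$start, end = rec$triggers$end,
               category = vapply(rec$triggers$category,
                                 eventbtm:::.trigger_abbr, character(1)),
               stringsAsFactors = FALSE),
    rec$arguments)
  got <- got[order(got$start), ]
  rownames(got) <- NULL
  expect_equal(got, gold[order(gold$start), ])
  # checkpoints reload bit-identically
  f <- tempfile(fileext = ".rds")
  save_tagger(model, f)
  m2 <- load_tagger(f)
  expect_identical(m2$params, model$params)
  expect_identical(predict(m2, sent$tokens), predict(model, sent$tokens))
})

test_that("token F1 scores agreement on non-O labels", {
  expect_equal(token_f1(c("B-TSK", "O"), c("B-TSK", "O")), 1)
  expect_equal(token_f1(c("O", "O"), c("B-TSK", "O")), 0)
  f1 <- token_f1(c("B-TSK", "B-GRO", "O"), c("B-TSK", "O", "O"))
  expect_equal(f1, 2 * (1 / 2) * 1 / (1 / 2 + 1))
})
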