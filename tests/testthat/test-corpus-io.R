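test_that("the stemmer strips suffixes the way the canonical keys expect", {
  expect_equal(porter_stem(c("reveals", "responses", "difficulty", "BOLD",
                             "activates", "networks")),
               c("reveal", "respons", "difficulti", "bold", "activ",
                 "network"))
})

test_that("tokenization splits on whitespace and punctuation, keeping case", {
  toks <- tokenize_text("Task difficulty reveals BOLD responses .")[[1]]
  expect_length(toks, 6L)
  expect_equal(toks[1], "Task")
  expect_equal(tokenize_text("fMRI-based study.")[[1]],
               c("fMRI", "-", "based", "study", "."))
  tt <- token_table(c("reveals", "BOLD"))
  expect_equal(tt$stem, c("reveal", "bold"))
  expect_equal(tt$affix, c("s", ""))
  expect_equal(tt$index, c(0L, 1L))
})

test_that("documents are read with stable sentence ordering and ids", {
  f <- tempfile()
  writeLines(c("Task difficulty reveals BOLD responses .",
               "The experiment was conducted ."), f)
  corp <- read_documents(f)
  expect_length(corp$documents, 1L)
  sents <- corp$documents[[1]]$sentences
  expect_length(sents, 2L)
  expect_equal(vapply(sents, `[[`, integer(1), "id"), c(0L, 1L))
  expect_length(sents[[1]]$tokens, 6L)
  # empty file: empty document with a warning
  empty <- tempfile()
  file.create(empty)
  expect_warning(ec <- read_documents(empty), "empty document")
  expect_length(ec$documents[[1]]$sentences, 0L)
  # raw mode splits on terminal punctuation
  f2 <- tempfile()
  writeLines("First sentence here. Second one follows!", f2)
  corp2 <- read_documents(f2, mode = "raw")
  expect_length(corp2$documents[[1]]$sentences, 2L)
})

test_that("BIO files round-trip exactly and repair invalid transitions", {
  sentences <- list(
    list(tokens = c("Task", "difficulty"), labels = c("B-TSK", "I-TSK")),
    list(tokens = c("no", "entities", "."), labels = c("O", "O", "O")))
  path <- tempfile()
  write_bio(sentences, path)
  lines <- readLines(path)
  expect_equal(lines[1:2], c("Task\tB-TSK", "difficulty\tI-TSK"))
  expect_identical(read_bio(path), sentences)
  # write(read(write(x))) is stable at the byte level
  path2 <- tempfile()
  write_bio(read_bio(path), path2)
  expect_identical(readLines(path2), lines)
  # I- after O is repaired to B- with a warning
  writeLines(c("the\tO", "cortex\tI-GRO", ""), path)
  expect_warning(rep <- read_bio(path), "repaired")
  expect_equal(rep[[1]]$labels, c("O", "B-GRO"))
  # unknown abbreviations are rejected with the valid inventory listed
  writeLines(c("x\tB-FOO", ""), path)
  expect_error(read_bio(path), "valid tags")
  expect_error(write_bio(list(list(tokens = "x", labels = "B-FOO")), path),
               "valid tags")
})

test_that("role-annotation lines parse positionally and validate spans", {
  ann <- parse_role_line("4 2 3 4 4")
  expect_equal(ann, list(role_index = 4L, e1_start = 2L, e1_end = 3L,
                         e2_start = 4L, e2_end = 4L))
  expect_equal(parse_role_line("0 0 0 1 1")$e2_start, 1L)
  expect_error(parse_role_line("1 3 2 0 0"), "inverted")
  expect_error(parse_role_line("1 2 3 4", line_number = 7L), "line 7")
  # file round-trip preserves empty sentence groups
  groups <- list(list(parse_role_line("4 2 3 4 4"),
                      parse_role_line("2 2 2 5 6")),
                 list(),
                 list(parse_role_line("1 0 0 2 3")))
  path <- tempfile()
  write_role_file(groups, path)
  expect_identical(read_role_file(path), groups)
  path2 <- tempfile()
  write_role_file(read_role_file(path), path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("term dictionaries lower-case, de-duplicate and warn when empty", {
  f <- tempfile()
  writeLines(c("visual", "Visual"), f)
  d <- suppressMessages(load_term_dictionary(f, "GRO"))
  expect_length(d$terms, 1L)
  expect_equal(d$category, "GRO")
  writeLines("auditory cortex", f)
  expect_length(suppressMessages(load_term_dictionary(f, "GRO"))$terms, 1L)
  file.create(f2 <- tempfile())
  expect_warning(suppressMessages(load_term_dictionary(f2, "COG")),
                 "empty term dictionary")
})

test_that("distant supervision applies left-to-right longest match", {
  dicts <- default_dictionaries()
  out <- distant_annotate(list(c("the", "auditory", "cortex", "responded")),
                          dicts)
  expect_equal(out[[1]]$labels, c("O", "B-GRO", "I-GRO", "O"))
  # longest match beats an embedded shorter term
  out <- distant_annotate(list(c("a", "delayed", "memory", "task")), dicts)
  expect_equal(out[[1]]$labels, c("O", "B-TSK", "I-TSK", "I-TSK"))
  # no hits
  out <- distant_annotate(list(c("nothing", "matches", "here")), dicts)
  expect_true(all(out[[1]]$labels == "O"))
  # matching is case-insensitive
  out <- distant_annotate(list(c("Auditory", "Cortex")), dicts)
  expect_equal(out[[1]]$labels, c("B-GRO", "I-GRO"))
  # equal-length cross-category ties resolve by priority, with a warning
  tie <- list(term_dictionary("auditory cortex", "GRO"),
              term_dictionary("auditory cortex", "RLT"))
  expect_warning(out <- distant_annotate(list(c("auditory", "cortex")), tie),
                 "priority")
  expect_equal(out[[1]]$labels, c("B-GRO", "I-GRO"))
})

test_that("distant supervision output has no overlaps or bad transitions", {
  bundle <- fix_bundle()
  ann <- distant_annotate(bundle$corpus, default_dictionaries())
  for (doc in ann) {
    for (s in doc) {
      expect_identical(eventbtm:::repair_bio(s$labels), s$labels)
      spans <- bio_spans(s$labels)
      if (nrow(spans) > 1L) {
        o <- order(spans$start)
        expect_true(all(spans$start[o][-1] > spans$end[o][-nrow(spans)]))
      }
    }
  }
})

test_that("the corpus split is reproducible, rounded and a partition", {
  mk <- function(n) {
    docs <- lapply(seq_len(n), function(i)
      eventbtm:::.make_document(
        list(eventbtm:::.make_sentence(c("a", "b"), 0L)),
        sprintf("d%03d", i)))
    eventbtm:::.make_corpus(docs)
  }
  sp <- split_corpus(mk(126L), 0.9, seed = 4L)
  expect_length(sp$train$documents, 113L)
  expect_length(sp$test$documents, 13L)
  sp10 <- split_corpus(mk(10L), 0.9, seed = 4L)
  expect_length(sp10$train$documents, 9L)
  expect_length(sp10$test$documents, 1L)
  sp10b <- split_corpus(mk(10L), 0.9, seed = 4L)
  expect_identical(sp10, sp10b)
  ids <- function(cc) vapply(cc$documents, `[[`, character(1), "id")
  expect_setequal(c(ids(sp$train), ids(sp$test)), ids(mk(126L)))
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0L)
  expect_error(split_corpus(mk(1L), 0.9), "at least 2")
})

test_that("embedding files round-trip through the text format", {
  emb <- random_embeddings(c("task", "cortex"), dim = 4L, seed = 9L)
  f <- tempfile()
  write_embeddings(emb, f)
  back <- read_embeddings(f)
  expect_equal(colnames(back), colnames(emb))
  expect_equal(back, emb, tolerance = 1e-12)
  writeLines(c("a 1 2", "b 1 2 3"), f)
  expect_error(read_embeddings(f), "inconsistent")
})
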