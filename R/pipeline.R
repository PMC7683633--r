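# End-to-end orchestration: a validated config, one function per stage
# (simulate, annotate, train_ner, train_roles, extract, topics, evaluate)
# and run_all chaining recognition, extraction and topic learning.
# Every stage logs seeds and timings and writes an effective-config
# snapshot, so repeated runs with fixed seeds are byte-identical.

.pipeline_defaults <- function() {
  list(
    out_dir = "eventbtm_out",
    seed = 1L,
    split_ratio = 0.9,
    simulate = list(n_docs = 200L, sentences_per_doc = 8L, K_true = 2L,
                    topic_dominance = 0.9, noise_rate = 0.1),
    embeddings = list(path = NULL, dim = 100L),
    tagger = list(epochs = 50L, hidden = 200L, word_dim = 100L,
                  char_dim = 25L, conv_width = 3L, char_out = 30L,
                  lr = 1e-3, clip = 5, batch_size = 8L),
    roles = list(epochs = 50L, n_filters = 30L, conv_width = 3L,
                 sf_dim = 30L, pos_dim = 5L, pos_clip = 30L, lr = 1e-3,
                 clip = 5, batch_size = 8L),
    btm = list(K = 2L, alpha = NULL, beta = 0.01, iterations = 1000L,
               burn_in = 500L, granularity = "full"),
    evaluate = list(top_n = 2L, eps = 1))
}

.merge_config <- function(defaults, overrides, path = character(0)) {
  for (nm in names(overrides)) {
    full <- paste(c(path, nm), collapse = ".")
    if (!nm %in% names(defaults))
      stop(structure(class = c("config_error", "error", "condition"),
                     list(message = paste0("unknown config key: ", full),
                          call = NULL)))
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])))
      defaults[[nm]] <- .merge_config(defaults[[nm]], overrides[[nm]],
                                      c(path, nm))
    else defaults[[nm]] <- overrides[[nm]]
  }
  defaults
}

#' Pipeline configuration
#'
#' Defaults follow the method's stated settings: 50 training epochs,
#' 100-dimensional word vectors, convolution width 3, CNN output size 30,
#' LSTM hidden size 200 per direction, K = 2 topics with 2 topic words
#' each, and a 9:1 document-level train/test split.
#'
#' @param path Optional YAML config file.
#' @param overrides Named list of overrides (applied after the file);
#'   unknown keys raise a `config_error`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- .pipeline_defaults()
  if (!is.null(path)) cfg <- .merge_config(cfg, yaml::read_yaml(path))
  cfg <- .merge_config(cfg, overrides)
  if (is.null(cfg$btm$alpha)) cfg$btm$alpha <- 50 / cfg$btm$K
  structure(cfg, class = "pipeline_config")
}

.plog <- function(cfg, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...))
  message(line)
  logf <- file.path(cfg$out_dir, "pipeline.log")
  if (dir.exists(cfg$out_dir)) cat(line, "\n", file = logf, append = TRUE)
}

.snapshot_config <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  snap <- unclass(cfg)
  snap$package_version <- as.character(utils::packageVersion("eventbtm"))
  yaml::write_yaml(snap, file.path(cfg$out_dir, "config_used.yml"))
}

.paths <- function(cfg) {
  o <- cfg$out_dir
  list(corpus = file.path(o, "corpus"), dicts = file.path(o, "dictionaries"),
       gold = file.path(o, "gold"), annotated = file.path(o, "annotated"),
       models = file.path(o, "models"),
       embeddings = file.path(o, "embeddings.txt"),
       split = file.path(o, "split.tsv"), events = file.path(o, "events.tsv"),
       btm = file.path(o, "model_btm.yml"),
       doc_topics = file.path(o, "doc_topics.tsv"),
       report = file.path(o, "report.tsv"))
}

# ---------------------------------------------------------------------------
# Event record serialization
# ---------------------------------------------------------------------------

#' Write or read extracted events
#'
#' Tab-separated records: document id, sentence id, meta-event, trigger
#' span and text, and the arguments packed as
#' `start:end:category:role:prob` separated by `" ; "`.
#'
#' @param events List of `event_mention` objects.
#' @param tokens_lookup Unused, reserved.
#' @param path File path.
#' @export
write_events <- function(events, path, tokens_lookup = NULL) {
  rows <- vapply(events, function(ev) {
    args <- vapply(ev$arguments, function(a)
      paste(a$start, a$end, a$category, a$role,
            if (is.null(a$prob)) 1 else round(a$prob, 6), a$text,
            sep = ":"),
      character(1))
    paste(ev$document_id, ev$sentence_id, ev$meta_event, ev$trigger$start,
          ev$trigger$end, ev$trigger$text,
          if (length(args)) paste(args, collapse = " ; ") else "-",
          sep = "\t")
  }, character(1))
  writeLines(c(paste("document", "sentence", "meta_event", "trigger_start",
                     "trigger_end", "trigger_text", "arguments", sep = "\t"),
               rows), path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  lines <- readLines(path, warn = FALSE)[-1L]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    args <- list()
    if (f[7] != "-") {
      for (rec in strsplit(f[7], " ; ", fixed = TRUE)[[1]]) {
        p <- strsplit(rec, ":", fixed = TRUE)[[1]]
        args[[length(args) + 1L]] <- list(
          start = as.integer(p[1]), end = as.integer(p[2]), category = p[3],
          role = p[4], prob = as.numeric(p[5]),
          text = paste(p[-(1:5)], collapse = ":"))
      }
    }
    event_mention(f[3],
                  trigger = list(start = as.integer(f[4]),
                                 end = as.integer(f[5]), text = f[6]),
                  arguments = args, sentence_id = as.integer(f[2]),
                  document_id = f[1])
  })
}

# ---------------------------------------------------------------------------
# Stages
# ---------------------------------------------------------------------------

#' Pipeline stages
#'
#' Each stage reads its inputs from the configured output directory,
#' writes its artifacts there, and logs seeds and timings;
#' `pipeline_run_all` chains simulate, annotate, tagger and role-classifier
#' training, event extraction, topic fitting and evaluation.  Runs are
#' idempotent under fixed seeds.
#'
#' @param cfg A `pipeline_config`.
#' @return Each stage returns its main artifact path(s) invisibly;
#'   `pipeline_run_all` returns the full path list.
#' @export
pipeline_simulate <- function(cfg) {
  .snapshot_config(cfg)
  p <- .paths(cfg)
  sc <- synthetic_config(
    n_docs = cfg$simulate$n_docs,
    sentences_per_doc = cfg$simulate$sentences_per_doc,
    K_true = cfg$simulate$K_true,
    topic_dominance = cfg$simulate$topic_dominance,
    noise_rate = cfg$simulate$noise_rate, seed = cfg$seed)
  bundle <- generate_corpus(sc)
  for (d in c(p$corpus, p$dicts, p$gold))
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
  for (doc in bundle$corpus$documents) {
    writeLines(vapply(doc$sentences, function(s)
      paste(s$tokens, collapse = " "), character(1)),
      file.path(p$corpus, paste0(doc$id, ".txt")))
    write_bio(bundle$bio[[doc$id]],
              file.path(p$gold, paste0(doc$id, ".bio")))
    write_role_file(bundle$roles[[doc$id]],
                    file.path(p$gold, paste0(doc$id, ".roles")))
  }
  for (d in sc$dictionaries)
    writeLines(sort(d$terms), file.path(p$dicts, paste0(d$category, ".txt")))
  vocab <- sort(unique(tolower(unlist(lapply(bundle$corpus$documents,
    function(doc) unlist(lapply(doc$sentences, `[[`, "tokens")))))))
  if (!is.null(cfg$embeddings$path)) {
    file.copy(cfg$embeddings$path, p$embeddings, overwrite = TRUE)
  } else {
    write_embeddings(random_embeddings(vocab, cfg$embeddings$dim,
                                       seed = cfg$seed), p$embeddings)
  }
  utils::write.table(
    data.frame(document = rownames(bundle$doc_topics), bundle$doc_topics),
    file.path(p$gold, "doc_topics.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  .plog(cfg, "simulate: wrote %d documents (seed %d)",
        cfg$simulate$n_docs, cfg$seed)
  invisible(bundle)
}

.load_corpus <- function(cfg) {
  corpus <- read_documents(.paths(cfg)$corpus)
  corpus$documents <- lapply(corpus$documents, function(d) {
    d$id <- sub("[.]txt$", "", d$id)
    d
  })
  corpus
}

.load_dictionaries <- function(cfg) {
  p <- .paths(cfg)
  files <- list.files(p$dicts, full.names = TRUE)
  suppressMessages(lapply(files, function(f)
    load_term_dictionary(f, sub("[.]txt$", "", basename(f)))))
}

#' @rdname pipeline_simulate
#' @export
pipeline_annotate <- function(cfg) {
  p <- .paths(cfg)
  corpus <- .load_corpus(cfg)
  dicts <- .load_dictionaries(cfg)
  ann <- distant_annotate(corpus, dicts)
  dir.create(p$annotated, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(corpus$documents))
    write_bio(ann[[i]], file.path(p$annotated,
                                  paste0(corpus$documents[[i]]$id, ".bio")))
  .plog(cfg, "annotate: distant supervision over %d documents",
        length(corpus$documents))
  invisible(p$annotated)
}

.load_split <- function(cfg) {
  p <- .paths(cfg)
  if (!file.exists(p$split)) {
    corpus <- .load_corpus(cfg)
    sp <- split_corpus(corpus, cfg$split_ratio, cfg$seed)
    df <- data.frame(
      document = c(vapply(sp$train$documents, `[[`, character(1), "id"),
                   vapply(sp$test$documents, `[[`, character(1), "id")),
      split = c(rep("train", length(sp$train$documents)),
                rep("test", length(sp$test$documents))))
    utils::write.table(df[order(df$document), ], p$split, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::read.table(p$split, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

.gold_bio <- function(cfg, doc_ids) {
  p <- .paths(cfg)
  setNames(lapply(doc_ids, function(d)
    read_bio(file.path(p$gold, paste0(d, ".bio")))), doc_ids)
}

#' @rdname pipeline_simulate
#' @export
pipeline_train_ner <- function(cfg) {
  p <- .paths(cfg)
  split <- .load_split(cfg)
  train_ids <- split$document[split$split == "train"]
  test_ids <- split$document[split$split == "test"]
  sentences <- unlist(.gold_bio(cfg, train_ids), recursive = FALSE,
                      use.names = FALSE)
  emb <- read_embeddings(p$embeddings)
  dicts <- .load_dictionaries(cfg)
  t0 <- Sys.time()
  model <- train_tagger(
    sentences, dictionaries = dicts, embeddings = emb,
    hidden = cfg$tagger$hidden, epochs = cfg$tagger$epochs,
    word_dim = cfg$tagger$word_dim, char_dim = cfg$tagger$char_dim,
    conv_width = cfg$tagger$conv_width, char_out = cfg$tagger$char_out,
    lr = cfg$tagger$lr, clip = cfg$tagger$clip,
    batch_size = cfg$tagger$batch_size, seed = cfg$seed)
  dir.create(p$models, showWarnings = FALSE, recursive = TRUE)
  save_tagger(model, file.path(p$models, "tagger.rds"))
  test_sents <- unlist(.gold_bio(cfg, test_ids), recursive = FALSE,
                       use.names = FALSE)
  f1 <- token_f1(lapply(test_sents, function(s) predict(model, s$tokens)),
                 lapply(test_sents, `[[`, "labels"))
  .plog(cfg, "train_ner: %d sentences, %d epochs, %.1fs, held-out F1 %.3f",
        length(sentences), cfg$tagger$epochs,
        as.numeric(difftime(Sys.time(), t0, units = "secs")), f1)
  invisible(file.path(p$models, "tagger.rds"))
}

# Training examples for the role classifier from gold BIO + role files:
# one positive per gold relation, one mismatched-role negative, and one
# unrelated-pair negative per sentence where available.
.role_examples <- function(bio_sentences, role_groups, role_table) {
  examples <- list()
  for (i in seq_along(bio_sentences)) {
    s <- bio_sentences[[i]]
    anns <- role_groups[[i]]
    if (length(anns) == 0L) next
    spans <- bio_spans(s$labels)
    gold_args <- vapply(anns, function(a)
      paste(a$e2_start, a$e2_end), character(1))
    for (a in anns) {
      examples[[length(examples) + 1L]] <- list(
        tokens = s$tokens, trigger = c(a$e1_start, a$e1_end),
        argument = c(a$e2_start, a$e2_end), r = a$role_index,
        label = as.character(a$role_index))
      other <- setdiff(role_table$role_index, a$role_index)
      wrong <- other[(a$role_index + i) %% length(other) + 1L]
      examples[[length(examples) + 1L]] <- list(
        tokens = s$tokens, trigger = c(a$e1_start, a$e1_end),
        argument = c(a$e2_start, a$e2_end), r = wrong, label = "none")
    }
    arg_spans <- spans[spans$category %in% .ARGUMENT_CATEGORIES$abbreviation,
                       , drop = FALSE]
    for (j in seq_len(nrow(arg_spans))) {
      key <- paste(arg_spans$start[j], arg_spans$end[j])
      if (!key %in% gold_args) {
        a1 <- anns[[1]]
        examples[[length(examples) + 1L]] <- list(
          tokens = s$tokens, trigger = c(a1$e1_start, a1$e1_end),
          argument = c(arg_spans$start[j], arg_spans$end[j]),
          r = a1$role_index, label = "none")
      }
    }
  }
  examples
}

#' @rdname pipeline_simulate
#' @export
pipeline_train_roles <- function(cfg) {
  p <- .paths(cfg)
  split <- .load_split(cfg)
  train_ids <- split$document[split$split == "train"]
  bio <- unlist(.gold_bio(cfg, train_ids), recursive = FALSE,
                use.names = FALSE)
  roles <- unlist(lapply(train_ids, function(d)
    read_role_file(file.path(p$gold, paste0(d, ".roles")))),
    recursive = FALSE, use.names = FALSE)
  table <- default_event_role_table()
  examples <- .role_examples(bio, roles, table)
  emb <- read_embeddings(p$embeddings)
  t0 <- Sys.time()
  model <- role_classifier(table, emb, n_filters = cfg$roles$n_filters,
                           conv_width = cfg$roles$conv_width,
                           sf_dim = cfg$roles$sf_dim,
                           pos_dim = cfg$roles$pos_dim,
                           pos_clip = cfg$roles$pos_clip, seed = cfg$seed)
  model <- train_role_classifier(examples, model, epochs = cfg$roles$epochs,
                                 lr = cfg$roles$lr, clip = cfg$roles$clip,
                                 batch_size = cfg$roles$batch_size,
                                 seed = cfg$seed)
  dir.create(p$models, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(p$models, "roles.rds"))
  .plog(cfg, "train_roles: %d examples, %d epochs, %.1fs",
        length(examples), cfg$roles$epochs,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(file.path(p$models, "roles.rds"))
}

#' @rdname pipeline_simulate
#' @export
pipeline_extract <- function(cfg) {
  p <- .paths(cfg)
  corpus <- .load_corpus(cfg)
  tagger <- load_tagger(file.path(p$models, "tagger.rds"))
  roles <- readRDS(file.path(p$models, "roles.rds"))
  events <- list()
  for (doc in corpus$documents) {
    for (s in doc$sentences) {
      rec <- recognize(s$tokens, tagger)
      evs <- suppressMessages(
        assemble_events(rec, s$tokens, roles, sentence_id = s$id,
                        document_id = doc$id))
      events <- c(events, evs)
    }
  }
  write_events(events, p$events)
  .plog(cfg, "extract: %d event mention(s) from %d document(s)",
        length(events), length(corpus$documents))
  invisible(p$events)
}

#' @rdname pipeline_simulate
#' @export
pipeline_topics <- function(cfg) {
  p <- .paths(cfg)
  events <- read_events(p$events)
  by_doc <- split(events, vapply(events, `[[`, character(1), "document_id"))
  biterms <- build_biterms(by_doc, granularity = cfg$btm$granularity)
  model <- event_btm(biterms, K = cfg$btm$K, alpha = cfg$btm$alpha,
                     beta = cfg$btm$beta, iterations = cfg$btm$iterations,
                     burn_in = cfg$btm$burn_in, seed = cfg$seed)
  write_btm(model, p$btm)
  dt <- predict(model)
  utils::write.table(data.frame(document = rownames(dt), dt), p$doc_topics,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .plog(cfg, "topics: fitted K = %d on %d biterm(s), logLik %.2f",
        model$K, length(biterms$wi), as.numeric(logLik(model)))
  invisible(p$btm)
}

#' @rdname pipeline_simulate
#' @export
pipeline_evaluate <- function(cfg) {
  p <- .paths(cfg)
  events <- read_events(p$events)
  by_doc <- split(events, vapply(events, `[[`, character(1), "document_id"))
  biterms <- build_biterms(by_doc, granularity = cfg$btm$granularity)
  model <- event_btm(biterms, K = cfg$btm$K, alpha = cfg$btm$alpha,
                     beta = cfg$btm$beta, iterations = cfg$btm$iterations,
                     burn_in = cfg$btm$burn_in, seed = cfg$seed)
  corpus <- .load_corpus(cfg)
  docs <- lapply(corpus$documents, function(d)
    unique(porter_stem(unlist(lapply(d$sentences, `[[`, "tokens")))))
  report <- evaluation_report(model, docs, top_n = cfg$evaluate$top_n,
                              eps = cfg$evaluate$eps)
  write_evaluation_report(report, p$report)
  .plog(cfg, "evaluate: coherence %.4f, mean KL %.4f",
        report$value[1], report$value[2])
  invisible(p$report)
}

#' @rdname pipeline_simulate
#' @export
pipeline_run_all <- function(cfg) {
  pipeline_simulate(cfg)
  pipeline_annotate(cfg)
  pipeline_train_ner(cfg)
  pipeline_train_roles(cfg)
  pipeline_extract(cfg)
  pipeline_topics(cfg)
  pipeline_evaluate(cfg)
  .plog(cfg, "run_all: complete")
  invisible(.paths(cfg))
}
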