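# Seeded synthetic-corpus generator: sentences realize planted events
# (trigger + arguments drawn from the category lexicons) under a planted
# topic-over-events mixture, so every pipeline stage has gold data.
# Structure, not prose style, is what is emulated.

#' Default mini term dictionaries
#'
#' Five terms per argument category, drawn from the example terms of the
#' taxonomy tables; lexicons are disjoint across categories and include
#' nested terms ("memory task" inside "delayed memory task") so
#' longest-match annotation is exercised.
#'
#' @return Named list of `term_dictionary` objects, one per category
#'   abbreviation.
#' @export
default_dictionaries <- function() {
  terms <- list(
    GRO = c("auditory cortex", "visual cortex", "frontal gyri",
            "parietal cortex", "limbic system"),
    COG = c("attention", "visual perception", "working memory",
            "language processing", "episodic memory"),
    SUB = c("patients", "healthy adults", "children", "older adults",
            "volunteers"),
    MDI = c("hypertension", "depression", "schizophrenia", "epilepsy",
            "chronic pain"),
    SEN = c("visual stimuli", "auditory stimuli", "emotional stimuli",
            "tactile stimuli", "auditory sense"),
    TSK = c("delayed memory task", "motion discrimination task",
            "stroop task", "memory task", "verbal fluency task"),
    MEA = c("functional magnetic resonance imaging", "magnetoencephalography",
            "electroencephalography", "diffusion optical imaging",
            "magnetic resonance imaging"),
    TOL = c("multivariate analysis", "independent component analysis",
            "general linear model", "support vector machine",
            "random forest"),
    RLT = c("visual network", "sensory motor network", "auditory network",
            "cerebellar network", "default mode network"))
  lapply(setNames(names(terms), names(terms)), function(cat)
    term_dictionary(terms[[cat]], cat))
}

#' Default trigger lexicon
#'
#' Three trigger words per trigger category, disjoint across categories.
#'
#' @return Named list of character vectors keyed by meta-event name.
#' @export
default_trigger_lexicon <- function() {
  list(
    Activate = c("activates", "activated", "hyperactivates"),
    Deactivate = c("deactivates", "deactivated", "suppresses"),
    Include = c("includes", "contains", "comprises"),
    Affect = c("affects", "influences", "modulates"),
    DesignCognitiveTask = c("designed", "presented", "constructed"),
    PerformCognitiveTask = c("performed", "completed", "undertook"),
    AcquireData = c("recorded", "scanned", "measured"),
    AnalyzeData = c("analyzed", "applied", "computed"),
    DeduceResult = c("reveals", "indicates", "suggests"))
}

# Planted event specifications: fully specified (meta-event, trigger,
# arg1, arg2) tuples.  The two default topics have disjoint event sets and
# jointly exercise all 9 trigger and all 9 argument categories.
.default_event_specs <- function() {
  spec <- function(meta, trg, a1, c1, a2, c2)
    list(meta = meta, trigger = trg, arg1 = a1, cat1 = c1,
         arg2 = a2, cat2 = c2)
  list(
    topic1 = list(
      spec("PerformCognitiveTask", "performed", "patients", "SUB",
           "stroop task", "TSK"),
      spec("AcquireData", "recorded", "volunteers", "SUB",
           "magnetoencephalography", "MEA"),
      spec("AnalyzeData", "analyzed", "general linear model", "TOL",
           "electroencephalography", "MEA"),
      spec("DesignCognitiveTask", "designed", "verbal fluency task", "TSK",
           "random forest", "TOL"),
      spec("DeduceResult", "reveals", "motion discrimination task", "TSK",
           "visual cortex", "GRO"),
      spec("DeduceResult", "indicates", "depression", "MDI",
           "sensory motor network", "RLT")),
    topic2 = list(
      spec("Activate", "activates", "working memory", "COG",
           "frontal gyri", "GRO"),
      spec("Deactivate", "deactivates", "memory task", "TSK",
           "default mode network", "RLT"),
      spec("Affect", "affects", "attention", "COG",
           "parietal cortex", "GRO"),
      spec("Include", "contains", "visual network", "RLT",
           "auditory network", "RLT"),
      spec("Activate", "activated", "episodic memory", "COG",
           "auditory cortex", "GRO"),
      spec("AcquireData", "scanned", "children", "SUB",
           "auditory sense", "SEN")))
}

.FILLER_SENTENCES <- list(
  c("The", "experiment", "was", "conducted", "over", "two", "days", "."),
  c("Ethical", "approval", "was", "obtained", "for", "this", "study", "."),
  c("All", "procedures", "followed", "the", "relevant", "guidelines", "."),
  c("Participants", "gave", "written", "informed", "consent", "."))

#' Synthetic-corpus generator configuration
#'
#' Defaults describe the study conditions exercised by the package's
#' tests: 200 documents of 8 sentences, two planted topics with disjoint
#' event sets, 0.9 within-document topic dominance, and a 0.1 chance that
#' a sentence carries no event.
#'
#' @param n_docs,sentences_per_doc Corpus size.
#' @param K_true Number of planted topics (1 or 2 with the default event
#'   specs).
#' @param phi_true List of per-topic probability vectors over the planted
#'   event specs (simplex vectors; defaults decay geometrically).
#' @param topic_dominance Weight of a document's dominant topic in its
#'   topic mixture.
#' @param noise_rate Probability that a sentence is an event-free filler.
#' @param dictionaries,trigger_lexicon Category lexicons (defaults as
#'   above; must be disjoint across categories).
#' @param event_specs Planted events per topic (default: the built-in
#'   two-topic specification).
#' @param seed Integer seed.
#' @export
synthetic_config <- function(n_docs = 200L, sentences_per_doc = 8L,
                             K_true = 2L, phi_true = NULL,
                             topic_dominance = 0.9, noise_rate = 0.1,
                             dictionaries = default_dictionaries(),
                             trigger_lexicon = default_trigger_lexicon(),
                             event_specs = .default_event_specs(),
                             seed = 1L) {
  stopifnot(K_true >= 1L, K_true <= length(event_specs),
            noise_rate >= 0, noise_rate < 1,
            topic_dominance > 0, topic_dominance <= 1)
  event_specs <- event_specs[seq_len(K_true)]
  if (is.null(phi_true))
    phi_true <- lapply(event_specs, function(sp) {
      w <- 0.6^(seq_along(sp) - 1L)
      w / sum(w)
    })
  stopifnot(length(phi_true) == K_true)
  for (k in seq_len(K_true)) {
    stopifnot(length(phi_true[[k]]) == length(event_specs[[k]]),
              abs(sum(phi_true[[k]]) - 1) < 1e-8, all(phi_true[[k]] >= 0))
  }
  all_terms <- unlist(lapply(dictionaries, `[[`, "terms"))
  if (anyDuplicated(all_terms))
    stop("category lexicons are not disjoint: ",
         paste(unique(all_terms[duplicated(all_terms)]), collapse = ", "))
  structure(list(n_docs = n_docs, sentences_per_doc = sentences_per_doc,
                 K_true = K_true, phi_true = phi_true,
                 topic_dominance = topic_dominance, noise_rate = noise_rate,
                 dictionaries = dictionaries,
                 trigger_lexicon = trigger_lexicon,
                 event_specs = event_specs, seed = seed),
            class = "synthetic_config")
}

# Realize one event spec as tokens + gold layers.  Three templates; the
# first puts the argument sentence-initial and adjacent to the trigger so
# the NULL-vector cases of the lexical features are always exercised.
.realize_event <- function(spec, template_id, role_table) {
  a1 <- strsplit(spec$arg1, " ", fixed = TRUE)[[1]]
  a2 <- strsplit(spec$arg2, " ", fixed = TRUE)[[1]]
  trg <- spec$trigger
  if (template_id == 1L) {
    tokens <- c(a1, trg, a2, ".")
    off <- 0L
  } else if (template_id == 2L) {
    tokens <- c("The", a1, trg, "the", a2, "during", "the", "experiment", ".")
    off <- 1L
  } else {
    tokens <- c("Researchers", "found", "that", a1, trg, a2, ".")
    off <- 3L
  }
  s1 <- off; e1 <- off + length(a1) - 1L
  st <- e1 + 1L; et <- st
  gap <- if (template_id == 2L) 1L else 0L
  s2 <- et + 1L + gap; e2 <- s2 + length(a2) - 1L
  rows <- .roles_for(role_table, spec$meta)
  labels <- rep("O", length(tokens))
  tab <- .trigger_abbr(spec$meta)
  labels[st + 1L] <- paste0("B-", tab)
  labels[(s1:e1) + 1L] <- c(paste0("B-", spec$cat1),
                            rep(paste0("I-", spec$cat1), length(a1) - 1L))
  labels[(s2:e2) + 1L] <- c(paste0("B-", spec$cat2),
                            rep(paste0("I-", spec$cat2), length(a2) - 1L))
  roles <- list(
    list(role_index = rows$role_index[1], e1_start = st, e1_end = et,
         e2_start = s1, e2_end = e1),
    list(role_index = rows$role_index[2], e1_start = st, e1_end = et,
         e2_start = s2, e2_end = e2))
  mention <- event_mention(
    spec$meta,
    trigger = list(start = st, end = et, text = trg),
    arguments = list(
      list(start = s1, end = e1, text = spec$arg1, category = spec$cat1,
           role = rows$role_name[1]),
      list(start = s2, end = e2, text = spec$arg2, category = spec$cat2,
           role = rows$role_name[2])))
  list(tokens = tokens, labels = labels, roles = roles, mention = mention)
}

#' Generate a synthetic gold bundle
#'
#' Per document, draws a topic mixture (one dominant planted topic); per
#' sentence, draws a topic, an event specification from that topic's
#' planted event distribution and a surface template, and emits the
#' tokens together with all gold layers (BIO labels, role annotations,
#' event mentions, document topic mixtures).  Byte-identical across runs
#' with the same config.
#'
#' @param config A `synthetic_config`.
#' @param role_table Event-role table used for gold roles.
#' @return A `gold_bundle`: list with `corpus`, `bio`, `roles`, `events`
#'   (each indexed by document), `doc_topics` (documents x K matrix),
#'   `dominant_topic`, and `config`.
#' @export
generate_corpus <- function(config = synthetic_config(),
                            role_table = default_event_role_table()) {
  stopifnot(inherits(config, "synthetic_config"))
  .with_seed(config$seed, {
    K <- config$K_true
    docs <- vector("list", config$n_docs)
    bio <- vector("list", config$n_docs)
    roles <- vector("list", config$n_docs)
    events <- vector("list", config$n_docs)
    doc_topics <- matrix(0, config$n_docs, K)
    dominant <- integer(config$n_docs)
    for (d in seq_len(config$n_docs)) {
      doc_id <- sprintf("doc%04d", d)
      td <- sample.int(K, 1L)
      pi_d <- rep((1 - config$topic_dominance) / max(K - 1L, 1L), K)
      pi_d[td] <- if (K == 1L) 1 else config$topic_dominance
      dominant[d] <- td
      doc_topics[d, ] <- pi_d
      sents <- list(); sbio <- list(); srole <- list(); sevents <- list()
      for (s in seq_len(config$sentences_per_doc)) {
        if (runif(1) < config$noise_rate) {
          tokens <- .FILLER_SENTENCES[[sample.int(
            length(.FILLER_SENTENCES), 1L)]]
          sents[[s]] <- .make_sentence(tokens, s - 1L)
          sbio[[s]] <- list(tokens = tokens,
                            labels = rep("O", length(tokens)))
          srole[[s]] <- list()
          next
        }
        z <- sample.int(K, 1L, prob = pi_d)
        ei <- sample.int(length(config$event_specs[[z]]), 1L,
                         prob = config$phi_true[[z]])
        tpl <- sample.int(3L, 1L)
        real <- .realize_event(config$event_specs[[z]][[ei]], tpl,
                               role_table)
        real$mention$sentence_id <- s - 1L
        real$mention$document_id <- doc_id
        sents[[s]] <- .make_sentence(real$tokens, s - 1L)
        sbio[[s]] <- list(tokens = real$tokens, labels = real$labels)
        srole[[s]] <- real$roles
        sevents[[length(sevents) + 1L]] <- real$mention
      }
      docs[[d]] <- .make_document(sents, doc_id)
      bio[[d]] <- sbio
      roles[[d]] <- srole
      events[[d]] <- sevents
    }
    ids <- vapply(docs, `[[`, character(1), "id")
    names(bio) <- ids; names(roles) <- ids; names(events) <- ids
    rownames(doc_topics) <- ids
    structure(list(corpus = .make_corpus(docs), bio = bio, roles = roles,
                   events = events, doc_topics = doc_topics,
                   dominant_topic = setNames(dominant, ids),
                   config = config),
              class = "gold_bundle")
  })
}

#' @export
print.gold_bundle <- function(x, ...) {
  cat(sprintf(paste0("<gold_bundle> %d documents, %d planted topic(s), ",
                     "%d gold event(s)\n"),
              length(x$corpus$documents), x$config$K_true,
              sum(lengths(x$events))))
  invisible(x)
}

#' Corrupt BIO labels for robustness testing
#'
#' Flips a random fraction of the non-O BIO labels to O, reproducibly per
#' seed; `swap_rate = 0` is the identity.
#'
#' @param bundle A `gold_bundle`.
#' @param swap_rate Fraction in \[0, 1).
#' @param seed Integer seed.
#' @return The bundle with corrupted `bio` labels.
#' @export
corrupt_labels <- function(bundle, swap_rate, seed = 1L) {
  stopifnot(inherits(bundle, "gold_bundle"), swap_rate >= 0, swap_rate < 1)
  if (swap_rate == 0) return(bundle)
  .with_seed(seed, {
    for (d in seq_along(bundle$bio)) {
      for (s in seq_along(bundle$bio[[d]])) {
        labs <- bundle$bio[[d]][[s]]$labels
        non_o <- which(labs != "O")
        flip <- non_o[runif(length(non_o)) < swap_rate]
        labs[flip] <- "O"
        bundle$bio[[d]][[s]]$labels <- labs
      }
    }
    bundle
  })
}

# Flatten a bundle's BIO layer into the sentence list the tagger trains on.
#' Flatten a gold bundle's BIO layer
#'
#' @param bundle A `gold_bundle`.
#' @return List of `list(tokens, labels)` across all documents.
#' @export
bundle_bio_sentences <- function(bundle) {
  unlist(bundle$bio, recursive = FALSE, use.names = FALSE)
}
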