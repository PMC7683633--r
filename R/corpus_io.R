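# Readers/writers for the pipeline's file formats (plain-text documents,
# CoNLL-style BIO files, five-field role-annotation files, term
# dictionaries, text-format word embeddings) plus dictionary-based distant
# supervision and the train/test split.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---------------------------------------------------------------------------
# Tokenization
# ---------------------------------------------------------------------------

#' Tokenize text
#'
#' Rule-based word tokenizer: splits on whitespace and separates punctuation
#' into standalone tokens, preserving case (the case features of the tagger
#' need it).
#'
#' @param text Character vector; each element is tokenized independently.
#' @return List of character vectors of tokens.
#' @export
tokenize_text <- function(text) {
  padded <- gsub("([[:punct:]])", " \\1 ", text)
  lapply(strsplit(trimws(padded), "[[:space:]]+"), function(x)
    x[nzchar(x)])
}

#' Token table for a sentence
#'
#' Expands surface tokens into the token representation used by the
#' pipeline: surface form, Porter stem and affix (surface minus stem),
#' with 0-based positions.
#'
#' @param tokens Character vector of surface tokens.
#' @return Data frame with columns `surface`, `stem`, `affix`, `index`.
#' @export
token_table <- function(tokens) {
  stems <- porter_stem(tokens)
  lower <- tolower(tokens)
  affix <- substring(lower, nchar(stems) + 1L)
  affix[!startsWith(lower, stems)] <- ""
  data.frame(surface = tokens, stem = stems, affix = affix,
             index = seq_along(tokens) - 1L, stringsAsFactors = FALSE)
}

.make_sentence <- function(tokens, id) list(id = id, tokens = tokens)

.make_document <- function(sentences, id) list(id = id, sentences = sentences)

.make_corpus <- function(documents, split = NA_character_) {
  structure(list(documents = documents, split = split), class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  ns <- sum(vapply(x$documents, function(d) length(d$sentences), integer(1)))
  cat(sprintf("<corpus> %d document(s), %d sentence(s)\n",
              length(x$documents), ns))
  invisible(x)
}

#' Read plain-text documents into a tokenized corpus
#'
#' @param path A file, a directory (one file per document) or a character
#'   vector of files.
#' @param mode `"sentence_per_line"` treats each non-empty line as one
#'   sentence; `"raw"` applies rule-based sentence splitting on
#'   terminal punctuation first.
#' @return A `corpus`: a list of documents, each a list of sentences with
#'   token vectors; document ids are file names.
#' @export
read_documents <- function(path, mode = c("sentence_per_line", "raw")) {
  mode <- match.arg(mode)
  files <- if (length(path) == 1L && dir.exists(path))
    list.files(path, full.names = TRUE) else path
  docs <- lapply(files, function(f) {
    lines <- readLines(f, encoding = "UTF-8", warn = FALSE)
    if (any(validUTF8(lines) == FALSE))
      stop("undecodable bytes in ", f)
    if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
      warning("empty document: ", f)
      return(.make_document(list(), basename(f)))
    }
    sents <- if (mode == "sentence_per_line") {
      lines[nzchar(trimws(lines))]
    } else {
      text <- paste(lines, collapse = " ")
      parts <- strsplit(text, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
      parts[nzchar(trimws(parts))]
    }
    toks <- tokenize_text(sents)
    .make_document(
      lapply(seq_along(toks), function(i)
        .make_sentence(toks[[i]], i - 1L)),
      basename(f))
  })
  .make_corpus(docs)
}

# ---------------------------------------------------------------------------
# BIO files
# ---------------------------------------------------------------------------

.valid_bio_tags <- function() {
  abbrs <- c(.TRIGGER_CATEGORIES$abbreviation,
             .ARGUMENT_CATEGORIES$abbreviation)
  c("O", paste0("B-", abbrs), paste0("I-", abbrs))
}

# Repair invalid transitions: an I-x that begins an entity after O, after a
# different category, or at sentence start becomes B-x.
repair_bio <- function(labels) {
  prev <- "O"
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (startsWith(lab, "I-")) {
      cat_i <- substring(lab, 3L)
      prev_cat <- if (prev == "O") "" else substring(prev, 3L)
      if (prev_cat != cat_i) labels[i] <- paste0("B-", cat_i)
    }
    prev <- labels[i]
  }
  labels
}

#' Read and write CoNLL-style BIO files
#'
#' Two-column files: token, tab, BIO label; sentences separated by blank
#' lines.  Unknown label abbreviations are an error; invalid `I-` starts
#' are repaired to `B-` with a warning, to tolerate hand annotation.
#' `read_bio` and `write_bio` are exact inverses on valid files.
#'
#' @param path File path.
#' @param sentences List of sentences, each a list with character vectors
#'   `tokens` and `labels` of equal length.
#' @return `read_bio` returns such a list; `write_bio` returns `path`
#'   invisibly.
#' @export
read_bio <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  valid <- .valid_bio_tags()
  sentences <- list()
  toks <- character(0); labs <- character(0)
  flush <- function() {
    if (length(toks)) {
      repaired <- repair_bio(labs)
      if (!identical(repaired, labs))
        warning("repaired invalid BIO transition(s) (I- without matching B-)")
      sentences[[length(sentences) + 1L]] <<-
        list(tokens = toks, labels = repaired)
    }
    toks <<- character(0); labs <<- character(0)
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) { flush(); next }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("malformed BIO line (expected token<TAB>label): ", ln)
    if (!parts[2] %in% valid)
      stop("unknown BIO tag '", parts[2], "'; valid tags: ",
           paste(valid, collapse = " "))
    toks <- c(toks, parts[1]); labs <- c(labs, parts[2])
  }
  flush()
  sentences
}

#' @rdname read_bio
#' @export
write_bio <- function(sentences, path) {
  valid <- .valid_bio_tags()
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (s in sentences) {
    stopifnot(length(s$tokens) == length(s$labels))
    if (any(!s$labels %in% valid))
      stop("unknown BIO tag(s): ",
           paste(setdiff(s$labels, valid), collapse = ", "),
           "; valid tags: ", paste(valid, collapse = " "))
    writeLines(paste(s$tokens, s$labels, sep = "\t"), con)
    writeLines("", con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Role-annotation files
# ---------------------------------------------------------------------------

#' Parse one role-annotation line
#'
#' A role annotation is five whitespace-separated integers: role-type
#' index, trigger begin, trigger end, argument begin, argument end
#' (0-based inclusive token positions, stored verbatim).
#'
#' @param line Character scalar.
#' @param line_number Optional line number for error messages.
#' @return List with `role_index`, `e1_start`, `e1_end`, `e2_start`,
#'   `e2_end`.
#' @export
parse_role_line <- function(line, line_number = NA_integer_) {
  parts <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  where <- if (is.na(line_number)) "" else sprintf(" at line %d", line_number)
  if (length(parts) != 5L)
    stop(sprintf("role annotation%s has %d field(s), expected 5: '%s'",
                 where, length(parts), line))
  vals <- suppressWarnings(as.integer(parts))
  if (anyNA(vals))
    stop(sprintf("role annotation%s has non-integer field(s): '%s'",
                 where, line))
  ann <- list(role_index = vals[1], e1_start = vals[2], e1_end = vals[3],
              e2_start = vals[4], e2_end = vals[5])
  if (ann$e1_start > ann$e1_end || ann$e2_start > ann$e2_end)
    stop(sprintf("role annotation%s has inverted span(s): '%s'", where, line))
  ann
}

#' Read and write role-annotation files
#'
#' One five-integer line per annotation; blank lines separate sentences,
#' parallel to the BIO file.  Sentences without annotations are kept as
#' empty groups so positions stay aligned.
#'
#' @param path File path.
#' @param annotations List (one element per sentence) of lists of role
#'   annotations as returned by [parse_role_line()].
#' @export
read_role_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  groups <- list(); current <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) {
      groups[[length(groups) + 1L]] <- current
      current <- list()
    } else {
      current[[length(current) + 1L]] <- parse_role_line(ln, i)
    }
  }
  if (length(current)) groups[[length(groups) + 1L]] <- current
  groups
}

#' @rdname read_role_file
#' @export
write_role_file <- function(annotations, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (group in annotations) {
    for (a in group)
      writeLines(paste(a$role_index, a$e1_start, a$e1_end, a$e2_start,
                       a$e2_end), con)
    writeLines("", con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Term dictionaries and embeddings
# ---------------------------------------------------------------------------

#' Load a term dictionary
#'
#' Plain-text dictionary, one (possibly multi-word) term per line.  Terms
#' are lower-cased and de-duplicated; lookup is case-insensitive.
#'
#' @param path File path.
#' @param category Argument category name or abbreviation the dictionary
#'   annotates.
#' @return A `term_dictionary`: list with `category` (abbreviation) and
#'   `terms` (character set).
#' @export
load_term_dictionary <- function(path, category) {
  category <- .check_argument_category(category)
  terms <- readLines(path, encoding = "UTF-8", warn = FALSE)
  terms <- unique(tolower(trimws(terms)))
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0L)
    warning("empty term dictionary for category ", category, ": ", path)
  message(sprintf("loaded %d term(s) for category %s", length(terms),
                  category))
  term_dictionary(terms, category)
}

#' @rdname load_term_dictionary
#' @param terms Character vector of terms.
#' @export
term_dictionary <- function(terms, category) {
  category <- .check_argument_category(category)
  terms <- unique(tolower(trimws(terms)))
  terms <- terms[nzchar(terms)]
  structure(list(category = category, terms = terms),
            class = "term_dictionary")
}

#' Read and write text-format word embeddings
#'
#' One token per line followed by its space-separated vector values
#' (GloVe text layout).
#'
#' @param path File path.
#' @param embeddings Numeric matrix, one column per token, column names
#'   are tokens.
#' @return `read_embeddings` returns such a matrix.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, " ", fixed = TRUE)
  toks <- vapply(parts, `[[`, character(1), 1L)
  vecs <- lapply(parts, function(p) as.numeric(p[-1]))
  d <- unique(lengths(vecs))
  if (length(d) != 1L)
    stop("embedding file has inconsistent dimensions: ",
         paste(d, collapse = ", "))
  mat <- matrix(unlist(vecs), nrow = d,
                dimnames = list(NULL, toks))
  mat
}

#' @rdname read_embeddings
#' @export
write_embeddings <- function(embeddings, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (j in seq_len(ncol(embeddings)))
    writeLines(paste(colnames(embeddings)[j],
                     paste(sprintf("%.15g", embeddings[, j]),
                           collapse = " ")), con)
  invisible(path)
}

#' Random fallback embeddings
#'
#' Seeded uniform embeddings on \[-0.5, 0.5\] for a vocabulary, used when no
#' pretrained embedding file is supplied.
#'
#' @param vocab Character vector of tokens.
#' @param dim Embedding dimension (default 100).
#' @param seed Integer seed.
#' @export
random_embeddings <- function(vocab, dim = 100L, seed = 1L) {
  .with_seed(seed, {
    matrix(runif(dim * length(vocab), -0.5, 0.5), nrow = dim,
           dimnames = list(NULL, vocab))
  })
}

# ---------------------------------------------------------------------------
# Distant supervision
# ---------------------------------------------------------------------------

.DEFAULT_CATEGORY_PRIORITY <- c("GRO", "COG", "MDI", "TSK", "RLT", "SEN",
                                "SUB", "MEA", "TOL")

# Match dictionary terms in one token vector: left-to-right longest match,
# ties across categories broken by a fixed priority order.
.match_terms <- function(tokens, dict_index, max_len, priority) {
  lower <- tolower(tokens)
  n <- length(lower)
  labels <- rep("O", n)
  match_cat <- rep(NA_character_, n)
  ties <- 0L
  i <- 1L
  while (i <= n) {
    hit_cat <- NULL; hit_len <- 0L
    for (L in seq(min(max_len, n - i + 1L), 1L)) {
      phrase <- paste(lower[i:(i + L - 1L)], collapse = " ")
      cats <- get0(phrase, envir = dict_index, inherits = FALSE)
      if (!is.null(cats)) {
        if (length(cats) > 1L) {
          cats <- cats[order(match(cats, priority))]
          ties <- ties + 1L
        }
        hit_cat <- cats[1]; hit_len <- L
        break
      }
    }
    if (is.null(hit_cat)) { i <- i + 1L; next }
    idx <- i:(i + hit_len - 1L)
    labels[idx] <- c(paste0("B-", hit_cat),
                     rep(paste0("I-", hit_cat), hit_len - 1L))
    match_cat[idx] <- hit_cat
    i <- i + hit_len
  }
  list(labels = labels, match_cat = match_cat, ties = ties)
}

.dict_lookup_index <- function(dictionaries) {
  idx <- new.env(parent = emptyenv())
  max_len <- 1L
  for (d in dictionaries) {
    stopifnot(inherits(d, "term_dictionary"))
    for (term in d$terms) {
      max_len <- max(max_len, length(strsplit(term, " ", fixed = TRUE)[[1]]))
      assign(term, c(get0(term, envir = idx, inherits = FALSE), d$category),
             envir = idx)
    }
  }
  list(index = idx, max_len = max_len)
}

#' Dictionary-based distant supervision
#'
#' Annotates argument spans in a tokenized corpus by left-to-right
#' longest match against the term dictionaries; matched spans get
#' `B-`/`I-` labels with the category abbreviation.  Output spans never
#' overlap.  Equal-length matches in two categories are resolved by a
#' fixed, configurable priority order (a warning reports how many ties
#' were broken).
#'
#' @param corpus A `corpus` (or a list of token vectors).
#' @param dictionaries List of `term_dictionary` objects.
#' @param priority Category priority for tie-breaking.
#' @return For a `corpus`: list (per document) of lists of
#'   `list(tokens, labels)`.  For a list of token vectors: list of
#'   `list(tokens, labels)`.
#' @export
distant_annotate <- function(corpus, dictionaries,
                             priority = .DEFAULT_CATEGORY_PRIORITY) {
  lk <- .dict_lookup_index(dictionaries)
  total_ties <- 0L
  annotate_tokens <- function(tokens) {
    m <- .match_terms(tokens, lk$index, lk$max_len, priority)
    total_ties <<- total_ties + m$ties
    list(tokens = tokens, labels = m$labels)
  }
  out <- if (inherits(corpus, "corpus")) {
    lapply(corpus$documents, function(d)
      lapply(d$sentences, function(s) annotate_tokens(s$tokens)))
  } else {
    lapply(corpus, annotate_tokens)
  }
  if (total_ties > 0L)
    warning(total_ties, " equal-length dictionary overlap(s) resolved by ",
            "category priority")
  out
}

# ---------------------------------------------------------------------------
# Train/test split
# ---------------------------------------------------------------------------

#' Document-level train/test split
#'
#' Splits the corpus into train and test at the document level with
#' `round(ratio * M)` training documents (round half up), reproducibly
#' per seed.
#'
#' @param corpus A `corpus`.
#' @param ratio Training fraction in (0, 1); default 0.9.
#' @param seed Integer seed.
#' @return List with `train` and `test` corpora.
#' @export
split_corpus <- function(corpus, ratio = 0.9, seed = 1L) {
  stopifnot(inherits(corpus, "corpus"), ratio > 0, ratio < 1)
  M <- length(corpus$documents)
  if (M < 2L) stop("need at least 2 documents to split, got ", M)
  n_train <- as.integer(floor(ratio * M + 0.5))
  n_train <- max(1L, min(M - 1L, n_train))
  idx <- .with_seed(seed, sample.int(M))
  train_idx <- sort(idx[seq_len(n_train)])
  test_idx <- sort(idx[-seq_len(n_train)])
  list(train = .make_corpus(corpus$documents[train_idx], "train"),
       test = .make_corpus(corpus$documents[test_idx], "test"))
}
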