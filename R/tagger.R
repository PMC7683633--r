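# BiLSTM-CNN event element recognizer: text vectorization (word embedding,
# one-hot case vector, terminology dictionary scalar, character CNN) and a
# bidirectional LSTM with per-token log-softmax over the BIO tag set.

.CASE_CATEGORIES <- c("numeric", "allLower", "allUpper", "initialUpper",
                      "mainly_numeric", "contains_digit", "other")

#' One-hot case vector of a token
#'
#' Maps a token to exactly one of the case categories, first match in the
#' order: numeric, allLower, allUpper, initialUpper, mainly_numeric,
#' contains_digit, other.
#'
#' @param token Non-empty character scalar.
#' @return Named 0/1 vector over the seven case categories.
#' @export
case_vector <- function(token) {
  stopifnot(is.character(token), length(token) == 1L, nzchar(token))
  n_digit <- nchar(gsub("[^0-9]", "", token))
  cat <- if (grepl("^[0-9]+([.,][0-9]+)*$", token)) "numeric"
    else if (grepl("^[a-z]+$", token)) "allLower"
    else if (grepl("^[A-Z]+$", token)) "allUpper"
    else if (grepl("^[A-Z][a-z]+$", token)) "initialUpper"
    else if (n_digit > nchar(token) / 2) "mainly_numeric"
    else if (n_digit > 0L) "contains_digit"
    else "other"
  out <- setNames(numeric(length(.CASE_CATEGORIES)), .CASE_CATEGORIES)
  out[cat] <- 1
  out
}

#' Terminology dictionary scalar feature
#'
#' For every token of a sentence, the dictionary index (1..9) of the
#' argument category whose term dictionary matches the span containing the
#' token under left-to-right longest match, and 0 for tokens outside any
#' matched term.
#'
#' @param tokens Character vector of sentence tokens.
#' @param dictionaries List of `term_dictionary` objects.
#' @return Integer vector, one value per token.
#' @export
dict_scalar <- function(tokens, dictionaries) {
  if (length(tokens) == 0L) return(integer(0))
  lk <- .dict_lookup_index(dictionaries)
  m <- .match_terms(tokens, lk$index, lk$max_len, .DEFAULT_CATEGORY_PRIORITY)
  idx <- .ARGUMENT_CATEGORIES$dictionary_index[
    match(m$match_cat, .ARGUMENT_CATEGORIES$abbreviation)]
  idx[is.na(idx)] <- 0L
  as.integer(idx)
}

# ---------------------------------------------------------------------------
# Tag inventory: B/I per trigger abbreviation + B/I per argument
# abbreviation + O (37 tags).
# ---------------------------------------------------------------------------

.tag_set <- function() .valid_bio_tags()

# ---------------------------------------------------------------------------
# Character CNN
# ---------------------------------------------------------------------------

.char_ids <- function(token, chars) {
  ids <- match(strsplit(token, "", fixed = TRUE)[[1]], chars)
  ids[is.na(ids)] <- 1L    # reserved unknown row at column 1
  ids
}

# Stacked convolution windows (char_dim*width x L) with zero padding so
# every token, including 1-character ones, yields at least one window.
.char_windows <- function(token, char_emb, width) {
  d <- nrow(char_emb)
  ids <- .char_ids(token, colnames(char_emb))
  pad <- (width - 1L) %/% 2L
  E <- cbind(matrix(0, d, pad), char_emb[, ids, drop = FALSE],
             matrix(0, d, pad))
  L <- length(ids)
  win <- matrix(0, d * width, L)
  for (j in seq_len(L)) win[, j] <- as.numeric(E[, j:(j + width - 1L)])
  win
}

.char_conv <- function(win, Fc, bc) {
  Z <- Fc %*% win + bc
  amax <- max.col(Z, ties.method = "first")
  list(out = Z[cbind(seq_len(nrow(Z)), amax)], amax = amax)
}

#' Character-CNN feature vector of a token
#'
#' Convolution (width 3 by default) over fixed random character embeddings,
#' max-pooled over positions to the configured output size.
#'
#' @param token Character scalar.
#' @param model A `bilstm_tagger`.
#' @return Numeric vector of length `model$hyper$char_out`.
#' @export
char_features <- function(token, model) {
  win <- .char_windows(token, model$char_emb, model$hyper$conv_width)
  .char_conv(win, model$params$Fc, model$params$bc)$out
}

# ---------------------------------------------------------------------------
# Sentence vectorization and encoding
# ---------------------------------------------------------------------------

# Per-sentence fixed features (word ids, case block, dictionary scalar,
# char windows) computed once and cached across epochs.
.prepare_sentence <- function(model, tokens) {
  n <- length(tokens)
  ids <- match(tolower(tokens), model$vocab)
  ids[is.na(ids)] <- length(model$vocab) + 1L   # shared unknown column
  case_mat <- if (n) vapply(tokens, case_vector,
                            numeric(length(.CASE_CATEGORIES)))
              else matrix(0, length(.CASE_CATEGORIES), 0L)
  m <- .match_terms(tokens, model$dict_lookup$index, model$dict_lookup$max_len,
                    .DEFAULT_CATEGORY_PRIORITY)
  dict_idx <- .ARGUMENT_CATEGORIES$dictionary_index[
    match(m$match_cat, .ARGUMENT_CATEGORIES$abbreviation)]
  dict_idx[is.na(dict_idx)] <- 0L
  wins <- lapply(tokens, .char_windows, char_emb = model$char_emb,
                 width = model$hyper$conv_width)
  list(tokens = tokens, n = n, ids = ids,
       case_mat = matrix(case_mat, nrow = length(.CASE_CATEGORIES)),
       dict_row = matrix(as.numeric(dict_idx), nrow = 1L), wins = wins)
}

.build_X <- function(model, prep) {
  n <- prep$n
  co <- model$hyper$char_out
  conv <- lapply(prep$wins, .char_conv, Fc = model$params$Fc,
                 bc = model$params$bc)
  char_mat <- if (n) vapply(conv, `[[`, numeric(co), "out")
              else matrix(0, co, 0L)
  X <- rbind(model$params$E[, prep$ids, drop = FALSE],
             prep$case_mat, prep$dict_row,
             matrix(char_mat, nrow = co))
  list(X = X, conv = conv)
}

#' Combined word vectors of a sentence
#'
#' Concatenates, in this order, the word embedding, the one-hot case
#' vector, the terminology dictionary scalar and the character-CNN vector
#' for every token.  Out-of-vocabulary words use the shared unknown
#' embedding.
#'
#' @param tokens Character vector of tokens.
#' @param model A `bilstm_tagger`.
#' @return Matrix with one column per token; row count equals the declared
#'   total dimension (`sum(unlist(model$dims))`).
#' @export
vectorize_sentence <- function(tokens, model) {
  prep <- .prepare_sentence(model, tokens)
  .build_X(model, prep)$X
}

.tagger_forward <- function(model, prep) {
  bx <- .build_X(model, prep)
  X <- bx$X
  p <- model$params
  if (prep$n == 0L)
    return(list(X = X, conv = bx$conv, logp = matrix(0, length(model$tags), 0L),
                h = matrix(0, 2L * model$hyper$hidden, 0L)))
  fwd <- .lstm_forward(X, p$Wf, p$Uf, p$bf)
  Xr <- X[, rev(seq_len(prep$n)), drop = FALSE]
  bwd <- .lstm_forward(Xr, p$Wb, p$Ub, p$bb)
  Hb <- bwd$H[, rev(seq_len(prep$n)), drop = FALSE]
  Hcat <- rbind(fwd$H, Hb)
  logits <- p$P %*% Hcat + p$bp
  list(X = X, conv = bx$conv, fwd = fwd, bwd = bwd, Hcat = Hcat,
       h = Hcat, logp = .log_softmax(logits))
}

#' Encode a sentence with the bidirectional recurrent layer
#'
#' Returns the concatenated forward/backward hidden states (the forward
#' state reads tokens left to right, the backward state right to left) and
#' the per-token log-probabilities over the BIO tag set.
#'
#' @param tokens Character vector of tokens.
#' @param model A trained `bilstm_tagger`.
#' @return List with `h` (2*hidden x n) and `log_probs` (tags x n, columns
#'   are log-softmax normalized).
#' @export
encode_sentence <- function(tokens, model) {
  out <- .tagger_forward(model, .prepare_sentence(model, tokens))
  lp <- out$logp
  rownames(lp) <- model$tags
  list(h = out$h, log_probs = lp)
}

.tagger_backward <- function(model, prep, cache, gold_ids) {
  p <- model$params
  n <- prep$n
  H <- model$hyper$hidden
  dlogits <- exp(cache$logp)
  dlogits[cbind(gold_ids, seq_len(n))] <-
    dlogits[cbind(gold_ids, seq_len(n))] - 1
  gP <- dlogits %*% t(cache$Hcat)
  gbp <- rowSums(dlogits)
  dHcat <- crossprod(p$P, dlogits)
  dHf <- dHcat[seq_len(H), , drop = FALSE]
  dHb <- dHcat[H + seq_len(H), rev(seq_len(n)), drop = FALSE]
  gf <- .lstm_backward(cache$fwd, dHf, p$Wf, p$Uf)
  gb <- .lstm_backward(cache$bwd, dHb, p$Wb, p$Ub)
  dX <- gf$dX + gb$dX[, rev(seq_len(n)), drop = FALSE]
  dw <- model$dims$word
  co <- model$hyper$char_out
  gE <- p$E * 0
  for (t in seq_len(n)) {
    j <- prep$ids[t]
    gE[, j] <- gE[, j] + dX[seq_len(dw), t]
  }
  char_rows <- (nrow(dX) - co + 1L):nrow(dX)
  gFc <- p$Fc * 0
  gbc <- p$bc * 0
  for (t in seq_len(n)) {
    dch <- dX[char_rows, t]
    amax <- cache$conv[[t]]$amax
    gFc <- gFc + dch * t(prep$wins[[t]][, amax, drop = FALSE])
    gbc <- gbc + dch
  }
  list(Wf = gf$dW, Uf = gf$dU, bf = gf$db,
       Wb = gb$dW, Ub = gb$dU, bb = gb$db,
       P = gP, bp = gbp, E = gE, Fc = gFc, bc = gbc)
}

# ---------------------------------------------------------------------------
# Training
# ---------------------------------------------------------------------------

#' Train the BiLSTM-CNN event element tagger
#'
#' Minimizes the per-token negative log-likelihood of the BIO labels with
#' Adam (learning rate 1e-3, global gradient clipping at 5 by default).
#' Word embeddings (including the shared unknown vector), the character
#' convolution and all recurrent/output parameters are trained; the
#' character embedding table is a fixed random table drawn uniform on
#' \[-0.5, 0.5\].  Training is reproducible: same data and seed give the
#' same parameters.
#'
#' @param sentences List of labeled sentences, each
#'   `list(tokens = <character>, labels = <character>)` with BIO labels
#'   over the schema tag set.
#' @param dictionaries Term dictionaries for the dictionary scalar feature.
#' @param embeddings Optional pretrained embedding matrix (tokens in
#'   columns); words not covered (and the unknown vector) are initialized
#'   randomly.
#' @param hidden Per-direction LSTM hidden size (default 200; the
#'   concatenated state has 400 dimensions).
#' @param epochs Training epochs (default 50).
#' @param word_dim,char_dim,conv_width,char_out Vectorization sizes
#'   (defaults 100, 25, 3, 30).
#' @param lr,clip,batch_size Optimizer settings.
#' @param seed Integer seed controlling initialization and shuffling.
#' @param verbose Log the loss each epoch.
#' @return A `bilstm_tagger` with a `loss_history` attribute (mean
#'   per-token negative log-likelihood per epoch).
#' @export
train_tagger <- function(sentences, dictionaries = list(),
                         embeddings = NULL, hidden = 200L, epochs = 50L,
                         word_dim = 100L, char_dim = 25L, conv_width = 3L,
                         char_out = 30L, lr = 1e-3, clip = 5, batch_size = 8L,
                         seed = 1L, verbose = FALSE) {
  stopifnot(length(sentences) > 0L)
  tags <- .tag_set()
  all_labels <- unlist(lapply(sentences, `[[`, "labels"))
  if (any(!all_labels %in% tags))
    stop("label(s) outside the schema tag set: ",
         paste(unique(setdiff(all_labels, tags)), collapse = ", "))
  if (!is.null(embeddings) && nrow(embeddings) != word_dim)
    stop("pretrained embeddings have dimension ", nrow(embeddings),
         ", expected word_dim = ", word_dim)

  all_tokens <- unlist(lapply(sentences, `[[`, "tokens"))
  vocab <- sort(unique(tolower(all_tokens)))
  chars <- c("<unk>", sort(unique(strsplit(paste(all_tokens, collapse = ""),
                                           "", fixed = TRUE)[[1]])))
  D <- word_dim + length(.CASE_CATEGORIES) + 1L + char_out

  model <- .with_seed(seed, {
    E <- matrix(runif(word_dim * (length(vocab) + 1L), -0.5, 0.5),
                word_dim, dimnames = list(NULL, c(vocab, "<unk>")))
    if (!is.null(embeddings)) {
      hit <- intersect(vocab, tolower(colnames(embeddings)))
      E[, hit] <- embeddings[, match(hit, tolower(colnames(embeddings)))]
    }
    char_emb <- matrix(runif(char_dim * length(chars), -0.5, 0.5),
                       char_dim, dimnames = list(NULL, chars))
    char_emb[, 1L] <- 0   # unknown character row
    params <- list(
      E = E,
      Fc = .uniform_init(char_out, char_dim * conv_width),
      bc = numeric(char_out),
      Wf = .uniform_init(4L * hidden, D), Uf = .uniform_init(4L * hidden, hidden),
      bf = numeric(4L * hidden),
      Wb = .uniform_init(4L * hidden, D), Ub = .uniform_init(4L * hidden, hidden),
      bb = numeric(4L * hidden),
      P = .uniform_init(length(tags), 2L * hidden), bp = numeric(length(tags)))
    # encourage remembering early in training (standard forget-gate bias)
    params$bf[hidden + seq_len(hidden)] <- 1
    params$bb[hidden + seq_len(hidden)] <- 1
    structure(list(
      tags = tags, vocab = vocab, params = params, char_emb = char_emb,
      dictionaries = dictionaries,
      dict_lookup = .dict_lookup_index(dictionaries),
      dims = list(word = word_dim, case = length(.CASE_CATEGORIES),
                  dict = 1L, char = char_out),
      hyper = list(hidden = hidden, epochs = epochs, word_dim = word_dim,
                   char_dim = char_dim, conv_width = conv_width,
                   char_out = char_out, lr = lr, clip = clip,
                   batch_size = batch_size, seed = seed)),
      class = "bilstm_tagger")
  })

  preps <- lapply(sentences, function(s)
    .prepare_sentence(model, s$tokens))
  gold <- lapply(sentences, function(s) match(s$labels, tags))
  keep <- vapply(preps, function(p) p$n > 0L, logical(1))
  preps <- preps[keep]; gold <- gold[keep]

  opt <- .adam_init(model$params)
  loss_history <- numeric(epochs)
  n_tokens <- sum(vapply(preps, `[[`, integer(1), "n"))

  .with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(preps))
      total_loss <- 0
      batch <- .zero_like(model$params)
      in_batch <- 0L
      for (si in ord) {
        prep <- preps[[si]]
        cache <- .tagger_forward(model, prep)
        g <- gold[[si]]
        total_loss <- total_loss -
          sum(cache$logp[cbind(g, seq_len(prep$n))])
        batch <- .add_grads(batch, .tagger_backward(model, prep, cache, g))
        in_batch <- in_batch + 1L
        if (in_batch == model$hyper$batch_size || si == ord[length(ord)]) {
          batch <- .clip_grads(batch, clip)
          step <- .adam_step(model$params, batch, opt, lr = lr)
          model$params <- step$params
          opt <- step$state
          batch <- .zero_like(model$params)
          in_batch <- 0L
        }
      }
      loss_history[ep] <- total_loss / n_tokens
      if (verbose)
        message(sprintf("epoch %d/%d  loss %.4f", ep, epochs,
                        loss_history[ep]))
    }
  })
  model$loss_history <- loss_history
  model
}

#' @export
print.bilstm_tagger <- function(x, ...) {
  cat(sprintf(paste0("BiLSTM-CNN tagger: %d tags, vocab %d, input dim %d, ",
                     "hidden %d per direction\n"),
              length(x$tags), length(x$vocab), sum(unlist(x$dims)),
              x$hyper$hidden))
  if (!is.null(x$loss_history))
    cat(sprintf("trained %d epoch(s), final loss %.4f\n",
                length(x$loss_history), tail(x$loss_history, 1)))
  invisible(x)
}

#' @importFrom utils tail
#' @export
predict.bilstm_tagger <- function(object, tokens, ...) {
  if (length(tokens) == 0L) return(character(0))
  lp <- encode_sentence(tokens, object)$log_probs
  repair_bio(object$tags[apply(lp, 2L, which.max)])
}

# ---------------------------------------------------------------------------
# Span decoding
# ---------------------------------------------------------------------------

#' Decode BIO labels into typed spans
#'
#' Groups maximal `B-x I-x ...` runs into spans with 0-based inclusive
#' token indices.  Decoded spans never overlap and never mix categories.
#'
#' @param labels Character vector of BIO labels.
#' @return Data frame with columns `start`, `end`, `category`.
#' @export
bio_spans <- function(labels) {
  labels <- repair_bio(labels)
  out <- data.frame(start = integer(0), end = integer(0),
                    category = character(0), stringsAsFactors = FALSE)
  i <- 1L
  while (i <= length(labels)) {
    if (startsWith(labels[i], "B-")) {
      cat_i <- substring(labels[i], 3L)
      j <- i
      while (j < length(labels) && labels[j + 1L] == paste0("I-", cat_i))
        j <- j + 1L
      out <- rbind(out, data.frame(start = i - 1L, end = j - 1L,
                                   category = cat_i,
                                   stringsAsFactors = FALSE))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

#' Recognize event elements in a sentence
#'
#' Tags the sentence with the trained model (argmax per token, BIO
#' repaired) and groups the labels into typed trigger and argument spans.
#'
#' @param tokens Character vector of tokens.
#' @param model A trained `bilstm_tagger`.
#' @return List with data frames `triggers` (columns `start`, `end`,
#'   `category` = meta-event name) and `arguments` (columns `start`,
#'   `end`, `category` = argument abbreviation).
#' @export
recognize <- function(tokens, model) {
  spans <- bio_spans(predict(model, tokens))
  is_trig <- spans$category %in% .TRIGGER_CATEGORIES$abbreviation
  trig <- spans[is_trig, , drop = FALSE]
  trig$category <- .TRIGGER_CATEGORIES$name[
    match(trig$category, .TRIGGER_CATEGORIES$abbreviation)]
  list(triggers = trig[, c("start", "end", "category")],
       arguments = spans[!is_trig, c("start", "end", "category"),
                         drop = FALSE])
}

#' Token-level F1 of predicted against gold BIO labels
#'
#' Micro-averaged over tokens: a token counts as a true positive when the
#' predicted and gold labels agree and are not `O`.
#'
#' @param pred,gold Character vectors (or lists of vectors) of BIO labels.
#' @return F1 in \[0, 1\].
#' @export
token_f1 <- function(pred, gold) {
  pred <- unlist(pred); gold <- unlist(gold)
  stopifnot(length(pred) == length(gold))
  tp <- sum(pred == gold & gold != "O")
  fp <- sum(pred != "O" & pred != gold)
  fn <- sum(gold != "O" & pred != gold)
  if (tp == 0L) return(0)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

#' Save or load a tagger checkpoint
#'
#' Single-file checkpoint holding parameters, configuration and the tag
#' inventory; reloads bit-identically.
#'
#' @param model A `bilstm_tagger`.
#' @param path File path.
#' @export
save_tagger <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_tagger
#' @export
load_tagger <- function(path) readRDS(path)
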