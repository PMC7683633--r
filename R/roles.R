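# Argument-role classification: lexical-level features (trigger/argument
# word vectors, their sentence neighbors, the candidate role index),
# sentence-level convolutional features over word + position-distance
# representations, and a softmax over the role inventory plus a "none"
# class.  Assembles validated event mentions from recognizer output.

.span_overlap <- function(a, b) !(a[2] < b[1] || b[2] < a[1])

#' Token-offset position distances
#'
#' Signed token offset from the first token of the target span to the
#' first token of the trigger span (`d_pft`) and of the argument span
#' (`d_pfa`).  Overlapping spans have distance 0.
#'
#' @param target,trigger,argument Integer spans `c(start, end)`, 0-based
#'   inclusive.
#' @return Named numeric vector `c(d_pft, d_pfa)`.
#' @export
position_distances <- function(target, trigger, argument) {
  d1 <- if (.span_overlap(target, trigger)) 0L else target[1] - trigger[1]
  d2 <- if (.span_overlap(target, argument)) 0L else target[1] - argument[1]
  c(d_pft = as.integer(d1), d_pfa = as.integer(d2))
}

.emb_token <- function(emb, token) {
  j <- match(tolower(token), tolower(colnames(emb)))
  if (is.na(j)) numeric(nrow(emb)) else emb[, j]
}

.emb_span <- function(emb, tokens, span) {
  idx <- (span[1]:span[2]) + 1L
  vs <- vapply(tokens[idx], .emb_token, numeric(nrow(emb)), emb = emb)
  rowMeans(matrix(vs, nrow = nrow(emb)))
}

# Word vector of the token at 0-based position i; the NULL (all-zero)
# vector when the position falls outside the sentence or inside the other
# event element's span.
.neighbor_vec <- function(emb, tokens, i, other_span) {
  n <- length(tokens)
  if (i < 0L || i >= n) return(numeric(nrow(emb)))
  if (i >= other_span[1] && i <= other_span[2]) return(numeric(nrow(emb)))
  .emb_token(emb, tokens[i + 1L])
}

#' Lexical-level role features
#'
#' The concatenation of the trigger word vector, the argument word vector,
#' the words before/after the trigger, the words before/after the
#' argument, and the candidate role index.  A neighbor slot is the NULL
#' (all-zero) vector when the position is outside the sentence or inside
#' the other span (trigger and argument adjacent).  Multi-token spans use
#' the mean of their token vectors.
#'
#' @param tokens Character vector of sentence tokens.
#' @param trigger,argument Integer spans `c(start, end)`, 0-based inclusive.
#' @param role_index Candidate role index from the event-role table.
#' @param embeddings Word embedding matrix (tokens in columns).
#' @return List with the six word-vector components (`E1t`, `E2t`, `E1tf`,
#'   `E1tb`, `E2tf`, `E2tb`), `r`, and their concatenation `vlf` of length
#'   `6 * nrow(embeddings) + 1`.
#' @export
lexical_features <- function(tokens, trigger, argument, role_index,
                             embeddings) {
  comp <- list(
    E1t = .emb_span(embeddings, tokens, trigger),
    E2t = .emb_span(embeddings, tokens, argument),
    E1tf = .neighbor_vec(embeddings, tokens, trigger[1] - 1L, argument),
    E1tb = .neighbor_vec(embeddings, tokens, trigger[2] + 1L, argument),
    E2tf = .neighbor_vec(embeddings, tokens, argument[1] - 1L, trigger),
    E2tb = .neighbor_vec(embeddings, tokens, argument[2] + 1L, trigger))
  comp$r <- as.numeric(role_index)
  comp$vlf <- c(comp$E1t, comp$E2t, comp$E1tf, comp$E1tb, comp$E2tf,
                comp$E2tb, comp$r)
  comp
}

# ---------------------------------------------------------------------------
# Role classifier model
# ---------------------------------------------------------------------------

.pos_col <- function(offset, clip) pmin(pmax(offset, -clip), clip) + clip + 1L

#' Construct an untrained role classifier
#'
#' @param role_table An `event_role_table`; its role indices plus a
#'   trailing "none" class form the softmax inventory.
#' @param embeddings Word embedding matrix (frozen during training).
#' @param n_filters Convolution filters (default 30, the CNN output size).
#' @param conv_width Convolution width over token positions (default 3).
#' @param sf_dim Dimension of the sentence-level feature vector (default 30).
#' @param pos_dim,pos_clip Position-embedding dimension (5) and offset
#'   clipping range (30).
#' @param seed Integer seed for initialization.
#' @export
role_classifier <- function(role_table = default_event_role_table(),
                            embeddings, n_filters = 30L, conv_width = 3L,
                            sf_dim = 30L, pos_dim = 5L, pos_clip = 30L,
                            seed = 1L) {
  d_w <- nrow(embeddings)
  d_wp <- d_w + 2L * pos_dim
  classes <- c(as.character(role_table$role_index[
    order(role_table$role_index)]), "none")
  max_role <- max(role_table$role_index)
  # the scalar role index of the lexical features is one-hot expanded at
  # the classifier input so the softmax can express the role-match pattern
  vin <- 6L * d_w + max_role + sf_dim
  params <- .with_seed(seed, list(
    Dpft = matrix(runif(pos_dim * (2L * pos_clip + 1L), -0.1, 0.1), pos_dim),
    Dpfa = matrix(runif(pos_dim * (2L * pos_clip + 1L), -0.1, 0.1), pos_dim),
    M1 = .uniform_init(n_filters, d_wp * conv_width), b1 = numeric(n_filters),
    W2 = .uniform_init(sf_dim, n_filters), b2 = numeric(sf_dim),
    Wout = .uniform_init(length(classes), vin), bout = numeric(length(classes))))
  structure(list(role_table = role_table, classes = classes,
                 max_role = max_role,
                 embeddings = embeddings, params = params,
                 hyper = list(d_w = d_w, n_filters = n_filters,
                              conv_width = conv_width, sf_dim = sf_dim,
                              pos_dim = pos_dim, pos_clip = pos_clip,
                              seed = seed)),
            class = "role_classifier")
}

# Word + position representations of every token, v_wp = [v_wf, d_pft, d_pfa]
.vwp_matrix <- function(model, tokens, trigger, argument) {
  n <- length(tokens)
  p <- model$params; hy <- model$hyper
  Xw <- vapply(tokens, .emb_token, numeric(hy$d_w), emb = model$embeddings)
  off_t <- .pos_col(seq_len(n) - 1L - trigger[1], hy$pos_clip)
  off_a <- .pos_col(seq_len(n) - 1L - argument[1], hy$pos_clip)
  list(V = rbind(matrix(Xw, nrow = hy$d_w),
                 p$Dpft[, off_t, drop = FALSE],
                 p$Dpfa[, off_a, drop = FALSE]),
       off_t = off_t, off_a = off_a)
}

.sf_forward <- function(model, tokens, trigger, argument) {
  hy <- model$hyper; p <- model$params
  vwp <- .vwp_matrix(model, tokens, trigger, argument)
  V <- vwp$V
  d_wp <- nrow(V); n <- ncol(V)
  pad <- (hy$conv_width - 1L) %/% 2L
  Vp <- cbind(matrix(0, d_wp, pad), V, matrix(0, d_wp, pad))
  wins <- matrix(0, d_wp * hy$conv_width, n)
  for (j in seq_len(n))
    wins[, j] <- as.numeric(Vp[, j:(j + hy$conv_width - 1L)])
  Z <- p$M1 %*% wins + p$b1
  amax <- max.col(Z, ties.method = "first")
  nvec <- Z[cbind(seq_len(nrow(Z)), amax)]
  vsf <- tanh(p$W2 %*% nvec + p$b2)
  list(vsf = as.numeric(vsf), nvec = nvec, amax = amax, wins = wins,
       vwp = vwp, n = n, pad = pad)
}

#' Sentence-level convolutional role features
#'
#' Convolution over word + position-distance representations, max-pooling
#' over positions, then a tanh hidden transform; every coordinate of the
#' output lies in (-1, 1).
#'
#' @inheritParams lexical_features
#' @param model A `role_classifier`.
#' @return Numeric vector of length `model$hyper$sf_dim`.
#' @export
sentence_features <- function(tokens, trigger, argument, model) {
  .sf_forward(model, tokens, trigger, argument)$vsf
}

#' Role probabilities from feature vectors
#'
#' Softmax over the role inventory (role indices of the event-role table
#' plus "none") given the concatenated lexical- and sentence-level feature
#' vectors.
#'
#' @param model A `role_classifier`.
#' @param vlf,vsf Feature vectors from [lexical_features()] and
#'   [sentence_features()].
#' @return Named probability vector summing to 1.
#' @export
role_probabilities <- function(model, vlf, vsf) {
  setNames(.softmax_vec(as.numeric(
    model$params$Wout %*% .classifier_input(model, vlf, vsf) +
      model$params$bout)), model$classes)
}

# [word-vector slots, one-hot(r), sentence features]; the trailing scalar
# r of the lexical vector is expanded to a one-hot over role indices.
.classifier_input <- function(model, vlf, vsf) {
  r <- vlf[length(vlf)]
  onehot <- numeric(model$max_role)
  if (r >= 1 && r <= model$max_role) onehot[r] <- 1
  c(vlf[-length(vlf)], onehot, vsf)
}

#' Classify the role of a candidate trigger-argument pair
#'
#' Computes the lexical and sentence features for the pair under candidate
#' role `role_index` and returns the softmax distribution over the role
#' inventory plus "none".
#'
#' @inheritParams sentence_features
#' @param role_index Candidate role index fed into the lexical features.
#' @export
classify_role <- function(tokens, trigger, argument, role_index, model) {
  lf <- lexical_features(tokens, trigger, argument, role_index,
                         model$embeddings)
  sf <- sentence_features(tokens, trigger, argument, model)
  role_probabilities(model, lf$vlf, sf)
}

.role_forward <- function(model, ex) {
  lf <- lexical_features(ex$tokens, ex$trigger, ex$argument, ex$r,
                         model$embeddings)
  sf <- .sf_forward(model, ex$tokens, ex$trigger, ex$argument)
  v <- .classifier_input(model, lf$vlf, sf$vsf)
  probs <- .softmax_vec(as.numeric(model$params$Wout %*% v +
                                     model$params$bout))
  list(lf = lf, sf = sf, v = v, probs = probs)
}

.role_backward <- function(model, ex, cache, gold_class) {
  p <- model$params; hy <- model$hyper
  dscores <- cache$probs
  dscores[gold_class] <- dscores[gold_class] - 1
  gWout <- dscores %*% t(cache$v)
  dv <- as.numeric(crossprod(p$Wout, dscores))
  nv <- length(cache$v)
  dvsf <- dv[(nv - hy$sf_dim + 1L):nv]
  da <- dvsf * (1 - cache$sf$vsf^2)
  gW2 <- da %*% t(cache$sf$nvec)
  dn <- as.numeric(crossprod(p$W2, da))
  gM1 <- dn * t(cache$sf$wins[, cache$sf$amax, drop = FALSE])
  # route max-pooled gradients back to the position embeddings
  d_wp <- hy$d_w + 2L * hy$pos_dim
  n <- cache$sf$n; pad <- cache$sf$pad
  dV <- matrix(0, d_wp, n)
  for (k in seq_along(dn)) {
    j <- cache$sf$amax[k]
    dwin <- matrix(p$M1[k, ] * dn[k], d_wp, hy$conv_width)
    for (w in seq_len(hy$conv_width)) {
      col <- j + w - 1L - pad
      if (col >= 1L && col <= n) dV[, col] <- dV[, col] + dwin[, w]
    }
  }
  gDpft <- p$Dpft * 0; gDpfa <- p$Dpfa * 0
  rows_t <- hy$d_w + seq_len(hy$pos_dim)
  rows_a <- hy$d_w + hy$pos_dim + seq_len(hy$pos_dim)
  off_t <- cache$sf$vwp$off_t; off_a <- cache$sf$vwp$off_a
  for (i in seq_len(n)) {
    gDpft[, off_t[i]] <- gDpft[, off_t[i]] + dV[rows_t, i]
    gDpfa[, off_a[i]] <- gDpfa[, off_a[i]] + dV[rows_a, i]
  }
  list(Dpft = gDpft, Dpfa = gDpfa, M1 = gM1, b1 = dn, W2 = gW2, b2 = da,
       Wout = gWout, bout = dscores)
}

#' Train the role classifier
#'
#' Cross-entropy over gold role annotations with Adam; word embeddings are
#' frozen, position embeddings, convolution, hidden transform and softmax
#' projection are trained.
#'
#' @param examples List of training examples, each
#'   `list(tokens, trigger, argument, r, label)` where `r` is the
#'   candidate role index fed to the features and `label` is the gold
#'   class (a role index as character, or `"none"`).
#' @param model A `role_classifier` (untrained), or arguments to build one.
#' @param epochs,lr,clip,batch_size Optimizer settings.
#' @param seed Seed controlling shuffling.
#' @param verbose Log loss per epoch.
#' @return The trained `role_classifier` with a `loss_history` field.
#' @export
train_role_classifier <- function(examples, model, epochs = 50L, lr = 1e-3,
                                  clip = 5, batch_size = 8L, seed = 1L,
                                  verbose = FALSE) {
  stopifnot(inherits(model, "role_classifier"), length(examples) > 0L)
  gold <- match(vapply(examples, function(e) as.character(e$label),
                       character(1)), model$classes)
  if (anyNA(gold))
    stop("example label(s) outside the role inventory")
  opt <- .adam_init(model$params)
  loss_history <- numeric(epochs)
  .with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(examples))
      total <- 0
      batch <- .zero_like(model$params); in_batch <- 0L
      for (i in ord) {
        cache <- .role_forward(model, examples[[i]])
        total <- total - log(max(cache$probs[gold[i]], 1e-300))
        batch <- .add_grads(batch,
                            .role_backward(model, examples[[i]], cache,
                                           gold[i]))
        in_batch <- in_batch + 1L
        if (in_batch == batch_size || i == ord[length(ord)]) {
          batch <- .clip_grads(batch, clip)
          step <- .adam_step(model$params, batch, opt, lr = lr)
          model$params <- step$params; opt <- step$state
          batch <- .zero_like(model$params); in_batch <- 0L
        }
      }
      loss_history[ep] <- total / length(examples)
      if (verbose)
        message(sprintf("epoch %d/%d  loss %.4f", ep, epochs,
                        loss_history[ep]))
    }
  })
  model$loss_history <- loss_history
  model
}

#' @export
print.role_classifier <- function(x, ...) {
  cat(sprintf("role classifier: %d classes (incl. none), %d filters\n",
              length(x$classes), x$hyper$n_filters))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Event assembly
# ---------------------------------------------------------------------------

# Score a candidate pair under every role the table admits for the
# trigger's meta-event and the argument's category; the classifier is run
# once per candidate role and the per-role scores are renormalized
# together with the averaged "none" score.
.score_pair <- function(model, tokens, trigger, argument, arg_cat,
                        meta_event) {
  rows <- .roles_for(model$role_table, meta_event)
  rows <- rows[vapply(seq_len(nrow(rows)), function(i)
    .role_allows(rows[i, ], arg_cat), logical(1)), , drop = FALSE]
  if (nrow(rows) == 0L) return(NULL)
  s <- numeric(nrow(rows)); s_none <- numeric(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    pr <- classify_role(tokens, trigger, argument, rows$role_index[i], model)
    s[i] <- pr[[as.character(rows$role_index[i])]]
    s_none[i] <- pr[["none"]]
  }
  probs <- c(s, mean(s_none))
  probs <- probs / sum(probs)
  list(rows = rows, probs = probs[seq_len(nrow(rows))],
       p_none = probs[length(probs)])
}

#' Assemble event mentions from recognition and role predictions
#'
#' For each recognized trigger, attaches the argument spans whose best
#' predicted role is not "none" and whose category the event-role table
#' admits; the meta-event type is the trigger category.  Role
#' cardinalities are enforced (for `0..1` roles only the highest-scoring
#' argument survives); dropped combinations are reported via `message`.
#' Every returned mention passes [validate_event()].
#'
#' @param recognition Output of [recognize()] for one sentence.
#' @param tokens Character vector of the sentence tokens.
#' @param model A trained `role_classifier`.
#' @param sentence_id,document_id Provenance identifiers.
#' @return List of `event_mention` objects.
#' @export
assemble_events <- function(recognition, tokens, model,
                            sentence_id = NA_integer_,
                            document_id = NA_character_) {
  table <- model$role_table
  events <- list()
  trig <- recognition$triggers
  args <- recognition$arguments
  for (ti in seq_len(nrow(trig))) {
    meta <- trig$category[ti]
    tspan <- c(trig$start[ti], trig$end[ti])
    chosen <- list()
    for (ai in seq_len(nrow(args))) {
      aspan <- c(args$start[ai], args$end[ai])
      acat <- args$category[ai]
      sc <- .score_pair(model, tokens, tspan, aspan, acat, meta)
      if (is.null(sc)) {
        message(sprintf(
          "dropped argument [%s] for %s: category not admitted by any role",
          acat, meta))
        next
      }
      best <- which.max(c(sc$probs, sc$p_none))
      if (best > length(sc$probs)) next   # "none" wins: not an argument
      chosen[[length(chosen) + 1L]] <- list(
        span = aspan, category = acat,
        role = sc$rows$role_name[best],
        role_index = sc$rows$role_index[best],
        prob = sc$probs[best])
    }
    # cardinality: keep the best-scoring argument per 0..1 role
    if (length(chosen) > 1L) {
      by_role <- split(seq_along(chosen),
                       vapply(chosen, `[[`, character(1), "role"))
      keep <- unlist(lapply(by_role, function(idx) {
        row <- table[table$meta_event == meta &
                       table$role_name == chosen[[idx[1]]]$role, ,
                     drop = FALSE]
        card <- row$cardinality[1]
        if (card %in% c("0..1", "1") && length(idx) > 1L) {
          ps <- vapply(chosen[idx], `[[`, numeric(1), "prob")
          message(sprintf("cardinality: kept 1 of %d arguments for role '%s'",
                          length(idx), chosen[[idx[1]]]$role))
          idx[which.max(ps)]
        } else idx
      }))
      chosen <- chosen[sort(keep)]
    }
    arguments <- lapply(chosen, function(ch) list(
      start = ch$span[1], end = ch$span[2],
      text = paste(tokens[(ch$span[1]:ch$span[2]) + 1L], collapse = " "),
      category = ch$category, role = ch$role, prob = ch$prob))
    ev <- event_mention(
      meta_event = meta,
      trigger = list(start = tspan[1], end = tspan[2],
                     text = paste(tokens[(tspan[1]:tspan[2]) + 1L],
                                  collapse = " ")),
      arguments = arguments, sentence_id = sentence_id,
      document_id = document_id)
    if (length(validate_event(ev, table)) == 0L)
      events[[length(events) + 1L]] <- ev
    else
      message("dropped invalid assembled event for trigger '",
              ev$trigger$text, "'")
  }
  events
}
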