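# Event-biterm topic model: canonical event keys, biterm construction,
# collapsed Gibbs fitting, biterm probabilities, corpus likelihood,
# document-topic inference and topic reporting.

#' Canonical event key
#'
#' Discretizes an event mention into a vocabulary unit for the topic
#' model: meta-event type, stemmed trigger, and the sorted stemmed
#' argument texts, joined with reserved separators
#' (`"Type|trigger|arg+arg"`).  Mentions differing only in position share
#' one key.
#'
#' @param event An `event_mention`.
#' @param granularity `"full"` (type + trigger + arguments, default),
#'   `"type_trigger"`, or `"type"`.
#' @return Character scalar.
#' @export
canonicalize_event <- function(event,
                               granularity = c("full", "type_trigger",
                                               "type")) {
  granularity <- match.arg(granularity)
  stopifnot(inherits(event, "event_mention"))
  stem_phrase <- function(text) {
    toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
    paste(porter_stem(toks), collapse = "_")
  }
  key <- event$meta_event
  if (granularity %in% c("type_trigger", "full"))
    key <- paste(key, stem_phrase(event$trigger$text), sep = "|")
  if (granularity == "full") {
    args <- vapply(event$arguments, function(a) stem_phrase(a$text),
                   character(1))
    key <- paste(key, paste(sort(args), collapse = "+"), sep = "|")
  }
  key
}

#' Build the event-biterm set
#'
#' All unordered pairs of canonical event tokens within each context
#' window (default: the whole document).  Documents with fewer than two
#' events contribute no biterms (with a warning); an empty corpus-wide
#' biterm set is an error since the model is undefined.
#'
#' @param events_by_doc Named list: one element per document, each a list
#'   of `event_mention` objects (or a character vector of precomputed
#'   event keys).
#' @param window Number of consecutive events forming a context
#'   (default `Inf` = whole document).
#' @param granularity Passed to [canonicalize_event()].
#' @return A `biterm_set`: list with `wi`, `wj` (1-based vocabulary ids,
#'   `wi <= wj`), `doc` (document of each biterm), `vocab` (event keys)
#'   and `doc_ids`.
#' @export
build_biterms <- function(events_by_doc, window = Inf,
                          granularity = "full") {
  if (is.null(names(events_by_doc)))
    names(events_by_doc) <- as.character(seq_along(events_by_doc))
  keys_by_doc <- lapply(events_by_doc, function(evs) {
    if (is.character(evs)) evs
    else vapply(evs, canonicalize_event, character(1),
                granularity = granularity)
  })
  vocab <- sort(unique(unlist(keys_by_doc)))
  wi <- integer(0); wj <- integer(0); doc <- character(0)
  n_small <- 0L
  for (d in names(keys_by_doc)) {
    ids <- match(keys_by_doc[[d]], vocab)
    n <- length(ids)
    if (n < 2L) { n_small <- n_small + 1L; next }
    for (a in seq_len(n - 1L)) {
      bmax <- min(n, if (is.finite(window)) a + window - 1L else n)
      for (b in seq(a + 1L, bmax)) {
        pair <- sort(c(ids[a], ids[b]))
        wi <- c(wi, pair[1]); wj <- c(wj, pair[2]); doc <- c(doc, d)
      }
    }
  }
  if (n_small > 0L)
    warning(n_small, " document(s) with fewer than 2 events contribute ",
            "no biterms")
  if (length(wi) == 0L)
    stop("no biterms could be built: the topic model is undefined")
  structure(list(wi = wi, wj = wj, doc = doc, vocab = vocab,
                 doc_ids = names(keys_by_doc)),
            class = "biterm_set")
}

#' @export
print.biterm_set <- function(x, ...) {
  cat(sprintf("<biterm_set> %d biterm(s), vocabulary %d, %d document(s)\n",
              length(x$wi), length(x$vocab), length(unique(x$doc))))
  invisible(x)
}

#' Fit the event biterm topic model by collapsed Gibbs sampling
#'
#' Biterms are pooled corpus-wide; each sweep resamples every biterm's
#' topic assignment from its collapsed conditional.  After burn-in, count
#' sums give the topic distribution
#' `theta_k = (n_k + alpha) / (|B| + K alpha)` and the per-topic event
#' distributions
#' `phi_{e|k} = (n_{e|k} + beta) / (sum_e n_{e|k} + W beta)`.
#'
#' @param biterms A `biterm_set` (or a list of per-document event-mention
#'   lists, passed through [build_biterms()]).
#' @param K Number of topics (default 2).
#' @param alpha,beta Dirichlet hyperparameters (defaults `50/K` and 0.01).
#' @param iterations,burn_in Gibbs sweeps (defaults 1000 / 500).
#' @param seed Integer seed; same seed gives identical fits.
#' @return An `event_btm` object with elements `theta` (K-simplex),
#'   `phi` (K x W matrix, rows on the simplex), `vocab`, `z`
#'   (final assignments), `z_marginal` (post-burn-in per-biterm topic
#'   frequencies), `biterms`, and the hyperparameters.
#' @export
event_btm <- function(biterms, K = 2L, alpha = 50 / K, beta = 0.01,
                      iterations = 1000L, burn_in = 500L, seed = 1L) {
  if (!inherits(biterms, "biterm_set"))
    biterms <- build_biterms(biterms)
  stopifnot(K >= 1L, alpha > 0, beta > 0)
  if (iterations <= burn_in)
    stop("iterations must exceed burn_in")
  B <- length(biterms$wi)
  W <- length(biterms$vocab)
  if (K > B)
    warning("more topics (", K, ") than biterms (", B, "): degenerate fit")
  res <- .with_seed(seed,
    gibbs_btm_cpp(biterms$wi - 1L, biterms$wj - 1L, as.integer(K),
                  alpha, beta, as.integer(W), as.integer(iterations),
                  as.integer(burn_in)))
  nk <- res$nk_sum / res$n_samples
  nek <- res$nek_sum / res$n_samples
  theta <- (nk + alpha) / (B + K * alpha)
  phi <- t((nek + beta) / rep(2 * nk + W * beta, each = W))
  dimnames(phi) <- list(paste0("topic", seq_len(K)), biterms$vocab)
  structure(list(theta = theta, phi = phi, vocab = biterms$vocab,
                 z = res$z + 1L, z_marginal = res$zfreq / res$n_samples,
                 biterms = biterms, K = K, alpha = alpha, beta = beta,
                 iterations = iterations, burn_in = burn_in, seed = seed),
            class = "event_btm")
}

#' @export
print.event_btm <- function(x, ...) {
  cat(sprintf(paste0("Event biterm topic model: K = %d, |B| = %d, ",
                     "vocabulary %d\n"),
              x$K, length(x$biterms$wi), length(x$vocab)))
  cat("theta:", paste(sprintf("%.3f", x$theta), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.event_btm <- function(object, n = 2L, ...) {
  cat(sprintf("Event biterm topic model (K = %d, alpha = %.3g, beta = %.3g)\n",
              object$K, object$alpha, object$beta))
  cat(sprintf("%d biterm(s) over %d event token(s); logLik %.3f\n\n",
              length(object$biterms$wi), length(object$vocab),
              as.numeric(logLik(object))))
  for (k in seq_len(object$K)) {
    te <- top_events(object, k, n)
    cat(sprintf("topic %d (theta = %.3f):\n", k, object$theta[k]))
    for (i in seq_len(nrow(te)))
      cat(sprintf("  %.4f  %s\n", te$prob[i], te$event[i]))
  }
  invisible(object)
}

#' Joint probability of an event biterm
#'
#' `P(b) = sum_z theta_z phi_{i|z} phi_{j|z}`; summing over all ordered
#' event pairs gives 1.
#'
#' @param model A fitted `event_btm`.
#' @param e_i,e_j Event keys (or 1-based vocabulary ids).
#' @export
biterm_probability <- function(model, e_i, e_j) {
  to_id <- function(e) {
    if (is.character(e)) {
      id <- match(e, model$vocab)
      if (is.na(id)) stop("unknown event token: ", e)
      id
    } else as.integer(e)
  }
  i <- to_id(e_i); j <- to_id(e_j)
  if (i < 1L || i > length(model$vocab) || j < 1L || j > length(model$vocab))
    stop("event id out of range")
  sum(model$theta * model$phi[, i] * model$phi[, j])
}

#' @export
logLik.event_btm <- function(object, ...) {
  ll <- sum(log(vapply(seq_along(object$biterms$wi), function(b)
    biterm_probability(object, object$biterms$wi[b], object$biterms$wj[b]),
    numeric(1))))
  structure(ll, df = object$K * (length(object$vocab) - 1L) + object$K - 1L,
            class = "logLik")
}

#' Corpus log-likelihood of a biterm set
#'
#' Sum over biterms of the log joint biterm probability (a duplicated
#' biterm contributes twice).
#'
#' @param model A fitted `event_btm`.
#' @param biterms A `biterm_set`; defaults to the fitted set.
#' @export
corpus_log_likelihood <- function(model, biterms = model$biterms) {
  sum(log(vapply(seq_along(biterms$wi), function(b)
    biterm_probability(model, biterms$wi[b], biterms$wj[b]), numeric(1))))
}

#' Infer the topic distribution of a document
#'
#' `P(z|d) = sum_b p(z|b) p(b|d)` with `p(z|b)` proportional to
#' `theta_z phi_{i|z} phi_{j|z}` and `p(b|d)` the empirical relative
#' frequency of the biterm among the document's biterms.
#'
#' @param model A fitted `event_btm`.
#' @param doc_biterms Either a 2-column matrix / data frame of vocabulary
#'   ids (one row per biterm), a list with `wi` and `wj`, or a document id
#'   present in the fitted biterm set.
#' @return Numeric K-vector summing to 1.
#' @export
infer_document_topics <- function(model, doc_biterms) {
  if (is.character(doc_biterms) && length(doc_biterms) == 1L) {
    sel <- model$biterms$doc == doc_biterms
    if (!any(sel)) stop("document has no biterms: ", doc_biterms)
    wi <- model$biterms$wi[sel]; wj <- model$biterms$wj[sel]
  } else if (is.list(doc_biterms) && !is.null(doc_biterms$wi)) {
    wi <- doc_biterms$wi; wj <- doc_biterms$wj
  } else {
    m <- as.matrix(doc_biterms)
    wi <- m[, 1]; wj <- m[, 2]
  }
  if (length(wi) == 0L)
    stop("document has no biterms: topic distribution undefined")
  pz <- numeric(model$K)
  for (b in seq_along(wi)) {
    w <- model$theta * model$phi[, wi[b]] * model$phi[, wj[b]]
    pz <- pz + w / sum(w)
  }
  pz / length(wi)
}

#' @export
predict.event_btm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    docs <- unique(object$biterms$doc)
  } else docs <- newdata
  out <- t(vapply(docs, function(d) infer_document_topics(object, d),
                  numeric(object$K)))
  colnames(out) <- paste0("topic", seq_len(object$K))
  out
}

#' Top events of a topic
#'
#' The `n` highest-probability event tokens of topic `k`, ties broken
#' lexicographically, with each key expanded into its constituent terms
#' for reporting.
#'
#' @param model A fitted `event_btm`.
#' @param k Topic index.
#' @param n Number of events (default 2, the configured topic words per
#'   topic).
#' @return Data frame with columns `event`, `prob`, `terms`.
#' @export
top_events <- function(model, k, n = 2L) {
  stopifnot(k >= 1L, k <= model$K)
  W <- length(model$vocab)
  if (n > W) {
    warning("requested ", n, " events but vocabulary has ", W)
    n <- W
  }
  p <- model$phi[k, ]
  ord <- order(-p, model$vocab)[seq_len(n)]
  data.frame(event = model$vocab[ord], prob = unname(p[ord]),
             terms = vapply(model$vocab[ord], function(key)
               paste(event_key_terms(key), collapse = ", "), character(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Constituent terms of a canonical event key
#'
#' Splits `"Type|trigger|arg+arg"` into its trigger and argument terms
#' (underscores back to spaces); used when expanding event topics into
#' topic words.
#'
#' @param key Character scalar event key.
#' @export
event_key_terms <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)[[1]]
  if (length(parts) == 1L) return(gsub("_", " ", parts, fixed = TRUE))
  terms <- parts[2]
  if (length(parts) >= 3L && nzchar(parts[3]))
    terms <- c(terms, strsplit(parts[3], "+", fixed = TRUE)[[1]])
  gsub("_", " ", terms, fixed = TRUE)
}

# ---------------------------------------------------------------------------
# Model dump (structured text)
# ---------------------------------------------------------------------------

#' Write or read an Event-BTM model dump
#'
#' Structured YAML text with K, the hyperparameters, the vocabulary,
#' theta and the phi rows; `read_btm(write_btm(m))` restores the
#' distributions exactly up to printed precision.
#'
#' @param model An `event_btm`.
#' @param path File path.
#' @export
write_btm <- function(model, path) {
  yaml::write_yaml(list(
    K = model$K, alpha = model$alpha, beta = model$beta,
    iterations = model$iterations, burn_in = model$burn_in,
    seed = model$seed, vocab = as.list(model$vocab),
    theta = as.list(model$theta),
    phi = lapply(seq_len(model$K), function(k) as.list(unname(model$phi[k, ])))),
    path, precision = 12L)
  invisible(path)
}

#' @rdname write_btm
#' @export
read_btm <- function(path) {
  d <- yaml::read_yaml(path)
  vocab <- unlist(d$vocab)
  phi <- do.call(rbind, lapply(d$phi, unlist))
  dimnames(phi) <- list(paste0("topic", seq_len(d$K)), vocab)
  structure(list(theta = unlist(d$theta), phi = phi, vocab = vocab,
                 z = NULL, z_marginal = NULL, biterms = NULL, K = d$K,
                 alpha = d$alpha, beta = d$beta,
                 iterations = d$iterations, burn_in = d$burn_in,
                 seed = d$seed),
            class = "event_btm")
}

# Brute-force posterior over all K^B topic assignments of a biterm set;
# the independent oracle used to check the Gibbs sampler on tiny
# instances.  Returns the exact marginal P(z_b = k | B) matrix.
#' Exact assignment marginals by exhaustive enumeration
#'
#' Enumerates every topic assignment of the biterms and computes the
#' collapsed posterior weight of each in closed form (ratios of gamma
#' functions from the Dirichlet integrals), returning exact per-biterm
#' topic marginals.  Only feasible for tiny instances; used to validate
#' the Gibbs sampler.
#'
#' @param biterms A `biterm_set`.
#' @param K,alpha,beta Model hyperparameters.
#' @return `B x K` matrix of exact marginals.
#' @export
enumerate_assignment_marginals <- function(biterms, K, alpha, beta) {
  B <- length(biterms$wi)
  W <- length(biterms$vocab)
  stopifnot(K^B <= 2^20)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), B)))
  logw <- apply(grid, 1L, function(z) {
    lw <- 0
    for (k in seq_len(K)) {
      sel <- z == k
      nk <- sum(sel)
      ne <- tabulate(c(biterms$wi[sel], biterms$wj[sel]), nbins = W)
      lw <- lw + lgamma(nk + alpha) + sum(lgamma(ne + beta)) -
        lgamma(2 * nk + W * beta)
    }
    lw
  })
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  marg <- matrix(0, B, K)
  for (k in seq_len(K))
    for (b in seq_len(B))
      marg[b, k] <- sum(w[grid[, b] == k])
  marg
}
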