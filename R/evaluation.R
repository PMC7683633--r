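# Topic evaluation: document co-occurrence coherence and mean pairwise
# Kullback-Leibler divergence, with the document-frequency statistics they
# need.

# Documents for counting are sets of unit strings.  A multi-word unit
# ("task difficulti" or "task_difficulti") is contained in a document when
# every constituent word is present.
.unit_words <- function(unit) {
  strsplit(gsub("_", " ", tolower(unit), fixed = TRUE), "[[:space:]]+")[[1]]
}

.doc_contains <- function(doc_set, unit) all(.unit_words(unit) %in% doc_set)

#' Document frequency of a unit or unit pair
#'
#' Counts documents (never occurrences) containing a unit, or containing
#' both units of a pair.  Matching is case-insensitive; multi-word units
#' require every constituent word.
#'
#' @param docs List of documents, each a character vector of units
#'   (typically token stems).
#' @param units Character vector of length 1 (a unit) or 2 (a pair).
#' @return Integer count.
#' @export
doc_frequency <- function(docs, units) {
  stopifnot(length(units) %in% c(1L, 2L))
  sets <- lapply(docs, tolower)
  sum(vapply(sets, function(s)
    all(vapply(unique(units), .doc_contains, logical(1), doc_set = s)),
    logical(1)))
}

#' Topic coherence from document co-occurrence
#'
#' For a topic's ranked units `v_1 > v_2 > ...`, sums
#' `log((D(v_i, v_j) + eps) / D(v_j))` over all ranked pairs with the
#' higher-ranked unit as `v_i` and the lower-ranked as `v_j`.  A
#' single-unit topic scores 0 (empty pair sum).  Higher is better.
#'
#' @param units Character vector of topic units, ranked by topic
#'   probability.
#' @param docs List of documents (character vectors of units).
#' @param eps Smoothing factor added to the co-document count (default 1).
#' @return Numeric coherence score.
#' @export
topic_coherence <- function(units, docs, eps = 1) {
  n <- length(units)
  if (n < 2L) return(0)
  score <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      dj <- doc_frequency(docs, units[j])
      if (dj == 0L)
        stop("unit '", units[j], "' occurs in no document; ",
             "coherence denominator undefined")
      dij <- doc_frequency(docs, c(units[i], units[j]))
      score <- score + log((dij + eps) / dj)
    }
  }
  score
}

#' Kullback-Leibler divergence
#'
#' `KL(p||q) = sum_x p(x) log(p(x)/q(x))` with natural logarithm;
#' `q` is additively smoothed and renormalized so the sum stays finite,
#' and `0 * log(0/q) = 0`.  Always non-negative.
#'
#' @param p,q Probability vectors on the same support.
#' @param smoothing Additive smoothing applied to `q` (default 1e-12).
#' @export
kl_divergence <- function(p, q, smoothing = 1e-12) {
  if (length(p) != length(q))
    stop("p and q have different lengths (", length(p), " vs ",
         length(q), ")")
  q <- q + smoothing
  q <- q / sum(q)
  pos <- p > 0
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' Mean pairwise KL divergence between topics
#'
#' The mean of `KL(p||q)` over all ordered pairs of distinct topics;
#' permutation-invariant and non-negative.  Higher values indicate more
#' distinct topics.
#'
#' @param topics A list of probability vectors on a shared support, or a
#'   matrix with one topic per row (e.g. the fitted `phi`).
#' @param smoothing Passed to [kl_divergence()].
#' @export
mean_pairwise_kl <- function(topics, smoothing = 1e-12) {
  if (is.matrix(topics))
    topics <- lapply(seq_len(nrow(topics)), function(k) topics[k, ])
  K <- length(topics)
  if (K < 2L) stop("need at least 2 topics, got ", K)
  vals <- c()
  for (a in seq_len(K))
    for (b in seq_len(K))
      if (a != b)
        vals <- c(vals, kl_divergence(topics[[a]], topics[[b]], smoothing))
  mean(vals)
}

#' Evaluate a fitted topic model
#'
#' Computes the mean topic coherence (each topic expanded from its top
#' events into constituent topic words) and the mean pairwise KL
#' divergence of the per-topic event distributions, as a tidy
#' model/metric/value table.
#'
#' @param model A fitted `event_btm`.
#' @param docs List of documents as character vectors of units (stems) for
#'   the coherence counts.
#' @param top_n Topic words per topic (default 2).
#' @param eps Coherence smoothing factor.
#' @param label Model label in the report.
#' @return Data frame with columns `model`, `metric`, `value`.
#' @export
evaluation_report <- function(model, docs, top_n = 2L, eps = 1,
                              label = "Event-BTM") {
  coh <- vapply(seq_len(model$K), function(k) {
    terms <- unique(unlist(lapply(
      top_events(model, k, top_n)$event, event_key_terms)))
    terms <- head(terms, top_n)
    topic_coherence(terms, docs, eps)
  }, numeric(1))
  kl <- mean_pairwise_kl(model$phi)
  data.frame(model = label,
             metric = c("mean_topic_coherence", "mean_pairwise_kl"),
             value = c(mean(coh), kl), stringsAsFactors = FALSE)
}

#' @rdname evaluation_report
#' @param report A report data frame.
#' @param path Output TSV path.
#' @export
write_evaluation_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
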