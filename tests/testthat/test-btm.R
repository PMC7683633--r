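make_mention <- function(meta = "DeduceResult", trigger = "reveals",
                         args = list(c("task difficulty", "TSK",
                                       "research object"),
                                     c("BOLD responses", "GRO",
                                       "biological mechanism")),
                         sid = 0L, did = "d1") {
  event_mention(meta, trigger = list(start = 2, end = 2, text = trigger),
                arguments = lapply(args, function(a)
                  list(start = 0, end = 1, text = a[1], category = a[2],
                       role = a[3])),
                sentence_id = sid, document_id = did)
}

test_that("canonical event keys are deterministic and position-free", {
  ev <- make_mention()
  expect_equal(canonicalize_event(ev),
               "DeduceResult|reveal|bold_respons+task_difficulti")
  ev2 <- make_mention(sid = 5L, did = "d9")
  expect_equal(canonicalize_event(ev2), canonicalize_event(ev))
  # same trigger under a different meta-event gives a different key
  ev3 <- make_mention(meta = "AnalyzeData", trigger = "reveals",
                      args = list())
  expect_false(canonicalize_event(ev3) == canonicalize_event(ev))
  expect_equal(canonicalize_event(ev, granularity = "type_trigger"),
               "DeduceResult|reveal")
  expect_equal(canonicalize_event(ev, granularity = "type"), "DeduceResult")
  expect_equal(event_key_terms(canonicalize_event(ev)),
               c("reveal", "bold respons", "task difficulti"))
})

test_that("biterm sets enumerate within-document pairs as a multiset", {
  evs <- list(d1 = c("a", "b", "c"))
  bt <- build_biterms(evs)
  expect_equal(length(bt$wi), 3L)
  pairs <- paste(bt$vocab[bt$wi], bt$vocab[bt$wj])
  expect_setequal(pairs, c("a b", "a c", "b c"))
  # a single-event document contributes nothing, with a warning
  expect_warning(bt2 <- build_biterms(list(d1 = c("a", "b"), d2 = "a")),
                 "fewer than 2")
  expect_equal(length(bt2$wi), 1L)
  # duplicated documents duplicate biterms (multiset semantics)
  bt3 <- build_biterms(list(d1 = c("a", "b"), d2 = c("a", "b")))
  expect_equal(length(bt3$wi), 2L)
  expect_equal(bt3$wi, c(1L, 1L))
  # |B| = sum over documents of choose(n_d, 2) with whole-document windows
  bundle <- fix_bundle()
  bt4 <- suppressWarnings(build_biterms(bundle$events))
  nd <- lengths(bundle$events)
  expect_equal(length(bt4$wi), sum(choose(nd, 2)))
  # sliding window restricts pairs
  bt5 <- build_biterms(list(d1 = c("a", "b", "c")), window = 2L)
  expect_equal(length(bt5$wi), 2L)
  expect_error(suppressWarnings(build_biterms(list(d1 = "a"))),
               "undefined")
})

test_that("a single-topic fit reduces to smoothed empirical frequencies", {
  bt <- fix_tiny_biterms()
  m <- event_btm(bt, K = 1L, alpha = 1, beta = 0.5, iterations = 20L,
                 burn_in = 10L, seed = 1L)
  expect_equal(m$theta, 1)
  emp <- (tabulate(c(bt$wi, bt$wj), 3L) + 0.5) / (8 + 3 * 0.5)
  expect_equal(unname(m$phi[1, ]), emp, tolerance = 1e-12)
})

test_that("sampled assignment marginals match exhaustive enumeration", {
  bt <- fix_tiny_biterms()
  exact <- enumerate_assignment_marginals(bt, K = 2L, alpha = 1, beta = 0.1)
  expect_equal(rowSums(exact), rep(1, 4L))
  # several independent chains; compare the across-chain mean against the
  # exact marginal at 3 standard errors (label symmetry makes every
  # marginal 0.5 here, so no alignment is needed)
  chains <- vapply(1:8, function(s) {
    m <- event_btm(bt, K = 2L, alpha = 1, beta = 0.1, iterations = 3000L,
                   burn_in = 500L, seed = 100L + s)
    m$z_marginal[, 1]
  }, numeric(4L))
  est <- rowMeans(chains)
  se <- apply(chains, 1L, stats::sd) / sqrt(ncol(chains))
  expect_true(all(abs(est - exact[, 1]) <= 3 * se + 1e-3))
})

test_that("fits are reproducible and their distributions normalized", {
  bt <- fix_tiny_biterms()
  m1 <- event_btm(bt, K = 2L, iterations = 200L, burn_in = 100L, seed = 9L)
  m2 <- event_btm(bt, K = 2L, iterations = 200L, burn_in = 100L, seed = 9L)
  expect_identical(m1$theta, m2$theta)
  expect_identical(m1$phi, m2$phi)
  expect_equal(sum(m1$theta), 1, tolerance = 1e-12)
  expect_equal(unname(rowSums(m1$phi)), c(1, 1), tolerance = 1e-12)
  expect_warning(event_btm(bt, K = 8L, iterations = 20L, burn_in = 10L),
                 "degenerate")
  expect_error(event_btm(bt, K = 2L, iterations = 10L, burn_in = 10L),
               "exceed")
})

test_that("biterm probabilities implement the mixture identity", {
  m <- event_btm(fix_tiny_biterms(), K = 2L, iterations = 100L,
                 burn_in = 50L, seed = 2L)
  # hand-evaluated joint probability
  m$theta <- c(0.6, 0.4)
  m$phi <- matrix(c(0.5, 0.9, 0.5, 0.1, 0, 0), 2L, 3L)
  colnames(m$phi) <- m$vocab
  expect_equal(biterm_probability(m, "a", "b"),
               0.6 * 0.5 * 0.5 + 0.4 * 0.9 * 0.1)
  expect_error(biterm_probability(m, "a", "zzz"), "unknown event")
  # K = 1 with uniform phi over two events: every ordered pair has p 0.25
  m1 <- list(theta = 1, phi = matrix(c(0.5, 0.5), 1L, 2L,
                                     dimnames = list(NULL, c("x", "y"))),
             vocab = c("x", "y"), K = 1L)
  class(m1) <- "event_btm"
  expect_equal(biterm_probability(m1, "x", "y"), 0.25)
  # normalization over all ordered pairs, for a genuinely fitted model
  m3 <- event_btm(fix_tiny_biterms(), K = 2L, iterations = 100L,
                  burn_in = 50L, seed = 3L)
  tot <- sum(outer(seq_len(3L), seq_len(3L),
                   Vectorize(function(i, j) biterm_probability(m3, i, j))))
  expect_equal(tot, 1, tolerance = 1e-9)
})

test_that("the corpus log-likelihood sums log biterm probabilities", {
  m <- event_btm(fix_tiny_biterms(), K = 2L, iterations = 100L,
                 burn_in = 50L, seed = 4L)
  one <- structure(list(wi = 1L, wj = 2L), class = "biterm_set")
  expect_equal(corpus_log_likelihood(m, one),
               log(biterm_probability(m, 1L, 2L)))
  two <- structure(list(wi = c(1L, 1L), wj = c(2L, 2L)),
                   class = "biterm_set")
  expect_equal(corpus_log_likelihood(m, two),
               2 * log(biterm_probability(m, 1L, 2L)))
  expect_true(is.finite(as.numeric(logLik(m))))
})

test_that("document topic inference mixes per-biterm posteriors", {
  m <- event_btm(fix_tiny_biterms(), K = 2L, iterations = 200L,
                 burn_in = 100L, seed = 5L)
  pz <- infer_document_topics(m, "d1")
  expect_equal(sum(pz), 1, tolerance = 1e-9)
  # one biterm: P(z|d) equals p(z|b)
  one <- list(wi = 1L, wj = 2L)
  w <- m$theta * m$phi[, 1] * m$phi[, 2]
  expect_equal(infer_document_topics(m, one), w / sum(w))
  expect_error(infer_document_topics(m, list(wi = integer(0),
                                             wj = integer(0))),
               "no biterms")
  dt <- predict(m)
  expect_equal(unname(rowSums(dt)), rep(1, 2L), tolerance = 1e-9)
})

test_that("top events rank by probability with lexicographic ties", {
  m <- event_btm(fix_tiny_biterms(), K = 2L, iterations = 200L,
                 burn_in = 100L, seed = 6L)
  te <- top_events(m, 1L, 3L)
  expect_equal(te$prob, sort(te$prob, decreasing = TRUE))
  expect_equal(top_events(m, 1L, 1L)$event,
               m$vocab[which.max(m$phi[1, ])])
  expect_warning(te_all <- top_events(m, 1L, 10L), "vocabulary has")
  expect_equal(nrow(te_all), 3L)
  # a model dump round-trips the distributions
  f <- tempfile(fileext = ".yml")
  write_btm(m, f)
  back <- read_btm(f)
  expect_equal(back$theta, m$theta, tolerance = 1e-9)
  expect_equal(back$phi, m$phi, tolerance = 1e-9)
  expect_equal(back$vocab, m$vocab)
})
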