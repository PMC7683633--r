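test_that("the taxonomy enumerations are closed and sized as defined", {
  expect_length(topic_events(), 3L)
  me <- meta_events()
  expect_equal(nrow(me), 10L)
  expect_equal(as.integer(table(me$parent)[c("CognitiveResponse",
                                             "Experiment", "Analysis")]),
               c(5L, 3L, 2L))
  tc <- trigger_categories()
  expect_equal(nrow(tc), 9L)
  expect_false("CoOccur" %in% tc$name)
  ac <- argument_categories()
  expect_equal(nrow(ac), 9L)
  expect_false(anyDuplicated(ac$abbreviation) > 0)
  expect_setequal(ac$dictionary_index, 1:9)
  # constructing anything outside the tables fails
  expect_error(event_mention("Summarize",
                             trigger = list(start = 0, end = 0, text = "x")),
               "unknown meta-event")
  expect_error(
    event_mention("Activate", trigger = list(start = 0, end = 0, text = "x"),
                  arguments = list(list(start = 1, end = 1, text = "y",
                                        category = "XYZ", role = "task agent"))),
    "unknown argument category")
})

test_that("the event-role table validates and round-trips through YAML", {
  tab <- default_event_role_table()
  expect_false(anyDuplicated(tab$role_index) > 0)
  ded <- tab[tab$meta_event == "DeduceResult", ]
  expect_equal(ded$role_name, c("research object", "biological mechanism"))
  expect_setequal(strsplit(ded$categories[1], "+", fixed = TRUE)[[1]],
                  c("TSK", "COG", "MDI"))
  path <- tempfile(fileext = ".yml")
  write_event_role_table(tab, path)
  back <- read_event_role_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  # loader enforces the invariants
  bad <- tab
  bad$role_index[2] <- bad$role_index[1]
  write_event_role_table <- function(t, p) {   # bypass writer validation
    yaml::write_yaml(lapply(seq_len(nrow(t)), function(i)
      list(meta_event = t$meta_event[i], role_name = t$role_name[i],
           role_index = t$role_index[i],
           categories = as.list(strsplit(t$categories[i], "+",
                                         fixed = TRUE)[[1]]),
           cardinality = t$cardinality[i])), p)
  }
  write_event_role_table(bad, path)
  expect_error(read_event_role_table(path), "unique")
})

make_deduce <- function(arguments) {
  event_mention("DeduceResult",
                trigger = list(start = 2, end = 2, text = "reveals"),
                arguments = arguments)
}

test_that("event validation follows the role table and its cardinalities", {
  tab <- default_event_role_table()
  ok <- make_deduce(list(
    list(start = 0, end = 1, text = "task difficulty", category = "TSK",
         role = "research object"),
    list(start = 4, end = 5, text = "BOLD responses", category = "GRO",
         role = "biological mechanism")))
  expect_identical(validate_event(ok, tab), character(0))
  # both arguments are optional
  expect_identical(validate_event(make_deduce(list()), tab), character(0))
  # 0..1 cardinality violated by a duplicated role
  dup <- make_deduce(list(
    list(start = 0, end = 1, text = "task difficulty", category = "TSK",
         role = "research object"),
    list(start = 4, end = 5, text = "depression", category = "MDI",
         role = "research object")))
  v <- validate_event(dup, tab)
  expect_length(v, 1L)
  expect_match(v, "at most one")
  # category outside the role's allowed set
  bad_cat <- make_deduce(list(
    list(start = 0, end = 0, text = "patients", category = "SUB",
         role = "research object")))
  expect_match(validate_event(bad_cat, tab), "not allowed")
  # order-independence over arguments
  rev_args <- make_deduce(rev(ok$arguments))
  expect_identical(validate_event(rev_args, tab), validate_event(ok, tab))
  # unknown meta-event in the table is a schema error
  expect_error(validate_event(
    event_mention("CoOccur", trigger = list(start = 0, end = 0, text = "x")),
    tab[tab$meta_event != "CoOccur", ]), "absent from")
})

test_that("event vectors compose by elementwise product", {
  expect_equal(compose_event_vector(c(1, 1, 1), list(c(2, 3, 4))), c(2, 3, 4))
  expect_equal(compose_event_vector(c(1, 2), list(c(3, 4), c(0.5, 1))),
               c(1.5, 8))
  expect_equal(compose_event_vector(c(0, 5), list(c(7, 7))), c(0, 35))
  expect_equal(compose_event_vector(c(1, 2), list()), c(1, 2))
  expect_error(compose_event_vector(c(1, 2), list(c(1, 2, 3))),
               "argument vector 1")
  # commutative and associative over the argument list
  set.seed(42)
  for (i in 1:20) {
    vt <- rnorm(5)
    args <- replicate(3, rnorm(5), simplify = FALSE)
    ref <- compose_event_vector(vt, args)
    perm <- sample(3)
    expect_equal(compose_event_vector(vt, args[perm]), ref)
    nested <- compose_event_vector(
      compose_event_vector(vt, args[1]), args[2:3])
    expect_equal(nested, ref)
  }
})
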