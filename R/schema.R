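#' @useDynLib eventbtm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm setNames
#' @importFrom utils head
NULL

# ---------------------------------------------------------------------------
# Fixed event taxonomy: 3 topic events, 10 meta-events, 9 trigger categories,
# 9 argument categories.  The enumerations are closed: constructors reject
# anything outside the tables below.
# ---------------------------------------------------------------------------

.TOPIC_EVENTS <- c("CognitiveResponse", "Experiment", "Analysis")

.META_EVENTS <- data.frame(
  name = c("Activate", "Deactivate", "Affect", "CoOccur", "Include",
           "DesignCognitiveTask", "PerformCognitiveTask", "AcquireData",
           "AnalyzeData", "DeduceResult"),
  parent = c(rep("CognitiveResponse", 5), rep("Experiment", 3),
             rep("Analysis", 2)),
  stringsAsFactors = FALSE
)

# CoOccur has no trigger category: 9 trigger categories for 10 meta-events.
.TRIGGER_CATEGORIES <- data.frame(
  name = c("Activate", "Deactivate", "Include", "Affect",
           "DesignCognitiveTask", "PerformCognitiveTask", "AcquireData",
           "AnalyzeData", "DeduceResult"),
  abbreviation = c("ACT", "DEA", "INC", "AFF", "DSG", "PFM", "ACQ",
                   "ANA", "DED"),
  stringsAsFactors = FALSE
)

.ARGUMENT_CATEGORIES <- data.frame(
  name = c("GrossBrainAnatomy", "CognitiveFunction", "Subject",
           "MedicalProblem", "SensoryStimuliOrResponse", "ExperimentalTask",
           "ExperimentalMeasurement", "AnalyticalToolAndMethod",
           "BrainNetwork"),
  abbreviation = c("GRO", "COG", "SUB", "MDI", "SEN", "TSK", "MEA",
                   "TOL", "RLT"),
  dictionary_index = 1:9,
  stringsAsFactors = FALSE
)

#' Event taxonomy tables
#'
#' Accessors for the fixed neuroimaging research event taxonomy: three topic
#' events (cognitive response, experiment, analysis), ten meta-events grouped
#' under them, nine trigger categories (the co-occur meta-event has none) and
#' nine argument categories with their BIO abbreviations and dictionary
#' indices.
#'
#' @return A character vector (`topic_events`) or a data frame with one row
#'   per category.
#' @export
topic_events <- function() .TOPIC_EVENTS

#' @rdname topic_events
#' @export
meta_events <- function() .META_EVENTS

#' @rdname topic_events
#' @export
trigger_categories <- function() .TRIGGER_CATEGORIES

#' @rdname topic_events
#' @export
argument_categories <- function() .ARGUMENT_CATEGORIES

.check_meta_event <- function(x) {
  if (!is.character(x) || length(x) != 1L || !x %in% .META_EVENTS$name)
    stop("unknown meta-event type: ", paste(x, collapse = ", "),
         " (valid: ", paste(.META_EVENTS$name, collapse = ", "), ")")
  x
}

.check_argument_category <- function(x) {
  if (!is.character(x) || length(x) != 1L ||
      !(x %in% .ARGUMENT_CATEGORIES$abbreviation ||
        x %in% .ARGUMENT_CATEGORIES$name))
    stop("unknown argument category: ", paste(x, collapse = ", "))
  if (x %in% .ARGUMENT_CATEGORIES$name)
    x <- .ARGUMENT_CATEGORIES$abbreviation[.ARGUMENT_CATEGORIES$name == x]
  x
}

.trigger_abbr <- function(meta_event) {
  i <- match(meta_event, .TRIGGER_CATEGORIES$name)
  if (is.na(i))
    stop("meta-event '", meta_event, "' has no trigger category")
  .TRIGGER_CATEGORIES$abbreviation[i]
}

# ---------------------------------------------------------------------------
# Event-role table
# ---------------------------------------------------------------------------

#' Default event-role table
#'
#' The table mapping each meta-event to its argument roles, the argument
#' categories each role admits, and the role cardinality.  Role indices are
#' global (the scalar role feature of the lexical feature vector and the
#' first field of role-annotation files).  The deduce-result entry carries
#' role 1 "research object" over experimental task / cognitive function /
#' medical problem and role 2 "biological mechanism" over gross brain
#' anatomy / brain network; the remaining meta-events get one agent-style
#' and one object-style role each.  Index 0 is reserved for "none".
#'
#' @return A data frame of class `event_role_table` with columns
#'   `meta_event`, `role_name`, `role_index`, `categories`
#'   (plus-separated abbreviations) and `cardinality` (one of `0..1`, `1`,
#'   `0..n`).
#' @export
default_event_role_table <- function() {
  tab <- rbind(
    c("DeduceResult",         "research object",      1, "TSK+COG+MDI", "0..1"),
    c("DeduceResult",         "biological mechanism", 2, "GRO+RLT",     "0..1"),
    c("Activate",             "task agent",           3, "TSK+COG",     "0..1"),
    c("Activate",             "affected region",      4, "GRO+RLT",     "0..1"),
    c("Deactivate",           "task agent",           5, "TSK+COG",     "0..1"),
    c("Deactivate",           "affected region",      6, "GRO+RLT",     "0..1"),
    c("Affect",               "task agent",           7, "TSK+COG",     "0..1"),
    c("Affect",               "affected region",      8, "GRO+RLT",     "0..1"),
    c("CoOccur",              "member 1",             9, "GRO+RLT+TSK", "0..1"),
    c("CoOccur",              "member 2",            10, "GRO+RLT+TSK", "0..1"),
    c("Include",              "member 1",            11, "GRO+RLT+TSK", "0..1"),
    c("Include",              "member 2",            12, "GRO+RLT+TSK", "0..1"),
    c("DesignCognitiveTask",  "designed task",       13, "TSK",         "0..1"),
    c("DesignCognitiveTask",  "design tool",         14, "TOL",         "0..1"),
    c("PerformCognitiveTask", "performer",           15, "SUB",         "0..1"),
    c("PerformCognitiveTask", "performed task",      16, "TSK",         "0..1"),
    c("AcquireData",          "recorded subject",    17, "SUB",         "0..1"),
    c("AcquireData",          "recording device",    18, "MEA+SEN",     "0..1"),
    c("AnalyzeData",          "analysis method",     19, "TOL",         "0..1"),
    c("AnalyzeData",          "analyzed signal",     20, "MEA+GRO+RLT", "0..1")
  )
  out <- data.frame(meta_event = tab[, 1], role_name = tab[, 2],
                    role_index = as.integer(tab[, 3]), categories = tab[, 4],
                    cardinality = tab[, 5], stringsAsFactors = FALSE)
  class(out) <- c("event_role_table", "data.frame")
  .validate_role_table(out)
  out
}

.validate_role_table <- function(tab) {
  stopifnot(is.data.frame(tab),
            all(c("meta_event", "role_name", "role_index", "categories",
                  "cardinality") %in% names(tab)))
  if (any(!tab$meta_event %in% .META_EVENTS$name))
    stop("event-role table names unknown meta-events: ",
         paste(setdiff(tab$meta_event, .META_EVENTS$name), collapse = ", "))
  if (anyDuplicated(tab$role_index) || any(tab$role_index < 0))
    stop("role indices must be unique and >= 0")
  cats <- unlist(strsplit(tab$categories, "+", fixed = TRUE))
  if (any(!cats %in% .ARGUMENT_CATEGORIES$abbreviation))
    stop("event-role table names unknown argument categories: ",
         paste(setdiff(cats, .ARGUMENT_CATEGORIES$abbreviation),
               collapse = ", "))
  if (any(!tab$cardinality %in% c("0..1", "1", "0..n")))
    stop("cardinality must be one of 0..1, 1, 0..n")
  invisible(tab)
}

#' Read or write an event-role table
#'
#' The table is stored as a human-editable YAML list with one entry per
#' role; the reader validates meta-event names, category abbreviations,
#' cardinalities and role-index uniqueness.
#'
#' @param path File path.
#' @param table An `event_role_table`.
#' @return `read_event_role_table` returns an `event_role_table`;
#'   `write_event_role_table` returns `path` invisibly.
#' @export
read_event_role_table <- function(path) {
  entries <- yaml::read_yaml(path)
  out <- do.call(rbind, lapply(entries, function(e) {
    data.frame(meta_event = e$meta_event, role_name = e$role_name,
               role_index = as.integer(e$role_index),
               categories = paste(e$categories, collapse = "+"),
               cardinality = e$cardinality, stringsAsFactors = FALSE)
  }))
  class(out) <- c("event_role_table", "data.frame")
  .validate_role_table(out)
  out
}

#' @rdname read_event_role_table
#' @export
write_event_role_table <- function(table, path) {
  .validate_role_table(table)
  entries <- lapply(seq_len(nrow(table)), function(i) {
    list(meta_event = table$meta_event[i], role_name = table$role_name[i],
         role_index = table$role_index[i],
         categories = as.list(strsplit(table$categories[i], "+",
                                       fixed = TRUE)[[1]]),
         cardinality = table$cardinality[i])
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}

.roles_for <- function(table, meta_event) {
  table[table$meta_event == meta_event, , drop = FALSE]
}

.role_allows <- function(row, category) {
  category %in% strsplit(row$categories, "+", fixed = TRUE)[[1]]
}

# ---------------------------------------------------------------------------
# Event mentions
# ---------------------------------------------------------------------------

#' Construct an event mention
#'
#' An event mention is a trigger span plus zero or more role-bearing
#' argument spans, typed by a meta-event.  Spans are 0-based inclusive
#' token index pairs.
#'
#' @param meta_event Meta-event type name.
#' @param trigger List with `start`, `end` (0-based inclusive token
#'   indices) and `text`.
#' @param arguments List of arguments, each a list with `start`, `end`,
#'   `text`, `category` (argument category abbreviation or name) and
#'   `role` (role name from the event-role table).
#' @param sentence_id,document_id Provenance identifiers.
#' @return An object of class `event_mention`.
#' @export
event_mention <- function(meta_event, trigger, arguments = list(),
                          sentence_id = NA_integer_,
                          document_id = NA_character_) {
  .check_meta_event(meta_event)
  stopifnot(is.list(trigger), !is.null(trigger$start), !is.null(trigger$end))
  if (trigger$end < trigger$start)
    stop("trigger span is empty or inverted")
  arguments <- lapply(arguments, function(a) {
    a$category <- .check_argument_category(a$category)
    a
  })
  structure(list(meta_event = meta_event, trigger = trigger,
                 arguments = arguments, sentence_id = sentence_id,
                 document_id = document_id),
            class = "event_mention")
}

#' @export
print.event_mention <- function(x, ...) {
  args <- vapply(x$arguments, function(a)
    sprintf("%s[%s/%s]", a$text, a$category, a$role), character(1))
  cat(sprintf("<%s> trigger: \"%s\"", x$meta_event, x$trigger$text))
  if (length(args)) cat(" | args:", paste(args, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Validate an event mention against an event-role table
#'
#' Checks that each argument's role exists for the mention's meta-event,
#' that the argument category is admitted by that role, and that role
#' cardinalities hold.  Validation is order-independent over arguments.
#'
#' @param event An `event_mention`.
#' @param table An `event_role_table`.
#' @return Character vector of violations; empty when the event is valid.
#' @export
validate_event <- function(event, table = default_event_role_table()) {
  stopifnot(inherits(event, "event_mention"))
  .check_meta_event(event$meta_event)
  rows <- .roles_for(table, event$meta_event)
  if (nrow(rows) == 0L)
    stop("meta-event '", event$meta_event, "' is absent from the ",
         "event-role table")
  violations <- character(0)
  used <- setNames(integer(nrow(rows)), rows$role_name)
  for (a in event$arguments) {
    i <- match(a$role, rows$role_name)
    if (is.na(i)) {
      violations <- c(violations, sprintf(
        "role '%s' is not defined for meta-event %s", a$role,
        event$meta_event))
      next
    }
    used[i] <- used[i] + 1L
    if (!.role_allows(rows[i, ], a$category))
      violations <- c(violations, sprintf(
        "category %s not allowed for role '%s' (allowed: %s)",
        a$category, a$role, rows$categories[i]))
  }
  for (i in seq_len(nrow(rows))) {
    card <- rows$cardinality[i]
    n <- used[i]
    if (card == "0..1" && n > 1L)
      violations <- c(violations, sprintf(
        "role '%s' admits at most one argument, got %d",
        rows$role_name[i], n))
    if (card == "1" && n != 1L)
      violations <- c(violations, sprintf(
        "role '%s' requires exactly one argument, got %d",
        rows$role_name[i], n))
  }
  violations
}

#' Distributed event representation
#'
#' Composes an event vector as the elementwise (Hadamard) product of the
#' trigger vector and all argument vectors; with no arguments the trigger
#' vector is returned unchanged.  All vectors must share the embedding
#' dimension.
#'
#' @param v_trigger Numeric trigger vector.
#' @param v_args List of numeric argument vectors (possibly empty).
#' @return Numeric vector of the same dimension.
#' @export
compose_event_vector <- function(v_trigger, v_args = list()) {
  stopifnot(is.numeric(v_trigger), length(v_trigger) > 0L)
  out <- v_trigger
  for (i in seq_along(v_args)) {
    v <- v_args[[i]]
    if (length(v) != length(v_trigger))
      stop(sprintf(
        "argument vector %d has dimension %d, trigger has %d",
        i, length(v), length(v_trigger)))
    out <- out * v
  }
  out
}
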