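# Porter (1980) suffix-stripping stemmer.  Used for canonical event keys,
# dictionary matching on stems, and the stem/affix token fields.

.p_cons <- function(chs, i) {
  ch <- chs[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!.p_cons(chs, i - 1L))
  }
  TRUE
}

# measure m: number of vowel->consonant transitions in the form C?(VC){m}V?
.p_m <- function(chs) {
  if (length(chs) == 0L) return(0L)
  flags <- vapply(seq_along(chs), function(i) .p_cons(chs, i), logical(1))
  r <- rle(flags)
  v <- r$values
  if (length(v) && v[1]) v <- v[-1]                 # leading consonants
  floor(length(v) / 2)
}

.p_has_vowel <- function(chs) {
  if (length(chs) == 0L) return(FALSE)
  any(!vapply(seq_along(chs), function(i) .p_cons(chs, i), logical(1)))
}

.p_double_cons <- function(chs) {
  n <- length(chs)
  n >= 2L && chs[n] == chs[n - 1L] && .p_cons(chs, n)
}

# consonant-vowel-consonant ending, final consonant not w, x or y
.p_cvc <- function(chs) {
  n <- length(chs)
  n >= 3L && .p_cons(chs, n) && !.p_cons(chs, n - 1L) &&
    .p_cons(chs, n - 2L) && !chs[n] %in% c("w", "x", "y")
}

.p_ends <- function(word, suffix) {
  nchar(word) > nchar(suffix) &&
    substring(word, nchar(word) - nchar(suffix) + 1L) == suffix
}

.p_trunc <- function(word, k) substring(word, 1L, nchar(word) - k)

.p_stem1 <- function(word) {
  # step 1a
  if (.p_ends(word, "sses")) word <- .p_trunc(word, 2L)
  else if (.p_ends(word, "ies")) word <- .p_trunc(word, 2L)
  else if (!.p_ends(word, "ss") && .p_ends(word, "s"))
    word <- .p_trunc(word, 1L)
  # step 1b
  chs <- function(w) strsplit(w, "", fixed = TRUE)[[1]]
  fix_up <- FALSE
  if (.p_ends(word, "eed")) {
    if (.p_m(chs(.p_trunc(word, 3L))) > 0L) word <- .p_trunc(word, 1L)
  } else if (.p_ends(word, "ed") && .p_has_vowel(chs(.p_trunc(word, 2L)))) {
    word <- .p_trunc(word, 2L); fix_up <- TRUE
  } else if (.p_ends(word, "ing") && .p_has_vowel(chs(.p_trunc(word, 3L)))) {
    word <- .p_trunc(word, 3L); fix_up <- TRUE
  }
  if (fix_up) {
    w <- chs(word)
    if (.p_ends(word, "at") || .p_ends(word, "bl") || .p_ends(word, "iz"))
      word <- paste0(word, "e")
    else if (.p_double_cons(w) && !w[length(w)] %in% c("l", "s", "z"))
      word <- .p_trunc(word, 1L)
    else if (.p_m(w) == 1L && .p_cvc(w))
      word <- paste0(word, "e")
  }
  # step 1c
  if (.p_ends(word, "y") &&
      .p_has_vowel(chs(.p_trunc(word, 1L))))
    word <- paste0(.p_trunc(word, 1L), "i")
  word
}

.P_STEP2 <- c(ational = "ate", tional = "tion", enci = "ence", anci = "ance",
  izer = "ize", bli = "ble", alli = "al", entli = "ent", eli = "e",
  ousli = "ous", ization = "ize", ation = "ate", ator = "ate", alism = "al",
  iveness = "ive", fulness = "ful", ousness = "ous", aliti = "al",
  iviti = "ive", biliti = "ble", logi = "log")

.P_STEP3 <- c(icate = "ic", ative = "", alize = "al", iciti = "ic",
  ical = "ic", ful = "", ness = "")

.P_STEP4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
  "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous",
  "ive", "ize")

.p_map_suffix <- function(word, map, min_m) {
  chs <- function(w) strsplit(w, "", fixed = TRUE)[[1]]
  for (suf in names(map)) {
    if (.p_ends(word, suf)) {
      stem <- .p_trunc(word, nchar(suf))
      if (.p_m(chs(stem)) > min_m - 1L) word <- paste0(stem, map[[suf]])
      return(word)
    }
  }
  word
}

.p_stem_word <- function(word) {
  if (nchar(word) <= 2L) return(word)
  chs <- function(w) strsplit(w, "", fixed = TRUE)[[1]]
  word <- .p_stem1(word)
  word <- .p_map_suffix(word, .P_STEP2, 1L)
  word <- .p_map_suffix(word, .P_STEP3, 1L)
  # step 4: drop suffix when measure of the stem exceeds 1
  for (suf in .P_STEP4) {
    if (.p_ends(word, suf)) {
      stem <- .p_trunc(word, nchar(suf))
      if (suf == "ion" && !substring(stem, nchar(stem)) %in% c("s", "t"))
        break
      if (.p_m(chs(stem)) > 1L) word <- stem
      break
    }
  }
  # step 5a
  if (.p_ends(word, "e")) {
    stem <- .p_trunc(word, 1L)
    m <- .p_m(chs(stem))
    if (m > 1L || (m == 1L && !.p_cvc(chs(stem)))) word <- stem
  }
  # step 5b
  if (.p_ends(word, "ll") && .p_m(chs(word)) > 1L)
    word <- .p_trunc(word, 1L)
  word
}

#' Porter stemmer
#'
#' Suffix-stripping stemmer used throughout the package for stem/affix token
#' features, stem-level dictionary matching and canonical event keys.
#' Input is lower-cased before stemming.
#'
#' @param words Character vector.
#' @return Character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("reveals", "responses", "difficulty"))
#' @export
porter_stem <- function(words) {
  vapply(tolower(words), .p_stem_word, character(1), USE.NAMES = FALSE)
}
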