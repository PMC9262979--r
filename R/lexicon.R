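#' The packaged tangram-task lexicon
#'
#' A closed lexicon (~300 entries) themed on the tangram description task:
#' shapes, animals, everyday objects, spatial terms, and the function words
#' needed to talk about them. Each entry carries the surface form, its lemma,
#' a coarse part-of-speech tag (`pronoun`, `verb`, `preposition`,
#' `determiner`, `noun`, `adjective`, `adverb`, `conjunction`, `number`,
#' `interjection`), and a topic label used by the synthetic dyad generator.
#'
#' @return a tibble with columns `word`, `lemma`, `pos`, `topic`.
#' @export
default_lexicon <- function() {
  if (is.null(.entrainr_cache$lexicon)) {
    path <- system.file("extdata", "tangram_lexicon.tsv", package = "entrainr",
                        mustWork = TRUE)
    .entrainr_cache$lexicon <- readr::read_tsv(
      path, col_types = readr::cols(.default = readr::col_character())
    )
  }
  .entrainr_cache$lexicon
}

.entrainr_cache <- new.env(parent = emptyenv())

#' Construct a lexicon-based lemmatizer / POS tagger
#'
#' The NLP backend used by [lemmatize_and_tag()]. Lookups are exact-match on
#' the lowercased token; unknown tokens fall through a small set of English
#' suffix rules (plural -s/-es/-ies, progressive -ing, past -ed, possessive
#' 's) and are re-looked-up; tokens still unknown keep themselves as lemma
#' and are tagged `noun` (the majority class in referential descriptions).
#' Deterministic by construction.
#'
#' @param lexicon a data frame with columns `word`, `lemma`, `pos`
#'   (defaults to [default_lexicon()]).
#' @return an object of class `lexicon_backend`.
#' @export
lexicon_backend <- function(lexicon = default_lexicon()) {
  stopifnot(all(c("word", "lemma", "pos") %in% names(lexicon)))
  env <- new.env(parent = emptyenv(), size = nrow(lexicon) * 2L)
  for (i in seq_len(nrow(lexicon))) {
    assign(lexicon$word[i], c(lexicon$lemma[i], lexicon$pos[i]), envir = env)
  }
  structure(list(table = env, lexicon = lexicon), class = "lexicon_backend")
}

#' @export
print.lexicon_backend <- function(x, ...) {
  cat("<lexicon_backend> ", nrow(x$lexicon), " entries\n", sep = "")
  invisible(x)
}

# candidate base forms for an unknown inflected token, most specific first
unsuffix_candidates <- function(tok) {
  out <- character()
  n <- nchar(tok)
  add <- function(x) out <<- c(out, x)
  if (endsWith(tok, "'s")) add(substr(tok, 1, n - 2))
  if (endsWith(tok, "ies") && n > 4) add(paste0(substr(tok, 1, n - 3), "y"))
  if (endsWith(tok, "es") && n > 3) add(substr(tok, 1, n - 2))
  if (endsWith(tok, "s") && n > 2 && !endsWith(tok, "ss")) add(substr(tok, 1, n - 1))
  if (endsWith(tok, "ing") && n > 4) {
    stem <- substr(tok, 1, n - 3)
    add(stem)
    add(paste0(stem, "e"))                       # making -> make
    if (nchar(stem) > 2 &&
        substr(stem, nchar(stem), nchar(stem)) ==
        substr(stem, nchar(stem) - 1, nchar(stem) - 1)) {
      add(substr(stem, 1, nchar(stem) - 1))      # running -> run
    }
  }
  if (endsWith(tok, "ed") && n > 3) {
    stem <- substr(tok, 1, n - 2)
    add(stem)
    add(paste0(stem, "e"))                       # angled -> angle
    if (nchar(stem) > 2 &&
        substr(stem, nchar(stem), nchar(stem)) ==
        substr(stem, nchar(stem) - 1, nchar(stem) - 1)) {
      add(substr(stem, 1, nchar(stem) - 1))
    }
  }
  unique(out)
}

lookup_token <- function(tok, backend) {
  hit <- get0(tok, envir = backend$table, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  for (cand in unsuffix_candidates(tok)) {
    hit <- get0(cand, envir = backend$table, inherits = FALSE)
    if (!is.null(hit)) return(hit)
  }
  c(tok, "noun")
}

#' Tokenize a stretch of transcribed speech
#'
#' Unicode-aware, lowercasing, punctuation-stripping tokenizer. Hyphenated
#' compounds and internal apostrophes are kept intact; everything else that
#' is not a letter or digit is removed before splitting on whitespace.
#'
#' @param text a character vector.
#' @return a list of character vectors of tokens (one element per input).
#' @export
tokenize_text <- function(text) {
  text <- tolower(text)
  text <- gsub("[^\\p{L}\\p{N}'\\- ]+", " ", text, perl = TRUE)
  text <- gsub("(^|\\s)['\\-]+|['\\-]+(\\s|$)", " ", text, perl = TRUE)
  lapply(strsplit(trimws(text), "\\s+"), function(x) x[nzchar(x)])
}

#' Lemmatize and POS-tag one turn
#'
#' @param turn a single row of a turns table (see [build_turns()]), or a
#'   character string of raw text.
#' @param backend a [lexicon_backend()].
#' @return an object of class `tokenized_turn`: a list with `turn` (index),
#'   `role`, and parallel character vectors `tokens`, `lemmas`, `pos`.
#' @export
lemmatize_and_tag <- function(turn, backend = lexicon_backend()) {
  if (is.character(turn)) {
    text <- turn
    idx <- NA_integer_
    role <- NA_character_
  } else {
    text <- turn$text
    idx <- turn$turn %||% NA_integer_
    role <- turn$role %||% NA_character_
  }
  toks <- tokenize_text(text)[[1]]
  if (length(toks) == 0) {
    return(structure(list(turn = idx, role = role, tokens = character(),
                          lemmas = character(), pos = character()),
                     class = "tokenized_turn"))
  }
  hits <- vapply(toks, lookup_token, character(2), backend = backend)
  structure(list(turn = idx, role = role, tokens = toks,
                 lemmas = unname(hits[1, ]), pos = unname(hits[2, ])),
            class = "tokenized_turn")
}

#' @export
print.tokenized_turn <- function(x, ...) {
  cat("<tokenized_turn> turn ", x$turn, " (", x$role, "): ",
      paste0(x$tokens, "/", x$pos, collapse = " "), "\n", sep = "")
  invisible(x)
}
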