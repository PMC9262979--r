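#' Part-of-speech bigrams of a tokenized turn
#'
#' Adjacent pairs of coarse POS tags, e.g. the tags of "It looks like a bird"
#' yield `"pronoun verb"`, `"verb preposition"`, `"preposition determiner"`,
#' `"determiner noun"`. A turn of n tokens yields max(0, n - 1) bigrams.
#'
#' @param tt a `tokenized_turn` (see [lemmatize_and_tag()]).
#' @return a character vector of space-joined tag pairs.
#' @export
pos_bigrams <- function(tt) {
  tags <- tt$pos
  n <- length(tags)
  if (n < 2) return(character())
  paste(tags[-n], tags[-1])
}

count_vector_cosine <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(NA_real_)
  vocab <- union(a, b)
  ca <- tabulate(match(a, vocab), nbins = length(vocab))
  cb <- tabulate(match(b, vocab), nbins = length(vocab))
  cosine_similarity(ca, cb)
}

#' Lexical alignment between a prime and a response turn
#'
#' Cosine similarity between lemma unigram count vectors over the union
#' vocabulary of the two turns; ranges from 0 (no shared lemmas) to 1
#' (identical lemma distribution). An empty turn yields `NA` (exchange
#' excluded).
#'
#' @param prime,response `tokenized_turn` objects.
#' @return a scalar in `[0, 1]` or `NA_real_`.
#' @export
lexical_score <- function(prime, response) {
  count_vector_cosine(prime$lemmas, response$lemmas)
}

#' Syntactic alignment between a prime and a response turn
#'
#' Cosine similarity between part-of-speech bigram count vectors; 0 = no
#' shared POS bigrams, 1 = identical bigram distribution. A turn with fewer
#' than two tokens has no bigrams and yields `NA` (exchange excluded for the
#' syntactic domain).
#'
#' @param prime,response `tokenized_turn` objects.
#' @return a scalar in `[0, 1]` or `NA_real_`.
#' @export
syntactic_score <- function(prime, response) {
  count_vector_cosine(pos_bigrams(prime), pos_bigrams(response))
}

#' Score every examiner-prime / participant-response exchange in a turn
#' sequence
#'
#' Walks an alternating turn sequence and scores each pair of an examiner
#' turn and the immediately following participant turn (the
#' participant-responds-to-examiner direction). The cosine scores themselves
#' are symmetric; directionality lives entirely in this pair selection.
#'
#' @param turns a turns table from [build_turns()], or a pre-tokenized list of
#'   `tokenized_turn` objects.
#' @param model an [embedding_model()] for the semantic domain, or `NULL` to
#'   skip semantic scoring.
#' @param backend a [lexicon_backend()] used when `turns` is a turns table.
#' @param direction currently only `"participant_responds"`.
#' @return a tibble of class `exchange_scores` with columns `prime_turn`,
#'   `response_turn`, `lexical`, `syntactic`, `semantic`,
#'   `response_word_count`. Excluded components are `NA`.
#' @export
score_conversation <- function(turns, model = NULL,
                               backend = lexicon_backend(),
                               direction = "participant_responds") {
  stopifnot(identical(direction, "participant_responds"))
  tts <- as_tokenized_turns(turns, backend)
  n <- length(tts)
  out <- tibble::tibble(prime_turn = integer(), response_turn = integer(),
                        lexical = double(), syntactic = double(),
                        semantic = double(), response_word_count = integer())
  if (n < 2) return(structure(out, class = c("exchange_scores", class(out))))
  rows <- list()
  for (k in seq_len(n - 1)) {
    if (!identical(tts[[k]]$role, "examiner") ||
        !identical(tts[[k + 1]]$role, "participant")) next
    prime <- tts[[k]]
    resp <- tts[[k + 1]]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      prime_turn = prime$turn,
      response_turn = resp$turn,
      lexical = lexical_score(prime, resp),
      syntactic = syntactic_score(prime, resp),
      semantic = if (is.null(model)) NA_real_ else
        semantic_score(prime, resp, model),
      response_word_count = length(resp$tokens)
    )
  }
  out <- dplyr::bind_rows(out, rows)
  structure(out, class = c("exchange_scores", class(out)))
}

as_tokenized_turns <- function(turns, backend) {
  if (is.list(turns) && length(turns) > 0 &&
      inherits(turns[[1]], "tokenized_turn")) {
    return(turns)
  }
  if (is.data.frame(turns)) {
    return(lapply(seq_len(nrow(turns)),
                  function(i) lemmatize_and_tag(turns[i, ], backend)))
  }
  if (is.list(turns) && length(turns) == 0) return(list())
  abort("turns must be a turns table or a list of tokenized_turn objects",
        class = "entrainr_invalid_input")
}
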