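#' Wrap a matrix of word vectors as an embedding model
#'
#' @param vectors a numeric matrix with one row per lemma; rownames are the
#'   vocabulary.
#' @return an object of class `embedding_model`.
#' @export
embedding_model <- function(vectors) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  structure(list(vectors = vectors, dims = ncol(vectors)),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat("<embedding_model> ", nrow(x$vectors), " lemmas x ", x$dims,
      " dims\n", sep = "")
  invisible(x)
}

#' Train distributional lemma embeddings on the study corpus
#'
#' Count-based distributional embeddings: lemma-by-lemma co-occurrence counts
#' within a symmetric window are reweighted by positive pointwise mutual
#' information (PPMI) and factorized by truncated SVD; the left singular
#' vectors scaled by the square root of the singular values are the word
#' vectors. This is the closed-form counterpart of skip-gram training and is
#' fully deterministic (`seed` is accepted for interface stability but the
#' procedure involves no randomness; SVD column signs are fixed so that the
#' largest-magnitude entry of each dimension is positive).
#'
#' @param corpus a list of `tokenized_turn` objects (or character vectors of
#'   lemmas).
#' @param dims requested embedding dimensionality (truncated to the matrix
#'   rank when smaller).
#' @param window symmetric co-occurrence window size in tokens.
#' @param min_count lemmas with fewer occurrences are dropped from the
#'   vocabulary.
#' @param min_tokens minimum pooled corpus size; below this training refuses
#'   and asks for injected vectors.
#' @param seed unused (kept for call-signature stability).
#' @return an [embedding_model()]. Out-of-vocabulary lemmas are looked up as
#'   zero vectors by [semantic_score()].
#' @export
train_corpus_embeddings <- function(corpus, dims = 100, window = 5,
                                    min_count = 1, min_tokens = 50,
                                    seed = NULL) {
  sents <- lapply(corpus, function(x) if (is.character(x)) x else x$lemmas)
  sents <- sents[lengths(sents) > 0]
  total <- sum(lengths(sents))
  if (total < min_tokens) {
    abort(paste0("corpus too small (", total, " tokens < ", min_tokens,
                 "); inject pretrained vectors via embedding_model()"),
          class = "entrainr_invalid_input")
  }
  counts <- table(unlist(sents))
  vocab <- sort(names(counts)[counts >= min_count])
  v <- length(vocab)
  idx <- setNames(seq_len(v), vocab)
  cooc <- matrix(0, v, v, dimnames = list(vocab, vocab))
  for (s in sents) {
    s <- s[s %in% vocab]
    n <- length(s)
    if (n < 2) next
    ii <- idx[s]
    for (off in seq_len(min(window, n - 1))) {
      a <- ii[seq_len(n - off)]
      b <- ii[seq.int(off + 1L, n)]
      for (k in seq_along(a)) {
        cooc[a[k], b[k]] <- cooc[a[k], b[k]] + 1
        cooc[b[k], a[k]] <- cooc[b[k], a[k]] + 1
      }
    }
  }
  tot <- sum(cooc)
  rs <- rowSums(cooc)
  expected <- outer(rs, rs) / tot
  pmi <- log(pmax(cooc, 0) * tot / pmax(expected, .Machine$double.eps))
  pmi[!is.finite(pmi) | cooc == 0] <- 0
  ppmi <- pmax(pmi, 0)
  d <- min(dims, v)
  sv <- svd(ppmi, nu = d, nv = 0)
  keep <- sv$d[seq_len(d)] > 1e-10
  d_eff <- max(1L, sum(keep))
  w <- sv$u[, seq_len(d_eff), drop = FALSE] %*%
    diag(sqrt(sv$d[seq_len(d_eff)]), d_eff)
  # deterministic sign convention per dimension
  for (j in seq_len(ncol(w))) {
    if (w[which.max(abs(w[, j])), j] < 0) w[, j] <- -w[, j]
  }
  rownames(w) <- vocab
  embedding_model(w)
}

# mean lemma vector for a turn; OOV lemmas contribute zero vectors.
# "none" averages over distinct lemmas (unweighted); "freq" over token
# occurrences (frequency-weighted).
turn_vector <- function(lemmas, model, weighting = c("none", "freq")) {
  weighting <- match.arg(weighting)
  if (length(lemmas) == 0) return(NULL)
  if (weighting == "none") lemmas <- unique(lemmas)
  vecs <- matrix(0, length(lemmas), model$dims)
  inv <- lemmas %in% rownames(model$vectors)
  if (!any(inv)) return(NULL)
  vecs[inv, ] <- model$vectors[lemmas[inv], , drop = FALSE]
  colMeans(vecs)
}

#' Semantic alignment between a prime and a response turn
#'
#' Cosine similarity between the unweighted means of the two turns' lemma
#' vectors. Ranges from -1 (opposite content) to 1 (identical content).
#' A turn with no in-vocabulary lemma yields `NA` (exchange excluded).
#'
#' @param prime,response `tokenized_turn` objects.
#' @param model an [embedding_model()].
#' @param weighting `"none"` (default, unweighted mean) or `"freq"`.
#' @return a scalar in `[-1, 1]` or `NA_real_`.
#' @export
semantic_score <- function(prime, response, model,
                           weighting = c("none", "freq")) {
  vp <- turn_vector(prime$lemmas, model, weighting)
  vr <- turn_vector(response$lemmas, model, weighting)
  if (is.null(vp) || is.null(vr)) return(NA_real_)
  cosine_similarity(vp, vr)
}
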