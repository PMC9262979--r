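backend <- lexicon_backend()

test_that("lemmatizer maps inflected forms to their root", {
  expect_equal(lemmatize_and_tag("running", backend)$lemmas, "run")
  expect_equal(lemmatize_and_tag("runs", backend)$lemmas, "run")
  expect_equal(lemmatize_and_tag("ran", backend)$lemmas, "run")
  tt <- lemmatize_and_tag("It looks like a bird", backend)
  expect_equal(tt$tokens, c("it", "looks", "like", "a", "bird"))
  expect_equal(tt$pos,
               c("pronoun", "verb", "preposition", "determiner", "noun"))
  empty <- lemmatize_and_tag("", backend)
  expect_length(empty$tokens, 0)
  expect_length(empty$lemmas, 0)
  expect_length(empty$pos, 0)
})

test_that("tokenizer strips punctuation but keeps hyphenated compounds", {
  expect_equal(tokenize_text("Well, it's a bird!")[[1]],
               c("well", "it's", "a", "bird"))
  expect_equal(tokenize_text("upside-down shape.")[[1]],
               c("upside-down", "shape"))
  expect_equal(tokenize_text("  ")[[1]], character(0))
})

test_that("POS bigrams follow the adjacent-pair definition", {
  tt <- lemmatize_and_tag("It looks like a bird", backend)
  expect_equal(pos_bigrams(tt),
               c("pronoun verb", "verb preposition",
                 "preposition determiner", "determiner noun"))
  expect_equal(pos_bigrams(manual_turn("yes", "interjection")), character(0))
  expect_equal(pos_bigrams(manual_turn(c("go", "run", "jump"),
                                       c("verb", "verb", "verb"))),
               c("verb verb", "verb verb"))
  # n tokens -> n - 1 bigrams
  for (n in 2:6) {
    tt <- manual_turn(letters[1:n], rep("noun", n))
    expect_length(pos_bigrams(tt), n - 1)
  }
})

test_that("lexical score matches hand-computed cosines", {
  prime <- manual_turn(c("the", "bird", "flies"), rep("x", 3))
  resp <- manual_turn(c("the", "bird", "sits"), rep("x", 3))
  expect_equal(lexical_score(prime, resp), 2 / 3, tolerance = 1e-12)
  expect_equal(lexical_score(prime, prime), 1)
  disjoint <- manual_turn(c("a", "square"), rep("x", 2))
  expect_equal(lexical_score(prime, disjoint), 0)
  empty <- manual_turn(character(0), character(0))
  expect_true(is.na(lexical_score(prime, empty)))
})

test_that("syntactic score matches hand-computed cosines", {
  # prime bigrams {DT NN, NN VB}; response {DT NN, NN NN} -> cos = 1/2
  prime <- manual_turn(c("the", "bird", "flies"), c("DT", "NN", "VB"))
  resp <- manual_turn(c("the", "bird", "house"), c("DT", "NN", "NN"))
  expect_equal(syntactic_score(prime, resp), 0.5, tolerance = 1e-12)
  expect_equal(syntactic_score(prime, prime), 1)
  other <- manual_turn(c("go", "fast"), c("VB", "RB"))
  expect_equal(syntactic_score(prime, other), 0)
  short <- manual_turn("yes", "UH")
  expect_true(is.na(syntactic_score(prime, short)))
})

test_that("scores agree with an independent cosine oracle on toy exchanges", {
  set.seed(42)
  vocab <- c("bird", "shape", "triangle", "the", "a", "big", "small",
             "face", "left", "right")
  tags <- c("noun", "determiner", "adjective", "verb", "adverb")
  for (i in 1:12) {
    np <- sample(2:6, 1)
    nr <- sample(2:6, 1)
    prime <- manual_turn(sample(vocab, np, replace = TRUE),
                         sample(tags, np, replace = TRUE))
    resp <- manual_turn(sample(vocab, nr, replace = TRUE),
                        sample(tags, nr, replace = TRUE))
    expect_equal(lexical_score(prime, resp),
                 oracle_cosine(prime$lemmas, resp$lemmas),
                 tolerance = 1e-12)
    expect_equal(syntactic_score(prime, resp),
                 oracle_cosine(pos_bigrams(prime), pos_bigrams(resp)),
                 tolerance = 1e-12)
  }
})

test_that("scores are symmetric and invariant to token duplication", {
  set.seed(7)
  vecs <- matrix(rnorm(20), 10, 2,
                 dimnames = list(c("bird", "shape", "big", "small", "face",
                                   "left", "right", "the", "a", "see"), NULL))
  model <- embedding_model(vecs)
  for (i in 1:8) {
    np <- sample(2:5, 1)
    prime <- manual_turn(sample(rownames(vecs), np, replace = TRUE),
                         sample(c("noun", "verb", "adjective"), np,
                                replace = TRUE))
    nr <- sample(2:5, 1)
    resp <- manual_turn(sample(rownames(vecs), nr, replace = TRUE),
                        sample(c("noun", "verb", "adjective"), nr,
                               replace = TRUE))
    expect_equal(lexical_score(prime, resp), lexical_score(resp, prime))
    expect_equal(syntactic_score(prime, resp), syntactic_score(resp, prime))
    expect_equal(semantic_score(prime, resp, model),
                 semantic_score(resp, prime, model))
    doubled <- manual_turn(rep(resp$tokens, each = 2),
                           rep(resp$pos, each = 2))
    expect_equal(lexical_score(prime, doubled), lexical_score(prime, resp),
                 tolerance = 1e-12)
    expect_equal(semantic_score(prime, doubled, model),
                 semantic_score(prime, resp, model), tolerance = 1e-12)
  }
})

test_that("semantic score behaves like a cosine over mean vectors", {
  vecs <- rbind(bird = c(1, 0), flamingo = c(1, 1) / sqrt(2),
                opposite = c(-1, 0))
  model <- embedding_model(vecs)
  prime <- manual_turn("bird", "noun")
  resp_same <- manual_turn("bird", "noun")
  expect_equal(semantic_score(prime, resp_same, model), 1)
  resp_anti <- manual_turn("opposite", "noun")
  expect_equal(semantic_score(prime, resp_anti, model), -1)
  resp_45 <- manual_turn("flamingo", "noun")
  expect_equal(semantic_score(prime, resp_45, model), sqrt(2) / 2,
               tolerance = 1e-12)
  oov <- manual_turn("zzz", "noun")
  expect_true(is.na(semantic_score(prime, oov, model)))
})

test_that("corpus embeddings are deterministic and context-sensitive", {
  sents <- c(rep(list(c("the", "cat", "sat", "on", "the", "mat")), 6),
             rep(list(c("the", "feline", "sat", "on", "the", "mat")), 6),
             rep(list(c("a", "rocket", "flew", "to", "space")), 6))
  m1 <- train_corpus_embeddings(sents, dims = 8)
  m2 <- train_corpus_embeddings(sents, dims = 8)
  expect_identical(m1$vectors, m2$vectors)
  expect_equal(ncol(m1$vectors), 8)
  cos <- function(a, b) cosine_similarity(m1$vectors[a, ], m1$vectors[b, ])
  expect_gt(cos("cat", "feline"), cos("cat", "rocket"))
  expect_gt(cos("cat", "feline"), 0.9)
  # tiny corpus refuses and directs to injected vectors
  expect_error(train_corpus_embeddings(list(c("a", "b")), dims = 4),
               "inject", class = "entrainr_invalid_input")
})

test_that("score_conversation pairs examiner primes with participant responses", {
  roles4 <- list(
    manual_turn(c("a", "bird"), c("determiner", "noun"), "examiner", 1L),
    manual_turn(c("a", "bird"), c("determiner", "noun"), "participant", 2L),
    manual_turn(c("the", "shape"), c("determiner", "noun"), "examiner", 3L),
    manual_turn(c("the", "shape"), c("determiner", "noun"), "participant", 4L))
  sc <- score_conversation(roles4)
  expect_equal(nrow(sc), 2)
  expect_equal(sc$lexical, c(1, 1))
  expect_equal(sc$response_turn, sc$prime_turn + 1L)

  # a leading participant turn is not a response to anything
  roles3 <- list(
    manual_turn(c("big", "shape"), c("adjective", "noun"), "participant", 1L),
    manual_turn(c("the", "square"), c("determiner", "noun"), "examiner", 2L),
    manual_turn(c("a", "square"), c("determiner", "noun"), "participant", 3L))
  sc3 <- score_conversation(roles3)
  expect_equal(nrow(sc3), 1)
  expect_equal(sc3$prime_turn, 2L)

  expect_equal(nrow(score_conversation(roles4[1])), 0)
})

test_that("expected lexical score increases with the reuse probability", {
  mean_lex <- function(p_lex, seed) {
    cfg <- generator_config(n_dyads = 3, turns_per_conversation = 14,
                            p_lex = p_lex, seed = seed)
    coh <- generate_cohort(cfg)
    scores <- unlist(lapply(coh$conversations, function(cv) {
      score_conversation(build_turns(cv), backend = backend)$lexical
    }))
    mean(scores, na.rm = TRUE)
  }
  for (seed in c(11, 12, 13)) {
    lo <- mean_lex(0.05, seed)
    mid <- mean_lex(0.5, seed)
    hi <- mean_lex(0.95, seed)
    expect_lt(lo, mid)
    expect_lt(mid, hi)
  }
})
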