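test_that("surrogate pairings draw examiners from different dyads", {
  p <- make_surrogate_dyads(c("d1", "d2"), seed = 1)
  expect_equal(nrow(p), 2)
  expect_true(all(p$participant_dyad != p$examiner_dyad))
  expect_setequal(p$examiner_dyad, c("d2", "d1"))

  expect_error(make_surrogate_dyads("only", seed = 1),
               class = "entrainr_invalid_input")

  many1 <- make_surrogate_dyads(paste0("d", 1:8), n_per_dyad = 2, seed = 42)
  many2 <- make_surrogate_dyads(paste0("d", 1:8), n_per_dyad = 2, seed = 42)
  expect_identical(many1, many2)
  expect_true(all(many1$participant_dyad != many1$examiner_dyad))
})

test_that("surrogate scoring interleaves positionally up to the shorter dyad", {
  mk_dyad <- function(n_ex) {
    turns <- list()
    for (k in seq_len(2 * n_ex)) {
      role <- if (k %% 2 == 1) "examiner" else "participant"
      turns[[k]] <- manual_turn(c("the", "shape"), c("determiner", "noun"),
                                role, as.integer(k))
    }
    turns
  }
  turns_by_dyad <- list(dA = mk_dyad(6), dB = mk_dyad(4))
  pairing <- tibble::tibble(pseudo_dyad_id = "dA~dB", participant_dyad = "dA",
                            examiner_dyad = "dB", seed = 1L)
  sc <- score_surrogate_conversations(pairing, turns_by_dyad)
  expect_equal(nrow(sc), 4)   # min(6 participant, 4 examiner source turns)

  self <- tibble::tibble(pseudo_dyad_id = "x", participant_dyad = "dA",
                         examiner_dyad = "dA", seed = 1L)
  expect_error(score_surrogate_conversations(self, turns_by_dyad),
               class = "entrainr_invalid_input")
})

test_that("surrogate and real lexical scores agree on an exchangeable corpus", {
  # all speakers draw from the same closed vocabulary with no reuse:
  # real dyads carry no alignment signal beyond chance, so surrogate
  # pairings should look the same
  cfgs <- lapply(1:6, function(i) {
    generator_config(n_dyads = 1, turns_per_conversation = 20, p_lex = 0,
                     p_syn = 0, w_sem = 0, seed = 100 + i)
  })
  convs <- lapply(cfgs, function(cfg) generate_cohort(cfg)$conversations[[1]])
  for (i in seq_along(convs)) convs[[i]]$dyad_id <- paste0("dy", i)
  backend <- lexicon_backend()
  tokenized <- lapply(convs, function(cv) {
    turns <- build_turns(cv)
    lapply(seq_len(nrow(turns)), function(i)
      lemmatize_and_tag(turns[i, ], backend))
  })
  names(tokenized) <- paste0("dy", 1:6)
  real <- unlist(lapply(tokenized, function(tt)
    score_conversation(tt, backend = backend)$lexical))
  pairing <- make_surrogate_dyads(paste0("dy", 1:6), seed = 3)
  surr <- score_surrogate_conversations(pairing, tokenized,
                                        backend = backend)$lexical
  expect_lt(abs(mean(real, na.rm = TRUE) - mean(surr, na.rm = TRUE)), 0.08)
})

test_that("standardization uses the population sd and drops constants", {
  z <- standardize_variable(c(1, 2, 3))
  expect_equal(z$values, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(z$mean, 2)
  expect_false(z$dropped)

  expect_warning(zc <- standardize_variable(rep(5, 10)), "constant")
  expect_true(zc$dropped)
  expect_null(zc$values)

  # idempotence: re-standardizing standardized values changes nothing
  z2 <- standardize_variable(z$values)
  expect_equal(z2$values, z$values, tolerance = 1e-12)
})

test_that("entrainment distance is a symmetric non-negative difference", {
  expect_equal(entrainment_distance(1.5, -0.5), 2)
  expect_equal(entrainment_distance(0.3, 0.3), 0)
  set.seed(2)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(entrainment_distance(x, y), entrainment_distance(y, x))
  expect_true(all(entrainment_distance(x, y) >= 0))
  expect_true(all((entrainment_distance(x, y) == 0) == (x == y)))
})

test_that("mean distance matches exhaustive enumeration on a small unit set", {
  xa <- c(-1.2, 0.3, 0.8, 1.9)
  xb <- c(-0.4, 0.0, 2.2)
  # brute-force double loop oracle
  acc <- 0
  for (a in xa) for (b in xb) acc <- acc + abs(a - b)
  oracle <- acc / (length(xa) * length(xb))
  pairs <- expand.grid(a = xa, b = xb)
  expect_equal(mean(entrainment_distance(pairs$a, pairs$b)), oracle,
               tolerance = 1e-12)
})

test_that("pair resampling honours condition constraints and draw counts", {
  units <- tibble::tibble(
    dyad_id = rep(c("d1", "d2"), each = 4),
    role = rep(c("participant", "participant", "examiner", "examiner"), 2),
    dialog_act = rep(c("query_yn", "statement"), 4),
    x = c(0, 0, 0, 100, 0, 0, 0, 100))
  # same-dyad same-da: participant query_yn (0) pairs with examiner query_yn
  # (0); participant statement (0) with examiner statement (100)
  s <- sample_prosodic_pairs(units, "x", "same_dyad_same_da",
                             n_draws = 200, seed = 1)
  expect_equal(nrow(s), 400)   # 200 per participant
  expect_true(all(s$x %in% c(0, 100)))
  # cross-da draws flip the mapping
  s2 <- sample_prosodic_pairs(units, "x", "same_dyad_cross_da",
                              n_draws = 50, seed = 1)
  expect_true(all(s2$x %in% c(0, 100)))

  # both speakers single equal-valued unit: all distances zero
  eq <- tibble::tibble(dyad_id = "d1", role = c("participant", "examiner"),
                       dialog_act = "statement", x = c(1.3, 1.3))
  s3 <- sample_prosodic_pairs(eq, "x", "same_dyad_same_da", n_draws = 20,
                              seed = 2)
  expect_true(all(s3$x == 0))

  # disjoint tag support: cell flagged missing
  disj <- tibble::tibble(dyad_id = "d1", role = c("participant", "examiner"),
                         dialog_act = c("query_yn", "statement"),
                         x = c(0, 1))
  s4 <- sample_prosodic_pairs(disj, "x", "same_dyad_same_da", n_draws = 10,
                              seed = 3)
  expect_equal(nrow(s4), 0)
  expect_equal(attr(s4, "missing_cells"), "d1")

  # determinism
  sa <- sample_prosodic_pairs(units, "x", "cross_dyad_same_da", n_draws = 100,
                              seed = 9)
  sb <- sample_prosodic_pairs(units, "x", "cross_dyad_same_da", n_draws = 100,
                              seed = 9)
  expect_identical(sa, sb)
})

test_that("aggregation reproduces a streaming-mean oracle", {
  const <- tibble::tibble(participant = "p1",
                          condition = "same_dyad_same_da",
                          draw = 1:1000, x = 0.37)
  tab <- aggregate_distances(const, variables = "x")
  expect_equal(tab$mean_distance, 0.37)
  expect_equal(tab$n_samples, 1000L)
  expect_equal(tab$conversation_type, "real")
  expect_equal(tab$da_pairing, "same")

  set.seed(4)
  two <- tibble::tibble(
    participant = rep(c("p1", "p2"), each = 100),
    condition = rep(c("cross_dyad_cross_da", "same_dyad_cross_da"), each = 100),
    draw = rep(1:100, 2), x = runif(200))
  tab2 <- aggregate_distances(two, variables = "x")
  expect_equal(nrow(tab2), 2)
  oracle <- tapply(two$x, two$participant, mean)
  expect_equal(tab2$mean_distance[tab2$participant == "p1"],
               unname(oracle["p1"]), tolerance = 1e-12)
  expect_equal(tab2$da_pairing, c("different", "different"))
  expect_equal(tab2$conversation_type, c("surrogate", "real"))
})

test_that("real and surrogate distances are exchangeable under zero coupling", {
  # across simulated cohorts with rho = 0, the real-minus-surrogate mean
  # distance difference is centred at zero
  diffs <- vapply(1:60, function(i) {
    cfg <- generator_config(n_dyads = 5, turns_per_conversation = 14,
                            rho = 0, seed = 5000 + i)
    units <- generate_cohort(cfg, features_only = TRUE)$units
    units$f0_mean <- standardize_variable(units$f0_mean)$values
    s_real <- sample_prosodic_pairs(units, "f0_mean", "same_dyad_same_da",
                                    n_draws = 60, seed = i)
    s_sur <- sample_prosodic_pairs(units, "f0_mean", "cross_dyad_same_da",
                                   n_draws = 60, seed = i + 1)
    if (nrow(s_real) == 0 || nrow(s_sur) == 0) return(NA_real_)
    mean(s_real$f0_mean) - mean(s_sur$f0_mean)
  }, numeric(1))
  diffs <- diffs[!is.na(diffs)]
  expect_gt(length(diffs), 50)
  mc_se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 2 * mc_se + 1e-8)
})

test_that("positive coupling shrinks real distances below the baseline", {
  hits <- vapply(1:30, function(i) {
    cfg <- generator_config(n_dyads = 20, turns_per_conversation = 10,
                            rho = 0.7, seed = 7000 + i)
    units <- generate_cohort(cfg, features_only = TRUE)$units
    units$f0_mean <- standardize_variable(units$f0_mean)$values
    s_real <- sample_prosodic_pairs(units, "f0_mean", "same_dyad_same_da",
                                    n_draws = 60, seed = i)
    s_sur <- sample_prosodic_pairs(units, "f0_mean", "cross_dyad_same_da",
                                   n_draws = 60, seed = i + 1)
    mean(s_real$f0_mean) < mean(s_sur$f0_mean)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
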