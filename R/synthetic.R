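# generating model for the per-unit prosodic variables: three measurement
# blocks, each split into two variable families that load on separate latent
# factors (loading 0.8), mirroring the envelope-vs-trend interpretation of
# the factor solutions
synthetic_variable_spec <- function() {
  tibble::tribble(
    ~variable,          ~block,                ~family,     ~mu,  ~sigma,
    "f0_mean",          "f0_dialog_act",       "envelope",   2.0,  1,
    "f0_max",           "f0_dialog_act",       "envelope",   5.0,  1,
    "f0_range",         "f0_dialog_act",       "envelope",   6.0,  1,
    "base_slope",       "f0_dialog_act",       "trend",     -1.0,  1,
    "mid_slope",        "f0_dialog_act",       "trend",     -1.0,  1,
    "top_slope",        "f0_dialog_act",       "trend",     -1.0,  1,
    "syl_f0_mean",      "f0_salient_syllable", "envelope",   2.5,  1,
    "syl_f0_max",       "f0_salient_syllable", "envelope",   4.0,  1,
    "syl_c1",           "f0_salient_syllable", "trend",      0.0,  1,
    "syl_c2",           "f0_salient_syllable", "trend",     -2.0,  1,
    "syll_rate",        "rhythm_dialog_act",   "rate",       4.0,  1,
    "syll_dur",         "rhythm_dialog_act",   "rate",       0.18, 1,
    "energy_influence", "rhythm_dialog_act",   "influence",  0.5,  1,
    "f0_influence",     "rhythm_dialog_act",   "influence",  0.35, 1
  )
}

#' Configuration for the synthetic dyad generator
#'
#' Defines the study conditions a generated cohort emulates: dyad and turn
#' counts, the cross-speaker prosodic coupling, and the lexical/syntactic/
#' semantic reuse behaviour of the participant.
#'
#' @param n_dyads dyads in the cohort (default 20).
#' @param turns_per_conversation alternating turns per conversation
#'   (default 30; the task alternates describer roles over several rounds).
#' @param cohort cohort label for the generated dyads.
#' @param rho prosodic coupling in `[-1, 1]`: scalar, or named per family
#'   (`envelope`, `trend`, `rate`, `influence`). The participant's
#'   session-level register on each variable is `rho` times the examiner's
#'   (about the population mean): 0 = independent speakers, positive =
#'   convergence, negative = divergence inflation; at `rho = 1` with zero
#'   noise the speakers' unit values coincide exactly.
#' @param p_lex probability that the participant reuses each examiner
#'   content lemma in the response (default 0.3).
#' @param p_syn probability that the participant reuses the examiner's POS
#'   template (default 0.3).
#' @param w_sem probability that the participant draws content words from
#'   the examiner's current topic rather than a random one (default 0.7).
#' @param noise_sd sd of unit-level scatter around each speaker's session
#'   register, in units of the variable sd (default 0.5).
#' @param factor_loading loading of each variable on its family factor
#'   (default 0.8).
#' @param incomplete_rate probability of inserting an incomplete (abandoned)
#'   utterance into a turn (default 0.05).
#' @param split_turn_prob probability that a turn is realized as two
#'   contiguous utterances rather than one (default 0.1).
#' @param seed mandatory integer seed.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_dyads = 20, turns_per_conversation = 30,
                             cohort = "asd", rho = 0, p_lex = 0.3,
                             p_syn = 0.3, w_sem = 0.7, noise_sd = 0.5,
                             factor_loading = 0.8, incomplete_rate = 0.05,
                             split_turn_prob = 0.1, seed) {
  if (missing(seed)) abort("seed is mandatory", class = "entrainr_invalid_input")
  stopifnot(all(abs(rho) <= 1), p_lex >= 0, p_lex <= 1, p_syn >= 0,
            p_syn <= 1, w_sem >= 0, w_sem <= 1, noise_sd >= 0)
  structure(list(n_dyads = n_dyads,
                 turns_per_conversation = turns_per_conversation,
                 cohort = cohort, rho = rho, p_lex = p_lex, p_syn = p_syn,
                 w_sem = w_sem, noise_sd = noise_sd,
                 factor_loading = factor_loading,
                 incomplete_rate = incomplete_rate,
                 split_turn_prob = split_turn_prob,
                 seed = as.integer(seed)),
            class = "generator_config")
}

rho_for_family <- function(rho, family) {
  if (length(rho) == 1 && is.null(names(rho))) return(unname(rho))
  out <- rho[family]
  ifelse(is.na(out), 0, unname(out))
}

examiner_da <- c(query_yn = 0.25, query_wh = 0.20, check = 0.15,
                 instruct = 0.10, statement = 0.20, align = 0.05,
                 clarify = 0.05)
participant_da <- c(reply_y = 0.20, reply_n = 0.10, reply_w = 0.20,
                    statement = 0.30, acknowledge = 0.15, check = 0.05)

pos_templates <- list(
  c("pronoun", "verb", "preposition", "determiner", "noun"),
  c("determiner", "adjective", "noun"),
  c("pronoun", "verb", "determiner", "adjective", "noun"),
  c("determiner", "noun", "verb", "adverb"),
  c("interjection", "pronoun", "verb", "determiner", "noun"),
  c("pronoun", "verb", "adjective"),
  c("verb", "pronoun", "verb", "determiner", "noun"),
  c("interjection")
)

# family-structured standard normal vector: latent factor per family
# (loading lambda) plus unique part, one value per variable in `spec`
structured_draw <- function(spec, fam_names, loading) {
  g <- setNames(rnorm(length(fam_names)), fam_names)[spec$family]
  loading * g + sqrt(1 - loading^2) * rnorm(nrow(spec))
}

#' Generate a synthetic cohort of dyadic conversations
#'
#' Each dyad alternates examiner and participant turns over a closed
#' tangram-description vocabulary. Prosodic features are generated per
#' dialog-act unit from a latent two-factor model per measurement block at
#' two levels: a speaker-session register (the stable component of the
#' speaker's prosody) and unit-level scatter scaled by `noise_sd`. The
#' participant's register on each variable couples to the examiner's with
#' the configured `rho` (`x_P = mu + rho * (x_E - mu) + noise`), so positive
#' `rho` shrinks same-dyad distances relative to the cross-dyad baseline and
#' negative `rho` inflates them. Lexical, syntactic, and semantic alignment
#' is controlled by the reuse probabilities.
#'
#' @param config a [generator_config()].
#' @param features_only skip transcript text generation and return only the
#'   unit feature table (fast path for simulation studies).
#' @return a list with `conversations` (list of [conversation()], `NULL`
#'   when `features_only`), `units` (unit feature tibble with one column per
#'   variable in the generating spec), and `ground_truth` (generating
#'   parameters, per-variable means and sds).
#' @export
generate_cohort <- function(config, features_only = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  spec <- synthetic_variable_spec()
  loading <- config$factor_loading
  fam_names <- unique(spec$family)
  rho_v <- vapply(fam_names, function(f) rho_for_family(config$rho, f),
                  numeric(1))
  lex <- if (!features_only) default_lexicon() else NULL
  conversations <- if (features_only) NULL else vector("list", config$n_dyads)
  unit_rows <- vector("list", config$n_dyads)
  for (d in seq_len(config$n_dyads)) {
    dyad_id <- sprintf("%s_d%02d", config$cohort, d)
    n_turns <- config$turns_per_conversation
    roles <- rep(c("examiner", "participant"), length.out = n_turns)
    das <- character(n_turns)
    das[roles == "examiner"] <- sample(names(examiner_da),
                                       sum(roles == "examiner"),
                                       replace = TRUE, prob = examiner_da)
    das[roles == "participant"] <- sample(names(participant_da),
                                          sum(roles == "participant"),
                                          replace = TRUE,
                                          prob = participant_da)
    # prosodic features per turn (one dialog-act unit per turn): the
    # examiner's session register b_E sets the speaker-level value of each
    # variable; the participant's register couples to it with rho; units
    # scatter around their speaker's register with sd noise_sd * sigma
    rho_var <- rho_v[spec$family]
    b_e <- spec$sigma * structured_draw(spec, fam_names, loading)
    feat <- matrix(NA_real_, n_turns, nrow(spec),
                   dimnames = list(NULL, spec$variable))
    for (k in seq_len(n_turns)) {
      w <- config$noise_sd * spec$sigma *
        structured_draw(spec, fam_names, loading)
      feat[k, ] <- if (roles[k] == "examiner") {
        spec$mu + b_e + w
      } else {
        spec$mu + rho_var * b_e + w
      }
    }
    unit_rows[[d]] <- dplyr::bind_cols(
      tibble::tibble(dyad_id = dyad_id, role = roles,
                     unit_index = seq_len(n_turns), dialog_act = das),
      tibble::as_tibble(feat))
    if (!features_only) {
      conversations[[d]] <- synthesize_transcript(dyad_id, roles, das,
                                                  config, lex)
    }
  }
  population <- tibble::tibble(
    variable = spec$variable,
    mean = spec$mu,
    sd = spec$sigma * sqrt(1 + config$noise_sd^2))
  list(conversations = conversations,
       units = dplyr::bind_rows(unit_rows),
       ground_truth = list(config = unclass(config), variable_spec = spec,
                           rho = rho_v, population = population))
}

sample_word <- function(lex, pos, topic = NULL) {
  pool <- lex[lex$pos == pos, ]
  if (!is.null(topic)) {
    tp <- pool[pool$topic == topic, ]
    if (nrow(tp) > 0) pool <- tp
  }
  if (nrow(pool) == 0) return(NULL)
  pool[sample.int(nrow(pool), 1L), ]
}

content_pos <- c("noun", "adjective", "verb")
topics <- c("shape", "animal", "object")

synthesize_transcript <- function(dyad_id, roles, das, config, lex) {
  n_turns <- length(roles)
  topic_seq <- topics[((seq_len(n_turns) - 1) %/% 6) %% length(topics) + 1]
  t_now <- 0
  utt_rows <- list()
  prev_examiner <- NULL   # list(lemmas_by_pos, template, topic)
  for (k in seq_len(n_turns)) {
    if (roles[k] == "examiner") {
      template <- pos_templates[[sample.int(length(pos_templates), 1L)]]
      words <- character(0)
      slot_words <- character(length(template))
      for (si in seq_along(template)) {
        w <- sample_word(lex, template[si],
                         if (template[si] %in% content_pos) topic_seq[k]
                         else NULL)
        if (is.null(w)) next
        slot_words[si] <- w$word
        words <- c(words, w$word)
      }
      keep <- nzchar(slot_words)
      prev_examiner <- list(template = template[keep],
                            slot_words = slot_words[keep],
                            topic = topic_seq[k])
    } else {
      # response construction: the examiner's content lemmas are each reused
      # with probability p_lex; the syntactic frame (POS template, including
      # its function words) is reused with probability p_syn; remaining
      # content slots are filled from the examiner's topic with probability
      # w_sem, otherwise from a random topic. With p_lex = p_syn = 1 the
      # response echoes the prime exactly.
      reuse_template <- !is.null(prev_examiner) && runif(1) < config$p_syn
      template <- if (reuse_template) prev_examiner$template
                  else pos_templates[[sample.int(length(pos_templates), 1L)]]
      reused <- list()
      if (!is.null(prev_examiner)) {
        is_content <- prev_examiner$template %in% content_pos
        for (si in which(is_content)) {
          if (runif(1) < config$p_lex) {
            reused[[length(reused) + 1L]] <-
              list(word = prev_examiner$slot_words[si],
                   pos = prev_examiner$template[si])
          }
        }
      }
      topic_here <- if (!is.null(prev_examiner) && runif(1) < config$w_sem) {
        prev_examiner$topic
      } else {
        topics[sample.int(length(topics), 1L)]
      }
      words <- character(0)
      for (si in seq_along(template)) {
        pos <- template[si]
        if (pos %in% content_pos) {
          hit <- which(vapply(reused, function(w) w$pos == pos, logical(1)))
          if (length(hit) > 0) {
            words <- c(words, reused[[hit[1]]]$word)
            reused <- reused[-hit[1]]
            next
          }
          w <- sample_word(lex, pos, topic_here)
          if (!is.null(w)) words <- c(words, w$word)
        } else if (reuse_template) {
          words <- c(words, prev_examiner$slot_words[si])
        } else {
          w <- sample_word(lex, pos, NULL)
          if (!is.null(w)) words <- c(words, w$word)
        }
      }
      # reused lemmas not consumed by the frame are still produced, keeping
      # the per-lemma reuse probability interpretable
      for (w in reused) words <- c(words, w$word)
    }
    if (length(words) == 0) words <- "okay"
    sp <- if (roles[k] == "examiner") paste0("E_", dyad_id)
          else paste0("P_", dyad_id)
    if (runif(1) < config$incomplete_rate) {
      dur0 <- 0.3
      utt_rows[[length(utt_rows) + 1L]] <- tibble::tibble(
        speaker_id = sp, role = roles[k], t_start = t_now,
        t_end = t_now + dur0, dialog_act = "UNTAGGED", complete = FALSE,
        text = paste0(words[1], "-"))
      t_now <- t_now + dur0 + 0.1
    }
    split <- length(words) >= 4 && runif(1) < config$split_turn_prob
    parts <- if (split) {
      cut <- sample.int(length(words) - 1L, 1L)
      list(words[seq_len(cut)], words[-seq_len(cut)])
    } else list(words)
    for (ptxt in parts) {
      dur <- 0.35 * length(ptxt) + 0.2
      utt_rows[[length(utt_rows) + 1L]] <- tibble::tibble(
        speaker_id = sp, role = roles[k], t_start = t_now,
        t_end = t_now + dur, dialog_act = das[k], complete = TRUE,
        text = paste(ptxt, collapse = " "))
      t_now <- t_now + dur + 0.05
    }
    t_now <- t_now + 0.15
  }
  conversation(dyad_id, dplyr::bind_rows(utt_rows), cohort = config$cohort)
}

#' Render synthetic pitch and energy tracks realizing target unit features
#'
#' Builds 100 Hz tracks over a unit of the given duration whose extracted
#' features recover the targets: a pitch contour with the target mean (Hz)
#' and semitone slope, and an energy contour with flat-topped bursts at the
#' target salient-syllable rate.
#'
#' @param duration unit duration in seconds.
#' @param f0_mean_hz target mean F0 in Hz.
#' @param f0_slope_st target F0 slope in semitones per second.
#' @param syll_rate target salient syllables per second; must satisfy
#'   `syll_rate * duration >= 1`.
#' @return a list with `pitch` (a `pitch_track`) and `energy` (an
#'   `energy_track`).
#' @export
synthesize_tracks <- function(duration, f0_mean_hz, f0_slope_st, syll_rate) {
  if (syll_rate * duration < 1) {
    abort("infeasible targets: syll_rate * duration < 1",
          class = "entrainr_invalid_input")
  }
  tt <- seq(0, duration, by = 0.01)
  st <- f0_slope_st * (tt - duration / 2)
  f0 <- f0_mean_hz * 2^(st / 12)
  period <- 1 / syll_rate
  burst <- 0.15
  phase <- tt %% period
  rms <- ifelse(phase < burst, 1, 0.05)
  # soften burst edges by one frame to avoid knife-edge transitions
  edge <- abs(phase - burst) < 0.005 | phase < 0.005
  rms[edge] <- 0.5
  pitch <- structure(tibble::tibble(time = tt, f0 = f0),
                     class = c("pitch_track", "tbl_df", "tbl", "data.frame"))
  energy <- structure(tibble::tibble(time = tt, rms = rms),
                      class = c("energy_track", "tbl_df", "tbl", "data.frame"))
  list(pitch = pitch, energy = energy)
}

#' Detection-rate study over a grid of coupling values
#'
#' For each grid point, generates case and control cohorts with the given
#' couplings, runs the prosodic distance pipeline on one variable, fits the
#' mixed-effects contrast, and records the classification. Reports the rate
#' of each classification, the rate of a significant conversation-type
#' effect, the interaction detection rate, and Monte-Carlo standard errors.
#'
#' @param grid a data frame with columns `rho_case`, `rho_control`.
#' @param n_replicates replicates per grid point.
#' @param config base [generator_config()] (its `rho` and `seed` are
#'   overridden per replicate).
#' @param n_draws resampling draws per condition (default 200 for
#'   simulation studies; analyses of real cohorts use 1000).
#' @param variable outcome variable for the contrast (default `"f0_mean"`).
#' @param alpha significance level.
#' @param seed master seed.
#' @return a tibble, one row per grid point, with detection rates and
#'   `mc_se` (binomial Monte-Carlo SE of the significance rate).
#' @export
power_study <- function(grid, n_replicates, config = generator_config(seed = 1),
                        n_draws = 200, variable = "f0_mean", alpha = 0.05,
                        seed = 1) {
  out <- list()
  for (gi in seq_len(nrow(grid))) {
    cls <- character(n_replicates)
    sig <- logical(n_replicates)
    inter <- logical(n_replicates)
    for (r in seq_len(n_replicates)) {
      s <- derive_seed(seed, gi * 100003L + r)
      rep_res <- simulate_and_classify(
        rho_case = grid$rho_case[gi], rho_control = grid$rho_control[gi],
        config = config, n_draws = n_draws, variable = variable,
        alpha = alpha, seed = s)
      cls[r] <- rep_res$classification
      sig[r] <- rep_res$p_value < alpha
      inter[r] <- rep_res$group_difference
    }
    p_sig <- mean(sig)
    out[[gi]] <- tibble::tibble(
      rho_case = grid$rho_case[gi], rho_control = grid$rho_control[gi],
      n_replicates = n_replicates,
      rate_entrainment = mean(cls == "entrainment"),
      rate_disentrainment = mean(cls == "disentrainment"),
      rate_none = mean(cls == "none"),
      rate_significant = p_sig,
      rate_interaction = mean(inter),
      mc_se = sqrt(p_sig * (1 - p_sig) / n_replicates))
  }
  dplyr::bind_rows(out)
}

# one replicate of the two-group prosodic contrast on a single variable.
# Standardization uses the generator's known population scale (carried in
# GroundTruth): estimating the scale inside each small simulated cohort
# couples participants through the shared scale estimate and makes the
# calibration study conservative, which is a property of scale estimation,
# not of the contrast under study.
simulate_and_classify <- function(rho_case, rho_control, config, n_draws,
                                  variable, alpha, seed) {
  cfg_case <- config
  cfg_case$rho <- rho_case
  cfg_case$cohort <- "asd"
  cfg_case$seed <- seed
  cfg_ctrl <- config
  cfg_ctrl$rho <- rho_control
  cfg_ctrl$cohort <- "asd_control"
  cfg_ctrl$seed <- derive_seed(seed, 7L)
  case <- generate_cohort(cfg_case, features_only = TRUE)
  ctrl <- generate_cohort(cfg_ctrl, features_only = TRUE)
  units <- dplyr::bind_rows(case$units, ctrl$units)
  pop <- case$ground_truth$population
  pop <- pop[pop$variable == variable, ]
  units[[variable]] <- (units[[variable]] - pop$mean) / pop$sd
  groups <- tibble::tibble(
    participant = unique(units$dyad_id),
    group = ifelse(startsWith(unique(units$dyad_id), "asd_control"),
                   "control", "case"))
  frame <- prosodic_model_frame(units, variable, groups,
                                n_draws = n_draws,
                                seed = derive_seed(seed, 11L),
                                standardize = "none")
  res <- fit_prosodic_model(frame)
  classify_entrainment(res, alpha = alpha, smaller_is_entrained = TRUE)
}

#' Build a prosodic model frame for one variable from raw units
#'
#' Standardizes the variable over the pooled stratum, resamples all four
#' baseline conditions, aggregates per-cell mean distances, and attaches
#' group labels: one ready-to-fit row per participant x conversation type x
#' dialog-act pairing.
#'
#' @param units pooled unit feature table (both groups).
#' @param variable variable column name.
#' @param groups tibble mapping `participant` (dyad id) to `group`
#'   (`"case"`/`"control"`).
#' @param n_draws draws per condition.
#' @param seed integer seed.
#' @param standardize `"stratum"` (default; z-scale the variable over the
#'   pooled stratum) or `"none"` (the variable is already on a known scale,
#'   e.g. standardized by generator ground truth in simulation studies).
#' @return a tibble with columns `participant`, `group`,
#'   `conversation_type`, `da_pairing`, `score`.
#' @export
prosodic_model_frame <- function(units, variable, groups, n_draws = 1000,
                                 seed, standardize = c("stratum", "none")) {
  standardize <- match.arg(standardize)
  if (standardize == "stratum") {
    z <- standardize_variable(units[[variable]])
    if (z$dropped) abort("variable is constant",
                         class = "entrainr_invalid_input")
    units[[variable]] <- z$values
  }
  samples <- dplyr::bind_rows(lapply(seq_along(prosody_conditions), function(ci) {
    sample_prosodic_pairs(units, variable, prosody_conditions[ci],
                          n_draws = n_draws, seed = derive_seed(seed, ci))
  }))
  tab <- aggregate_distances(samples, variables = variable)
  frame <- dplyr::inner_join(tab, groups, by = "participant")
  dplyr::transmute(frame, participant = .data$participant,
                   group = .data$group,
                   conversation_type = .data$conversation_type,
                   da_pairing = .data$da_pairing,
                   score = .data$mean_distance)
}
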