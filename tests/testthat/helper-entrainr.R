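# fixtures built in code, shared across the suite

toy_utterances <- function() {
  tibble::tibble(
    speaker_id = c("EX1", "P1", "EX1", "P1"),
    role = c("examiner", "participant", "examiner", "participant"),
    t_start = c(0, 2.1, 4.0, 6.2),
    t_end = c(2.0, 3.9, 6.0, 8.0),
    dialog_act = c("query_wh", "statement", "check", "reply_y"),
    complete = TRUE,
    text = c("what do you see", "it looks like a bird",
             "does it face left", "yes it does")
  )
}

toy_conversation <- function() {
  conversation("dyad01", toy_utterances(), cohort = "asd")
}

# independent oracle: cosine over explicit count tables
oracle_cosine <- function(a, b) {
  vocab <- union(a, b)
  ca <- as.numeric(table(factor(a, levels = vocab)))
  cb <- as.numeric(table(factor(b, levels = vocab)))
  num <- sum(ca * cb)
  den <- sqrt(sum(ca^2)) * sqrt(sum(cb^2))
  if (den == 0) NA_real_ else num / den
}

# tokenized turn built directly (bypasses the lexicon backend)
manual_turn <- function(tokens, pos, role = "participant", turn = 1L,
                        lemmas = tokens) {
  structure(list(turn = turn, role = role, tokens = tokens, lemmas = lemmas,
                 pos = pos), class = "tokenized_turn")
}

make_pitch_track <- function(time, f0) {
  structure(tibble::tibble(time = time, f0 = f0),
            class = c("pitch_track", "tbl_df", "tbl", "data.frame"))
}

make_energy_track <- function(time, rms) {
  structure(tibble::tibble(time = time, rms = rms),
            class = c("energy_track", "tbl_df", "tbl", "data.frame"))
}

# small two-group cohort of unit features for distance-pipeline tests
two_group_units <- function(n_dyads = 6, turns = 12, rho = 0, seed = 1) {
  cfg_case <- generator_config(n_dyads = n_dyads,
                               turns_per_conversation = turns,
                               rho = rho, seed = seed)
  cfg_ctrl <- generator_config(n_dyads = n_dyads,
                               turns_per_conversation = turns,
                               rho = rho, seed = seed + 1000)
  cfg_ctrl$cohort <- "asd_control"
  units <- dplyr::bind_rows(
    generate_cohort(cfg_case, features_only = TRUE)$units,
    generate_cohort(cfg_ctrl, features_only = TRUE)$units)
  groups <- tibble::tibble(
    participant = unique(units$dyad_id),
    group = ifelse(startsWith(unique(units$dyad_id), "asd_control"),
                   "control", "case"))
  list(units = units, groups = groups)
}
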