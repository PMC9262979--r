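#' Default dialog-act tag inventory
#'
#' Closed inventory of dialog-act tags for task-oriented dialogue, covering
#' queries, replies, statements, and dialogue-management moves. Utterances may
#' also carry the reserved value `"UNTAGGED"`.
#'
#' @return a character vector of tag names.
#' @export
default_dialog_acts <- function() {
  c("query_yn", "query_wh", "reply_y", "reply_n", "reply_w", "statement",
    "acknowledge", "check", "align", "clarify", "instruct", "other")
}

transcript_columns <- c("dyad_id", "speaker_id", "role", "t_start", "t_end",
                        "dialog_act", "complete", "text")

#' Construct and validate a dyadic conversation
#'
#' @param dyad_id identifier of the dyad.
#' @param utterances a data frame with columns `speaker_id`, `role`
#'   (`"participant"`/`"examiner"`), `t_start`, `t_end` (seconds),
#'   `dialog_act`, `complete` (logical), `text`.
#' @param cohort optional cohort label, one of `"asd"`, `"asd_control"`,
#'   `"asd_parent"`, `"parent_control"` (or `NA` when unknown).
#' @param dialog_acts the permitted tag inventory.
#' @return an object of class `conversation`: a list with `dyad_id`,
#'   `cohort`, and `utterances` (a tibble sorted by `t_start`, ties broken by
#'   `t_end`).
#' @export
conversation <- function(dyad_id, utterances, cohort = NA_character_,
                         dialog_acts = default_dialog_acts()) {
  utt <- tibble::as_tibble(utterances)
  required <- setdiff(transcript_columns, "dyad_id")
  missing <- setdiff(required, names(utt))
  if (length(missing) > 0) {
    abort(paste0("utterances missing column(s): ", paste(missing, collapse = ", ")),
          class = "entrainr_parse_error")
  }
  if (nrow(utt) == 0) {
    abort("no utterances", class = "entrainr_parse_error")
  }
  bad_role <- !utt$role %in% c("participant", "examiner")
  if (any(bad_role)) {
    abort(paste0("unknown role label(s) in row(s) ",
                 paste(which(bad_role), collapse = ", ")),
          class = "entrainr_parse_error")
  }
  bad_span <- !(utt$t_end > utt$t_start)
  if (any(bad_span)) {
    abort(paste0("t_end <= t_start in row(s) ",
                 paste(which(bad_span), collapse = ", ")),
          class = "entrainr_parse_error")
  }
  bad_tag <- !utt$dialog_act %in% c(dialog_acts, "UNTAGGED")
  if (any(bad_tag)) {
    abort(paste0("dialog_act outside configured inventory in row(s) ",
                 paste(which(bad_tag), collapse = ", ")),
          class = "entrainr_parse_error")
  }
  empty_complete <- utt$complete & !nzchar(trimws(utt$text))
  if (any(empty_complete)) {
    abort(paste0("complete utterance with empty text in row(s) ",
                 paste(which(empty_complete), collapse = ", ")),
          class = "entrainr_parse_error")
  }
  role_map <- unique(utt[, c("speaker_id", "role")])
  if (length(unique(role_map$speaker_id)) != 2 ||
      !setequal(role_map$role, c("participant", "examiner")) ||
      nrow(role_map) != 2) {
    abort("conversation must have exactly two speakers, one per role",
          class = "entrainr_parse_error")
  }
  if (!is.na(cohort) &&
      !cohort %in% c("asd", "asd_control", "asd_parent", "parent_control")) {
    abort(paste0("unknown cohort: ", cohort), class = "entrainr_parse_error")
  }
  utt <- utt[order(utt$t_start, utt$t_end), ]
  # overlap check within speaker (cross-speaker overlap is permitted speech)
  for (sp in unique(utt$speaker_id)) {
    u <- utt[utt$speaker_id == sp, ]
    if (nrow(u) > 1 && any(u$t_start[-1] < u$t_end[-nrow(u)])) {
      abort(paste0("overlapping spans for speaker ", sp),
            class = "entrainr_parse_error")
    }
  }
  structure(list(dyad_id = dyad_id, cohort = cohort, utterances = utt),
            class = "conversation")
}

#' @export
print.conversation <- function(x, ...) {
  cat("<conversation> dyad ", x$dyad_id,
      if (!is.na(x$cohort)) paste0(" [", x$cohort, "]"),
      ": ", nrow(x$utterances), " utterances, ",
      sum(!x$utterances$complete), " incomplete\n", sep = "")
  invisible(x)
}

#' Read a dyadic transcript
#'
#' Native dialect is a UTF-8 TSV with header columns `dyad_id`, `speaker_id`,
#' `role`, `t_start`, `t_end`, `dialog_act`, `complete`, `text`. A minimal
#' ELAN EAF reader is provided as a secondary dialect: one tier per speaker,
#' tier `PARTICIPANT` attribute used as `speaker_id`, alignable annotations
#' only; dialog-act tags default to `UNTAGGED`.
#'
#' @param path path to the transcript file.
#' @param dialect `"native_tsv"` or `"eaf"`.
#' @param cohort optional cohort label attached to the conversation.
#' @param dialog_acts permitted dialog-act inventory.
#' @param roles (eaf only) named character vector mapping `speaker_id` to
#'   `"participant"`/`"examiner"`.
#' @return a validated [conversation()].
#' @export
read_transcript <- function(path, dialect = c("native_tsv", "eaf"),
                            cohort = NA_character_,
                            dialog_acts = default_dialog_acts(),
                            roles = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "entrainr_parse_error")
  }
  if (dialect == "native_tsv") {
    read_transcript_tsv(path, cohort, dialog_acts)
  } else {
    read_transcript_eaf(path, cohort, dialog_acts, roles)
  }
}

read_transcript_tsv <- function(path, cohort, dialog_acts) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      dyad_id = readr::col_character(),
      speaker_id = readr::col_character(),
      role = readr::col_character(),
      t_start = readr::col_double(),
      t_end = readr::col_double(),
      dialog_act = readr::col_character(),
      complete = readr::col_logical(),
      text = readr::col_character()
    ),
    progress = FALSE
  )
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0("malformed transcript rows (line ",
                 paste(unique(probs$row) + 1L, collapse = ", "), ") in ", path),
          class = "entrainr_parse_error")
  }
  if (nrow(raw) == 0) abort("no utterances", class = "entrainr_parse_error")
  missing <- setdiff(transcript_columns, names(raw))
  if (length(missing) > 0) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")),
          class = "entrainr_parse_error")
  }
  if (any(is.na(raw$t_start) | is.na(raw$t_end))) {
    abort(paste0("malformed timestamps in row(s) ",
                 paste(which(is.na(raw$t_start) | is.na(raw$t_end)),
                       collapse = ", ")),
          class = "entrainr_parse_error")
  }
  raw$text[is.na(raw$text)] <- ""
  dyads <- unique(raw$dyad_id)
  if (length(dyads) != 1) {
    abort("transcript file must contain exactly one dyad",
          class = "entrainr_parse_error")
  }
  conversation(dyads, raw[setdiff(names(raw), "dyad_id")],
               cohort = cohort, dialog_acts = dialog_acts)
}

read_transcript_eaf <- function(path, cohort, dialog_acts, roles) {
  doc <- xml2::read_xml(path)
  slots <- xml2::xml_find_all(doc, ".//TIME_ORDER/TIME_SLOT")
  slot_ms <- setNames(as.numeric(xml2::xml_attr(slots, "TIME_VALUE")),
                      xml2::xml_attr(slots, "TIME_SLOT_ID"))
  tiers <- xml2::xml_find_all(doc, ".//TIER")
  rows <- list()
  for (tier in tiers) {
    sp <- xml2::xml_attr(tier, "PARTICIPANT")
    if (is.na(sp)) sp <- xml2::xml_attr(tier, "TIER_ID")
    anns <- xml2::xml_find_all(tier, ".//ALIGNABLE_ANNOTATION")
    if (length(anns) == 0) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      speaker_id = sp,
      t_start = unname(slot_ms[xml2::xml_attr(anns, "TIME_SLOT_REF1")]) / 1000,
      t_end = unname(slot_ms[xml2::xml_attr(anns, "TIME_SLOT_REF2")]) / 1000,
      text = xml2::xml_text(xml2::xml_find_first(anns, ".//ANNOTATION_VALUE"))
    )
  }
  if (length(rows) == 0) abort("no utterances", class = "entrainr_parse_error")
  utt <- dplyr::bind_rows(rows)
  if (is.null(roles)) {
    abort("eaf dialect requires a `roles` mapping from speaker_id to role",
          class = "entrainr_parse_error")
  }
  utt$role <- unname(roles[utt$speaker_id])
  utt$dialog_act <- "UNTAGGED"
  utt$complete <- nzchar(trimws(utt$text))
  dyad <- tools::file_path_sans_ext(basename(path))
  conversation(dyad, utt, cohort = cohort, dialog_acts = dialog_acts)
}

#' Write a conversation in the native TSV dialect
#'
#' @param conv a [conversation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(conv, path) {
  out <- dplyr::mutate(conv$utterances, dyad_id = conv$dyad_id,
                       .before = 1L)
  readr::write_tsv(out[transcript_columns], path, progress = FALSE)
  invisible(path)
}

#' Merge contiguous same-speaker utterances into alternating turns
#'
#' Contiguous utterances by the same speaker are merged so the sequence of
#' turns strictly alternates between the two roles. Incomplete or abandoned
#' utterances can be excluded before merging, mirroring their exclusion from
#' dialog-act analysis.
#'
#' @param conv a [conversation()].
#' @param drop_incomplete drop utterances flagged `complete = FALSE` before
#'   merging (default `TRUE`).
#' @return a tibble with one row per turn: `turn` (1-based index), `role`,
#'   `speaker_id`, `t_start`, `t_end`, `n_utterances`, `dialog_acts`
#'   (list-column of member tags), `text` (space-concatenated).
#' @export
build_turns <- function(conv, drop_incomplete = TRUE) {
  stopifnot(inherits(conv, "conversation"))
  utt <- conv$utterances
  if (drop_incomplete) utt <- utt[utt$complete, ]
  if (nrow(utt) == 0 || length(unique(utt$role)) < 2) {
    abort("conversation has utterances from fewer than two speakers",
          class = "entrainr_invalid_input")
  }
  runs <- cumsum(c(TRUE, utt$role[-1] != utt$role[-nrow(utt)]))
  utt$.run <- runs
  turns <- dplyr::summarise(
    dplyr::group_by(utt, .run = .data$.run),
    role = .data$role[1],
    speaker_id = .data$speaker_id[1],
    t_start = min(.data$t_start),
    t_end = max(.data$t_end),
    n_utterances = dplyr::n(),
    dialog_acts = list(.data$dialog_act),
    text = paste(.data$text, collapse = " "),
    .groups = "drop"
  )
  turns <- dplyr::arrange(turns, .data$t_start)
  turns$.run <- NULL
  turns <- dplyr::mutate(turns, turn = dplyr::row_number(), .before = 1L)
  turns
}

#' Count spoken word tokens for one role
#'
#' Whitespace-delimited tokens after punctuation stripping, summed over the
#' complete utterances of the requested role.
#'
#' @param conv a [conversation()].
#' @param role `"participant"` or `"examiner"`.
#' @return an integer count (0 when the role has no complete utterances).
#' @export
word_count <- function(conv, role = c("participant", "examiner")) {
  role <- match.arg(role)
  utt <- conv$utterances
  utt <- utt[utt$role == role & utt$complete, ]
  if (nrow(utt) == 0) return(0L)
  sum(lengths(tokenize_text(utt$text)))
}
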