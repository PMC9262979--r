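prosody_conditions <- c("same_dyad_same_da", "cross_dyad_same_da",
                        "same_dyad_cross_da", "cross_dyad_cross_da")

#' Build surrogate dyad pairings within a cohort stratum
#'
#' For each dyad, pairs its participant with the examiner of a uniformly
#' chosen *different* dyad from the same stratum, providing the
#' no-interaction control baseline against which entrainment is measured.
#'
#' @param dyads a character vector of dyad ids, or a list of
#'   [conversation()]s (ids are taken from them).
#' @param n_per_dyad surrogate pairings per dyad (default 1).
#' @param seed integer seed; pairings are reproducible given the seed.
#' @return a tibble with `pseudo_dyad_id`, `participant_dyad`,
#'   `examiner_dyad`, `seed`.
#' @export
make_surrogate_dyads <- function(dyads, n_per_dyad = 1, seed) {
  if (is.list(dyads)) {
    dyads <- vapply(dyads, function(cv) cv$dyad_id, character(1))
  }
  dyads <- unique(dyads)
  if (length(dyads) < 2) {
    abort("need at least two dyads in the stratum to build surrogates",
          class = "entrainr_invalid_input")
  }
  stopifnot(is_scalar_number(seed))
  set.seed(as.integer(seed))
  rows <- list()
  for (d in dyads) {
    others <- setdiff(dyads, d)
    pick <- if (n_per_dyad > length(others)) resample(others, n_per_dyad)
            else others[sample.int(length(others), n_per_dyad)]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      pseudo_dyad_id = paste0(d, "~", pick, "_", seq_len(n_per_dyad)),
      participant_dyad = d,
      examiner_dyad = pick,
      seed = as.integer(seed)
    )
  }
  dplyr::bind_rows(rows)
}

#' Score surrogate conversations
#'
#' For each surrogate pairing, the examiner turns of the source dyad are
#' interleaved positionally with the participant turns of the target dyad
#' (turn k of each, up to the shorter sequence), then scored with exactly the
#' same lexical/syntactic/semantic operations as real conversations.
#'
#' @param pairing a tibble from [make_surrogate_dyads()].
#' @param turns_by_dyad named list: for each dyad id, its turns table from
#'   [build_turns()] (or a pre-tokenized list of `tokenized_turn`s).
#' @param model an [embedding_model()] or `NULL`.
#' @param backend a [lexicon_backend()].
#' @return a tibble of exchange scores with a `pseudo_dyad_id` column.
#' @export
score_surrogate_conversations <- function(pairing, turns_by_dyad,
                                          model = NULL,
                                          backend = lexicon_backend()) {
  out <- list()
  for (i in seq_len(nrow(pairing))) {
    pd <- pairing$participant_dyad[i]
    ed <- pairing$examiner_dyad[i]
    if (identical(pd, ed)) {
      abort("surrogate pairing of a dyad with itself is forbidden",
            class = "entrainr_invalid_input")
    }
    p_turns <- as_tokenized_turns(turns_by_dyad[[pd]], backend)
    e_turns <- as_tokenized_turns(turns_by_dyad[[ed]], backend)
    p_turns <- p_turns[vapply(p_turns, function(t) identical(t$role, "participant"),
                              logical(1))]
    e_turns <- e_turns[vapply(e_turns, function(t) identical(t$role, "examiner"),
                              logical(1))]
    k <- min(length(p_turns), length(e_turns))
    if (k == 0) next
    inter <- vector("list", 2L * k)
    for (j in seq_len(k)) {
      prime <- e_turns[[j]]
      resp <- p_turns[[j]]
      prime$turn <- 2L * j - 1L
      resp$turn <- 2L * j
      inter[[2L * j - 1L]] <- prime
      inter[[2L * j]] <- resp
    }
    sc <- score_conversation(inter, model = model, backend = backend)
    if (nrow(sc) > 0) {
      sc$pseudo_dyad_id <- pairing$pseudo_dyad_id[i]
      sc$participant_dyad <- pd
      out[[length(out) + 1L]] <- sc
    }
  }
  dplyr::bind_rows(out)
}

#' Z-scale a variable over its sampling stratum
#'
#' Standardizes to mean 0 and (population) standard deviation 1 over the
#' stratum. Because the entrainment distance is an absolute pairwise
#' difference, referencing both speakers' values to the stratum grand mean is
#' absorbed by this standardization.
#'
#' @param values numeric vector.
#' @return a list with `values` (z-scaled), `mean`, `sd`, and `dropped`
#'   (`TRUE` with a warning when the variable is constant).
#' @export
standardize_variable <- function(values) {
  m <- mean(values, na.rm = TRUE)
  s <- pop_sd(values)
  if (!is.finite(s) || s == 0) {
    warn("constant variable dropped from standardization")
    return(list(values = NULL, mean = m, sd = s, dropped = TRUE))
  }
  list(values = (values - m) / s, mean = m, sd = s, dropped = FALSE)
}

#' Absolute entrainment distance between two z-scaled values
#'
#' Smaller values reflect greater entrainment. Symmetric, non-negative, zero
#' iff the values are equal.
#'
#' @param x_a,x_b numeric vectors (z-scaled by [standardize_variable()]).
#' @return `abs(x_a - x_b)`.
#' @export
entrainment_distance <- function(x_a, x_b) abs(x_a - x_b)

#' Resample speaker pairs under one of the four baseline conditions
#'
#' For each target participant, unit pairs are drawn with replacement between
#' the participant's dialog-act units and an examiner unit pool constrained
#' by the condition: same vs. cross dyad, same vs. different dialog act. Each
#' drawn pair yields the absolute distance on every requested variable, so
#' the same draws support both the per-variable distance table and the joint
#' rows needed for factor analysis.
#'
#' @param units a unit feature table (e.g. [prosodic_unit_features()] rows
#'   pooled over the stratum) with columns `dyad_id`, `role`, `dialog_act`
#'   plus variable columns; variables should already be z-scaled over the
#'   stratum.
#' @param variables character vector of variable column names.
#' @param condition one of `"same_dyad_same_da"`, `"cross_dyad_same_da"`,
#'   `"same_dyad_cross_da"`, `"cross_dyad_cross_da"`.
#' @param n_draws pairs per participant (default 1000).
#' @param seed integer seed.
#' @return a tibble with `participant` (dyad id), `condition`, `draw`, and
#'   one distance column per variable. Participants with no eligible pair
#'   under the condition are flagged in the `missing_cells` attribute.
#' @export
sample_prosodic_pairs <- function(units, variables, condition,
                                  n_draws = 1000, seed) {
  condition <- match.arg(condition, prosody_conditions)
  stopifnot(all(variables %in% names(units)), is_scalar_number(seed))
  set.seed(as.integer(seed))
  same_dyad <- startsWith(condition, "same_dyad")
  same_da <- endsWith(condition, "same_da")
  p_units <- units[units$role == "participant", ]
  e_units <- units[units$role == "examiner", ]
  out <- list()
  missing_cells <- character()
  for (d in unique(p_units$dyad_id)) {
    pu <- p_units[p_units$dyad_id == d, ]
    eu <- if (same_dyad) e_units[e_units$dyad_id == d, ]
          else e_units[e_units$dyad_id != d, ]
    if (nrow(pu) == 0 || nrow(eu) == 0) {
      missing_cells <- c(missing_cells, d)
      next
    }
    # eligible examiner units per participant unit, by dialog-act constraint
    elig <- lapply(pu$dialog_act, function(tag) {
      if (same_da) which(eu$dialog_act == tag) else which(eu$dialog_act != tag)
    })
    ok <- lengths(elig) > 0
    if (!any(ok)) {
      missing_cells <- c(missing_cells, d)
      next
    }
    p_idx <- resample(which(ok), n_draws)
    # examiner draws share an eligible pool within each dialog-act tag, so
    # sample per tag rather than per draw
    e_idx <- integer(n_draws)
    for (tag in unique(pu$dialog_act[p_idx])) {
      sel <- pu$dialog_act[p_idx] == tag
      cand <- elig[[match(TRUE, pu$dialog_act == tag & ok)]]
      e_idx[sel] <- resample(cand, sum(sel))
    }
    xp <- as.matrix(pu[p_idx, variables, drop = FALSE])
    xe <- as.matrix(eu[e_idx, variables, drop = FALSE])
    dmat <- entrainment_distance(xp, xe)
    row <- tibble::as_tibble(as.data.frame(dmat))
    row <- dplyr::mutate(row, participant = d, condition = condition,
                         draw = seq_len(n_draws), .before = 1L)
    out[[length(out) + 1L]] <- row
  }
  res <- dplyr::bind_rows(out)
  attr(res, "missing_cells") <- missing_cells
  res
}

#' Aggregate resampled distances into the entrainment distance table
#'
#' Per participant x variable x condition cell: draw count and mean distance.
#' Same-dyad conditions map to `conversation_type = "real"`, cross-dyad to
#' `"surrogate"`; the dialog-act axis of the condition becomes `da_pairing`.
#'
#' @param samples a tibble from [sample_prosodic_pairs()] (conditions may be
#'   row-bound together).
#' @param variables variable columns to aggregate; defaults to every column
#'   other than the keys.
#' @return a tibble of class `entrainment_distance_table` with columns
#'   `participant`, `variable`, `conversation_type`, `da_pairing`,
#'   `n_samples`, `mean_distance`.
#' @export
aggregate_distances <- function(samples, variables = NULL) {
  keys <- c("participant", "condition", "draw")
  variables <- variables %||% setdiff(names(samples), keys)
  long <- tidyr::pivot_longer(samples, dplyr::all_of(variables),
                              names_to = "variable", values_to = "distance")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$participant, .data$variable, .data$condition),
    n_samples = sum(!is.na(.data$distance)),
    mean_distance = mean(.data$distance, na.rm = TRUE),
    .groups = "drop"
  )
  out$conversation_type <- ifelse(startsWith(out$condition, "same_dyad"),
                                  "real", "surrogate")
  out$da_pairing <- ifelse(endsWith(out$condition, "same_da"),
                           "same", "different")
  out <- out[, c("participant", "variable", "conversation_type",
                 "da_pairing", "n_samples", "mean_distance")]
  structure(out, class = c("entrainment_distance_table", class(out)))
}
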