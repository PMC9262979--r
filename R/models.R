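# tidy fixed-effect table from an lmer or lm fit, with Wald z p-values
tidy_fixed_effects <- function(fit) {
  if (inherits(fit, "lmerMod")) {
    sm <- summary(fit)$coefficients
  } else {
    sm <- summary(fit)$coefficients
  }
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, 1],
    se = sm[, 2],
    statistic = sm[, 1] / sm[, 2],
    p_value = 2 * pnorm(-abs(sm[, 1] / sm[, 2]))
  )
}

new_model_result <- function(terms, fit, converged, random_structure,
                             domain, ct_term, ct_group_term) {
  structure(list(terms = terms, fit = fit, converged = converged,
                 random_structure = random_structure, domain = domain,
                 ct_term = ct_term, ct_group_term = ct_group_term),
            class = "entrainment_model_result")
}

#' @export
print.entrainment_model_result <- function(x, digits = 3, ...) {
  cat("<entrainment_model_result> domain=", x$domain,
      " random=", x$random_structure,
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  print(as.data.frame(lapply(x$terms, function(col)
    if (is.numeric(col)) signif(col, digits) else col)))
  invisible(x)
}

prepare_model_frame <- function(frame) {
  frame$conversation_type <- factor(frame$conversation_type,
                                    levels = c("surrogate", "real"))
  frame$group <- factor(frame$group, levels = c("control", "case"))
  if ("da_pairing" %in% names(frame)) {
    frame$da_pairing <- factor(frame$da_pairing,
                               levels = c("different", "same"))
  }
  frame[stats::complete.cases(frame), ]
}

fit_lmer_quietly <- function(formula, data) {
  warnings <- character()
  fit <- withCallingHandlers(
    tryCatch(lme4::lmer(formula, data = data,
                        control = lme4::lmerControl(calc.derivs = FALSE)),
             error = function(e) e),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )
  list(fit = fit, warnings = warnings,
       failed = inherits(fit, "error") ||
         any(grepl("failed to converge|unable to evaluate|Downdated",
                   warnings)),
       singular = !inherits(fit, "error") && lme4::isSingular(fit, tol = 1e-4))
}

#' Fit the prosodic entrainment contrast model
#'
#' Linear mixed model of a prosodic factor score on the full three-way fixed
#' structure `conversation_type * da_pairing * group` with a by-participant
#' random intercept. The reference levels are surrogate, different-dialog-act
#' pairing, and the control group, so a positive conversation-type
#' coefficient means larger real-conversation distances than baseline, i.e.
#' divergence. P-values are Wald z.
#'
#' @param frame a data frame with columns `participant`, `score`,
#'   `conversation_type` (`"surrogate"`/`"real"`), `da_pairing`
#'   (`"different"`/`"same"`), `group` (`"control"`/`"case"`).
#' @param outcome name of the outcome column (default `"score"`).
#' @return an `entrainment_model_result`: tidy term table, convergence flag,
#'   and the random structure actually used (falls back to a fixed-effects
#'   fit when the mixed fit fails, recording the fallback).
#' @export
fit_prosodic_model <- function(frame, outcome = "score") {
  frame <- prepare_model_frame(frame)
  if (length(unique(frame$group)) < 2) {
    abort("need both groups present", class = "entrainr_invalid_input")
  }
  if (length(unique(frame$conversation_type)) < 2) {
    abort("need both conversation types present",
          class = "entrainr_invalid_input")
  }
  if (sd(frame[[outcome]], na.rm = TRUE) == 0) {
    abort("outcome has zero variance", class = "entrainr_degenerate_model")
  }
  f <- stats::as.formula(paste(
    outcome, "~ conversation_type * da_pairing * group + (1 | participant)"))
  res <- fit_lmer_quietly(f, frame)
  if (res$failed) {
    fit <- lm(stats::as.formula(paste(
      outcome, "~ conversation_type * da_pairing * group")), data = frame)
    return(new_model_result(tidy_fixed_effects(fit), fit, converged = TRUE,
                            random_structure = "none (fallback)",
                            domain = "prosodic",
                            ct_term = "conversation_typereal",
                            ct_group_term = "conversation_typereal:groupcase"))
  }
  new_model_result(tidy_fixed_effects(res$fit), res$fit, converged = TRUE,
                   random_structure = "(1 | participant)",
                   domain = "prosodic",
                   ct_term = "conversation_typereal",
                   ct_group_term = "conversation_typereal:groupcase")
}

#' Fit the lexical/semantic/syntactic entrainment model
#'
#' Linear mixed model of exchange-level alignment scores on
#' `conversation_type * time * group`, controlling for the participant's
#' word count (z-scaled), with by-participant random intercepts and random
#' slopes for the within-participant fixed effects. Singular or
#' non-converging fits degrade gracefully: slopes are dropped one at a time
#' (time first, then conversation type), ending at a random intercept; the
#' structure actually used is recorded in the result.
#'
#' @param frame a data frame with columns `participant`, `score`, `time`
#'   (turn index), `conversation_type`, `group`, `word_count`.
#' @param domain label for the result (`"lexical"`, `"semantic"`,
#'   `"syntactic"`).
#' @return an `entrainment_model_result`.
#' @export
fit_alignment_model <- function(frame, domain = "lexical") {
  frame <- prepare_model_frame(frame)
  if (length(unique(frame$group)) < 2) {
    abort("need both groups present", class = "entrainr_invalid_input")
  }
  if (sd(frame$score, na.rm = TRUE) == 0) {
    abort("scores have zero variance", class = "entrainr_degenerate_model")
  }
  frame$word_count_z <- as.numeric(scale(frame$word_count))
  if (all(is.na(frame$word_count_z)) || sd(frame$word_count, na.rm = TRUE) == 0) {
    frame$word_count_z <- 0
  }
  structures <- c("(1 + conversation_type + time | participant)",
                  "(1 + conversation_type | participant)",
                  "(1 | participant)")
  for (rs in structures) {
    f <- stats::as.formula(paste(
      "score ~ conversation_type * time * group + word_count_z +", rs))
    res <- fit_lmer_quietly(f, frame)
    if (!res$failed && !res$singular) {
      return(new_model_result(tidy_fixed_effects(res$fit), res$fit,
                              converged = TRUE, random_structure = rs,
                              domain = domain,
                              ct_term = "conversation_typereal",
                              ct_group_term = "conversation_typereal:groupcase"))
    }
    if (!res$failed && res$singular && rs == utils::tail(structures, 1)) {
      # singular intercept-only fit: keep it but note the singularity
      return(new_model_result(tidy_fixed_effects(res$fit), res$fit,
                              converged = TRUE,
                              random_structure = paste(rs, "(singular)"),
                              domain = domain,
                              ct_term = "conversation_typereal",
                              ct_group_term = "conversation_typereal:groupcase"))
    }
  }
  fit <- lm(score ~ conversation_type * time * group + word_count_z,
            data = frame)
  new_model_result(tidy_fixed_effects(fit), fit, converged = TRUE,
                   random_structure = "none (fallback)", domain = domain,
                   ct_term = "conversation_typereal",
                   ct_group_term = "conversation_typereal:groupcase")
}

#' Classify a model result as entrainment, disentrainment, or neither
#'
#' Uses the conversation-type main effect: for distance outcomes
#' (`smaller_is_entrained = TRUE`) a significantly *negative* coefficient
#' (real distances below the surrogate baseline) is entrainment and a
#' significantly positive one is disentrainment; for alignment scores
#' (`smaller_is_entrained = FALSE`) the signs invert. The group-difference
#' flag is set when the conversation-type x group interaction is significant.
#'
#' @param result an `entrainment_model_result` (must have converged).
#' @param alpha significance level (default 0.05).
#' @param smaller_is_entrained `TRUE` for prosodic distance outcomes,
#'   `FALSE` for alignment scores.
#' @return an object of class `entrainment_classification`: a list with
#'   `classification` (`"entrainment"`/`"disentrainment"`/`"none"`),
#'   `group_difference`, `beta`, `p_value`, `interaction_p`.
#' @export
classify_entrainment <- function(result, alpha = 0.05, smaller_is_entrained) {
  stopifnot(inherits(result, "entrainment_model_result"))
  if (!isTRUE(result$converged)) {
    abort("cannot classify a non-converged model",
          class = "entrainr_invalid_input")
  }
  stopifnot(is.logical(smaller_is_entrained))
  ct <- result$terms[result$terms$term == result$ct_term, ]
  if (nrow(ct) != 1) {
    abort(paste0("conversation-type term '", result$ct_term,
                 "' not found in model"), class = "entrainr_invalid_input")
  }
  beta <- ct$estimate
  p <- ct$p_value
  cls <- "none"
  if (p < alpha) {
    negative_means_entrained <- smaller_is_entrained
    cls <- if ((beta < 0) == negative_means_entrained) "entrainment"
           else "disentrainment"
  }
  ia <- result$terms[result$terms$term == result$ct_group_term, ]
  ia_p <- if (nrow(ia) == 1) ia$p_value else NA_real_
  structure(list(classification = cls,
                 group_difference = isTRUE(ia_p < alpha),
                 beta = beta, p_value = p, interaction_p = ia_p,
                 alpha = alpha,
                 smaller_is_entrained = smaller_is_entrained),
            class = "entrainment_classification")
}

#' @export
print.entrainment_classification <- function(x, ...) {
  cat("<entrainment_classification> ", x$classification,
      if (x$group_difference) " *group difference*",
      sprintf("  (beta = %.3g, p = %.3g)\n", x$beta, x$p_value), sep = "")
  invisible(x)
}

#' Per-group simple effects of conversation type
#'
#' Derives the conversation-type effect separately for the control group (the
#' reference coefficient) and the case group (reference + interaction), with
#' standard errors from the fixed-effect covariance, averaged over the
#' dialog-act pairing axis when present (the coding makes the reported
#' coefficient the effect at the reference pairing level; the average over
#' pairing adds half the three-way/two-way pairing interactions).
#'
#' @param result an `entrainment_model_result`.
#' @return a tibble with one row per group: `group`, `estimate`, `se`,
#'   `p_value`.
#' @export
simple_effects <- function(result) {
  fit <- result$fit
  b <- if (inherits(fit, "lmerMod")) lme4::fixef(fit) else coef(fit)
  V <- as.matrix(vcov(fit))
  ct <- result$ct_term
  ctg <- result$ct_group_term
  nm <- names(b)
  contrast_for <- function(terms_weights) {
    v <- setNames(rep(0, length(nm)), nm)
    for (t in names(terms_weights)) if (t %in% nm) v[t] <- terms_weights[[t]]
    v
  }
  has_da <- any(grepl("da_pairingsame", nm))
  base <- setNames(list(1), ct)
  if (has_da) base[[paste0(ct, ":da_pairingsame")]] <- 0.5
  rows <- list()
  for (g in c("control", "case")) {
    w <- base
    if (g == "case") {
      w[[ctg]] <- 1
      if (has_da) {
        tri <- paste0(ct, ":da_pairingsame:groupcase")
        w[[tri]] <- 0.5
      }
    }
    v <- contrast_for(w)
    est <- sum(v * b)
    se <- sqrt(drop(t(v) %*% V %*% v))
    rows[[g]] <- tibble::tibble(group = g, estimate = est, se = se,
                                p_value = 2 * pnorm(-abs(est / se)))
  }
  dplyr::bind_rows(rows)
}
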