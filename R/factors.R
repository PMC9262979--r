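# principal-axis factoring with iterated communalities on a correlation
# matrix; returns unrotated loadings
principal_axis <- function(R, n_factors, max_iter = 100, tol = 1e-6) {
  p <- ncol(R)
  inv <- tryCatch(solve(R), error = function(e) NULL)
  h2 <- if (is.null(inv)) rep(0.5, p) else pmin(pmax(1 - 1 / diag(inv), 0.05), 0.99)
  L <- NULL
  for (it in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    k <- n_factors
    lam <- pmax(e$values[seq_len(k)], 0)
    L <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k)
    h2_new <- pmin(rowSums(L^2), 0.998)
    if (max(abs(h2_new - h2)) < tol) {
      h2 <- h2_new
      break
    }
    h2 <- h2_new
  }
  rownames(L) <- colnames(R)
  colnames(L) <- paste0("factor", seq_len(n_factors))
  L
}

#' Choose the number of factors to retain
#'
#' Applies the Kaiser criterion (retain factors with eigenvalue strictly
#' greater than 1) and, for comparison, a scree heuristic (the count of
#' eigenvalues before the largest consecutive drop). Returns the Kaiser count
#' and messages when the two disagree; a Kaiser count of zero is flagged
#' degenerate.
#'
#' @param eigenvalues eigenvalues of the unreduced correlation matrix, sorted
#'   descending.
#' @param quiet suppress the disagreement message.
#' @return integer count, with attributes `kaiser` and `scree`.
#' @export
select_n_factors <- function(eigenvalues, quiet = FALSE) {
  stopifnot(!is.unsorted(rev(eigenvalues)))
  kaiser <- sum(eigenvalues > 1)
  scree <- if (length(eigenvalues) > 1) which.max(-diff(eigenvalues)) else 1L
  if (kaiser == 0 && !quiet) {
    warn("Kaiser criterion retains 0 factors (no eigenvalue > 1); degenerate")
  }
  if (kaiser != scree && kaiser > 0 && !quiet) {
    inform(paste0("Kaiser criterion retains ", kaiser,
                  " factor(s) but the scree drop suggests ", scree))
  }
  structure(kaiser, kaiser = kaiser, scree = scree)
}

#' Exploratory factor analysis of a block of distance variables
#'
#' Principal-axis extraction with iterated communalities, followed by an
#' oblique promax rotation. The number of factors defaults to the Kaiser
#' criterion applied to the eigenvalues of the (unreduced) correlation
#' matrix. Each factor is oriented so that the mean loading on its defining
#' variables (|loading| >= `assign_threshold`) is positive, so that larger
#' factor scores track larger distances.
#'
#' @param x a data frame / tibble of numeric variables (rows = resampled
#'   distance observations pooled across conditions).
#' @param n_factors override the Kaiser choice.
#' @param rotation `"promax"` (oblique) or `"none"`.
#' @param block optional label (`"f0_dialog_act"`, `"f0_salient_syllable"`,
#'   `"rhythm_dialog_act"`, ...).
#' @param assign_threshold absolute loading needed for a variable to define a
#'   factor (default 0.4).
#' @return an object of class `factor_model`: loadings (pattern matrix),
#'   eigenvalues, factor correlations `Phi`, the correlation matrix `R`,
#'   variable names, `n_factors`, and a stability flag.
#' @export
run_efa <- function(x, n_factors = NULL, rotation = c("promax", "none"),
                    block = NA_character_, assign_threshold = 0.4) {
  rotation <- match.arg(rotation)
  x <- as.data.frame(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  p <- ncol(x)
  if (p < 3) abort("EFA needs at least 3 variables",
                   class = "entrainr_invalid_input")
  if (nrow(x) < 5 * p) {
    abort("EFA needs at least 5 rows per variable",
          class = "entrainr_invalid_input")
  }
  R <- cor(x)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  dup <- which(abs(R - 1) < 1e-10 & upper.tri(R), arr.ind = TRUE)
  if (nrow(dup) > 0 || min(ev) < 1e-10) {
    culprits <- if (nrow(dup) > 0) {
      paste(rownames(R)[dup[, 1]], colnames(R)[dup[, 2]],
            sep = " ~ ", collapse = ", ")
    } else "near-singular correlation matrix"
    abort(paste0("collinear variables: ", culprits),
          class = "entrainr_singular_error")
  }
  k <- n_factors %||% as.integer(select_n_factors(ev, quiet = TRUE))
  if (k < 1) {
    abort("no factor with eigenvalue > 1; nothing to retain",
          class = "entrainr_invalid_input")
  }
  L <- principal_axis(R, k)
  Phi <- diag(k)
  if (rotation == "promax" && k > 1) {
    pr <- stats::promax(L, m = 4)
    L <- unclass(pr$loadings)
    U <- pr$rotmat
    Phi <- solve(crossprod(U))
    # rescale Phi to a correlation matrix (promax rotmat columns are not
    # exactly unit-length)
    s <- sqrt(diag(Phi))
    Phi <- Phi / tcrossprod(s)
  }
  # orient each factor so its defining loadings are positive on average
  for (j in seq_len(k)) {
    def <- abs(L[, j]) >= assign_threshold
    if (!any(def)) def <- rep(TRUE, nrow(L))
    if (mean(L[def, j]) < 0) {
      L[, j] <- -L[, j]
      Phi[j, ] <- -Phi[j, ]
      Phi[, j] <- -Phi[, j]
    }
  }
  structure(list(block = block, n_factors = k, loadings = L,
                 eigenvalues = ev, rotation = rotation, Phi = Phi, R = R,
                 variables = colnames(R),
                 assign_threshold = assign_threshold,
                 unstable = max(ev) < 1.5),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, digits = 2, ...) {
  cat("<factor_model>", if (!is.na(x$block)) paste0(" block=", x$block),
      " factors=", x$n_factors,
      " rotation=", x$rotation,
      if (x$unstable) " [unstable]", "\n", sep = "")
  cat("eigenvalues:", paste(round(x$eigenvalues, digits), collapse = ", "),
      "\n")
  print(round(x$loadings, digits))
  invisible(x)
}

# simple-structure assignment: each variable to its dominant factor,
# provided the dominant |loading| clears the threshold
assign_variables <- function(model) {
  L <- model$loadings
  dom <- apply(abs(L), 1, which.max)
  keep <- abs(L[cbind(seq_len(nrow(L)), dom)]) >= model$assign_threshold
  split(rownames(L)[keep], dom[keep])
}

#' Confirmatory factor scores from the EFA simple structure
#'
#' Re-estimates the EFA's simple structure confirmatorily: each variable
#' loads on exactly one factor (its dominant EFA factor); per factor, a
#' one-factor principal-axis solution on that factor's variables gives the
#' confirmatory loadings, and scores are computed by the regression
#' (Thurstone) method from those variables alone, then scaled to unit
#' variance. Factors may correlate through the data. With identity loadings
#' (one variable per factor) the score reduces to the standardized variable
#' itself.
#'
#' @param cells a tibble with key columns (e.g. `participant`,
#'   `conversation_type`, `da_pairing`) and one column per model variable
#'   (typically per-cell mean distances).
#' @param model a [run_efa()] fit.
#' @param keys character vector of key column names (defaults to every
#'   non-variable column).
#' @return a tibble of class `factor_scores`: the key columns plus `factor1`,
#'   `factor2`, ... Missing cells propagate as `NA`.
#' @export
cfa_scores <- function(cells, model, keys = NULL) {
  stopifnot(inherits(model, "factor_model"))
  missing_vars <- setdiff(model$variables, names(cells))
  if (length(missing_vars) > 0) {
    abort(paste0("cells table missing model variable(s): ",
                 paste(missing_vars, collapse = ", ")),
          class = "entrainr_invalid_input")
  }
  keys <- keys %||% setdiff(names(cells), model$variables)
  groups <- assign_variables(model)
  X <- as.matrix(cells[, model$variables, drop = FALSE])
  # standardize the scoring frame columns
  Z <- scale(X)
  Z[, attr(Z, "scaled:scale") == 0] <- 0
  out <- cells[, keys, drop = FALSE]
  for (j in seq_len(model$n_factors)) {
    vars <- groups[[as.character(j)]]
    col <- paste0("factor", j)
    if (is.null(vars) || length(vars) == 0) {
      out[[col]] <- NA_real_
      next
    }
    if (length(vars) == 1) {
      out[[col]] <- as.numeric(Z[, vars])
      next
    }
    cc <- stats::complete.cases(Z[, vars, drop = FALSE])
    Rf <- cor(X[cc, vars, drop = FALSE])
    lam <- principal_axis(Rf, 1)[, 1]
    if (mean(lam) < 0) lam <- -lam
    w <- solve(Rf, lam)
    f <- as.numeric(Z[, vars, drop = FALSE] %*% w)
    s <- sd(f, na.rm = TRUE)
    out[[col]] <- if (is.finite(s) && s > 0) f / s else f
  }
  structure(out, class = c("factor_scores", class(out)))
}
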