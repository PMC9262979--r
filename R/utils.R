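#' Cosine similarity between two count or embedding vectors
#'
#' The similarity functional used for all three alignment domains. Computed as
#' `sum(x*y) / sqrt(sum(x^2) * sum(y^2))`; a zero-norm operand yields `NA`,
#' which callers treat as "exchange excluded".
#'
#' @param x,y numeric vectors of equal length.
#' @return a scalar in `[-1, 1]`, or `NA_real_` when either norm is zero.
#' @export
cosine_similarity <- function(x, y) {
  stopifnot(length(x) == length(y))
  sx <- sum(x * x)
  sy <- sum(y * y)
  if (sx == 0 || sy == 0) return(NA_real_)
  sum(x * y) / sqrt(sx * sy)
}

# population (divide-by-n) standard deviation; the z-scaling convention used
# for entrainment distance variables
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

# clamp a derived seed into the valid 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset) %% .Machine$integer.max)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# sample() without the scalar-x surprise
resample <- function(x, size, replace = TRUE) {
  x[sample.int(length(x), size, replace = replace)]
}
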