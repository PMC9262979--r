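#' Construct an in-memory mono waveform
#'
#' @param samples numeric vector of amplitudes (nominally in `[-1, 1]`).
#' @param sample_rate sampling rate in Hz.
#' @return an object of class `waveform`.
#' @export
waveform <- function(samples, sample_rate) {
  stopifnot(is.numeric(samples), is_scalar_number(sample_rate),
            sample_rate > 0)
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate),
            class = "waveform")
}

#' Read a mono 16-bit PCM WAV file
#'
#' Minimal RIFF reader for the single format the pipeline consumes
#' (uncompressed mono PCM, 16-bit). Amplitudes are scaled to `[-1, 1]`.
#'
#' @param path path to a `.wav` file.
#' @return a [waveform()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort("not a RIFF file",
                                      class = "entrainr_parse_error")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort("not a WAVE file",
                                      class = "entrainr_parse_error")
  sr <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", size / 2, 2, endian = "little",
                     signed = FALSE)
      channels <- fmt[2]
      sr <- fmt[3] + fmt[4] * 65536
      bits <- fmt[8]
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", size / 2, 2, endian = "little",
                         signed = TRUE)
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(samples) || is.null(sr)) {
    abort("missing fmt or data chunk", class = "entrainr_parse_error")
  }
  if (!identical(as.integer(channels), 1L) || !identical(as.integer(bits), 16L)) {
    abort("only mono 16-bit PCM supported", class = "entrainr_parse_error")
  }
  waveform(samples / 32768, sr)
}

#' F0 extraction configuration
#'
#' @param fmin,fmax pitch search range in Hz.
#' @param frame_length analysis frame length in seconds.
#' @param voicing_threshold minimum normalized autocorrelation peak for a
#'   frame to count as voiced.
#' @param silence_threshold frames whose RMS falls below this fraction of the
#'   track maximum are treated as unvoiced.
#' @return a list of settings.
#' @export
f0_config <- function(fmin = 75, fmax = 500, frame_length = 0.04,
                      voicing_threshold = 0.45, silence_threshold = 0.03) {
  list(fmin = fmin, fmax = fmax, frame_length = frame_length,
       voicing_threshold = voicing_threshold,
       silence_threshold = silence_threshold)
}

#' Extract an F0 track at 100 Hz
#'
#' For a [waveform()], fundamental frequency is estimated by frame-wise
#' normalized autocorrelation (peak picking with parabolic interpolation in
#' the configured pitch range) on a 10 ms hop; unvoiced or silent frames are
#' `NA`. An externally computed track (data frame with columns `time`, `f0`)
#' on any grid is resampled onto the uniform 10 ms grid by linear
#' interpolation within voiced runs.
#'
#' @param x a [waveform()] or a data frame `time`/`f0` (NA = unvoiced).
#' @param config an [f0_config()].
#' @return a `pitch_track` tibble with columns `time` (s) and `f0` (Hz,
#'   `NA` where unvoiced).
#' @export
extract_f0 <- function(x, config = f0_config()) {
  if (inherits(x, "waveform")) {
    track <- extract_f0_autocorr(x, config)
  } else if (is.data.frame(x)) {
    track <- resample_track(x, value_col = "f0", voiced_only = TRUE)
  } else {
    abort("x must be a waveform or a time/f0 data frame",
          class = "entrainr_invalid_input")
  }
  if (all(is.na(track$f0))) {
    warn("no voiced frames found; returning all-NA pitch track")
  }
  structure(track, class = c("pitch_track", class(track)))
}

extract_f0_autocorr <- function(wav, config) {
  sr <- wav$sample_rate
  x <- wav$samples
  hop <- round(sr * 0.01)
  win <- round(sr * config$frame_length)
  centers <- seq(1, max(1, length(x) - 1), by = hop)
  lag_min <- max(2L, floor(sr / config$fmax))
  lag_max <- ceiling(sr / config$fmin)
  rms_all <- sqrt(mean(x^2))
  f0 <- rep(NA_real_, length(centers))
  for (i in seq_along(centers)) {
    a <- max(1L, centers[i] - win %/% 2L)
    b <- min(length(x), centers[i] + win %/% 2L)
    frame <- x[a:b]
    if (length(frame) < 2L * lag_min) next
    frame <- frame - mean(frame)
    e0 <- sum(frame^2)
    if (e0 == 0 || sqrt(mean(frame^2)) < config$silence_threshold * rms_all) next
    lmax <- min(lag_max, length(frame) - 1L)
    if (lmax <= lag_min) next
    r <- vapply(lag_min:lmax, function(l) {
      n <- length(frame) - l
      sum(frame[1:n] * frame[(l + 1):(l + n)]) /
        sqrt(sum(frame[1:n]^2) * sum(frame[(l + 1):(l + n)]^2))
    }, numeric(1))
    pk <- which.max(r)
    if (r[pk] < config$voicing_threshold) next
    lag <- lag_min + pk - 1L
    # parabolic interpolation around the peak
    if (pk > 1 && pk < length(r)) {
      denom <- r[pk - 1] - 2 * r[pk] + r[pk + 1]
      if (denom < 0) lag <- lag + 0.5 * (r[pk - 1] - r[pk + 1]) / denom
    }
    f0[i] <- sr / lag
  }
  tibble::tibble(time = (centers - 1) / sr, f0 = f0)
}

resample_track <- function(df, value_col, voiced_only = FALSE) {
  stopifnot(all(c("time", value_col) %in% names(df)))
  t0 <- min(df$time)
  t1 <- max(df$time)
  grid <- seq(t0, t1, by = 0.01)
  v <- rep(NA_real_, length(grid))
  val <- df[[value_col]]
  if (voiced_only) {
    voiced <- !is.na(val)
    runs <- rle(voiced)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      ta <- df$time[starts[k]]
      tb <- df$time[ends[k]]
      sel <- grid >= ta & grid <= tb
      if (!any(sel)) next
      if (starts[k] == ends[k]) {
        v[sel] <- val[starts[k]]
      } else {
        v[sel] <- approx(df$time[starts[k]:ends[k]], val[starts[k]:ends[k]],
                         xout = grid[sel])$y
      }
    }
  } else {
    v <- approx(df$time, val, xout = grid, rule = 2)$y
  }
  out <- tibble::tibble(time = grid)
  out[[value_col]] <- v
  out
}

#' Short-time RMS energy track
#'
#' Hamming-weighted root-mean-square amplitude in 50 ms windows hopped at
#' 10 ms (the same 100 Hz grid as the pitch track). A window longer than the
#' signal degrades to a single whole-signal window.
#'
#' @param wav a [waveform()].
#' @param window_length analysis window in seconds (default 0.05).
#' @param hop hop size in seconds (default 0.01).
#' @return an `energy_track` tibble with columns `time`, `rms`.
#' @export
compute_energy <- function(wav, window_length = 0.05, hop = 0.01) {
  stopifnot(inherits(wav, "waveform"))
  sr <- wav$sample_rate
  x <- wav$samples
  win <- round(sr * window_length)
  if (win >= length(x)) {
    w <- hamming_window(length(x))
    return(structure(
      tibble::tibble(time = 0, rms = sqrt(sum(w * x^2) / sum(w))),
      class = c("energy_track", "tbl_df", "tbl", "data.frame")))
  }
  hop_n <- round(sr * hop)
  centers <- seq(1, length(x), by = hop_n)
  w_full <- hamming_window(win)
  rms <- vapply(centers, function(c0) {
    a <- max(1L, c0 - win %/% 2L)
    b <- min(length(x), c0 + win %/% 2L - 1L)
    seg <- x[a:b]
    w <- if (length(seg) == win) w_full else hamming_window(length(seg))
    sqrt(sum(w * seg^2) / sum(w))
  }, numeric(1))
  structure(tibble::tibble(time = (centers - 1) / sr, rms = rms),
            class = c("energy_track", "tbl_df", "tbl", "data.frame"))
}

hamming_window <- function(n) {
  if (n == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Salient-syllable detection configuration
#'
#' @param energy_quantile quantile of the speaker's RMS distribution used as
#'   the energy threshold (default 0.7).
#' @param min_duration_s minimum syllable duration in seconds (default 0.1).
#' @param min_gap_s runs separated by a sub-threshold gap shorter than this
#'   are merged (default 0.05).
#' @return a list of settings.
#' @export
syllable_config <- function(energy_quantile = 0.7, min_duration_s = 0.1,
                            min_gap_s = 0.05) {
  list(energy_quantile = energy_quantile, min_duration_s = min_duration_s,
       min_gap_s = min_gap_s)
}

#' Detect salient syllables from an energy track
#'
#' A salient (stressed) syllable is a maximal run of frames whose RMS energy
#' meets the quantile threshold, lasting at least the minimum duration; runs
#' separated by less than `min_gap_s` are merged first. Output intervals are
#' disjoint and time-ordered.
#'
#' @param energy an `energy_track` from [compute_energy()].
#' @param config a [syllable_config()].
#' @param threshold optional absolute RMS threshold overriding the quantile
#'   rule (used when a speaker-session threshold is computed once upstream).
#' @return a tibble with columns `t_start`, `t_end`, `duration`, `peak_rms`.
#' @export
detect_salient_syllables <- function(energy, config = syllable_config(),
                                     threshold = NULL) {
  stopifnot(nrow(energy) > 0)
  thr <- threshold %||% quantile(energy$rms, config$energy_quantile,
                                 names = FALSE)
  if (thr <= 0) thr <- .Machine$double.eps   # all-zero track: nothing salient
  # frames sitting exactly at the track floor are background, not syllables,
  # even when the quantile threshold lands on the floor value
  above <- energy$rms >= thr & energy$rms > min(energy$rms) & energy$rms > 0
  if (!any(above)) {
    return(tibble::tibble(t_start = double(), t_end = double(),
                          duration = double(), peak_rms = double()))
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  iv <- data.frame(a = starts[runs$values], b = ends[runs$values])
  dt <- if (nrow(energy) > 1) energy$time[2] - energy$time[1] else 0.01
  # merge across short gaps
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) {
    for (k in 2:nrow(iv)) {
      gap <- (iv$a[k] - merged$b[nrow(merged)] - 1) * dt
      if (gap < config$min_gap_s) {
        merged$b[nrow(merged)] <- iv$b[k]
      } else {
        merged <- rbind(merged, iv[k, ])
      }
    }
  }
  out <- tibble::tibble(
    t_start = energy$time[merged$a],
    t_end = energy$time[merged$b] + dt,
    peak_rms = vapply(seq_len(nrow(merged)),
                      function(k) max(energy$rms[merged$a[k]:merged$b[k]]),
                      numeric(1))
  )
  out$duration <- out$t_end - out$t_start
  out <- out[out$duration >= config$min_duration_s, ]
  out[, c("t_start", "t_end", "duration", "peak_rms")]
}

#' Convert F0 in Hz to semitones relative to a reference
#'
#' @param f0 F0 values in Hz.
#' @param ref reference frequency in Hz (typically the speaker's session
#'   median F0, removing speaker register).
#' @return semitone values.
#' @export
hz_to_semitones <- function(f0, ref) 12 * log2(f0 / ref)

# frames of a pitch track inside [t_start, t_end], semitone-converted, with
# interior unvoiced gaps linearly interpolated for contour fitting
span_contour <- function(f0_track, t_start, t_end, ref_f0) {
  sel <- f0_track$time >= t_start & f0_track$time <= t_end
  tt <- f0_track$time[sel]
  st <- hz_to_semitones(f0_track$f0[sel], ref_f0)
  voiced <- !is.na(st)
  st_i <- st
  if (sum(voiced) >= 2) {
    st_i <- approx(tt[voiced], st[voiced], xout = tt, rule = 2)$y
  }
  list(time = tt, st = st, st_interp = st_i, n_voiced = sum(voiced))
}

fit_line <- function(t, y) {
  if (length(t) < 2 || length(unique(t)) < 2) {
    return(c(intercept = if (length(y)) mean(y) else NA_real_, slope = 0,
             rmsd = 0))
  }
  fit <- lm(y ~ t)
  c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
    rmsd = sqrt(mean(resid(fit)^2)))
}

#' Stylize the global (dialog-act level) F0 contour
#'
#' Summarizes the pitch contour of one dialog-act unit as: the F0 envelope
#' (`f0_mean`, `f0_max`, `f0_range`, semitones re the speaker reference);
#' linear fits to the baseline (100 ms window minima), midline (window
#' medians), and topline (window maxima), each reported as intercept, slope
#' (st/s), and RMSD of fit residuals; and raw polynomial coefficients of the
#' contour over the time-normalized `[0, 1]` span.
#'
#' @param f0_track a `pitch_track`.
#' @param t_start,t_end unit span in seconds.
#' @param ref_f0 the speaker's session median F0 in Hz.
#' @param poly_order order of the trend polynomial (default 3).
#' @param min_voiced minimum voiced frames required (default 5); below this
#'   the unit is unusable and `NULL` is returned.
#' @return a named numeric vector, or `NULL` when the unit is unusable.
#' @export
stylize_global <- function(f0_track, t_start, t_end, ref_f0, poly_order = 3,
                           min_voiced = 5) {
  sc <- span_contour(f0_track, t_start, t_end, ref_f0)
  if (sc$n_voiced < min_voiced) return(NULL)
  st_v <- sc$st[!is.na(sc$st)]
  out <- c(f0_mean = mean(st_v), f0_max = max(st_v),
           f0_range = max(st_v) - min(st_v))
  # base/mid/topline over 100 ms sub-windows (frame-level fallback when the
  # span is too short for two windows)
  t_rel <- sc$time - sc$time[1]
  bins <- floor(t_rel / 0.1)
  if (length(unique(bins)) < 2) bins <- seq_along(t_rel)
  centers <- tapply(t_rel, bins, mean)
  lo <- tapply(sc$st_interp, bins, min)
  mid <- tapply(sc$st_interp, bins, median)
  hi <- tapply(sc$st_interp, bins, max)
  for (nm in c("base", "mid", "top")) {
    y <- switch(nm, base = lo, mid = mid, top = hi)
    fit <- fit_line(as.numeric(centers), as.numeric(y))
    names(fit) <- paste0(nm, "_", c("icpt", "slope", "rmsd"))
    out <- c(out, fit)
  }
  # trend polynomial on time-normalized span
  tn <- if (max(t_rel) > 0) t_rel / max(t_rel) else t_rel
  cf <- poly_coefs(tn, sc$st_interp, poly_order)
  names(cf) <- paste0("poly_c", seq_along(cf) - 1L)
  c(out, cf)
}

poly_coefs <- function(tn, y, order) {
  order <- min(order, max(1L, length(unique(tn)) - 1L))
  X <- outer(tn, 0:order, `^`)
  cf <- qr.coef(qr(X), y)
  cf[is.na(cf)] <- 0
  unname(cf)
}

#' Stylize the local (salient-syllable level) F0 contour
#'
#' Pitch contour of one salient syllable window (optionally padded)
#' summarized as the envelope (`f0_mean`, `f0_max`, semitones) and order-2
#' polynomial coefficients `c0`, `c1`, `c2` on the time-normalized window.
#'
#' @param f0_track a `pitch_track`.
#' @param t_start,t_end syllable span in seconds.
#' @param ref_f0 speaker session median F0 (Hz).
#' @param padding seconds added on each side of the window (default 0).
#' @param poly_order polynomial order (default 2).
#' @return a named numeric vector, or `NULL` when fewer than 3 voiced frames.
#' @export
stylize_local <- function(f0_track, t_start, t_end, ref_f0, padding = 0,
                          poly_order = 2) {
  sc <- span_contour(f0_track, t_start - padding, t_end + padding, ref_f0)
  if (sc$n_voiced < 3) return(NULL)
  st_v <- sc$st[!is.na(sc$st)]
  t_rel <- sc$time - sc$time[1]
  tn <- if (max(t_rel) > 0) t_rel / max(t_rel) else t_rel
  cf <- poly_coefs(tn, sc$st_interp, poly_order)
  out <- c(f0_mean = mean(st_v), f0_max = max(st_v))
  names(cf) <- paste0("c", seq_along(cf) - 1L)
  c(out, cf)
}

# type-II DCT power spectrum of a mean-removed contour; frequency of
# component k (k >= 1) on an N-point 100 Hz contour is k * 50 / N Hz
dct_band_fraction <- function(x, dt, center_hz, bandwidth_hz = 1) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4) return(NA_real_)
  x <- x - mean(x)
  if (all(x == 0)) return(0)
  k <- seq_len(n - 1)
  basis <- cos(pi * outer(k, (2 * seq_len(n) - 1)) / (2 * n))
  coefs <- as.numeric(basis %*% x)
  freqs <- k / (2 * n * dt)
  pw <- coefs^2
  band <- freqs >= (center_hz - bandwidth_hz) & freqs <= (center_hz + bandwidth_hz)
  sum(pw[band]) / sum(pw)
}

#' Rhythm features of a dialog-act unit
#'
#' The salient-syllable rate (`syll_rate`, syllables per second) and the
#' influence of the syllable level on the unit's energy and F0 contours,
#' measured as the fraction of discrete-cosine spectral power of the
#' mean-removed contour lying within `syll_rate` +/- `bandwidth_hz`.
#'
#' @param energy an `energy_track` restricted or restrictable to the unit.
#' @param f0_track a `pitch_track` (or `NULL` to skip the F0 influence).
#' @param t_start,t_end unit span (seconds).
#' @param syllables optional precomputed syllable table for the span;
#'   detected from `energy` when `NULL`.
#' @param config a [syllable_config()].
#' @param bandwidth_hz half-width of the spectral band (default 1).
#' @return a named vector `syll_rate`, `energy_influence`, `f0_influence`
#'   (influences `NA` when no syllable was detected).
#' @export
rhythm_features <- function(energy, f0_track = NULL, t_start, t_end,
                            syllables = NULL, config = syllable_config(),
                            bandwidth_hz = 1) {
  dur <- t_end - t_start
  stopifnot(dur > 0)
  sel <- energy$time >= t_start & energy$time <= t_end
  en <- energy[sel, ]
  if (is.null(syllables)) {
    syllables <- detect_salient_syllables(en, config)
  }
  rate <- nrow(syllables) / dur
  if (nrow(syllables) == 0) {
    return(c(syll_rate = 0, energy_influence = NA_real_,
             f0_influence = NA_real_))
  }
  dt <- if (nrow(en) > 1) en$time[2] - en$time[1] else 0.01
  e_inf <- dct_band_fraction(en$rms, dt, rate, bandwidth_hz)
  f_inf <- NA_real_
  if (!is.null(f0_track)) {
    fsel <- f0_track$time >= t_start & f0_track$time <= t_end
    f0 <- f0_track$f0[fsel]
    voiced <- !is.na(f0)
    if (sum(voiced) >= 4) {
      tt <- f0_track$time[fsel]
      f0i <- approx(tt[voiced], f0[voiced], xout = tt, rule = 2)$y
      f_inf <- dct_band_fraction(f0i, dt, rate, bandwidth_hz)
    }
  }
  c(syll_rate = rate, energy_influence = e_inf, f0_influence = f_inf)
}

#' Per-unit prosodic feature table for a conversation
#'
#' Runs the full prosodic stylization for every complete utterance (= dialog
#' act unit) of a conversation: global F0 stylization, rhythm features, and
#' per-unit means of the salient-syllable local stylization. Units with too
#' few voiced frames are flagged unusable and dropped.
#'
#' @param conv a [conversation()].
#' @param tracks named list, one entry per `speaker_id`, each a list with
#'   `pitch` (a `pitch_track`) and `energy` (an `energy_track`).
#' @param config a [syllable_config()].
#' @param poly_order global trend polynomial order.
#' @return a tibble keyed by (`dyad_id`, `role`, `unit_index`, `dialog_act`)
#'   with one column per prosodic feature.
#' @export
prosodic_unit_features <- function(conv, tracks, config = syllable_config(),
                                   poly_order = 3) {
  stopifnot(inherits(conv, "conversation"))
  utt <- conv$utterances[conv$utterances$complete, ]
  ref <- lapply(tracks, function(tr) median(tr$pitch$f0, na.rm = TRUE))
  rows <- list()
  for (i in seq_len(nrow(utt))) {
    sp <- utt$speaker_id[i]
    tr <- tracks[[sp]]
    if (is.null(tr)) next
    g <- stylize_global(tr$pitch, utt$t_start[i], utt$t_end[i], ref[[sp]],
                        poly_order = poly_order)
    if (is.null(g)) next
    sel <- tr$energy$time >= utt$t_start[i] & tr$energy$time <= utt$t_end[i]
    syl <- detect_salient_syllables(tr$energy[sel, ], config)
    rhy <- rhythm_features(tr$energy, tr$pitch, utt$t_start[i], utt$t_end[i],
                           syllables = syl, config = config)
    loc <- NULL
    if (nrow(syl) > 0) {
      mats <- lapply(seq_len(nrow(syl)), function(k) {
        stylize_local(tr$pitch, syl$t_start[k], syl$t_end[k], ref[[sp]])
      })
      mats <- mats[!vapply(mats, is.null, logical(1))]
      if (length(mats) > 0) loc <- colMeans(do.call(rbind, mats))
    }
    if (is.null(loc)) {
      loc <- c(f0_mean = NA_real_, f0_max = NA_real_, c0 = NA_real_,
               c1 = NA_real_, c2 = NA_real_)
    }
    names(loc) <- paste0("syl_", names(loc))
    rows[[length(rows) + 1L]] <- tibble::as_tibble(
      c(list(dyad_id = conv$dyad_id, role = utt$role[i], unit_index = i,
             dialog_act = utt$dialog_act[i]),
        as.list(c(g, rhy, loc))))
  }
  dplyr::bind_rows(rows)
}
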