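test_that("autocorrelation F0 recovers a pure tone and flags silence", {
  sr <- 16000
  tone <- waveform(sin(2 * pi * 200 * seq(0, 1, length.out = sr)), sr)
  track <- extract_f0(tone)
  expect_s3_class(track, "pitch_track")
  expect_lt(abs(median(track$f0, na.rm = TRUE) - 200), 2)
  expect_equal(diff(track$time)[1], 0.01, tolerance = 1e-9)

  silence <- waveform(rep(0, sr), sr)
  expect_warning(tr0 <- extract_f0(silence), "no voiced")
  expect_true(all(is.na(tr0$f0)))
})

test_that("external pitch tracks are resampled onto the 10 ms grid", {
  # 200 Hz grid over 1.5 s
  ext <- data.frame(time = seq(0, 1.5, by = 0.005),
                    f0 = 150 + 10 * seq(0, 1.5, by = 0.005))
  track <- extract_f0(ext)
  expect_lt(abs(nrow(track) - 1.5 * 100), 2)
  expect_equal(track$f0[track$time == 1], 160, tolerance = 1e-6)
  # unvoiced gaps stay unvoiced rather than being bridged
  ext$f0[ext$time > 0.5 & ext$time < 0.7] <- NA
  track2 <- extract_f0(ext)
  expect_true(all(is.na(track2$f0[track2$time > 0.52 & track2$time < 0.68])))
})

test_that("energy is Hamming-weighted RMS with expected invariances", {
  sr <- 8000
  x <- sin(2 * pi * 220 * seq(0, 1, length.out = sr))
  en <- compute_energy(waveform(x, sr))
  inner <- en$rms[en$time > 0.1 & en$time < 0.9]
  expect_lt(sd(inner) / mean(inner), 0.05)

  zeros <- compute_energy(waveform(rep(0, sr), sr))
  expect_true(all(zeros$rms == 0))

  en2 <- compute_energy(waveform(2 * x, sr))
  expect_equal(en2$rms, 2 * en$rms, tolerance = 1e-12)

  # window longer than the signal: one whole-signal window
  short <- compute_energy(waveform(x[1:100], sr))
  expect_equal(nrow(short), 1)
})

test_that("salient syllables are maximal supra-threshold runs", {
  t <- seq(0, 2, by = 0.01)
  silence <- make_energy_track(t, rep(0, length(t)))
  expect_equal(nrow(detect_salient_syllables(silence)), 0)

  burst <- make_energy_track(t, ifelse(t >= 0.9 & t < 1.1, 1, 0.01))
  syl <- detect_salient_syllables(burst)
  expect_equal(nrow(syl), 1)
  expect_lt(abs(syl$t_start - 0.9), 0.011)
  expect_lt(abs(syl$t_end - 1.1), 0.011)

  two <- make_energy_track(t, ifelse((t >= 0.2 & t < 0.4) |
                                       (t >= 1.2 & t < 1.4), 1, 0.01))
  syl2 <- detect_salient_syllables(two)
  expect_equal(nrow(syl2), 2)
  # disjoint and ordered
  expect_true(all(syl2$t_start[-1] >= syl2$t_end[-nrow(syl2)]))

  # count is non-increasing in the minimum duration
  counts <- vapply(c(0.05, 0.1, 0.25, 0.5), function(md) {
    nrow(detect_salient_syllables(two, syllable_config(min_duration_s = md)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("global stylization satisfies closed forms", {
  t <- seq(0, 1, by = 0.01)
  const <- make_pitch_track(t, rep(180, length(t)))
  g <- stylize_global(const, 0, 1, ref_f0 = 180)
  expect_equal(unname(g["f0_mean"]), 0, tolerance = 1e-10)
  expect_equal(unname(g["f0_mean"]), unname(g["f0_max"]))
  expect_equal(unname(g[c("base_slope", "mid_slope", "top_slope")]),
               rep(0, 3), tolerance = 1e-10)
  expect_equal(unname(g[c("base_rmsd", "mid_rmsd", "top_rmsd")]),
               rep(0, 3), tolerance = 1e-10)

  # exact semitone ramp: midline slope = b, rmsd ~ 0
  b <- 4
  ramp <- make_pitch_track(t, 200 * 2^((b * (t - 0.5)) / 12))
  g2 <- stylize_global(ramp, 0, 1, ref_f0 = 200)
  expect_equal(unname(g2["mid_slope"]), b, tolerance = 1e-6)
  expect_lt(unname(g2["mid_rmsd"]), 1e-8)

  # too few voiced frames -> unusable
  sparse <- make_pitch_track(t, c(rep(NA, 97), 180, 181, 180, NA))
  expect_null(stylize_global(sparse, 0, 1, ref_f0 = 180))
})

test_that("midline RMSD equals an independent least-squares refit", {
  set.seed(3)
  t <- seq(0, 1.2, by = 0.01)
  f0 <- 200 * 2^((2 * t + 0.8 * sin(2 * pi * 3 * t) +
                    rnorm(length(t), sd = 0.2)) / 12)
  g <- stylize_global(make_pitch_track(t, f0), 0, 1.2, ref_f0 = 200)
  # oracle: rebuild window medians and refit with lm
  st <- 12 * log2(f0 / 200)
  bins <- floor(t / 0.1)
  centers <- as.numeric(tapply(t, bins, mean))
  med <- as.numeric(tapply(st, bins, median))
  fit <- lm(med ~ centers)
  expect_equal(unname(g["mid_slope"]), unname(coef(fit)[2]),
               tolerance = 1e-8)
  expect_equal(unname(g["mid_rmsd"]), sqrt(mean(resid(fit)^2)),
               tolerance = 1e-8)
})

test_that("fitted baseline <= midline <= topline across generated contours", {
  set.seed(11)
  t <- seq(0, 1.5, by = 0.01)
  for (rep in 1:10) {
    slope <- runif(1, -4, 4)
    mod <- runif(1, 0.5, 2) * abs(sin(2 * pi * runif(1, 2, 5) * t))
    st <- slope * t + mod
    g <- stylize_global(make_pitch_track(t, 220 * 2^(st / 12)), 0, 1.5,
                        ref_f0 = 220)
    for (tt in seq(0, 1.5, by = 0.1)) {
      base_v <- g["base_icpt"] + g["base_slope"] * tt
      mid_v <- g["mid_icpt"] + g["mid_slope"] * tt
      top_v <- g["top_icpt"] + g["top_slope"] * tt
      expect_lte(base_v, mid_v + 1e-8)
      expect_lte(mid_v, top_v + 1e-8)
    }
  }
})

test_that("semitone conversion removes register", {
  set.seed(5)
  t <- seq(0, 1, by = 0.01)
  st <- 2 * t + 0.5 * sin(2 * pi * 2 * t)
  f0 <- 180 * 2^(st / 12)
  g1 <- stylize_global(make_pitch_track(t, f0), 0, 1, ref_f0 = 180)
  g2 <- stylize_global(make_pitch_track(t, 1.5 * f0), 0, 1, ref_f0 = 1.5 * 180)
  expect_equal(g1, g2, tolerance = 1e-9)
})

test_that("local stylization recovers quadratic shapes", {
  t <- seq(0, 0.3, by = 0.01)
  const <- make_pitch_track(t, rep(200, length(t)))
  l <- stylize_local(const, 0, 0.3, ref_f0 = 200)
  expect_equal(unname(l[c("c1", "c2")]), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(l["c0"]), 0, tolerance = 1e-9)

  # symmetric downward parabola on normalized time: c1 = 4, c2 = -4 gives
  # peak at the window centre
  st <- 4 * (t / 0.3) - 4 * (t / 0.3)^2
  par <- make_pitch_track(t, 200 * 2^(st / 12))
  l2 <- stylize_local(par, 0, 0.3, ref_f0 = 200)
  expect_equal(unname(l2["c1"]), 4, tolerance = 1e-6)
  expect_equal(unname(l2["c2"]), -4, tolerance = 1e-6)
  expect_lt(l2["c2"], 0)

  # three voiced frames: exact interpolation
  t3 <- c(0, 0.01, 0.02)
  tr3 <- make_pitch_track(t3, c(180, 190, 185))
  l3 <- stylize_local(tr3, 0, 0.02, ref_f0 = 180)
  fitted <- l3["c0"] + l3["c1"] * c(0, 0.5, 1) + l3["c2"] * c(0, 0.5, 1)^2
  expect_equal(unname(fitted), 12 * log2(c(180, 190, 185) / 180),
               tolerance = 1e-8)
  # unvoiced syllable flagged
  expect_null(stylize_local(make_pitch_track(t3, rep(NA_real_, 3)), 0, 0.02,
                            ref_f0 = 180))
})

test_that("rhythm features measure rate and contour modulation", {
  t <- seq(0, 2, by = 0.01)
  syl5 <- tibble::tibble(t_start = seq(0.1, 1.7, length.out = 5),
                         t_end = seq(0.25, 1.85, length.out = 5),
                         duration = 0.15, peak_rms = 1)
  flat <- make_energy_track(t, rep(0.5, length(t)))
  r <- rhythm_features(flat, NULL, 0, 2, syllables = syl5)
  expect_equal(unname(r["syll_rate"]), 2.5)
  expect_equal(unname(r["energy_influence"]), 0)

  # 4 Hz amplitude modulation with detected rate 4/s: band fraction near max
  tr <- synthesize_tracks(2, 180, 0, 4)
  syl <- detect_salient_syllables(tr$energy)
  r4 <- rhythm_features(tr$energy, tr$pitch, 0, 2, syllables = syl)
  expect_equal(unname(r4["syll_rate"]), 4, tolerance = 0.13)
  other_bands <- vapply(c(1, 2, 7, 9), function(hz) {
    entrainr:::dct_band_fraction(tr$energy$rms, 0.01, hz, 1)
  }, numeric(1))
  expect_gt(r4["energy_influence"], max(other_bands))

  # zero syllables: rate 0, influence undefined
  quiet <- make_energy_track(t, rep(0, length(t)))
  r0 <- rhythm_features(quiet, NULL, 0, 2,
                        syllables = detect_salient_syllables(quiet))
  expect_equal(unname(r0["syll_rate"]), 0)
  expect_true(is.na(r0["energy_influence"]))
})

test_that("feature extraction is deterministic for fixed inputs", {
  tr <- synthesize_tracks(1.5, 200, 2, 3)
  g1 <- stylize_global(tr$pitch, 0, 1.5, ref_f0 = 200)
  g2 <- stylize_global(tr$pitch, 0, 1.5, ref_f0 = 200)
  expect_identical(g1, g2)
  s1 <- detect_salient_syllables(tr$energy)
  s2 <- detect_salient_syllables(tr$energy)
  expect_identical(s1, s2)
})

test_that("track synthesis round-trips through feature extraction", {
  tr <- synthesize_tracks(2, 180, 3, 4)
  g <- stylize_global(tr$pitch, 0, 2, ref_f0 = 180)
  expect_lt(abs(g["f0_mean"]), 0.5)              # mean on target (semitones)
  expect_lt(abs(g["mid_slope"] - 3) / 3, 0.1)    # slope within 10%
  syl <- detect_salient_syllables(tr$energy)
  expect_lte(abs(nrow(syl) - 8), 1)              # 4/s over 2 s
  expect_error(synthesize_tracks(0.5, 180, 0, 1),
               class = "entrainr_invalid_input")
})

test_that("prosodic unit features integrate tracks and transcripts", {
  utt <- tibble::tibble(
    speaker_id = c("EX1", "P1"), role = c("examiner", "participant"),
    t_start = c(0, 2.2), t_end = c(2, 4.2),
    dialog_act = c("query_wh", "reply_w"), complete = TRUE,
    text = c("describe the shape", "a big triangle"))
  conv <- conversation("d", utt)
  tre <- synthesize_tracks(2, 190, 1, 3)
  trp <- synthesize_tracks(2, 210, -1, 4)
  trp$pitch$time <- trp$pitch$time + 2.2
  trp$energy$time <- trp$energy$time + 2.2
  tracks <- list(EX1 = list(pitch = tre$pitch, energy = tre$energy),
                 P1 = list(pitch = trp$pitch, energy = trp$energy))
  feats <- prosodic_unit_features(conv, tracks)
  expect_equal(nrow(feats), 2)
  expect_true(all(c("f0_mean", "mid_slope", "syll_rate", "syl_f0_mean") %in%
                    names(feats)))
  expect_equal(feats$role, c("examiner", "participant"))
  expect_gt(feats$syll_rate[2], feats$syll_rate[1])
})
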