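test_that("WAV write/read round trip is sample-exact at 16-bit", {
  w <- synthesize_call("coo", jitter = 0.05, seed = 42)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(w, path)
  back <- read_wav(path)
  expect_equal(back$sample_rate, 44100)
  # quantize once: a second write/read cycle must be bit-identical
  path2 <- withr::local_tempfile(fileext = ".wav")
  write_wav(back, path2)
  back2 <- read_wav(path2)
  expect_identical(back$samples, back2$samples)
  expect_lt(max(abs(back$samples - w$samples)), 1 / 32767)
})

test_that("f0 tracker is accurate within 1% on pure tones at 20 dB SNR", {
  sr <- 44100
  t <- seq(0, 0.5, by = 1 / sr)
  set.seed(11)
  for (f0 in c(100, 170, 250, 333, 450, 500)) {
    sig <- 0.5 * sin(2 * pi * f0 * t)
    noise <- rnorm(length(t), 0, sqrt(mean(sig^2)) / 10^(20 / 20))
    ct <- compute_f0_contour(waveform(sig + noise, sr))
    expect_true(all(!is.na(ct$f0)))
    expect_lt(max(abs(ct$f0 - f0) / f0), 0.01)
  }
})

test_that("silence and sub-window inputs are handled", {
  sr <- 44100
  ct <- compute_f0_contour(waveform(rep(0, sr / 2), sr))
  expect_true(all(is.na(ct$f0)))
  expect_error(extract_features(waveform(rep(0, sr / 2), sr)), "no call")
  expect_error(compute_f0_contour(waveform(rep(0.1, 100), sr)), "shorter")
  expect_error(compute_f0_contour(waveform(sin(1:22050), 44100),
                                  fmin = 500, fmax = 400))
})

test_that("constant-amplitude tone yields flat intensity and exact pitch", {
  sr <- 44100
  t <- seq(0, 0.4, by = 1 / sr)
  ft <- extract_features(waveform(0.3 * sin(2 * pi * 300 * t), sr))
  expect_lt(ft$max_amp - ft$min_amp, 0.1)
  expect_lt(abs(ft$mean_f0 - 300), 1)
  # feature ordering invariants
  expect_lte(ft$min_f0, ft$mean_f0)
  expect_lte(ft$mean_f0, ft$max_f0)
  expect_lte(ft$min_amp, ft$mean_amp)
  expect_gt(ft$duration, 0)
})

test_that("jitter-free synthesis round-trips to the type centroids", {
  prof <- call_type_profiles()
  for (ty in c("coo", "leap_coo", "bark")) {
    cen <- setNames(prof$centroid[prof$type == ty],
                    prof$feature[prof$type == ty])
    ft <- extract_features(synthesize_call(ty, jitter = 0))
    expect_lt(abs(ft$duration - cen["duration"]) / cen["duration"], 0.02)
    for (f in c("mean_f0", "min_f0", "max_f0")) {
      expect_lt(abs(ft[[f]] - cen[f]) / cen[f], 0.02)
    }
    for (f in c("mean_amp", "min_amp", "max_amp")) {
      expect_lt(abs(ft[[f]] - cen[f]), 1)
    }
  }
})

test_that("bark contour stays inside its tabulated f0 band", {
  ct <- compute_f0_contour(synthesize_call("bark", jitter = 0))
  voiced <- ct$f0[!is.na(ct$f0)]
  expect_gt(length(voiced), 0)
  expect_true(all(voiced >= 360 * 0.98 & voiced <= 398 * 1.02))
})

test_that("classification: centroid identity, tie break, gain invariance", {
  prof <- call_type_profiles()
  coo_cen <- as.list(setNames(prof$centroid[prof$type == "coo"],
                              prof$feature[prof$type == "coo"]))
  cl <- classify_call(coo_cen, prof)
  expect_identical(cl$type, "coo")
  expect_equal(cl$distance, 0)
  # equidistant between coo and leap_coo: first profile in order wins
  two <- prof[prof$type %in% c("coo", "leap_coo"), ]
  mid <- as.list(setNames((two$centroid[two$type == "coo"] +
                             two$centroid[two$type == "leap_coo"]) / 2 *
                            c(1, 1, 1, 1, 1, 1, 1),
                          two$feature[two$type == "coo"]))
  # force exact equidistance by using equal dispersions
  two$sd <- rep(two$sd[two$type == "coo"], 2)
  expect_identical(classify_call(mid, two)$type, "coo")
  # halving the gain leaves f0/duration classification features unchanged
  w <- synthesize_call("leap_coo", jitter = 0)
  ft1 <- extract_features(w)
  ft2 <- extract_features(waveform(w$samples * 0.5, w$sample_rate))
  expect_equal(ft2$mean_f0, ft1$mean_f0, tolerance = 1e-6)
  expect_equal(ft2$duration, ft1$duration)
  expect_equal(ft1$mean_amp - ft2$mean_amp, 20 * log10(2), tolerance = 0.05)
})

test_that("synthesis is deterministic and rejects unknown call types", {
  expect_error(synthesize_call("screech"), "unknown call type")
  w1 <- synthesize_call("coo", jitter = 0.1, seed = 3)
  w2 <- synthesize_call("coo", jitter = 0.1, seed = 3)
  expect_identical(w1$samples, w2$samples)
  w3 <- synthesize_call("coo", jitter = 0, seed = 1)
  w4 <- synthesize_call("coo", jitter = 0, seed = 99) # jitter 0: seed-free
  expect_identical(w3$samples, w4$samples)
})

test_that("directory batch extraction classifies a synthesized set", {
  dir <- withr::local_tempdir()
  set <- synthesize_call_set(c(coo = 2L, bark = 1L), jitter = 0, seed = 5)
  for (i in seq_along(set$waveforms)) {
    write_wav(set$waveforms[[i]], file.path(dir, sprintf("c%02d.wav", i)))
  }
  tab <- extract_features_dir(dir)
  expect_equal(nrow(tab), 3)
  expect_equal(sort(table(tab$call_type), decreasing = TRUE),
               sort(table(set$types), decreasing = TRUE))
})
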