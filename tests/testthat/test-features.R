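# Time- and frequency-domain feature definitions.

test_that("canonical test vector reproduces hand-evaluated feature values", {
  x <- c(1, -2, 3, -1)
  expected <- c(MAV = 1.75, SSI = 15, IEMG = 7, P2P = 5, MAXAV = 3,
                MINAV = 1, WL = 12, AAC = 3, DAMV = 4,
                DASDV = sqrt(50 / 3), ZC = 3, SSC = 2, WAMP = 3, VAR = 3,
                LD = 6^(1 / 4), TM3 = 4.75, TM5 = 52.75, RSSQ = sqrt(15),
                BP = 3.75, MAD0 = 1.75, MAD1 = 1.75)
  for (nm in names(expected))
    expect_equal(compute_time_feature(nm, x), unname(expected[nm]),
                 tolerance = 1e-12, info = nm)
})

test_that("constant signals zero out the change-sensitive features", {
  x <- rep(2.5, 40)
  for (nm in c("ZC", "SSC", "WL", "AAC", "WAMP", "P2P", "SD", "ENTROPY"))
    expect_equal(compute_time_feature(nm, x), 0, info = nm)
  expect_equal(compute_time_feature("MAV", x), 2.5)
  expect_equal(compute_time_feature("VAR", x), 40 * 2.5^2 / 41)
})

test_that("input validation rejects bad windows and names", {
  expect_error(compute_time_feature("NOPE", c(1, 2)), "unknown feature")
  expect_error(compute_time_feature("MAV", 1), "2 samples")
  expect_error(compute_time_feature("MAV", c(1, NA, 2)), "non-finite")
  expect_error(compute_time_feature("MNF", c(1, 2, 3)), "spectral")
  expect_error(signal_window(c(1, 2), -5), "positive")
})

test_that("amplitude scaling laws hold", {
  set.seed(7)
  x <- rnorm(256)
  a <- 3.7
  p <- feature_params()
  w1 <- signal_window(x, 500)
  w2 <- signal_window(a * x, 500)
  lin <- c("MAV", "RMS", "WL", "P2P", "IEMG", "MAD0", "MAD1", "SD", "RSSQ",
           "DAMV", "DASDV", "AAC")
  for (nm in lin)
    expect_equal(compute_time_feature(nm, a * x, p),
                 a * compute_time_feature(nm, x, p), tolerance = 1e-9,
                 info = nm)
  for (nm in c("SSI", "VAR", "BP"))
    expect_equal(compute_time_feature(nm, a * x, p),
                 a^2 * compute_time_feature(nm, x, p), tolerance = 1e-9,
                 info = nm)
  for (nm in c("ZC", "SSC", "SKEW", "KURT"))
    expect_equal(compute_time_feature(nm, a * x, p),
                 compute_time_feature(nm, x, p), tolerance = 1e-9, info = nm)
  expect_equal(compute_time_feature("TM3", a * x, p),
               a^3 * compute_time_feature("TM3", x, p), tolerance = 1e-9)
  expect_equal(compute_time_feature("TM5", a * x, p),
               a^5 * compute_time_feature("TM5", x, p), tolerance = 1e-9)
  s1 <- compute_spectral_features(w1, p)
  s2 <- compute_spectral_features(w2, p)
  expect_equal(s1$MNF, s2$MNF, tolerance = 1e-9)
  expect_equal(s1$MDF, s2$MDF)
  expect_equal(s2$PKF, a^2 * s1$PKF, tolerance = 1e-9)
})

test_that("counting features are bounded and monotone in their thresholds", {
  set.seed(11)
  for (rep in 1:20) {
    x <- rnorm(50)
    N <- length(x)
    zc <- compute_time_feature("ZC", x)
    ssc <- compute_time_feature("SSC", x)
    wamp <- compute_time_feature("WAMP", x)
    expect_true(zc >= 0 && zc <= N - 1)
    expect_true(ssc >= 0 && ssc <= N - 2)
    expect_true(wamp >= 0 && wamp <= N - 1)
    for (thr in c(0.5, 1, 2)) {
      expect_lte(compute_time_feature("ZC", x,
                                      feature_params(zc_threshold = thr)), zc)
      expect_lte(compute_time_feature("WAMP", x,
                                      feature_params(wamp_threshold = thr)),
                 wamp)
    }
  }
})

test_that("sign symmetry: negation preserves even features, flips skewness", {
  set.seed(13)
  x <- rnorm(300)
  w <- signal_window(x, 500)
  wn <- signal_window(-x, 500)
  for (nm in c("MAV", "SSI", "RMS", "WL", "ZC", "SSC", "WAMP", "KURT"))
    expect_equal(compute_time_feature(nm, -x), compute_time_feature(nm, x),
                 tolerance = 1e-9, info = nm)
  expect_equal(compute_time_feature("SKEW", -x),
               -compute_time_feature("SKEW", x), tolerance = 1e-9)
  expect_equal(unlist(compute_spectral_features(wn)),
               unlist(compute_spectral_features(w)), tolerance = 1e-9)
})

test_that("amplitude ordering MINAV <= MAV <= MAXAV and MAXAV >= RMS", {
  set.seed(17)
  for (rep in 1:20) {
    x <- rnorm(64) * runif(1, 0.1, 10)
    mav <- compute_time_feature("MAV", x)
    expect_lte(compute_time_feature("MINAV", x), mav)
    expect_lte(mav, compute_time_feature("MAXAV", x))
    expect_gte(compute_time_feature("MAXAV", x),
               compute_time_feature("RMS", x))
  }
})

test_that("pure tone concentrates MNF and MDF at the tone frequency", {
  fs <- 500
  N <- 2000
  t <- (0:(N - 1)) / fs
  w <- signal_window(sin(2 * pi * 50 * t), fs)
  sp <- compute_spectral_features(w)
  bin <- fs / N
  expect_lt(abs(sp$MNF - 50), bin)
  expect_lt(abs(sp$MDF - 50), bin)
  wf <- compute_spectral_features(w, feature_params(pkf_mode = "frequency"))
  expect_equal(wf$PKF, 50)
})

test_that("white noise has mean frequency near half Nyquist", {
  set.seed(19)
  w <- signal_window(rnorm(2000), 500)
  sp <- compute_spectral_features(w)
  expect_lt(abs(sp$MNF - 125) / 125, 0.05)
  expect_true(sp$MDF >= 0 && sp$MDF <= 250)
})

test_that("all-zero window yields zero MNF/MDF with a warning", {
  w <- signal_window(rep(0, 64), 500)
  expect_warning(sp <- compute_spectral_features(w), "all-zero")
  expect_equal(sp$MNF, 0)
  expect_equal(sp$MDF, 0)
})

test_that("welch spectral method stays close to the periodogram for a tone", {
  fs <- 500
  t <- (0:1999) / fs
  w <- signal_window(sin(2 * pi * 50 * t) + 0.01 * sin(2 * pi * 120 * t), fs)
  spw <- compute_spectral_features(w, feature_params(spectral_method = "welch"))
  expect_lt(abs(spw$MDF - 50), 2)
})

test_that("per-trial vectors have channel-major canonical naming", {
  chans <- make_trial_windows(n_channels = 8, n = 64)
  fv <- extract_window_features(chans)
  expect_length(fv, 296)
  expect_equal(names(fv)[1:3], c("ch1_KURT", "ch1_SKEW", "ch1_SSI"))
  expect_equal(names(fv)[38], "ch2_KURT")
  expect_equal(unname(fv["ch3_WAMP"]),
               compute_time_feature("WAMP", chans[[3]]$samples))
  expect_equal(unname(fv["ch5_ENTROPY"]),
               compute_time_feature("ENTROPY", chans[[5]]$samples))
  fv1 <- extract_window_features(chans[1])
  expect_length(fv1, 37)
})

test_that("inconsistent trial metadata is rejected", {
  chans <- make_trial_windows(n_channels = 2)
  chans[[2]]$gesture_label <- "other"
  expect_error(extract_window_features(chans), "inconsistent")
  chans <- make_trial_windows(n_channels = 2)
  chans[[2]]$channel_id <- 1L
  expect_error(extract_window_features(chans), "duplicate channel")
})

test_that("extract_dataset matches single-window recomputation cell by cell", {
  ds <- generate_semg_dataset(small_emg_config(seed = 5))
  fm <- extract_dataset(ds)
  expect_equal(dim(fm), c(160, 3 + 37 * 4))
  expect_equal(fm$gesture[1], ds$manifest$gesture[1])
  set.seed(23)
  feats <- semg_feature_names()
  for (k in 1:10) {
    i <- sample(nrow(fm), 1)
    ch <- sample(4, 1)
    nm <- sample(feats, 1)
    col <- paste0("ch", ch, "_", nm)
    x <- ds$trials[[i]][, ch]
    ref <- if (nm %in% c("MNF", "MDF", "PKF")) {
      compute_spectral_features(signal_window(x, ds$sampling_rate))[[nm]]
    } else {
      compute_time_feature(nm, x)
    }
    expect_equal(fm[[col]][i], ref, tolerance = 1e-9,
                 info = paste(i, col))
  }
})

test_that("extract_dataset handles empty input and ragged channels", {
  empty <- extract_dataset(list(), sampling_rate = 500)
  expect_equal(nrow(empty), 0)
  expect_equal(ncol(empty), 3 + 296)
  tr <- list(matrix(rnorm(40), 20, 2), matrix(rnorm(60), 20, 3))
  expect_error(extract_dataset(tr, sampling_rate = 500), "ragged")
})
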