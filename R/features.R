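# Feature extraction: 37 time- and frequency-domain descriptors per
# single-channel sEMG window, and assembly of per-trial feature vectors.

#' Canonical feature names
#'
#' The fixed, ordered list of the 37 per-channel features computed by this
#' package. Column names of extracted feature matrices are
#' \code{ch<channel>_<NAME>} in channel-major order, iterating this list
#' within each channel.
#'
#' @return Character vector of length 37.
#' @export
semg_feature_names <- function() {
  c("KURT", "SKEW", "SSI", "SD", "RMS", "ENTROPY", "MAV", "AAC", "DASDV",
    "LD", "MMAV1", "MMAV2", "SSC", "WAMP", "WL", "VAR", "RSSQ", "MNF",
    "MDF", "PKF", "P2P", "BP", "TM3", "TM5", "V0", "MAD0", "MAD1", "IEMG",
    "MAXAV", "ZC", "AVSER", "AVSSR", "COV", "DAMV", "IQR", "MVSR", "MINAV")
}

.spectral_names <- c("MNF", "MDF", "PKF")

#' Feature extraction parameters
#'
#' Conventions and thresholds used by the feature definitions. Defaults follow
#' common myoelectric-control practice: detection thresholds at zero,
#' temporal moments at orders 3 and 5, excess kurtosis (offset 3), a 64-bin
#' amplitude histogram for Shannon entropy, and a full-window rectangular
#' periodogram for the spectral descriptors.
#'
#' @param zc_threshold Amplitude-gap threshold in the zero-crossing count.
#' @param ssc_threshold Threshold on the slope-product in the slope-sign-change
#'   count (amplitude-squared units).
#' @param wamp_threshold Threshold T on consecutive-sample differences in the
#'   Willison amplitude.
#' @param tm_orders Orders at which the absolute temporal moment is
#'   instantiated (canonical list uses 3 and 5).
#' @param v_order Order v of the v-order feature (default 3).
#' @param entropy_bins Number of equal-width amplitude histogram bins for
#'   Shannon entropy.
#' @param mmav_weight_rule Weighting for MMAV2: \code{"literature-standard"}
#'   uses the ramp weights 4i/L and 4(L-i)/L outside the central half;
#'   \code{"paper-literal"} keeps the ramp on the leading quarter only and
#'   weights the trailing quarter at 0.5.
#' @param spectral_method \code{"periodogram"} (full-window, rectangular,
#'   deterministic) or \code{"welch"} (averaged modified periodograms,
#'   Hann window, 50 percent overlap).
#' @param pkf_mode \code{"power-value"} returns the maximum of the power
#'   spectrum; \code{"frequency"} returns the frequency at which it occurs.
#' @param kurtosis_offset Constant subtracted from the fourth standardized
#'   moment (3 gives excess kurtosis).
#' @return An object of class \code{feature_params}.
#' @export
feature_params <- function(zc_threshold = 0, ssc_threshold = 0,
                           wamp_threshold = 0, tm_orders = c(3, 5),
                           v_order = 3, entropy_bins = 64,
                           mmav_weight_rule = c("literature-standard",
                                                "paper-literal"),
                           spectral_method = c("periodogram", "welch"),
                           pkf_mode = c("power-value", "frequency"),
                           kurtosis_offset = 3) {
  mmav_weight_rule <- match.arg(mmav_weight_rule)
  spectral_method <- match.arg(spectral_method)
  pkf_mode <- match.arg(pkf_mode)
  if (zc_threshold < 0 || ssc_threshold < 0 || wamp_threshold < 0)
    stopf("feature thresholds must be >= 0")
  if (entropy_bins < 1) stopf("entropy_bins must be >= 1")
  if (any(tm_orders <= 0) || any(tm_orders != round(tm_orders)))
    stopf("tm_orders must be positive integers")
  structure(list(zc_threshold = zc_threshold, ssc_threshold = ssc_threshold,
                 wamp_threshold = wamp_threshold, tm_orders = tm_orders,
                 v_order = v_order, entropy_bins = entropy_bins,
                 mmav_weight_rule = mmav_weight_rule,
                 spectral_method = spectral_method, pkf_mode = pkf_mode,
                 kurtosis_offset = kurtosis_offset),
            class = "feature_params")
}

#' Single-channel signal window
#'
#' One channel's samples for one labelled trial: the unit on which every
#' per-channel feature is defined.
#'
#' @param samples Numeric vector of raw amplitudes (length >= 2, finite).
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_id Integer channel index (1-based).
#' @param trial_id Trial identifier.
#' @param gesture_label Gesture class label.
#' @return An object of class \code{signal_window}.
#' @export
signal_window <- function(samples, sampling_rate, channel_id = 1L,
                          trial_id = "trial1", gesture_label = NA) {
  samples <- as.numeric(samples)
  if (length(samples) < 2) stopf("signal window needs at least 2 samples")
  if (!all(is.finite(samples))) stopf("signal window contains non-finite samples")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stopf("sampling_rate must be positive")
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 channel_id = as.integer(channel_id), trial_id = trial_id,
                 gesture_label = gesture_label),
            class = "signal_window")
}

.as_window_samples <- function(w) {
  if (inherits(w, "signal_window")) w$samples else as.numeric(w)
}

# MMAV weight vectors for a window of length L.
.mmav_weights <- function(L, rule) {
  i <- seq_len(L)
  w1 <- ifelse(i >= 0.25 * L & i <= 0.75 * L, 1, 0.5)
  if (rule == "literature-standard") {
    w2 <- ifelse(i < 0.25 * L, 4 * i / L,
                 ifelse(i > 0.75 * L, 4 * (L - i) / L, 1))
  } else {
    w2 <- ifelse(i < 0.25 * L, 4 * i / L,
                 ifelse(i > 0.75 * L, 0.5, 1))
  }
  list(w1 = w1, w2 = w2)
}

#' Compute one time-domain feature from a window
#'
#' Evaluates a single named time-domain feature on one signal window. The
#' spectral descriptors (MNF, MDF, PKF) are computed by
#' \code{\link{compute_spectral_features}} instead.
#'
#' @param name Feature name from \code{\link{semg_feature_names}} (time-domain
#'   members only).
#' @param w A \code{\link{signal_window}} or numeric vector.
#' @param params A \code{\link{feature_params}} object.
#' @return A single numeric value.
#' @export
compute_time_feature <- function(name, w, params = feature_params()) {
  x <- .as_window_samples(w)
  N <- length(x)
  if (N < 2) stopf("feature '%s': window must have >= 2 samples", name)
  if (!all(is.finite(x))) stopf("feature '%s': non-finite samples", name)
  if (!name %in% semg_feature_names())
    stopf("unknown feature name '%s'", name)
  if (name %in% .spectral_names)
    stopf("'%s' is a spectral feature; use compute_spectral_features()", name)
  p <- params
  a <- abs(x)
  d <- x[-1] - x[-N]
  switch(name,
    KURT = {
      y <- x - mean(x)
      m2 <- mean(y^2)
      if (m2 > 0) mean(y^4) / m2^2 - p$kurtosis_offset else 0
    },
    SKEW = {
      y <- x - mean(x)
      m2 <- mean(y^2)
      if (m2 > 0) mean(y^3) / m2^1.5 else 0
    },
    SSI = sum(x^2),
    SD = stats::sd(x),
    RMS = sqrt(mean(x^2)),
    ENTROPY = {
      rng <- max(x) - min(x)
      if (rng == 0) return(0)
      b <- p$entropy_bins
      idx <- pmin(floor((x - min(x)) / rng * b) + 1L, b)
      pr <- tabulate(idx, nbins = b) / N
      -sum(pr[pr > 0] * log(pr[pr > 0]))
    },
    MAV = mean(a),
    AAC = sum(abs(d)) / N,
    DASDV = sqrt(sum(d^2) / (N - 1)),
    LD = exp(mean(log(pmax(a, 1e-12)))),
    MMAV1 = sum(.mmav_weights(N, p$mmav_weight_rule)$w1 * a) / N,
    MMAV2 = sum(.mmav_weights(N, p$mmav_weight_rule)$w2 * a) / N,
    SSC = {
      if (N < 3) return(0)
      mid <- x[2:(N - 1)]
      sum((mid - x[1:(N - 2)]) * (mid - x[3:N]) > p$ssc_threshold)
    },
    WAMP = sum(abs(d) > p$wamp_threshold),
    WL = sum(abs(d)),
    VAR = sum(x^2) / (N + 1),
    RSSQ = sqrt(sum(x^2)),
    P2P = max(x) - min(x),
    BP = mean(x^2),
    TM3 = abs(mean(x^3)),
    TM5 = abs(mean(x^5)),
    V0 = mean(a^p$v_order)^(1 / p$v_order),
    MAD0 = mean(abs(x - mean(x))),
    MAD1 = mean(abs(x - stats::median(x))),
    IEMG = sum(a),
    MAXAV = max(a),
    ZC = sum(x[-N] * x[-1] < 0 & abs(d) >= p$zc_threshold),
    AVSER = sum(a^(1 / exp(1))),
    AVSSR = sum(sqrt(a)),
    COV = {
      sdv <- stats::sd(x)
      if (sdv == 0) return(0)
      m <- mean(x)
      fl <- 1e-12 * sdv
      if (abs(m) < fl) m <- if (m < 0) -fl else fl
      100 * sdv / m
    },
    DAMV = sum(abs(d)) / (N - 1),
    IQR = {
      q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
      q[2] - q[1]
    },
    MVSR = mean(sqrt(a)),
    MINAV = min(a)
  )
}

#' Power spectral estimate of a window
#'
#' One-sided power spectrum used by the spectral features. The default
#' full-window rectangular periodogram has resolution \code{fs/N} and is
#' deterministic; the Welch option averages Hann-windowed, 50-percent
#' overlapping segment periodograms for lower variance at coarser resolution.
#'
#' @param x Numeric vector of samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param method \code{"periodogram"} or \code{"welch"}.
#' @return A list with \code{frequencies} (Hz, increasing, within
#'   \code{[0, sampling_rate/2]}) and \code{power} (non-negative).
#' @export
spectral_estimate <- function(x, sampling_rate,
                              method = c("periodogram", "welch")) {
  method <- match.arg(method)
  x <- as.numeric(x)
  N <- length(x)
  if (method == "periodogram") {
    M <- floor(N / 2) + 1L
    pw <- Mod(stats::fft(x)[seq_len(M)])^2 / N
    freq <- (seq_len(M) - 1) * sampling_rate / N
  } else {
    seg <- min(256L, 2^floor(log2(N / 2)))
    step <- seg %/% 2L
    win <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg - 1) / seg)
    starts <- seq(1L, N - seg + 1L, by = step)
    M <- seg %/% 2L + 1L
    acc <- numeric(M)
    for (s in starts) {
      xs <- x[s:(s + seg - 1L)] * win
      acc <- acc + Mod(stats::fft(xs)[seq_len(M)])^2
    }
    pw <- acc / (length(starts) * sum(win^2))
    freq <- (seq_len(M) - 1) * sampling_rate / seg
  }
  list(frequencies = freq, power = pw)
}

#' Spectral features of a window
#'
#' Mean frequency (MNF, the power-weighted mean of frequency), median
#' frequency (MDF, the smallest frequency at which cumulative power reaches
#' half the total), peak frequency (PKF, per \code{pkf_mode}) and band power
#' (BP, the average signal power). An all-zero window has no defined spectrum;
#' MNF and MDF are reported as 0 with a warning so downstream matrices stay
#' finite.
#'
#' @param w A \code{\link{signal_window}} (its sampling rate is used).
#' @param params A \code{\link{feature_params}} object.
#' @return Named list with elements MNF, MDF, PKF, BP.
#' @export
compute_spectral_features <- function(w, params = feature_params()) {
  if (!inherits(w, "signal_window"))
    stopf("compute_spectral_features() needs a signal_window (sampling rate required)")
  x <- w$samples
  N <- length(x)
  if (N < 8) stopf("spectral features need at least 8 samples")
  est <- spectral_estimate(x, w$sampling_rate, params$spectral_method)
  f <- est$frequencies
  pw <- est$power
  tot <- sum(pw)
  if (tot <= 0) {
    warning("all-zero window: MNF/MDF undefined, reported as 0", call. = FALSE)
    mnf <- 0
    mdf <- 0
  } else {
    mnf <- sum(f * pw) / tot
    mdf <- f[which(cumsum(pw) >= tot / 2)[1]]
  }
  pkf <- if (params$pkf_mode == "power-value") max(pw) else f[which.max(pw)]
  list(MNF = mnf, MDF = mdf, PKF = pkf, BP = mean(x^2))
}

# Evaluation of all 37 features for a block of equal-length windows.
# S is an N x m matrix (one window per column). Returns an m x 37 matrix in
# the canonical column order. The time-domain features run in compiled code;
# per-window results are identical to the scalar functions above (asserted in
# the test suite).
.features_block <- function(S, sampling_rate, p) {
  N <- nrow(S)
  m <- ncol(S)
  if (N < 2) stopf("windows must have >= 2 samples")
  td <- .time_features_block_cpp(S, p$zc_threshold, p$ssc_threshold,
                                 p$wamp_threshold, p$v_order,
                                 as.integer(p$entropy_bins),
                                 as.integer(p$mmav_weight_rule ==
                                              "literature-standard"),
                                 p$kurtosis_offset)

  # Spectral block.
  if (p$spectral_method == "periodogram") {
    M <- floor(N / 2) + 1L
    Pw <- Mod(stats::mvfft(S)[seq_len(M), , drop = FALSE])^2 / N
    freq <- (seq_len(M) - 1) * sampling_rate / N
    ss <- .spectral_summary_cpp(Pw, freq)
    mnf <- ss[, "MNF"]
    degenerate <- ss[, "MDF_IDX"] == 0
    mdf <- ifelse(degenerate, 0, freq[pmax(ss[, "MDF_IDX"], 1)])
    pkf <- if (p$pkf_mode == "power-value") ss[, "PKF_MAX"]
           else freq[ss[, "PKF_IDX"]]
    if (any(degenerate))
      warning(sprintf("%d all-zero window(s): MNF/MDF reported as 0",
                      sum(degenerate)), call. = FALSE)
  } else {
    sp <- vapply(seq_len(m), function(j) {
      sw <- signal_window(S[, j], sampling_rate)
      unlist(compute_spectral_features(sw, params = p)[c("MNF", "MDF", "PKF")])
    }, numeric(3))
    mnf <- sp[1, ]
    mdf <- sp[2, ]
    pkf <- sp[3, ]
  }

  out <- cbind(td, MNF = mnf, MDF = mdf, PKF = pkf)
  out[, semg_feature_names(), drop = FALSE]
}

#' Per-trial multi-channel feature vector
#'
#' Computes all 37 features on every channel window of one trial and returns
#' them as a named vector in channel-major canonical order
#' (\code{ch1_KURT ... ch1_MINAV, ch2_KURT, ...}).
#'
#' @param channels List of \code{\link{signal_window}} objects sharing
#'   \code{trial_id} and \code{gesture_label}, with distinct channel ids.
#' @param params A \code{\link{feature_params}} object.
#' @return Named numeric vector of length \code{37 * length(channels)} with
#'   attributes \code{trial_id} and \code{gesture_label}.
#' @export
extract_window_features <- function(channels, params = feature_params()) {
  if (!length(channels)) stopf("no channel windows supplied")
  if (!all(vapply(channels, inherits, logical(1), "signal_window")))
    stopf("channels must be a list of signal_window objects")
  ids <- vapply(channels, function(w) w$channel_id, integer(1))
  if (anyDuplicated(ids)) stopf("duplicate channel ids in trial")
  tids <- unique(vapply(channels, function(w) as.character(w$trial_id),
                        character(1)))
  gls <- unique(vapply(channels, function(w) as.character(w$gesture_label),
                       character(1)))
  if (length(tids) > 1 || length(gls) > 1)
    stopf("inconsistent trial metadata across channel windows")
  ord <- order(ids)
  channels <- channels[ord]
  ids <- ids[ord]
  lens <- vapply(channels, function(w) length(w$samples), integer(1))
  fs <- vapply(channels, function(w) w$sampling_rate, numeric(1))
  if (length(unique(lens)) != 1 || length(unique(fs)) != 1)
    stopf("channel windows of one trial must share length and sampling rate")
  S <- vapply(channels, function(w) w$samples, numeric(lens[1]))
  vals <- .features_block(S, fs[1], params)
  out <- as.vector(t(vals))
  names(out) <- as.vector(vapply(ids, function(c)
    paste0("ch", c, "_", semg_feature_names()), character(37)))
  attr(out, "trial_id") <- tids
  attr(out, "gesture_label") <- gls
  out
}

#' Extract the full feature matrix from a trial collection
#'
#' Applies the 37-feature extraction to every channel of every trial and
#' assembles the trials x (channel, feature) matrix, preserving trial order
#' and labels. With 8 channels this yields the 296-column design matrix.
#'
#' @param trials A trial collection as returned by
#'   \code{\link{generate_semg_dataset}} or \code{\link{read_trial_manifest}}:
#'   a list with elements \code{trials} (list of per-trial sample matrices,
#'   samples x channels), \code{manifest} (data frame with \code{trial_id},
#'   \code{gesture}, \code{subject}) and \code{sampling_rate}; or the list of
#'   matrices itself together with \code{manifest}/\code{sampling_rate}
#'   arguments.
#' @param params A \code{\link{feature_params}} object.
#' @param manifest,sampling_rate Overrides when \code{trials} is a bare list
#'   of matrices.
#' @return Data frame: \code{trial_id}, \code{gesture}, \code{subject},
#'   then \code{ch<c>_<NAME>} columns in channel-major canonical order.
#' @export
extract_dataset <- function(trials, params = feature_params(),
                            manifest = NULL, sampling_rate = NULL) {
  if (is.list(trials) && !is.null(trials$trials)) {
    manifest <- manifest %||% trials$manifest
    sampling_rate <- sampling_rate %||% trials$sampling_rate
    trials <- trials$trials
  }
  if (is.null(sampling_rate)) stopf("sampling_rate is required")
  n_tr <- length(trials)
  ncols <- vapply(trials, ncol, integer(1))
  if (n_tr > 0 && length(unique(ncols)) != 1)
    stopf("ragged channel sets: all trials must have the same channels")
  nrows <- vapply(trials, nrow, integer(1))
  if (n_tr > 0 && length(unique(nrows)) != 1)
    stopf("all trials must have the same window length")
  C <- if (n_tr > 0) ncols[1] else 8L
  feat_names <- as.vector(vapply(seq_len(C), function(c)
    paste0("ch", c, "_", semg_feature_names()), character(37)))
  meta <- if (!is.null(manifest)) {
    data.frame(trial_id = as.character(manifest$trial_id),
               gesture = as.character(manifest$gesture),
               subject = if (!is.null(manifest$subject))
                 as.character(manifest$subject) else NA_character_,
               stringsAsFactors = FALSE)
  } else {
    data.frame(trial_id = paste0("trial", seq_len(n_tr)),
               gesture = NA_character_, subject = NA_character_,
               stringsAsFactors = FALSE)
  }
  if (n_tr == 0) {
    out <- cbind(meta[0, , drop = FALSE],
                 as.data.frame(matrix(numeric(0), 0, 37L * C,
                                      dimnames = list(NULL, feat_names))))
    return(out)
  }
  if (nrow(meta) != n_tr) stopf("manifest rows (%d) != trials (%d)",
                                nrow(meta), n_tr)
  N <- nrows[1]
  vals <- matrix(NA_real_, n_tr, 37L * C, dimnames = list(NULL, feat_names))
  # Process windows in chunks of trials to bound memory while keeping the
  # per-feature computations vectorized across windows.
  chunk <- max(1L, floor(2048 / C))
  starts <- seq(1L, n_tr, by = chunk)
  for (s in starts) {
    e <- min(s + chunk - 1L, n_tr)
    idx <- s:e
    S <- matrix(unlist(trials[idx], use.names = FALSE), nrow = N)
    fb <- .features_block(S, sampling_rate, params)  # (C*ntr) x 37
    for (j in seq_along(idx)) {
      block <- fb[((j - 1L) * C + 1L):(j * C), , drop = FALSE]
      vals[idx[j], ] <- as.vector(t(block))
    }
  }
  cbind(meta, as.data.frame(vals))
}

# Split a feature-matrix data frame into the numeric design matrix and labels.
.design_matrix <- function(fm, label = "gesture") {
  meta_cols <- intersect(c("trial_id", "gesture", "subject"), names(fm))
  X <- as.matrix(fm[, setdiff(names(fm), meta_cols), drop = FALSE])
  y <- factor(fm[[label]])
  list(X = X, y = y)
}
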