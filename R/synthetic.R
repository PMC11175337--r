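# Synthetic data with known ground truth: (a) multi-channel sEMG-like gesture
# trials built from amplitude-modulated band-limited Gaussian noise, the
# standard surrogate for sEMG interference patterns; (b) labelled tabular
# datasets with planted informative / redundant / noise features.

#' Synthetic sEMG study configuration
#'
#' Defaults emulate the acquisition geometry of a 15-gesture, 14-subject,
#' 20-repetition study recorded from 8 channels at 500 Hz in 4-second trials.
#' Gesture separability is injected through a gesture-by-channel gain map and
#' a per-gesture spectral tilt on the informative channels; the remaining
#' channels carry gesture-independent activity and serve as negative controls
#' for channel-membership analyses.
#'
#' @param n_gestures,n_subjects,n_repetitions,n_channels Study dimensions.
#' @param sampling_rate Sampling rate in Hz.
#' @param trial_seconds Trial duration; the window length is
#'   \code{sampling_rate * trial_seconds} samples.
#' @param gain_map Optional \code{n_gestures x n_channels} matrix of envelope
#'   amplitudes. The default assigns each informative channel a cyclic gain
#'   ladder (range 0.5 to 2) with channel-specific periods 3, 4, 5, 7, 11, 13,
#'   so any two gestures differ on at least two channels; non-informative
#'   channels have constant gain 1.
#' @param informative_channels Channels whose gain and tilt vary by gesture
#'   (default: all but the last two).
#' @param spectral_tilt Per-gesture tilt of the in-band spectrum on
#'   informative channels (default: evenly spaced in [-1, 1]; 0 = flat).
#' @param band Passband (Hz) of the interference-pattern noise; the upper
#'   edge must stay below Nyquist.
#' @param subject_gain_sd Log-scale standard deviation of the multiplicative
#'   per-subject gain.
#' @param trial_jitter_sd Log-scale standard deviation of the per-trial
#'   amplitude jitter.
#' @param noise_floor Standard deviation of the additive white measurement
#'   noise relative to the unit-variance shaped signal.
#' @param dc_offset Constant baseline bias added to every channel, emulating
#'   the offset that single-supply sEMG front-ends and ADC exports leave in
#'   raw recordings. A strictly zero-mean surrogate would make the
#'   coefficient-of-variation feature scale-free noise, which real
#'   acquisitions do not produce.
#' @param seed Integer seed; generation is a pure function of config + seed.
#' @return An object of class \code{synthetic_emg_config}.
#' @export
synthetic_emg_config <- function(n_gestures = 15, n_subjects = 14,
                                 n_repetitions = 20, n_channels = 8,
                                 sampling_rate = 500, trial_seconds = 4,
                                 gain_map = NULL, informative_channels = NULL,
                                 spectral_tilt = NULL, band = c(20, 240),
                                 subject_gain_sd = 0.1,
                                 trial_jitter_sd = 0.05, noise_floor = 0.05,
                                 dc_offset = 0.5, seed = 1) {
  if (band[2] >= sampling_rate / 2)
    stopf("band upper edge (%g Hz) must be below Nyquist (%g Hz)",
          band[2], sampling_rate / 2)
  if (is.null(informative_channels))
    informative_channels <- seq_len(max(1, n_channels - 2))
  if (is.null(spectral_tilt))
    spectral_tilt <- seq(-1, 1, length.out = n_gestures)
  if (is.null(gain_map)) {
    moduli <- rep(c(3, 4, 5, 7, 11, 13), length.out = n_channels)
    gain_map <- matrix(1, n_gestures, n_channels)
    for (c in informative_channels) {
      m <- moduli[c]
      lev <- ((seq_len(n_gestures) - 1) %% m) / (m - 1)
      gain_map[, c] <- 0.5 + 1.5 * lev
    }
  }
  if (!all(dim(gain_map) == c(n_gestures, n_channels)))
    stopf("gain_map must be n_gestures x n_channels")
  if (any(gain_map < 0)) stopf("gain_map must be non-negative")
  structure(list(n_gestures = n_gestures, n_subjects = n_subjects,
                 n_repetitions = n_repetitions, n_channels = n_channels,
                 sampling_rate = sampling_rate, trial_seconds = trial_seconds,
                 gain_map = gain_map,
                 informative_channels = informative_channels,
                 spectral_tilt = spectral_tilt, band = band,
                 subject_gain_sd = subject_gain_sd,
                 trial_jitter_sd = trial_jitter_sd,
                 noise_floor = noise_floor, dc_offset = dc_offset,
                 seed = seed),
            class = "synthetic_emg_config")
}

# Real, symmetric spectral magnitude mask of length N for band [lo, hi] with
# exponential in-band tilt, normalized to unit output variance.
.band_mask <- function(N, fs, band, tilt) {
  f <- (seq_len(N) - 1) * fs / N
  fm <- pmin(f, fs - f)
  h <- numeric(N)
  inband <- fm >= band[1] & fm <= band[2]
  ramp <- (fm[inband] - band[1]) / (band[2] - band[1])
  h[inband] <- exp(tilt * (2 * ramp - 1))
  h / sqrt(mean(h^2))
}

#' Generate a synthetic multi-channel sEMG dataset
#'
#' Each trial channel is unit-variance Gaussian noise spectrally shaped to the
#' configured band (tilted per gesture on informative channels), scaled by
#' subject gain x gesture/channel gain x trial jitter, plus white measurement
#' noise and the constant acquisition baseline (\code{dc_offset}). Fully
#' reproducible from the config seed.
#'
#' @param cfg A \code{\link{synthetic_emg_config}}.
#' @return List with \code{trials} (list of samples x channels matrices),
#'   \code{manifest} (\code{trial_id, gesture, subject, repetition,
#'   sampling_rate}), \code{sampling_rate}, and \code{ground_truth}
#'   (gain map, informative channels, tilts, band, subject gains).
#' @export
generate_semg_dataset <- function(cfg = synthetic_emg_config()) {
  N <- as.integer(cfg$sampling_rate * cfg$trial_seconds)
  C <- cfg$n_channels
  R <- cfg$n_repetitions
  ntr <- cfg$n_gestures * cfg$n_subjects * R
  ch_names <- paste0("ch", seq_len(C))
  masks_inf <- lapply(seq_len(cfg$n_gestures), function(g)
    .band_mask(N, cfg$sampling_rate, cfg$band, cfg$spectral_tilt[g]))
  mask_flat <- .band_mask(N, cfg$sampling_rate, cfg$band, 0)
  trials <- vector("list", ntr)
  manifest <- data.frame(
    trial_id = character(ntr), gesture = character(ntr),
    subject = character(ntr), repetition = integer(ntr),
    sampling_rate = rep(cfg$sampling_rate, ntr), stringsAsFactors = FALSE)
  with_local_seed(child_seed(cfg$seed, 3), {
    subj_gain <- exp(rnorm(cfg$n_subjects) * cfg$subject_gain_sd)
    ti <- 0L
    for (s in seq_len(cfg$n_subjects)) {
      for (g in seq_len(cfg$n_gestures)) {
        m <- R * C
        W <- matrix(rnorm(N * m), N, m)
        Z <- stats::mvfft(W)
        inf <- rep(seq_len(C) %in% cfg$informative_channels, times = R)
        Z[, inf] <- Z[, inf, drop = FALSE] * masks_inf[[g]]
        Z[, !inf] <- Z[, !inf, drop = FALSE] * mask_flat
        X <- Re(stats::mvfft(Z, inverse = TRUE)) / N
        jit <- exp(rnorm(R) * cfg$trial_jitter_sd)
        gains <- subj_gain[s] * rep(cfg$gain_map[g, ], times = R) *
          rep(jit, each = C)
        X <- X * rep(gains, each = N) +
          cfg$noise_floor * matrix(rnorm(N * m), N, m) + cfg$dc_offset
        for (r in seq_len(R)) {
          ti <- ti + 1L
          M <- X[, ((r - 1L) * C + 1L):(r * C), drop = FALSE]
          colnames(M) <- ch_names
          trials[[ti]] <- M
          manifest$trial_id[ti] <- sprintf("s%02d_g%02d_r%02d", s, g, r)
          manifest$gesture[ti] <- sprintf("G%02d", g)
          manifest$subject[ti] <- sprintf("S%02d", s)
          manifest$repetition[ti] <- r
        }
      }
    }
  })
  list(trials = trials, manifest = manifest,
       sampling_rate = cfg$sampling_rate,
       ground_truth = list(gain_map = cfg$gain_map,
                           informative_channels = cfg$informative_channels,
                           spectral_tilt = cfg$spectral_tilt,
                           band = cfg$band),
       config = cfg)
}

#' Tabular simulation configuration
#'
#' Planted-structure design for testing selectors: informative features have
#' class-dependent means separated by \code{effect_size} pooled standard
#' deviations, redundant features are noisy copies of informative ones, noise
#' features are class-independent.
#'
#' @param n_samples,n_informative,n_redundant,n_noise,class_count Dimensions.
#' @param effect_size Gap between adjacent class means in pooled-SD units.
#' @param redundancy_noise_sd SD of the noise added to redundant copies.
#' @param seed Integer seed.
#' @return An object of class \code{tabular_sim_config}.
#' @export
tabular_sim_config <- function(n_samples = 1000, n_informative = 5,
                               n_redundant = 5, n_noise = 20, class_count = 3,
                               effect_size = 3, redundancy_noise_sd = 0.3,
                               seed = 1) {
  if (class_count < 2) stopf("class_count must be >= 2")
  if (effect_size <= 0) stopf("effect_size must be positive")
  if (any(c(n_samples, n_informative, n_redundant, n_noise) < 0))
    stopf("counts must be non-negative")
  structure(list(n_samples = n_samples, n_informative = n_informative,
                 n_redundant = n_redundant, n_noise = n_noise,
                 class_count = class_count, effect_size = effect_size,
                 redundancy_noise_sd = redundancy_noise_sd, seed = seed),
            class = "tabular_sim_config")
}

#' Generate a labelled tabular dataset with planted structure
#'
#' @param cfg A \code{\link{tabular_sim_config}}.
#' @return List with \code{X} (matrix, columns \code{inf*}, \code{red*},
#'   \code{noise*}), \code{y} (balanced factor) and \code{ground_truth}
#'   (column roles and the informative source of each redundant copy).
#' @export
generate_tabular_dataset <- function(cfg = tabular_sim_config()) {
  n <- cfg$n_samples
  K <- cfg$class_count
  y <- factor(rep(paste0("C", seq_len(K)), length.out = n))
  cls <- as.integer(y)
  inf_names <- if (cfg$n_informative) paste0("inf", seq_len(cfg$n_informative))
               else character(0)
  red_names <- if (cfg$n_redundant) paste0("red", seq_len(cfg$n_redundant))
               else character(0)
  noise_names <- if (cfg$n_noise) paste0("noise", seq_len(cfg$n_noise))
                 else character(0)
  src <- if (cfg$n_redundant)
    ((seq_len(cfg$n_redundant) - 1L) %% max(1L, cfg$n_informative)) + 1L
  else integer(0)
  X <- with_local_seed(child_seed(cfg$seed, 5), {
    Xi <- if (cfg$n_informative) {
      sapply(seq_len(cfg$n_informative), function(j) {
        lev <- (cls - 1L + (j - 1L)) %% K  # rotated class-mean ladder
        cfg$effect_size * lev + rnorm(n)
      })
    } else NULL
    Xr <- if (cfg$n_redundant) {
      sapply(seq_len(cfg$n_redundant), function(j)
        Xi[, src[j]] + rnorm(n) * cfg$redundancy_noise_sd)
    } else NULL
    Xn <- if (cfg$n_noise) matrix(rnorm(n * cfg$n_noise), n) else NULL
    cbind(Xi, Xr, Xn)
  })
  colnames(X) <- c(inf_names, red_names, noise_names)
  list(X = X, y = y,
       ground_truth = list(informative = inf_names, redundant = red_names,
                           noise = noise_names,
                           redundant_source = stats::setNames(
                             inf_names[src], red_names)))
}
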