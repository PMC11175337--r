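# Independent direct-transcription oracle for the 37 feature definitions,
# written with explicit per-sample loops and kept separate from the package's
# implementation path. Conventions (thresholds, histogram entropy, excess
# kurtosis, absolute-value fractional powers) follow the documented defaults.

oracle_feature <- function(name, x, fs = NULL, zc_thr = 0, ssc_thr = 0,
                           wamp_thr = 0, bins = 64, v = 3) {
  N <- length(x)
  L <- N
  switch(name,
    KURT = {
      y <- x - sum(x) / N
      m2 <- sum(y^2) / N
      if (m2 == 0) 0 else (sum(y^4) / N) / m2^2 - 3
    },
    SKEW = {
      y <- x - sum(x) / N
      m2 <- sum(y^2) / N
      if (m2 == 0) 0 else (sum(y^3) / N) / m2^(3 / 2)
    },
    SSI = sum(x^2),
    SD = sqrt(sum((x - mean(x))^2) / (N - 1)),
    RMS = sqrt(sum(x^2) / N),
    ENTROPY = {
      lo <- min(x)
      hi <- max(x)
      if (hi == lo) return(0)
      cnt <- integer(bins)
      for (i in 1:N) {
        b <- min(floor((x[i] - lo) / (hi - lo) * bins) + 1, bins)
        cnt[b] <- cnt[b] + 1
      }
      h <- 0
      for (b in 1:bins) if (cnt[b] > 0) {
        pr <- cnt[b] / N
        h <- h - pr * log(pr)
      }
      h
    },
    MAV = sum(abs(x)) / N,
    AAC = {
      s <- 0
      for (i in 1:(N - 1)) s <- s + abs(x[i + 1] - x[i])
      s / N
    },
    DASDV = {
      s <- 0
      for (i in 1:(N - 1)) s <- s + (x[i + 1] - x[i])^2
      sqrt(s / (N - 1))
    },
    LD = {
      s <- 0
      for (i in 1:N) s <- s + log(max(abs(x[i]), 1e-12))
      exp(s / N)
    },
    MMAV1 = {
      s <- 0
      for (i in 1:N) {
        w <- if (i >= 0.25 * L && i <= 0.75 * L) 1 else 0.5
        s <- s + w * abs(x[i])
      }
      s / N
    },
    MMAV2 = {
      s <- 0
      for (i in 1:N) {
        w <- if (i >= 0.25 * L && i <= 0.75 * L) 1
             else if (i < 0.25 * L) 4 * i / L
             else 4 * (L - i) / L
        s <- s + w * abs(x[i])
      }
      s / N
    },
    SSC = {
      cnt <- 0
      if (N >= 3) for (i in 2:(N - 1))
        if ((x[i] - x[i - 1]) * (x[i] - x[i + 1]) > ssc_thr) cnt <- cnt + 1
      cnt
    },
    WAMP = {
      cnt <- 0
      for (i in 1:(N - 1)) if (abs(x[i + 1] - x[i]) > wamp_thr) cnt <- cnt + 1
      cnt
    },
    WL = {
      s <- 0
      for (i in 2:N) s <- s + abs(x[i] - x[i - 1])
      s
    },
    VAR = sum(x^2) / (N + 1),
    RSSQ = sqrt(sum(abs(x)^2)),
    P2P = max(x) - min(x),
    BP = sum(x^2) / N,
    TM3 = abs(sum(x^3) / N),
    TM5 = abs(sum(x^5) / N),
    V0 = (sum(abs(x)^v) / N)^(1 / v),
    MAD0 = sum(abs(x - mean(x))) / N,
    MAD1 = sum(abs(x - median(x))) / N,
    IEMG = sum(abs(x)),
    MAXAV = max(abs(x)),
    ZC = {
      cnt <- 0
      for (i in 1:(N - 1))
        if (x[i] * x[i + 1] < 0 && abs(x[i] - x[i + 1]) >= zc_thr)
          cnt <- cnt + 1
      cnt
    },
    AVSER = sum(abs(x)^(1 / exp(1))),
    AVSSR = sum(abs(x)^(1 / 2)),
    COV = {
      sdv <- sqrt(sum((x - mean(x))^2) / (N - 1))
      if (sdv == 0) return(0)
      m <- mean(x)
      if (abs(m) < 1e-12 * sdv) m <- sign(m + (m == 0)) * 1e-12 * sdv
      100 * sdv / m
    },
    DAMV = {
      s <- 0
      for (i in 1:(N - 1)) s <- s + abs(x[i + 1] - x[i])
      s / (N - 1)
    },
    IQR = {
      q <- function(p) {
        xs <- sort(x)
        h <- (N - 1) * p + 1
        lo <- floor(h)
        if (lo >= N) return(xs[N])
        xs[lo] + (h - lo) * (xs[lo + 1] - xs[lo])
      }
      q(0.75) - q(0.25)
    },
    MVSR = sum(abs(x)^(1 / 2)) / L,
    MINAV = min(abs(x)),
    MNF = {
      sp <- oracle_periodogram(x, fs)
      if (sum(sp$p) == 0) 0 else sum(sp$f * sp$p) / sum(sp$p)
    },
    MDF = {
      sp <- oracle_periodogram(x, fs)
      tot <- sum(sp$p)
      if (tot == 0) return(0)
      cum <- 0
      for (i in seq_along(sp$p)) {
        cum <- cum + sp$p[i]
        if (cum >= tot / 2) return(sp$f[i])
      }
    },
    PKF = {
      sp <- oracle_periodogram(x, fs)
      max(sp$p)
    },
    stop("oracle: unknown feature ", name)
  )
}

oracle_periodogram <- function(x, fs) {
  N <- length(x)
  M <- floor(N / 2) + 1
  X <- fft(x)
  list(f = (0:(M - 1)) * fs / N, p = Mod(X[1:M])^2 / N)
}

oracle_all_features <- function(x, fs) {
  vapply(semg_feature_names(), oracle_feature, numeric(1), x = x, fs = fs)
}

# --- shared fixtures -------------------------------------------------------

make_trial_windows <- function(n_channels = 8, n = 64, fs = 500,
                               trial_id = "t1", gesture = "G1", seed = 42) {
  set.seed(seed)
  lapply(seq_len(n_channels), function(c)
    signal_window(rnorm(n), fs, channel_id = c, trial_id = trial_id,
                  gesture_label = gesture))
}

small_emg_config <- function(...) {
  synthetic_emg_config(n_gestures = 5, n_subjects = 4, n_repetitions = 8,
                       n_channels = 4, trial_seconds = 0.5, ...)
}

# Brute-force step oracle for greedy mRMR (quotient scheme) on small matrices.
oracle_mrmr <- function(X, y, n_select) {
  f_stat <- function(x) {
    groups <- split(x, y)
    ng <- lengths(groups)
    gm <- vapply(groups, mean, numeric(1))
    grand <- mean(x)
    ssb <- sum(ng * (gm - grand)^2)
    ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
    if (ssw == 0) return(if (ssb > 0) Inf else 0)
    (ssb / (length(ng) - 1)) / (ssw / (length(x) - length(ng)))
  }
  rel <- apply(X, 2, f_stat)
  usable <- which(apply(X, 2, sd) > 0)
  sel <- integer(0)
  for (s in seq_len(n_select)) {
    avail <- setdiff(usable, sel)
    crit <- sapply(avail, function(j) {
      if (length(sel) == 0) return(rel[j])
      cors <- abs(sapply(sel, function(k) cor(X[, j], X[, k])))
      cors[is.na(cors)] <- 0
      if (max(cors) >= 1 - 1e-12 &&
          !all(sapply(avail, function(a) {
            ca <- abs(sapply(sel, function(k) cor(X[, a], X[, k])))
            ca[is.na(ca)] <- 0
            max(ca) >= 1 - 1e-12
          }))) return(-Inf)
      red <- mean(cors)
      if (red == 0) Inf else rel[j] / red
    })
    sel <- c(sel, avail[order(-crit, avail)][1])
  }
  colnames(X)[sel]
}

# Refit-and-argmax-p oracle for one backward-elimination removal.
oracle_be_next_removal <- function(X, y, active, alpha) {
  y_num <- as.numeric(factor(y))
  df <- data.frame(.y = y_num, X[, active, drop = FALSE])
  fit <- lm(.y ~ ., data = df)
  pv <- summary(fit)$coefficients[-1, 4]
  names(pv) <- active
  if (max(pv) < alpha) return(NULL)
  active[order(-pv, -seq_along(active))][1]
}
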