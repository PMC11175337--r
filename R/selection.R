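# Feature-evaluation methods: three filter-style rankers (mutual information,
# univariate F test, minimum-redundancy maximum-relevance) and three
# model-based methods (logistic-regression RFE, extra-trees importance,
# OLS backward elimination).

#' Selection configuration
#'
#' @param method One of \code{"MI"}, \code{"UST"}, \code{"RFE"}, \code{"FI"},
#'   \code{"MRMR"}, \code{"BE"}.
#' @param n_select Number of features to select (subset methods; for rankers
#'   it sets the default \code{\link{take_n_best}} cut).
#' @param alpha Significance threshold for backward elimination.
#' @param mi_neighbors Neighbour count k of the nearest-neighbour mutual
#'   information estimator.
#' @param fi_trees Tree count of the extremely randomized trees ensemble.
#' @param rfe_step Features removed per RFE iteration; a value in (0,1) is
#'   interpreted as a fraction of the remaining features.
#' @param mrmr_scheme \code{"quotient"} (relevance / redundancy) or
#'   \code{"difference"} (relevance - redundancy).
#' @param seed Integer seed for the stochastic components (tie-breaking noise,
#'   tree ensemble).
#' @return An object of class \code{selection_config}.
#' @export
selection_config <- function(method = c("MI", "UST", "RFE", "FI", "MRMR", "BE"),
                             n_select = NULL, alpha = 0.05, mi_neighbors = 3,
                             fi_trees = 100, rfe_step = 1,
                             mrmr_scheme = c("quotient", "difference"),
                             seed = 1) {
  method <- match.arg(method)
  mrmr_scheme <- match.arg(mrmr_scheme)
  if (!is.null(n_select) && n_select < 1) stopf("n_select must be >= 1")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0,1)")
  structure(list(method = method, n_select = n_select, alpha = alpha,
                 mi_neighbors = mi_neighbors, fi_trees = fi_trees,
                 rfe_step = rfe_step, mrmr_scheme = mrmr_scheme, seed = seed),
            class = "selection_config")
}

.as_selection_input <- function(X, y) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.numeric(X)) stopf("feature matrix must be numeric")
  if (anyNA(X)) stopf("feature matrix contains missing values")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- factor(y)
  if (nlevels(y) < 2) stopf("need at least 2 classes")
  if (length(y) != nrow(X)) stopf("label length does not match rows")
  list(X = X, y = y)
}

.selection_result <- function(method, ranking, scores, selected, n_requested,
                              config, trace = NULL) {
  structure(list(method = method, ranking = ranking, scores = scores,
                 selected = selected, n_requested = n_requested,
                 trace = trace, config = config),
            class = "selection_result")
}

# Stable ranking: score descending, original column order breaking ties.
.stable_rank <- function(scores) order(-scores, seq_along(scores))

# Vectorized one-way ANOVA F statistic for every column of X.
# Zero within-class variance with non-zero between-class variance yields +Inf;
# a globally constant feature yields 0.
.anova_f <- function(X, y) {
  n <- nrow(X)
  g <- nlevels(y)
  ng <- as.vector(table(y))
  sums <- rowsum(X, y, reorder = TRUE)
  means <- sums / ng
  grand <- colMeans(X)
  ssb <- colSums(ng * (means - rep(grand, each = g))^2)
  ssw <- colSums(X^2) - colSums(ng * means^2)
  ssw <- pmax(ssw, 0)  # guard tiny negative rounding
  f <- (ssb / (g - 1)) / (ssw / (n - g))
  f[ssw == 0 & ssb > 1e-12 * pmax(ssb, 1)] <- Inf
  f[ssb <= 0] <- 0
  f[ssw == 0 & ssb <= 1e-12] <- 0
  f
}

# Distance to the k-th nearest neighbour for each element of a sorted vector.
.kth_nn_sorted <- function(xs, k) {
  n <- length(xs)
  best <- rep(Inf, n)
  for (j in 0:k) {
    l <- if (j == 0) rep(0, n) else {
      dl <- rep(Inf, n)
      if (n > j) dl[(j + 1):n] <- xs[(j + 1):n] - xs[1:(n - j)]
      dl
    }
    r <- if (k - j == 0) rep(0, n) else {
      dr <- rep(Inf, n)
      if (n > k - j) dr[1:(n - (k - j))] <- xs[(k - j + 1):n] - xs[1:(n - (k - j))]
      dr
    }
    best <- pmin(best, pmax(l, r))
  }
  best
}

# Nearest-neighbour mutual information between a continuous feature and a
# discrete label (Kraskov-style continuous/discrete estimator): for each point,
# the radius is the distance to its k-th neighbour within the same class and
# the full-sample neighbour count inside that radius enters the digamma sum.
.mi_feature_label <- function(x, y, k = 3) {
  n <- length(x)
  radius <- numeric(n)
  kall <- numeric(n)
  labcnt <- numeric(n)
  for (lv in levels(y)) {
    idx <- which(y == lv)
    cnt <- length(idx)
    labcnt[idx] <- cnt
    if (cnt > 1) {
      ki <- min(k, cnt - 1)
      o <- order(x[idx])
      xs <- x[idx][o]
      d <- .kth_nn_sorted(xs, ki)
      radius[idx[o]] <- d * (1 - 1e-12)
      kall[idx] <- ki
    }
  }
  keep <- labcnt > 1
  if (!any(keep)) return(0)
  xk <- x[keep]
  rk <- radius[keep]
  s <- sort(xk)
  m_all <- findInterval(xk + rk, s) -
    findInterval(xk - rk, s, left.open = TRUE)
  mi <- digamma(sum(keep)) + mean(digamma(kall[keep])) -
    mean(digamma(labcnt[keep])) - mean(digamma(pmax(m_all, 1)))
  max(0, mi)
}

#' Rank features by mutual information with the class label
#'
#' Scores every feature by a nearest-neighbour (Kraskov-style) estimate of the
#' mutual information between the feature and the class label, in nats.
#' Features are rescaled to unit variance and perturbed by tiny seeded noise
#' to break ties, as is standard for this estimator. Constant features score 0.
#'
#' @param X Numeric feature matrix (rows = samples) with column names.
#' @param y Class labels.
#' @param config A \code{\link{selection_config}}.
#' @return A \code{selection_result} with descending ranking and MI scores.
#' @export
rank_mutual_information <- function(X, y, config = selection_config("MI")) {
  inp <- .as_selection_input(X, y)
  X <- inp$X
  y <- inp$y
  p <- ncol(X)
  scores <- with_local_seed(child_seed(config$seed, 11), {
    vapply(seq_len(p), function(j) {
      x <- X[, j]
      sdx <- stats::sd(x)
      if (sdx == 0) return(0)
      x <- x / sdx
      x <- x + rnorm(length(x)) * 1e-10
      .mi_feature_label(x, y, config$mi_neighbors)
    }, numeric(1))
  })
  names(scores) <- colnames(X)
  ord <- .stable_rank(scores)
  sel <- if (!is.null(config$n_select))
    colnames(X)[ord][seq_len(config$n_select)] else NULL
  .selection_result("MI", colnames(X)[ord], scores, sel, config$n_select,
                    config)
}

#' Rank features by univariate one-way ANOVA F statistic
#'
#' Filter ranking by the between-class F statistic of each feature. Features
#' with zero within-class variance but class-separated means receive an
#' infinite sentinel score and rank first (with a message).
#'
#' @inheritParams rank_mutual_information
#' @return A \code{selection_result} with descending F ranking.
#' @export
rank_univariate <- function(X, y, config = selection_config("UST")) {
  inp <- .as_selection_input(X, y)
  f <- .anova_f(inp$X, inp$y)
  names(f) <- colnames(inp$X)
  if (any(is.infinite(f)))
    message(sum(is.infinite(f)),
            " feature(s) with zero within-class variance ranked first")
  ord <- .stable_rank(f)
  sel <- if (!is.null(config$n_select))
    colnames(inp$X)[ord][seq_len(config$n_select)] else NULL
  .selection_result("UST", colnames(inp$X)[ord], f, sel, config$n_select,
                    config)
}

# One multinomial/binomial ridge-logistic fit on pre-standardized features;
# returns per-feature importance as the L2 norm of the class coefficients.
# Retries with stronger regularization on failure.
.logistic_importance <- function(X, y, lambda = 0.05) {
  fam <- if (nlevels(y) == 2) "binomial" else "multinomial"
  fit <- NULL
  for (lam in lambda * c(1, 10, 100)) {
    fit <- tryCatch(
      suppressWarnings(
        glmnet::glmnet(X, y, family = fam, alpha = 0, lambda = lam,
                       standardize = FALSE, thresh = 1e-4, maxit = 50000)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      if (lam > lambda)
        message("logistic base model refitted with lambda = ", lam)
      break
    }
  }
  if (is.null(fit)) stopf("logistic base model failed to converge")
  cf <- stats::coef(fit)
  if (fam == "binomial") {
    abs(as.vector(cf)[-1])
  } else {
    mats <- lapply(cf, function(m) as.vector(m)[-1])
    sqrt(Reduce(`+`, lapply(mats, function(v) v^2)))
  }
}

#' Recursive feature elimination with a logistic-regression base model
#'
#' Fits a (multinomial) logistic regression on the current feature set,
#' removes the \code{rfe_step} features with the smallest coefficient
#' magnitude (L2 norm across classes), and repeats until \code{n_select}
#' features remain. Features are compared on the model's internally
#' standardized scale. The elimination order also provides a full ranking:
#' survivors (by final-fit importance) first, then eliminated features in
#' reverse elimination order.
#'
#' @inheritParams rank_mutual_information
#' @param config A \code{\link{selection_config}}; \code{n_select} is
#'   required.
#' @return A \code{selection_result}; \code{selected} has exactly
#'   \code{n_select} features, \code{trace} holds the elimination order
#'   (first eliminated first).
#' @export
select_rfe <- function(X, y, config = selection_config("RFE", n_select = 1)) {
  inp <- .as_selection_input(X, y)
  X <- inp$X
  y <- inp$y
  n_select <- config$n_select
  if (is.null(n_select)) stopf("RFE requires n_select")
  if (n_select > ncol(X)) stopf("n_select exceeds feature count")
  # Standardize once so coefficient magnitudes are comparable across features
  # (internal to RFE; the evaluation protocol is unaffected).
  X <- scale(X)
  X[, attr(X, "scaled:scale") == 0] <- 0
  active <- colnames(X)
  eliminated <- character(0)
  imp <- rep(NA_real_, length(active))
  names(imp) <- active
  while (length(active) > n_select) {
    imp_a <- .logistic_importance(X[, active, drop = FALSE], y)
    names(imp_a) <- active
    imp[active] <- imp_a
    step <- config$rfe_step
    k <- if (step < 1) max(1L, floor(step * length(active))) else as.integer(step)
    k <- min(k, length(active) - n_select)
    drop_idx <- order(imp_a, -seq_along(imp_a))[seq_len(k)]  # lowest first
    drop_feats <- active[drop_idx]
    eliminated <- c(eliminated, drop_feats)
    active <- setdiff(active, drop_feats)
  }
  if (length(active) > 1) {
    imp_a <- .logistic_importance(X[, active, drop = FALSE], y)
    names(imp_a) <- active
    imp[active] <- imp_a
  } else if (length(active) == 1 && is.na(imp[active])) {
    imp[active] <- Inf
  }
  surv_order <- active[order(-imp[active], match(active, colnames(X)))]
  ranking <- c(surv_order, rev(eliminated))
  .selection_result("RFE", ranking, imp, active, n_select, config,
                    trace = list(elimination_order = eliminated))
}

#' Rank features by extremely-randomized-trees importance
#'
#' Impurity-based importances from an extra-trees ensemble (no bootstrap,
#' random split points, \code{sqrt(p)} candidate features per split),
#' normalized to sum to one. Deterministic given the configuration seed.
#'
#' @inheritParams rank_mutual_information
#' @return A \code{selection_result} with normalized importances.
#' @export
rank_feature_importance <- function(X, y, config = selection_config("FI")) {
  inp <- .as_selection_input(X, y)
  X <- inp$X
  y <- inp$y
  fit <- ranger::ranger(
    x = X, y = y, num.trees = config$fi_trees, splitrule = "extratrees",
    num.random.splits = 1, importance = "impurity", replace = FALSE,
    sample.fraction = 1, mtry = max(1L, floor(sqrt(ncol(X)))),
    num.threads = 1, seed = child_seed(config$seed, 13))
  imp <- fit$variable.importance
  imp <- pmax(imp, 0)
  tot <- sum(imp)
  imp <- if (tot > 0) imp / tot else rep(1 / length(imp), length(imp))
  names(imp) <- colnames(X)
  ord <- .stable_rank(imp)
  sel <- if (!is.null(config$n_select))
    colnames(X)[ord][seq_len(config$n_select)] else NULL
  .selection_result("FI", colnames(X)[ord], imp, sel, config$n_select, config)
}

#' Greedy minimum-redundancy maximum-relevance selection
#'
#' Relevance is the one-way ANOVA F statistic against the label; redundancy is
#' the mean absolute Pearson correlation with the already-selected features.
#' The default criterion is the quotient relevance / redundancy; candidates
#' that exactly duplicate a selected feature are deferred until no
#' non-duplicate candidate remains. Zero-variance features are excluded.
#'
#' @inheritParams select_rfe
#' @return A \code{selection_result}; \code{selected} lists exactly
#'   \code{n_select} features in selection order (the greedy order is also the
#'   ranking).
#' @export
select_mrmr <- function(X, y, config = selection_config("MRMR", n_select = 1)) {
  inp <- .as_selection_input(X, y)
  X <- inp$X
  y <- inp$y
  n_select <- config$n_select
  if (is.null(n_select)) stopf("mRMR requires n_select")
  sds <- apply(X, 2, stats::sd)
  cand <- which(sds > 0)
  if (length(cand) < length(sds))
    message(length(sds) - length(cand),
            " zero-variance feature(s) excluded from mRMR candidacy")
  if (n_select > length(cand)) stopf("n_select exceeds usable feature count")
  rel <- .anova_f(X, y)
  selected <- integer(0)
  crit_log <- numeric(0)
  redsum <- rep(0, ncol(X))      # running sum of |cor| with selected
  redsum_max <- rep(0, ncol(X))  # max |cor| with any selected feature
  for (step in seq_len(n_select)) {
    avail <- setdiff(cand, selected)
    if (step == 1) {
      crit <- rel[avail]
    } else {
      red <- redsum[avail] / length(selected)
      crit <- ifelse(red > 0, rel[avail] / red, Inf)
      if (config$mrmr_scheme == "difference")
        crit <- rel[avail] - red
      dup <- redsum_max[avail] >= 1 - 1e-12
      if (any(dup) && !all(dup)) crit[dup] <- -Inf
    }
    pick <- avail[order(-crit, avail)][1]
    crit_log <- c(crit_log, unname(crit[match(pick, avail)]))
    selected <- c(selected, pick)
    cors <- abs(suppressWarnings(stats::cor(X[, cand, drop = FALSE],
                                            X[, pick])))
    cors[is.na(cors)] <- 0
    redsum[cand] <- redsum[cand] + as.vector(cors)
    redsum_max[cand] <- pmax(redsum_max[cand], as.vector(cors))
  }
  feats <- colnames(X)[selected]
  scores <- stats::setNames(crit_log, feats)
  .selection_result("MRMR", feats, scores, feats, n_select, config,
                    trace = list(relevance = rel))
}

#' Backward elimination on an ordinary-least-squares fit
#'
#' Regresses the numerically coded class label on all features (with
#' intercept) and iteratively removes the single feature with the largest
#' p-value while any p-value is at or above \code{alpha}. Perfectly collinear
#' (aliased) features are removed first, later columns first. Returns the
#' surviving set (possibly empty) and the removal trace.
#'
#' @inheritParams rank_mutual_information
#' @return A \code{selection_result}; \code{selected} is the surviving set and
#'   \code{trace$removals} records each removal with its p-value. The ranking
#'   orders survivors by final p-value then removed features in reverse
#'   removal order.
#' @export
select_backward_elimination <- function(X, y,
                                        config = selection_config("BE")) {
  inp <- .as_selection_input(X, y)
  X <- inp$X
  y_num <- as.numeric(inp$y)
  active <- colnames(X)
  removals <- data.frame(feature = character(0), p_value = numeric(0),
                         stringsAsFactors = FALSE)
  final_p <- stats::setNames(numeric(0), character(0))
  while (length(active) > 0) {
    Xa <- X[, active, drop = FALSE]
    fit <- stats::lm(y_num ~ Xa)
    cf <- stats::coef(fit)[-1]
    names(cf) <- active
    if (anyNA(cf)) {
      aliased <- names(cf)[is.na(cf)]
      drop_f <- aliased[length(aliased)]
      message("aliased (collinear) feature dropped: ", drop_f)
      removals <- rbind(removals,
                        data.frame(feature = drop_f, p_value = NA_real_))
      active <- setdiff(active, drop_f)
      next
    }
    sm <- summary(fit)$coefficients
    pv <- sm[-1, 4]
    names(pv) <- active
    final_p <- pv
    if (max(pv) < config$alpha) break
    drop_f <- active[order(-pv, -seq_along(active))][1]
    removals <- rbind(removals,
                      data.frame(feature = drop_f,
                                 p_value = unname(pv[drop_f])))
    active <- setdiff(active, drop_f)
    if (length(active) == 0) final_p <- numeric(0)
  }
  surv <- if (length(active))
    active[order(final_p[active], match(active, colnames(X)))]
  else character(0)
  ranking <- c(surv, rev(removals$feature))
  scores <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
  scores[names(final_p)] <- final_p
  .selection_result("BE", ranking, scores, surv, NULL, config,
                    trace = list(removals = removals, final_p = final_p))
}

#' Dispatch a selection method by name
#'
#' @inheritParams rank_mutual_information
#' @param config A \code{\link{selection_config}}; its \code{method} field
#'   chooses the algorithm.
#' @return A \code{selection_result}.
#' @export
select_features <- function(X, y, config) {
  switch(config$method,
         MI = rank_mutual_information(X, y, config),
         UST = rank_univariate(X, y, config),
         RFE = select_rfe(X, y, config),
         FI = rank_feature_importance(X, y, config),
         MRMR = select_mrmr(X, y, config),
         BE = select_backward_elimination(X, y, config),
         stopf("unknown method '%s'", config$method))
}

#' First n features of a ranking
#'
#' @param r A \code{selection_result} or \code{sweep_result} carrying a
#'   ranking.
#' @param n Number of features to take (0 allowed).
#' @return Character vector of the top \code{n} feature ids.
#' @export
take_n_best <- function(r, n) {
  if (!is.list(r) || is.null(r$ranking))
    stopf("take_n_best() needs a result object with a ranking")
  if (n < 0 || n > length(r$ranking))
    stopf("n must be between 0 and the ranking length (%d)", length(r$ranking))
  r$ranking[seq_len(n)]
}

#' Channel-membership table of a selected feature set
#'
#' Maps a set of \code{ch<c>_<NAME>} feature ids onto a 37-row by
#' channel-count boolean table showing which channels contributed each
#' feature, with row and column sums attached as attributes.
#'
#' @param selected Character vector of selected feature ids.
#' @param n_channels Number of channels C.
#' @return A 37 x C logical matrix (rows = canonical features, columns =
#'   \code{ch1..chC}) with attributes \code{row_sums} and \code{col_sums}.
#' @export
membership_table <- function(selected, n_channels = 8) {
  feats <- semg_feature_names()
  tab <- matrix(FALSE, length(feats), n_channels,
                dimnames = list(feats, paste0("ch", seq_len(n_channels))))
  if (length(selected)) {
    m <- regmatches(selected, regexec("^ch([0-9]+)_(.+)$", selected))
    for (i in seq_along(selected)) {
      if (length(m[[i]]) != 3) stopf("malformed feature id '%s'", selected[i])
      ch <- as.integer(m[[i]][2])
      nm <- m[[i]][3]
      if (!nm %in% feats) stopf("unknown feature name in id '%s'", selected[i])
      if (ch < 1 || ch > n_channels)
        stopf("channel out of range in id '%s'", selected[i])
      tab[nm, ch] <- TRUE
    }
  }
  attr(tab, "row_sums") <- rowSums(tab)
  attr(tab, "col_sums") <- colSums(tab)
  tab
}
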