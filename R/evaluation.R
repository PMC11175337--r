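# kNN evaluation protocol: stratified hold-out, accuracy/confusion reporting,
# n-best sweeps, greedy subset refinement and the tabular benchmark harness.

#' Evaluation configuration
#'
#' @param k_neighbors Neighbour count K of the kNN classifier (default 3).
#' @param test_fraction Held-out fraction of the stratified split.
#' @param seed Integer seed controlling the split and kNN tie-breaking.
#' @param standardize Standardize features (train-set mean/sd) before kNN.
#'   Off by default: raw feature scales enter the Euclidean distance.
#' @param metric Distance metric (only \code{"euclidean"} is supported).
#' @return An object of class \code{eval_config}.
#' @export
eval_config <- function(k_neighbors = 3, test_fraction = 0.2, seed = 1,
                        standardize = FALSE, metric = "euclidean") {
  if (test_fraction <= 0 || test_fraction >= 1)
    stopf("test_fraction must be in (0,1)")
  if (k_neighbors < 1) stopf("k_neighbors must be >= 1")
  if (metric != "euclidean") stopf("only the euclidean metric is supported")
  structure(list(k_neighbors = k_neighbors, test_fraction = test_fraction,
                 seed = seed, standardize = standardize, metric = metric),
            class = "eval_config")
}

#' Stratified train/test split
#'
#' Deterministic (seeded) disjoint, exhaustive split. The total test size is
#' \code{ceiling(n * test_fraction)}; it is apportioned to classes by the
#' largest-remainder rule on \code{n_class * test_fraction}, keeping at least
#' one training member per class.
#'
#' @param y Class labels (every class needs >= 2 members).
#' @param config An \code{\link{eval_config}}.
#' @return List with integer index vectors \code{train} and \code{test}.
#' @export
stratified_split <- function(y, config = eval_config()) {
  y <- factor(y)
  tab <- table(y)
  if (any(tab < 2))
    stopf("singleton class '%s': every class needs >= 2 members",
          names(tab)[which(tab < 2)[1]])
  n <- length(y)
  total_test <- ceiling(n * config$test_fraction)
  quota <- as.vector(tab) * config$test_fraction
  base <- floor(quota)
  rem <- total_test - sum(base)
  if (rem > 0) {
    extra_order <- order(-(quota - base), seq_along(base))
    base[extra_order[seq_len(rem)]] <- base[extra_order[seq_len(rem)]] + 1
  }
  base <- pmin(base, as.vector(tab) - 1)  # keep >= 1 train per class
  test_idx <- integer(0)
  with_local_seed(child_seed(config$seed, 29), {
    for (g in seq_along(tab)) {
      idx <- which(y == names(tab)[g])
      if (base[g] > 0)
        test_idx <- c(test_idx, sort(sample(idx, base[g])))
    }
  })
  list(train = setdiff(seq_len(n), test_idx), test = sort(test_idx))
}

#' Evaluate a feature subset with kNN
#'
#' Fits a K-nearest-neighbour classifier (Euclidean distance, majority vote,
#' seeded tie-breaking) on the training part of a stratified hold-out split,
#' restricted to the given feature subset, and scores the held-out part.
#'
#' @param X Numeric feature matrix with column names (or a feature-matrix data
#'   frame from \code{\link{extract_dataset}}).
#' @param y Class labels (taken from the data frame's \code{gesture} column
#'   when omitted).
#' @param feature_subset Character vector of column names (default: all).
#' @param config An \code{\link{eval_config}}.
#' @param split Optional precomputed split from \code{\link{stratified_split}}
#'   so that several subsets are compared on identical folds.
#' @return An \code{evaluation_result}: \code{accuracy} (percent),
#'   \code{confusion} (true class x predicted class counts),
#'   \code{per_class_accuracy} (percent), \code{n_features_used},
#'   \code{split}, \code{config}.
#' @export
evaluate_knn <- function(X, y = NULL, feature_subset = NULL,
                         config = eval_config(), split = NULL) {
  if (is.data.frame(X) && "gesture" %in% names(X)) {
    d <- .design_matrix(X)
    if (is.null(y)) y <- d$y
    X <- d$X
  }
  X <- as.matrix(X)
  y <- factor(y)
  if (is.null(feature_subset)) feature_subset <- colnames(X)
  if (length(feature_subset) == 0) stopf("feature subset must be non-empty")
  if (!all(feature_subset %in% colnames(X)))
    stopf("unknown feature(s) in subset: %s",
          paste(setdiff(feature_subset, colnames(X))[1:3], collapse = ", "))
  if (is.null(split)) split <- stratified_split(y, config)
  if (config$k_neighbors > length(split$train))
    stopf("k exceeds training-set size")
  Xtr <- X[split$train, feature_subset, drop = FALSE]
  Xte <- X[split$test, feature_subset, drop = FALSE]
  if (config$standardize) {
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    Xtr <- scale(Xtr, mu, sdv)
    Xte <- scale(Xte, mu, sdv)
  }
  ytr <- y[split$train]
  yte <- y[split$test]
  pred <- with_local_seed(child_seed(config$seed, 101),
                          class::knn(Xtr, Xte, ytr, k = config$k_neighbors))
  conf <- table(true = factor(yte, levels = levels(y)),
                predicted = factor(pred, levels = levels(y)))
  acc <- 100 * sum(diag(conf)) / sum(conf)
  structure(list(accuracy = acc, confusion = conf,
                 per_class_accuracy = per_class_accuracy(conf),
                 n_features_used = length(feature_subset),
                 feature_subset = feature_subset,
                 split = split, config = config),
            class = "evaluation_result")
}

#' Accuracy improvement
#'
#' Signed change in accuracy after feature selection: new minus original,
#' in percentage points.
#'
#' @param new_acc Accuracy (percent) with the selected subset.
#' @param original_acc Accuracy (percent) with all features.
#' @return \code{new_acc - original_acc}.
#' @export
accuracy_improvement <- function(new_acc, original_acc) {
  if (any(new_acc < 0 | new_acc > 100 | original_acc < 0 | original_acc > 100))
    stopf("accuracies must be in [0,100]")
  new_acc - original_acc
}

#' Per-class accuracy from a confusion matrix
#'
#' @param confusion Square matrix of true class (rows) by predicted class
#'   (columns) counts.
#' @return Percent correct per true class; classes with zero test count are
#'   \code{NA}.
#' @export
per_class_accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stopf("confusion matrix must be square")
  rs <- rowSums(confusion)
  out <- ifelse(rs > 0, 100 * diag(confusion) / rs, NA_real_)
  names(out) <- rownames(confusion)
  out
}

#' Default n-best sweep grid
#'
#' Fifteen subset sizes from 35 to 250 features used for the n-best accuracy
#' sweep on the 296-column sEMG feature matrix.
#'
#' @return Integer vector of length 15.
#' @export
default_sweep_grid <- function() {
  c(35, 45, 55, 65, 75, 85, 100, 115, 130, 140, 160, 175, 200, 225, 250)
}

# Produce a full ranking for any of the six methods (used by sweeps and the
# benchmark harness). For subset methods the greedy/elimination order is the
# ranking; `depth` bounds how far mRMR/RFE need to go.
.method_ranking <- function(X, y, sel_config, depth = NULL, rfe_to = NULL) {
  p <- ncol(as.matrix(X))
  depth <- min(depth %||% p, p)
  cfg <- sel_config
  if (cfg$method == "RFE") {
    # Eliminating down to the smallest subset of interest makes every top-n
    # prefix of the ranking coincide with RFE stopped at n.
    cfg$n_select <- max(1L, min(rfe_to %||% 1L, p))
    res <- select_rfe(X, y, cfg)
  } else if (cfg$method == "MRMR") {
    sds <- apply(as.matrix(X), 2, stats::sd)
    cfg$n_select <- min(depth, sum(sds > 0))
    res <- select_mrmr(X, y, cfg)
  } else {
    cfg$n_select <- NULL
    res <- select_features(X, y, cfg)
  }
  res
}

#' Accuracy sweep over the n best features
#'
#' Ranks the features once with the requested method, then evaluates the kNN
#' classifier on the top-n subset for every n in the grid, on one fixed
#' stratified split. For RFE the ranking is the reverse elimination order; for
#' mRMR it is the greedy selection order.
#'
#' @inheritParams evaluate_knn
#' @param method Method name (\code{"MI"}, \code{"UST"}, \code{"RFE"},
#'   \code{"FI"}, \code{"MRMR"}, \code{"BE"}) or a
#'   \code{\link{selection_config}}.
#' @param grid Integer vector of subset sizes (default
#'   \code{\link{default_sweep_grid}}). Values exceeding the feature count are
#'   skipped with a warning.
#' @param config An \code{\link{eval_config}}.
#' @param split Optional precomputed split.
#' @return A \code{sweep_result}: \code{grid}, \code{accuracies},
#'   \code{best_n}, \code{best_accuracy} (ties resolved to the smallest n),
#'   \code{ranking}, \code{method}.
#' @export
sweep_n_best <- function(X, y = NULL, method = "RFE",
                         grid = default_sweep_grid(),
                         config = eval_config(), split = NULL) {
  if (is.data.frame(X) && "gesture" %in% names(X)) {
    d <- .design_matrix(X)
    if (is.null(y)) y <- d$y
    X <- d$X
  }
  X <- as.matrix(X)
  y <- factor(y)
  sel_config <- if (inherits(method, "selection_config")) method
                else selection_config(method, seed = config$seed)
  p <- ncol(X)
  keep <- grid <= p
  if (!all(keep)) {
    warning(sprintf("%d grid value(s) exceed the feature count and were skipped",
                    sum(!keep)), call. = FALSE)
    grid <- grid[keep]
  }
  if (is.null(split)) split <- stratified_split(y, config)
  res <- .method_ranking(X, y, sel_config, depth = max(grid),
                         rfe_to = min(grid))
  ranking <- res$ranking
  acc <- vapply(grid, function(n) {
    if (n > length(ranking)) return(NA_real_)
    evaluate_knn(X, y, ranking[seq_len(n)], config, split)$accuracy
  }, numeric(1))
  ok <- !is.na(acc)
  best_i <- which(acc == max(acc[ok]))[1]
  structure(list(grid = grid, accuracies = acc, best_n = grid[best_i],
                 best_accuracy = acc[best_i], ranking = ranking,
                 method = sel_config$method, split = split),
            class = "sweep_result")
}

# channel index of ch<c>_<NAME> feature ids
.feature_channel <- function(ids) {
  as.integer(sub("^ch([0-9]+)_.*$", "\\1", ids))
}

#' Greedy refinement of a feature subset with priority channels
#'
#' Starting from a base subset, discards candidate features whose channel is
#' not in the priority set, scores each remaining candidate added alone to the
#' base, then greedily accumulates candidates (best singleton first) that
#' strictly improve hold-out accuracy, always on the same split.
#'
#' @inheritParams evaluate_knn
#' @param base_set Character vector of base feature ids (non-empty).
#' @param candidate_set Character vector of candidate ids, disjoint from
#'   \code{base_set}.
#' @param priority_channels Integer channel ids to keep among candidates.
#' @return List with \code{selected} (the augmented set), \code{result} (its
#'   \code{evaluation_result}), \code{base_accuracy}, and \code{trace} (one
#'   row per evaluated combination).
#' @export
refine_subset <- function(X, y = NULL, base_set, candidate_set,
                          priority_channels, config = eval_config(),
                          split = NULL) {
  if (is.data.frame(X) && "gesture" %in% names(X)) {
    d <- .design_matrix(X)
    if (is.null(y)) y <- d$y
    X <- d$X
  }
  if (length(base_set) == 0) stopf("base set must be non-empty")
  if (length(intersect(base_set, candidate_set)))
    stopf("base and candidate sets must be disjoint")
  y <- factor(y)
  if (is.null(split)) split <- stratified_split(y, config)
  cand <- candidate_set[.feature_channel(candidate_set) %in% priority_channels]
  base_res <- evaluate_knn(X, y, base_set, config, split)
  trace <- data.frame(added = "<base>", n_features = length(base_set),
                      accuracy = base_res$accuracy, accepted = TRUE,
                      stringsAsFactors = FALSE)
  if (length(cand) == 0)
    return(list(selected = base_set, result = base_res,
                base_accuracy = base_res$accuracy, trace = trace))
  single <- vapply(cand, function(f)
    evaluate_knn(X, y, c(base_set, f), config, split)$accuracy, numeric(1))
  trace <- rbind(trace, data.frame(added = cand,
                                   n_features = length(base_set) + 1,
                                   accuracy = unname(single),
                                   accepted = FALSE))
  current <- base_set
  cur_acc <- base_res$accuracy
  cur_res <- base_res
  for (f in cand[order(-single, seq_along(cand))]) {
    r <- evaluate_knn(X, y, c(current, f), config, split)
    accept <- r$accuracy > cur_acc
    trace <- rbind(trace, data.frame(added = f,
                                     n_features = length(current) + 1,
                                     accuracy = r$accuracy,
                                     accepted = accept))
    if (accept) {
      current <- c(current, f)
      cur_acc <- r$accuracy
      cur_res <- r
    }
  }
  list(selected = current, result = cur_res,
       base_accuracy = base_res$accuracy, trace = trace)
}

#' Benchmark one labelled tabular dataset across methods
#'
#' Computes the no-selection kNN baseline, then one (accuracy, n) pair per
#' method: RFE at n = floor(p/2); backward elimination at its
#' significance-determined size; the rankers (MI, UST, FI, mRMR) at the
#' accuracy-maximizing n (over all 1..p when p <= 25, otherwise over a coarse
#' grid), ties resolved to the smallest n.
#'
#' @inheritParams evaluate_knn
#' @param dataset_name Label for the output row.
#' @param methods Methods to run.
#' @param config An \code{\link{eval_config}}.
#' @param seed Seed passed to the selection configurations.
#' @return A one-row data frame: dataset, n_features, baseline accuracy, and
#'   \code{<method>_accuracy} / \code{<method>_n} columns.
#' @export
run_benchmark <- function(X, y = NULL, dataset_name = "dataset",
                          methods = c("RFE", "FI", "UST", "MI", "BE", "MRMR"),
                          config = eval_config(), seed = 1) {
  if (is.data.frame(X) && "gesture" %in% names(X)) {
    d <- .design_matrix(X)
    if (is.null(y)) y <- d$y
    X <- d$X
  }
  X <- as.matrix(X)
  if (is.null(y)) stopf("labels are required")
  y <- factor(y)
  p <- ncol(X)
  split <- stratified_split(y, config)
  baseline <- evaluate_knn(X, y, colnames(X), config, split)$accuracy
  out <- data.frame(dataset = dataset_name, n_features = p,
                    baseline_accuracy = baseline, stringsAsFactors = FALSE)
  grid <- if (p <= 25) seq_len(p)
          else sort(unique(pmax(1, round(seq(1, p, length.out = 25)))))
  for (m in methods) {
    cfg <- selection_config(m, seed = seed)
    if (m == "RFE") {
      cfg$n_select <- max(1L, floor(p / 2))
      sel <- select_rfe(X, y, cfg)$selected
      acc <- evaluate_knn(X, y, sel, config, split)$accuracy
      n_used <- length(sel)
    } else if (m == "BE") {
      sel <- select_backward_elimination(X, y, cfg)$selected
      n_used <- length(sel)
      acc <- if (n_used > 0)
        evaluate_knn(X, y, sel, config, split)$accuracy else NA_real_
    } else {
      res <- .method_ranking(X, y, cfg, depth = p)
      g <- grid[grid <= length(res$ranking)]
      accs <- vapply(g, function(n)
        evaluate_knn(X, y, res$ranking[seq_len(n)], config, split)$accuracy,
        numeric(1))
      best <- which(accs == max(accs))[1]
      acc <- accs[best]
      n_used <- g[best]
    }
    out[[paste0(m, "_accuracy")]] <- acc
    out[[paste0(m, "_n")]] <- n_used
  }
  out
}
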