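# Readers and writers: per-trial channel CSVs with a manifest, generic
# labelled tabular datasets, and the report bundle (tables, plots,
# provenance).

#' Write a trial collection to per-trial CSV files plus a manifest
#'
#' One CSV per trial (header \code{ch1..chC}, one row per sample) and a
#' \code{manifest.csv} with columns \code{trial_id, file, gesture, subject,
#' repetition, sampling_rate}.
#'
#' @param dataset A trial collection (as from
#'   \code{\link{generate_semg_dataset}}).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_trials <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  man <- dataset$manifest
  man$file <- paste0(man$trial_id, ".csv")
  for (i in seq_along(dataset$trials)) {
    utils::write.csv(as.data.frame(dataset$trials[[i]]),
                     file.path(dir, man$file[i]), row.names = FALSE)
  }
  man <- man[, c("trial_id", "file", "gesture", "subject", "repetition",
                 "sampling_rate")]
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' Read a trial collection from a manifest
#'
#' Loads the per-trial channel CSVs referenced by a manifest file, validating
#' that every trial has the same channels and window length and that all
#' cells are numeric.
#'
#' @param path Path to a manifest CSV with columns \code{trial_id, file,
#'   gesture, subject, repetition, sampling_rate}.
#' @return A trial collection: list with \code{trials}, \code{manifest},
#'   \code{sampling_rate}.
#' @export
read_trial_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("trial_id", "file", "gesture", "sampling_rate")
  missing_cols <- setdiff(required, names(man))
  if (length(missing_cols))
    stopf("manifest lacks required column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (length(unique(man$sampling_rate)) != 1)
    stopf("all trials must share one sampling rate")
  dir <- dirname(path)
  trials <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    f <- file.path(dir, man$file[i])
    if (!file.exists(f))
      stopf("trial '%s': referenced file missing: %s", man$trial_id[i], f)
    d <- utils::read.csv(f, stringsAsFactors = FALSE)
    M <- as.matrix(d)
    if (!is.numeric(M)) {
      bad <- which(!vapply(d, is.numeric, logical(1)))[1]
      stopf("trial '%s': non-numeric cells in column '%s'",
            man$trial_id[i], names(d)[bad])
    }
    trials[[i]] <- M
  }
  dims <- vapply(trials, dim, integer(2))
  if (nrow(man) > 1 &&
      (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1))
    stopf("ragged trials: lengths %s, channels %s",
          paste(unique(dims[1, ]), collapse = "/"),
          paste(unique(dims[2, ]), collapse = "/"))
  list(trials = trials,
       manifest = man[, setdiff(names(man), "file")],
       sampling_rate = man$sampling_rate[1])
}

#' Write an extracted feature matrix to CSV
#'
#' Header \code{trial_id, gesture, subject, ch1_KURT, ...} in channel-major
#' canonical order.
#'
#' @param fm Feature-matrix data frame from \code{\link{extract_dataset}}.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_feature_matrix <- function(fm, path) {
  utils::write.csv(fm, path, row.names = FALSE)
  invisible(path)
}

#' Load a labelled tabular dataset from delimited text
#'
#' Reads a header-ed delimited file, coerces the feature columns to numeric,
#' and drops rows containing unparseable cells (reporting the count).
#'
#' @param path Path to a CSV/TSV file (delimiter inferred from the
#'   extension; comma by default).
#' @param label_column Name of the label column.
#' @return List with \code{X} (numeric matrix), \code{y} (factor) and
#'   \code{n_dropped}.
#' @export
load_tabular_dataset <- function(path, label_column) {
  if (!file.exists(path)) stopf("dataset not found: %s", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!label_column %in% names(d))
    stopf("label column '%s' absent from %s", label_column, path)
  y_raw <- d[[label_column]]
  feats <- d[, setdiff(names(d), label_column), drop = FALSE]
  suppressWarnings(num <- lapply(feats, function(col) as.numeric(col)))
  Xall <- do.call(cbind, num)
  colnames(Xall) <- names(feats)
  bad <- rowSums(is.na(Xall)) > 0 | is.na(y_raw)
  if (any(bad))
    warning(sprintf("%d row(s) with unparseable cells dropped", sum(bad)),
            call. = FALSE)
  list(X = Xall[!bad, , drop = FALSE], y = factor(y_raw[!bad]),
       n_dropped = sum(bad))
}

#' Write the analysis report bundle
#'
#' Emits whichever components are present in \code{results}: a benchmark
#' table CSV, an n-best sweep curve (CSV + PNG), a confusion matrix
#' (CSV + heatmap PNG), a channel-membership table CSV (37 rows x channels),
#' and a provenance JSON recording configurations and seeds.
#'
#' @param results Named list; recognized elements: \code{benchmark} (data
#'   frame), \code{sweep} (\code{sweep_result}), \code{evaluation}
#'   (\code{evaluation_result}), \code{membership} (logical matrix),
#'   \code{provenance} (list).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, character vector of the files written.
#' @export
write_reports <- function(results, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2) != 0)
    stopf("output directory not writable: %s", out_dir)
  written <- character(0)
  w <- function(p) {
    written <<- c(written, p)
    p
  }
  if (!is.null(results$benchmark))
    utils::write.csv(results$benchmark,
                     w(file.path(out_dir, "benchmark.csv")),
                     row.names = FALSE)
  if (!is.null(results$sweep)) {
    sw <- results$sweep
    utils::write.csv(data.frame(n = sw$grid, accuracy = sw$accuracies),
                     w(file.path(out_dir, "sweep.csv")), row.names = FALSE)
    grDevices::png(w(file.path(out_dir, "sweep.png")), 800, 600)
    graphics::plot(sw$grid, sw$accuracies, type = "b", pch = 19,
                   xlab = "n selected features", ylab = "accuracy (%)",
                   main = paste("n-best sweep -", sw$method))
    graphics::abline(v = sw$best_n, lty = 2)
    grDevices::dev.off()
  }
  if (!is.null(results$evaluation)) {
    conf <- as.matrix(unclass(results$evaluation$confusion))
    utils::write.csv(conf, w(file.path(out_dir, "confusion.csv")))
    grDevices::png(w(file.path(out_dir, "confusion.png")), 800, 800)
    graphics::image(seq_len(ncol(conf)), seq_len(nrow(conf)),
                    t(conf[rev(seq_len(nrow(conf))), ]),
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    axes = FALSE, xlab = "predicted", ylab = "true",
                    main = "confusion matrix")
    graphics::axis(1, seq_len(ncol(conf)), colnames(conf), las = 2)
    graphics::axis(2, seq_len(nrow(conf)), rev(rownames(conf)), las = 2)
    grDevices::dev.off()
  }
  if (!is.null(results$membership)) {
    mt <- results$membership
    df <- data.frame(feature = rownames(mt), as.data.frame(unclass(mt)))
    utils::write.csv(df, w(file.path(out_dir, "membership.csv")),
                     row.names = FALSE)
  }
  if (!is.null(results$provenance)) {
    jsonlite::write_json(results$provenance,
                         w(file.path(out_dir, "provenance.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(written)
}
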