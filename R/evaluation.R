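.STATUS_LEVELS <- c("illicit", "legitimate", "unknown")

#' Build a three-way confusion summary
#'
#' Cross-tabulates predicted against actual status over the levels
#' `illicit`, `legitimate`, `unknown`. Rows are predictions, columns the
#' actual status; `unknown` rows hold the model's abstentions (no referral
#' data), `unknown` columns hold pharmacies whose true status is not in the
#' reference database.
#'
#' @param predicted,actual character vectors of equal length with values in
#'   `illicit`, `legitimate`, `unknown`.
#' @return An object of class `confusion_summary`: a 3 x 3 integer matrix.
#' @export
confusion_summary <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  if (!all(predicted %in% .STATUS_LEVELS) || !all(actual %in% .STATUS_LEVELS)) {
    stop("statuses must be one of illicit, legitimate, unknown")
  }
  m <- table(factor(predicted, .STATUS_LEVELS), factor(actual, .STATUS_LEVELS))
  m <- matrix(as.integer(m), 3L, 3L,
              dimnames = list(predicted = .STATUS_LEVELS, actual = .STATUS_LEVELS))
  structure(m, class = c("confusion_summary", "matrix"))
}

#' Assemble a confusion summary from counts
#'
#' Convenience constructor for published confusion tables: counts are given
#' cell by cell, unmentioned cells are zero.
#'
#' @param ... named counts `<predicted>_<actual>`, e.g. `illicit_illicit = 104`,
#'   `legitimate_illicit = 2`, `unknown_illicit = 7`.
#' @return A [confusion_summary()].
#' @export
confusion_from_counts <- function(...) {
  cells <- list(...)
  m <- matrix(0L, 3L, 3L,
              dimnames = list(predicted = .STATUS_LEVELS, actual = .STATUS_LEVELS))
  for (nm in names(cells)) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !all(parts %in% .STATUS_LEVELS)) {
      stop(sprintf("cell name '%s' must be '<predicted>_<actual>'", nm))
    }
    m[parts[1L], parts[2L]] <- as.integer(cells[[nm]])
  }
  structure(m, class = c("confusion_summary", "matrix"))
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("<confusion_summary> predicted (rows) x actual (cols)\n")
  print(unclass(x))
  invisible(x)
}

# Cohen's kappa on a 2x2 decided-class table (rows predicted, cols actual).
# p_e from the marginal products; the degenerate p_e = 1 case (all mass in
# one class both ways) is 1 for perfect agreement, else 0.
.cohen_kappa <- function(m2) {
  n <- sum(m2)
  p_o <- sum(diag(m2)) / n
  p_e <- sum(rowSums(m2) * colSums(m2)) / n^2
  if (abs(1 - p_e) < 1e-15) {
    return(list(kappa = if (p_o >= 1 - 1e-15) 1 else 0, degenerate = TRUE))
  }
  list(kappa = (p_o - p_e) / (1 - p_e), degenerate = FALSE)
}

#' Performance metrics from a confusion summary
#'
#' Computes accuracy, Cohen's kappa, sensitivity and specificity with
#' illicit as the positive class, so sensitivity is the fraction of illicit
#' pharmacies correctly flagged and specificity the fraction of legitimate
#' ones correctly cleared (type I error = 1 - specificity, type II error =
#' 1 - sensitivity). Only pharmacies whose actual status is known enter the
#' metrics. Predicted-unknown abstentions are handled per `unknown_policy`:
#' `exclude` drops them; `count_as_error` keeps them in the denominators of
#' accuracy, sensitivity and specificity as errors against their actual
#' class. Kappa is always computed on the two decided classes only.
#'
#' @param confusion a [confusion_summary()].
#' @param unknown_policy `"exclude"` or `"count_as_error"`.
#' @return An object of class `metrics_report`: list with `accuracy`,
#'   `kappa`, `sensitivity`, `specificity`, `n_evaluated`,
#'   `n_unknown_predictions`, `kappa_degenerate`.
#' @export
compute_metrics <- function(confusion, unknown_policy = c("exclude", "count_as_error")) {
  stopifnot(inherits(confusion, "confusion_summary"))
  unknown_policy <- match.arg(unknown_policy)
  m <- unclass(confusion)[, c("illicit", "legitimate"), drop = FALSE]
  decided <- m[c("illicit", "legitimate"), , drop = FALSE]
  n_unk <- sum(m["unknown", ])
  n <- if (unknown_policy == "exclude") sum(decided) else sum(m)
  if (n == 0L) stop("no evaluated pharmacies after applying the unknown policy")
  tp <- decided["illicit", "illicit"]
  tn <- decided["legitimate", "legitimate"]
  sens_den <- sum(decided[, "illicit"]) +
    if (unknown_policy == "count_as_error") m["unknown", "illicit"] else 0L
  spec_den <- sum(decided[, "legitimate"]) +
    if (unknown_policy == "count_as_error") m["unknown", "legitimate"] else 0L
  kap <- .cohen_kappa(decided)
  structure(list(
    accuracy = (tp + tn) / n,
    kappa = kap$kappa,
    sensitivity = if (sens_den > 0) tp / sens_den else NA_real_,
    specificity = if (spec_den > 0) tn / spec_den else NA_real_,
    n_evaluated = as.integer(n),
    n_unknown_predictions = as.integer(n_unk),
    kappa_degenerate = kap$degenerate
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> accuracy %.3f, kappa %.3f, ",
                     "sensitivity %.3f, specificity %.3f (n = %d, unknown = %d)\n"),
              x$accuracy, x$kappa, x$sensitivity, x$specificity,
              x$n_evaluated, x$n_unknown_predictions))
  invisible(x)
}

#' Stratified k-fold split of labeled pharmacies
#'
#' Partitions the labeled pharmacies into `n_folds` test folds with
#' per-class counts differing by at most one across folds, so each fold
#' sees both classes even under heavy imbalance. Reproducible given `seed`.
#'
#' @param labels a [label_set].
#' @param n_folds number of folds, at least 2; every class must have at
#'   least `n_folds` members.
#' @param seed integer seed.
#' @return List of `n_folds` elements, each `list(train =, test =)` of
#'   pharmacy identifier vectors.
#' @export
stratified_kfold_split <- function(labels, n_folds, seed) {
  stopifnot(inherits(labels, "label_set"))
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("n_folds must be at least 2")
  classes <- list(labels$rogue, labels$safe)
  if (any(vapply(classes, length, 0L) < n_folds)) {
    stop(sprintf("each class needs at least %d members for %d folds",
                 n_folds, n_folds))
  }
  assign_fold <- withr::with_seed(seed, {
    lapply(classes, function(ids) {
      stats::setNames(rep_len(seq_len(n_folds), length(ids)), sample(ids))
    })
  })
  fold_of <- c(assign_fold[[1L]], assign_fold[[2L]])
  all_ids <- names(labels$status)
  lapply(seq_len(n_folds), function(f) {
    test <- sort(names(fold_of)[fold_of == f])
    list(train = setdiff(all_ids, test), test = test)
  })
}

# Fit + predict one fold for a method spec (list(method =, k =, strategy =,
# log1p =)).
.fit_predict_fold <- function(graph, labels, fold, spec) {
  train_labels <- .subset_labels(labels, fold$train)
  if (spec$method == "rrpm") {
    model <- fit_rrpm(graph, train_labels, strategy = spec$strategy)
    predict(model, graph, fold$test)
  } else {
    model <- fit_rknn(graph, train_labels, k = spec$k,
                      log1p = isTRUE(spec$log1p))
    predict(model, graph, fold$test)
  }
}

.parse_method <- function(method, k = NULL, strategy = "conservative") {
  if (method == "rrpm_conservative") {
    list(method = "rrpm", strategy = "conservative")
  } else if (method == "rrpm_accuracy_max") {
    list(method = "rrpm", strategy = "accuracy_max")
  } else if (method == "rrpm") {
    list(method = "rrpm", strategy = strategy)
  } else if (method == "rknn") {
    if (is.null(k)) stop("rknn needs k")
    list(method = "rknn", k = as.integer(k))
  } else stop(sprintf("unknown method '%s'", method))
}

#' Cross-validate a classifier on a labeled referral graph
#'
#' For each stratified fold the model (RRPM's referrer qualities and
#' threshold, or RKNN's axis and training vectors) is fitted only on the
#' training fold; test-fold pharmacies are classified and pooled into one
#' confusion table (per-fold averaging available via `aggregate`).
#'
#' @param graph a [referral_graph].
#' @param labels a [label_set].
#' @param method `"rrpm_conservative"`, `"rrpm_accuracy_max"`, or `"rknn"`.
#' @param k neighbour count (rknn only).
#' @param n_folds number of folds (default 10).
#' @param seed integer seed for the fold split.
#' @param unknown_policy passed to [compute_metrics()].
#' @param aggregate `"pool"` (one pooled confusion table, the default) or
#'   `"average"` (mean of per-fold metrics).
#' @return List with `metrics` (a `metrics_report`) and `confusion` (the
#'   pooled [confusion_summary()]).
#' @export
cross_validate <- function(graph, labels, method, k = NULL, n_folds = 10L,
                           seed = 1L,
                           unknown_policy = c("exclude", "count_as_error"),
                           aggregate = c("pool", "average")) {
  unknown_policy <- match.arg(unknown_policy)
  aggregate <- match.arg(aggregate)
  spec <- .parse_method(method, k)
  folds <- stratified_kfold_split(labels, n_folds, seed)
  preds <- lapply(folds, function(fold) {
    p <- .fit_predict_fold(graph, labels, fold, spec)
    data.frame(predicted = p$status,
               actual = unname(labels$status[p$pharmacy]),
               stringsAsFactors = FALSE)
  })
  pooled <- do.call(rbind, preds)
  confusion <- confusion_summary(pooled$predicted, pooled$actual)
  metrics <- if (aggregate == "pool") {
    compute_metrics(confusion, unknown_policy)
  } else {
    per <- lapply(preds, function(p)
      compute_metrics(confusion_summary(p$predicted, p$actual), unknown_policy))
    avg <- function(f) mean(vapply(per, `[[`, 0, f))
    structure(list(accuracy = avg("accuracy"), kappa = avg("kappa"),
                   sensitivity = avg("sensitivity"),
                   specificity = avg("specificity"),
                   n_evaluated = sum(vapply(per, `[[`, 0L, "n_evaluated")),
                   n_unknown_predictions = sum(vapply(per, `[[`, 0L, "n_unknown_predictions")),
                   kappa_degenerate = any(vapply(per, `[[`, TRUE, "kappa_degenerate"))),
              class = "metrics_report")
  }
  list(metrics = metrics, confusion = confusion)
}

#' Sweep the neighbour count K of RKNN under paired cross-validation
#'
#' Evaluates RKNN for each K on identical folds (a paired comparison), so
#' differences between rows reflect K alone. Neighbour rankings are
#' computed once per fold and reused across K.
#'
#' @param graph a [referral_graph].
#' @param labels a [label_set].
#' @param k_values positive integers, each at most the smallest
#'   training-fold size.
#' @param n_folds,seed,unknown_policy as in [cross_validate()].
#' @return Data frame with one row per K: `model` (`"R<k>NN"`), `k`,
#'   `accuracy`, `kappa`, `specificity`, `sensitivity`, `n_evaluated`,
#'   `n_unknown_predictions`, `seed`.
#' @export
sweep_k <- function(graph, labels, k_values = 1:9, n_folds = 10L, seed = 1L,
                    unknown_policy = c("exclude", "count_as_error")) {
  unknown_policy <- match.arg(unknown_policy)
  k_values <- as.integer(k_values)
  if (!length(k_values) || any(k_values < 1L)) stop("k_values must be positive")
  folds <- stratified_kfold_split(labels, n_folds, seed)
  min_train <- min(vapply(folds, function(f) length(f$train), 0L))
  if (any(k_values > min_train)) {
    stop(sprintf("k_values must not exceed the smallest training fold (%d)",
                 min_train))
  }
  # ordered neighbour labels per test pharmacy, shared by every K
  fold_rank <- lapply(folds, function(fold) {
    train_labels <- .subset_labels(labels, fold$train)
    model <- fit_rknn(graph, train_labels, k = 1L)
    has_edges <- fold$test %in% .pharmacies_with_edges(graph)
    nbs <- if (any(has_edges)) {
      .neighbor_order(model, graph, fold$test[has_edges])
    } else list()
    list(test = fold$test, has_edges = has_edges,
         neighbor_status = lapply(nbs, function(nb)
           unname(model$labels[nb$pharmacy])),
         actual = unname(labels$status[fold$test]))
  })
  rows <- lapply(k_values, function(k) {
    pred <- unlist(lapply(fold_rank, function(fr) {
      p <- rep("unknown", length(fr$test))
      if (any(fr$has_edges)) {
        r_x <- vapply(fr$neighbor_status, function(st)
          mean(st[seq_len(k)] == "legitimate"), 0)
        p[fr$has_edges] <- ifelse(r_x > 0.5, "legitimate", "illicit")
      }
      p
    }))
    actual <- unlist(lapply(fold_rank, `[[`, "actual"))
    m <- compute_metrics(confusion_summary(pred, actual), unknown_policy)
    data.frame(model = sprintf("R%dNN", k), k = k,
               accuracy = m$accuracy, kappa = m$kappa,
               specificity = m$specificity, sensitivity = m$sensitivity,
               n_evaluated = m$n_evaluated,
               n_unknown_predictions = m$n_unknown_predictions,
               seed = as.integer(seed), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Error rate including abstentions, over reference-known pharmacies
#'
#' Restricted to pharmacies whose actual status is known in the reference
#' database, the error rate counts both misclassifications and the model's
#' `unknown` abstentions as errors:
#' \deqn{\mathrm{error\ rate} = \frac{\mathrm{misclassified} + \mathrm{predicted\ unknown}}{\mathrm{reference\mbox{-}known}} \times 100.}
#'
#' @param confusion a [confusion_summary()] whose `unknown` row holds the
#'   model's abstentions.
#' @return Error rate as a percentage.
#' @export
error_rate_with_unknown <- function(confusion) {
  stopifnot(inherits(confusion, "confusion_summary"))
  m <- unclass(confusion)[, c("illicit", "legitimate"), drop = FALSE]
  total <- sum(m)
  if (total == 0L) stop("no pharmacies with known actual status")
  correct <- m["illicit", "illicit"] + m["legitimate", "legitimate"]
  100 * (total - correct) / total
}

#' Write a metrics table as delimited text
#'
#' One row per model with the four headline metrics plus n and seed
#' metadata; metadata header lines start with `#`.
#'
#' @param table data frame as returned by [sweep_k()] or assembled from
#'   [cross_validate()] results.
#' @param path output file path or connection.
#' @param meta optional named character vector echoed as `# key: value`
#'   header lines.
#' @param delim field delimiter.
#' @export
write_metrics_table <- function(table, path, meta = NULL, delim = "\t") {
  lines <- character()
  if (length(meta)) lines <- sprintf("# %s: %s", names(meta), unname(meta))
  lines <- c(lines, paste(names(table), collapse = delim),
             do.call(paste, c(unname(as.list(table)), sep = delim)))
  writeLines(lines, path)
  invisible(path)
}
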