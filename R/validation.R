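#' Classification statistics from a confusion matrix
#'
#' Rows are true classes; columns are predicted classes, optionally plus a
#' [NOT_ASSIGNED] column. Per-class statistics are one-vs-rest, computed on
#' the assigned samples only: sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, Matthews correlation coefficient (0 when any denominator
#' factor is 0), and call rate (assigned samples of the class over its
#' total). Global accuracy is correct assigned over total assigned (1 with
#' a flag when nothing is assigned), global call rate is assigned over
#' total.
#'
#' @param confusion Non-negative integer matrix with row/column names; an
#'   optional `NOT_ASSIGNED` column counts unassigned samples.
#' @param mode `"all_assigned"` or `"with_not_assigned"` (metadata only).
#' @return An object of class `validation_stats`: the confusion matrix and
#'   its row percentages, a `per_class` data frame (class, sensitivity,
#'   specificity, mcc, call_rate), `global_accuracy`, `global_call_rate`
#'   and a `degenerate` flag (no sample assigned).
#' @export
confusion_stats <- function(confusion,
                            mode = c("with_not_assigned", "all_assigned")) {
  mode <- match.arg(mode)
  if (!is.matrix(confusion) || length(confusion) == 0)
    stop("'confusion' must be a non-empty matrix")
  if (any(confusion < 0)) stop("confusion counts must be non-negative")
  if (is.null(rownames(confusion)) || is.null(colnames(confusion)))
    stop("'confusion' needs row and column names")
  classes <- rownames(confusion)
  na_col <- colnames(confusion) == NOT_ASSIGNED
  assigned_mat <- confusion[, !na_col, drop = FALSE]
  if (!all(classes %in% colnames(assigned_mat)))
    stop("every true class needs a predicted-class column")
  assigned_mat <- assigned_mat[, classes, drop = FALSE]

  total <- sum(confusion)
  assigned_total <- sum(assigned_mat)
  row_totals <- rowSums(confusion)

  per_class <- do.call(rbind, lapply(classes, function(k) {
    tp <- assigned_mat[k, k]
    fn <- sum(assigned_mat[k, ]) - tp
    fp <- sum(assigned_mat[, k]) - tp
    tn <- assigned_total - tp - fn - fp
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    mcc <- if (denom > 0)
      (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom) else 0
    call_rate <- if (row_totals[k] > 0)
      sum(assigned_mat[k, ]) / row_totals[k] else NA_real_
    data.frame(class = k, sensitivity = sens, specificity = spec,
               mcc = mcc, call_rate = call_rate, stringsAsFactors = FALSE)
  }))
  rownames(per_class) <- NULL

  degenerate <- assigned_total == 0
  global_accuracy <- if (degenerate) 1
    else sum(diag(assigned_mat)) / assigned_total
  pct <- confusion
  nonzero <- row_totals > 0
  pct[nonzero, ] <- 100 * confusion[nonzero, , drop = FALSE] /
    row_totals[nonzero]

  structure(list(confusion = confusion, percentages = pct,
                 per_class = per_class,
                 global_accuracy = global_accuracy,
                 global_call_rate = if (total > 0)
                   assigned_total / total else NA_real_,
                 degenerate = degenerate, mode = mode),
            class = "validation_stats")
}

#' @export
print.validation_stats <- function(x, ...) {
  cat("validation_stats (mode:", x$mode, ")\n")
  print(x$per_class, digits = 4)
  cat(sprintf("global accuracy %.4f, global call rate %.4f%s\n",
              x$global_accuracy, x$global_call_rate,
              if (x$degenerate) " [no sample assigned]" else ""))
  invisible(x)
}

# Builds the confusion matrix of truth vs predictions over a fixed class
# set, with a NOT_ASSIGNED column when requested.
confusion_matrix <- function(truth, predicted, classes,
                             with_na = TRUE) {
  cols <- if (with_na) c(classes, NOT_ASSIGNED) else classes
  tab <- table(factor(truth, levels = classes),
               factor(predicted, levels = cols))
  m <- matrix(as.integer(tab), nrow = length(classes),
              dimnames = list(classes, cols))
  m
}

#' External validation of the whole pipeline
#'
#' Repeats `runs` times: stratified train/test split of the samples, full
#' pipeline on the training part (empirical Bayes ranking, forward gene
#' selection, final classifier), classification of the held-out part, and
#' statistics in both modes: `all_assigned` (every sample goes to its most
#' likely class) and `with_not_assigned` (doubtful samples are left
#' unassigned). Averaged percentage confusion matrices and averaged
#' statistics are reported per mode.
#'
#' @param dataset A labelled [expression_dataset()].
#' @param config A [marker_config()].
#' @param runs Number of random splits. Default 10.
#' @param train_fraction Fraction of each class used for training.
#'   Default 0.5.
#' @return A list of class `external_validation` with elements
#'   `all_assigned` and `with_not_assigned`, each containing
#'   `avg_percentages` (averaged row-percentage confusion matrix),
#'   `avg_per_class`, `avg_global_accuracy`, `avg_global_call_rate` and the
#'   per-run `runs` list; plus `selection_counts` (runs x classes matrix of
#'   selected gene counts).
#' @export
external_validation <- function(dataset, config = marker_config(),
                                runs = 10L, train_fraction = 0.5) {
  assert_analysis_ready(dataset)
  cls <- dataset$classes
  y <- dataset$labels
  min_train <- min(floor(table(y) * train_fraction))
  if (min_train < 3)
    stop("train_fraction leaves a class with fewer than 3 training ",
         "samples")

  per_mode <- list(all_assigned = list(), with_not_assigned = list())
  sel_counts <- matrix(NA_integer_, runs, length(cls),
                       dimnames = list(NULL, cls))

  for (run in seq_len(runs)) {
    set.seed(derive_seed(config$seed, "validation_split", run))
    train_idx <- unlist(lapply(cls, function(k) {
      idx <- which(y == k)
      sample(idx, max(3, floor(length(idx) * train_fraction)))
    }))
    test_idx <- setdiff(seq_along(y), train_idx)
    if (!length(test_idx)) stop("train_fraction leaves no test samples")
    train_ds <- subset_samples(dataset, train_idx)
    test_ds <- subset_samples(dataset, test_idx)

    model <- fit_eb_model(train_ds)
    post <- posterior_probabilities(model, train_ds)
    ranking <- build_ranking(post, train_ds,
                             config$significance_threshold)
    run_cfg <- config
    run_cfg$seed <- derive_seed(config$seed, "validation_pipeline", run)
    selection <- forward_select(train_ds, ranking, run_cfg)
    sel_counts[run, ] <- selection$final_counts
    clf <- train_classifier(train_ds, selection$selected_genes,
                            cost = config$svm_cost,
                            seed = derive_seed(config$seed,
                                               "validation_train", run))
    qr <- predict_query(clf, test_ds, config)
    truth <- as.character(test_ds$labels)

    cm_all <- confusion_matrix(truth, qr$most_likely, cls, with_na = FALSE)
    cm_na <- confusion_matrix(truth, qr$assigned, cls, with_na = TRUE)
    per_mode$all_assigned[[run]] <-
      confusion_stats(cm_all, mode = "all_assigned")
    per_mode$with_not_assigned[[run]] <-
      confusion_stats(cm_na, mode = "with_not_assigned")
  }

  summarize <- function(stats_list) {
    pcts <- lapply(stats_list, `[[`, "percentages")
    avg_pct <- Reduce(`+`, pcts) / length(pcts)
    pc <- lapply(stats_list, `[[`, "per_class")
    avg_pc <- pc[[1]]
    for (col in c("sensitivity", "specificity", "mcc", "call_rate"))
      avg_pc[[col]] <- rowMeans(sapply(pc, `[[`, col))
    list(avg_percentages = avg_pct, avg_per_class = avg_pc,
         avg_global_accuracy =
           mean(sapply(stats_list, `[[`, "global_accuracy")),
         avg_global_call_rate =
           mean(sapply(stats_list, `[[`, "global_call_rate")),
         runs = stats_list)
  }

  structure(list(all_assigned = summarize(per_mode$all_assigned),
                 with_not_assigned = summarize(per_mode$with_not_assigned),
                 selection_counts = sel_counts,
                 n_runs = runs, train_fraction = train_fraction,
                 classes = cls),
            class = "external_validation")
}

#' @export
print.external_validation <- function(x, ...) {
  cat(sprintf("external_validation: %d runs, train fraction %.2f\n",
              x$n_runs, x$train_fraction))
  for (mode in c("with_not_assigned", "all_assigned")) {
    s <- x[[mode]]
    cat(sprintf("  %-18s global accuracy %6.2f%%, call rate %6.2f%%\n",
                mode, 100 * s$avg_global_accuracy,
                100 * s$avg_global_call_rate))
  }
  invisible(x)
}

#' Restrict a dataset to a subset of samples
#' @param dataset An [expression_dataset()].
#' @param idx Sample indices or names.
#' @return An [expression_dataset()] over the selected samples.
#' @export
subset_samples <- function(dataset, idx) {
  stopifnot(inherits(dataset, "expression_dataset"))
  mat <- dataset$exprs[, idx, drop = FALSE]
  labels <- if (!is.null(dataset$labels))
    setNames(as.character(dataset$labels)[
      match(colnames(mat), colnames(dataset$exprs))], colnames(mat))
  suppressWarnings(expression_dataset(mat, labels))
}
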