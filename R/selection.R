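#' Wrapper forward selection of the minimum gene subset per class
#'
#' Repeated stratified cross-validation around the one-vs-one linear SVM.
#' Each cross-validation fold starts with the first ranked gene of every
#' class, trains a temporary classifier on the fold's training samples and
#' evaluates it on the held-out samples; one more gene (taken in ranking
#' order) is then added to every class that still has misclassified
#' held-out samples. The iteration stops at zero error (unless
#' `continue_zero_error`) or when a class prefix reaches `max_genes_train`.
#' Within each repeat the smallest genes-per-class vector attaining the
#' minimum observed error is kept; the final per-class count is a trimmed
#' consensus over the repeats: counts strictly greater than
#' `Q3 + 1.5 * IQR` of the repeat counts are discarded as outliers and the
#' maximum of the remainder is taken (at least 1 gene per class).
#'
#' The number of folds is capped at the smallest class size so every fold
#' keeps per-class representation.
#'
#' @param dataset A labelled [expression_dataset()].
#' @param ranking A [build_ranking()] result with at least one ranked gene
#'   per class.
#' @param config A [marker_config()]; uses `cv_folds`, `cv_repeats`,
#'   `max_genes_train`, `continue_zero_error`, `svm_cost` and `seed`.
#' @return An object of class `selection_result`: `final_counts` (named
#'   integer vector), `selected_genes` (named list of per-class gene
#'   vectors, ranking prefixes), `per_repeat_counts` (repeats x classes
#'   matrix of kept counts), `per_repeat_error` (minimum CV error per
#'   repeat) and `cv_error_trace` (data frame: repeat, fold, iter, the
#'   genes-per-class counts and the fold error).
#' @export
forward_select <- function(dataset, ranking, config = marker_config()) {
  assert_analysis_ready(dataset)
  stopifnot(inherits(ranking, "gene_ranking"))
  cls <- dataset$classes
  K <- length(cls)
  gene_lists <- lapply(cls, function(k) genes_for_class(ranking, k))
  names(gene_lists) <- cls
  n_avail <- vapply(gene_lists, length, integer(1))
  if (any(n_avail == 0))
    stop("no ranked genes for class(es): ",
         paste(cls[n_avail == 0], collapse = ", "))
  cap <- pmin(n_avail, config$max_genes_train)

  min_class <- min(table(dataset$labels))
  folds <- min(config$cv_folds, min_class)
  if (folds < 2)
    stop("cannot form ", config$cv_folds, "-fold cross-validation: ",
         "a class has fewer than 2 samples; use fewer folds or more samples")

  y <- dataset$labels
  trace <- list()
  kept_counts <- matrix(NA_integer_, config$cv_repeats, K,
                        dimnames = list(NULL, cls))
  kept_error <- numeric(config$cv_repeats)

  for (r in seq_len(config$cv_repeats)) {
    set.seed(derive_seed(config$seed, "selection", r))
    fold_of <- integer(length(y))
    for (k in cls) {
      idx <- which(y == k)
      fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    repeat_rows <- list()
    for (f in seq_len(folds)) {
      test_idx <- which(fold_of == f)
      train_idx <- which(fold_of != f)
      if (min(table(y[train_idx])) < 2)
        stop("a class has fewer than 2 samples in a training fold; ",
             "use fewer folds")
      counts <- rep(1L, K)
      iter <- 0L
      repeat {
        iter <- iter + 1L
        genes <- unlist(mapply(function(gl, nc) gl[seq_len(nc)],
                               gene_lists, counts, SIMPLIFY = FALSE),
                        use.names = FALSE)
        genes <- unique(genes)
        err_info <- cv_fold_error(dataset, genes, train_idx, test_idx,
                                  config$svm_cost)
        repeat_rows[[length(repeat_rows) + 1L]] <-
          c(list(repeat_ = r, fold = f, iter = iter),
            as.list(setNames(counts, cls)), list(error = err_info$error))
        if (err_info$error == 0 && !config$continue_zero_error) break
        if (any(counts >= config$max_genes_train)) break
        grow <- if (err_info$error == 0) cls else err_info$miss_classes
        can_grow <- cls %in% grow & counts < cap
        if (!any(can_grow)) break
        counts[can_grow] <- counts[can_grow] + 1L
      }
    }
    rows <- do.call(rbind, lapply(repeat_rows, as.data.frame))
    trace[[r]] <- rows
    errs <- rows$error
    best <- min(errs)
    cand <- rows[errs == best, cls, drop = FALSE]
    sums <- rowSums(cand)
    cand <- cand[sums == min(sums), , drop = FALSE]
    # deterministic tie-break: lexicographically smallest counts vector
    ordc <- do.call(order, as.list(cand))
    kept_counts[r, ] <- as.integer(cand[ordc[1], ])
    kept_error[r] <- best
  }

  final <- vapply(seq_len(K), function(k)
    trimmed_max(kept_counts[, k]), numeric(1))
  final <- pmax(1L, pmin(as.integer(final), n_avail))
  names(final) <- cls
  selected <- mapply(function(gl, nc) gl[seq_len(nc)], gene_lists, final,
                     SIMPLIFY = FALSE)

  structure(list(final_counts = final, selected_genes = selected,
                 per_repeat_counts = kept_counts,
                 per_repeat_error = kept_error,
                 cv_error_trace = do.call(rbind, trace),
                 classes = cls, config = config),
            class = "selection_result")
}

# Trains a temporary (uncalibrated) classifier on the training part of a
# fold and returns the held-out error plus the true classes of the
# misclassified held-out samples.
cv_fold_error <- function(dataset, genes, train_idx, test_idx, cost) {
  x <- t(dataset$exprs[genes, , drop = FALSE])
  y <- dataset$labels
  xtr <- x[train_idx, , drop = FALSE]
  usable <- apply(xtr, 2, sd) > 0
  if (!any(usable)) {
    return(list(error = 1,
                miss_classes = unique(as.character(y[test_idx]))))
  }
  fit <- e1071::svm(xtr[, usable, drop = FALSE], droplevels(y[train_idx]),
                    kernel = "linear", cost = cost, scale = TRUE)
  pred <- predict(fit, x[test_idx, usable, drop = FALSE])
  truth <- as.character(y[test_idx])
  wrong <- as.character(pred) != truth
  list(error = mean(wrong), miss_classes = unique(truth[wrong]))
}

# "Highest number excluding outliers": drop values strictly above
# Q3 + 1.5 * IQR, then take the maximum of what remains.
trimmed_max <- function(x) {
  q3 <- quantile(x, 0.75, names = FALSE, type = 7)
  upper <- q3 + 1.5 * IQR(x, type = 7)
  max(x[x <= upper])
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result: minimum gene subset per class\n")
  for (k in x$classes)
    cat(sprintf("  %-12s %3d genes: %s%s\n", k, x$final_counts[[k]],
                paste(head(x$selected_genes[[k]], 5), collapse = ", "),
                if (x$final_counts[[k]] > 5) ", ..." else ""))
  cat(sprintf("  minimum CV error per repeat: %s\n",
              paste(signif(x$per_repeat_error, 3), collapse = ", ")))
  invisible(x)
}

#' Selection report as a data frame
#' @param selection A [forward_select()] result.
#' @return Data frame: class, gene, rank within class, final count.
#' @export
selection_table <- function(selection) {
  stopifnot(inherits(selection, "selection_result"))
  do.call(rbind, lapply(selection$classes, function(k) {
    g <- selection$selected_genes[[k]]
    data.frame(class = k, gene = g, rank = seq_along(g),
               final_count = selection$final_counts[[k]],
               stringsAsFactors = FALSE)
  }))
}
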