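#' Train the one-vs-one linear multiclass SVM
#'
#' Fits one linear-kernel binary SVM per unordered class pair on the
#' selected genes (standardized to training mean 0 / sd 1), with per-machine
#' sigmoid probability calibration; query-time class probabilities combine
#' the pairwise estimates by iterative pairwise coupling. The SVM and its
#' calibration come from \pkg{e1071} (libsvm). Calibration involves an
#' internal cross-validation, so a `seed` is taken to make training
#' reproducible.
#'
#' @param dataset A labelled [expression_dataset()].
#' @param genes Character vector of gene ids, or a named list of per-class
#'   gene vectors (as produced by [forward_select()]); the union is used as
#'   the feature set.
#' @param cost Soft-margin cost C of the linear SVM. Default 1.
#' @param seed Integer seed for the calibration's internal resampling.
#' @return An object of class `marker_classifier` holding the fitted SVM
#'   ensemble, the feature genes (and their per-class origin, when given),
#'   the class set and the per-class training means of every feature gene.
#' @export
train_classifier <- function(dataset, genes, cost = 1, seed = 1L) {
  assert_analysis_ready(dataset, min_per_class = 2L)
  genes_by_class <- NULL
  if (is.list(genes)) {
    genes_by_class <- genes
    genes <- unique(unlist(genes, use.names = FALSE))
  }
  missing <- setdiff(genes, rownames(dataset$exprs))
  if (length(missing))
    stop("selected genes absent from dataset: ",
         paste(missing, collapse = ", "))
  x <- t(dataset$exprs[genes, , drop = FALSE])
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance genes: ",
            paste(genes[sds == 0], collapse = ", "))
    genes <- genes[sds > 0]
    x <- x[, sds > 0, drop = FALSE]
  }
  if (!length(genes)) stop("no usable genes left after dropping ",
                           "zero-variance features")
  y <- dataset$labels
  set.seed(as.integer(seed))
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = TRUE,
                    probability = TRUE)
  class_means <- vapply(dataset$classes, function(k)
    rowMeans(dataset$exprs[genes, dataset$labels == k, drop = FALSE]),
    numeric(length(genes)))
  if (!is.matrix(class_means))
    class_means <- matrix(class_means, nrow = 1,
                          dimnames = list(genes, dataset$classes))
  structure(list(svm = fit, genes = genes,
                 genes_by_class = genes_by_class,
                 classes = dataset$classes, cost = cost,
                 class_means = class_means,
                 class_sizes = as.integer(table(y)[dataset$classes]),
                 seed = as.integer(seed)),
            class = "marker_classifier")
}

#' @export
print.marker_classifier <- function(x, ...) {
  K <- length(x$classes)
  cat(sprintf("marker_classifier: %d classes, %d binary machines, %d genes\n",
              K, K * (K - 1) / 2, length(x$genes)))
  invisible(x)
}

#' Number of binary machines in the ensemble
#' @param model A [train_classifier()] model.
#' @return Integer, `K * (K - 1) / 2`.
#' @export
n_machines <- function(model) {
  K <- length(model$classes)
  as.integer(K * (K - 1) / 2)
}

# Expression input for prediction: dataset or genes x samples matrix.
query_matrix <- function(model, newdata) {
  mat <- if (inherits(newdata, "expression_dataset")) newdata$exprs
         else newdata
  if (!is.matrix(mat)) stop("'newdata' must be an expression_dataset or ",
                            "a genes x samples matrix")
  missing <- setdiff(model$genes, rownames(mat))
  if (length(missing))
    stop("query is missing model genes: ", paste(missing, collapse = ", "))
  t(mat[model$genes, , drop = FALSE])
}

#' Calibrated class probabilities for query samples
#'
#' Pairwise sigmoid-calibrated probabilities from each binary machine are
#' coupled into a single probability vector per sample (sums to 1).
#'
#' @param model A [train_classifier()] model.
#' @param newdata An [expression_dataset()] or genes x samples matrix
#'   carrying all model genes.
#' @return Samples x classes matrix of probabilities, columns in the
#'   model's class order.
#' @export
predict_probabilities <- function(model, newdata) {
  x <- query_matrix(model, newdata)
  pred <- predict(model$svm, x, probability = TRUE)
  probs <- attr(pred, "probabilities")
  probs[, model$classes, drop = FALSE]
}

#' Apply the assignment rule to one probability vector
#'
#' With `K` classes the random probability is `r = 1/K`. The most likely
#' class is assigned iff its probability is at least `lp_factor * r` and its
#' gap to the second most likely class exceeds `diff_factor * r`; otherwise
#' the sample is left `NOT_ASSIGNED`.
#'
#' @param probs Numeric probability vector over the classes (sums to 1),
#'   named by class.
#' @param lp_factor Multiple of the random probability the top class must
#'   reach. Default 2.
#' @param diff_factor Multiple of the random probability the top-two gap
#'   must exceed. Default 0.8.
#' @return The assigned class name, or [NOT_ASSIGNED].
#' @export
#' @examples
#' assign_class(c(A = 0.5, B = 0.3, C = 0.1, D = 0.06, E = 0.04)) # "A"
#' assign_class(c(A = 0.35, B = 0.30, C = 0.15, D = 0.1, E = 0.1))
assign_class <- function(probs, lp_factor = 2, diff_factor = 0.8) {
  K <- length(probs)
  stopifnot(K >= 2)
  r <- 1 / K
  o <- order(probs, decreasing = TRUE)
  p1 <- probs[o[1]]
  p2 <- probs[o[2]]
  if (p1 >= lp_factor * r && (p1 - p2) > diff_factor * r)
    names(probs)[o[1]]
  else NOT_ASSIGNED
}

#' Classify query samples, with the Not-Assigned rule
#'
#' @param model A [train_classifier()] model.
#' @param newdata An [expression_dataset()] or genes x samples matrix.
#' @param config A [marker_config()] supplying `lp_factor` and
#'   `diff_factor`.
#' @return A data frame of class `query_result`: one row per sample with
#'   the per-class probabilities, `most_likely`, `second` and `assigned`
#'   (class name or [NOT_ASSIGNED]).
#' @export
predict_query <- function(model, newdata, config = marker_config()) {
  probs <- predict_probabilities(model, newdata)
  o <- t(apply(probs, 1, order, decreasing = TRUE))
  most_likely <- model$classes[o[, 1]]
  second <- model$classes[o[, 2]]
  assigned <- vapply(seq_len(nrow(probs)), function(i)
    assign_class(probs[i, ], config$lp_factor, config$diff_factor),
    character(1))
  res <- data.frame(sample = rownames(probs), probs,
                    most_likely = most_likely, second = second,
                    assigned = assigned,
                    stringsAsFactors = FALSE, row.names = NULL,
                    check.names = FALSE)
  class(res) <- c("query_result", class(res))
  res
}

# Decomposes the libsvm one-vs-one dual coefficients: for the machine on
# class pair (i, j), i < j (in the model's internal label order), the
# class-i support vectors' coefficients sit in column j - 1 of $coefs and
# the class-j ones in column i. Returns, per class, the matrix of
# |dual coefficient| weights (rows = that class's SVs, cols = partner
# classes).
ovo_blocks <- function(fit) {
  nSV <- fit$nSV
  K <- length(nSV)
  starts <- cumsum(c(0L, nSV))
  blocks <- lapply(seq_len(K), function(i)
    seq.int(starts[i] + 1L, length.out = nSV[i]))
  pair_cols <- function(i, j) if (i < j) c(j - 1L, i) else c(j, i - 1L)
  list(K = K, blocks = blocks, pair_cols = pair_cols)
}

#' Discriminant power of the classifier's genes
#'
#' For every gene and class, the dual (Lagrange) coefficients of that
#' class's support vectors across all binary machines involving the class
#' are summed, each weighted by the support vector's standardized expression
#' of the gene, giving one "pile" per class (the piled-up bars of a
#' discriminant-power plot). Each machine's per-side dual mass is
#' normalized so that all binary machines contribute on the same scale.
#' The discriminant power magnitude is the distance between the most
#' extreme pile (tallest bar, upward or downward) and the pile value
#' closest to it; its class is the class of that extreme pile, and its
#' sign follows the gene's expression direction there (positive when
#' overexpressed, negative when repressed relative to the remaining
#' samples).
#'
#' @param model A [train_classifier()] model.
#' @return An object of class `discriminant_power`: a `table` data frame
#'   (gene, dp, dp_class, direction) ordered by decreasing `|dp|`, plus the
#'   genes x classes `piles` matrix of signed pile values.
#' @export
discriminant_power <- function(model) {
  stopifnot(inherits(model, "marker_classifier"))
  fit <- model$svm
  ob <- ovo_blocks(fit)
  K <- ob$K
  class_order <- fit$levels[fit$labels]   # class name per internal label
  SV <- fit$SV                            # standardized support vectors
  genes <- model$genes
  piles <- matrix(0, length(genes), K,
                  dimnames = list(genes, class_order))
  for (i in seq_len(K)) {
    rows <- ob$blocks[[i]]
    if (!length(rows)) next
    acc <- numeric(length(genes))
    for (j in seq_len(K)) {
      if (j == i) next
      col <- ob$pair_cols(i, j)[1]
      w <- abs(fit$coefs[rows, col])
      sw <- sum(w)
      if (sw <= 0) next
      # per-machine dual mass is normalized so that easily separated
      # machines (small alpha) contribute on the same scale as hard ones
      acc <- acc + colSums((w / sw) * SV[rows, genes, drop = FALSE])
    }
    piles[, i] <- acc
  }
  piles <- piles[, model$classes, drop = FALSE]

  dp <- numeric(length(genes))
  dp_class <- character(length(genes))
  direction <- character(length(genes))
  for (g in seq_along(genes)) {
    p <- piles[g, ]
    i0 <- which.max(abs(p))              # most extreme bar, up or down
    gap <- min(abs(p[i0] - p[-i0]))      # distance to the closest bar
    cls <- model$classes[i0]
    m_in <- model$class_means[genes[g], cls]
    rest <- model$classes != cls
    m_out <- sum(model$class_means[genes[g], rest] *
                   model$class_sizes[rest]) / sum(model$class_sizes[rest])
    up <- m_in >= m_out
    dp[g] <- if (up) gap else -gap
    dp_class[g] <- cls
    direction[g] <- if (up) "UP" else "DOWN"
  }
  tab <- data.frame(gene = genes, dp = dp, dp_class = dp_class,
                    direction = direction, stringsAsFactors = FALSE)
  tab <- tab[order(-abs(tab$dp)), ]
  rownames(tab) <- NULL
  structure(list(table = tab, piles = piles),
            class = "discriminant_power")
}

#' @export
print.discriminant_power <- function(x, ...) {
  cat("discriminant_power of", nrow(x$table), "genes\n")
  print(head(x$table, 10))
  invisible(x)
}
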