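#' Marginal log-density of a group of observations under the hierarchical
#' normal model
#'
#' The model is `x_i = mu + e_i`, with `mu ~ Normal(mu0, tau2)` and
#' `e_i ~ Normal(0, sigma2)` i.i.d. Marginally `x` is multivariate normal
#' with mean `mu0 * 1` and covariance `sigma2 * I + tau2 * J`; this function
#' evaluates that log-density in closed form (Woodbury identity), avoiding
#' the dense covariance solve.
#'
#' @param x Numeric vector of observations (length >= 1).
#' @param mu0 Prior mean of the gene-level mean.
#' @param tau2 Prior variance of the gene-level mean (> 0).
#' @param sigma2 Within-group observation variance (> 0).
#' @return The log marginal density (scalar).
#' @export
#' @examples
#' lnn_group_logdensity(c(7.1, 6.8, 7.3), mu0 = 7, tau2 = 1, sigma2 = 0.25)
lnn_group_logdensity <- function(x, mu0, tau2, sigma2) {
  if (!is.numeric(x) || length(x) < 1) stop("'x' must be a nonempty vector")
  if (tau2 <= 0 || sigma2 <= 0) stop("tau2 and sigma2 must be positive")
  n <- length(x)
  lnn_logdens_stats(n, sum(x), sum(x^2), mu0, tau2, sigma2)
}

# Vectorized version over genes from sufficient statistics (n scalar,
# sx/sxx vectors of per-gene sums and sums of squares).
lnn_logdens_stats <- function(n, sx, sxx, mu0, tau2, sigma2) {
  s2 <- sxx - 2 * mu0 * sx + n * mu0^2          # sum((x - mu0)^2)
  m_dev <- sx / n - mu0                          # xbar - mu0
  quad <- (s2 - tau2 * n^2 * m_dev^2 / (sigma2 + n * tau2)) / sigma2
  logdet <- (n - 1) * log(sigma2) + log(sigma2 + n * tau2)
  -0.5 * (n * log(2 * pi) + logdet + quad)
}

# Per-class sufficient statistics for every gene: a list with n (K-vector),
# sx and sxx (genes x K matrices), plus totals.
class_suffstats <- function(dataset) {
  cls <- dataset$classes
  x <- dataset$exprs
  sx <- vapply(cls, function(k)
    rowSums(x[, dataset$labels == k, drop = FALSE]), numeric(nrow(x)))
  sxx <- vapply(cls, function(k)
    rowSums(x[, dataset$labels == k, drop = FALSE]^2), numeric(nrow(x)))
  if (!is.matrix(sx)) {
    sx <- matrix(sx, nrow = 1, dimnames = list(rownames(x), cls))
    sxx <- matrix(sxx, nrow = 1, dimnames = list(rownames(x), cls))
  }
  list(n = as.integer(table(dataset$labels)[cls]),
       sx = sx, sxx = sxx,
       n_tot = ncol(x), sx_tot = rowSums(x), sxx_tot = rowSums(x^2))
}

# Genes x (K + 1) matrix of pattern log-likelihoods. Pattern 1 ("EE") is
# equivalent expression across all classes; pattern k + 1 contrasts class k
# against the pooled rest (one-vs-rest).
pattern_loglik <- function(ss, mu0, tau2, sigma2) {
  K <- length(ss$n)
  ll <- matrix(NA_real_, length(ss$sx_tot), K + 1)
  ll[, 1] <- lnn_logdens_stats(ss$n_tot, ss$sx_tot, ss$sxx_tot,
                               mu0, tau2, sigma2)
  for (k in seq_len(K)) {
    nr <- ss$n_tot - ss$n[k]
    ll[, k + 1] <-
      lnn_logdens_stats(ss$n[k], ss$sx[, k], ss$sxx[, k],
                        mu0, tau2, sigma2) +
      lnn_logdens_stats(nr, ss$sx_tot - ss$sx[, k],
                        ss$sxx_tot - ss$sxx[, k], mu0, tau2, sigma2)
  }
  ll
}

# log-sum-exp over rows
row_logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Fit the empirical Bayes mixture model by EM
#'
#' Every gene is modelled as coming from one of `K + 1` expression patterns:
#' equivalent expression across all classes ("EE"), or differential
#' expression of one class versus the pooled rest (one pattern per class).
#' Within each pattern group the data follow the hierarchical normal model
#' of [lnn_group_logdensity()] with shared hyperparameters
#' `(mu0, tau2, sigma2)`. EM alternates posterior responsibilities (E-step)
#' with a closed-form update of the mixing proportions and a bounded
#' quasi-Newton maximization of the expected complete log-likelihood over
#' `(mu0, log tau2, log sigma2)` (M-step). The update is only accepted when
#' it improves the expected complete log-likelihood, so the observed
#' log-likelihood trace is non-decreasing.
#'
#' @param dataset A labelled [expression_dataset()] with >= 2 classes and
#'   >= 3 samples per class.
#' @param tol Relative log-likelihood change below which EM stops.
#' @param max_iter Maximum EM iterations.
#' @return An object of class `eb_model`: hyperparameters `mu0`, `tau2`,
#'   `sigma2`, mixing proportions `mix` (named `EE` then the classes),
#'   `loglik_trace`, the class set and iteration count.
#' @export
fit_eb_model <- function(dataset, tol = 1e-6, max_iter = 250L) {
  assert_analysis_ready(dataset)
  ss <- class_suffstats(dataset)
  K <- length(ss$n)
  G <- nrow(dataset$exprs)

  # initialization: grand mean, between-gene variance, pooled within-class
  # variance; 10% of mass spread over the DE patterns
  mu0 <- mean(dataset$exprs)
  gene_means <- ss$sx_tot / ss$n_tot
  tau2 <- max(var(gene_means), 1e-6)
  within <- (ss$sxx_tot - ss$sx_tot^2 / ss$n_tot) / (ss$n_tot - 1)
  sigma2 <- max(mean(within), 1e-6)
  mix <- c(0.9, rep(0.1 / K, K))

  q_of <- function(par, resp) {
    ll <- pattern_loglik(ss, par[1], exp(par[2]), exp(par[3]))
    -sum(resp * ll)
  }

  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    ll <- pattern_loglik(ss, mu0, tau2, sigma2)
    post_log <- sweep(ll, 2, log(mix), "+")
    gene_ll <- row_logsumexp(post_log)
    total <- sum(gene_ll)
    if (!is.finite(total))
      stop("EM diverged (non-finite log-likelihood) at iteration ", iter)
    trace <- c(trace, total)
    if (iter > 1 &&
        abs(total - trace[iter - 1]) <=
          tol * (abs(trace[iter - 1]) + .Machine$double.eps)) break

    resp <- exp(post_log - gene_ll)
    mix <- pmax(colSums(resp) / G, 1e-12)
    mix <- mix / sum(mix)

    par0 <- c(mu0, log(tau2), log(sigma2))
    opt <- tryCatch(
      optim(par0, q_of, resp = resp, method = "L-BFGS-B",
            lower = c(-Inf, log(1e-8), log(1e-8)),
            upper = c(Inf, log(1e8), log(1e8)),
            control = list(maxit = 50)),
      error = function(e) NULL)
    # generalized EM: only accept hyperparameters that improve Q
    if (!is.null(opt) && is.finite(opt$value) &&
        opt$value <= q_of(par0, resp)) {
      mu0 <- opt$par[1]
      tau2 <- exp(opt$par[2])
      sigma2 <- exp(opt$par[3])
    }
  }

  structure(list(mu0 = mu0, tau2 = tau2, sigma2 = sigma2,
                 mix = setNames(mix, c("EE", dataset$classes)),
                 loglik_trace = trace, classes = dataset$classes,
                 n_iter = length(trace)),
            class = "eb_model")
}

#' @export
print.eb_model <- function(x, ...) {
  cat(sprintf(
    "eb_model: mu0 = %.3f, tau2 = %.3f, sigma2 = %.3f (%d EM iterations)\n",
    x$mu0, x$tau2, x$sigma2, x$n_iter))
  cat("mixing proportions:\n")
  print(round(x$mix, 4))
  invisible(x)
}

#' Posterior pattern probabilities for every gene
#'
#' Bayes responsibilities under the fitted mixture:
#' `posterior(g, p) = mix[p] * L(g | p) / sum_q mix[q] * L(g | q)`. Rows sum
#' to 1. Column `EE` is the equivalent-expression pattern; the remaining
#' columns are the one-vs-rest patterns, one per class.
#'
#' @param model A fitted [fit_eb_model()] object.
#' @param dataset The labelled dataset the model was fitted on (same classes).
#' @return Genes x (K + 1) matrix of posterior probabilities.
#' @export
posterior_probabilities <- function(model, dataset) {
  stopifnot(inherits(model, "eb_model"))
  assert_analysis_ready(dataset)
  if (!identical(model$classes, dataset$classes))
    stop("model and dataset classes differ")
  ss <- class_suffstats(dataset)
  ll <- pattern_loglik(ss, model$mu0, model$tau2, model$sigma2)
  post_log <- sweep(ll, 2, log(model$mix), "+")
  post <- exp(post_log - row_logsumexp(post_log))
  dimnames(post) <- list(rownames(dataset$exprs),
                         c("EE", dataset$classes))
  post
}

#' Build non-overlapping per-class gene rankings
#'
#' Three steps: (1) per class, genes are ordered by decreasing posterior
#' probability for that class's pattern, ties broken by decreasing
#' `|expr_diff|` (the gene's mean in the class minus its mean in the closest
#' other class), remaining ties by gene id; (2) every gene is assigned to
#' the class where its rank position is best, cross-class ties going to the
#' higher posterior, then larger `|expr_diff|`; (3) genes whose maximum
#' pattern posterior is the equivalent-expression pattern are filtered out
#' entirely. The resulting per-class lists are disjoint and re-ranked
#' consecutively from 1.
#'
#' @param posteriors Matrix from [posterior_probabilities()].
#' @param dataset The labelled dataset.
#' @param significance_threshold Posterior above which a gene is flagged
#'   significant. Default 0.95.
#' @return An object of class `gene_ranking`: a `table` data frame with
#'   columns gene, class, rank, posterior_prob, expr_diff, direction,
#'   significant; plus the posterior matrix, classes and threshold.
#' @export
build_ranking <- function(posteriors, dataset,
                          significance_threshold = 0.95) {
  assert_analysis_ready(dataset)
  cls <- dataset$classes
  K <- length(cls)
  genes <- rownames(dataset$exprs)
  stopifnot(identical(rownames(posteriors), genes),
            ncol(posteriors) == K + 1)

  means <- vapply(cls, function(k)
    rowMeans(dataset$exprs[, dataset$labels == k, drop = FALSE]),
    numeric(length(genes)))
  if (!is.matrix(means))
    means <- matrix(means, nrow = 1, dimnames = list(genes, cls))
  # expr_diff[g, k]: class-k mean minus the mean of the other class whose
  # mean is nearest to class k's for that gene
  ed <- matrix(NA_real_, length(genes), K, dimnames = list(genes, cls))
  for (k in seq_len(K)) {
    d <- means[, -k, drop = FALSE] - means[, k]
    closest <- apply(abs(d), 1, which.min)
    ed[, k] <- -d[cbind(seq_along(genes), closest)]
  }

  post <- posteriors[, cls, drop = FALSE]
  keep <- max.col(posteriors, ties.method = "first") != 1L
  kept <- which(keep)
  if (!length(kept)) {
    tab <- data.frame(gene = character(0), class = character(0),
                      rank = integer(0), posterior_prob = numeric(0),
                      expr_diff = numeric(0), direction = character(0),
                      significant = logical(0), stringsAsFactors = FALSE)
    return(structure(list(table = tab, posteriors = posteriors,
                          classes = cls,
                          threshold = significance_threshold),
                     class = "gene_ranking"))
  }

  # per-class rank position of every kept gene
  pos <- matrix(NA_integer_, length(kept), K)
  for (k in seq_len(K)) {
    ord <- order(-post[kept, k], -abs(ed[kept, k]), genes[kept])
    pos[ord, k] <- seq_along(kept)
  }

  best_pos <- integer(length(kept))
  best_class <- integer(length(kept))
  for (i in seq_along(kept)) {
    p <- pos[i, ]
    cand <- which(p == min(p))
    if (length(cand) > 1) {
      o <- order(-post[kept[i], cand], -abs(ed[kept[i], cand]), cand)
      cand <- cand[o[1]]
    }
    best_class[i] <- cand
    best_pos[i] <- p[cand]
  }

  rows <- vector("list", K)
  for (k in seq_len(K)) {
    sel <- which(best_class == k)
    if (!length(sel)) next
    sel <- sel[order(pos[sel, k])]
    g <- genes[kept[sel]]
    pp <- post[kept[sel], k]
    dd <- ed[kept[sel], k]
    rows[[k]] <- data.frame(
      gene = g, class = cls[k], rank = seq_along(sel),
      posterior_prob = pp, expr_diff = dd,
      direction = ifelse(dd > 0, "UP", "DOWN"),
      significant = pp > significance_threshold,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  structure(list(table = tab, posteriors = posteriors, classes = cls,
                 threshold = significance_threshold),
            class = "gene_ranking")
}

#' @export
print.gene_ranking <- function(x, ...) {
  cat("gene_ranking over classes:", paste(x$classes, collapse = ", "), "\n")
  counts <- count_significant(x)
  for (k in x$classes) {
    n <- sum(x$table$class == k)
    cat(sprintf("  %-12s %5d ranked genes (%d significant at > %.2f)\n",
                k, n, counts[[k]], x$threshold))
  }
  invisible(x)
}

#' Ordered gene ids of one class's ranking
#' @param ranking A [build_ranking()] result.
#' @param class Class name.
#' @return Character vector of gene ids, best rank first.
#' @export
genes_for_class <- function(ranking, class) {
  stopifnot(inherits(ranking, "gene_ranking"))
  if (!class %in% ranking$classes) stop("unknown class: ", class)
  sub <- ranking$table[ranking$table$class == class, ]
  sub$gene[order(sub$rank)]
}

#' Count significant genes per class
#'
#' @param ranking A [build_ranking()] result.
#' @param threshold Posterior probability threshold; defaults to the one
#'   the ranking was built with.
#' @return Named integer vector, one count per class (zero included).
#' @export
count_significant <- function(ranking, threshold = ranking$threshold) {
  stopifnot(inherits(ranking, "gene_ranking"))
  sig <- ranking$table[ranking$table$posterior_prob > threshold, ]
  counts <- table(factor(sig$class, levels = ranking$classes))
  setNames(as.integer(counts), ranking$classes)
}
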