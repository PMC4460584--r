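# Shared fixture builders. Everything is generated in code under fixed
# seeds; heavier simulations are cached per test run.

toy_matrix <- function(n_genes = 4, n_samples = 6, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples, 7, 1), n_genes, n_samples,
         dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}

# Two classes, one gene with disjoint ranges, the rest pure noise.
separable_toy <- function(n_per_class = 8, n_noise = 5, gap = 6, seed = 2) {
  set.seed(seed)
  n <- 2 * n_per_class
  mat <- matrix(rnorm((n_noise + 1) * n, 7, 0.5), n_noise + 1, n,
                dimnames = list(sprintf("g%02d", seq_len(n_noise + 1)),
                                sprintf("s%02d", seq_len(n))))
  mat[1, seq_len(n_per_class)] <- mat[1, seq_len(n_per_class)] + gap
  labels <- setNames(rep(c("A", "B"), each = n_per_class), colnames(mat))
  expression_dataset(mat, labels)
}

# Hand-built gene_ranking over explicit per-class gene lists, for modules
# that only consume the ranking order.
manual_ranking <- function(gene_lists, threshold = 0.95) {
  tab <- do.call(rbind, lapply(names(gene_lists), function(k) {
    g <- gene_lists[[k]]
    data.frame(gene = g, class = k, rank = seq_along(g),
               posterior_prob = seq(0.99, 0.90, length.out = length(g)),
               expr_diff = rep(1, length(g)), direction = "UP",
               significant = TRUE, stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, posteriors = NULL,
                 classes = names(gene_lists), threshold = threshold),
            class = "gene_ranking")
}

# Cached planted 5-class simulation shared across test files.
.fixture_env <- new.env(parent = emptyenv())

planted_sim <- function() {
  if (is.null(.fixture_env$planted)) {
    .fixture_env$planted <- simulate_expression(
      n_classes = 5, n_per_class = 12, n_genes = 800, de_per_class = 25,
      effect = 4, seed = 21)
  }
  .fixture_env$planted
}

planted_ranking <- function() {
  if (is.null(.fixture_env$planted_rk)) {
    ds <- planted_sim()$dataset
    m <- fit_eb_model(ds)
    .fixture_env$planted_rk <-
      build_ranking(posterior_probabilities(m, ds), ds)
  }
  .fixture_env$planted_rk
}

# Dense multivariate-normal log-density oracle with explicit solve and
# determinant (independent of the closed-form implementation).
mvn_logpdf_oracle <- function(x, mu0, tau2, sigma2) {
  n <- length(x)
  S <- diag(sigma2, n) + matrix(tau2, n, n)
  d <- x - mu0
  as.numeric(-0.5 * (n * log(2 * pi) +
                       determinant(S, logarithm = TRUE)$modulus +
                       t(d) %*% solve(S, d)))
}
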