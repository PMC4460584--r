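#' Simulate a multiclass expression dataset with planted structure
#'
#' Generates a genes x samples log2-scale matrix under the hierarchical
#' normal model the ranking stage assumes: gene baseline means are drawn
#' from `Normal(mu0, tau2)` and observations add `Normal(0, sigma2)` noise.
#' On top of this null structure the generator plants, per class:
#'
#' * `de_per_class` differentially expressed genes, shifted by
#'   `effect * sqrt(sigma2)` in that class's samples only, with alternating
#'   UP/DOWN directions;
#' * one co-regulated block of `block_size` genes (a subset of the planted
#'   genes) sharing a latent factor that induces pairwise correlation of
#'   about 0.94; block genes get a proportionally larger shift so their
#'   standardized effect matches the other planted genes;
#' * one planted gene pair carrying a quadratic dependency with zero linear
#'   correlation between the latent components, detectable by mutual
#'   information but not by Pearson correlation.
#'
#' The full ground truth is returned alongside the dataset. A fixed seed
#' yields a byte-identical matrix.
#'
#' @param n_classes Number of classes K (>= 2).
#' @param n_per_class Samples per class.
#' @param n_genes Total number of genes.
#' @param de_per_class Planted differential genes per class: a scalar, or a
#'   length-`n_classes` vector for unequal class signal (0 allowed). The
#'   total must not exceed `n_genes`.
#' @param effect Effect size in units of the within-class standard deviation
#'   `sqrt(sigma2)`.
#' @param block_size Size of the co-regulated block per class (0 disables;
#'   must be `<= de_per_class`).
#' @param quad_pair If `TRUE` (and `de_per_class >= block_size + 2`), plant
#'   the quadratic-dependency pair per class.
#' @param mu0,tau2,sigma2 Hyperparameters of the hierarchical normal model
#'   (defaults 7, 4, 0.25: typical log2 microarray location, broad gene
#'   means, residual sd 0.5).
#' @param seed Integer seed.
#' @return A list with `dataset` (an [expression_dataset()]) and `truth`,
#'   a list recording planted genes, directions, blocks, quadratic pairs
#'   and all generative parameters.
#' @export
#' @examples
#' sim <- simulate_expression(n_classes = 3, n_per_class = 5,
#'                            n_genes = 100, de_per_class = 5, seed = 1)
#' sim$dataset
simulate_expression <- function(n_classes = 5, n_per_class = 12,
                                n_genes = 2000, de_per_class = 50,
                                effect = 4, block_size = 5,
                                quad_pair = TRUE,
                                mu0 = 7, tau2 = 4, sigma2 = 0.25,
                                seed = 1L) {
  de_per_class <- rep_len(as.integer(de_per_class), n_classes)
  stopifnot(n_classes >= 2, n_per_class >= 1, effect >= 0,
            sum(de_per_class) <= n_genes, all(de_per_class >= 0),
            block_size <= max(de_per_class), tau2 > 0, sigma2 > 0)
  set.seed(as.integer(seed))
  K <- n_classes
  n <- K * n_per_class
  classes <- paste0("class_", LETTERS[seq_len(K)])
  samples <- paste0(rep(classes, each = n_per_class), "_s",
                    sprintf("%02d", rep(seq_len(n_per_class), K)))
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  class_of <- rep(classes, each = n_per_class)

  base_mean <- rnorm(n_genes, mu0, sqrt(tau2))
  mat <- matrix(rnorm(n_genes * n, 0, sqrt(sigma2)), n_genes, n,
                dimnames = list(genes, samples))
  mat <- mat + base_mean

  delta <- effect * sqrt(sigma2)
  de_idx <- sample.int(n_genes, sum(de_per_class))
  de_by_class <- split(de_idx, factor(rep(seq_len(K), times = de_per_class),
                                      levels = seq_len(K)))

  truth <- list(
    de_genes = setNames(vector("list", K), classes),
    blocks = setNames(vector("list", K), classes),
    quad_pairs = setNames(vector("list", K), classes),
    params = list(n_classes = K, n_per_class = n_per_class,
                  n_genes = n_genes, de_per_class = de_per_class,
                  effect = effect, block_size = block_size,
                  mu0 = mu0, tau2 = tau2, sigma2 = sigma2,
                  seed = as.integer(seed))
  )

  # shared-factor loading giving pairwise correlation lambda^2/(lambda^2 +
  # sigma2) ~ 0.94 among block genes
  lambda <- 4 * sqrt(sigma2)
  for (k in seq_len(K)) {
    idx <- de_by_class[[k]]
    if (!length(idx)) next
    in_class <- class_of == classes[k]
    dir <- rep(c(1, -1), length.out = length(idx))
    dirs <- ifelse(dir > 0, "UP", "DOWN")
    eff <- rep(delta, length(idx))

    if (block_size > 0 && length(idx) >= block_size) {
      blk <- seq_len(block_size)
      f <- rnorm(n)                      # latent factor over all samples
      mat[idx[blk], ] <- mat[idx[blk], , drop = FALSE] +
        matrix(lambda, block_size, 1) %*% matrix(f, 1, n)
      # same direction for the whole block (opposite class shifts would
      # cancel the planted correlation) and a proportionally larger shift so
      # the standardized effect matches the other planted genes
      dir[blk] <- 1
      dirs[blk] <- "UP"
      eff[blk] <- delta * sqrt(1 + lambda^2 / sigma2)
      truth$blocks[[k]] <- genes[idx[blk]]
    }
    if (quad_pair && length(idx) >= block_size + 2) {
      qp <- block_size + c(1L, 2L)
      z <- rnorm(n)
      s <- sqrt(sigma2)
      # the latent z dominates the first gene's variance so that the shared
      # class shift cannot push the pair's linear correlation above ~0.5
      mat[idx[qp[1]], ] <- base_mean[idx[qp[1]]] + 2 * s * z
      mat[idx[qp[2]], ] <- base_mean[idx[qp[2]]] + s * (z^2 - 1) / sqrt(2)
      dir[qp] <- c(1, 1)                 # same class shift keeps the pair's
      dirs[qp] <- "UP"                   # z-relation deterministic per class
      truth$quad_pairs[[k]] <- genes[idx[qp]]
    }
    mat[idx, in_class] <- mat[idx, in_class, drop = FALSE] + dir * eff
    truth$de_genes[[k]] <- data.frame(gene = genes[idx], direction = dirs,
                                      effect = eff,
                                      stringsAsFactors = FALSE)
  }

  labels <- setNames(class_of, samples)
  list(dataset = expression_dataset(mat, labels), truth = truth)
}

#' Simulate an RNA-Seq-like dataset on the log2(RPKM + 1) scale
#'
#' Draws nonnegative RPKM-like values (log-normal: `2^latent`, with the
#' latent layer generated exactly as in [simulate_expression()] but centred
#' at a log2-RPKM location) and applies the `log2(x + 1)` transform used for
#' RNA-Seq input. Planted structure and ground truth are as in
#' [simulate_expression()].
#'
#' @inheritParams simulate_expression
#' @param rpkm_scale Multiplicative scale applied to the RPKM values before
#'   the transform. Default 1.
#' @return As [simulate_expression()].
#' @export
simulate_rnaseq <- function(n_classes = 2, n_per_class = 12,
                            n_genes = 1000, de_per_class = 30,
                            effect = 4, block_size = 5, quad_pair = TRUE,
                            mu0 = 4, tau2 = 4, sigma2 = 0.25,
                            rpkm_scale = 1, seed = 1L) {
  sim <- simulate_expression(n_classes = n_classes,
                             n_per_class = n_per_class, n_genes = n_genes,
                             de_per_class = de_per_class, effect = effect,
                             block_size = block_size, quad_pair = quad_pair,
                             mu0 = mu0, tau2 = tau2, sigma2 = sigma2,
                             seed = seed)
  rpkm <- rpkm_scale * 2^sim$dataset$exprs
  mat <- log2(rpkm + 1)
  sim$dataset$exprs <- mat
  sim$truth$params$rpkm_scale <- rpkm_scale
  sim
}
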