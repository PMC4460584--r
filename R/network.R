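#' Co-expression (correlation) edges between genes
#'
#' Pearson (default) correlation over all samples for every gene pair; an
#' edge is kept when `|r| >= threshold` and carries the signed `r` as its
#' weight. Zero-variance genes are excluded with a warning.
#'
#' @param dataset An [expression_dataset()].
#' @param genes Gene ids to consider.
#' @param threshold Minimum `|r|`. Default 0.8.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Data frame: gene1, gene2, type (`"correlation"`), weight.
#' @export
correlation_edges <- function(dataset, genes, threshold = 0.8,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "expression_dataset"),
            threshold >= 0, threshold <= 1)
  if (ncol(dataset$exprs) < 3) stop("need at least 3 samples")
  missing <- setdiff(genes, rownames(dataset$exprs))
  if (length(missing)) stop("genes absent from dataset: ",
                            paste(missing, collapse = ", "))
  x <- dataset$exprs[genes, , drop = FALSE]
  sds <- apply(x, 1, sd)
  if (any(sds == 0)) {
    warning("excluding zero-variance genes from correlation: ",
            paste(genes[sds == 0], collapse = ", "))
    x <- x[sds > 0, , drop = FALSE]
  }
  empty <- data.frame(gene1 = character(0), gene2 = character(0),
                      type = character(0), weight = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(x) < 2) return(empty)
  r <- cor(t(x), method = method)
  idx <- which(upper.tri(r) & abs(r) >= threshold, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  data.frame(gene1 = rownames(r)[idx[, 1]], gene2 = rownames(r)[idx[, 2]],
             type = "correlation", weight = r[idx],
             stringsAsFactors = FALSE, row.names = NULL)
}

# Equal-frequency discretization into `bins` bins; returns an integer
# factor, or NULL when the gene is (near-)constant.
discretize_ef <- function(v, bins) {
  brk <- unique(quantile(v, probs = seq(0, 1, length.out = bins + 1),
                         names = FALSE, type = 7))
  if (length(brk) < 3) return(NULL)
  cut(v, breaks = brk, include.lowest = TRUE, labels = FALSE)
}

# Empirical mutual information (nats) and marginal entropies from two
# discretized vectors.
mi_from_discrete <- function(a, b) {
  joint <- table(a, b) / length(a)
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  list(mi = mi, hx = hx, hy = hy)
}

#' Mutual-information edges between genes
#'
#' Each gene is discretized into equal-frequency bins
#' (`ceiling(sqrt(n_samples))` by default); mutual information is the
#' empirical plug-in estimate from the joint histogram, normalized to [0, 1]
#' by the smaller marginal entropy so that the threshold is scale-free.
#' Genes that cannot be discretized (constant or near-constant) are excluded
#' with a warning.
#'
#' @param dataset An [expression_dataset()].
#' @param genes Gene ids to consider.
#' @param threshold Minimum normalized MI. Default 0.5.
#' @param bins Number of bins (>= 2); default `ceiling(sqrt(n_samples))`.
#' @return Data frame: gene1, gene2, type (`"mutual_information"`), weight.
#' @export
mutual_information_edges <- function(dataset, genes, threshold = 0.5,
                                     bins = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"),
            threshold >= 0, threshold <= 1)
  n <- ncol(dataset$exprs)
  if (is.null(bins)) bins <- ceiling(sqrt(n))
  bins <- as.integer(bins)
  if (bins < 2) stop("'bins' must be at least 2")
  missing <- setdiff(genes, rownames(dataset$exprs))
  if (length(missing)) stop("genes absent from dataset: ",
                            paste(missing, collapse = ", "))
  disc <- lapply(genes, function(g)
    discretize_ef(dataset$exprs[g, ], bins))
  names(disc) <- genes
  bad <- vapply(disc, is.null, logical(1))
  if (any(bad)) {
    warning("excluding genes with undefined mutual information ",
            "(constant expression): ", paste(genes[bad], collapse = ", "))
    disc <- disc[!bad]
  }
  out <- list()
  gs <- names(disc)
  if (length(gs) >= 2) {
    for (i in seq_len(length(gs) - 1)) {
      for (j in seq.int(i + 1, length(gs))) {
        m <- mi_from_discrete(disc[[i]], disc[[j]])
        hmin <- min(m$hx, m$hy)
        if (hmin <= 0) next
        nmi <- m$mi / hmin
        if (nmi >= threshold)
          out[[length(out) + 1L]] <-
            data.frame(gene1 = gs[i], gene2 = gs[j],
                       type = "mutual_information", weight = nmi,
                       stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(gene1 = character(0), gene2 = character(0),
                      type = character(0), weight = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Build the annotated gene network of one class
#'
#' Nodes are the class's `top_n` top-ranked genes, annotated with their
#' posterior probability, expression difference, direction, whether they
#' were selected for classification, and discriminant power. Edges (of both
#' types) are computed within the class's gene list only, at the configured
#' thresholds, and restricted to the included nodes; a pair may carry both a
#' correlation and a mutual-information edge.
#'
#' @param ranking A [build_ranking()] result.
#' @param class Class name.
#' @param dataset The [expression_dataset()] (needed unless `edges` is
#'   supplied).
#' @param selection Optional [forward_select()] result.
#' @param dp Optional [discriminant_power()] result.
#' @param edges Optional precomputed edge data frame (as returned by
#'   [correlation_edges()] / [mutual_information_edges()], possibly
#'   row-bound); computed from `dataset` when `NULL`.
#' @param top_n Number of top-ranked genes to include. Default 30.
#' @param correlations_threshold,interactions_threshold,bins Passed to the
#'   edge estimators when `edges` is `NULL`.
#' @return An object of class `gene_network`: the class name, a `nodes`
#'   data frame (gene, rank, posterior_prob, expr_diff, direction,
#'   selected_for_classification, dp, redundant) and an `edges` data frame.
#' @export
build_network <- function(ranking, class, dataset = NULL, selection = NULL,
                          dp = NULL, edges = NULL, top_n = 30,
                          correlations_threshold = 0.8,
                          interactions_threshold = 0.5, bins = NULL) {
  stopifnot(inherits(ranking, "gene_ranking"))
  if (!class %in% ranking$classes)
    stop("class not present in ranking: ", class)
  sub <- ranking$table[ranking$table$class == class, ]
  sub <- sub[order(sub$rank), ]
  sub <- head(sub, top_n)
  nodes <- data.frame(gene = sub$gene, rank = sub$rank,
                      posterior_prob = sub$posterior_prob,
                      expr_diff = sub$expr_diff, direction = sub$direction,
                      stringsAsFactors = FALSE)
  sel_genes <- if (!is.null(selection))
    selection$selected_genes[[class]] else character(0)
  nodes$selected_for_classification <- nodes$gene %in% sel_genes
  nodes$dp <- NA_real_
  if (!is.null(dp)) {
    m <- match(nodes$gene, dp$table$gene)
    nodes$dp <- dp$table$dp[m]
  }
  if (is.null(edges)) {
    if (is.null(dataset))
      stop("either 'dataset' or precomputed 'edges' must be supplied")
    edges <- rbind(
      correlation_edges(dataset, nodes$gene,
                        threshold = correlations_threshold),
      mutual_information_edges(dataset, nodes$gene,
                               threshold = interactions_threshold,
                               bins = bins))
  }
  edges <- edges[edges$gene1 %in% nodes$gene &
                   edges$gene2 %in% nodes$gene &
                   edges$gene1 != edges$gene2, , drop = FALSE]
  rownames(edges) <- NULL
  nodes$redundant <- unname(flag_redundancy(nodes$gene, edges))
  structure(list(class = class, nodes = nodes, edges = edges),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network for %s: %d nodes, %d edges (%d correlation, %d MI)\n",
              x$class, nrow(x$nodes), nrow(x$edges),
              sum(x$edges$type == "correlation"),
              sum(x$edges$type == "mutual_information")))
  invisible(x)
}

#' Flag genes that are redundant with others in their list
#'
#' A gene is redundant when it has at least one correlation or
#' mutual-information edge (at the configured thresholds) to another gene
#' of the same class list.
#'
#' @param genes Character vector of gene ids.
#' @param edges Edge data frame with columns gene1, gene2.
#' @return Named logical vector over `genes`.
#' @export
flag_redundancy <- function(genes, edges) {
  connected <- unique(c(edges$gene1, edges$gene2))
  setNames(genes %in% connected, genes)
}

#' Export a network's edges as a SIF file
#' @param network A [build_network()] result.
#' @param path Output path.
#' @export
export_sif <- function(network, path) {
  stopifnot(inherits(network, "gene_network"))
  lines <- sprintf("%s\t%s\t%s", network$edges$gene1, network$edges$type,
                   network$edges$gene2)
  writeLines(lines, path)
  invisible(path)
}

#' Export a network as GraphML with node and edge attributes
#' @param network A [build_network()] result.
#' @param path Output path.
#' @export
export_graphml <- function(network, path) {
  stopifnot(inherits(network, "gene_network"))
  nodes <- network$nodes
  nodes$dp[is.na(nodes$dp)] <- 0
  g <- igraph::graph_from_data_frame(
    d = network$edges, directed = FALSE,
    vertices = data.frame(name = nodes$gene, nodes[-1],
                          stringsAsFactors = FALSE))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a network's node attribute table as TSV
#' @param network A [build_network()] result.
#' @param path Output path.
#' @export
write_node_attributes <- function(network, path) {
  stopifnot(inherits(network, "gene_network"))
  write_table(network$nodes, path)
}
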