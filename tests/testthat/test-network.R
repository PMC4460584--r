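test_that("correlation edges match a brute-force cor() oracle", {
  set.seed(23)
  m <- matrix(rnorm(6 * 20, 7, 1), 6, 20,
              dimnames = list(sprintf("g%02d", 1:6), sprintf("s%02d", 1:20)))
  m[2, ] <- 0.9 * m[1, ] + 0.1 * rnorm(20)       # strong positive pair
  m[4, ] <- -m[3, ] + 0.05 * rnorm(20)           # strong negative pair
  ds <- expression_dataset(m)
  genes <- rownames(m)
  edges <- correlation_edges(ds, genes, threshold = 0.8)
  # oracle: every unordered pair, plain cor()
  expected <- list()
  for (i in 1:5) for (j in (i + 1):6) {
    r <- cor(m[i, ], m[j, ])
    if (abs(r) >= 0.8)
      expected[[length(expected) + 1]] <-
        data.frame(gene1 = genes[i], gene2 = genes[j], weight = r)
  }
  expected <- do.call(rbind, expected)
  expect_identical(nrow(edges), nrow(expected))
  key <- function(d) paste(d$gene1, d$gene2)
  o <- match(key(expected), key(edges))
  expect_false(anyNA(o))
  expect_equal(edges$weight[o], expected$weight, tolerance = 1e-10)
  expect_true(all(edges$type == "correlation"))
  # the planted negative pair keeps its sign
  neg <- edges[edges$gene1 == "g03" & edges$gene2 == "g04", ]
  expect_lt(neg$weight, -0.8)
})

test_that("mutual information matches a brute-force histogram oracle", {
  set.seed(24)
  x <- rnorm(50); y <- x + rnorm(50, 0, 0.1)
  m <- rbind(gx = x, gy = y, gz = rnorm(50))
  colnames(m) <- sprintf("s%02d", 1:50)
  ds <- expression_dataset(m)
  bins <- 5L
  edges <- mutual_information_edges(ds, rownames(m), threshold = 0,
                                    bins = bins)
  # oracle: discretize by quantile cut, sum p log(p / (px py)), normalize
  # by the smaller marginal entropy
  oracle_nmi <- function(a, b) {
    da <- cut(a, unique(quantile(a, seq(0, 1, length.out = bins + 1))),
              include.lowest = TRUE)
    db <- cut(b, unique(quantile(b, seq(0, 1, length.out = bins + 1))),
              include.lowest = TRUE)
    p <- table(da, db) / length(a)
    px <- rowSums(p); py <- colSums(p)
    mi <- 0
    for (i in seq_along(px)) for (j in seq_along(py))
      if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (px[i] * py[j]))
    h <- function(q) -sum(q[q > 0] * log(q[q > 0]))
    unname(mi / min(h(px), h(py)))
  }
  w <- function(a, b) edges$weight[edges$gene1 == a & edges$gene2 == b]
  expect_equal(w("gx", "gy"), oracle_nmi(x, y), tolerance = 1e-12)
  expect_equal(w("gx", "gz"), oracle_nmi(x, m["gz", ]), tolerance = 1e-12)
})

test_that("normalized mutual information behaves at its extremes", {
  set.seed(25)
  x <- rnorm(400)
  # strictly monotone transform: every bin maps 1-1, NMI exactly 1
  m <- rbind(g1 = x, g2 = exp(x), g3 = rnorm(400))
  colnames(m) <- sprintf("s%03d", 1:400)
  ds <- expression_dataset(m)
  e <- mutual_information_edges(ds, rownames(m), threshold = 0)
  w <- function(a, b) e$weight[e$gene1 == a & e$gene2 == b]
  expect_equal(w("g1", "g2"), 1, tolerance = 1e-12)
  # independent genes: NMI near 0 (finite-sample bias only)
  expect_lt(w("g1", "g3"), 0.25)
  expect_true(all(e$weight >= 0 & e$weight <= 1 + 1e-12))
})

test_that("edge estimators exclude constant genes with a warning", {
  m <- rbind(g1 = rnorm(10, 7), g2 = rep(3, 10), g3 = rnorm(10, 7))
  colnames(m) <- sprintf("s%02d", 1:10)
  ds <- expression_dataset(m)
  expect_warning(ce <- correlation_edges(ds, rownames(m), threshold = 0),
                 "zero-variance.*g2")
  expect_false("g2" %in% c(ce$gene1, ce$gene2))
  expect_warning(me <- mutual_information_edges(ds, rownames(m),
                                                threshold = 0),
                 "constant.*g2")
  expect_false("g2" %in% c(me$gene1, me$gene2))
  expect_error(correlation_edges(ds, "ghost"), "absent.*ghost")
})

test_that("raising a threshold can only remove edges", {
  sim <- simulate_expression(n_classes = 2, n_per_class = 15, n_genes = 100,
                             de_per_class = 10, seed = 26)
  genes <- sim$truth$de_genes$class_A$gene
  lo <- correlation_edges(sim$dataset, genes, threshold = 0.3)
  hi <- correlation_edges(sim$dataset, genes, threshold = 0.8)
  key <- function(d) paste(d$gene1, d$gene2)
  expect_true(all(key(hi) %in% key(lo)))
  mlo <- mutual_information_edges(sim$dataset, genes, threshold = 0.2)
  mhi <- mutual_information_edges(sim$dataset, genes, threshold = 0.5)
  expect_true(all(key(mhi) %in% key(mlo)))
})

test_that("the class network annotates nodes and keeps in-list edges only", {
  sim <- planted_sim()
  rk <- planted_ranking()
  cfg <- marker_config(cv_repeats = 2, seed = 9)
  sel <- forward_select(sim$dataset, rk, cfg)
  clf <- train_classifier(sim$dataset, sel$selected_genes,
                          seed = derive_seed(cfg$seed, "train"))
  dp <- discriminant_power(clf)
  net <- build_network(rk, "class_A", dataset = sim$dataset,
                       selection = sel, dp = dp, top_n = 20)
  expect_s3_class(net, "gene_network")
  expect_lte(nrow(net$nodes), 20)
  expect_identical(net$nodes$gene, genes_for_class(rk, "class_A")[
    seq_len(nrow(net$nodes))])
  expect_true(all(net$edges$gene1 %in% net$nodes$gene))
  expect_true(all(net$edges$gene2 %in% net$nodes$gene))
  expect_true(all(net$nodes$selected_for_classification ==
                    (net$nodes$gene %in% sel$selected_genes$class_A)))
  in_dp <- net$nodes$gene %in% dp$table$gene
  expect_true(all(!is.na(net$nodes$dp[in_dp])))
  # redundancy flag marks exactly the genes touching an edge
  touched <- unique(c(net$edges$gene1, net$edges$gene2))
  expect_identical(net$nodes$redundant, net$nodes$gene %in% touched)
})

test_that("the planted co-regulated block forms a connected correlation component", {
  sim <- planted_sim()
  rk <- planted_ranking()
  blk <- sim$truth$blocks$class_A
  net <- build_network(rk, "class_A", dataset = sim$dataset, top_n = 30)
  in_net <- intersect(blk, net$nodes$gene)
  expect_gte(length(in_net), 2)
  ce <- net$edges[net$edges$type == "correlation", ]
  g <- igraph::graph_from_data_frame(ce[, c("gene1", "gene2")],
                                     directed = FALSE,
                                     vertices = net$nodes$gene)
  comp <- igraph::components(g)$membership
  expect_identical(length(unique(comp[in_net])), 1L)
})

test_that("the quadratic pair is caught by mutual information but not correlation", {
  sim <- planted_sim()
  qp <- sim$truth$quad_pairs$class_A
  expect_lt(abs(cor(sim$dataset$exprs[qp[1], ], sim$dataset$exprs[qp[2], ])),
            0.8)
  me <- mutual_information_edges(sim$dataset, qp, threshold = 0.5)
  expect_identical(nrow(me), 1L)
  expect_gte(me$weight, 0.5)
})

test_that("network exports write valid SIF, GraphML and node tables", {
  sim <- planted_sim()
  rk <- planted_ranking()
  net <- build_network(rk, "class_B", dataset = sim$dataset, top_n = 15)
  sif <- tempfile(fileext = ".sif")
  export_sif(net, sif)
  lines <- readLines(sif)
  expect_identical(length(lines), nrow(net$edges))
  if (length(lines)) {
    parts <- strsplit(lines[1], "\t")[[1]]
    expect_identical(length(parts), 3L)
    expect_true(parts[2] %in% c("correlation", "mutual_information"))
  }
  gml <- tempfile(fileext = ".graphml")
  export_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_true("posterior_prob" %in%
                igraph::vertex_attr_names(g))
  tsv <- tempfile(fileext = ".tsv")
  write_node_attributes(net, tsv)
  back <- read_result_table(tsv)
  expect_identical(back$gene, net$nodes$gene)
})
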