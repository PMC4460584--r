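test_that("training builds one binary machine per class pair and is seed-reproducible", {
  sim <- simulate_expression(n_classes = 4, n_per_class = 6, n_genes = 100,
                             de_per_class = 6, seed = 17)
  genes <- unlist(lapply(sim$truth$de_genes, function(d) d$gene[1:2]),
                  use.names = FALSE)
  clf <- train_classifier(sim$dataset, genes, seed = 3)
  expect_s3_class(clf, "marker_classifier")
  expect_identical(n_machines(clf), 6L)
  expect_identical(clf$classes, sim$dataset$classes)

  p1 <- predict_probabilities(clf, sim$dataset)
  clf2 <- train_classifier(sim$dataset, genes, seed = 3)
  expect_identical(predict_probabilities(clf2, sim$dataset), p1)
  expect_equal(unname(rowSums(p1)), rep(1, ncol(sim$dataset$exprs)),
               tolerance = 1e-9)
})

test_that("a per-class gene list trains on the union and remembers provenance", {
  sim <- simulate_expression(n_classes = 3, n_per_class = 5, n_genes = 80,
                             de_per_class = 5, seed = 18)
  gl <- lapply(sim$truth$de_genes, function(d) d$gene[1:2])
  clf <- train_classifier(sim$dataset, gl, seed = 1)
  expect_setequal(clf$genes, unique(unlist(gl, use.names = FALSE)))
  expect_identical(clf$genes_by_class, gl)
})

test_that("decision values agree with an independent quadratic-programming SVM", {
  # kernlab solves the same linear soft-margin dual with a different
  # optimizer; on a separable 2-class problem both must recover the same
  # decision function up to sign
  ds <- separable_toy(n_per_class = 10, gap = 4, seed = 19)
  genes <- rownames(ds$exprs)
  clf <- train_classifier(ds, genes, cost = 1, seed = 1)
  x <- scale(t(ds$exprs[clf$genes, ]))
  dv <- attr(predict(clf$svm, t(ds$exprs[clf$genes, ]),
                     decision.values = TRUE), "decision.values")[, 1]
  kfit <- kernlab::ksvm(x, ds$labels, kernel = "vanilladot", C = 1,
                        scaled = FALSE, kpar = list())
  kdv <- kernlab::predict(kfit, x, type = "decision")[, 1]
  s <- sign(cor(dv, kdv))
  expect_gt(abs(cor(dv, kdv)), 0.999)
  expect_equal(unname(dv), s * unname(kdv), tolerance = 0.02)
})

test_that("zero-variance genes are dropped with a warning, never silently used", {
  ds <- separable_toy()
  flat <- rbind(ds$exprs, gFLAT = rep(5, ncol(ds$exprs)))
  ds2 <- expression_dataset(flat, setNames(as.character(ds$labels),
                                           colnames(flat)))
  expect_warning(clf <- train_classifier(ds2, c("g01", "gFLAT"), seed = 1),
                 "zero-variance.*gFLAT")
  expect_identical(clf$genes, "g01")
  expect_warning(
    expect_error(train_classifier(ds2, "gFLAT", seed = 1),
                 "no usable genes"),
    "zero-variance")
})

test_that("queries missing model genes are rejected with the gene names", {
  ds <- separable_toy()
  clf <- train_classifier(ds, c("g01", "g02"), seed = 1)
  q <- ds$exprs["g01", , drop = FALSE]
  expect_error(predict_probabilities(clf, q), "missing model genes: g02")
  expect_error(train_classifier(ds, "nope", seed = 1), "absent.*nope")
})

test_that("assignment rule applies both probability and gap conditions exactly", {
  # K = 5: random probability r = 0.2, need p1 >= 0.4 and p1 - p2 > 0.16
  p <- function(...) {
    v <- c(...)
    names(v) <- LETTERS[seq_along(v)]
    v
  }
  expect_identical(assign_class(p(0.50, 0.30, 0.10, 0.06, 0.04)), "A")
  # fails the probability condition
  expect_identical(assign_class(p(0.35, 0.10, 0.25, 0.15, 0.15)),
                   NOT_ASSIGNED)
  # fails the gap condition: 0.45 - 0.35 = 0.10 <= 0.16
  expect_identical(assign_class(p(0.45, 0.35, 0.10, 0.05, 0.05)),
                   NOT_ASSIGNED)
  # boundary: p1 = 0.40 meets the >= condition, gap 0.30 passes
  expect_identical(assign_class(p(0.40, 0.10, 0.20, 0.15, 0.15)), "A")
  # boundary: gap exactly 0.16 fails the strict > condition
  expect_identical(assign_class(p(0.48, 0.32, 0.10, 0.05, 0.05)),
                   NOT_ASSIGNED)
  expect_identical(assign_class(p(0.2, 0.2, 0.2, 0.2, 0.2)), NOT_ASSIGNED)
  # the winner needn't be the first element
  expect_identical(assign_class(p(0.05, 0.60, 0.15, 0.10, 0.10)), "B")
  # factors scale the rule
  expect_identical(assign_class(p(0.30, 0.10, 0.20, 0.20, 0.20),
                                lp_factor = 1, diff_factor = 0.4), "A")
})

test_that("query results carry probabilities, top classes and assignments", {
  ds <- separable_toy(n_per_class = 8)
  clf <- train_classifier(ds, rownames(ds$exprs), seed = 2)
  qr <- predict_query(clf, ds, marker_config())
  expect_s3_class(qr, "query_result")
  expect_identical(qr$sample, colnames(ds$exprs))
  expect_true(all(c("A", "B", "most_likely", "second", "assigned") %in%
                    names(qr)))
  expect_true(all(qr$most_likely != qr$second))
  # assigned is either the most likely class or NOT_ASSIGNED
  expect_true(all(qr$assigned %in% c(qr$most_likely, NOT_ASSIGNED)))
  # clearly separated training samples classify correctly
  expect_identical(qr$most_likely, as.character(ds$labels))
})

test_that("discriminant power identifies each informative gene's class and direction", {
  # 3 classes; one clean marker gene per class, one UP and one DOWN among
  # them, plus noise genes
  set.seed(20)
  n <- 18
  m <- matrix(rnorm(5 * n, 7, 0.4), 5, n,
              dimnames = list(c("up_A", "down_B", "up_C", "noise1", "noise2"),
                              sprintf("s%02d", 1:n)))
  cls <- rep(c("A", "B", "C"), each = 6)
  m["up_A", cls == "A"] <- m["up_A", cls == "A"] + 4
  m["down_B", cls == "B"] <- m["down_B", cls == "B"] - 4
  m["up_C", cls == "C"] <- m["up_C", cls == "C"] + 4
  ds <- expression_dataset(m, setNames(cls, colnames(m)))
  clf <- train_classifier(ds, rownames(m), seed = 4)
  dp <- discriminant_power(clf)
  expect_s3_class(dp, "discriminant_power")
  expect_identical(dim(dp$piles), c(5L, 3L))
  tab <- dp$table
  row_of <- function(g) tab[tab$gene == g, ]
  expect_identical(row_of("up_A")$dp_class, "A")
  expect_identical(row_of("up_A")$direction, "UP")
  expect_gt(row_of("up_A")$dp, 0)
  expect_identical(row_of("down_B")$dp_class, "B")
  expect_identical(row_of("down_B")$direction, "DOWN")
  expect_lt(row_of("down_B")$dp, 0)
  expect_identical(row_of("up_C")$dp_class, "C")
  # marker genes dominate noise genes in |dp|, and the table is sorted
  expect_gt(min(abs(tab$dp[tab$gene %in% c("up_A", "down_B", "up_C")])),
            max(abs(tab$dp[tab$gene %in% c("noise1", "noise2")])))
  expect_identical(tab$dp, tab$dp[order(-abs(tab$dp))])
})

test_that("discriminant power class matches planted origin for most selected genes", {
  sim <- simulate_expression(n_classes = 4, n_per_class = 10, n_genes = 300,
                             de_per_class = 8, effect = 4, block_size = 0,
                             quad_pair = FALSE, seed = 33)
  origin <- do.call(rbind, lapply(names(sim$truth$de_genes), function(k)
    data.frame(gene = sim$truth$de_genes[[k]]$gene, class = k,
               direction = sim$truth$de_genes[[k]]$direction,
               stringsAsFactors = FALSE)))
  gl <- lapply(sim$truth$de_genes, function(d) d$gene[1:4])
  clf <- train_classifier(sim$dataset, gl, seed = 2)
  dp <- discriminant_power(clf)
  m <- merge(dp$table, origin, by = "gene")
  expect_gte(mean(m$dp_class == m$class), 0.9)
  expect_gte(mean(m$direction.x == m$direction.y), 0.9)
})

test_that("two-class discriminant power separates informative from noise genes", {
  ds <- separable_toy(n_per_class = 10, gap = 5, seed = 22)
  clf <- train_classifier(ds, rownames(ds$exprs), seed = 1)
  dp <- discriminant_power(clf)
  expect_identical(dp$table$gene[1], "g01")
  expect_gt(abs(dp$table$dp[1]), max(abs(dp$table$dp[-1])))
})
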