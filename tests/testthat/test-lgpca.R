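test_that("uniform proximity reduces LgPCA to standard PCA", {
  n <- 8
  x <- rand_expr(60, n, seed = 5)
  star <- read_lineage_tree(star_newick(colnames(x)))
  fit <- lgpca(x, star, scale. = FALSE)
  expect_length(fit$eigenvalues, n - 1)

  Xc <- scale(t(x), scale = FALSE)
  sv <- svd(Xc)
  pca_ev <- sv$d[1:(n - 1)]^2 / n          # 1/n covariance convention
  # lambda_k = -lambda^PCA_k / (n-1): all negative, reversed order
  expect_true(all(fit$eigenvalues < 0))
  expect_equal(sort(fit$eigenvalues), sort(-pca_ev / (n - 1)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # axes coincide with PCA axes up to sign
  cosines <- vapply(seq_len(n - 1), function(k)
    max(abs(crossprod(fit$loadings, sv$v[, k]))), numeric(1))
  expect_true(all(cosines > 1 - 1e-8))
})

test_that("duality computation matches direct gene-space eigendecomposition", {
  n <- 10; p <- 40
  x <- rand_expr(p, n, seed = 9)
  tr <- read_lineage_tree(
    "(((s1,s2),(s3,s4,s5)),((s6,s7),(s8,(s9,s10))));")
  W <- abouheif_proximity(tr)
  fit <- lgpca(x, W, scale. = FALSE)

  # independent oracle: direct p x p eigendecomposition
  Xc <- scale(t(x)[rownames(W), ], scale = FALSE)
  Ws <- (W + t(W)) / 2
  H <- t(Xc) %*% Ws %*% Xc / n
  ed <- eigen((H + t(H)) / 2, symmetric = TRUE)
  keep <- abs(ed$values) > 1e-9 * max(abs(ed$values))
  expect_equal(unname(fit$eigenvalues), ed$values[keep], tolerance = 1e-8)
  for (k in seq_along(fit$eigenvalues))
    expect_gt(abs(sum(ed$vectors[, which(keep)[k]] * fit$loadings[, k])),
              1 - 1e-8)
})

test_that("eigen-identity lambda = var x Moran's I holds on random data", {
  for (seed in 1:5) {
    x <- rand_expr(50, 7, seed = seed)
    tr <- read_lineage_tree("(((s1,s2),s3),((s4,s5),(s6,s7)));")
    fit <- lgpca(x, tr, scale. = seed %% 2 == 0)
    expect_equal(fit$eigenvalues, fit$var_scores * fit$moran,
                 tolerance = 1e-10)
    # orthonormal axes; scores H-conjugate across axes
    G <- crossprod(fit$loadings)
    expect_equal(G, diag(ncol(G)), tolerance = 1e-10, ignore_attr = TRUE)
    W <- abouheif_proximity(tr)
    Ws <- (W[rownames(fit$scores), rownames(fit$scores)] +
             t(W[rownames(fit$scores), rownames(fit$scores)])) / 2
    C <- crossprod(fit$scores, Ws %*% fit$scores) / fit$n
    expect_equal(C, diag(fit$eigenvalues), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("label mismatches and degenerate genes are handled", {
  x <- rand_expr(30, 4, seed = 2)
  tr <- read_lineage_tree("((s1,s2),(s3,sX));")
  expect_error(lgpca(x, tr), "only in expression: \\{s4\\}")
  tr4 <- read_lineage_tree("((s1,s2),(s3,s4));")
  x["g1", ] <- 5
  expect_warning(fit <- lgpca(x, tr4, scale. = TRUE), "constant gene")
  expect_equal(unname(fit$loadings["g1", ]), rep(0, ncol(fit$loadings)))
})

test_that("the synthetic atlas yields n - 1 axes and a recoverable module", {
  at <- planted_atlas()
  nm <- quantile_normalize(at$sim$counts)
  fit <- lgpca(nm, at$prox)
  expect_length(fit$eigenvalues, 31)

  part <- partition_axes(fit, 15)
  expect_length(part$global, 15)
  expect_length(part$local, 16)
  expect_error(partition_axes(fit, 40), "between 0 and 31")
  expect_identical(partition_axes(fit, 0)$global, character())

  tips <- clade_tips(at$tree, "foregut")
  ind <- as.numeric(rownames(fit$scores) %in% tips)
  cors <- vapply(part$global, function(ax) stats::cor(fit$scores[, ax], ind),
                 numeric(1))
  best <- part$global[which.max(abs(cors))]
  # the planted clade module surfaces as a positive-eigenvalue (global) axis
  expect_gt(fit$eigenvalues[best], 0)
  # k scaled proportionally to the atlas condition (1000 of 5000 genes)
  ex <- extreme_genes(fit, best, k = 400)
  pole <- if (cors[best] > 0) ex$high else ex$low
  expect_gte(mean(at$sim$truth$gene %in% pole), 0.95)
})

test_that("extreme gene sets are disjoint, sized k, and tie-broken by ID", {
  x <- rand_expr(100, 6, seed = 4)
  fit <- lgpca(x, read_lineage_tree(star_newick(colnames(x))))
  ex <- extreme_genes(fit, 1, k = 40)
  expect_length(ex$high, 40)
  expect_length(ex$low, 40)
  expect_length(intersect(ex$high, ex$low), 0)
  expect_error(extreme_genes(fit, 1, k = 60), "half the gene count")
  expect_error(extreme_genes(fit, "PC99", k = 1), "no such axis")

  # hand-built loadings: k = 1 selects the poles; ties go to the smaller ID
  fit2 <- fit
  fit2$loadings <- matrix(c(0.9, -0.9, 0, 0.9), 4, 1,
                          dimnames = list(c("g1", "g2", "g3", "g0"), "PC1"))
  ex2 <- extreme_genes(fit2, 1, k = 1)
  expect_identical(ex2$high, "g0")   # tie 0.9/0.9 -> lexicographic
  expect_identical(ex2$low, "g2")
})

test_that("gene-set rank-sum test detects extremes and skips small sets", {
  x <- rand_expr(400, 8, seed = 6)
  fit <- lgpca(x, read_lineage_tree(star_newick(colnames(x))))
  top <- extreme_genes(fit, 1, k = 40)$high
  res <- loading_gene_set_test(fit, 1, top)
  expect_identical(res$status, "ok")
  expect_lt(res$p_value, 1e-6)
  expect_identical(res$direction, "high")
  expect_gt(res$rank_biserial, 0.9)

  low <- extreme_genes(fit, 1, k = 40)$low
  expect_identical(loading_gene_set_test(fit, 1, low)$direction, "low")

  skip10 <- loading_gene_set_test(fit, 1, rownames(x)[1:10], min_size = 10)
  expect_identical(skip10$status, "skipped")   # strict > 10 rule
  ok11 <- loading_gene_set_test(fit, 1, rownames(x)[1:11], min_size = 10)
  expect_identical(ok11$status, "ok")
})

test_that("rank-sum p-values are uniform under random sets", {
  x <- rand_expr(500, 8, seed = 8)
  fit <- lgpca(x, read_lineage_tree(star_newick(colnames(x))))
  set.seed(123)
  ps <- replicate(500, loading_gene_set_test(
    fit, 1, sample(rownames(x), 30))$p_value)
  # approximate p-values can tie across draws; the KS check tolerates that
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("projection of the training data reproduces the fitted scores", {
  x <- rand_expr(50, 6, seed = 10)
  fit <- lgpca(x, read_lineage_tree(star_newick(colnames(x))))
  expect_equal(predict(fit, x), fit$scores, tolerance = 1e-10)
  expect_error(predict(fit, x[-1, , drop = FALSE]), "missing")
})

test_that("summary and print expose the axis decomposition", {
  x <- rand_expr(40, 5, seed = 11)
  fit <- lgpca(x, read_lineage_tree(star_newick(colnames(x))))
  s <- summary(fit)
  expect_s3_class(s, "summary.lgpca")
  expect_identical(nrow(s), 4L)
  expect_true(all(s$structure %in% c("global", "local")))
  expect_output(print(fit), "retained axes: 4")
})
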