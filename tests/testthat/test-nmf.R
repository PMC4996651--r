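exact_rank3 <- function(seed = 1) {
  set.seed(seed)
  W0 <- matrix(0, 18, 3); W0[cbind(1:18, rep(1:3, each = 6))] <- runif(18, 1, 2)
  H0 <- matrix(0, 3, 9); H0[cbind(rep(1:3, each = 3), 1:9)] <- runif(9, 1, 2)
  V <- W0 %*% H0
  dimnames(V) <- list(paste0("g", 1:18), paste0("s", 1:9))
  V
}

test_that("KL divergence is monotone non-increasing and reaches an exact factorization", {
  V <- exact_rank3()
  fit <- nmf_brunet(V, 3, max_iter = 5000, seed = 11, stall_checks = Inf)
  expect_lt(utils::tail(fit$kl_trace, 1), 1e-6)
  d <- diff(fit$kl_trace)
  expect_true(all(d <= 1e-9 * (1 + abs(fit$kl_trace[-length(fit$kl_trace)]))))
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))
  expect_equal(fitted(fit), V, tolerance = 1e-3)
})

test_that("KL trace stays monotone on random instances", {
  for (seed in 1:8) {
    set.seed(seed)
    V <- matrix(stats::rpois(15 * 8, 20), 15, 8,
                dimnames = list(paste0("g", 1:15), paste0("s", 1:8)))
    fit <- nmf_brunet(V, 3, max_iter = 150, seed = seed + 100,
                      stall_checks = Inf)
    d <- diff(fit$kl_trace)
    expect_true(all(d <= 1e-9 * (1 + abs(fit$kl_trace[-length(fit$kl_trace)]))))
  }
})

test_that("the factorization is a pure function of its seed", {
  V <- exact_rank3()
  f1 <- nmf_brunet(V, 3, max_iter = 120, seed = 42, stall_checks = Inf)
  f2 <- nmf_brunet(V, 3, max_iter = 120, seed = 42, stall_checks = Inf)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H, f2$H)
  f3 <- nmf_brunet(V, 3, max_iter = 120, seed = 43, stall_checks = Inf)
  expect_false(identical(f1$W, f3$W))
})

test_that("invalid factorization inputs fail with named offenders", {
  V <- exact_rank3()
  expect_error(nmf_brunet(V, 9, seed = 1), "must be < min")
  Vz <- V; Vz["g5", ] <- 0
  expect_error(nmf_brunet(Vz, 3, seed = 1), "all-zero row.*g5")
  expect_error(nmf_brunet(-V, 3, seed = 1), "non-negative")
  expect_error(nmf_brunet(V, 3), "`seed` is mandatory")
})

test_that("consensus rank selection recovers a planted 3-block structure", {
  sim <- simulate_block_counts(seed = 5)
  cons <- consensus_select_rank(sim$counts, ranks = 2:5, runs = 8, seed = 3,
                                max_iter = 300)
  expect_identical(cons$best_rank, 3L)
  expect_gt(cons$cophenetic[["3"]], 0.95)
  C <- cons$consensus[["3"]]
  expect_true(isSymmetric(C))
  expect_equal(unname(diag(C)), rep(1, ncol(C)))
  expect_true(all(C >= 0 & C <= 1))
  expect_error(consensus_select_rank(sim$counts, ranks = 3, runs = 1),
               "at least 2 runs")
})

test_that("noiseless blocks give a 0/1 consensus with cophenetic 1", {
  sim <- simulate_block_counts(background_noise = 0, seed = 1)
  cons <- consensus_select_rank(sim$counts, ranks = 3, runs = 4, seed = 2,
                                max_iter = 300)
  C <- cons$consensus[["3"]]
  expect_true(all(C %in% c(0, 1)))
  expect_equal(cons$cophenetic[["3"]], 1)
  expect_identical(cons$best_rank, 3L)   # single-rank list returns that rank
})

test_that("a single degenerate block flags rank-selection instability", {
  sim <- simulate_block_counts(n_blocks = 1, samples_per_block = 6,
                               background_noise = 0, seed = 1)
  expect_warning(
    cons <- consensus_select_rank(sim$counts + 1, ranks = 2, runs = 3,
                                  seed = 4, max_iter = 200),
    "degenerate")
  expect_false(cons$stable)
})

test_that("basis-contribution gene assignment follows the strict threshold", {
  fit <- structure(list(W = matrix(c(9, 3, 0, 0, 1, 2, 5, 0), 4, 2,
                                   dimnames = list(paste0("g", 1:4),
                                                   c("m1", "m2"))),
                        H = matrix(1, 2, 3), rank = 2),
                   class = "nmf_brunet")
  sets <- metagene_genes(fit, threshold = 0.8)
  expect_identical(sets$m1, "g1")          # 9/10 > 0.8
  expect_identical(sets$m2, "g3")          # 5/5 > 0.8
  expect_false("g2" %in% unlist(sets))     # 0.6 <= 0.8 stays unassigned
  expect_false("g4" %in% unlist(sets))     # all-zero basis row
})

test_that("metagene sets are disjoint for any threshold above 0.5", {
  sim <- simulate_block_counts(seed = 9)
  fit <- nmf_brunet(sim$counts, 3, seed = 13, max_iter = 400)
  for (thr in c(0.55, 0.8, 0.95)) {
    sets <- metagene_genes(fit, thr)
    all_genes <- unlist(sets)
    expect_identical(anyDuplicated(all_genes), 0L)
  }
})

test_that("planted block memberships are recovered with high precision/recall", {
  sim <- simulate_block_counts(seed = 5)
  fit <- nmf_brunet(sim$counts, 3, seed = 9, max_iter = 500)
  sets <- metagene_genes(fit, 0.8)
  truth <- sim$truth$gene_block
  for (k in seq_along(sets)) {
    g <- sets[[k]]
    expect_gt(length(g), 0)
    b <- as.integer(names(which.max(table(truth[g]))))
    expect_gte(mean(truth[g] == b), 0.95)                       # precision
    expect_gte(mean(names(truth)[truth == b] %in% g), 0.95)     # recall
  }
})

test_that("metagene scores rank the matching tissue first", {
  sim <- simulate_block_counts(background_noise = 0, seed = 1)
  fit <- nmf_brunet(sim$counts, 3, seed = 21, max_iter = 400)
  sets <- metagene_genes(fit, 0.8)
  # external sample = pure block-2 profile, 4x elevated
  truth <- sim$truth$gene_block
  prof <- ifelse(truth == 2, 400, 5)
  ext <- matrix(c(prof, rep(10, length(prof))), ncol = 2,
                dimnames = list(names(truth), c("block2_like", "flat")))
  sc <- metagene_score(sets, ext)
  block2_set <- which(vapply(sets, function(g)
    mean(truth[g] == 2) > 0.5, logical(1)))
  expect_identical(unname(which.max(sc[, "block2_like"])),
                   unname(block2_set))
  # uniform expression z-scores to zero
  expect_equal(unname(sc[, "flat"]), rep(0, 3), tolerance = 1e-12)
})

test_that("consensus is equivariant under sample permutation", {
  sim <- simulate_block_counts(background_noise = 0, seed = 5)
  V <- sim$counts
  perm <- c(5, 1, 9, 12, 3, 7, 2, 11, 4, 8, 10, 6)
  c1 <- consensus_select_rank(V, ranks = 3, runs = 4, seed = 6,
                              max_iter = 250)$consensus[["3"]]
  c2 <- consensus_select_rank(V[, perm], ranks = 3, runs = 4, seed = 6,
                              max_iter = 250)$consensus[["3"]]
  labs <- colnames(V)
  expect_equal(c1[labs, labs], c2[labs, labs])
})
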