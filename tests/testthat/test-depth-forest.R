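test_that("chi-square split statistic matches hand values and degenerates to 0", {
  expect_equal(chi_square_stat(5, 5, 5, 5), 0)
  expect_equal(chi_square_stat(10, 0, 0, 10), 20)
  expect_equal(chi_square_stat(0, 0, 7, 3), 0)
  expect_error(chi_square_stat(-1, 0, 1, 1), "non-negative")
})

test_that("chi-square statistic agrees with the Pearson oracle exhaustively", {
  for (a in 0:6) for (b in 0:6) for (c_ in 0:6) for (d in 0:6) {
    if (a + b + c_ + d == 0) next
    expect_equal(chi_square_stat(a, b, c_, d), pearson_oracle(a, b, c_, d),
                 tolerance = 1e-12)
  }
})

test_that("a perfect separator yields a single root split with pure leaves", {
  X <- cbind(noise = rep(1, 20), sep = rep(c(0, 1), each = 10))
  y <- rep(c(0L, 1L), each = 10)
  tr <- grow_chi_tree(X, y, min_node_size = 2)
  expect_equal(nrow(tr), 3)
  expect_equal(tr$split_otu[1], "sep")
  expect_equal(tr$chi_square[1], 20)
  leaves <- tr[is.na(tr$split_otu), ]
  expect_true(all(leaves$n_case %in% c(0, leaves$n_samples)))
})

test_that("stopping rules: node-size floor gives a single leaf", {
  withr::with_seed(3, {
    X <- random_block(30, 4)
    y <- sample(balanced_labels(30))
  })
  tr <- grow_chi_tree(X, y, min_node_size = 30 + 1)
  expect_equal(nrow(tr), 1)
  expect_true(is.na(tr$split_otu[1]))
})

test_that("the root split maximises the chi-square over all (OTU, threshold) pairs", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      X <- random_block(40, 3, presence = 0.7)
      y <- balanced_labels(40)
    })
    oracle <- best_split_oracle(X, y)
    tr <- grow_chi_tree(X, y)
    expect_equal(tr$split_col[1], oracle$otu)
    expect_equal(tr$chi_square[1], oracle$chi, tolerance = 1e-12)
    expect_equal(tr$threshold[1], oracle$thr)
  }
})

test_that("depth importance follows the 2^(-L) G accumulation rule", {
  lone <- tibble::tibble(node_id = 1:3, depth = c(1, 2, 2),
                         split_otu = c("a", NA, NA), split_col = c(1, NA, NA),
                         threshold = c(0.5, NA, NA), chi_square = c(20, 0, 0),
                         n_samples = c(20, 10, 10), n_case = c(10, 10, 0),
                         left = c(2, NA, NA), right = c(3, NA, NA))
  expect_equal(tree_depth_importance(lone, "a"), 10)   # 2^-1 * 20
  expect_equal(tree_depth_importance(lone, "b"), 0)    # never used
  two <- dplyr::bind_rows(lone,
    tibble::tibble(node_id = 4, depth = 2, split_otu = "a", split_col = 1,
                   threshold = 1, chi_square = 4, n_samples = 10, n_case = 5,
                   left = NA, right = NA))
  expect_equal(tree_depth_importance(two, "a"), 11)    # 2^-1*20 + 2^-2*4
})

test_that("depth importance is conserved across features within a tree", {
  withr::with_seed(7, {
    X <- random_block(100, 6)
    y <- sample(balanced_labels(100))
  })
  tr <- grow_chi_tree(X, y, min_node_size = 5)
  per_otu <- vapply(seq_len(ncol(X)), function(j) tree_depth_importance(tr, j),
                    numeric(1))
  internal <- !is.na(tr$split_col)
  expect_equal(sum(per_otu),
               sum(2^(-tr$depth[internal]) * tr$chi_square[internal]))
})

test_that("forest importance equals the single-tree computation when trees coincide", {
  withr::with_seed(11, {
    X <- random_block(60, 5)
    y <- balanced_labels(60)
  })
  # all OTUs in every tree and deterministic splits: every tree is identical
  fp <- forest_params(n_trees = 4, otus_per_tree = 5, seed = 1)
  imp <- forest_importance(X, y, fp)
  tr <- grow_chi_tree(X, y, min_node_size = 10)
  ref <- vapply(seq_len(5), function(j) tree_depth_importance(tr, j),
                numeric(1))
  expect_equal(unname(imp), ref, tolerance = 1e-12)
})

test_that("forest importance is deterministic given the seed", {
  withr::with_seed(12, {
    X <- random_block(80, 10)
    y <- balanced_labels(80)
  })
  fp <- forest_params(n_trees = 20, seed = 42)
  expect_identical(forest_importance(X, y, fp), forest_importance(X, y, fp))
  fp2 <- forest_params(n_trees = 20, seed = 43)
  expect_false(identical(forest_importance(X, y, fp),
                         forest_importance(X, y, fp2)))
})

test_that("an associated OTU outranks permuted noise on average", {
  diffs <- vapply(1:30, function(seed) {
    withr::with_seed(seed, {
      n <- 80
      y <- balanced_labels(n)
      X <- random_block(n, 5)
      X[, 2] <- ifelse(y == 1 & runif(n) < 0.7, rexp(n) + 0.5, 0)  # signal
      X[, 5] <- sample(X[, 2])                                     # permuted
      imp <- forest_importance(X, y, forest_params(n_trees = 20, seed = seed))
      imp[2] - imp[5]
    })
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.8)
})

test_that("ranking is invariant to strictly monotone feature transforms", {
  withr::with_seed(21, {
    X <- random_block(60, 6)
    y <- balanced_labels(60)
  })
  fp <- forest_params(n_trees = 10, seed = 9)
  r1 <- rank_otus(forest_importance(X, y, fp))
  X2 <- X
  X2[, 3] <- log1p(X2[, 3]) * 10
  r2 <- rank_otus(forest_importance(X2, y, fp))
  expect_equal(r1, r2)
})

test_that("rank_otus orders by descending score with index tie-breaks", {
  expect_equal(rank_otus(c(0.2, 0.4, 0.3, 0.6, 0.1)), c(4, 2, 3, 1, 5))
  expect_equal(rank_otus(rep(1, 4)), 1:4)
  expect_equal(rank_otus(c(0.1, 0.3, 0.6)), rev(rank_otus(c(0.6, 0.3, 0.1))))
})

test_that("st_rank_otus returns one ranked row per OTU per block", {
  toy <- toy_cohort()
  rk <- st_rank_otus(toy$table, toy$meta, toy$partition, small_forest())
  expect_equal(nrow(rk), 8)
  expect_setequal(unique(rk$block_id), c("gA", "gB"))
  by_block <- split(rk$rank, rk$block_id)
  expect_true(all(vapply(by_block, function(r) setequal(r, 1:4), logical(1))))
  # the planted marker dominates its block
  expect_equal(rk$otu_id[rk$block_id == "gA" & rk$rank == 1], "otu3")
})
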