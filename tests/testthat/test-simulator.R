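test_that("graph covariances are unit-diagonal and positive definite", {
  for (kind in c("random", "hub", "cluster")) {
    for (seed in 1:50) {
      Om <- withr::with_seed(seed, {
        make_covariance(graph_spec(kind, p = 30, hub_size = 10,
                                   cluster_size = 10, edge_prob = 0.1))
      })
      expect_equal(unname(diag(Om)), rep(1, 30))
      expect_gt(min(eigen(Om, symmetric = TRUE, only.values = TRUE)$values), 0)
    }
  }
})

test_that("an empty random graph gives independent OTUs (identity covariance)", {
  Om <- withr::with_seed(1, {
    make_covariance(graph_spec("random", p = 12, edge_prob = 0))
  })
  expect_equal(Om, diag(12))
})

test_that("cluster covariance is block-diagonal across communities", {
  Om <- withr::with_seed(2, {
    make_covariance(graph_spec("cluster", p = 20, cluster_size = 5))
  })
  for (i in 1:4) for (j in 1:4) {
    blk <- Om[((i - 1) * 5 + 1):(i * 5), ((j - 1) * 5 + 1):(j * 5)]
    if (i != j) expect_equal(unname(blk), matrix(0, 5, 5))
  }
})

test_that("precision-graph mode also returns a valid correlation matrix", {
  Om <- withr::with_seed(3, {
    make_covariance(graph_spec("hub", p = 20, hub_size = 5),
                    graph_on = "precision")
  })
  expect_equal(unname(diag(Om)), rep(1, 20))
  expect_gt(min(eigen(Om, symmetric = TRUE, only.values = TRUE)$values), 0)
})

small_null <- function(n_samples = 100, n_otus = 100, n_blocks = 4, ...) {
  sim_scenario(n_samples = n_samples, n_otus = n_otus, n_blocks = n_blocks,
               graph = graph_spec("random", p = n_otus), ...)
}

test_that("multinomial counts conserve the drawn read depths", {
  dat <- simulate_dataset(small_null(), seed = 1)
  expect_equal(unname(rowSums(dat$counts)), as.numeric(dat$n_reads))
  expect_equal(sum(dat$labels), 50)
})

test_that("read depths follow N(3000, 250) and sparsity sits near 0.6", {
  dat <- simulate_dataset(sim_scenario(n_samples = 200, n_otus = 1000,
                                       n_blocks = 20), seed = 2)
  expect_gt(mean(dat$n_reads), 2900)
  expect_lt(mean(dat$n_reads), 3100)
  zf <- mean(dat$counts == 0)
  expect_gt(zf, 0.5)
  expect_lt(zf, 0.7)
})

test_that("simulation is bit-identical under a fixed seed", {
  d1 <- simulate_dataset(small_null(), seed = 9)
  d2 <- simulate_dataset(small_null(), seed = 9)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$b0, d2$b0)
  d3 <- simulate_dataset(small_null(), seed = 10)
  expect_false(identical(d1$counts, d3$counts))
})

test_that("diagonal covariance yields uncorrelated log-abundances under the null", {
  sc <- sim_scenario(n_samples = 100, n_otus = 50, n_blocks = 2,
                     graph = graph_spec("random", p = 50, edge_prob = 0))
  dat <- simulate_dataset(sc, seed = 4)
  co <- cor(log(dat$alpha))
  expect_lt(abs(mean(co[upper.tri(co)])), 0.02)
})

test_that("null datasets show no systematic case-control presence differences", {
  dat <- simulate_dataset(small_null(n_otus = 200, n_blocks = 4), seed = 5)
  pres <- dat$counts > 0
  ps <- vapply(seq_len(ncol(pres)), function(j) {
    tab <- table(factor(pres[, j], c(FALSE, TRUE)), factor(dat$labels, 0:1))
    if (any(rowSums(tab) == 0)) return(1)
    suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value
  }, numeric(1))
  expect_lt(mean(ps < 0.05, na.rm = TRUE), 0.12)
})

test_that("preset scenarios encode the study designs", {
  sn <- scenario_null()
  expect_equal(sn$n_samples, 800)
  expect_equal(sn$n_otus, 1000)
  expect_equal(sn$n_blocks, 20)
  expect_equal(length(sn$truth_otus), 0)

  sp <- scenario_power("hub")
  expect_equal(sp$graph$kind, "hub")
  expect_equal(sp$truth_blocks, 1:4)
  expect_equal(length(sp$truth_otus), 40)
  blk <- ceiling(sp$truth_otus / sp$block_size)
  expect_equal(unname(table(blk)), rep(10L, 4), ignore_attr = TRUE)

  ss <- scenario_sparsity(5)
  expect_equal(ss$b0_spec$hi_lo, 5)
  expect_warning(scenario_sparsity(9), "outside the studied range")
})

test_that("power effects are drawn from the configured per-dataset mixture", {
  sp <- scenario_power("random")
  dat <- simulate_dataset(sp, seed = 11)
  expect_true(all(dat$b[-sp$truth_otus] == 0))
  expect_true(all(dat$b[sp$truth_otus] >= 0.1))
  expect_true(all(dat$b[sp$truth_otus] <= 5))
  ds <- simulate_dataset(scenario_sparsity(6), seed = 12)
  expect_true(all(ds$b[11:20 * 5 - 4] <= 0))   # block-2 OTUs have negative effects
})

test_that("higher sparsity knob produces more zeros", {
  zf <- sparsity_sweep(a_values = c(4, 8), n_datasets = 1, base_seed = 3,
                       n_samples = 100)
  expect_lt(zf$zero_fraction[1], zf$zero_fraction[2])
})

test_that("tidy accessors expose counts, metadata and partition", {
  dat <- simulate_dataset(small_null(), seed = 1)
  tb <- as_tibble(dat)
  expect_equal(dim(tb), c(100, 101))
  expect_equal(sim_metadata(dat)$label, dat$labels)
  part <- sim_partition(dat)
  expect_equal(nrow(part), 100)
  expect_equal(dplyr::n_distinct(part$block_id), 4)
})
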