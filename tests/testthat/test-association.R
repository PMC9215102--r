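test_that("logistic fit on a saturated binary predictor reproduces the 2x2 OR", {
  # exposed cases 30, exposed controls 10, unexposed cases 20, unexposed 40
  S <- rep(c(1, 1, 0, 0), c(30, 10, 20, 40))
  y <- rep(c(1, 0, 1, 0), c(30, 10, 20, 40))
  fit <- fit_logistic(S, y)
  expect_equal(fit$odds_ratio, 6, tolerance = 1e-6)
  expect_equal(fit$ci95[["low"]], exp(fit$beta - 1.96 * fit$se))
  expect_equal(fit$ci95[["high"]], exp(fit$beta + 1.96 * fit$se))
  expect_equal(unname(fit$n), 100)
  td <- tidy(fit)
  expect_equal(td$odds.ratio, 6, tolerance = 1e-6)
  expect_error(fit_logistic(rep(1, 100), y), "constant")
})

test_that("the fast binary path agrees with glm and flags separation", {
  withr::with_seed(8, {
    S <- rbinom(200, 1, 0.4)
    y <- rbinom(200, 1, plogis(-0.5 + S))
  })
  fast <- supertaxa:::fast_logit_binary(S, y)
  ref <- fit_logistic(S, y)
  expect_equal(fast$beta, ref$beta, tolerance = 1e-5)
  expect_equal(fast$p, ref$pvalue, tolerance = 1e-5)
  # perfect separation -> likelihood-ratio fallback
  sep <- supertaxa:::fast_logit_binary(rep(c(1, 0), each = 10),
                                       rep(c(1, 0), each = 10))
  expect_equal(sep$method, "lrt")
  expect_lt(sep$p, 0.001)
})

test_that("null features give small effects on average", {
  ps <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      y <- balanced_labels(100)
      S <- rbinom(100, 1, 0.5)
    })
    fit_logistic(S, y)$pvalue
  }, numeric(1))
  expect_gt(mean(ps), 0.25)
  expect_gt(mean(ps > 0.05), 0.7)
})

test_that("split_halves stratifies, partitions, and is seed-deterministic", {
  y <- rep(c(0L, 1L), each = 400)
  sp <- split_halves(y, seed = 3)
  expect_equal(length(sp$train), 400)
  expect_equal(sum(y[sp$train]), 200)
  expect_equal(sort(c(sp$train, sp$test)), 1:800)
  expect_identical(sp, split_halves(y, seed = 3))
  expect_false(identical(sp, split_halves(y, seed = 4)))
  expect_error(split_halves(c(0L, 1L, 1L, 1L)), "at least 2")
  # odd class sizes differ by at most one across halves
  y2 <- c(rep(0L, 7), rep(1L, 9))
  sp2 <- split_halves(y2, seed = 1)
  expect_lte(abs(sum(y2[sp2$train] == 0) - sum(y2[sp2$test] == 0)), 1)
})

test_that("a perfect marker block is significant with a large odds ratio", {
  toy <- toy_cohort(n = 80, seed = 6)
  bt <- test_block(toy$table, toy$meta, paste0("otu", 1:4), mode = "STB",
                   params = small_forest(), alpha = 0.05,
                   split = split_halves(toy$meta$label, seed = 2))
  expect_true(bt$significant)
  expect_gt(bt$test$odds_ratio, 5)
  expect_equal(bt$contributing[1], "otu3")
})

test_that("a single-OTU block reduces to a presence test of that OTU", {
  withr::with_seed(13, {
    n <- 100
    y <- balanced_labels(n)
    v <- ifelse(runif(n) < 0.3 + 0.3 * y, rexp(n), 0)
    tab <- supertaxa:::otu_tibble(cbind(solo = v))
    meta <- tibble::tibble(sample_id = paste0("sample_", 1:n), label = y)
  })
  sp <- split_halves(y, seed = 1)
  bt <- test_block(tab, meta, "solo", mode = "STB", params = small_forest(),
                   alpha = 0.05, split = sp)
  ref <- fit_logistic(as.numeric(v[sp$test] > 0), y[sp$test])
  expect_equal(bt$pvalue, ref$pvalue, tolerance = 1e-9)
})

test_that("discovery retains the planted block and is bit-reproducible", {
  toy <- toy_cohort(n = 80, seed = 10)
  rep1 <- run_discovery(toy$table, toy$meta, toy$partition, mode = "STB",
                        n_repeats = 2, retain_threshold = 2,
                        params = small_forest(), alpha = 0.05, base_seed = 3)
  expect_true("gA" %in% rep1$stable$block_id)
  expect_false("gB" %in% rep1$stable$block_id)
  expect_equal(rep1$stable$n_significant[rep1$stable$block_id == "gA"], 2)
  fits <- tidy(rep1)
  expect_true(all(c("odds_ratio", "aic", "contributing_otus") %in% names(fits)))
  rep2 <- run_discovery(toy$table, toy$meta, toy$partition, mode = "STB",
                        n_repeats = 2, retain_threshold = 2,
                        params = small_forest(), alpha = 0.05, base_seed = 3)
  expect_identical(rep1$repeats, rep2$repeats)
  expect_identical(tidy(rep1), tidy(rep2))
})

test_that("identity-mapped self-verification reproduces the full-cohort fit", {
  toy <- toy_cohort(n = 80, seed = 10)
  rep1 <- run_discovery(toy$table, toy$meta, toy$partition, mode = "STC",
                        n_repeats = 2, retain_threshold = 1,
                        params = small_forest(), alpha = 0.1, base_seed = 3)
  expect_gt(nrow(rep1$stable), 0)
  ver <- verify_supertaxa(rep1, toy$table, toy$meta, mapping = NULL)
  joined <- dplyr::inner_join(rep1$full_fits, ver, by = "block_id",
                              suffix = c("_d", "_v"))
  expect_equal(joined$pvalue_v, joined$pvalue_d, tolerance = 1e-9)
  expect_equal(joined$odds_ratio_v, joined$odds_ratio_d, tolerance = 1e-9)
})

test_that("verification translates OTUs via best identity and flags gaps", {
  toy <- toy_cohort(n = 80, seed = 10)
  rep1 <- run_discovery(toy$table, toy$meta, toy$partition, mode = "STB",
                        n_repeats = 2, retain_threshold = 1,
                        params = small_forest(), alpha = 0.05, base_seed = 3)
  contributing <- unique(unlist(strsplit(rep1$full_fits$contributing_otus, ",")))
  # rename the verification columns; keep a decoy lower-identity match
  vt <- toy$table
  names(vt) <- sub("^otu", "v", names(vt))
  mapping <- tibble::tibble(
    discovery_otu_id = rep(contributing, each = 2),
    verification_otu_id = c(rbind(sub("^otu", "v", contributing),
                                  rep("v1", length(contributing)))),
    identity_score = rep(c(99, 50), length(contributing)))
  ver <- verify_supertaxa(rep1, vt, toy$meta, mapping)
  expect_equal(nrow(ver), nrow(rep1$stable))
  expect_true(all(grepl("^v", unlist(strsplit(ver$verification_otus, ",")))))
  bad <- mapping[mapping$discovery_otu_id != contributing[1], ]
  expect_error(verify_supertaxa(rep1, vt, toy$meta, bad), "unmapped")
  # empty stable set: vacuous verification
  rep_none <- rep1
  rep_none$stable <- rep1$stable[0, ]
  expect_equal(nrow(suppressMessages(
    verify_supertaxa(rep_none, vt, toy$meta, mapping))), 0)
})

test_that("verification alpha defaults to 0.05 over the stable-block count", {
  toy <- toy_cohort(n = 80, seed = 10)
  rep1 <- run_discovery(toy$table, toy$meta, toy$partition, mode = "STC",
                        n_repeats = 2, retain_threshold = 1,
                        params = small_forest(), alpha = 0.5, base_seed = 3)
  expect_equal(nrow(rep1$stable), 2)   # both blocks pass at this loose level
  ver <- verify_supertaxa(rep1, toy$table, toy$meta)
  # significance recomputed at 0.05/2 = 0.025
  expect_equal(ver$significant, ver$pvalue < 0.025)
})

test_that("AIC comparison favours a true joint effect and keeps its shape", {
  withr::with_seed(17, {
    n <- 300
    y <- balanced_labels(n)
    v1 <- ifelse(runif(n) < 0.15 + 0.35 * y, rexp(n) + 0.3, 0)
    v2 <- ifelse(runif(n) < 0.15 + 0.35 * y, rexp(n) + 0.3, 0)
    tab <- supertaxa:::otu_tibble(cbind(u = v1, w = v2))
    meta <- tibble::tibble(sample_id = paste0("sample_", 1:n), label = y)
  })
  x <- compute_exposure(cbind(v1, v2), 1:2)
  st <- stb_feature(x, 3, J_g = 2, features = cbind(u = v1, w = v2),
                    ranking = 1:2)
  cmp <- compare_aic(tab, meta, st)
  expect_equal(nrow(cmp), 3)
  expect_equal(cmp$model, c("supertaxon", "u", "w"))
  expect_lt(cmp$aic[1], min(cmp$aic[2:3]))
  # a super-taxon identical to its single member has the same AIC
  x1 <- compute_exposure(cbind(v1, v1), 1:2)
  st1 <- stb_feature(x1, 3, J_g = 2, features = cbind(u = v1, u2 = v1),
                     ranking = 1:2)
  cmp1 <- compare_aic(supertaxa:::otu_tibble(cbind(u = v1, u2 = v1)), meta, st1)
  expect_equal(cmp1$aic[1], cmp1$aic[2], tolerance = 1e-8)
})
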