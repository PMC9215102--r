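# Programmatic fixtures shared across the test files.

# Sparse abundance block: n samples x J OTUs, exponential abundances thinned
# to the requested presence probability.
random_block <- function(n, J, presence = 0.4) {
  matrix(rexp(n * J) * (runif(n * J) < presence), n, J,
         dimnames = list(paste0("s", seq_len(n)), paste0("otu", seq_len(J))))
}

balanced_labels <- function(n) rep(c(0L, 1L), length.out = n)

# Independent Pearson oracle for a single 2x2 table.
pearson_oracle <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(0)
  unname(suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic)
}

# Exhaustive (OTU, threshold) chi-square scan: the brute-force oracle for
# the root split of a tree.
best_split_oracle <- function(X, y) {
  best <- list(chi = 0, otu = NA, thr = NA)
  for (j in seq_len(ncol(X))) {
    v <- sort(unique(X[, j]))
    if (length(v) < 2) next
    thr <- head(v, -1) + diff(v) / 2
    for (tt in thr) {
      right <- X[, j] > tt
      chi <- pearson_oracle(sum(!right & y == 1), sum(!right & y == 0),
                            sum(right & y == 1), sum(right & y == 0))
      if (chi > best$chi) best <- list(chi = chi, otu = j, thr = tt)
    }
  }
  best
}

# Two-cohort toy data with one block carrying a near-perfect marker OTU;
# synthetic stand-in for a discovery/verification cohort pair.
toy_cohort <- function(n = 60, seed = 5, flip = 0) {
  withr::with_seed(seed, {
    y <- balanced_labels(n)
    X <- matrix(rexp(n * 8) * (runif(n * 8) < 0.3), n, 8)
    marker <- ifelse(y == 1, rexp(n, 1) + 0.5, 0)
    noisy <- sample(which(y == 1), flip)
    marker[noisy] <- 0
    X[, 3] <- marker
    X[, 4] <- ifelse(y == 1 & runif(n) < 0.6, rexp(n) + 0.2, X[, 4])
    colnames(X) <- paste0("otu", 1:8)
    rownames(X) <- paste0("s", seq_len(n))
    list(table = supertaxa:::otu_tibble(X),
         meta = tibble::tibble(sample_id = rownames(X), label = y),
         partition = tibble::tibble(
           block_id = rep(c("gA", "gB"), each = 4),
           otu_id = colnames(X)))
  })
}

small_forest <- function(...) forest_params(n_trees = 10, seed = 1, ...)

# Exhaustive cutoff-scan oracle: every observed exposure value refitted with
# plain glm(), honouring the same statistical contract as the search (Wald p,
# likelihood-ratio fallback on separation).
cutoff_scan_oracle <- function(V, d, y, mode) {
  x <- compute_exposure(V, d)
  purrr::map_dfr(sort(unique(x)), function(cc) {
    S <- if (mode == "STB") as.numeric(x < cc)
         else supertaxa:::build_feature(V, d, cc, "STC")$S
    if (length(unique(S)) < 2)
      return(tibble::tibble(cutoff = cc, p = NA_real_))
    fit <- suppressWarnings(glm(y ~ S, family = binomial()))
    co <- summary(fit)$coefficients["S", ]
    separated <- !fit$converged || abs(co["Estimate"]) > 15 ||
      co["Std. Error"] > 100 ||
      (mode == "STB" && any(table(S, y) == 0))
    p <- if (separated) {
      fit0 <- suppressWarnings(glm(y ~ 1, family = binomial()))
      as.numeric(stats::anova(fit0, fit, test = "Chisq")[2, "Pr(>Chi)"])
    } else co["Pr(>|z|)"]
    tibble::tibble(cutoff = cc, p = unname(p))
  })
}
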