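#' Graph specification for the OTU covariance
#'
#' Describes the graph whose edges carry the dependence among OTU
#' log-abundances. Three structures are supported: `random` (independent
#' Bernoulli edges), `hub` (consecutive groups whose members all connect to
#' one hub node), and `cluster` (disjoint fully-connected communities).
#'
#' @param kind `"random"`, `"hub"` or `"cluster"`.
#' @param p Number of OTUs (dimension).
#' @param edge_prob Edge probability for the random graph (default 0.02).
#' @param hub_size Group size for the hub graph (default 50; the first node
#'   of each consecutive group is its hub).
#' @param cluster_size Community size for the cluster graph (default 50).
#' @param weight_range Absolute edge weights are drawn uniformly from this
#'   interval (default `c(0.2, 0.5)`) with a random sign.
#' @return A list of class `graph_spec`.
#' @export
graph_spec <- function(kind = c("random", "hub", "cluster"), p,
                       edge_prob = 0.02, hub_size = 50, cluster_size = 50,
                       weight_range = c(0.2, 0.5)) {
  kind <- match.arg(kind)
  stopifnot(p >= 2)
  structure(list(kind = kind, p = as.integer(p), edge_prob = edge_prob,
                 hub_size = as.integer(hub_size),
                 cluster_size = as.integer(cluster_size),
                 weight_range = weight_range),
            class = "graph_spec")
}

#' Build a positive-definite graph-structured covariance
#'
#' Draws signed uniform weights on the edges of the specified graph, loads
#' the diagonal just past the most negative eigenvalue to force positive
#' definiteness, and standardises the result to unit diagonal (a correlation
#' matrix), so the marginal variance of each OTU's log-abundance is 1 and
#' the graph only shapes the dependence. With `graph_on = "precision"` the
#' loaded matrix is inverted first, so the graph structures the conditional
#' (Markov) dependence instead of the covariance.
#'
#' @param spec A [graph_spec()].
#' @param graph_on `"covariance"` (default) or `"precision"`.
#' @return A symmetric positive-definite `p x p` matrix with unit diagonal.
#' @export
make_covariance <- function(spec, graph_on = c("covariance", "precision")) {
  stopifnot(inherits(spec, "graph_spec"))
  graph_on <- match.arg(graph_on)
  p <- spec$p
  W <- matrix(0, p, p)
  edges <- switch(spec$kind,
    random = {
      ut <- which(upper.tri(W))
      ut[runif(length(ut)) < spec$edge_prob]
    },
    hub = {
      grp <- split(seq_len(p), ceiling(seq_len(p) / spec$hub_size))
      unlist(lapply(grp, function(g) {
        hub <- g[1]
        if (length(g) < 2) return(integer(0))
        (g[-1] - 1L) * p + hub      # upper-triangle cells (hub, member)
      }))
    },
    cluster = {
      grp <- split(seq_len(p), ceiling(seq_len(p) / spec$cluster_size))
      unlist(lapply(grp, function(g) {
        if (length(g) < 2) return(integer(0))
        pairs <- utils::combn(g, 2)
        (pairs[2, ] - 1L) * p + pairs[1, ]
      }))
    })
  if (length(edges) > 0) {
    w <- runif(length(edges), spec$weight_range[1], spec$weight_range[2]) *
      sample(c(-1, 1), length(edges), replace = TRUE)
    W[edges] <- w
    W <- W + t(W)
  }
  lam_min <- min(eigen(W, symmetric = TRUE, only.values = TRUE)$values)
  A <- W + diag(max(0, -lam_min) + 0.05, p)
  if (graph_on == "precision") A <- solve(A)
  Om <- stats::cov2cor(A)
  # guard against a numerically non-PD result (must not trigger)
  if (min(eigen(Om, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("internal error: covariance not positive definite", call. = FALSE)
  Om
}

# Effect/intercept mixture specifications ------------------------------------

# B0 mixture: U(hi_lo, hi_lo + 2) with prob p_hi, else U(2, 4).
b0_mixture <- function(hi_lo = 6, p_hi = 0.2) {
  list(hi_lo = hi_lo, p_hi = p_hi)
}

draw_b0 <- function(spec, p) {
  hi <- runif(p) < spec$p_hi
  ifelse(hi, runif(p, spec$hi_lo, spec$hi_lo + 2), runif(p, 2, 4))
}

# B specification: either a fixed numeric vector of length p, or a list of
# per-OTU uniform ranges for the truth set (drawn once per dataset).
draw_b <- function(b_spec, p) {
  if (is.numeric(b_spec)) {
    stopifnot(length(b_spec) %in% c(1L, p))
    return(rep_len(b_spec, p))
  }
  B <- numeric(p)
  for (blk in b_spec) {
    idx <- blk$otus
    if (!is.null(blk$mixture)) {
      pick <- runif(length(idx)) < 0.5
      B[idx] <- ifelse(pick,
                       runif(length(idx), blk$mixture[[1]][1], blk$mixture[[1]][2]),
                       runif(length(idx), blk$mixture[[2]][1], blk$mixture[[2]][2]))
    } else {
      B[idx] <- runif(length(idx), blk$range[1], blk$range[2])
    }
  }
  B
}

#' Simulation scenario for the Dirichlet-multinomial generator
#'
#' Full parameterisation of the case-control generative model
#' \deqn{n_i \sim N(3000, 250), \quad
#'       X_i \sim \mathrm{Multinomial}(n_i, h_i), \quad
#'       h_i \sim \mathrm{Dirichlet}(\alpha_i), \quad
#'       \log(\alpha_i) \sim \mathrm{MVN}(Y_i B + B_0, \Omega)}
#' with N(3000, 250) read as mean 3000, standard deviation 250. Half the
#' samples are controls (Y = 0), half cases (Y = 1). The OTU-level intercept
#' `B_0` is drawn once per dataset from a two-component uniform mixture, and
#' effect sizes `B` are either a fixed vector or drawn per dataset from the
#' scenario's per-block ranges.
#'
#' @param n_samples Total samples N (even; default 800).
#' @param n_otus Number of OTUs p (default 1000).
#' @param n_blocks Number of equal-sized blocks (default 20).
#' @param b_spec Effect specification: numeric vector (length 1 or p) or a
#'   list of per-block ranges (see [scenario_power()]).
#' @param b0_spec Intercept mixture from `b0_mixture()`.
#' @param graph A [graph_spec()].
#' @param total_count_mean,total_count_sd Per-sample read-depth distribution
#'   (defaults 3000 and 250).
#' @param truth_otus,truth_blocks Indices of truly associated OTUs/blocks.
#' @param seed Optional default seed for [simulate_dataset()].
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_samples = 800, n_otus = 1000, n_blocks = 20,
                         b_spec = 0, b0_spec = b0_mixture(),
                         graph = graph_spec("random", p = n_otus),
                         total_count_mean = 3000, total_count_sd = 250,
                         truth_otus = integer(0), truth_blocks = integer(0),
                         seed = NULL) {
  stopifnot(n_samples %% 2 == 0, n_otus %% n_blocks == 0)
  structure(list(n_samples = as.integer(n_samples),
                 n_otus = as.integer(n_otus), n_blocks = as.integer(n_blocks),
                 block_size = as.integer(n_otus / n_blocks), b_spec = b_spec,
                 b0_spec = b0_spec, graph = graph,
                 total_count_mean = total_count_mean,
                 total_count_sd = total_count_sd,
                 truth_otus = as.integer(truth_otus),
                 truth_blocks = as.integer(truth_blocks), seed = seed),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("Simulation scenario: N = %d, %d OTUs in %d blocks of %d (%s graph)\n",
              x$n_samples, x$n_otus, x$n_blocks, x$block_size, x$graph$kind))
  cat(sprintf("  true OTUs: %d in blocks {%s}\n", length(x$truth_otus),
              paste(x$truth_blocks, collapse = ", ")))
  invisible(x)
}

# evenly spaced positions of the 10 true OTUs inside each of blocks 1..4
power_truth_otus <- function(block_size = 50, n_true_blocks = 4,
                             per_block = 10) {
  unlist(lapply(seq_len(n_true_blocks) - 1L, function(b) {
    b * block_size + seq(1L, block_size, by = block_size %/% per_block)
  }))
}

#' Preset scenarios: null, power, and sparsity sweep
#'
#' `scenario_null()` sets every effect to zero (global null, used for
#' family-wise error rate). `scenario_power()` plants 40 associated OTUs,
#' 10 evenly spaced in each of the first 4 blocks, with effects drawn per
#' dataset from the mixture U(0.5, 1) w.p. 0.5 / U(0.1, 5) w.p. 0.5.
#' `scenario_sparsity(a)` uses per-block effect ranges U(0.1, 0.5),
#' U(-0.5, -0.1), U(0.5, 1), U(-1, -0.5) for blocks 1-4 and shifts the
#' high-abundance intercept component to U(a, a + 2), so the expected zero
#' fraction rises from about 0.4 at `a = 4` to about 0.8 at `a = 8`.
#'
#' @param graph_kind `"random"`, `"hub"` or `"cluster"`.
#' @param a Sparsity knob in the studied range 4..8 (values outside warn).
#' @param ... Passed on to [sim_scenario()] (e.g. `n_samples`, `seed`).
#' @return A `sim_scenario`.
#' @export
scenario_null <- function(graph_kind = "random", ...) {
  args <- list(...)
  n_otus <- args$n_otus %||% 1000
  sim_scenario(b_spec = 0, graph = graph_spec(graph_kind, p = n_otus), ...)
}

#' @rdname scenario_null
#' @export
scenario_power <- function(graph_kind = c("random", "hub", "cluster"), ...) {
  graph_kind <- match.arg(graph_kind)
  args <- list(...)
  n_otus <- args$n_otus %||% 1000
  n_blocks <- args$n_blocks %||% 20
  block_size <- n_otus / n_blocks
  truth <- power_truth_otus(block_size = block_size)
  b_spec <- list(list(otus = truth,
                      mixture = list(c(0.5, 1), c(0.1, 5))))
  sim_scenario(b_spec = b_spec, graph = graph_spec(graph_kind, p = n_otus),
               truth_otus = truth, truth_blocks = 1:4, ...)
}

#' @rdname scenario_null
#' @export
scenario_sparsity <- function(a, ...) {
  if (a < 4 || a > 8)
    warning("sparsity knob a = ", a, " is outside the studied range [4, 8]")
  args <- list(...)
  n_otus <- args$n_otus %||% 1000
  n_blocks <- args$n_blocks %||% 20
  block_size <- n_otus / n_blocks
  per <- split(power_truth_otus(block_size = block_size), rep(1:4, each = 10))
  ranges <- list(c(0.1, 0.5), c(-0.5, -0.1), c(0.5, 1), c(-1, -0.5))
  b_spec <- purrr::map2(per, ranges, function(otus, rg)
    list(otus = otus, range = rg))
  sim_scenario(b_spec = b_spec, b0_spec = b0_mixture(hi_lo = a),
               graph = graph_spec("random", p = n_otus),
               truth_otus = unlist(per), truth_blocks = 1:4, ...)
}

#' Simulate a case-control OTU count dataset
#'
#' Draws one dataset from the scenario's Dirichlet-multinomial model:
#' `B_0` (and, for preset scenarios, `B`) once per dataset; per sample the
#' log concentration `log(alpha_i) = Y_i B + B_0 + MVN(0, Omega)` draw,
#' relative abundances `h_i ~ Dirichlet(exp(log alpha_i))`, the read depth
#' `n_i ~ N(3000, 250)` rounded and clipped at 1, and counts
#' `X_i ~ Multinomial(n_i, h_i)`.
#'
#' @param scenario A [sim_scenario()].
#' @param seed Integer seed (defaults to `scenario$seed`); the same seed
#'   reproduces the dataset bit for bit. `NULL` uses the ambient RNG.
#' @return A list of class `sim_data`: `counts` (N x p integer matrix with
#'   sample/OTU dimnames), `labels` (0/1), `n_reads`, `alpha`, `h`, `omega`,
#'   `b`, `b0`, `truth_otus`, `truth_blocks`, `scenario`.
#' @export
simulate_dataset <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "sim_scenario"))
  with_seed_or_ambient(seed, {
    N <- scenario$n_samples; p <- scenario$n_otus
    Y <- rep(c(0L, 1L), each = N / 2)
    Om <- make_covariance(scenario$graph)
    B0 <- draw_b0(scenario$b0_spec, p)
    B <- draw_b(scenario$b_spec, p)
    R <- chol(Om)
    Z <- matrix(rnorm(N * p), N, p) %*% R
    log_alpha <- Z + outer(Y, B) + matrix(B0, N, p, byrow = TRUE)
    alpha <- exp(log_alpha)
    g <- matrix(rgamma(N * p, shape = alpha), N, p)
    # a gamma draw with tiny shape can underflow to 0; h only needs ratios
    h <- g / pmax(rowSums(g), .Machine$double.xmin)
    n_reads <- pmax(1L, as.integer(round(rnorm(N, scenario$total_count_mean,
                                               scenario$total_count_sd))))
    X <- matrix(0L, N, p)
    for (i in seq_len(N)) X[i, ] <- rmultinom(1, n_reads[i], h[i, ])
    dimnames(X) <- list(paste0("sample_", seq_len(N)),
                        sprintf("otu_%04d", seq_len(p)))
    structure(list(counts = X, labels = Y, n_reads = n_reads, alpha = alpha,
                   h = h, omega = Om, b = B, b0 = B0,
                   truth_otus = scenario$truth_otus,
                   truth_blocks = scenario$truth_blocks, scenario = scenario),
              class = "sim_data")
  })
}

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf("Simulated dataset: %d samples x %d OTUs, zero fraction %.3f\n",
              nrow(x$counts), ncol(x$counts), mean(x$counts == 0)))
  invisible(x)
}

#' Tidy accessors for a simulated dataset
#' @param x A `sim_data` object.
#' @param ... Unused.
#' @return `as_tibble()`: the counts as a sample-by-OTU tibble;
#'   `sim_metadata()`: a `(sample_id, label)` tibble;
#'   `sim_partition()`: the block partition tibble.
#' @export
as_tibble.sim_data <- function(x, ...) otu_tibble(x$counts)

#' @rdname as_tibble.sim_data
#' @export
sim_metadata <- function(x) {
  tibble::tibble(sample_id = rownames(x$counts), label = x$labels)
}

#' @rdname as_tibble.sim_data
#' @export
sim_partition <- function(x) {
  sc <- x$scenario
  tibble::tibble(
    block_id = sprintf("block_%02d", rep(seq_len(sc$n_blocks),
                                         each = sc$block_size)),
    otu_id = colnames(x$counts))
}
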