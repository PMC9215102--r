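#' Pearson chi-square statistic of a 2x2 split-by-label table
#'
#' The split statistic used at every node of the chi-square trees: the
#' Pearson independence statistic, without continuity correction, of the
#' table formed by split side (left/right of a threshold) and case/control
#' label. Returns 0 when any margin is 0.
#'
#' @param left_case,left_ctrl,right_case,right_ctrl Cell counts.
#' @return The chi-square statistic (a non-negative scalar); vectorised over
#'   the four arguments.
#' @examples
#' chi_square_stat(10, 0, 0, 10)  # 20
#' chi_square_stat(5, 5, 5, 5)    # 0
#' @export
chi_square_stat <- function(left_case, left_ctrl, right_case, right_ctrl) {
  n <- length(left_case)
  if (n == 1)
    return(cpp_chi_square(left_case, left_ctrl, right_case, right_ctrl))
  mapply(cpp_chi_square, left_case, left_ctrl, right_case, right_ctrl)
}

#' Forest parameters
#'
#' @param n_trees Number of trees per forest (default 100).
#' @param otus_per_tree Number of OTUs sampled (without replacement) per tree;
#'   a fraction in (0, 1] is resolved against the block size. Default
#'   `NULL` = ceiling(J_g / 2).
#' @param min_node_size Nodes with fewer samples are not split (default 10).
#' @param max_depth Maximum node depth (root = 1); `Inf` (default) grows
#'   unpruned trees to purity or the node-size floor.
#' @param seed Optional integer; when set, feature-subset sampling is run
#'   under this seed and the caller's RNG state is untouched.
#' @param bootstrap Draw a bootstrap resample of samples per tree (off by
#'   default: only feature subsetting randomises trees).
#' @param binarize Pre-binarise abundances at zero before tree growth
#'   (off by default: trees split continuous abundances directly).
#' @return A list of class `forest_params`.
#' @export
forest_params <- function(n_trees = 100, otus_per_tree = NULL,
                          min_node_size = 10, max_depth = Inf, seed = NULL,
                          bootstrap = FALSE, binarize = FALSE) {
  stopifnot(n_trees >= 1, min_node_size >= 2)
  structure(list(n_trees = as.integer(n_trees), otus_per_tree = otus_per_tree,
                 min_node_size = as.integer(min_node_size),
                 max_depth = max_depth, seed = seed, bootstrap = bootstrap,
                 binarize = binarize),
            class = "forest_params")
}

resolve_m_try <- function(otus_per_tree, p) {
  if (is.null(otus_per_tree)) return(max(1L, as.integer(ceiling(p / 2))))
  if (otus_per_tree > 0 && otus_per_tree <= 1 && otus_per_tree != as.integer(otus_per_tree))
    return(max(1L, as.integer(ceiling(otus_per_tree * p))))
  m <- as.integer(otus_per_tree)
  if (m < 1 || m > p) stop("otus_per_tree out of range", call. = FALSE)
  m
}

resolve_max_depth <- function(max_depth) {
  if (is.infinite(max_depth)) 0L else as.integer(max_depth)
}

#' Grow a single unpruned chi-square classification tree
#'
#' At every node the split maximising [chi_square_stat()] over all candidate
#' OTUs and all midpoint thresholds between consecutive distinct observed
#' values is chosen (ties: smaller OTU column, then smaller threshold).
#' Splitting stops at class purity, the node-size floor, the depth cap, or
#' when no split has a positive statistic.
#'
#' @param features Numeric sample-by-OTU matrix (a block's sub-matrix).
#' @param labels 0/1 vector with both classes present.
#' @param otus Columns available to the tree (indices or names); defaults to
#'   all.
#' @param min_node_size,max_depth See [forest_params()].
#' @return A tibble of nodes: `node_id`, `depth` (root = 1), `split_otu`
#'   (column name, `NA` for leaves), `split_col`, `threshold`, `chi_square`
#'   (the chosen split's statistic G_t), `n_samples`, `n_case`, `left`,
#'   `right` (child `node_id`s).
#' @export
grow_chi_tree <- function(features, labels, otus = NULL, min_node_size = 10,
                          max_depth = Inf) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- check_binary_labels(labels)
  if (is.null(otus)) otus <- seq_len(ncol(features))
  if (is.character(otus)) otus <- match(otus, colnames(features))
  nodes <- cpp_grow_tree(features, labels, as.integer(otus),
                         as.integer(min_node_size),
                         resolve_max_depth(max_depth))
  out <- tibble::as_tibble(nodes)
  out$node_id <- seq_len(nrow(out))
  out$split_otu <- if (is.null(colnames(features))) {
    as.character(out$split_col)
  } else {
    colnames(features)[out$split_col]
  }
  dplyr::select(out, "node_id", "depth", "split_otu", "split_col",
                "threshold", "chi_square", "n_samples", "n_case",
                "left", "right")
}

#' Depth importance of one OTU in one tree
#'
#' Sums \eqn{2^{-L_t} G_t} over the internal nodes split by the OTU, where
#' \eqn{L_t} is the node depth (root = 1) and \eqn{G_t} the node's chi-square
#' split statistic. An OTU never used contributes 0.
#'
#' @param tree Node tibble from [grow_chi_tree()].
#' @param otu Column index or name.
#' @return A non-negative scalar.
#' @export
tree_depth_importance <- function(tree, otu) {
  hit <- if (is.character(otu)) {
    !is.na(tree$split_otu) & tree$split_otu == otu
  } else {
    !is.na(tree$split_col) & tree$split_col == otu
  }
  sum(2^(-tree$depth[hit]) * tree$chi_square[hit])
}

#' Forest depth-importance scores for a block of OTUs
#'
#' Grows `n_trees` unpruned chi-square trees, each on a random OTU subset,
#' and averages each OTU's per-tree depth importance over all trees in the
#' forest.
#'
#' @param features Numeric sample-by-OTU matrix (one block).
#' @param labels 0/1 vector with both classes.
#' @param params [forest_params()].
#' @return Named numeric vector of scores \eqn{V_f}, one per column of
#'   `features`; deterministic given `params$seed`.
#' @export
forest_importance <- function(features, labels, params = forest_params()) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- check_binary_labels(labels)
  p <- ncol(features)
  if (p == 0) stop("empty feature matrix", call. = FALSE)
  m_try <- resolve_m_try(params$otus_per_tree, p)
  X <- if (isTRUE(params$binarize)) (features > 0) + 0 else features

  imp <- with_seed_or_ambient(params$seed, {
    subsets <- t(vapply(seq_len(params$n_trees),
                        function(i) sort(sample.int(p, m_try)),
                        integer(m_try)))
    if (isTRUE(params$bootstrap)) {
      tot <- numeric(p)
      for (t in seq_len(params$n_trees)) {
        repeat {
          rows <- sample.int(nrow(X), replace = TRUE)
          if (length(unique(labels[rows])) == 2L) break
        }
        tot <- tot + cpp_forest_importance(
          X[rows, , drop = FALSE], labels[rows],
          matrix(subsets[t, ], nrow = 1),
          params$min_node_size, resolve_max_depth(params$max_depth))
      }
      tot / params$n_trees
    } else {
      cpp_forest_importance(X, labels, subsets, params$min_node_size,
                            resolve_max_depth(params$max_depth))
    }
  })
  setNames(as.numeric(imp), colnames(features))
}

#' Rank OTUs by descending depth-importance score
#'
#' @param scores Numeric vector of importance scores (one per OTU in the
#'   block).
#' @return Integer permutation `d_g`: position `j` holds the index of the
#'   OTU with the j-th largest score; ties broken by ascending OTU index.
#' @examples
#' rank_otus(c(0.2, 0.4, 0.3, 0.6, 0.1))  # 4 2 3 1 5
#' @export
rank_otus <- function(scores) {
  order(-as.numeric(scores), seq_along(scores))
}

#' Rank the OTUs of every block of a partitioned table
#'
#' Tidy front end over [forest_importance()] and [rank_otus()]: one forest
#' per block, scores and ranks for every OTU.
#'
#' @param table Sample-by-OTU tibble (or matrix).
#' @param meta Metadata tibble (`sample_id`, `label`).
#' @param partition Block partition tibble (`block_id`, `otu_id`).
#' @param params [forest_params()]; when `params$seed` is set, block `k` uses
#'   seed `params$seed + k` so results are reproducible end to end.
#' @return Tibble `block_id`, `otu_id`, `score`, `rank`.
#' @export
st_rank_otus <- function(table, meta, partition, params = forest_params()) {
  m <- otu_matrix(table)
  al <- align_meta(meta, rownames(m))
  blocks <- split(partition$otu_id, partition$block_id)
  purrr::imap_dfr(blocks, function(otus, bid) {
    k <- match(bid, names(blocks))
    pars <- params
    if (!is.null(pars$seed)) pars$seed <- pars$seed + k
    sc <- forest_importance(m[, otus, drop = FALSE], al$labels, pars)
    rk <- rank_otus(sc)
    tibble::tibble(block_id = bid, otu_id = otus, score = as.numeric(sc),
                   rank = match(seq_along(otus), rk))
  })
}
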