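#' Stratified half-split of a cohort
#'
#' Randomly divides the samples into two even halves, stratified by disease
#' status so each half keeps the case/control balance (per-class size
#' difference at most 1). The first half is used to rank OTUs and select the
#' aggregation cutoff; the second only to test the frozen super-taxon.
#'
#' @param meta Metadata tibble (`sample_id`, `label`) or a bare 0/1 label
#'   vector.
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return `list(train = , test = )` of integer sample indices.
#' @export
split_halves <- function(meta, seed = NULL) {
  labels <- if (is.data.frame(meta)) check_binary_labels(meta$label)
            else check_binary_labels(meta)
  if (any(table(labels) < 2L))
    stop("each class needs at least 2 samples to split", call. = FALSE)
  with_seed_or_ambient(seed, {
    train <- integer(0)
    for (k in c(0L, 1L)) {
      idx <- sample(which(labels == k))
      train <- c(train, idx[seq_len(ceiling(length(idx) / 2))])
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

# p-value of the frozen feature on the held-out half (fast path).
fit_feature_p <- function(S, labels, mode, covariates = NULL) {
  if (length(unique(S)) < 2L) return(NA_real_)
  res <- if (mode == "STB" && is.null(covariates)) fast_logit_binary(S, labels)
         else fast_logit(S, labels, covariates)
  res$p
}

# Split-sample test of one block on a bare matrix; `light = TRUE` skips the
# glm-backed reporting fit (used by the simulation harness).
core_test_block <- function(Xb, labels, itrain, itest, mode, params, alpha,
                            covariates = NULL, light = FALSE) {
  ytr <- labels[itrain]
  cov_tr <- if (is.null(covariates)) NULL else covariates[itrain, , drop = FALSE]
  imp <- forest_importance(Xb[itrain, , drop = FALSE], ytr, params)
  ranking <- rank_otus(imp)
  sel <- select_cutoff(Xb[itrain, , drop = FALSE], ranking, ytr, mode, cov_tr)
  base <- list(ranking = ranking, importance = imp, train = sel,
               cutoff = sel$best_cutoff, mode = mode)
  if (sel$untestable)
    return(c(base, list(pvalue = NA_real_, significant = FALSE,
                        reason = "untestable_train", test = NULL,
                        contributing = integer(0))))
  feat <- build_feature(Xb[itest, , drop = FALSE], ranking, sel$best_cutoff,
                        mode)
  yte <- labels[itest]
  cov_te <- if (is.null(covariates)) NULL else covariates[itest, , drop = FALSE]
  contributing <- contributing_ids(Xb, ranking, sel$best_cutoff)
  if (length(unique(feat$S)) < 2L)
    return(c(base, list(pvalue = NA_real_, significant = FALSE,
                        reason = "degenerate_test", test = NULL,
                        contributing = contributing)))
  if (light) {
    p <- fit_feature_p(feat$S, yte, mode, cov_te)
    return(c(base, list(pvalue = p, significant = is.finite(p) && p < alpha,
                        reason = NA_character_, test = NULL,
                        contributing = contributing)))
  }
  fit <- fit_logistic(feat$S, yte, cov_te)
  c(base, list(pvalue = fit$pvalue,
               significant = is.finite(fit$pvalue) && fit$pvalue < alpha,
               reason = NA_character_, test = fit,
               contributing = contributing))
}

#' Split-sample super-taxon test of one block
#'
#' On the training half: forest depth-importance ranking, then cutoff
#' selection. On the held-out half: the super-taxon is rebuilt with the
#' frozen ranking and cutoff and tested by logistic regression; nothing
#' computed on the test half feeds back into the ranking or the cutoff.
#'
#' @param table Sample-by-OTU tibble (or matrix).
#' @param meta Metadata tibble (`sample_id`, `label`, optional covariates).
#' @param otus Character vector of the block's OTU ids (or column indices).
#' @param mode `"STB"` or `"STC"`.
#' @param params [forest_params()].
#' @param alpha Per-block significance level (e.g. `0.05 / n_blocks`).
#' @param split Optional precomputed [split_halves()] list; drawn from the
#'   ambient RNG otherwise.
#' @return A list of class `st_block_test`: ranking, cutoff search, test
#'   fit (`st_fit`), `pvalue`, `significant`, `contributing` OTU ids, and a
#'   failure `reason` when the block is untestable.
#' @export
test_block <- function(table, meta, otus, mode = c("STB", "STC"),
                       params = forest_params(), alpha = 0.05,
                       split = NULL) {
  mode <- match.arg(mode)
  m <- otu_matrix(table)
  al <- align_meta(meta, rownames(m))
  if (is.character(otus)) {
    missing_ <- setdiff(otus, colnames(m))
    if (length(missing_) > 0)
      stop("OTUs not in table: ", paste(head(missing_, 5), collapse = ", "),
           call. = FALSE)
  }
  Xb <- m[, otus, drop = FALSE]
  if (is.null(split)) split <- split_halves(al$labels)
  out <- core_test_block(Xb, al$labels, split$train, split$test, mode, params,
                         alpha, al$covariates)
  out$alpha <- alpha
  out$split <- split
  structure(out, class = "st_block_test")
}

#' @export
print.st_block_test <- function(x, ...) {
  cat(sprintf("%s block test: cutoff = %s, test p = %s, significant = %s\n",
              x$mode, x$cutoff,
              if (is.na(x$pvalue)) x$reason else format(x$pvalue, digits = 3),
              x$significant))
  invisible(x)
}

#' Repeated split-sample discovery across all blocks
#'
#' Repeats the stratified half-split `n_repeats` times (split `r` uses seed
#' `base_seed + r`), runs the split-sample super-taxon test for every block
#' at the Bonferroni level `0.05 / n_blocks`, and retains the blocks that
#' are significant in at least `retain_threshold` repeats. For each stable
#' block the ranking and cutoff are re-derived once on the complete
#' discovery cohort (under `base_seed`) and the final association is fitted
#' there; that canonical fit is what [verify_supertaxa()] carries to an
#' independent cohort.
#'
#' @param table Sample-by-OTU tibble (or matrix); relative abundances for
#'   STC.
#' @param meta Metadata tibble (`sample_id`, `label`).
#' @param partition Block partition tibble (`block_id`, `otu_id`).
#' @param mode `"STB"` or `"STC"`.
#' @param n_repeats Number of repeated splits (default 10).
#' @param retain_threshold Minimum number of significant repeats for a block
#'   to be stable (default 2).
#' @param params [forest_params()].
#' @param alpha Per-block level; default `0.05 / n_blocks`.
#' @param base_seed Integer seed driving every split and forest.
#' @return An object of class `st_discovery`: `repeats` (tibble of per-repeat
#'   per-block results), `stable` (tibble with selection counts), `full_fits`
#'   (tibble of complete-cohort fits for stable blocks), `frozen` (per-block
#'   ranking/cutoff for verification), plus the configuration.
#' @export
run_discovery <- function(table, meta, partition, mode = c("STB", "STC"),
                          n_repeats = 10, retain_threshold = 2,
                          params = forest_params(), alpha = NULL,
                          base_seed = 1) {
  mode <- match.arg(mode)
  m <- otu_matrix(table)
  al <- align_meta(meta, rownames(m))
  blocks <- split(partition$otu_id, partition$block_id)
  n_blocks <- length(blocks)
  if (is.null(alpha)) alpha <- 0.05 / n_blocks

  repeats <- purrr::map_dfr(seq_len(n_repeats), function(r) {
    withr::with_seed(base_seed + r, {
      sp <- split_halves(al$labels)
      purrr::imap_dfr(blocks, function(otus, bid) {
        res <- core_test_block(m[, otus, drop = FALSE], al$labels,
                               sp$train, sp$test, mode, params, alpha,
                               al$covariates)
        tibble::tibble(repeat_id = r, block_id = bid, mode = mode,
                       cutoff = res$cutoff %||% NA_integer_,
                       pvalue = res$pvalue, significant = res$significant,
                       reason = res$reason)
      })
    })
  })

  stable <- repeats |>
    dplyr::group_by(.data$block_id) |>
    dplyr::summarise(n_significant = sum(.data$significant), .groups = "drop") |>
    dplyr::filter(.data$n_significant >= retain_threshold)

  frozen <- list()
  fit_proto <- tibble::tibble(block_id = character(0), mode = character(0),
                              cutoff = integer(0), n_otus = integer(0),
                              contributing_otus = character(0),
                              odds_ratio = numeric(0), ci_low = numeric(0),
                              ci_high = numeric(0), pvalue = numeric(0),
                              aic = numeric(0))
  full_fits <- purrr::map_dfr(stable$block_id, function(bid) {
    otus <- blocks[[bid]]
    Xb <- m[, otus, drop = FALSE]
    withr::with_seed(base_seed, {
      imp <- forest_importance(Xb, al$labels, params)
      ranking <- rank_otus(imp)
      sel <- select_cutoff(Xb, ranking, al$labels, mode, al$covariates)
      if (sel$untestable) {
        frozen[[bid]] <<- list(mode = mode, cutoff = NA_integer_,
                               otu_order = otus[ranking])
        return(tibble::tibble(block_id = bid, mode = mode,
                              cutoff = NA_integer_, n_otus = length(otus),
                              contributing_otus = NA_character_,
                              odds_ratio = NA_real_, ci_low = NA_real_,
                              ci_high = NA_real_, pvalue = NA_real_,
                              aic = NA_real_))
      }
      feat <- build_feature(Xb, ranking, sel$best_cutoff, mode)
      fit <- fit_logistic(feat$S, al$labels, al$covariates)
      frozen[[bid]] <<- list(mode = mode, cutoff = sel$best_cutoff,
                             otu_order = otus[ranking])
      tibble::tibble(block_id = bid, mode = mode, cutoff = sel$best_cutoff,
                     n_otus = length(otus),
                     contributing_otus = paste(feat$contributing_otus,
                                               collapse = ","),
                     odds_ratio = fit$odds_ratio, ci_low = fit$ci95[["low"]],
                     ci_high = fit$ci95[["high"]], pvalue = fit$pvalue,
                     aic = fit$aic)
    })
  })
  full_fits <- dplyr::bind_rows(fit_proto, full_fits)

  structure(list(repeats = repeats, stable = stable, full_fits = full_fits,
                 frozen = frozen, mode = mode, alpha = alpha,
                 n_repeats = n_repeats, retain_threshold = retain_threshold,
                 base_seed = base_seed, n_blocks = n_blocks),
            class = "st_discovery")
}

#' @export
print.st_discovery <- function(x, ...) {
  cat(sprintf("Super-taxon discovery (%s): %d blocks, %d repeats, alpha = %.3g\n",
              x$mode, x$n_blocks, x$n_repeats, x$alpha))
  cat(sprintf("  stable blocks (>= %d repeats): %s\n", x$retain_threshold,
              if (nrow(x$stable) == 0) "none"
              else paste(x$stable$block_id, collapse = ", ")))
  invisible(x)
}

#' @rdname run_discovery
#' @param x An `st_discovery` object.
#' @param ... Unused.
#' @export
tidy.st_discovery <- function(x, ...) x$full_fits

#' @rdname run_discovery
#' @export
glance.st_discovery <- function(x, ...) {
  tibble::tibble(mode = x$mode, n_blocks = x$n_blocks,
                 n_repeats = x$n_repeats, alpha = x$alpha,
                 n_stable = nrow(x$stable))
}

#' Verify stable super-taxa in an independent cohort
#'
#' Each stable block's super-taxon is rebuilt in the verification cohort
#' with its frozen discovery-derived OTU ordering and cutoff — contributing
#' OTUs are translated through a sequence-identity mapping (best match per
#' discovery OTU) — and refitted by logistic regression at the level
#' `0.05 / (number of stable blocks)`. No re-ranking takes place in the
#' verification cohort: the frozen hypothesis is tested as-is.
#'
#' @param report An `st_discovery` object.
#' @param verif_table Verification sample-by-OTU tibble (or matrix).
#' @param verif_meta Verification metadata tibble.
#' @param mapping Tibble `(discovery_otu_id, verification_otu_id,
#'   identity_score)`; `NULL` means the cohorts share OTU ids (identity
#'   mapping).
#' @param alpha Verification level; default `0.05 / n_stable`.
#' @return A tibble of verification fits, one row per stable block.
#' @export
verify_supertaxa <- function(report, verif_table, verif_meta, mapping = NULL,
                             alpha = NULL) {
  stopifnot(inherits(report, "st_discovery"))
  if (nrow(report$stable) == 0) {
    message("no stable blocks to verify")
    return(tibble::tibble(block_id = character(0), mode = character(0),
                          cutoff = integer(0), verification_otus = character(0),
                          odds_ratio = numeric(0), ci_low = numeric(0),
                          ci_high = numeric(0), pvalue = numeric(0),
                          significant = logical(0)))
  }
  vm <- otu_matrix(verif_table)
  al <- align_meta(verif_meta, rownames(vm))
  if (is.null(alpha)) alpha <- 0.05 / nrow(report$stable)

  translate <- function(otus) {
    if (is.null(mapping)) return(otus)
    hit <- mapping |>
      dplyr::filter(.data$discovery_otu_id %in% otus) |>
      dplyr::group_by(.data$discovery_otu_id) |>
      dplyr::slice_max(.data$identity_score, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    unmapped <- setdiff(otus, hit$discovery_otu_id)
    if (length(unmapped) > 0)
      stop("unmapped discovery OTUs: ", paste(unmapped, collapse = ", "),
           call. = FALSE)
    hit$verification_otu_id[match(otus, hit$discovery_otu_id)]
  }

  purrr::map_dfr(report$stable$block_id, function(bid) {
    fz <- report$frozen[[bid]]
    cutoff <- fz$cutoff
    top <- fz$otu_order[seq_len(min(cutoff, length(fz$otu_order)))]
    vtop <- translate(top)
    missing_ <- setdiff(vtop, colnames(vm))
    if (length(missing_) > 0)
      stop("verification table lacks OTUs: ",
           paste(missing_, collapse = ", "), call. = FALSE)
    V <- vm[, vtop, drop = FALSE]
    feat <- build_feature(V, seq_len(ncol(V)), cutoff, fz$mode)
    if (length(unique(feat$S)) < 2L) {
      return(tibble::tibble(block_id = bid, mode = fz$mode, cutoff = cutoff,
                            verification_otus = paste(vtop, collapse = ","),
                            odds_ratio = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, pvalue = NA_real_,
                            significant = FALSE))
    }
    fit <- fit_logistic(feat$S, al$labels, al$covariates)
    tibble::tibble(block_id = bid, mode = fz$mode, cutoff = cutoff,
                   verification_otus = paste(vtop, collapse = ","),
                   odds_ratio = fit$odds_ratio, ci_low = fit$ci95[["low"]],
                   ci_high = fit$ci95[["high"]], pvalue = fit$pvalue,
                   significant = is.finite(fit$pvalue) && fit$pvalue < alpha)
  })
}

#' Compare the joint super-taxon model with individual-OTU models
#'
#' Fits the logistic model with the super-taxon as the sole predictor and,
#' for each contributing OTU, the model with that OTU alone (presence
#' indicator under STB, raw abundance under STC), reporting AIC and odds
#' ratio for each: a lower AIC for the super-taxon indicates the aggregated
#' joint effect fits better than any single member.
#'
#' @param table Sample-by-OTU tibble (or matrix).
#' @param meta Metadata tibble.
#' @param supertaxon An `st_feature` (from [stb_feature()]/[stc_feature()]
#'   with contributing OTUs recorded) with at least 2 contributing OTUs.
#' @return A tibble `(model, aic, odds_ratio, pvalue, flagged)` with
#'   `1 + n_contributing` rows.
#' @export
compare_aic <- function(table, meta, supertaxon) {
  stopifnot(inherits(supertaxon, "st_feature"))
  otus <- supertaxon$contributing_otus
  if (length(otus) < 2)
    stop("super-taxon needs at least 2 contributing OTUs", call. = FALSE)
  m <- otu_matrix(table)
  al <- align_meta(meta, rownames(m))
  joint <- fit_logistic(supertaxon$S, al$labels, al$covariates)
  rows <- list(tibble::tibble(model = "supertaxon", aic = joint$aic,
                              odds_ratio = joint$odds_ratio,
                              pvalue = joint$pvalue, flagged = FALSE))
  for (o in otus) {
    v <- m[, o]
    pred <- if (supertaxon$mode == "STB") as.numeric(v > 0) else v
    if (length(unique(pred)) < 2L) {
      rows[[length(rows) + 1]] <- tibble::tibble(model = o, aic = NA_real_,
                                                 odds_ratio = NA_real_,
                                                 pvalue = NA_real_,
                                                 flagged = TRUE)
    } else {
      fit <- fit_logistic(pred, al$labels, al$covariates)
      rows[[length(rows) + 1]] <- tibble::tibble(model = o, aic = fit$aic,
                                                 odds_ratio = fit$odds_ratio,
                                                 pvalue = fit$pvalue,
                                                 flagged = !fit$converged)
    }
  }
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
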