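#' Ranked-presence exposure of a block
#'
#' For each sample, the smallest rank position `j` (by depth importance)
#' whose OTU has a positive abundance: `x_i = min{ j : v[i, d_j] > 0 }`,
#' or `J_g + 1` when every OTU of the block is absent from the sample.
#'
#' @param features Numeric sample-by-OTU matrix of one block (columns in
#'   original block order).
#' @param ranking Integer permutation from [rank_otus()] (`d_g`): position
#'   `j` holds the block-column index of the j-th most important OTU.
#' @return Integer vector of exposures in `1..(J_g + 1)`.
#' @export
compute_exposure <- function(features, ranking) {
  features <- as.matrix(features)
  J <- ncol(features)
  if (length(ranking) != J || !setequal(ranking, seq_len(J)))
    stop("ranking must be a permutation of the block columns", call. = FALSE)
  pos <- features[, ranking, drop = FALSE] > 0
  # first TRUE position; the appended TRUE column encodes J + 1
  as.integer(max.col(cbind(pos, TRUE), ties.method = "first"))
}

st_feature_obj <- function(S, mode, cutoff, contributing) {
  structure(list(S = as.numeric(S), mode = mode, cutoff = as.integer(cutoff),
                 contributing_otus = contributing),
            class = "st_feature")
}

#' @export
print.st_feature <- function(x, ...) {
  cat(sprintf("%s super-taxon feature, cutoff c = %d, %d contributing OTUs\n",
              x$mode, x$cutoff, length(x$contributing_otus)))
  invisible(x)
}

contributing_ids <- function(features, ranking, cutoff) {
  J <- ncol(features)
  top <- ranking[seq_len(min(cutoff, J))]
  if (is.null(colnames(features))) as.character(top) else colnames(features)[top]
}

#' Binary super-taxon feature (STB)
#'
#' `S_i = I(x_i < c)`: sample `i` carries the super-taxon when one of the
#' OTUs ranked strictly above the cutoff is present.
#'
#' @param x Exposure vector from [compute_exposure()].
#' @param cutoff Integer threshold `c` in `1..(J_g + 1)`.
#' @param J_g Block size (defaults to `max(x) - 1`, which is only safe when
#'   some sample misses the whole block; pass it explicitly otherwise).
#' @param features,ranking Optional block matrix and ranking used to name
#'   the contributing OTUs (ranks `1..min(c, J_g)`).
#' @return An `st_feature` object; `$S` is the 0/1 vector.
#' @export
stb_feature <- function(x, cutoff, J_g = max(x) - 1L, features = NULL,
                        ranking = NULL) {
  cutoff <- as.integer(cutoff)
  if (cutoff < 1L || cutoff > J_g + 1L)
    stop("cutoff out of range 1..J_g+1", call. = FALSE)
  S <- as.numeric(x < cutoff)
  contributing <- if (!is.null(features) && !is.null(ranking))
    contributing_ids(features, ranking, cutoff) else integer(0)
  st_feature_obj(S, "STB", cutoff, contributing)
}

#' Continuous super-taxon feature (STC)
#'
#' Mean of the non-zero abundances among the top-`c` ranked OTUs of the
#' block; 0 when none of them is present in the sample (so absence of the
#' whole aggregated set is encoded as 0 rather than undefined).
#'
#' @param features Numeric sample-by-OTU matrix of one block.
#' @param ranking Integer permutation from [rank_otus()].
#' @param cutoff Integer threshold `c` in `1..(J_g + 1)`.
#' @return An `st_feature` object; `$S` is the non-negative vector.
#' @export
stc_feature <- function(features, ranking, cutoff) {
  features <- as.matrix(features)
  J <- ncol(features)
  cutoff <- as.integer(cutoff)
  if (cutoff < 1L || cutoff > J + 1L)
    stop("cutoff out of range 1..J_g+1", call. = FALSE)
  top <- ranking[seq_len(min(cutoff, J))]
  V <- features[, top, drop = FALSE]
  num <- rowSums(V)
  den <- rowSums(V > 0)
  S <- ifelse(den > 0, num / den, 0)
  st_feature_obj(S, "STC", cutoff, contributing_ids(features, ranking, cutoff))
}

build_feature <- function(features, ranking, cutoff, mode, x = NULL) {
  if (mode == "STB") {
    if (is.null(x)) x <- compute_exposure(features, ranking)
    stb_feature(x, cutoff, J_g = ncol(features), features = features,
                ranking = ranking)
  } else {
    stc_feature(features, ranking, cutoff)
  }
}

#' Select the aggregation cutoff of a super-taxon
#'
#' Candidate cutoffs are the distinct observed exposure values
#' `{x_1, ..., x_n}`. For each candidate the block's super-taxon feature
#' (STB or STC) is built and a univariate logistic regression of disease
#' status on the feature (plus optional covariates) is fitted; the selected
#' cutoff is the one with the smallest coefficient p-value (ties: smallest
#' cutoff). Candidates whose feature is constant are degenerate and skipped.
#'
#' @param features Numeric sample-by-OTU matrix of one block.
#' @param ranking Integer permutation from [rank_otus()].
#' @param labels 0/1 disease status (both classes present).
#' @param mode `"STB"` or `"STC"`.
#' @param covariates Optional numeric covariate matrix.
#' @return An object of class `st_cutoff`: `best_cutoff`, `best_pvalue`,
#'   `untestable` (TRUE when every candidate is degenerate), and
#'   `candidates`, a tibble of `(cutoff, pvalue, degenerate, method)`.
#'   [tidy()] returns the candidate table.
#' @export
select_cutoff <- function(features, ranking, labels,
                          mode = c("STB", "STC"), covariates = NULL) {
  mode <- match.arg(mode)
  features <- as.matrix(features)
  labels <- check_binary_labels(labels)
  x <- compute_exposure(features, ranking)
  cands <- sort(unique(x))

  rows <- lapply(cands, function(cc) {
    feat <- build_feature(features, ranking, cc, mode, x = x)
    S <- feat$S
    if (length(unique(S)) < 2L)
      return(list(cutoff = cc, pvalue = NA_real_, degenerate = TRUE,
                  method = "degenerate"))
    res <- if (mode == "STB" && is.null(covariates)) {
      fast_logit_binary(S, labels)
    } else {
      fast_logit(S, labels, covariates)
    }
    list(cutoff = cc, pvalue = res$p, degenerate = FALSE, method = res$method)
  })
  cand_tbl <- dplyr::bind_rows(rows)
  ok <- !cand_tbl$degenerate & !is.na(cand_tbl$pvalue)
  if (!any(ok)) {
    out <- list(best_cutoff = NA_integer_, best_pvalue = NA_real_,
                untestable = TRUE, mode = mode, candidates = cand_tbl)
    return(structure(out, class = "st_cutoff"))
  }
  pmin_ <- min(cand_tbl$pvalue[ok])
  best <- min(cand_tbl$cutoff[ok & cand_tbl$pvalue == pmin_])
  structure(list(best_cutoff = as.integer(best), best_pvalue = pmin_,
                 untestable = FALSE, mode = mode, candidates = cand_tbl),
            class = "st_cutoff")
}

#' @export
print.st_cutoff <- function(x, ...) {
  if (x$untestable) {
    cat(sprintf("%s cutoff search: untestable block (all candidates degenerate)\n",
                x$mode))
  } else {
    cat(sprintf("%s cutoff search: best c = %d, p = %.3g (%d candidates)\n",
                x$mode, x$best_cutoff, x$best_pvalue, nrow(x$candidates)))
  }
  invisible(x)
}

#' @rdname select_cutoff
#' @param x An `st_cutoff` object.
#' @param ... Unused.
#' @export
tidy.st_cutoff <- function(x, ...) x$candidates

#' @rdname select_cutoff
#' @export
glance.st_cutoff <- function(x, ...) {
  tibble::tibble(mode = x$mode, best_cutoff = x$best_cutoff,
                 best_pvalue = x$best_pvalue, untestable = x$untestable,
                 n_candidates = nrow(x$candidates))
}

#' @rdname select_cutoff
#' @export
autoplot.st_cutoff <- function(object, ...) {
  dat <- dplyr::filter(object$candidates, !.data$degenerate)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cutoff, y = -log10(.data$pvalue))) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_cutoff, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "aggregation cutoff c",
                  y = expression(-log[10](p)),
                  title = sprintf("%s cutoff search", object$mode))
}
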