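#' Family-wise error rate over null-simulation replicates
#'
#' An error is made in a replicate when any block is rejected; the FWER is
#' the fraction of replicates with at least one rejection. Only meaningful
#' under the global null (no true blocks).
#'
#' @param outcomes Tibble of per-replicate selections with columns
#'   `replicate_id` and `n_selected_blocks` (as produced by
#'   [run_benchmark()]), or a list of per-replicate selected-block sets.
#' @return A tibble `(fwer, se, n_replicates)`; `se` is the binomial
#'   standard error `sqrt(f(1 - f) / R)`.
#' @export
compute_fwer <- function(outcomes) {
  any_sel <- if (is.data.frame(outcomes)) outcomes$n_selected_blocks > 0
             else vapply(outcomes, function(s) length(s) > 0, logical(1))
  f <- mean(any_sel)
  tibble::tibble(fwer = f, se = sqrt(f * (1 - f) / length(any_sel)),
                 n_replicates = length(any_sel))
}

confusion <- function(selected, truth, universe_size) {
  tp <- length(intersect(selected, truth))
  fp <- length(selected) - tp
  fn <- length(truth) - tp
  tn <- universe_size - tp - fp - fn
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

rate_summary <- function(v) {
  ok <- !is.na(v)
  c(mean = mean(v[ok]), sd = stats::sd(v[ok]), n_na = sum(!ok))
}

#' Block- and OTU-level power metrics over simulation replicates
#'
#' Per replicate, confusion counts are formed at block level (over all
#' blocks) and OTU level (over all OTUs) from the selected sets versus the
#' planted truth, giving sensitivity TP/(TP+FN), specificity TN/(FP+TN) and
#' precision TP/(TP+FP); precision is undefined (NA, excluded from the mean
#' with a count) when nothing is selected. Per-block identification rates
#' are the fraction of replicates selecting each true block; their mean and
#' SD are taken across the true blocks.
#'
#' @param outcomes Tibble from [run_benchmark()] with list-columns
#'   `selected_blocks` and `selected_otus`.
#' @param truth_blocks,truth_otus True block indices and OTU indices.
#' @param n_blocks,n_otus Sizes of the two selection universes.
#' @return A list of class `st_metrics`: `identification` (per-block tibble),
#'   `avg_identification` (mean/sd over true blocks), `block` and `otu`
#'   summary tibbles (mean, sd, n_na per metric), `n_replicates`.
#' @export
compute_power_metrics <- function(outcomes, truth_blocks, truth_otus,
                                  n_blocks, n_otus) {
  if (length(truth_blocks) == 0)
    stop("no true blocks: use compute_fwer() for null scenarios",
         call. = FALSE)
  R <- nrow(outcomes)
  per_rep <- purrr::pmap_dfr(
    list(outcomes$selected_blocks, outcomes$selected_otus),
    function(sb, so) {
      cb <- confusion(sb, truth_blocks, n_blocks)
      co <- confusion(so, truth_otus, n_otus)
      tibble::tibble(
        block_sens = cb["tp"] / (cb["tp"] + cb["fn"]),
        block_spec = cb["tn"] / (cb["fp"] + cb["tn"]),
        block_prec = if ((cb["tp"] + cb["fp"]) == 0) NA_real_
                     else cb["tp"] / (cb["tp"] + cb["fp"]),
        otu_sens = co["tp"] / (co["tp"] + co["fn"]),
        otu_spec = co["tn"] / (co["fp"] + co["tn"]),
        otu_prec = if ((co["tp"] + co["fp"]) == 0) NA_real_
                   else co["tp"] / (co["tp"] + co["fp"]))
    })

  ident <- purrr::map_dfr(truth_blocks, function(b) {
    tibble::tibble(
      block = b,
      rate = mean(vapply(outcomes$selected_blocks,
                         function(s) b %in% s, logical(1))))
  })

  summarise_level <- function(prefix) {
    purrr::map_dfr(c("sens", "spec", "prec"), function(met) {
      s <- rate_summary(per_rep[[paste0(prefix, "_", met)]])
      tibble::tibble(metric = met, mean = s[["mean"]], sd = s[["sd"]],
                     n_na = s[["n_na"]])
    })
  }

  structure(list(identification = ident,
                 avg_identification = c(mean = mean(ident$rate),
                                        sd = stats::sd(ident$rate)),
                 block = summarise_level("block"),
                 otu = summarise_level("otu"),
                 per_replicate = per_rep, n_replicates = R),
            class = "st_metrics")
}

#' @export
print.st_metrics <- function(x, ...) {
  cat(sprintf("Power metrics over %d replicates\n", x$n_replicates))
  cat(sprintf("  identification rate over true blocks: %.4f (SD %.4f)\n",
              x$avg_identification[["mean"]], x$avg_identification[["sd"]]))
  cat("  block level:\n"); print(x$block)
  cat("  OTU level:\n"); print(x$otu)
  invisible(x)
}

#' @rdname compute_power_metrics
#' @param x An `st_metrics` object.
#' @param ... Unused.
#' @export
tidy.st_metrics <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$block, level = "block", .before = 1),
    dplyr::mutate(x$otu, level = "otu", .before = 1))
}

# Run STB/STC on one simulated dataset under one split; forests are shared
# between the two modes because the ranking does not depend on the
# aggregation. Returns, per mode, the selected block indices and the union
# of contributing OTU column indices of significant blocks.
st_select <- function(dat, modes, params, alpha, split = NULL) {
  X <- dat$counts
  y <- dat$labels
  sc <- dat$scenario
  if (is.null(split)) split <- split_halves(y)
  bs <- sc$block_size
  sel <- lapply(modes, function(m) list(blocks = integer(0), otus = integer(0)))
  names(sel) <- modes
  for (b in seq_len(sc$n_blocks)) {
    cols <- ((b - 1) * bs + 1):(b * bs)
    Xb <- X[, cols, drop = FALSE]
    ytr <- y[split$train]
    imp <- forest_importance(Xb[split$train, , drop = FALSE], ytr, params)
    ranking <- rank_otus(imp)
    Xtr <- Xb[split$train, , drop = FALSE]
    Xte <- Xb[split$test, , drop = FALSE]
    for (m in modes) {
      cs <- select_cutoff(Xtr, ranking, ytr, m)
      if (cs$untestable) next
      feat <- build_feature(Xte, ranking, cs$best_cutoff, m)
      if (length(unique(feat$S)) < 2L) next
      p <- fit_feature_p(feat$S, y[split$test], m)
      if (is.finite(p) && p < alpha) {
        top <- ranking[seq_len(min(cs$best_cutoff, bs))]
        sel[[m]]$blocks <- c(sel[[m]]$blocks, b)
        sel[[m]]$otus <- c(sel[[m]]$otus, cols[top])
      }
    }
  }
  sel
}

#' Simulation benchmark of the super-taxon pipeline
#'
#' Repeatedly simulates a dataset from `scenario`, splits it in half,
#' selects super-taxa on the first half and tests the frozen features on the
#' second at the Bonferroni level `0.05 / n_blocks`, and records which
#' blocks (and which contributing OTUs) each method rejects. Replicate `i`
#' runs entirely under seed `base_seed + i`, so reports are reproducible.
#' `"stb"` and `"stc"` share simulated data, splits and forests within a
#' replicate; an external method adapter (a `function(dat, split)` returning
#' `list(blocks = , otus = )` of selected indices, with a block counted as
#' selected when any of its OTUs is) can be benchmarked alongside.
#'
#' @param scenario A [sim_scenario()].
#' @param methods Character vector from `"stb"`, `"stc"`, and/or a named
#'   list of adapter functions.
#' @param n_replicates Number of simulation replicates.
#' @param base_seed Integer seed; replicate `i` uses `base_seed + i`.
#' @param params [forest_params()] for the ranking forests.
#' @param alpha Per-block level; default `0.05 / n_blocks`.
#' @return An object of class `st_benchmark`: `outcomes` (tibble with one
#'   row per replicate and method, list-columns `selected_blocks`,
#'   `selected_otus`), `failed` (tibble of failed replicates), plus the
#'   configuration. Use [compute_fwer()] / [compute_power_metrics()] or
#'   [tidy()] on it.
#' @export
run_benchmark <- function(scenario, methods = "stb", n_replicates = 100,
                          base_seed = 1, params = forest_params(),
                          alpha = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (is.null(alpha)) alpha <- 0.05 / scenario$n_blocks
  adapters <- NULL
  if (is.list(methods)) {
    adapters <- methods[vapply(methods, is.function, logical(1))]
    methods <- setdiff(unlist(methods[!vapply(methods, is.function,
                                              logical(1))]), character(0))
  }
  builtin <- intersect(tolower(methods), c("stb", "stc"))
  rows <- list(); failures <- list()
  for (i in seq_len(n_replicates)) {
    res <- tryCatch(
      withr::with_seed(base_seed + i, {
        dat <- simulate_dataset(scenario, seed = NULL)
        split <- split_halves(dat$labels)
        out <- list()
        if (length(builtin) > 0) {
          sel <- st_select(dat, toupper(builtin), params, alpha, split)
          for (m in builtin)
            out[[m]] <- sel[[toupper(m)]]
        }
        for (nm in names(adapters))
          out[[nm]] <- adapters[[nm]](dat, split)
        out
      }),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <-
        tibble::tibble(replicate_id = i, error = conditionMessage(res))
      next
    }
    for (nm in names(res)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        replicate_id = i, method = nm,
        n_selected_blocks = length(res[[nm]]$blocks),
        selected_blocks = list(res[[nm]]$blocks),
        selected_otus = list(res[[nm]]$otus))
    }
  }
  structure(list(outcomes = dplyr::bind_rows(rows),
                 failed = if (length(failures) > 0) dplyr::bind_rows(failures)
                          else tibble::tibble(replicate_id = integer(0),
                                              error = character(0)),
                 scenario = scenario, alpha = alpha, base_seed = base_seed,
                 n_replicates = n_replicates, params = params),
            class = "st_benchmark")
}

#' @export
print.st_benchmark <- function(x, ...) {
  cat(sprintf("Super-taxon benchmark: %d replicates (%d failed), alpha = %.4g\n",
              x$n_replicates, nrow(x$failed), x$alpha))
  print(tidy(x))
  invisible(x)
}

benchmark_outcomes <- function(x, method) {
  dplyr::filter(x$outcomes, .data$method == !!method)
}

#' @rdname run_benchmark
#' @param x An `st_benchmark` object.
#' @param ... Unused.
#' @export
tidy.st_benchmark <- function(x, ...) {
  sc <- x$scenario
  purrr::map_dfr(unique(x$outcomes$method), function(m) {
    oc <- benchmark_outcomes(x, m)
    if (length(sc$truth_blocks) == 0) {
      fw <- compute_fwer(oc)
      tibble::tibble(method = m, scenario = "null", fwer = fw$fwer,
                     fwer_se = fw$se, n_replicates = fw$n_replicates)
    } else {
      pm <- compute_power_metrics(oc, sc$truth_blocks, sc$truth_otus,
                                  sc$n_blocks, sc$n_otus)
      tibble::tibble(method = m, scenario = "power",
                     avg_identification = pm$avg_identification[["mean"]],
                     identification_sd = pm$avg_identification[["sd"]],
                     block_sens = pm$block$mean[pm$block$metric == "sens"],
                     block_spec = pm$block$mean[pm$block$metric == "spec"],
                     block_prec = pm$block$mean[pm$block$metric == "prec"],
                     otu_sens = pm$otu$mean[pm$otu$metric == "sens"],
                     otu_spec = pm$otu$mean[pm$otu$metric == "spec"],
                     otu_prec = pm$otu$mean[pm$otu$metric == "prec"],
                     n_replicates = nrow(oc))
    }
  })
}

#' @rdname run_benchmark
#' @param object An `st_benchmark` object (for `autoplot`).
#' @export
autoplot.st_benchmark <- function(object, ...) {
  sc <- object$scenario
  if (length(sc$truth_blocks) == 0) {
    dat <- tidy(object)
    return(ggplot2::ggplot(dat, ggplot2::aes(x = .data$method, y = .data$fwer)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$fwer - .data$fwer_se,
                                          ymax = .data$fwer + .data$fwer_se),
                             width = 0.2) +
      ggplot2::geom_hline(yintercept = 0.05, linetype = 2) +
      ggplot2::labs(y = "family-wise error rate", x = NULL))
  }
  dat <- purrr::map_dfr(unique(object$outcomes$method), function(m) {
    pm <- compute_power_metrics(benchmark_outcomes(object, m),
                                sc$truth_blocks, sc$truth_otus,
                                sc$n_blocks, sc$n_otus)
    dplyr::mutate(pm$identification, method = m)
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$block), y = .data$rate,
                                    fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "true block", y = "identification rate")
}

#' Zero-fraction sweep over the sparsity knob
#'
#' Simulates `n_datasets` datasets per value of `a` and records the average
#' fraction of zero cells, reproducing the generator's sparsity
#' calibration curve (about 0.4 at a = 4 up to about 0.8 at a = 8).
#'
#' @param a_values Sparsity knob values (default 4:8).
#' @param n_datasets Datasets per value (default 3).
#' @param base_seed Integer seed.
#' @param ... Passed to [scenario_sparsity()] (e.g. a smaller `n_samples`
#'   for a quick estimate; the per-cell zero fraction does not depend on N).
#' @return A tibble `(a, zero_fraction)`.
#' @export
sparsity_sweep <- function(a_values = 4:8, n_datasets = 3, base_seed = 1,
                           ...) {
  purrr::map_dfr(a_values, function(a) {
    sc <- scenario_sparsity(a, ...)
    zf <- vapply(seq_len(n_datasets), function(i) {
      mean(simulate_dataset(sc, seed = base_seed + 1000 * match(a, a_values) + i)$counts == 0)
    }, numeric(1))
    tibble::tibble(a = a, zero_fraction = mean(zf))
  })
}

#' @rdname sparsity_sweep
#' @param sweep A tibble from [sparsity_sweep()].
#' @export
plot_sparsity_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$a, y = .data$zero_fraction)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sparsity knob a", y = "zero fraction")
}
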