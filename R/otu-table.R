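#' Read an OTU abundance table
#'
#' Reads a dense delimited sample-by-OTU (or OTU-by-sample) count table with a
#' header row of ids and a leading id column, as distributed in MicrobiomeHD-
#' style deposits.
#'
#' @param path Path to a TSV (or other delimited) file.
#' @param orientation `"samples_by_otus"` (default) when rows are samples, or
#'   `"otus_by_samples"` when rows are OTUs; the result is always returned as
#'   samples by OTUs.
#' @param delim Field delimiter, tab by default.
#' @return A tibble with a `sample_id` column followed by one numeric column
#'   per OTU (counts).
#' @export
read_otu_table <- function(path,
                           orientation = c("samples_by_otus", "otus_by_samples"),
                           delim = "\t") {
  orientation <- match.arg(orientation)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids))
    stop("duplicate ids in first column of ", path, call. = FALSE)
  vals <- raw[-1]
  bad_col <- which(!vapply(vals, is.numeric, logical(1)))
  if (length(bad_col) > 0)
    stop("non-numeric cells in column '", names(vals)[bad_col[1]], "'",
         call. = FALSE)
  m <- as.matrix(vals)
  if (anyNA(m)) {
    w <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("missing/unparseable cell at row ", w[1], ", column ",
         colnames(m)[w[2]], call. = FALSE)
  }
  if (any(m < 0)) {
    w <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("negative cell at row '", ids[w[1]], "', column '",
         colnames(m)[w[2]], "'", call. = FALSE)
  }
  if (anyDuplicated(colnames(m)))
    stop("duplicate ids in header of ", path, call. = FALSE)
  rownames(m) <- ids
  if (orientation == "otus_by_samples") m <- t(m)
  otu_tibble(m)
}

#' Read a sample metadata table
#'
#' @param path TSV with columns `sample_id`, `label` (0/1 disease status) and
#'   optional numeric covariate columns.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                          show_col_types = FALSE)
  if (!all(c("sample_id", "label") %in% names(meta)))
    stop("metadata needs columns 'sample_id' and 'label'", call. = FALSE)
  meta$sample_id <- as.character(meta$sample_id)
  meta$label <- check_binary_labels(meta$label, require_both = FALSE)
  meta
}

#' Read an OTU taxonomy table
#'
#' Accepts either one column per rank (`kingdom`, `phylum`, `class`, `order`,
#' `family`, `genus`, optionally `species`) or a single `lineage` column with
#' RDP-style strings (`"k__Bacteria;p__Firmicutes;...;g__Parvimonas"`), which
#' are split on `";"`. Empty rank labels (e.g. `"g__"`) become `NA`.
#'
#' @param path TSV with an `otu_id` column plus rank columns or a `lineage`
#'   column.
#' @return A tibble with `otu_id` and one character column per rank.
#' @export
read_taxonomy <- function(path) {
  tax <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  if (!"otu_id" %in% names(tax))
    stop("taxonomy needs an 'otu_id' column", call. = FALSE)
  if ("lineage" %in% names(tax)) {
    ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
               "species")
    parts <- strsplit(tax$lineage, ";", fixed = TRUE)
    parsed <- lapply(seq_along(ranks), function(i) {
      v <- vapply(parts, function(p) if (length(p) >= i) p[[i]] else NA_character_,
                  character(1))
      v <- sub("^\\s*[kpcofgs]__", "", v)
      v[!nzchar(v) | is.na(v)] <- NA_character_
      v
    })
    names(parsed) <- ranks
    tax <- dplyr::bind_cols(tax["otu_id"], tibble::as_tibble(parsed))
  }
  tax
}

#' Quality-filter an OTU count table
#'
#' Applies the standard MicrobiomeHD-style filters in a fixed order: first
#' samples with fewer than `min_sample_reads` total reads are removed, then
#' OTUs with fewer than `min_otu_reads` total reads, then OTUs present (count
#' \eqn{> 0}) in less than `min_prevalence` of the remaining samples.
#'
#' @param table Sample-by-OTU count tibble (or matrix).
#' @param min_sample_reads Minimum total reads per sample (default 100).
#' @param min_otu_reads Minimum total reads per OTU (default 10).
#' @param min_prevalence Minimum fraction of samples in which an OTU must be
#'   present (default 0.01).
#' @return The filtered tibble, with a `"filter_report"` attribute: a tibble
#'   of the number of samples/OTUs removed at each step.
#' @export
filter_otu_table <- function(table, min_sample_reads = 100,
                             min_otu_reads = 10, min_prevalence = 0.01) {
  m <- otu_matrix(table)
  n0 <- nrow(m); p0 <- ncol(m)

  keep_s <- rowSums(m) >= min_sample_reads
  m <- m[keep_s, , drop = FALSE]
  if (nrow(m) == 0) stop("all samples removed by the read-count filter",
                         call. = FALSE)

  keep_reads <- colSums(m) >= min_otu_reads
  m <- m[, keep_reads, drop = FALSE]

  prev <- colMeans(m > 0)
  keep_prev <- prev >= min_prevalence
  m <- m[, keep_prev, drop = FALSE]
  if (ncol(m) == 0) stop("all OTUs removed by the filters", call. = FALSE)

  report <- tibble::tibble(
    step = c("sample_reads", "otu_reads", "otu_prevalence"),
    removed = c(sum(!keep_s), sum(!keep_reads), sum(!keep_prev)),
    kept = c(nrow(m), sum(keep_reads), ncol(m))
  )
  out <- otu_tibble(m)
  attr(out, "filter_report") <- report
  out
}

#' Filtering report of a filtered OTU table
#' @param table A table returned by [filter_otu_table()].
#' @return A tibble with columns `step`, `removed`, `kept`.
#' @export
filter_report <- function(table) attr(table, "filter_report")

#' Convert counts to relative abundances
#'
#' Divides each sample's counts by its total reads. Row totals are stored in
#' the `"row_totals"` attribute so the counts can be recovered exactly.
#'
#' @param table Sample-by-OTU count tibble (or matrix) with positive row
#'   totals (filter first).
#' @return A tibble of relative abundances (rows sum to 1).
#' @export
to_relative <- function(table) {
  m <- otu_matrix(table)
  tot <- rowSums(m)
  if (any(tot <= 0))
    stop("samples with zero total reads: ",
         paste(head(rownames(m)[tot <= 0], 5), collapse = ", "),
         "; filter before normalising", call. = FALSE)
  out <- otu_tibble(m / tot)
  attr(out, "row_totals") <- setNames(tot, rownames(m))
  out
}

#' Partition OTUs into taxonomic blocks
#'
#' Groups the columns of an OTU table into disjoint blocks by a taxonomy
#' level; blocks are the aggregation and testing unit for super-taxa. OTUs
#' with a missing assignment at the level are excluded (and reported), not
#' pooled into an artificial block.
#'
#' @param table Sample-by-OTU tibble (or matrix).
#' @param taxonomy Tibble from [read_taxonomy()]; must cover every OTU in
#'   `table`.
#' @param level One of `"genus"`, `"family"`, `"order"`, `"class"` (or any
#'   rank column present in `taxonomy`).
#' @return A tibble with columns `block_id` (the taxon name) and `otu_id`,
#'   plus an `"excluded"` attribute listing OTUs without an assignment.
#' @export
partition_by_taxonomy <- function(table, taxonomy, level = "genus") {
  m <- otu_matrix(table)
  if (!level %in% names(taxonomy))
    stop("taxonomy has no '", level, "' level", call. = FALSE)
  miss <- setdiff(colnames(m), taxonomy$otu_id)
  if (length(miss) > 0)
    stop("OTUs missing from taxonomy: ", paste(head(miss, 5), collapse = ", "),
         call. = FALSE)
  tax <- taxonomy[match(colnames(m), taxonomy$otu_id), c("otu_id", level)]
  names(tax)[2] <- "block_id"
  excluded <- tax$otu_id[is.na(tax$block_id)]
  part <- tax[!is.na(tax$block_id), c("block_id", "otu_id")]
  part <- dplyr::arrange(tibble::as_tibble(part), .data$block_id)
  attr(part, "excluded") <- excluded
  part
}

#' Block sizes of a partition
#' @param partition Tibble from [partition_by_taxonomy()] (columns `block_id`,
#'   `otu_id`).
#' @return A tibble with `block_id` and `n_otus` (the block size J_g).
#' @export
block_sizes <- function(partition) {
  dplyr::count(partition, .data$block_id, name = "n_otus")
}
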