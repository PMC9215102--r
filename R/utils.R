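# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed when `seed` is non-NULL, restoring the
# caller's RNG state afterwards; with seed = NULL the ambient RNG stream is
# used (callers that loop over replicates seed once per replicate).
with_seed_or_ambient <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(seed, force(code))
}

# Coerce a samples-by-OTUs table (tibble with a sample-id first column, a
# data.frame, or a numeric matrix) to a numeric matrix with sample ids as
# rownames. The id column is detected as the first non-numeric column.
otu_matrix <- function(table) {
  if (is.matrix(table)) {
    if (is.null(rownames(table)))
      rownames(table) <- paste0("sample_", seq_len(nrow(table)))
    storage.mode(table) <- "double"
    return(table)
  }
  stopifnot(is.data.frame(table))
  df <- as.data.frame(table)
  id_col <- which(!vapply(df, is.numeric, logical(1)))
  if (length(id_col) == 0) {
    ids <- rownames(df)
    m <- as.matrix(df)
  } else {
    if (!identical(unname(id_col), 1L))
      stop("non-numeric columns other than a leading sample-id column found",
           call. = FALSE)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[-1])
  }
  if (anyDuplicated(ids)) stop("duplicate sample ids", call. = FALSE)
  rownames(m) <- ids
  storage.mode(m) <- "double"
  m
}

# Inverse of otu_matrix(): matrix -> tibble with a sample_id column.
otu_tibble <- function(m) {
  ids <- rownames(m) %||% paste0("sample_", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("otu_", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(sample_id = ids),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

check_binary_labels <- function(labels, require_both = TRUE) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 0/1", call. = FALSE)
  labels <- as.integer(labels)
  if (require_both && length(unique(labels)) < 2L)
    stop("labels must contain both classes", call. = FALSE)
  labels
}

# Align a metadata data frame (sample_id, label, covariate columns) with the
# rownames of an OTU matrix; returns list(labels, covariates).
align_meta <- function(meta, sample_ids) {
  stopifnot(is.data.frame(meta))
  if (!all(c("sample_id", "label") %in% names(meta)))
    stop("metadata needs columns 'sample_id' and 'label'", call. = FALSE)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ids in metadata", call. = FALSE)
  miss <- setdiff(sample_ids, meta$sample_id)
  if (length(miss) > 0)
    stop("samples missing from metadata: ", paste(head(miss, 5), collapse = ", "),
         call. = FALSE)
  meta <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]
  covar_cols <- setdiff(names(meta), c("sample_id", "label"))
  covariates <- NULL
  if (length(covar_cols) > 0) {
    covariates <- as.matrix(meta[covar_cols])
    storage.mode(covariates) <- "double"
  }
  list(labels = check_binary_labels(meta$label), covariates = covariates)
}
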