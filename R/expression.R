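#' Read a gene-expression matrix from delimited text
#'
#' Reads a tab- or comma-delimited expression table with one header row and a
#' leading identifier column, and returns a genes-by-samples numeric matrix.
#' Cells matching one of `na_tokens` (or empty cells) become missing values;
#' any other non-numeric cell is an error, as are duplicated gene or sample
#' identifiers.
#'
#' @param path Path to a delimited text file.
#' @param orientation Either `"genes-in-rows"` (default) or
#'   `"samples-in-rows"`; the returned matrix is always genes x samples.
#' @param sep Field separator; `NULL` (default) picks `","` for `.csv` files
#'   and tab otherwise.
#' @param na_tokens Character vector of cell values treated as missing.
#' @return A numeric matrix (genes x samples) with gene identifiers as row
#'   names and sample identifiers as column names.
#' @export
read_expression <- function(path, orientation = c("genes-in-rows", "samples-in-rows"),
                            sep = NULL, na_tokens = c("NA", "NaN", "")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("expression file not found: %s", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.csv(path, sep = sep, header = TRUE, check.names = FALSE,
                  colClasses = "character", row.names = NULL)
  if (ncol(raw) < 2) stopf("expression file must have an identifier column plus data columns")
  ids <- raw[[1]]
  if (anyDuplicated(ids)) stopf("duplicated identifiers in expression file: %s",
                                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cn <- colnames(raw)[-1]
  if (anyDuplicated(cn)) stopf("duplicated identifiers in expression header: %s",
                               paste(unique(cn[duplicated(cn)]), collapse = ", "))
  cells <- as.matrix(raw[, -1, drop = FALSE])
  cells[cells %in% na_tokens] <- NA_character_
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- !is.na(cells) & is.na(num)
  if (any(bad)) stopf("non-numeric cell(s) in expression file, e.g. '%s'", cells[which(bad)[1]])
  dimnames(num) <- list(ids, cn)
  x <- if (orientation == "samples-in-rows") t(num) else num
  validate_expression(x, allow_na = TRUE)
  x
}

#' Read right-censored survival outcomes
#'
#' Reads a delimited file with columns `sample`, `time`, `status`
#' (1 = event observed, 0 = censored) and returns a tibble aligned to
#' `sample_ids` when given.
#'
#' @param path Path to a CSV/TSV file with columns sample, time, status.
#' @param sample_ids Optional character vector; rows are reordered to match and
#'   missing samples are an error.
#' @return A tibble with columns `sample`, `time`, `status`.
#' @export
read_survival <- function(path, sample_ids = NULL) {
  if (!file.exists(path)) stopf("survival file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- read.csv(path, sep = sep, header = TRUE, check.names = FALSE)
  need <- c("sample", "time", "status")
  if (!all(need %in% colnames(d))) stopf("survival file must have columns: %s", paste(need, collapse = ", "))
  d <- tibble::tibble(sample = as.character(d$sample),
                      time = as.numeric(d$time),
                      status = as.integer(d$status))
  validate_survival(d$time, d$status)
  if (!is.null(sample_ids)) {
    miss <- setdiff(sample_ids, d$sample)
    if (length(miss)) stopf("survival outcomes missing for sample(s): %s", paste(head(miss, 5), collapse = ", "))
    d <- d[match(sample_ids, d$sample), ]
  }
  d
}

validate_expression <- function(x, allow_na = FALSE) {
  if (!is.matrix(x) || !is.numeric(x)) stopf("expression data must be a numeric matrix (genes x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x))) stopf("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(x))) stopf("duplicated gene identifiers")
  if (anyDuplicated(colnames(x))) stopf("duplicated sample identifiers")
  if (!allow_na && anyNA(x)) stopf("expression matrix contains missing values; impute first")
  invisible(x)
}

validate_survival <- function(time, status) {
  if (length(time) != length(status)) stopf("survival time and status lengths differ")
  if (any(!is.finite(time)) || any(time <= 0)) stopf("survival times must be positive and finite")
  if (!all(status %in% c(0L, 1L))) stopf("status must be 0 (censored) or 1 (event)")
  if (sum(status) < 1) stopf("survival data contain no events")
  invisible(NULL)
}

#' K-nearest-neighbour imputation of missing expression values
#'
#' Each missing entry is replaced by the average of the same sample's values in
#' the `k` nearest gene rows, with distance the Euclidean distance over
#' samples observed in both rows (scaled to the common sample count so rows
#' with different overlaps are comparable). Observed entries are never changed.
#'
#' @param x Genes x samples numeric matrix, possibly with missing entries.
#' @param k Number of neighbouring genes to average (default 10).
#' @return The matrix with all missing entries filled.
#' @export
impute_knn <- function(x, k = 10) {
  validate_expression(x, allow_na = TRUE)
  if (!is_count(k) || k >= nrow(x)) stopf("`k` must be a positive integer smaller than the number of genes")
  if (!anyNA(x)) return(x)
  all_missing <- rowSums(!is.na(x)) == 0
  if (any(all_missing)) stopf("gene(s) with all values missing: %s",
                              paste(head(rownames(x)[all_missing], 5), collapse = ", "))
  need <- which(rowSums(is.na(x)) > 0)
  n <- ncol(x)
  for (g in need) {
    target <- x[g, ]
    obs_t <- !is.na(target)
    diffs <- sweep(x, 2, target, "-")
    co <- obs_t[col(x)] & !is.na(x)
    sq <- diffs^2
    sq[!co] <- 0
    overlap <- rowSums(co)
    # mean squared difference over co-observed samples, scaled to full length
    d2 <- ifelse(overlap > 0, rowSums(sq) / overlap, Inf)
    d2[g] <- Inf
    ord <- order(d2, seq_along(d2))
    for (s in which(!obs_t)) {
      donors <- ord[!is.na(x[ord, s]) & is.finite(d2[ord])]
      if (length(donors) < 1) stopf("no donor genes available to impute gene '%s'", rownames(x)[g])
      x[g, s] <- mean(x[donors[seq_len(min(k, length(donors)))], s])
    }
  }
  x
}

#' Keep the genes with the largest variances
#'
#' Unsupervised variance screening: retains the `d_keep` genes with largest
#' unbiased sample variance, breaking ties by input order, and preserves the
#' original gene order among survivors. Screening is applied before rescaling.
#'
#' @param x Genes x samples numeric matrix without missing values.
#' @param d_keep Number of genes to keep (default 2000).
#' @return The screened matrix.
#' @export
screen_by_variance <- function(x, d_keep = 2000) {
  validate_expression(x)
  if (!is_count(d_keep)) stopf("`d_keep` must be a positive integer")
  if (d_keep > nrow(x)) stopf("`d_keep` (%d) exceeds the number of genes (%d)", d_keep, nrow(x))
  v <- apply(x, 1, var)
  keep <- sort(order(-v, seq_along(v))[seq_len(d_keep)])
  x[keep, , drop = FALSE]
}

#' Rescale each gene to zero median and unit variance
#'
#' Every gene row is shifted by its median (midpoint of the two central order
#' statistics for even sample counts) and divided by its sample standard
#' deviation, so rows end with median 0 and unbiased variance 1.
#'
#' @param x Genes x samples numeric matrix without missing values.
#' @return The rescaled matrix.
#' @export
rescale_expression <- function(x) {
  validate_expression(x)
  s <- apply(x, 1, sd)
  if (any(s == 0)) stopf("constant gene row(s) cannot be rescaled: %s",
                         paste(head(rownames(x)[s == 0], 5), collapse = ", "))
  x <- x / s
  x - apply(x, 1, median)
}

#' Preprocess an expression matrix for network analysis
#'
#' Applies the standard preprocessing chain in order: impute missing values by
#' gene-wise K nearest neighbours, screen to the `d_keep` most variable genes,
#' then rescale every gene to zero median and unit variance.
#'
#' @inheritParams impute_knn
#' @inheritParams screen_by_variance
#' @return The preprocessed genes x samples matrix.
#' @export
preprocess_expression <- function(x, k = 10, d_keep = min(2000, nrow(x))) {
  x <- impute_knn(x, k = k)
  x <- screen_by_variance(x, d_keep = d_keep)
  rescale_expression(x)
}
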