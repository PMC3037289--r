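#' Principal component analysis within each module
#'
#' For every module, the samples x genes submatrix is column-centred (per
#' gene, over samples) and decomposed by singular values. Loaded directions
#' (loadings) have unit norm; score columns are the centred data times the
#' loadings, so they are mutually orthogonal and the variance explained by
#' successive components is nonincreasing. A deterministic sign convention is
#' applied: each score column is flipped, if needed, to correlate
#' non-negatively with the module's mean expression profile (ties broken by
#' forcing the largest-magnitude loading positive).
#'
#' @param x Rescaled genes x samples matrix.
#' @param modules A `module_assignment` from [detect_modules()].
#' @param tol Relative singular-value tolerance defining the rank.
#' @return A list of class `module_pca_set`; one element per module with
#'   fields `module`, `genes`, `center`, `loadings`, `scores`,
#'   `variance_fraction`, `rank`.
#' @export
module_pca <- function(x, modules, tol = 1e-10) {
  validate_expression(x)
  stopifnot(inherits(modules, "module_assignment"))
  if (modules$n_modules < 1) stopf("no modules to summarise")
  if (!all(modules$gene_ids %in% rownames(x))) stopf("expression matrix is missing module genes")
  out <- lapply(seq_len(modules$n_modules), function(m) {
    genes <- modules$gene_ids[modules$labels == m]
    if (length(genes) < 2) stopf("module %d has fewer than 2 genes", m)
    A <- t(x[genes, , drop = FALSE])             # samples x genes
    ctr <- colMeans(A)
    Ac <- sweep(A, 2, ctr)
    sv <- svd(Ac)
    r <- sum(sv$d > tol * sv$d[1])
    r <- max(1L, r)
    loadings <- sv$v[, seq_len(r), drop = FALSE]
    scores <- Ac %*% loadings
    # sign convention
    profile <- rowMeans(A)
    for (i in seq_len(r)) {
      cc <- sum(scores[, i] * (profile - mean(profile)))
      flip <- if (abs(cc) > 1e-12) cc < 0 else loadings[which.max(abs(loadings[, i])), i] < 0
      if (flip) {
        loadings[, i] <- -loadings[, i]
        scores[, i] <- -scores[, i]
      }
    }
    rownames(loadings) <- genes
    rownames(scores) <- colnames(x)
    vf <- sv$d[seq_len(r)]^2 / sum(sv$d^2)
    structure(list(module = m, genes = genes, center = ctr, loadings = loadings,
                   scores = scores, variance_fraction = vf, rank = r),
              class = "module_pca")
  })
  structure(out, class = "module_pca_set")
}

#' Number of leading components explaining a target share of variance
#'
#' @param pca A `module_pca` object.
#' @param xi Target percentage of variance to explain (0 < xi <= 100;
#'   default 80).
#' @return The smallest component count whose cumulative variance fraction
#'   reaches `xi`/100.
#' @export
select_pcs_by_variance <- function(pca, xi = 80) {
  stopifnot(inherits(pca, "module_pca"))
  if (!is.numeric(xi) || xi <= 0 || xi > 100) stopf("`xi` must be in (0, 100]")
  cum <- cumsum(pca$variance_fraction)
  hit <- which(cum >= xi / 100 - 1e-12)
  if (length(hit)) min(hit) else pca$rank
}

#' Build a representative-feature set from module principal components
#'
#' Four nested constructions:
#' \describe{
#'   \item{R1}{the first principal component of every module (M features);}
#'   \item{R2}{R1 plus all pairwise products of those components, including
#'     quadratics (M(M+3)/2 features);}
#'   \item{R3}{per module, the leading components explaining `xi`% of that
#'     module's variance, concatenated (P features);}
#'   \item{R4}{R3 plus all pairwise products of those P components
#'     (P(P+3)/2 features).}
#' }
#' First-order features carry index (0, i); the product of first-order
#' features i and j carries index (i, j) with i <= j (i = j are quadratics).
#'
#' @param pcas A `module_pca_set` from [module_pca()].
#' @param kind One of `"R1"`, `"R2"`, `"R3"`, `"R4"`.
#' @param xi Percent of module variance the leading components must explain
#'   for R3/R4 (default 80).
#' @return An object of class `feature_set`: list with `kind`, `Z`
#'   (samples x p matrix), `index` (tibble i, j), `provenance` (tibble
#'   feature, module, pc for first-order features), `P` (first-order count),
#'   `xi`.
#' @export
build_features <- function(pcas, kind = c("R1", "R2", "R3", "R4"), xi = 80) {
  kind <- match.arg(kind)
  stopifnot(inherits(pcas, "module_pca_set"), length(pcas) >= 1)
  per_module <- if (kind %in% c("R1", "R2")) {
    rep(1L, length(pcas))
  } else {
    vapply(pcas, function(p) as.integer(select_pcs_by_variance(p, xi = xi)), integer(1))
  }
  prov <- tibble::tibble(
    feature = integer(0), module = integer(0), pc = integer(0))
  cols <- list()
  f <- 0L
  for (m in seq_along(pcas)) {
    for (pc in seq_len(per_module[m])) {
      f <- f + 1L
      cols[[f]] <- pcas[[m]]$scores[, pc]
      prov <- tibble::add_row(prov, feature = f, module = m, pc = pc)
    }
  }
  Z1 <- do.call(cbind, cols)
  colnames(Z1) <- paste0("z0.", seq_len(f))
  assemble_features(Z1, kind, prov, xi = if (kind %in% c("R3", "R4")) xi else NA_real_)
}

# Shared tail of build_features()/project_features(): add second-order
# columns for R2/R4 and wrap the result.
assemble_features <- function(Z1, kind, prov, xi) {
  P <- ncol(Z1)
  index <- tibble::tibble(i = 0L, j = seq_len(P))
  Z <- Z1
  if (kind %in% c("R2", "R4")) {
    prod_cols <- list()
    ii <- integer(0); jj <- integer(0)
    k <- 0L
    for (i in seq_len(P)) {
      for (j in i:P) {
        k <- k + 1L
        prod_cols[[k]] <- Z1[, i] * Z1[, j]
        ii[k] <- i; jj[k] <- j
      }
    }
    Z2 <- do.call(cbind, prod_cols)
    colnames(Z2) <- paste0("z", ii, ".", jj)
    Z <- cbind(Z1, Z2)
    index <- rbind(index, tibble::tibble(i = ii, j = jj))
  }
  structure(list(kind = kind, Z = Z, index = index, provenance = prov,
                 P = P, xi = xi),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("Feature set", x$kind, ":", nrow(x$Z), "samples x", ncol(x$Z), "features (",
      x$P, "first-order,", ncol(x$Z) - x$P, "second-order )\n")
  invisible(x)
}

#' Project new samples onto an existing feature set
#'
#' Computes representative features for new samples using the *training*
#' centring and loadings stored in `pcas`, then rebuilds second-order columns
#' as products, so the feature index matches `template` exactly.
#'
#' @param x_new Genes x samples matrix containing every module gene,
#'   preprocessed identically to the training data.
#' @param pcas The training `module_pca_set`.
#' @param template The training `feature_set` to replicate.
#' @return A `feature_set` for the new samples with the same index metadata.
#' @export
project_features <- function(x_new, pcas, template) {
  validate_expression(x_new)
  stopifnot(inherits(pcas, "module_pca_set"), inherits(template, "feature_set"))
  prov <- template$provenance
  cols <- vector("list", nrow(prov))
  for (r in seq_len(nrow(prov))) {
    pca <- pcas[[prov$module[r]]]
    miss <- setdiff(pca$genes, rownames(x_new))
    if (length(miss)) stopf("new data are missing module gene(s): %s", paste(head(miss, 5), collapse = ", "))
    A <- t(x_new[pca$genes, , drop = FALSE])
    Ac <- sweep(A, 2, pca$center)
    cols[[r]] <- drop(Ac %*% pca$loadings[, prov$pc[r]])
  }
  Z1 <- do.call(cbind, cols)
  rownames(Z1) <- colnames(x_new)
  colnames(Z1) <- paste0("z0.", seq_len(ncol(Z1)))
  assemble_features(Z1, template$kind, prov, template$xi)
}
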